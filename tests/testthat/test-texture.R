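test_that("quantization hits exact bin edges and is monotone and affine-invariant", {
  expect_identical(quantize_voi(c(0, 1, 2, 3), ng = 4)$levels, 1:4)
  expect_identical(quantize_voi(rep(2.5, 9), ng = 8)$levels, rep(1L, 9))
  expect_identical(quantize_voi(c(0, 0.1, 9.9, 10), ng = 2)$levels,
                   c(1L, 1L, 2L, 2L))
  expect_error(quantize_voi(1:5, ng = 1), "at least 2")
  set.seed(3)
  v <- rnorm(50)
  lev <- quantize_voi(v, ng = 16)$levels
  expect_true(all(diff(lev[order(v)]) >= 0))          # monotone in SUV
  expect_identical(quantize_voi(3 * v + 7, ng = 16)$levels, lev)
})

test_that("NGLCM matches the exhaustive pair enumerator and its contracts", {
  # constant 2x2x2 lesion: all mass in one cell
  g0 <- build_nglcm(as_quantized(array(1L, c(2, 2, 2)), ng = 4))
  expect_equal(g0$p[1, 1], 1)
  expect_equal(sum(g0$p), 1)
  # checkerboard: verified against the brute-force enumerator
  cb <- checkerboard_grid(c(4, 4, 4))
  expect_equal(build_nglcm(as_quantized(cb, 2))$p, brute_nglcm(cb, 2))
  # randomized masked lesions: symmetry, normalization, exact oracle equality
  set.seed(4)
  for (i in 1:25) {
    grid <- rand_quantized_grid(ng = 4)
    g <- build_nglcm(as_quantized(grid, 4L))
    expect_equal(g$p, t(g$p))
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_equal(g$p, brute_nglcm(grid, 4L))
  }
  # an isolated voxel has no pair
  iso <- array(NA_integer_, c(3, 3, 3)); iso[2, 2, 2] <- 1L
  expect_error(build_nglcm(as_quantized(iso, 2L)), "isolated")
})

test_that("entropy, homogeneity and contrast match closed forms and hand sums", {
  one <- matrix(0, 4, 4); one[2, 2] <- 1
  expect_equal(glcm_entropy(as_nglcm(one)), 0)
  expect_equal(glcm_homogeneity(as_nglcm(one)), 1)
  expect_equal(glcm_contrast(as_nglcm(one)), 0)
  unif <- matrix(1 / 64^2, 64, 64)
  expect_equal(glcm_entropy(as_nglcm(unif)), 12)      # 2 log2(64)
  # all mass at |i-j| = 1
  od <- matrix(0, 3, 3); od[1, 2] <- od[2, 1] <- 0.5
  expect_equal(glcm_homogeneity(as_nglcm(od)), 0.5)
  expect_equal(glcm_contrast(as_nglcm(od)), 1)
  # hand sums
  h <- matrix(0, 3, 3); h[1, 1] <- 0.5; h[1, 3] <- h[3, 1] <- 0.25
  expect_equal(glcm_homogeneity(as_nglcm(h)), 0.5 + 0.5 / 3)
  e <- matrix(0, 2, 2); e[1, 1] <- 0.5; e[1, 2] <- e[2, 1] <- 0.25
  expect_equal(glcm_entropy(as_nglcm(e)), 1.5)
  c4 <- matrix(0, 3, 3); c4[1, 3] <- c4[3, 1] <- 0.5
  expect_equal(glcm_contrast(as_nglcm(c4)), 4)
  # log base is configurable
  expect_equal(glcm_entropy(as_nglcm(e), log_base = exp(1)), 1.5 * log(2))
})

test_that("COV uses the population SD of raw SUVs and scales out", {
  expect_equal(histogram_cov(rep(4.2, 10)), 0)
  expect_equal(histogram_cov(c(2, 4)), 1 / 3)
  expect_equal(histogram_cov(c(2, 4), sd_mode = "sample"), sqrt(2) / 3)
  set.seed(5)
  v <- abs(rnorm(40)) + 1
  expect_equal(histogram_cov(7 * v), histogram_cov(v))
  expect_error(histogram_cov(c(-3, 1)), "mean")
})

test_that("size variation matches the exhaustive neighbor oracle", {
  expect_equal(size_variation(as_quantized(array(3L, c(3, 3, 3)), 4)), 0)
  cb <- checkerboard_grid(c(4, 4, 5))
  expect_equal(size_variation(as_quantized(cb, 2)), brute_size_variation(cb))
  set.seed(6)
  for (i in 1:15) {
    grid <- rand_quantized_grid(ng = 6)
    expect_equal(size_variation(as_quantized(grid, 6L)),
                 brute_size_variation(grid))
  }
  # same binary pattern quantized to wider level ranges: value grows with
  # the level spread
  vals <- array(as.numeric(checkerboard_grid(c(4, 4, 4)) == 2), c(4, 4, 4))
  sv <- sapply(c(2, 4, 8), function(ng)
    size_variation(quantize_voi(vals, array(TRUE, c(4, 4, 4)), ng = ng)))
  expect_equal(sv, sapply(c(2, 4, 8), function(ng) {
    g <- array(NA_integer_, c(4, 4, 4))
    g[] <- 1L + as.integer(vals) * (ng - 1L)
    brute_size_variation(g)
  }))
  expect_true(all(diff(sv) > 0))
})

test_that("feature extraction: degenerate lesion, determinism, invariances", {
  d <- c(5, 5, 5)
  mask <- array(FALSE, d); mask[2:4, 2:4, 2:4] <- TRUE
  voi <- voi_mask(mask)
  flat <- pet_volume(array(6, d), spacing_mm = c(5, 5, 5))
  f <- suppressWarnings(extract_features(flat, voi))
  expect_equal(f$cov, 0); expect_equal(f$entropy, 0)
  expect_equal(f$homogeneity, 1); expect_equal(f$contrast, 0)
  expect_equal(f$size_variation, 0); expect_equal(f$suv_mean, 6)
  expect_true(f$small_lesion)

  set.seed(7)
  vol <- pet_volume(array(abs(rnorm(prod(d))) + 1, d), spacing_mm = c(5, 5, 5))
  cfg <- texture_config(ng = 8, min_voxels = 10)
  f1 <- extract_features(vol, voi, cfg)
  f2 <- extract_features(vol, voi, cfg)
  expect_identical(f1, f2)
  # entropy/homogeneity/contrast bounds
  expect_gte(f1$entropy, 0); expect_lte(f1$entropy, 2 * log2(8))
  expect_gt(f1$homogeneity, 0); expect_lte(f1$homogeneity, 1)
  expect_lte(f1$contrast, (8 - 1)^2)
  # invariant to background values outside the mask
  vol2 <- vol; vol2$values[!mask] <- 99
  f3 <- extract_features(vol2, voi, cfg)
  expect_equal(f3[fnames], f1[fnames])
  # invariant under axis permutation and flips (isotropic grid)
  perm <- aperm(vol$values, c(3, 1, 2))[, , 5:1]
  pmask <- aperm(mask, c(3, 1, 2))[, , 5:1]
  f4 <- extract_features(pet_volume(perm, spacing_mm = c(5, 5, 5)),
                         voi_mask(pmask), cfg)
  expect_equal(f4[fnames], f1[fnames])
  # GLCM features invariant under affine SUV rescaling inside the VOI
  vol5 <- vol; vol5$values <- 2.5 * vol5$values + 3
  f5 <- extract_features(vol5, voi, cfg)
  for (nm in c("entropy", "homogeneity", "contrast", "size_variation"))
    expect_equal(f5[[nm]], f1[[nm]])
  # small-lesion floor warns but computes
  expect_warning(extract_features(vol, voi, texture_config(ng = 8)), "floor")
})

test_that("patient aggregation averages per site over lesions", {
  one <- data.frame(patient_id = "P1", site = "bone", lesion_id = 1,
                    n_voxels = 100, volume_cm3 = 12, suv_mean = 5, cov = 0.2,
                    entropy = 4, homogeneity = 0.5, contrast = 10,
                    size_variation = 1)
  agg1 <- aggregate_patient(one)
  expect_equal(agg1$entropy, 4)
  three <- do.call(rbind, replicate(3, one, simplify = FALSE))
  three$lesion_id <- 1:3
  expect_equal(aggregate_patient(three)$entropy, 4)
  three$entropy <- c(4, 5, 6)
  expect_equal(aggregate_patient(three)$entropy, 5)
  # sites aggregate separately; absent sites absent
  two_sites <- rbind(one, transform(one, site = "lymph_node", entropy = 8))
  agg <- aggregate_patient(two_sites)
  expect_identical(sort(agg$site), c("bone", "lymph_node"))
  expect_equal(agg$entropy[agg$site == "bone"], 4)
  expect_equal(agg$entropy[agg$site == "lymph_node"], 8)
})
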