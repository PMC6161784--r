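#' Texture configuration
#'
#' Settings shared by the feature extractors. `ng` gray levels with
#' equal-width min--max quantization inside the VOI is standard radiomics
#' practice; with `ng = 64` the co-occurrence entropy lives on a 0--12 bit
#' scale. `sd_mode` selects the population or sample standard deviation for
#' the coefficient of variation.
#'
#' @param ng number of gray levels (>= 2), default 64.
#' @param distance neighbor distance in voxels for co-occurrence pairs.
#' @param log_base logarithm base for entropy (2 = bits).
#' @param sd_mode `"population"` or `"sample"` standard deviation for COV.
#' @param min_voxels lesions smaller than this are flagged (not dropped);
#'   default 62 voxels, the size of a 7.8 cm^3 lesion on a 5 mm grid.
#' @param size_variation_connectivity neighborhood for the size-variation
#'   statistic; only 26-connectivity is supported.
#' @return A list of class `texture_config`.
#' @export
texture_config <- function(ng = 64L, distance = 1L, log_base = 2,
                           sd_mode = c("population", "sample"),
                           min_voxels = 62L,
                           size_variation_connectivity = 26L) {
  sd_mode <- match.arg(sd_mode)
  if (ng < 2) stop("'ng' must be at least 2")
  if (distance < 1) stop("'distance' must be at least 1")
  if (size_variation_connectivity != 26L)
    stop("only 26-neighborhood size variation is implemented")
  structure(list(ng = as.integer(ng), distance = as.integer(distance),
                 log_base = log_base, sd_mode = sd_mode,
                 min_voxels = as.integer(min_voxels),
                 size_variation_connectivity = 26L),
            class = "texture_config")
}

#' Quantize VOI intensities to gray levels
#'
#' Equal-width bins spanning the VOI's own min--max intensity range: level
#' `floor((v - min) / width) + 1` clamped to `1..ng`, so the mapping is
#' monotone in SUV and invariant to affine rescaling of the intensities.
#' A constant VOI maps every voxel to level 1.
#'
#' @param x a [pet_volume()], a 3D array, or a bare numeric vector of VOI
#'   intensities.
#' @param mask 3D logical array selecting the VOI (required unless `x` is a
#'   vector).
#' @param ng number of gray levels.
#' @return An object of class `quantized_voi` with `levels` (integer vector,
#'   raster order), `ng`, and — when a grid was supplied — `grid` (3D integer
#'   array, `NA` outside the mask).
#' @export
quantize_voi <- function(x, mask = NULL, ng = 64L) {
  ng <- as.integer(ng)
  if (ng < 2) stop("'ng' must be at least 2")
  if (inherits(x, "pet_volume")) x <- x$values
  grid <- NULL
  if (is.array(x) && length(dim(x)) == 3L) {
    if (is.null(mask)) stop("a mask is required with a 3D input")
    if (inherits(mask, "voi_mask")) mask <- mask$mask
    if (!identical(dim(mask), dim(x))) stop("mask and grid shapes differ")
    vals <- x[mask]
  } else {
    vals <- as.numeric(x)
    mask <- NULL
  }
  if (length(vals) < 1L) stop("VOI has no voxels")
  rng <- range(vals)
  if (rng[1] == rng[2]) {
    lev <- rep.int(1L, length(vals))
  } else {
    width <- (rng[2] - rng[1]) / ng
    lev <- pmin.int(ng, as.integer(floor((vals - rng[1]) / width)) + 1L)
  }
  if (!is.null(mask)) {
    grid <- array(NA_integer_, dim = dim(mask))
    grid[mask] <- lev
  }
  structure(list(levels = lev, ng = ng, grid = grid), class = "quantized_voi")
}

# The 13 unique 3D direction offsets at distance 1 (half of the 26-neighborhood;
# the other half is covered by symmetric accumulation).
glcm_offsets <- function(distance = 1L) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(off, 1L, function(o) {
    nz <- o[o != 0]
    length(nz) > 0 && (o[3] > 0 || (o[3] == 0 && (o[2] > 0 || (o[2] == 0 && o[1] > 0))))
  })
  off[keep, , drop = FALSE] * as.integer(distance)
}

# Pairs (i-level, j-level) across one offset, both voxels inside the mask.
offset_pairs <- function(grid, off) {
  d <- dim(grid)
  src <- lapply(1:3, function(k) {
    lo <- max(1L, 1L - off[k]); hi <- min(d[k], d[k] - off[k])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(src) == 0L)) return(NULL)
  dst <- lapply(1:3, function(k) src[[k]] + off[k])
  a <- grid[src[[1]], src[[2]], src[[3]], drop = FALSE]
  b <- grid[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cbind(a[ok], b[ok])
}

#' Build the normalized gray-level co-occurrence matrix
#'
#' Co-occurrences of gray levels are accumulated over the 13 unique 3D
#' direction offsets at the configured distance, in both orderings
#' (symmetric), counting only pairs whose two voxels both lie inside the
#' mask, then normalized by the total pair count. Pooling all directions
#' into one matrix makes the derived features invariant under axis
#' permutations and flips of the lesion grid.
#'
#' @param qv a [quantize_voi()] result carrying a grid.
#' @param distance neighbor distance in voxels.
#' @return An object of class `nglcm`: `p` (ng x ng probability matrix),
#'   `offsets_used`, `pair_count`.
#' @export
build_nglcm <- function(qv, distance = 1L) {
  stopifnot(inherits(qv, "quantized_voi"))
  if (is.null(qv$grid)) stop("grid form required; quantize with a 3D input")
  offs <- glcm_offsets(distance)
  ng <- qv$ng
  counts <- matrix(0, ng, ng)
  npairs <- 0L
  for (r in seq_len(nrow(offs))) {
    pr <- offset_pairs(qv$grid, offs[r, ])
    if (is.null(pr)) next
    tab <- tabulate(pr[, 1] + (pr[, 2] - 1L) * ng, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng)
    npairs <- npairs + nrow(pr)
  }
  if (npairs == 0L)
    stop("no in-mask voxel pair at distance ", distance,
         "; co-occurrence undefined (isolated voxels)")
  counts <- counts + t(counts)            # symmetric accumulation
  structure(list(p = counts / (2 * npairs), offsets_used = offs,
                 pair_count = 2L * npairs),
            class = "nglcm")
}

#' Co-occurrence entropy, homogeneity and contrast
#'
#' `glcm_entropy` is `-sum p log(p)` (0 log 0 = 0) in the configured base
#' (bits by default): low for a near-deterministic co-occurrence structure,
#' up to `2 log2(ng)` for a uniform matrix. `glcm_homogeneity` is
#' `sum p/(1+|i-j|)`: 1 when all mass sits on the diagonal (neighbors share
#' a level). `glcm_contrast` is `sum (i-j)^2 p`: large when neighboring
#' voxels differ by many levels.
#'
#' @param g an [build_nglcm()] result.
#' @param log_base logarithm base for the entropy.
#' @return A single numeric value.
#' @export
glcm_entropy <- function(g, log_base = 2) {
  p <- g$p[g$p > 0]
  -sum(p * log(p, base = log_base))
}

#' @rdname glcm_entropy
#' @export
glcm_homogeneity <- function(g) {
  ij <- abs(row(g$p) - col(g$p))
  sum(g$p / (1 + ij))
}

#' @rdname glcm_entropy
#' @export
glcm_contrast <- function(g) {
  ij <- row(g$p) - col(g$p)
  sum(ij * ij * g$p)
}

#' Coefficient of variation of the VOI intensity histogram
#'
#' Standard deviation divided by the mean of the raw (unquantized) VOI
#' SUVs; population SD by default. Invariant under positive rescaling of
#' the intensities (but not under shifts).
#'
#' @param sample a `voi_sample` from [extract_voi()] or a numeric vector.
#' @param sd_mode `"population"` or `"sample"`.
#' @return COV, dimensionless and >= 0.
#' @export
histogram_cov <- function(sample, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  v <- if (inherits(sample, "voi_sample")) sample$suv_values else as.numeric(sample)
  m <- mean(v)
  if (!is.finite(m) || m <= 0) stop("COV undefined: VOI mean must be > 0")
  n <- length(v)
  if (n == 1L) return(0)
  s2 <- stats::var(v)
  if (sd_mode == "population") s2 <- s2 * (n - 1) / n
  sqrt(s2) / m
}

#' Neighborhood size-variation statistic
#'
#' A neighborhood gray-tone-difference statistic: for every in-mask voxel
#' having at least one in-mask 26-neighbor, the absolute difference between
#' its gray level and the mean gray level of those neighbors, averaged over
#' all such voxels. Zero for a constant lesion; large when intensity
#' alternates from voxel to voxel.
#'
#' @param qv a [quantize_voi()] result carrying a grid.
#' @return Size variation, dimensionless and >= 0.
#' @export
size_variation <- function(qv) {
  stopifnot(inherits(qv, "quantized_voi"))
  if (is.null(qv$grid)) stop("grid form required; quantize with a 3D input")
  g <- qv$grid
  d <- dim(g)
  nb_sum <- array(0, d)
  nb_n <- array(0L, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]     # the 26 neighbors
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    src <- lapply(1:3, function(k) {
      lo <- max(1L, 1L - off[k]); hi <- min(d[k], d[k] - off[k])
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(lengths(src) == 0L)) next
    dst <- lapply(1:3, function(k) src[[k]] + off[k])
    nb <- g[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    ok <- !is.na(nb)
    nb[!ok] <- 0L
    nb_sum[src[[1]], src[[2]], src[[3]]] <-
      nb_sum[src[[1]], src[[2]], src[[3]]] + nb
    nb_n[src[[1]], src[[2]], src[[3]]] <-
      nb_n[src[[1]], src[[2]], src[[3]]] + ok
  }
  use <- !is.na(g) & nb_n > 0L
  if (!any(use)) stop("no in-mask voxel has an in-mask 26-neighbor")
  mean(abs(g[use] - nb_sum[use] / nb_n[use]))
}

#' Extract the full lesion feature vector
#'
#' Computes SUVmean, COV, co-occurrence entropy, homogeneity and contrast,
#' the size-variation statistic, and lesion volume for one VOI. All features
#' of a constant lesion are defined (COV 0, entropy 0, homogeneity 1,
#' contrast 0, size variation 0) rather than erroring. Lesions below the
#' configured voxel floor are flagged via `small_lesion` and a warning, not
#' dropped: texture estimates from very few voxels are unstable but still
#' computable.
#'
#' @param vol a [pet_volume()].
#' @param voi a [voi_mask()] on the same grid.
#' @param config a [texture_config()].
#' @return A list of class `lesion_features` with fields `patient_id`,
#'   `site`, `lesion_id`, `n_voxels`, `volume_cm3`, `suv_mean`, `cov`,
#'   `entropy`, `homogeneity`, `contrast`, `size_variation`, `small_lesion`.
#' @export
extract_features <- function(vol, voi, config = texture_config()) {
  stopifnot(inherits(config, "texture_config"))
  samp <- extract_voi(vol, voi)
  n <- length(samp$suv_values)
  if (n < config$min_voxels)
    warning("lesion ", voi$patient_id, "/", voi$site, "/", voi$lesion_id,
            " has ", n, " voxels, below the ", config$min_voxels,
            "-voxel floor; texture estimates may be unstable")
  qv <- quantize_voi(vol, voi$mask, ng = config$ng)
  g <- build_nglcm(qv, distance = config$distance)
  structure(list(
    patient_id = voi$patient_id, site = voi$site, lesion_id = voi$lesion_id,
    n_voxels = n, volume_cm3 = samp$volume_cm3,
    suv_mean = mean(samp$suv_values),
    cov = histogram_cov(samp, sd_mode = config$sd_mode),
    entropy = glcm_entropy(g, log_base = config$log_base),
    homogeneity = glcm_homogeneity(g),
    contrast = glcm_contrast(g),
    size_variation = size_variation(qv),
    small_lesion = n < config$min_voxels
  ), class = "lesion_features")
}

feature_names <- c("suv_mean", "cov", "entropy", "homogeneity",
                   "contrast", "size_variation")

#' Lesion feature table
#'
#' Binds `lesion_features` objects into the canonical per-lesion table
#' (`patient_id, site, lesion_id, volume_cm3, suv_mean, cov, entropy,
#' homogeneity, contrast, size_variation`).
#'
#' @param feats list of `lesion_features`.
#' @return data.frame, one row per lesion.
#' @export
features_table <- function(feats) {
  if (inherits(feats, "lesion_features")) feats <- list(feats)
  do.call(rbind, lapply(feats, function(f)
    data.frame(patient_id = f$patient_id, site = f$site,
               lesion_id = f$lesion_id, n_voxels = f$n_voxels,
               volume_cm3 = f$volume_cm3, suv_mean = f$suv_mean,
               cov = f$cov, entropy = f$entropy, homogeneity = f$homogeneity,
               contrast = f$contrast, size_variation = f$size_variation,
               stringsAsFactors = FALSE)))
}

#' Aggregate lesion features to patient level
#'
#' Per patient and metastatic site, the unweighted arithmetic mean of every
#' feature over that site's lesions (up to three per site in the standard
#' delineation protocol). Sites without lesions for a patient are absent
#' from the output.
#'
#' @param lesion_table a [features_table()] data.frame.
#' @return data.frame with one row per (patient, site): mean features plus
#'   `n_lesions` and mean `volume_cm3`.
#' @export
aggregate_patient <- function(lesion_table) {
  stopifnot(all(c("patient_id", "site", feature_names) %in% names(lesion_table)))
  key <- interaction(lesion_table$patient_id, lesion_table$site, drop = TRUE)
  rows <- lapply(split(lesion_table, key), function(d) {
    out <- data.frame(patient_id = d$patient_id[1], site = d$site[1],
                      n_lesions = nrow(d),
                      volume_cm3 = mean(d$volume_cm3),
                      stringsAsFactors = FALSE)
    for (f in feature_names) out[[f]] <- mean(d[[f]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$patient_id, out$site), ]
}
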