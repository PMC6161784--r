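#' Specification of a synthetic phantom cohort
#'
#' Defines the study conditions the generator emulates: a cohort of
#' metastatic prostate-cancer patients imaged on a ~5 mm PET grid, every
#' patient carrying bone lesions (three delineated per site), lymph-node
#' involvement in roughly 47% and other (liver/prostate) lesions in roughly
#' 21% of patients; lesion volumes spanning 7.8--82.3 cm^3; and a signed
#' rank-scale link of strength `heterogeneity_link_rho` between a latent
#' per-patient heterogeneity score and the post-minus-pre PSA change, with
#' 60% of patients responding (negative change). Alkaline phosphatase and
#' its bone isoform get their own, weaker links.
#'
#' @param n_patients cohort size (>= 1), default 70.
#' @param voxel_spacing_mm voxel spacing, default `c(5.3, 5.3, 5.0)`.
#' @param n_bone bone lesions per patient (every patient has bone disease).
#' @param p_lymph_node probability a patient has lymph-node lesions
#'   (3 delineated when present).
#' @param p_other probability of other-site lesions (1--3 when present).
#' @param lesion_volume_range_cm3 lesion volume interval, default 7.8--82.3.
#' @param heterogeneity_link_rho signed Spearman-scale association between
#'   latent heterogeneity and delta-PSA; default -0.33 (more heterogeneous
#'   tumors respond better, i.e. larger PSA declines).
#' @param ap_link_rho,bap_link_rho analogous (weaker) links for alkaline
#'   phosphatase and bone alkaline phosphatase.
#' @param responder_fraction_target P(delta-PSA < 0), default 0.60.
#' @param ap_responder_fraction,bap_responder_fraction analogous fractions
#'   for AP (41/70) and bone AP (39/70).
#' @param background_suv background tracer uptake, SUV.
#' @param lesion_suv_mean_range interval the per-lesion mean SUV is drawn
#'   from.
#' @param noise_sd additive Gaussian image noise, SUV.
#' @param h_min heterogeneity floor: at `h <= h_min` the textured component
#'   has zero amplitude, so with `noise_sd = 0` the lesion is constant.
#' @param min_voxels smallest lesion the image generator accepts, in voxels.
#' @param seed integer master seed; all randomness flows from it.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 70L,
                         voxel_spacing_mm = c(5.3, 5.3, 5.0),
                         n_bone = 3L, p_lymph_node = 0.471, p_other = 0.214,
                         lesion_volume_range_cm3 = c(7.8, 82.3),
                         heterogeneity_link_rho = -0.33,
                         ap_link_rho = -0.10, bap_link_rho = -0.10,
                         responder_fraction_target = 0.60,
                         ap_responder_fraction = 41 / 70,
                         bap_responder_fraction = 39 / 70,
                         background_suv = 1.0,
                         lesion_suv_mean_range = c(5, 15),
                         noise_sd = 0.2, h_min = -3, min_voxels = 8L,
                         seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               voxel_spacing_mm = as.numeric(voxel_spacing_mm),
               n_bone = as.integer(n_bone),
               p_lymph_node = p_lymph_node, p_other = p_other,
               lesion_volume_range_cm3 = as.numeric(lesion_volume_range_cm3),
               heterogeneity_link_rho = heterogeneity_link_rho,
               ap_link_rho = ap_link_rho, bap_link_rho = bap_link_rho,
               responder_fraction_target = responder_fraction_target,
               ap_responder_fraction = ap_responder_fraction,
               bap_responder_fraction = bap_responder_fraction,
               background_suv = background_suv,
               lesion_suv_mean_range = as.numeric(lesion_suv_mean_range),
               noise_sd = noise_sd, h_min = h_min,
               min_voxels = as.integer(min_voxels),
               seed = as.integer(seed))
  if (spec$n_patients < 1L) stop("'n_patients' must be >= 1")
  if (length(spec$voxel_spacing_mm) != 3L || any(spec$voxel_spacing_mm <= 0))
    stop("voxel spacing must be 3 strictly positive numbers")
  if (spec$n_bone < 1L) stop("every patient must have at least one bone lesion")
  if (diff(spec$lesion_volume_range_cm3) <= 0 ||
      diff(spec$lesion_suv_mean_range) <= 0)
    stop("ranges must satisfy low < high")
  for (r in c(spec$heterogeneity_link_rho, spec$ap_link_rho, spec$bap_link_rho))
    if (abs(r) >= 0.999)
      stop("|link rho| must be < 1: a perfect rank link is infeasible with ",
           "an independent-noise copula")
  for (q in c(spec$responder_fraction_target, spec$ap_responder_fraction,
              spec$bap_responder_fraction))
    if (q <= 0 || q >= 1) stop("responder fractions must lie in (0, 1)")
  if (spec$noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(spec, class = "phantom_spec")
}

#' Read a phantom specification from YAML
#'
#' The YAML keys mirror the [phantom_spec()] arguments; absent keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `phantom_spec`.
#' @export
phantom_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(formals(phantom_spec)))
  if (length(bad)) stop("unknown phantom config keys: ", paste(bad, collapse = ", "))
  do.call(phantom_spec, cfg)
}

# Evaluate an expression under a seed derived from (master seed, stream id),
# restoring the caller's RNG state afterwards. Stream ids keep replicates and
# per-lesion draws independent yet fully determined by the master seed.
with_stream_seed <- function(seed, stream, expr) {
  derived <- (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(derived))
  expr
}

# Separable 3D Gaussian smoothing by shift-and-add convolution with a
# truncated (3 sigma) kernel, reflecting at the borders via renormalization.
gauss_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(a)
  for (ax in 1:3) {
    out <- array(0, d)
    wt <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      lo <- max(1L, 1L - off); hi <- min(d[ax], d[ax] - off)
      if (lo > hi) next
      src <- lo:hi; dst <- src + off
      idx_src <- idx_dst <- list(quote(expr =), quote(expr =), quote(expr =))
      idx_src[[ax]] <- src; idx_dst[[ax]] <- dst
      out_slice <- do.call(`[`, c(list(a), idx_dst, list(drop = FALSE)))
      tmp <- do.call(`[`, c(list(out), idx_src, list(drop = FALSE)))
      assign_call <- function(arr, idx, val) {
        do.call(`[<-`, c(list(arr), idx, list(val)))
      }
      out <- assign_call(out, idx_src, tmp + k[j] * out_slice)
      wtt <- do.call(`[`, c(list(wt), idx_src, list(drop = FALSE)))
      wt <- assign_call(wt, idx_src, wtt + k[j])
    }
    a <- out / wt
  }
  a
}

# Monotone map from the latent heterogeneity score to the Gaussian-field
# correlation length (in voxels): strictly decreasing, so higher h gives
# finer texture, higher co-occurrence entropy and lower homogeneity.
h_to_sigma <- function(h) 0.3 + 2.2 * stats::plogis(-h)

#' Generate one synthetic lesion image
#'
#' Builds an ellipsoidal VOI of the requested physical volume (the
#' `n = round(volume / voxel_volume)` voxels closest in ellipsoidal distance
#' to the lesion center, so the mask volume is within half a voxel of the
#' request) embedded in a background-filled grid. Voxels inside the mask
#' carry a Gaussian random field: white noise smoothed with an isotropic
#' Gaussian kernel whose correlation length decreases monotonically with the
#' heterogeneity score `h`, rank-transformed to a uniform marginal (so
#' texture statistics respond to the spatial correlation alone) and
#' rescaled to span 0.5--1.5 times a mean SUV drawn from the configured
#' range, plus additive Gaussian noise. At `h <= h_min` the field
#' amplitude is zero, so a noise-free lesion is constant.
#'
#' @param volume_cm3 requested lesion volume.
#' @param heterogeneity_h latent heterogeneity score (standard-normal scale).
#' @param spec a [phantom_spec()].
#' @param stream integer stream id combined with `spec$seed` (vary it per
#'   lesion); the same (seed, stream) pair reproduces the lesion bit-exactly.
#' @param patient_id,site,lesion_id metadata attached to the mask.
#' @return A list with `volume` ([pet_volume()]) and `mask` ([voi_mask()]).
#' @export
generate_lesion_image <- function(volume_cm3, heterogeneity_h,
                                  spec = phantom_spec(), stream = 0L,
                                  patient_id = "P1", site = "bone",
                                  lesion_id = 1L) {
  vv <- voxel_volume_cm3(spec$voxel_spacing_mm)
  n_target <- as.integer(round(volume_cm3 / vv))
  if (n_target < spec$min_voxels)
    stop("requested volume ", volume_cm3, " cm^3 holds ", n_target,
         " voxels, below the ", spec$min_voxels, "-voxel floor")
  with_stream_seed(spec$seed, stream, {
    ax_ratio <- stats::runif(3, 0.7, 1.3)        # mild anisotropy
    # physical semi-axes (mm) of an ellipsoid of the requested volume
    r_iso <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
    semi <- r_iso * ax_ratio / prod(ax_ratio)^(1 / 3)
    half <- ceiling(semi / spec$voxel_spacing_mm) + 2L
    d <- 2L * half + 1L
    ctr <- half + 1L
    cx <- (seq_len(d[1]) - ctr[1]) * spec$voxel_spacing_mm[1] / semi[1]
    cy <- (seq_len(d[2]) - ctr[2]) * spec$voxel_spacing_mm[2] / semi[2]
    cz <- (seq_len(d[3]) - ctr[3]) * spec$voxel_spacing_mm[3] / semi[3]
    dist <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
    ord <- order(dist)                           # stable: ties by raster order
    mask <- array(FALSE, d)
    mask[ord[seq_len(n_target)]] <- TRUE
    vals <- array(spec$background_suv, d)
    suv_mean <- stats::runif(1, spec$lesion_suv_mean_range[1],
                             spec$lesion_suv_mean_range[2])
    field <- array(stats::rnorm(prod(d)), d)
    if (heterogeneity_h > spec$h_min) {
      field <- gauss_smooth3d(field, h_to_sigma(heterogeneity_h))
      fv <- field[mask]
      # rank (copula) transform: the marginal becomes uniform whatever the
      # smoothing, so texture statistics respond to the spatial correlation
      # alone; then span 0.5x--1.5x the lesion mean SUV
      n_in <- length(fv)
      fv <- if (n_in > 1)
        suv_mean * (0.5 + (rank(fv, ties.method = "average") - 1) / (n_in - 1))
      else rep(suv_mean, n_in)
      vals[mask] <- fv
    } else {
      vals[mask] <- suv_mean
    }
    if (spec$noise_sd > 0)
      vals <- vals + stats::rnorm(prod(d), sd = spec$noise_sd)
    list(volume = pet_volume(vals, spacing_mm = spec$voxel_spacing_mm),
         mask = voi_mask(mask, patient_id = patient_id, site = site,
                         lesion_id = lesion_id))
  })
}

# Bivariate-normal (Pearson) correlation that induces a given Spearman rho
# under a Gaussian copula.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Strictly monotone quantile map from a copula uniform to a signed marker
# delta: P(delta < 0) = q exactly, magnitudes lognormal on both sides.
delta_from_u <- function(u, q, meanlog, sdlog) {
  d <- numeric(length(u))
  neg <- u < q
  d[neg] <- -stats::qlnorm((q - u[neg]) / q, meanlog, sdlog)
  d[!neg] <- stats::qlnorm((u[!neg] - q) / (1 - q), meanlog, sdlog)
  d
}

# One marker's deltas from the latent h via a Gaussian copula at the given
# Spearman-scale link.
marker_deltas <- function(h, rho_s, q, meanlog, sdlog) {
  rho_p <- spearman_to_pearson(rho_s)
  z <- rho_p * h + sqrt(1 - rho_p^2) * stats::rnorm(length(h))
  delta_from_u(stats::pnorm(z), q, meanlog, sdlog)
}

#' Fast-path synthetic cohort: latents and clinical deltas only
#'
#' Draws the latent heterogeneity score and the linked marker deltas from
#' the Gaussian copula without synthesizing any image, for statistical
#' studies needing thousands of replicates. Because each delta is a strictly
#' monotone transform of its copula coordinate, the population Spearman
#' correlation between `h` and delta-PSA equals `heterogeneity_link_rho`
#' and the responder fraction equals `responder_fraction_target` exactly.
#'
#' @param spec a [phantom_spec()].
#' @param replicate integer replicate index perturbing the seed
#'   deterministically.
#' @return data.frame with `patient_id`, `h`, `delta_psa`, `delta_ap`,
#'   `delta_bap`.
#' @export
generate_cohort_fast <- function(spec = phantom_spec(), replicate = 0L) {
  with_stream_seed(spec$seed, 1e6 + replicate, {
    n <- spec$n_patients
    h <- stats::rnorm(n)
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      h = h,
      delta_psa = marker_deltas(h, spec$heterogeneity_link_rho,
                                spec$responder_fraction_target,
                                meanlog = log(20), sdlog = 1),
      delta_ap = marker_deltas(h, spec$ap_link_rho,
                               spec$ap_responder_fraction,
                               meanlog = log(50), sdlog = 0.8),
      delta_bap = marker_deltas(h, spec$bap_link_rho,
                                spec$bap_responder_fraction,
                                meanlog = log(20), sdlog = 0.8),
      stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws per-patient latent heterogeneity and linked clinical deltas
#' (fast-path copula), then synthesizes every lesion image and mask. Lesion
#' volumes are drawn independently of `h`, reflecting the observed
#' independence of texture from lesion size. Pre-therapy marker levels are
#' drawn lognormally with a floor guaranteeing `post = pre + delta > 0`;
#' ECOG status is constant pre/post.
#'
#' @param spec a [phantom_spec()].
#' @param replicate replicate index (deterministic seed perturbation).
#' @param images if `FALSE`, skip image synthesis (clinical table and ground
#'   truth only).
#' @return A list of class `phantom_cohort`: `clinical` (the per-patient
#'   pre/post table), `truth` (`patient_id, h, delta_psa`), `lesions` (list
#'   of `volume`/`mask` pairs, one per VOI, or `NULL`), `lesion_info`
#'   (per-VOI metadata incl. site and requested volume) and `spec`.
#' @export
generate_cohort <- function(spec = phantom_spec(), replicate = 0L,
                            images = TRUE) {
  fast <- generate_cohort_fast(spec, replicate = replicate)
  with_stream_seed(spec$seed, 2e6 + replicate, {
    n <- spec$n_patients
    pre_psa <- pmax(stats::rlnorm(n, log(100), 1), abs(fast$delta_psa) / 0.8)
    pre_ap <- pmax(stats::rlnorm(n, log(150), 0.5), abs(fast$delta_ap) / 0.8)
    pre_bap <- pmax(stats::rlnorm(n, log(60), 0.5), abs(fast$delta_bap) / 0.8)
    ecog <- sample(0:3, n, replace = TRUE, prob = c(0.2, 0.4, 0.3, 0.1))
    clinical <- data.frame(
      patient_id = fast$patient_id,
      pre_psa = pre_psa, post_psa = pre_psa + fast$delta_psa,
      pre_ap = pre_ap, post_ap = pre_ap + fast$delta_ap,
      pre_bap = pre_bap, post_bap = pre_bap + fast$delta_bap,
      ecog_pre = ecog, ecog_post = ecog,   # no ECOG change under therapy
      stringsAsFactors = FALSE)
    has_ln <- stats::runif(n) < spec$p_lymph_node
    has_other <- stats::runif(n) < spec$p_other
    n_other <- ifelse(has_other, sample(1:3, n, replace = TRUE), 0L)
    info <- do.call(rbind, lapply(seq_len(n), function(i) {
      sites <- c(rep("bone", spec$n_bone),
                 rep("lymph_node", if (has_ln[i]) 3L else 0L),
                 rep("other", n_other[i]))
      data.frame(patient_id = fast$patient_id[i], site = sites,
                 lesion_id = stats::ave(seq_along(sites), sites,
                                        FUN = seq_along),
                 stringsAsFactors = FALSE)
    }))
    info$volume_cm3 <- stats::runif(nrow(info),
                                    spec$lesion_volume_range_cm3[1],
                                    spec$lesion_volume_range_cm3[2])
    info$h <- fast$h[match(info$patient_id, fast$patient_id)]
    info$stream <- seq_len(nrow(info))
    lesions <- NULL
    if (images)
      lesions <- lapply(seq_len(nrow(info)), function(r)
        generate_lesion_image(info$volume_cm3[r], info$h[r], spec,
                              stream = info$stream[r],
                              patient_id = info$patient_id[r],
                              site = info$site[r],
                              lesion_id = info$lesion_id[r]))
    structure(list(clinical = clinical,
                   truth = fast[, c("patient_id", "h", "delta_psa")],
                   lesions = lesions, lesion_info = info, spec = spec),
              class = "phantom_cohort")
  })
}

#' Write a phantom cohort to disk
#'
#' Clinical table and ground truth as CSV; every lesion volume and mask as
#' NIfTI-1 (`<patient>_<site>_<lesion>_{pet,mask}.nii.gz`). A JSON sidecar
#' records the generator settings and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$lesion_info[, c("patient_id", "site", "lesion_id",
                                          "volume_cm3")],
                   file.path(dir, "lesions.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(cohort$spec),
                       file.path(dir, "phantom_spec.json"), auto_unbox = TRUE)
  if (!is.null(cohort$lesions)) {
    for (i in seq_along(cohort$lesions)) {
      les <- cohort$lesions[[i]]
      stem <- with(cohort$lesion_info[i, ],
                   sprintf("%s_%s_%d", patient_id, site, lesion_id))
      write_volume(les$volume, file.path(dir, paste0(stem, "_pet.nii.gz")))
      write_volume(pet_volume(array(as.numeric(les$mask$mask),
                                    dim(les$mask$mask)),
                              les$volume$spacing_mm),
                   file.path(dir, paste0(stem, "_mask.nii.gz")))
    }
  }
  invisible(dir)
}
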