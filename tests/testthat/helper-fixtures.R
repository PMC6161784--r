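# Fixtures built in code.

# Random small quantized lesion grid: levels 1..ng inside a random mask,
# NA outside; guaranteed to contain at least one neighboring in-mask pair.
rand_quantized_grid <- function(ng = 4L, max_side = 6L) {
  repeat {
    d <- sample(3:max_side, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < 0.55, d)
    if (sum(mask) < 2) next
    grid <- array(NA_integer_, d)
    grid[mask] <- sample.int(ng, sum(mask), replace = TRUE)
    ok <- tryCatch({ brute_nglcm(grid, ng); TRUE }, error = function(e) FALSE)
    if (ok) return(grid)
  }
}

# 3D parity checkerboard of levels {1, 2}.
checkerboard_grid <- function(d = c(4L, 4L, 4L)) {
  g <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    g[i, j, k] <- 1L + (i + j + k) %% 2L
  g
}

# Wrap a probability matrix as an nglcm object for closed-form checks.
as_nglcm <- function(p) {
  structure(list(p = p, offsets_used = NULL, pair_count = 1L),
            class = "nglcm")
}

# A quantized_voi around a full-grid lesion of the given level array.
as_quantized <- function(grid, ng) {
  structure(list(levels = grid[!is.na(grid)], ng = as.integer(ng),
                 grid = grid),
            class = "quantized_voi")
}

# A 70-patient clinical table with the joint responder structure of a
# typical radioligand-therapy cohort: 42 PSA responders, 41 AP responders,
# 39 bAP responders, 24 joint PSA+AP, 22 triple responders.
crafted_clinical <- function() {
  # category counts: (psa, ap, bap) response pattern
  pats <- rbind(
    c(22, 1, 1, 1), c(2, 1, 1, 0), c(5, 1, 0, 1), c(13, 1, 0, 0),
    c(7, 0, 1, 1), c(10, 0, 1, 0), c(5, 0, 0, 1), c(6, 0, 0, 0))
  rows <- do.call(rbind, lapply(seq_len(nrow(pats)), function(r)
    matrix(rep(pats[r, 2:4], pats[r, 1]), ncol = 3, byrow = TRUE)))
  n <- nrow(rows)
  delta <- function(resp) ifelse(resp == 1, -5, 5)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    pre_psa = 100, post_psa = 100 + delta(rows[, 1]),
    pre_ap = 150, post_ap = 150 + delta(rows[, 2]),
    pre_bap = 60, post_bap = 60 + delta(rows[, 3]),
    ecog_pre = 1L, ecog_post = 1L, stringsAsFactors = FALSE)
}

fnames <- c("suv_mean", "cov", "entropy", "homogeneity", "contrast",
            "size_variation")
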