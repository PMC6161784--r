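# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops over voxels, pairs and thresholds.

# Exhaustive pair enumerator for the symmetric co-occurrence matrix: every
# ordered pair of in-mask voxels at Chebyshev distance `d` along one of the
# 26 neighbor directions.
brute_nglcm <- function(grid, ng, d = 1L) {
  dims <- dim(grid)
  counts <- matrix(0, ng, ng)
  offs <- expand.grid(dx = c(-d, 0, d), dy = c(-d, 0, d), dz = c(-d, 0, d))
  offs <- offs[rowSums(offs != 0) > 0, ]
  idx <- which(!is.na(grid), arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    p <- idx[v, ]
    for (o in seq_len(nrow(offs))) {
      q <- p + as.integer(offs[o, ])
      if (any(q < 1) || any(q > dims)) next
      lj <- grid[q[1], q[2], q[3]]
      if (is.na(lj)) next
      li <- grid[p[1], p[2], p[3]]
      counts[li, lj] <- counts[li, lj] + 1
    }
  }
  total <- sum(counts)
  if (total == 0) stop("no pair")
  counts / total
}

# Exhaustive neighborhood mean enumerator for the size-variation statistic.
brute_size_variation <- function(grid) {
  dims <- dim(grid)
  idx <- which(!is.na(grid), arr.ind = TRUE)
  diffs <- c()
  for (v in seq_len(nrow(idx))) {
    p <- idx[v, ]
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1) || any(q > dims)) next
      l <- grid[q[1], q[2], q[3]]
      if (!is.na(l)) nb <- c(nb, l)
    }
    if (length(nb) > 0)
      diffs <- c(diffs, abs(grid[p[1], p[2], p[3]] - mean(nb)))
  }
  mean(diffs)
}

# All positive-negative score pairs, ties counted one half.
brute_auc <- function(scores, labels, positive_class) {
  sp <- scores[labels == positive_class]
  sn <- scores[labels != positive_class]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Best Youden J over every threshold for a fixed direction.
brute_best_J <- function(scores, labels, positive_class, direction) {
  pos <- labels == positive_class
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- -Inf
  for (cut in cand) {
    tp_flag <- if (direction == "greater") scores > cut else scores <= cut
    J <- sum(tp_flag & pos) / sum(pos) + sum(!tp_flag & !pos) / sum(!pos) - 1
    if (J > best) best <- J
  }
  best
}

# Theoretical AUC of the latent heterogeneity score h for separating the
# classes defined by thresholding its copula partner z at the q-quantile
# (positive class: z >= qnorm(q), the non-responders), under a bivariate
# normal with Spearman-scale correlation rho_s. Computed by nested
# numerical integration, independent of any simulation.
binormal_auc <- function(rho_s, q) {
  rho <- 2 * sin(pi * rho_s / 6)
  cpt <- qnorm(q)
  s <- sqrt(2 * (1 - rho^2))
  inner <- function(z1) {
    vapply(z1, function(a)
      integrate(function(z2) pnorm(rho * (a - z2) / s) * dnorm(z2),
                -Inf, cpt, rel.tol = 1e-9)$value, numeric(1))
  }
  num <- integrate(function(z1) inner(z1) * dnorm(z1), cpt, Inf,
                   rel.tol = 1e-8)$value
  num / ((1 - q) * q)
}
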