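#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks (ties get midranks), with the
#' two-sided p-value from `t = rs * sqrt((n-2) / (1-rs^2))` on `n - 2`
#' degrees of freedom — the approximation used by mainstream clinical-stats
#' software. An exact permutation p-value is available for tiny samples.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @param feature_name,clinical_name labels carried into the result.
#' @param exact if `TRUE` (and `n <= 10`), enumerate all permutations
#'   instead of the t-approximation.
#' @return data.frame row: `feature`, `clinical`, `rs`, `p_value`, `n`.
#' @export
spearman_screen <- function(x, y, feature_name = "x", clinical_name = "y",
                            exact = FALSE) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant input vector")
  rs <- stats::cor(rank(x), rank(y))
  if (exact && n <= 10) {
    perms <- all_permutations(n)
    rx <- rank(x); ry <- rank(y)
    obs <- abs(rs)
    vals <- apply(perms, 1L, function(p) abs(stats::cor(rx, ry[p])))
    p_value <- mean(vals >= obs - 1e-12)
  } else {
    tt <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p_value <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  data.frame(feature = feature_name, clinical = clinical_name,
             rs = rs, p_value = p_value, n = n, stringsAsFactors = FALSE)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Nonparametric AUC with Hanley-McNeil standard error
#'
#' The area under the ROC curve as the Mann-Whitney probability that a
#' random positive scores above a random negative (ties count 1/2),
#' computed from midranks; its standard error by the Hanley-McNeil
#' exponential-approximation formula, and a normal-approximation confidence
#' interval clipped to [0, 1].
#'
#' @param scores numeric predictor values.
#' @param labels class labels, same length.
#' @param positive_class the label treated as positive.
#' @param conf_level confidence level for the CI.
#' @return list of class `roc_auc`: `auc`, `se`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `conf_level`, `ci_clipped`.
#' @export
roc_auc <- function(scores, labels, positive_class, conf_level = 0.95) {
  pos <- labels == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be non-empty (", n1, " positive, ", n0,
         " negative)")
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- auc - z * se; hi <- auc + z * se
  clipped <- lo < 0 || hi > 1
  structure(list(auc = auc, se = se, ci_low = max(0, lo), ci_high = min(1, hi),
                 n_pos = n1, n_neg = n0, conf_level = conf_level,
                 ci_clipped = clipped),
            class = "roc_auc")
}

#' Youden-index optimal cutoff with confusion metrics
#'
#' Scans every candidate threshold (midpoints between adjacent distinct
#' scores, plus one below and one above the range) and picks the one
#' maximizing Youden's `J = sensitivity + specificity - 1`. The test
#' direction is chosen so the reported orientation has AUC >= 0.5: either
#' "score > cutoff is test-positive" (`greater`) or "score <= cutoff"
#' (`less_equal`). Ties in J are broken toward the smallest `|cutoff|` and
#' all maximizing thresholds are reported.
#'
#' @inheritParams roc_auc
#' @return list of class `youden_cutoff`: `cutoff`, `direction`, `J`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `tp`, `fp`, `tn`, `fn`,
#'   `n_pos`, `n_neg`, `tied_cutoffs`.
#' @export
youden_cutoff <- function(scores, labels, positive_class) {
  pos <- labels == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  a <- roc_auc(scores, labels, positive_class)
  direction <- if (a$auc >= 0.5) "greater" else "less_equal"
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- NULL
  for (cut in cand) {
    test_pos <- if (direction == "greater") scores > cut else scores <= cut
    sens <- sum(test_pos & pos) / n1
    spec <- sum(!test_pos & !pos) / n0
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12) {
      best <- list(J = J, cuts = cut)
    } else if (abs(J - best$J) <= 1e-12) {
      best$cuts <- c(best$cuts, cut)
    }
  }
  cutoff <- best$cuts[which.min(abs(best$cuts))]
  test_pos <- if (direction == "greater") scores > cutoff else scores <= cutoff
  tp <- sum(test_pos & pos); fp <- sum(test_pos & !pos)
  fn <- sum(!test_pos & pos); tn <- sum(!test_pos & !pos)
  structure(list(cutoff = cutoff, direction = direction, J = best$J,
                 sensitivity = tp / n1, specificity = tn / n0,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 n_pos = n1, n_neg = n0, tied_cutoffs = best$cuts),
            class = "youden_cutoff")
}

#' Confusion metrics from sensitivity, specificity and class sizes
#'
#' Reconstructs the 2x2 table implied by a test's sensitivity and
#' specificity applied to `n_pos` positives and `n_neg` negatives, and
#' returns its predictive values — e.g. sensitivity = specificity = 71.4%
#' on 28 positives and 42 negatives gives PPV 62.5% and NPV 78.9%.
#'
#' @param sensitivity,specificity rates in [0, 1].
#' @param n_pos,n_neg class sizes.
#' @return list: `tp`, `fp`, `tn`, `fn`, `ppv`, `npv`.
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos > 0, n_neg > 0)
  tp <- sensitivity * n_pos
  fn <- n_pos - tp
  tn <- specificity * n_neg
  fp <- n_neg - tn
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' AND-rule combination of two binary tests
#'
#' Declares disease only when both tests are positive. Under conditional
#' independence the combined sensitivity is the product of the
#' sensitivities and the combined specificity is one minus the product of
#' the false-positive rates: `sens = s1 * s2`,
#' `spec = 1 - (1 - sp1) * (1 - sp2)`. The combination trades sensitivity
#' for specificity.
#'
#' @param sens1,spec1 first test's sensitivity and specificity in [0, 1].
#' @param sens2,spec2 second test's.
#' @return list of class `combined_test`: `sensitivity`, `specificity`,
#'   `rule = "AND"`.
#' @export
combined_and_rule <- function(sens1, spec1, sens2, spec2) {
  vals <- c(sens1, spec1, sens2, spec2)
  if (any(!is.finite(vals) | vals < 0 | vals > 1))
    stop("all sensitivities/specificities must lie in [0, 1]")
  structure(list(sensitivity = sens1 * sens2,
                 specificity = 1 - (1 - spec1) * (1 - spec2),
                 rule = "AND"),
            class = "combined_test")
}

#' Feature-volume independence check
#'
#' Pearson correlation and ordinary least-squares regression of a feature
#' on lesion volume, to verify that a heterogeneity parameter is not a
#' surrogate for lesion size.
#'
#' @param feature,volume paired numeric vectors, `n >= 3`.
#' @return list: `r`, `p_value`, `slope`, `intercept`, `r_squared`, `n`.
#' @export
volume_independence <- function(feature, volume) {
  ok <- is.finite(feature) & is.finite(volume)
  feature <- feature[ok]; volume <- volume[ok]
  if (length(feature) < 3) stop("need at least 3 complete pairs")
  ct <- stats::cor.test(volume, feature, method = "pearson")
  fit <- stats::lm(feature ~ volume)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = length(feature))
}
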