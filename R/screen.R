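#' Screen patient-level features against clinical response
#'
#' The full evaluation pipeline on aggregated features: (1) Spearman
#' correlation of every (site, feature) pair against every clinical delta,
#' two-sided, no multiple-testing correction (the number of tests performed
#' is reported so readers can judge the screen's multiplicity); (2) for
#' pairs significant against delta-PSA at `alpha`, ROC analysis versus the
#' PSA responder label with Hanley-McNeil AUC and a Youden-index cutoff
#' with confusion metrics; (3) an AND-rule combination of the two
#' best-ranked significant features; (4) a Pearson/regression check of each
#' significant feature against lesion volume.
#'
#' The positive class defaults to the non-responders (risk orientation:
#' the test flags patients unlikely to benefit).
#'
#' @param patient_features an [aggregate_patient()] table.
#' @param deltas a [compute_deltas()] table.
#' @param alpha two-sided significance level for the Spearman screen.
#' @param positive_class `"non_responder"` or `"responder"`.
#' @param conf_level confidence level for AUC intervals.
#' @return list of class `screen_result`: `correlations`, `roc`,
#'   `confusion`, `combined`, `volume_independence`, `n_tests`, `alpha`,
#'   `positive_class`.
#' @export
run_screen <- function(patient_features, deltas, alpha = 0.05,
                       positive_class = c("non_responder", "responder"),
                       conf_level = 0.95) {
  positive_class <- match.arg(positive_class)
  df <- merge(patient_features, deltas, by = "patient_id")
  clinical_vars <- c("delta_psa", "delta_ap", "delta_bap", "ecog_change")
  corr <- list(); n_tests <- 0L
  for (s in sort(unique(df$site))) {
    ds <- df[df$site == s, ]
    for (f in feature_names) for (cl in clinical_vars) {
      row <- tryCatch(
        spearman_screen(ds[[f]], as.numeric(ds[[cl]]), f, cl),
        error = function(e) data.frame(feature = f, clinical = cl,
                                       rs = NA_real_, p_value = NA_real_,
                                       n = nrow(ds), stringsAsFactors = FALSE))
      row <- cbind(site = s, row, stringsAsFactors = FALSE)
      corr[[length(corr) + 1L]] <- row
      n_tests <- n_tests + 1L
    }
  }
  corr <- do.call(rbind, corr)
  rownames(corr) <- NULL

  sig <- corr[corr$clinical == "delta_psa" & !is.na(corr$p_value) &
                corr$p_value < alpha, ]
  label <- ifelse(deltas$responder_psa, "responder", "non_responder")
  names(label) <- deltas$patient_id
  roc_rows <- list(); conf_rows <- list(); volind <- list()
  for (i in seq_len(nrow(sig))) {
    s <- sig$site[i]; f <- sig$feature[i]
    ds <- df[df$site == s, ]
    scores <- ds[[f]]
    lab <- label[ds$patient_id]
    if (length(unique(lab)) < 2L) next   # one-class subset: ROC undefined
    a <- roc_auc(scores, lab, positive_class, conf_level = conf_level)
    y <- youden_cutoff(scores, lab, positive_class)
    roc_rows[[i]] <- data.frame(
      site = s, feature = f, auc = a$auc, se = a$se,
      ci_low = a$ci_low, ci_high = a$ci_high,
      cutoff = y$cutoff, direction = y$direction,
      stringsAsFactors = FALSE)
    conf_rows[[i]] <- data.frame(
      site = s, feature = f, p_value = sig$p_value[i],
      sensitivity = y$sensitivity, specificity = y$specificity,
      ppv = y$ppv, npv = y$npv,
      n_pos = y$n_pos, n_neg = y$n_neg, stringsAsFactors = FALSE)
    vi <- volume_independence(ds[[f]], ds$volume_cm3)
    volind[[i]] <- data.frame(site = s, feature = f, r = vi$r,
                              slope = vi$slope, r_squared = vi$r_squared,
                              stringsAsFactors = FALSE)
  }
  roc_tab <- if (length(roc_rows)) do.call(rbind, roc_rows) else NULL
  conf_tab <- if (length(conf_rows)) do.call(rbind, conf_rows) else NULL
  vol_tab <- if (length(volind)) do.call(rbind, volind) else NULL
  combined <- NULL
  if (!is.null(conf_tab) && nrow(conf_tab) >= 2L) {
    ord <- order(conf_tab$p_value)[1:2]   # the two strongest signals
    combined <- combined_and_rule(conf_tab$sensitivity[ord[1]],
                                  conf_tab$specificity[ord[1]],
                                  conf_tab$sensitivity[ord[2]],
                                  conf_tab$specificity[ord[2]])
    combined$features <- paste(conf_tab$feature[ord], collapse = "+")
  }
  structure(list(correlations = corr, roc = roc_tab, confusion = conf_tab,
                 combined = combined, volume_independence = vol_tab,
                 n_tests = n_tests, alpha = alpha,
                 positive_class = positive_class),
            class = "screen_result")
}

#' Write a screening bundle to disk
#'
#' Emits the correlation, ROC and confusion tables as CSV (mirroring the
#' standard reporting layout: correlations; AUC/CI/cutoff; sensitivity,
#' specificity, PPV, NPV) plus a single JSON bundle with everything,
#' including the combined-test result and the test count.
#'
#' @param res a [run_screen()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_screen <- function(res, dir) {
  stopifnot(inherits(res, "screen_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  if (!is.null(res$roc))
    utils::write.csv(res$roc, file.path(dir, "roc.csv"), row.names = FALSE)
  if (!is.null(res$confusion))
    utils::write.csv(res$confusion, file.path(dir, "confusion.csv"),
                     row.names = FALSE)
  if (!is.null(res$volume_independence))
    utils::write.csv(res$volume_independence,
                     file.path(dir, "volume_independence.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(correlations = res$correlations, roc = res$roc,
         confusion = res$confusion,
         combined = if (!is.null(res$combined)) unclass(res$combined),
         volume_independence = res$volume_independence,
         n_tests = res$n_tests, alpha = res$alpha,
         positive_class = res$positive_class),
    file.path(dir, "screen.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
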