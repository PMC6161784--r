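#' Pre/post clinical deltas and responder labels
#'
#' Treatment response is read off marker changes as post-therapy minus
#' pre-therapy level: a strictly negative delta marks a responder (the
#' marker fell under therapy); zero change is a non-responder. Applied to
#' PSA, alkaline phosphatase (AP) and bone alkaline phosphatase (bAP), plus
#' the ECOG performance-status change.
#'
#' @param clinical data.frame with columns `patient_id`, `pre_psa`,
#'   `post_psa`, `pre_ap`, `post_ap`, `pre_bap`, `post_bap` and optionally
#'   `ecog_pre`, `ecog_post`.
#' @return data.frame with one row per patient: `delta_psa`, `delta_ap`,
#'   `delta_bap`, `ecog_change`, and strict responder flags
#'   `responder_psa`, `responder_ap`, `responder_bap`.
#' @export
compute_deltas <- function(clinical) {
  need <- c("patient_id", "pre_psa", "post_psa", "pre_ap", "post_ap",
            "pre_bap", "post_bap")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  num <- setdiff(need, "patient_id")
  for (col in num) {
    v <- clinical[[col]]
    bad <- !is.finite(suppressWarnings(as.numeric(v)))
    if (any(bad))
      stop("non-numeric or missing '", col, "' for patient(s) ",
           paste(clinical$patient_id[bad], collapse = ", "))
    clinical[[col]] <- as.numeric(v)
  }
  pre_bad <- clinical$pre_psa <= 0 | clinical$pre_ap <= 0 | clinical$pre_bap <= 0
  if (any(pre_bad))
    stop("non-positive pre-therapy level for patient(s) ",
         paste(clinical$patient_id[pre_bad], collapse = ", "))
  ecog_change <- if (all(c("ecog_pre", "ecog_post") %in% names(clinical)))
    as.integer(clinical$ecog_post) - as.integer(clinical$ecog_pre)
  else NA_integer_
  d <- data.frame(
    patient_id = clinical$patient_id,
    delta_psa = clinical$post_psa - clinical$pre_psa,
    delta_ap = clinical$post_ap - clinical$pre_ap,
    delta_bap = clinical$post_bap - clinical$pre_bap,
    ecog_change = ecog_change,
    stringsAsFactors = FALSE)
  d$responder_psa <- d$delta_psa < 0
  d$responder_ap <- d$delta_ap < 0
  d$responder_bap <- d$delta_bap < 0
  d
}

#' Summarize responder counts and percentages
#'
#' Counts of responders per marker plus the joint responders (PSA-and-AP,
#' PSA-and-AP-and-bAP), with percentages of the cohort. `percent_mode`
#' selects plain rounding or truncation to `digits` decimals; raw fractions
#' are always included so no formatting convention is lost.
#'
#' @param deltas a [compute_deltas()] result.
#' @param digits decimals for the percentage.
#' @param percent_mode `"round"` or `"trunc"`.
#' @return data.frame with `measure`, `count`, `n`, `fraction`, `percent`.
#' @export
summarize_response <- function(deltas, digits = 2,
                               percent_mode = c("round", "trunc")) {
  percent_mode <- match.arg(percent_mode)
  n <- nrow(deltas)
  counts <- c(
    psa = sum(deltas$responder_psa),
    ap = sum(deltas$responder_ap),
    bap = sum(deltas$responder_bap),
    psa_and_ap = sum(deltas$responder_psa & deltas$responder_ap),
    psa_and_ap_and_bap = sum(deltas$responder_psa & deltas$responder_ap &
                               deltas$responder_bap))
  frac <- counts / n
  pct <- if (percent_mode == "round") round(100 * frac, digits)
         else trunc(100 * frac * 10^digits) / 10^digits
  data.frame(measure = names(counts), count = as.integer(counts), n = n,
             fraction = as.numeric(frac), percent = as.numeric(pct),
             stringsAsFactors = FALSE)
}
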