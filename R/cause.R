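#' Two-step cause-specific mortality prediction and band evaluation
#'
#' A main model first produces a mortality probability; only when that
#' probability *exceeds* the decision threshold (0.5 by default; exactly
#' 0.5 counts as survivor) is the cause-specific model — trained on
#' non-survivors only — invoked to split the prediction into cardiac and
#' respiratory mortality. Predictions are evaluated against ground truth
#' relabelled per follow-up time band.
#'
#' @name cause-specific
NULL

#' Two-step decoupled prediction
#'
#' @param series model input (a `longitudinal_series` or pre-extracted
#'   feature list, as accepted by the models).
#' @param main_model main mortality model (`cnn_model` or `crnn_model`,
#'   classification mode), or a list of them (ensemble).
#' @param cause_model cause-specific classifier whose two classes are
#'   (cardiac, respiratory); may be `NULL` if the threshold is never
#'   passed, but a passing case with no cause model is a config error.
#' @param threshold decision threshold in (0, 1).
#' @return list of class `cause_prediction`: `label` (survivor, cardiac
#'   or respiratory), `p_main`, `p_cause` (named probabilities, `NULL`
#'   when the cause model was not invoked).
#' @export
two_step_predict <- function(series, main_model, cause_model = NULL,
                             threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop_config("threshold must lie in (0, 1)")
  predict1 <- function(m) {
    if (is.list(m) && !inherits(m, c("cnn_model", "crnn_model")))
      return(ensemble_predict(m, series))
    if (inherits(m, "crnn_model")) crnn_predict(m, series)
    else cnn_predict(m, series)
  }
  pm <- predict1(main_model)
  if (pm$mode != "classification")
    stop_config("two-step prediction requires classification models")
  p <- pm$p_event
  if (p <= threshold)
    return(structure(list(label = "survivor", p_main = p, p_cause = NULL),
                     class = "cause_prediction"))
  if (is.null(cause_model))
    stop_config("mortality probability exceeds threshold but no ",
                "cause-specific model was supplied")
  pc <- predict1(cause_model)
  probs <- setNames(as.numeric(pc$prob), c("cardiac", "respiratory"))
  structure(list(label = names(probs)[which.max(probs)], p_main = p,
                 p_cause = probs),
            class = "cause_prediction")
}

#' Relabel a survival record for a follow-up time band
#'
#' A subject counts as a non-survivor (with their recorded cause) for a
#' band iff the death occurred strictly before the band's upper bound;
#' otherwise — censored, or death beyond the bound — they count as a
#' survivor for that band.
#'
#' @param records `survival_records` with time in days from the last scan.
#' @param band_years band upper bound in years.
#' @return character vector of band labels (`"survivor"`, `"cardiac"`,
#'   `"respiratory"`).
#' @export
band_relabel <- function(records, band_years) {
  if (band_years <= 0) stop_invalid("band bound must be positive")
  if (any(records$time < 0)) stop_invalid("negative follow-up time")
  dead <- records$event == 1 & records$time < band_years * 365
  ifelse(dead, records$cause, "survivor")
}

#' Per-band, per-class sensitivity and specificity table
#'
#' One-vs-rest sensitivity (TP / (TP + FN)) and specificity
#' (TN / (TN + FP)) of the final two-step labels against band-relabelled
#' ground truth, with per-class case counts, for each band.
#'
#' @param predictions list of `cause_prediction` (or a character vector
#'   of labels), one per record.
#' @param records `survival_records`.
#' @param bands numeric band bounds in years, strictly increasing
#'   (default `c(3, 7, 11)`).
#' @return data.frame with columns `band_years`, `class`, `cases`,
#'   `sensitivity`, `specificity` (NA, not 0, for classes absent in a
#'   band).
#' @export
band_evaluate <- function(predictions, records, bands = c(3, 7, 11)) {
  if (any(diff(bands) <= 0) || any(bands <= 0))
    stop_invalid("bands must be positive and strictly increasing")
  labels <- if (is.character(predictions)) predictions
            else vapply(predictions, `[[`, "", "label")
  if (length(labels) != nrow(records))
    stop_invalid("one prediction per record required")
  classes <- c("survivor", "cardiac", "respiratory")
  rows <- list()
  for (b in bands) {
    truth <- band_relabel(records, b)
    for (cl in classes) {
      tp <- sum(labels == cl & truth == cl)
      fn <- sum(labels != cl & truth == cl)
      fp <- sum(labels == cl & truth != cl)
      tn <- sum(labels != cl & truth != cl)
      rows[[length(rows) + 1]] <- data.frame(
        band_years = b, class = cl, cases = tp + fn,
        sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
        specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
    }
  }
  do.call(rbind, rows)
}
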