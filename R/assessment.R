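# Meta-analysis pooling of literature study tables and model-performance
# statistics (fold errors, two-fold and Guest acceptance criteria).

#' One literature study record
#'
#' @param study_id Identifier.
#' @param n Sample size (>= 1).
#' @param mean Mean plasma concentration, ng/mL (> 0).
#' @param sd Standard deviation, ng/mL (>= 0).
#' @param ethnicity,sex Optional strata labels.
#' @return A `study_record` (one-row data.frame).
#' @export
study_record <- function(study_id, n, mean, sd, ethnicity = NA_character_,
                         sex = NA_character_) {
  stopifnot(n >= 1)
  check_positive(mean, "mean")
  check_positive(sd, "sd", strict = FALSE)
  structure(data.frame(study_id = study_id, n = as.integer(n), mean = mean,
                       sd = sd, ethnicity = ethnicity, sex = sex,
                       stringsAsFactors = FALSE),
            class = c("study_record", "data.frame"))
}

as_study_table <- function(records) {
  if (is.data.frame(records)) records else do.call(rbind, records)
}

#' Sample-size-weighted pooled mean and CV
#'
#' Weighted mean `sum(n_i m_i)/sum(n_i)`; the pooled SD combines
#' within-study variance and between-study mean dispersion (law of total
#' variance over study membership):
#' `var = sum(n_i (s_i^2 + (m_i - m)^2)) / sum(n_i)`; CV = SD/mean x 100.
#' Set `between_study = FALSE` for the within-only pooling variant.
#'
#' @param records A data.frame of study records (columns `n`, `mean`, `sd`)
#'   or a list of [study_record()]s.
#' @param between_study Include between-study dispersion (default TRUE).
#' @return List with `weighted_mean`, `pooled_sd`, `cv_percent`,
#'   `n_total`, `n_studies`.
#' @export
pooled_mean_cv <- function(records, between_study = TRUE) {
  tab <- as_study_table(records)
  if (!nrow(tab)) stop("empty study table", call. = FALSE)
  wm <- sum(tab$n * tab$mean) / sum(tab$n)
  v_within <- sum(tab$n * tab$sd^2) / sum(tab$n)
  v_between <- sum(tab$n * (tab$mean - wm)^2) / sum(tab$n)
  v <- v_within + if (between_study) v_between else 0
  list(weighted_mean = wm, pooled_sd = sqrt(v),
       cv_percent = sqrt(v) / wm * 100,
       n_total = sum(tab$n), n_studies = nrow(tab))
}

check_pred_obs <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (!length(predicted)) stop("empty input", call. = FALSE)
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("fold errors require strictly positive values", call. = FALSE)
  }
}

#' Average fold error (bias)
#'
#' `AFE = 10^(mean(log10(predicted/observed)))`; > 1 indicates
#' overprediction, < 1 underprediction.
#'
#' @param predicted,observed Positive vectors of equal length.
#' @return AFE.
#' @export
afe <- function(predicted, observed) {
  check_pred_obs(predicted, observed)
  10^mean(log10(predicted / observed))
}

#' Absolute average fold error (precision)
#'
#' `AAFE = 10^(mean(|log10(predicted/observed)|))`; always >= 1.
#'
#' @inheritParams afe
#' @return AAFE.
#' @export
aafe <- function(predicted, observed) {
  check_pred_obs(predicted, observed)
  10^mean(abs(log10(predicted / observed)))
}

#' Guest acceptance limits for a DDI ratio
#'
#' Prediction-success bounds that tighten towards unity for weak
#' interactions: with `R' = max(R, 1/R)`,
#' `L = (delta + 2 (R' - 1)) / R'` and the predicted/observed ratio must lie
#' in `(1/L, L)`. At `R = 1` the bounds are `(1/delta, delta)`; as `R` grows
#' they approach the classic two-fold limits. Symmetric under `R -> 1/R`.
#'
#' @param observed_ratio Observed DDI ratio (> 0).
#' @param delta Variability factor (>= 1), default 1.25.
#' @return Named vector `c(lower =, upper =)`.
#' @export
guest_limits <- function(observed_ratio, delta = 1.25) {
  check_positive(observed_ratio, "observed_ratio")
  if (delta < 1) stop_field("delta", "must be >= 1")
  r <- max(observed_ratio, 1 / observed_ratio)
  l <- (delta + 2 * (r - 1)) / r
  c(lower = 1 / l, upper = l)
}

#' Per-study prediction assessment table
#'
#' Computes per-study predicted/observed ratios, 1.25-fold, two-fold and
#' Guest acceptance flags, and the AFE/AAFE summary.
#'
#' @param predicted,observed Positive vectors of equal length.
#' @param labels Optional study labels.
#' @param delta Guest variability factor passed to [guest_limits()].
#' @return An `assessment_result`: `table` (per-study data.frame with
#'   `ratio`, `pass_1.25`, `pass_twofold`, `pass_guest`), `afe`, `aafe`.
#' @export
ratio_table <- function(predicted, observed, labels = NULL, delta = 1.25) {
  check_pred_obs(predicted, observed)
  if (is.null(labels)) labels <- paste0("study_", seq_along(predicted))
  if (length(labels) != length(predicted)) {
    stop("labels must align with predicted/observed", call. = FALSE)
  }
  ratio <- predicted / observed
  guest <- vapply(seq_along(ratio), function(i) {
    lim <- guest_limits(observed[i], delta)
    ratio[i] > lim["lower"] && ratio[i] < lim["upper"]
  }, logical(1))
  tab <- data.frame(study = labels, predicted = predicted, observed = observed,
                    ratio = ratio,
                    pass_1.25 = ratio > 0.8 & ratio < 1.25,
                    pass_twofold = ratio > 0.5 & ratio < 2,
                    pass_guest = guest,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, afe = afe(predicted, observed),
                 aafe = aafe(predicted, observed)),
            class = "assessment_result")
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(sprintf("<assessment_result> %d studies, AFE %.3f, AAFE %.3f\n",
              nrow(x$table), x$afe, x$aafe))
  print(x$table, row.names = FALSE)
  invisible(x)
}
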