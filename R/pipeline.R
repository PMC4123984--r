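#' @keywords internal
"_PACKAGE"

#' Merge automated and clinical scores of a study at the movement level
#'
#' Builds the movement-level table relating the quantitative score (mean
#' paretic reconstruction R^2 per participant x movement) to the
#' qualitative score (across-rater mean panel score), the input to the
#' score regression and the leave-one-subject-out decoder.
#'
#' @param study an `impairment_study` from [simulate_study()], or any list
#'   with `scores` and `panel` of the same shape.
#' @param system which capture system's scores to use (default the first
#'   present).
#' @return data.frame: `participant`, `movement`, `quant`, `qual`.
#' @export
study_score_table <- function(study, system = NULL) {
  sc <- study$scores
  if (is.null(system)) system <- sc$system[1]
  sc <- sc[sc$system == system & sc$limb == "paretic" & !is.na(sc$score), ]
  quant <- stats::aggregate(score ~ participant + movement, sc, mean)
  names(quant)[3] <- "quant"
  pe <- study$panel$entries
  qual <- stats::aggregate(score ~ participant + movement, pe, mean)
  names(qual)[3] <- "qual"
  out <- merge(quant, qual, by = c("participant", "movement"))
  out[order(out$participant, out$movement), ]
}

#' Squared error of the automated score on the qualitative scale
#'
#' Maps each (participant, movement) quantitative score onto the
#' qualitative scale through the fitted score regression and returns its
#' squared error against the panel-mean score — the model-performance
#' error that the raters-to-match bootstrap compares rater errors against.
#'
#' @param tab movement-level table from [study_score_table()].
#' @return data.frame: `participant`, `movement`, `limb`, `error`.
#' @export
model_errors_on_scale <- function(tab) {
  fit <- stats::lm(qual ~ quant, data = tab)
  data.frame(participant = tab$participant, movement = tab$movement,
             limb = "paretic",
             error = (tab$qual - stats::fitted(fit))^2)
}
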