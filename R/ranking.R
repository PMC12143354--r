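# Exhaustive ranking of the combination space, candidate selection and
# male-female sex-bias differencing.

#' Predict and rank every combination in a level space
#'
#' Evaluates the fitted quadratic model on every run of the space
#' (typically the full 3^8 = 6561 enumeration), back-transforms
#' predictions through the model's transform -- negative
#' transformed-scale predictions, which have no real preimage under an
#' even power transform, are assigned zero efficacy -- and ranks the
#' combinations by predicted response, descending. Ties are broken
#' lexicographically by level vector so the ranking is a deterministic
#' permutation.
#'
#' @param model a `quad_model`.
#' @param space a `combo_design` covering the level space (default the
#'   full 3-level factorial over the model's drugs).
#' @param coding level coding used at fit time.
#' @return Data frame of class `ranked_combinations`: `rank`, one level
#'   column per drug, `n_drugs` (count of nonzero codes),
#'   `predicted_pct`.
#' @export
predict_all <- function(model, space = NULL, coding = level_coding) {
  if (is.null(space)) {
    space <- full_factorial(length(model$drugs), 3, drugs = model$drugs)
  }
  lev <- space$levels
  pred <- predict(model, space, coding)
  ord <- do.call(order, c(list(-pred), as.data.frame(lev)))
  out <- data.frame(rank = seq_len(nrow(lev)),
                    lev[ord, , drop = FALSE],
                    n_drugs = rowSums(lev[ord, , drop = FALSE] > 0),
                    predicted_pct = pred[ord],
                    check.names = FALSE, row.names = NULL)
  class(out) <- c("ranked_combinations", "data.frame")
  attr(out, "drugs") <- space$drugs
  out
}

#' Top combinations with a given number of drugs
#'
#' The highest-ranked entries whose nonzero-code count equals
#' `k_drugs`; used to shortlist two-, three- and four-drug candidate
#' combinations for validation.
#'
#' @param ranked output of [predict_all()].
#' @param k_drugs required number of drugs per combination.
#' @param top_n how many entries to return.
#' @return Subset of `ranked`, highest rank first. If fewer than
#'   `top_n` match, all matches are returned with a warning.
#' @export
top_k_by_drug_count <- function(ranked, k_drugs, top_n = 3) {
  stopifnot(top_n >= 1)
  sub <- ranked[ranked$n_drugs == k_drugs, , drop = FALSE]
  if (nrow(sub) < top_n) {
    warning("only ", nrow(sub), " combinations with ", k_drugs,
            " drugs available (requested ", top_n, ")")
    return(sub)
  }
  sub[seq_len(top_n), , drop = FALSE]
}

#' Predicted-ineffective multi-drug combinations (negative controls)
#'
#' The lowest-ranked entries having at least `min_drugs` nonzero codes.
#'
#' @param ranked output of [predict_all()].
#' @param n number of controls (>= 1).
#' @param min_drugs minimum number of drugs per control combination.
#' @return Subset of `ranked`, lowest rank last.
#' @export
bottom_controls <- function(ranked, n = 2, min_drugs = 2) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  sub <- ranked[ranked$n_drugs >= min_drugs, , drop = FALSE]
  utils::tail(sub, n)
}

#' Male-female sex-bias table
#'
#' Aligns two ranked lists over the identical level space, subtracts
#' the predicted female response from the predicted male response per
#' combination, and sorts by the difference, descending. Positive
#' differences are male-biased, negative female-biased; differences
#' inside a small deadband are classed neutral because a literal sign
#' rule is unstable under noise.
#'
#' @param male_ranked,female_ranked outputs of [predict_all()] over the
#'   same space.
#' @param deadband half-width (response units) of the neutral class.
#' @return Data frame of class `sex_bias_table`: level columns,
#'   `n_drugs`, `male_pred`, `female_pred`, `difference`, `bias_class`.
#' @export
sex_bias_table <- function(male_ranked, female_ranked, deadband = 5) {
  drugs <- attr(male_ranked, "drugs")
  if (!identical(drugs, attr(female_ranked, "drugs")) ||
      nrow(male_ranked) != nrow(female_ranked)) {
    stop("alignment error: the two rankings cover different spaces",
         call. = FALSE)
  }
  key <- function(df) do.call(paste, c(as.list(df[drugs]), sep = "."))
  km <- key(male_ranked); kf <- key(female_ranked)
  idx <- match(km, kf)
  if (anyNA(idx)) {
    stop("alignment error: level vectors do not match between sexes",
         call. = FALSE)
  }
  out <- data.frame(male_ranked[drugs],
                    n_drugs = male_ranked$n_drugs,
                    male_pred = male_ranked$predicted_pct,
                    female_pred = female_ranked$predicted_pct[idx],
                    check.names = FALSE)
  out$difference <- out$male_pred - out$female_pred
  out$bias_class <- ifelse(out$difference > deadband, "male_biased",
                    ifelse(out$difference < -deadband, "female_biased",
                           "neutral"))
  ord <- do.call(order, c(list(-out$difference), as.list(out[drugs])))
  out <- out[ord, , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("sex_bias_table", "data.frame")
  attr(out, "drugs") <- drugs
  attr(out, "deadband") <- deadband
  out
}

#' Correlate model predictions with validation measurements
#'
#' Pearson correlation with a two-sided t-distribution p-value, plus
#' the least-squares line of measured on predicted.
#'
#' @param predicted,measured paired response vectors, length >= 3.
#' @return A list of class `validation_report`: `r`, `p_value`,
#'   `slope`, `intercept`, `n`.
#' @export
validate_predictions <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) < 3) {
    stop("need paired lists of length >= 3", call. = FALSE)
  }
  ct <- stats::cor.test(predicted, measured, method = "pearson")
  cf <- stats::coef(stats::lm(measured ~ predicted))
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 n = length(predicted)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: r=%.3f (P=%.4g, n=%d), measured ~ %.3g + %.3g * predicted\n",
              x$r, x$p_value, x$n, x$intercept, x$slope))
  invisible(x)
}
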