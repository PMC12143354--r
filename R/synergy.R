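# Bliss-independence synergy scoring of checkerboard dose matrices.

#' Map a percent response onto the [0, 1] effect scale
#'
#' Bliss independence is defined on probabilities, so percent reductions
#' are divided by 100 and clamped to [0, 1]; a negative reduction
#' (drug-worsened activation) counts as no effect.
#'
#' @param pct_reduction percent response vector.
#' @return Effect fractions in [0, 1].
#' @export
effect_fraction <- function(pct_reduction) {
  pmin(pmax(pct_reduction / 100, 0), 1)
}

#' Bliss synergy score
#'
#' `100 * (fAB - (fA + fB - fA * fB))`. Scores below -10 indicate
#' antagonism, above +10 synergy, and the band between additivity.
#'
#' @param fA,fB monotherapy effect fractions in [0, 1].
#' @param fAB observed combination effect fraction in [0, 1].
#' @return Score on the percent scale, in [-100, 100]; symmetric in
#'   `fA` and `fB`.
#' @export
bliss_score <- function(fA, fB, fAB) {
  stopifnot(all(fA >= 0 & fA <= 1), all(fB >= 0 & fB <= 1),
            all(fAB >= 0 & fAB <= 1))
  100 * (fAB - (fA + fB - fA * fB))
}

classify_bliss <- function(score) {
  ifelse(score > 10, "synergistic",
         ifelse(score < -10, "antagonistic", "additive"))
}

#' Score a checkerboard assay under Bliss independence
#'
#' Monotherapy effects are taken from the checkerboard's own zero row
#' and column (so the map is self-contained); every nonzero dose pair
#' is scored from replicate-mean effects. Per-cell significance of a
#' positive score is assessed by a one-sample t test of the
#' per-replicate scores against zero (the vehicle control is
#' thresholded to zero by the normalization).
#'
#' @param table data frame with columns `dose_a_uM`, `dose_b_uM`,
#'   `response_pct` and optionally `replicate` (defaults to a single
#'   replicate, in which case p-values are `NA`).
#' @return Data frame of class `synergy_map`: `dose_a_uM`, `dose_b_uM`,
#'   `observed`, `expected` (effect fractions), `score`, `p_value`,
#'   `class`, one row per nonzero-nonzero dose pair.
#' @export
score_checkerboard <- function(table) {
  req <- c("dose_a_uM", "dose_b_uM", "response_pct")
  if (!all(req %in% names(table))) {
    stop("checkerboard table needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (is.null(table$replicate)) table$replicate <- 1L
  da <- sort(unique(table$dose_a_uM))
  db <- sort(unique(table$dose_b_uM))
  if (!any(da == 0) || !any(db == 0)) {
    stop("reference missing: checkerboard must include the zero-dose ",
         "row and column", call. = FALSE)
  }
  cell_mean <- function(a, b) {
    mean(table$response_pct[table$dose_a_uM == a & table$dose_b_uM == b])
  }
  cell_rep <- function(a, b, r) {
    v <- table$response_pct[table$dose_a_uM == a & table$dose_b_uM == b &
                              table$replicate == r]
    if (length(v)) mean(v) else NA_real_
  }
  reps <- sort(unique(table$replicate))
  out <- expand.grid(dose_b_uM = db[db > 0], dose_a_uM = da[da > 0])[, 2:1]
  n_cell <- nrow(out)
  obs <- exp_eff <- sc <- pv <- numeric(n_cell)
  for (i in seq_len(n_cell)) {
    a <- out$dose_a_uM[i]; b <- out$dose_b_uM[i]
    if (!any(table$dose_a_uM == a & table$dose_b_uM == 0) ||
        !any(table$dose_a_uM == 0 & table$dose_b_uM == b)) {
      stop("reference missing: no monotherapy well for dose pair (",
           a, ", ", b, ")", call. = FALSE)
    }
    fA <- effect_fraction(cell_mean(a, 0))
    fB <- effect_fraction(cell_mean(0, b))
    fAB <- effect_fraction(cell_mean(a, b))
    obs[i] <- fAB
    exp_eff[i] <- fA + fB - fA * fB
    sc[i] <- bliss_score(fA, fB, fAB)
    rep_scores <- vapply(reps, function(r) {
      fa <- effect_fraction(cell_rep(a, 0, r))
      fb <- effect_fraction(cell_rep(0, b, r))
      fab <- effect_fraction(cell_rep(a, b, r))
      if (anyNA(c(fa, fb, fab))) NA_real_ else bliss_score(fa, fb, fab)
    }, numeric(1))
    rep_scores <- rep_scores[!is.na(rep_scores)]
    pv[i] <- if (length(rep_scores) >= 2 &&
                 stats::sd(rep_scores) > 0) {
      stats::t.test(rep_scores, mu = 0)$p.value
    } else {
      NA_real_
    }
  }
  out$observed <- obs
  out$expected <- exp_eff
  out$score <- sc
  out$p_value <- pv
  out$class <- classify_bliss(sc)
  class(out) <- c("synergy_map", "data.frame")
  attr(out, "ladder_a") <- da
  attr(out, "ladder_b") <- db
  out
}

#' Contrast male and female synergy maps
#'
#' Places male and female Bliss scores side by side for the selected
#' dose pairs (all shared pairs by default) and compares the two score
#' groups with a Welch two-sample t test.
#'
#' @param map_m,map_f `synergy_map` objects for the same drug pair and
#'   dose ladders.
#' @param cells optional data frame with `dose_a_uM`, `dose_b_uM`
#'   restricting the contrast to selected dose pairs.
#' @return A list of class `synergy_contrast`: `table` (per-cell male
#'   and female scores, classes and score difference), `t_statistic`,
#'   `p_value`.
#' @export
sex_synergy_contrast <- function(map_m, map_f, cells = NULL) {
  if (!identical(attr(map_m, "ladder_a"), attr(map_f, "ladder_a")) ||
      !identical(attr(map_m, "ladder_b"), attr(map_f, "ladder_b"))) {
    stop("maps must share the same dose ladders", call. = FALSE)
  }
  key <- function(df) paste(df$dose_a_uM, df$dose_b_uM, sep = "|")
  idx <- match(key(map_m), key(map_f))
  tab <- data.frame(dose_a_uM = map_m$dose_a_uM,
                    dose_b_uM = map_m$dose_b_uM,
                    male_score = map_m$score,
                    female_score = map_f$score[idx],
                    male_class = map_m$class,
                    female_class = map_f$class[idx])
  if (!is.null(cells)) {
    keep <- key(tab) %in% key(cells)
    tab <- tab[keep, , drop = FALSE]
  }
  tab$difference <- tab$male_score - tab$female_score
  tt <- if (nrow(tab) >= 2) {
    tryCatch(stats::t.test(tab$male_score, tab$female_score),
             error = function(e) NULL)  # constant scores: no test
  } else {
    NULL
  }
  structure(list(table = tab,
                 t_statistic = if (is.null(tt)) NA_real_ else
                   unname(tt$statistic),
                 p_value = if (is.null(tt)) NA_real_ else tt$p.value),
            class = "synergy_contrast")
}
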