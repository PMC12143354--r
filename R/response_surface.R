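# Second-order quadratic response-surface fitting: term basis, Box-Cox
# transform selection, F-test stepwise regression, outlier screening.

#' Full second-order term basis for a drug set
#'
#' Intercept, one linear and one quadratic term per drug, and one
#' bilinear term per unordered drug pair: `1 + d + d + choose(d, 2)`
#' terms (45 for 8 drugs).
#'
#' @param drugs character vector of drug identifiers.
#' @return Data frame with columns `label`, `kind` (`intercept`,
#'   `linear`, `quadratic`, `bilinear`), `a`, `b` (drug indices; `b` is
#'   `NA` except for bilinear terms).
#' @export
term_basis <- function(drugs) {
  d <- length(drugs)
  pairs <- if (d >= 2) utils::combn(d, 2) else matrix(nrow = 2, ncol = 0)
  data.frame(
    label = c("(Intercept)", drugs, paste0(drugs, "^2"),
              if (ncol(pairs)) paste0(drugs[pairs[1, ]], ":",
                                      drugs[pairs[2, ]])),
    kind = c("intercept", rep("linear", d), rep("quadratic", d),
             rep("bilinear", ncol(pairs))),
    a = c(NA, seq_len(d), seq_len(d), pairs[1, ]),
    b = c(rep(NA, 1 + 2 * d), pairs[2, ]))
}

#' Expand a design into the full second-order model matrix
#'
#' @param design a `combo_design`, or an integer matrix of level codes.
#' @param coding mapping of level codes 0/1/2 onto the real axis
#'   (default [level_coding]).
#' @return Numeric model matrix, one column per term of [term_basis()],
#'   column names the term labels.
#' @export
expand_terms <- function(design, coding = level_coding) {
  lev <- if (inherits(design, "combo_design")) design$levels else
    as.matrix(design)
  drugs <- if (inherits(design, "combo_design")) design$drugs else
    (if (!is.null(colnames(lev))) colnames(lev) else
       paste0("drug", seq_len(ncol(lev))))
  if (!all(lev %in% 0:2)) {
    stop("level codes must be 0, 1 or 2", call. = FALSE)
  }
  x <- matrix(coding[lev + 1L], nrow = nrow(lev))
  basis <- term_basis(drugs)
  X <- matrix(0, nrow(lev), nrow(basis),
              dimnames = list(NULL, basis$label))
  X[, 1] <- 1
  for (t in 2:nrow(basis)) {
    X[, t] <- switch(basis$kind[t],
                     linear = x[, basis$a[t]],
                     quadratic = x[, basis$a[t]]^2,
                     bilinear = x[, basis$a[t]] * x[, basis$b[t]])
  }
  X
}

# Power transform used for fitting/back-transform. lambda = 1 identity,
# 0 log, 2 square. Responses <= 0 are handled by the caller's shift.
power_transform <- function(y, lambda) {
  if (lambda == 0) log(y) else y^lambda
}

#' Back-transform model-scale predictions to the response scale
#'
#' Negative transformed predictions have no real preimage under even
#' power transforms (the square root of a negative number is imaginary)
#' and are assigned a response of zero -- no efficacy. The same clamp at
#' zero is applied after undoing any positivity shift.
#'
#' @param w transformed-scale predictions.
#' @param lambda power-transform exponent (0 = log).
#' @param shift positivity shift that was added before transforming.
#' @return Response-scale predictions, clamped below at 0.
#' @export
back_transform <- function(w, lambda, shift = 0) {
  y <- if (lambda == 0) {
    exp(w)
  } else {
    out <- rep(0, length(w))
    ok <- w > 0
    out[ok] <- w[ok]^(1 / lambda)
    out
  }
  pmax(y - shift, 0)
}

# SSE of least squares of y on columns X (assumed full rank).
ls_sse <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Select a Box-Cox response transform against the full quadratic basis
#'
#' Evaluates the Box-Cox profile log-likelihood of the full-basis
#' least-squares fit on a grid of candidate exponents and returns the
#' maximizer. Responses are shifted by `1 - min(y)` beforehand when any
#' response is nonpositive (the transform family needs a positive
#' domain); the shift is reported so predictions can be mapped back.
#' The identity is returned on ties, and for degenerate (constant)
#' responses with a warning.
#'
#' @param model_matrix full-basis model matrix from [expand_terms()].
#' @param responses response vector (% scale).
#' @param candidate_lambdas exponent grid; default
#'   `{-1, -0.5, 0, 0.5, 1, 2}` (0 = log, 2 = square).
#' @return A list: `lambda` (selected exponent), `shift`, and
#'   `loglik` (profile log-likelihood per candidate, named).
#' @export
boxcox_select <- function(model_matrix, responses,
                          candidate_lambdas = c(-1, -0.5, 0, 0.5, 1, 2)) {
  if (!length(candidate_lambdas)) {
    stop("empty candidate list", call. = FALSE)
  }
  y <- responses
  n <- length(y)
  shift <- if (any(y <= 0)) 1 - min(y) else 0
  z <- y + shift
  if (stats::var(y) == 0) {
    warning("constant responses: degenerate fit, keeping identity")
    ll <- rep(NA_real_, length(candidate_lambdas))
    names(ll) <- candidate_lambdas
    return(list(lambda = 1, shift = shift, loglik = ll))
  }
  ll <- vapply(candidate_lambdas, function(lam) {
    w <- if (lam == 0) log(z) else (z^lam - 1) / lam
    sse <- ls_sse(model_matrix, w)
    if (sse <= 0) return(Inf)
    -n / 2 * log(sse / n) + (lam - 1) * sum(log(z))
  }, numeric(1))
  names(ll) <- candidate_lambdas
  best <- max(ll)
  tied <- which(ll >= best - 1e-8)
  pick <- if (any(candidate_lambdas[tied] == 1)) {
    which(candidate_lambdas == 1)
  } else {
    tied[1]
  }
  list(lambda = candidate_lambdas[pick], shift = shift, loglik = ll)
}

#' Bidirectional F-test stepwise fit of the quadratic series
#'
#' Starting from an intercept-only model, repeatedly adds the excluded
#' term with the smallest partial-F p-value below `p_enter`, then
#' removes any included term whose partial-F p-value exceeds
#' `p_remove`, until the selected set is stable. Partial F statistics
#' are the sum-of-squares F tests comparing nested least-squares fits.
#' Responses may first be power-transformed (`lambda`, `shift`), in
#' which case coefficients are on the transformed scale and predictions
#' are mapped back through [back_transform()].
#'
#' @param model_matrix full-basis model matrix from [expand_terms()];
#'   column 1 must be the intercept.
#' @param responses response vector, one per row (replicates enter as
#'   separate rows).
#' @param p_enter p-value below which an excluded term may enter.
#' @param p_remove p-value above which an included term is removed
#'   (`p_enter <= p_remove`).
#' @param lambda,shift response transform applied before fitting
#'   (default identity; see [boxcox_select()]).
#' @return An object of class `quad_model`: `terms` (selected rows of
#'   the term basis), `coefficients`, `p_values`, `lambda`, `shift`,
#'   `adj_r2`, `sse`, `sst`, `n`, `fitted` (transformed scale),
#'   `residuals`, `hat`, `labels`.
#' @export
stepwise_fit <- function(model_matrix, responses, p_enter = 0.05,
                         p_remove = 0.10, lambda = 1, shift = 0) {
  X <- as.matrix(model_matrix)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows", call. = FALSE)
  if (p_enter > p_remove) {
    stop("`p_enter` must not exceed `p_remove`", call. = FALSE)
  }
  w <- power_transform(responses + shift, lambda)
  sst <- sum((w - mean(w))^2)
  eps <- max(1e-10 * sst, 1e-12)
  p_cols <- ncol(X)

  sse_of <- function(cols) ls_sse(X[, cols, drop = FALSE], w)

  sel <- 1L  # intercept always included
  sse_sel <- sse_of(sel)
  seen <- character()
  repeat {
    changed <- FALSE
    # entry step
    excl <- setdiff(seq_len(p_cols), sel)
    df2 <- n - (length(sel) + 1L)
    if (length(excl) && df2 >= 1) {
      pvals <- vapply(excl, function(j) {
        sse_new <- sse_of(c(sel, j))
        red <- sse_sel - sse_new
        if (sse_new < eps) {
          if (red < eps) 1 else 0
        } else {
          stats::pf(red / (sse_new / df2), 1, df2, lower.tail = FALSE)
        }
      }, numeric(1))
      if (min(pvals) < p_enter) {
        j <- excl[which.min(pvals)]
        sel <- c(sel, j)
        sse_sel <- sse_of(sel)
        changed <- TRUE
      }
    }
    # removal step (never the intercept)
    repeat {
      cand <- setdiff(sel, 1L)
      if (!length(cand)) break
      df2 <- n - length(sel)
      pvals <- vapply(cand, function(j) {
        sse_drop <- sse_of(setdiff(sel, j))
        red <- sse_drop - sse_sel
        if (sse_sel < eps) {
          if (red < eps) 1 else 0
        } else if (df2 < 1) {
          0
        } else {
          stats::pf(red / (sse_sel / df2), 1, df2, lower.tail = FALSE)
        }
      }, numeric(1))
      if (max(pvals) > p_remove) {
        j <- cand[which.max(pvals)]
        sel <- setdiff(sel, j)
        sse_sel <- sse_of(sel)
        changed <- TRUE
      } else break
    }
    key <- paste(sort(sel), collapse = ",")
    if (!changed || key %in% seen) break
    seen <- c(seen, key)
  }

  sel <- sort(sel)
  Xs <- X[, sel, drop = FALSE]
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    bad <- colnames(Xs)[qrX$pivot[(qrX$rank + 1):ncol(Xs)]]
    stop("deficient design: collinear terms ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(Xs, w)
  coefs <- fit$coefficients
  sse <- sum(fit$residuals^2)
  p <- length(sel)
  # per-term partial-F p-values (drop-one)
  pv <- vapply(seq_along(sel), function(k) {
    if (sel[k] == 1L) return(NA_real_)
    red <- sse_of(sel[-k]) - sse
    df2 <- n - p
    if (sse < eps) {
      if (red < eps) 1 else 0
    } else {
      stats::pf(red / (sse / df2), 1, df2, lower.tail = FALSE)
    }
  }, numeric(1))
  hat <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)

  drugs <- sub("\\^2$", "", grep("\\^2$", colnames(X), value = TRUE))
  basis <- term_basis(drugs)
  structure(list(drugs = drugs,
                 terms = basis[sel, , drop = FALSE],
                 selected = sel,
                 coefficients = stats::setNames(coefs, colnames(Xs)),
                 p_values = stats::setNames(pv, colnames(Xs)),
                 lambda = lambda, shift = shift,
                 adj_r2 = adjusted_r2_value(sse, sst, n, p),
                 sse = sse, sst = sst, n = n,
                 fitted = fit$fitted.values,
                 residuals = fit$residuals,
                 hat = hat,
                 labels = colnames(Xs)),
            class = "quad_model")
}

#' @export
print.quad_model <- function(x, ...) {
  cat(sprintf(
    "quad_model: %d terms, lambda=%g, shift=%g, adj R^2=%.4f (n=%d)\n",
    length(x$coefficients), x$lambda, x$shift, x$adj_r2, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict responses for new level combinations
#'
#' @param object a `quad_model`.
#' @param design a `combo_design` or level-code matrix.
#' @param coding level coding used at fit time.
#' @param transformed if `TRUE`, return transformed-scale predictions
#'   without back-transforming.
#' @param ... unused.
#' @return Predicted responses (percent scale unless `transformed`).
#' @export
predict.quad_model <- function(object, design, coding = level_coding,
                               transformed = FALSE, ...) {
  X <- expand_terms(design, coding)[, object$labels, drop = FALSE]
  w <- drop(X %*% object$coefficients)
  if (transformed) w else back_transform(w, object$lambda, object$shift)
}

adjusted_r2_value <- function(sse, sst, n, p) {
  if (sst <= 0) return(NA_real_)
  1 - (sse / (n - p)) / (sst / (n - 1))
}

#' Adjusted R-squared of a fitted quadratic model
#'
#' `1 - (SSE/(n - p)) / (SST/(n - 1))`; equals 1 for a perfect fit and
#' 0 for an intercept-only model.
#'
#' @param fit a `quad_model`, or a list with `sse`, `sst`, `n` and
#'   number of terms `p`.
#' @return Adjusted coefficient of determination.
#' @export
adjusted_r2 <- function(fit) {
  p <- if (!is.null(fit$coefficients)) length(fit$coefficients) else fit$p
  if (fit$n <= p) stop("need n > number of terms", call. = FALSE)
  adjusted_r2_value(fit$sse, fit$sst, fit$n, p)
}

#' Screen for outlying runs via externally studentized residuals
#'
#' Residuals are studentized against a leave-one-out estimate of the
#' error variance; runs with `|r| > threshold` are flagged.
#'
#' @param fit a `quad_model` (fitted with residual degrees of freedom
#'   of at least 2).
#' @param threshold absolute studentized-residual cutoff (default 3).
#' @return A list of class `outlier_report`: `flagged` (run indices),
#'   `rstudent`, `threshold`.
#' @export
outlier_scan <- function(fit, threshold = 3) {
  n <- fit$n
  p <- length(fit$coefficients)
  if (n - p < 2) {
    stop("need residual degrees of freedom >= 2", call. = FALSE)
  }
  e <- fit$residuals
  h <- pmin(fit$hat, 1 - 1e-12)
  if (fit$sse < max(1e-10 * fit$sst, 1e-12)) {
    rs <- rep(0, n)
  } else {
    s2i <- (fit$sse - e^2 / (1 - h)) / (n - p - 1)
    s2i <- pmax(s2i, 0)
    rs <- ifelse(s2i > 0, e / sqrt(s2i * (1 - h)), 0)
  }
  structure(list(flagged = which(abs(rs) > threshold),
                 rstudent = rs, threshold = threshold),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier report: ", length(x$flagged), " flagged (|r| > ",
      x$threshold, ")\n", sep = "")
  if (length(x$flagged)) {
    print(data.frame(run = x$flagged,
                     rstudent = round(x$rstudent[x$flagged], 3)))
  }
  invisible(x)
}

#' Fit a response surface with automatic transform selection
#'
#' Convenience wrapper running [boxcox_select()] on the full basis and
#' then [stepwise_fit()] with the selected transform.
#'
#' @param design a `combo_design`, expanded per run (replicate rows in
#'   `responses` must match `rep(runs, each = replicates)` ordering), or
#'   a pre-expanded model matrix.
#' @param responses response vector.
#' @inheritParams stepwise_fit
#' @param candidate_lambdas grid for [boxcox_select()].
#' @param coding level coding.
#' @return A `quad_model`.
#' @export
fit_surface <- function(design, responses, p_enter = 0.05,
                        p_remove = 0.10,
                        candidate_lambdas = c(-1, -0.5, 0, 0.5, 1, 2),
                        coding = level_coding) {
  X <- if (is.matrix(design) && "(Intercept)" %in% colnames(design)) {
    design
  } else {
    expand_terms(design, coding)
  }
  if (length(responses) != nrow(X) &&
      length(responses) %% nrow(X) == 0) {
    # replicate responses per run, run-major ordering
    X <- X[rep(seq_len(nrow(X)), each = length(responses) / nrow(X)), ,
           drop = FALSE]
  }
  bc <- boxcox_select(X, responses, candidate_lambdas)
  stepwise_fit(X, responses, p_enter, p_remove,
               lambda = bc$lambda, shift = bc$shift)
}
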