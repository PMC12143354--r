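# Constrained 4PL dose-response fitting, absolute EC/CC values and
# clinically bounded dose-level selection.

#' Percent aSMA reduction relative to control
#'
#' `100 * (control - drug) / control`. The control condition maps to 0
#' by construction, which is why downstream one-sample comparisons are
#' made against a theoretical mean of zero.
#'
#' @param control_mean mean control intensity (> 0).
#' @param drug_mean mean intensity under the drug condition.
#' @return Percent reduction (negative if the drug increases the
#'   readout).
#' @export
percent_reduction <- function(control_mean, drug_mean) {
  if (any(control_mean <= 0)) {
    stop("control mean must be positive: normalization undefined",
         call. = FALSE)
  }
  100 * (control_mean - drug_mean) / control_mean
}

#' Fit a constrained four-parameter logistic curve
#'
#' Least-squares fit of `top / (1 + (ec50/x)^hill)` with bottom fixed at
#' 0, `top` constrained to (0, 100] and `hill` to (0, 5]. The optimizer
#' is multi-start bounded BFGS from a fixed coarse grid over (ec50,
#' hill), so the fit is deterministic and robust to local minima.
#'
#' @param doses concentration vector (>= 0); at least 4 distinct doses.
#' @param responses matching response vector (% scale).
#' @param drug,sex,readout identifiers carried into the result.
#' @return An object of class `dr_curve`: `top`, `bottom` (0), `ec50`,
#'   `hill`, `sse`, `flat` (TRUE when responses are indistinguishable
#'   from zero and no EC is defined).
#' @export
fit_4pl <- function(doses, responses, drug = NA_character_,
                    sex = NA_character_, readout = "asma_reduction") {
  stopifnot(length(doses) == length(responses))
  if (any(doses < 0)) stop("doses must be nonnegative", call. = FALSE)
  if (length(unique(doses)) < 4) {
    stop("under-determined fit: need at least 4 distinct doses",
         call. = FALSE)
  }
  mk <- function(top, ec50, hill, sse, flat = FALSE) {
    structure(list(drug = drug, sex = sex, readout = readout,
                   top = top, bottom = 0, ec50 = ec50, hill = hill,
                   sse = sse, flat = flat),
              class = "dr_curve")
  }
  if (max(abs(responses)) < 1e-6) {
    return(mk(0, NA_real_, NA_real_, sum(responses^2), flat = TRUE))
  }
  pos <- doses[doses > 0]
  sse_fun <- function(p) {
    mu <- four_pl(doses, p[1], exp(p[2]), p[3])
    sum((responses - mu)^2)
  }
  lower <- c(1e-3, log(min(pos)) - 10, 1e-3)
  upper <- c(100, log(max(pos)) + 10, 5)
  top0 <- min(100, max(max(responses), 1))
  starts <- expand.grid(
    lec = log(exp(seq(log(min(pos)), log(max(pos)), length.out = 7))),
    hill = c(0.5, 1, 2, 4))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(stats::optim(c(top0, starts$lec[s], starts$hill[s]),
                            sse_fun, method = "L-BFGS-B",
                            lower = lower, upper = upper),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("4PL optimization failed", call. = FALSE)
  mk(best$par[1], exp(best$par[2]), best$par[3], best$value)
}

#' @export
print.dr_curve <- function(x, ...) {
  if (x$flat) {
    cat("dr_curve: flat (no EC defined)\n")
  } else {
    cat(sprintf("dr_curve: top=%.3g ec50=%.4g hill=%.3g (sse=%.3g)\n",
                x$top, x$ec50, x$hill, x$sse))
  }
  invisible(x)
}

#' Absolute effective concentration
#'
#' The concentration producing an absolute response of `f` percent
#' under the fitted curve (EC_f for efficacy curves, CC_f for
#' cytotoxicity curves), solved in closed form from the 4PL parameters:
#' `ec50 / (top/f - 1)^(1/hill)`.
#'
#' @param curve a `dr_curve` (or list with `top`, `ec50`, `hill`).
#' @param f target absolute response, 0 < f < top.
#' @return Concentration on the dose scale of the fit.
#' @export
absolute_ec <- function(curve, f) {
  if (isTRUE(curve$flat)) {
    stop("flat curve: no effective concentration defined", call. = FALSE)
  }
  stopifnot(length(f) == 1, f > 0)
  if (f >= curve$top) {
    stop("unreachable effect: curve tops out at ", signif(curve$top, 4),
         " < ", f, call. = FALSE)
  }
  curve$ec50 / (curve$top / f - 1)^(1 / curve$hill)
}

#' Log10 ratio of male to female effective concentrations
#'
#' `log10(EC_f,male / EC_f,female)`; negative values mean the drug is
#' more potent in male cells (lower concentration needed for the same
#' absolute effect).
#'
#' @param curve_m,curve_f fitted `dr_curve` objects for the two sexes.
#' @param f absolute effect level (percent), attainable by both curves.
#' @return log10 potency ratio.
#' @export
ec_sex_ratio <- function(curve_m, curve_f, f = 20) {
  log10(absolute_ec(curve_m, f) / absolute_ec(curve_f, f))
}

#' Percent cytotoxicity from per-cell marker intensities
#'
#' Cells are called dead when their apoptosis-marker intensity falls on
#' the dead-control side of a threshold placed midway between the mean
#' of the positive (dead) and negative (alive) control populations.
#'
#' @param cell_measures per-cell marker intensities for the condition.
#' @param alive_ref,dead_ref control intensity vectors (nonempty).
#' @return Percent of cells classified dead, in [0, 100].
#' @export
percent_cytotoxicity <- function(cell_measures, alive_ref, dead_ref) {
  if (!length(alive_ref) || !length(dead_ref)) {
    stop("both control lists must be nonempty", call. = FALSE)
  }
  ma <- mean(alive_ref); md <- mean(dead_ref)
  if (ma == md) {
    stop("degenerate threshold: control means are equal", call. = FALSE)
  }
  thr <- (ma + md) / 2
  dead <- if (md > ma) cell_measures > thr else cell_measures < thr
  100 * mean(dead)
}

#' Select clinically bounded L1/L2 dose levels
#'
#' L1 is the lowest of EC_1, CC_1 and 5% of the clinical Cmax; L2 the
#' lowest of EC_2, CC_2 and 10% of Cmax. The binding constraint is
#' recorded as provenance for each level.
#'
#' @param ec1,cc1,ec2,cc2 absolute effective / cytotoxic concentrations
#'   (> 0), same units as `cmax`.
#' @param info list with at least `name` and `cmax` (> 0); see
#'   [drug_info()].
#' @return A list of class `dose_levels`: `drug`, `l1`, `l2`,
#'   `l1_bound`, `l2_bound` (each one of `"EC"`, `"CC"`, `"Cmax"`).
#' @export
select_levels <- function(ec1, cc1, ec2, cc2, info) {
  vals1 <- c(EC = ec1, CC = cc1, Cmax = 0.05 * info$cmax)
  vals2 <- c(EC = ec2, CC = cc2, Cmax = 0.10 * info$cmax)
  if (any(c(vals1, vals2) <= 0)) {
    stop("all candidate concentrations must be positive", call. = FALSE)
  }
  structure(list(drug = info$name,
                 l1 = unname(min(vals1)), l2 = unname(min(vals2)),
                 l1_bound = names(vals1)[which.min(vals1)],
                 l2_bound = names(vals2)[which.min(vals2)]),
            class = "dose_levels")
}

#' Clinical drug information
#'
#' @param name drug identifier.
#' @param cmax maximum clinical serum concentration (> 0).
#' @param vehicle `"water"` or `"organic solvent"`.
#' @return A list of class `drug_info`.
#' @export
drug_info <- function(name, cmax, vehicle = "water") {
  stopifnot(is.numeric(cmax), cmax > 0)
  structure(list(name = name, cmax = cmax, vehicle = vehicle),
            class = "drug_info")
}

#' Sample size from a noncentral-t power analysis
#'
#' Smallest per-group n (>= 2) achieving the target power for a
#' two-sided t test of a mean difference `delta` with common SD `sd`.
#' Power is evaluated exactly through the noncentral t distribution.
#' The default is the two-sample formulation (experimental group vs
#' control); a one-sample variant is available because the control is
#' thresholded to zero in the screen's normalization.
#'
#' @param delta mean difference to detect (> 0), response units.
#' @param sd common standard deviation (> 0), response units.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param type `"two.sample"` (default) or `"one.sample"`.
#' @param n_cap largest n considered before giving up.
#' @return Integer sample size per group.
#' @export
#' @examples
#' power_n(35, 10, 0.05, 0.8)  # 3 replicates
power_n <- function(delta, sd, alpha = 0.05, power = 0.8,
                    type = c("two.sample", "one.sample"), n_cap = 1e5) {
  type <- match.arg(type)
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1,
            power > 0, power < 1)
  for (n in 2:n_cap) {
    df <- if (type == "two.sample") 2 * (n - 1) else n - 1
    ncp <- if (type == "two.sample") delta / (sd * sqrt(2 / n))
           else delta / (sd / sqrt(n))
    tcrit <- stats::qt(1 - alpha / 2, df)
    pw <- stats::pt(tcrit, df, ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp)
    if (pw >= power) return(n)
  }
  stop("required sample size exceeds cap of ", n_cap, call. = FALSE)
}
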