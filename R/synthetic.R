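# Seeded synthetic-data generator standing in for the wet-lab
# immunofluorescence measurements.

# Run code with a private RNG stream, restoring global state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Well-level noise model
#'
#' Additive Gaussian noise at the well level. The default SD of 10
#' %aSMA-reduction units matches the variability assumed by the screen's
#' power analysis; the default of 3 replicates is the sample size that
#' power analysis selects (see [power_n()]).
#'
#' @param well_sd standard deviation of well-level noise,
#'   %aSMA-reduction units (>= 0).
#' @param replicates number of replicate wells per condition (>= 1).
#' @param seed integer seed; identical seeds reproduce identical
#'   datasets.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(well_sd = 10, replicates = 3, seed = 1L) {
  stopifnot(is.numeric(well_sd), well_sd >= 0,
            replicates >= 1, is.numeric(seed))
  structure(list(well_sd = well_sd, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Four-parameter logistic response with bottom fixed at zero
#'
#' `top / (1 + (ec50 / dose) ^ hill)`, with the dose-0 limit handled
#' exactly (response 0) rather than via a log transform.
#'
#' @param dose concentration vector (>= 0).
#' @param top maximal response (0, 100].
#' @param ec50 concentration of half-maximal response (> 0).
#' @param hill Hill slope (0, 5].
#' @return Response vector on the same scale as `top`.
#' @export
four_pl <- function(dose, top, ec50, hill) {
  stopifnot(all(dose >= 0), ec50 > 0)
  ifelse(dose == 0, 0, top / (1 + (ec50 / dose)^hill))
}

#' Simulate monotherapy dose-response measurements
#'
#' One row per dose x replicate; responses are the 4PL value plus
#' Gaussian well noise.
#'
#' @param curve_params list with `top`, `ec50`, `hill` (bottom fixed 0);
#'   `top` in (0, 100], `hill` in (0, 5].
#' @param doses concentration vector (>= 0).
#' @param noise a [noise_model()].
#' @param drug,sex identifiers carried into the output table.
#' @return Data frame with columns `drug`, `sex`, `dose_uM`,
#'   `replicate`, `response_pct`.
#' @export
simulate_monotherapy <- function(curve_params, doses, noise,
                                 drug = "drug1", sex = NA_character_) {
  if (any(doses < 0)) stop("doses must be nonnegative", call. = FALSE)
  stopifnot(curve_params$top > 0, curve_params$top <= 100,
            curve_params$hill > 0, curve_params$hill <= 5)
  mu <- four_pl(doses, curve_params$top, curve_params$ec50,
                curve_params$hill)
  n <- length(doses) * noise$replicates
  out <- data.frame(
    drug = drug, sex = sex,
    dose_uM = rep(doses, each = noise$replicates),
    replicate = rep(seq_len(noise$replicates), length(doses)),
    response_pct = rep(mu, each = noise$replicates))
  out$response_pct <- out$response_pct +
    with_seed(noise$seed, stats::rnorm(n, 0, noise$well_sd))
  out
}

#' Simulate responses for a combination design
#'
#' Each run's mean response is the ground-truth quadratic series at its
#' coded levels, passed through the surface's monotone warp; Gaussian
#' well noise is added per replicate and the result clipped below at
#' -50 (drug-worsened activation is possible but physically bounded:
#' cells do not exceed roughly 150% of control activation).
#'
#' @param surface a [true_surface()].
#' @param design a `combo_design` over the same drugs.
#' @param noise a [noise_model()].
#' @param coding level-code mapping, see [level_coding].
#' @return Data frame with `run_id`, one level-code column per drug,
#'   `replicate`, `response_pct`.
#' @export
simulate_design_responses <- function(surface, design, noise,
                                      coding = level_coding) {
  raw <- eval_surface(surface, design, coding)
  mu <- warp_response(raw, surface$transform_exponent)
  nrun <- length(mu)
  out <- data.frame(run_id = rep(seq_len(nrun), each = noise$replicates),
                    design$levels[rep(seq_len(nrun),
                                      each = noise$replicates), ,
                                  drop = FALSE],
                    replicate = rep(seq_len(noise$replicates), nrun),
                    response_pct = rep(mu, each = noise$replicates),
                    check.names = FALSE, row.names = NULL)
  eps <- with_seed(noise$seed,
                   stats::rnorm(nrun * noise$replicates, 0, noise$well_sd))
  out$response_pct <- pmax(out$response_pct + eps, -50)
  out
}

#' Simulate a checkerboard (all-pairs dose grid) assay
#'
#' Monotherapy rows and columns follow the two 4PL curves; at cells
#' where both doses are nonzero the mean response is the Bliss
#' expectation of the two monotherapy effects plus a planted excess, so
#' that recomputing Bliss scores on the noiseless table returns exactly
#' the planted value.
#'
#' @param curveA,curveB lists with `top`, `ec50`, `hill`.
#' @param planted_bliss_excess synergy score units (percent scale)
#'   added at every nonzero-nonzero cell.
#' @param ladderA,ladderB dose vectors; each must include 0 (the
#'   monotherapy reference is undefined without the zero row/column).
#' @param noise a [noise_model()].
#' @return Data frame with `dose_a_uM`, `dose_b_uM`, `replicate`,
#'   `response_pct`.
#' @export
simulate_checkerboard <- function(curveA, curveB, planted_bliss_excess,
                                  ladderA, ladderB, noise) {
  if (inherits(ladderA, "dose_ladder")) ladderA <- ladderA$doses
  if (inherits(ladderB, "dose_ladder")) ladderB <- ladderB$doses
  if (!any(ladderA == 0) || !any(ladderB == 0)) {
    stop("dose ladders must include 0 (monotherapy reference)",
         call. = FALSE)
  }
  grid <- expand.grid(dose_b_uM = ladderB, dose_a_uM = ladderA)[, 2:1]
  fA <- effect_fraction(four_pl(grid$dose_a_uM, curveA$top, curveA$ec50,
                                curveA$hill))
  fB <- effect_fraction(four_pl(grid$dose_b_uM, curveB$top, curveB$ec50,
                                curveB$hill))
  both <- grid$dose_a_uM > 0 & grid$dose_b_uM > 0
  mu <- 100 * (fA + fB - fA * fB)
  mu[both] <- mu[both] + planted_bliss_excess
  n_cell <- nrow(grid)
  out <- data.frame(grid[rep(seq_len(n_cell), each = noise$replicates), ],
                    replicate = rep(seq_len(noise$replicates), n_cell),
                    response_pct = rep(mu, each = noise$replicates),
                    row.names = NULL)
  out$response_pct <- out$response_pct +
    with_seed(noise$seed,
              stats::rnorm(n_cell * noise$replicates, 0, noise$well_sd))
  out
}
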