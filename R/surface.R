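# Ground-truth combination surfaces for the synthetic-data generator.

#' Default coded values for the three dose levels
#'
#' Level codes 0/1/2 (absence, L1, L2) are mapped onto the ordinal
#' coded axis `{0, 0.5, 1}` for surface evaluation and model fitting.
#' The L1-to-L2 concentration spacing is drug specific, so an ordinal
#' coding keeps coefficients comparable across drugs.
#' @export
level_coding <- c(0, 0.5, 1)

#' Define a ground-truth quadratic combination surface
#'
#' The surface is a second-order quadratic series in coded drug levels:
#' intercept + per-drug linear and quadratic terms + sparse pairwise
#' (bilinear) interactions, optionally warped by a monotone power
#' transform. It is the generator-side ground truth the response-surface
#' fit is asked to recover.
#'
#' @param drugs ordered character vector of drug identifiers.
#' @param intercept baseline response, in %aSMA-reduction units.
#' @param linear named or positional numeric vector of per-drug linear
#'   coefficients (on the coded level).
#' @param quadratic per-drug coefficients on the squared coded level.
#' @param bilinear data frame with columns `drug_a`, `drug_b`, `coef`;
#'   unordered distinct drug pairs.
#' @param transform_exponent positive real: ground-truth monotone
#'   response warp (1 = none; 2 = square-law, i.e. the measured response
#'   is the square root of the quadratic series).
#' @return An object of class `true_surface`.
#' @export
true_surface <- function(drugs, intercept = 0,
                         linear = rep(0, length(drugs)),
                         quadratic = rep(0, length(drugs)),
                         bilinear = NULL,
                         transform_exponent = 1) {
  stopifnot(length(drugs) >= 1, transform_exponent > 0)
  linear <- rep_len(as.numeric(linear), length(drugs))
  quadratic <- rep_len(as.numeric(quadratic), length(drugs))
  if (is.null(bilinear)) {
    bilinear <- data.frame(drug_a = character(), drug_b = character(),
                           coef = numeric())
  }
  stopifnot(all(c("drug_a", "drug_b", "coef") %in% names(bilinear)))
  if (nrow(bilinear)) {
    if (any(bilinear$drug_a == bilinear$drug_b)) {
      stop("bilinear pairs must be distinct drugs", call. = FALSE)
    }
    if (!all(c(bilinear$drug_a, bilinear$drug_b) %in% drugs)) {
      stop("bilinear pairs must reference listed drugs", call. = FALSE)
    }
    key <- apply(bilinear[c("drug_a", "drug_b")], 1,
                 function(p) paste(sort(p), collapse = ":"))
    if (anyDuplicated(key)) {
      stop("duplicate bilinear pair", call. = FALSE)
    }
  }
  structure(list(drugs = drugs, intercept = intercept, linear = linear,
                 quadratic = quadratic, bilinear = bilinear,
                 transform_exponent = transform_exponent),
            class = "true_surface")
}

#' Evaluate a true surface at level-code vectors
#'
#' Returns the raw (unwarped) value of the quadratic series at each run.
#'
#' @param surface a `true_surface`.
#' @param levels integer matrix or vector of level codes in `{0,1,2}`,
#'   columns ordered as `surface$drugs`, or a `combo_design`.
#' @param coding mapping of codes 0/1/2 onto the real axis.
#' @return Numeric vector, one value per run.
#' @export
eval_surface <- function(surface, levels, coding = level_coding) {
  if (inherits(levels, "combo_design")) {
    if (!identical(levels$drugs, surface$drugs)) {
      stop("design drugs do not match surface drugs", call. = FALSE)
    }
    levels <- levels$levels
  }
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1)
  if (ncol(levels) != length(surface$drugs)) {
    stop("level vectors must have one code per drug", call. = FALSE)
  }
  if (!all(levels %in% 0:2)) {
    stop("level codes must be 0, 1 or 2", call. = FALSE)
  }
  x <- matrix(coding[levels + 1L], nrow = nrow(levels))
  y <- surface$intercept +
    drop(x %*% surface$linear) +
    drop((x^2) %*% surface$quadratic)
  if (nrow(surface$bilinear)) {
    ia <- match(surface$bilinear$drug_a, surface$drugs)
    ib <- match(surface$bilinear$drug_b, surface$drugs)
    for (r in seq_len(nrow(surface$bilinear))) {
      y <- y + surface$bilinear$coef[r] * x[, ia[r]] * x[, ib[r]]
    }
  }
  y
}

# Monotone warp: the measured response y satisfies y^tau = series value,
# extended to negative series values by sign symmetry.
warp_response <- function(value, tau) {
  if (tau == 1) return(value)
  sign(value) * abs(value)^(1 / tau)
}

#' Generate a male/female pair of ground-truth surfaces
#'
#' Default parameterization mirrors the screen's qualitative structure:
#' weak monotherapy effects at L1/L2 (every single-drug L2 run evaluates
#' to at most 15 %aSMA-reduction units), one strong male-specific
#' bilinear interaction (losartan x SD-208, +30 units at both-L2), one
#' strong female-specific bilinear interaction (LY294002 x H1152,
#' +30 units), and a weak interaction shared by both sexes. The seed
#' jitters the per-drug linear and quadratic coefficients within +/- 1
#' unit so different seeds give distinct but structurally identical
#' screens.
#'
#' @param seed integer seed; identical seeds reproduce identical pairs.
#' @param drugs optional 8 drug names; defaults to the eight
#'   myofibroblast-pathway inhibitors of the screen.
#' @return A list with elements `male` and `female`, both `true_surface`
#'   objects over the same drug list.
#' @export
make_sex_pair <- function(seed,
                          drugs = c("H1152", "irosustat", "losartan",
                                    "LY294002", "SB203580", "SD208",
                                    "TM5441", "Y27632")) {
  stopifnot(length(drugs) == 8)
  with_seed(seed, {
    jitter_m <- stats::runif(16, -1, 1)
    jitter_f <- stats::runif(16, -1, 1)
    mk <- function(jit, pair, shared_pair) {
      bil <- data.frame(
        drug_a = c(pair[1], shared_pair[1]),
        drug_b = c(pair[2], shared_pair[2]),
        coef = c(30, 6))
      true_surface(drugs,
                   intercept = 2,
                   linear = 6 + jit[1:8],
                   quadratic = 4 + jit[9:16],
                   bilinear = bil,
                   transform_exponent = 1)
    }
    list(male = mk(jitter_m, c("losartan", "SD208"), c("SB203580", "Y27632")),
         female = mk(jitter_f, c("LY294002", "H1152"), c("SB203580", "Y27632")))
  })
}
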