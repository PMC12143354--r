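# Combination designs: OACD, monotherapies, full factorial, checkerboard ladders.

#' Construct a combination design object
#'
#' A `combo_design` holds one level code per drug per run. Level codes are
#' 0 (drug absent), 1 (low dose L1) and 2 (high dose L2).
#'
#' @param levels integer matrix, runs x drugs, codes in `{0, 1, 2}`.
#' @param drugs character vector of drug identifiers, one per column.
#' @param block character vector of per-run block labels
#'   (`"two_level"`, `"three_level"`, `"monotherapy"` or `"custom"`).
#' @return An object of class `combo_design` with fields `drugs`,
#'   `levels` and `block`.
#' @export
combo_design <- function(levels, drugs = colnames(levels),
                         block = rep("custom", nrow(levels))) {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  if (is.null(drugs)) drugs <- paste0("drug", seq_len(ncol(levels)))
  if (length(drugs) != ncol(levels)) {
    stop("`drugs` must name every column of `levels`", call. = FALSE)
  }
  if (!all(levels %in% 0:2)) {
    stop("level codes must be 0, 1 or 2", call. = FALSE)
  }
  if (length(block) != nrow(levels)) {
    stop("`block` must label every run", call. = FALSE)
  }
  for (b in unique(block)) {
    sub <- levels[block == b, , drop = FALSE]
    if (anyDuplicated(as.data.frame(sub)) > 0) {
      stop("duplicate runs within block '", b, "'", call. = FALSE)
    }
  }
  colnames(levels) <- drugs
  structure(list(drugs = drugs, levels = levels, block = block),
            class = "combo_design")
}

#' @export
print.combo_design <- function(x, ...) {
  cat("combo_design:", nrow(x$levels), "runs x", length(x$drugs), "drugs\n")
  cat("blocks:", paste(sprintf("%s=%d", names(table(x$block)),
                               table(x$block)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.combo_design <- function(x, ...) {
  data.frame(run_id = seq_len(nrow(x$levels)), x$levels,
             block_label = x$block, check.names = FALSE)
}

#' Combine two designs run-wise
#'
#' @param d1,d2 `combo_design` objects over the same drugs.
#' @return A `combo_design` with the runs of `d1` followed by those of `d2`.
#' @export
bind_designs <- function(d1, d2) {
  if (!identical(d1$drugs, d2$drugs)) {
    stop("designs must share the same drug list", call. = FALSE)
  }
  combo_design(rbind(d1$levels, d2$levels), d1$drugs,
               c(d1$block, d2$block))
}

# 2^(8-3) resolution-IV generators: F = ABC, G = ABD, H = BCDE.
# Shortest defining word has length 4, so no main effect is aliased
# with any two-factor interaction.
oacd_two_level_block <- function(drugs) {
  base <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5))[, 5:1])
  A <- base[, 1]; B <- base[, 2]; C <- base[, 3]
  D <- base[, 4]; E <- base[, 5]
  pm <- cbind(A, B, C, D, E, A * B * C, A * B * D, B * C * D * E)
  codes <- (pm + 1L)  # -1 -> 0, +1 -> 2
  combo_design(codes, drugs, rep("two_level", nrow(codes)))
}

# 27-run strength-2 orthogonal array: columns are pairwise linearly
# independent GF(3) combinations of the three base factors, so every
# ordered level pair occurs exactly 3 times in every column pair.
oacd_three_level_block <- function(drugs) {
  base <- as.matrix(expand.grid(c = 0:2, b = 0:2, a = 0:2))[, 3:1]
  a <- base[, 1]; b <- base[, 2]; c <- base[, 3]
  cols <- cbind(a, b, c,
                (a + b) %% 3, (a + 2 * b) %% 3,
                (a + c) %% 3, (a + 2 * c) %% 3,
                (b + c) %% 3)
  combo_design(cols, drugs, rep("three_level", nrow(cols)))
}

#' Build the orthogonal array composite design (OACD)
#'
#' Builds the 59-run design used to screen eight drugs at three dose
#' levels: a 32-run resolution-IV two-level fractional factorial (levels
#' coded 0/2, i.e. absence vs L2) stacked on a 27-run strength-2
#' three-level orthogonal array (levels 0/1/2). The construction is
#' deterministic: a fixed generator set for the two-level fraction and a
#' fixed set of eight GF(3) columns for the orthogonal array.
#'
#' @param n_factors number of drugs; only 8 is supported.
#' @param drugs optional drug names (defaults to `drug1..drug8`).
#' @return A `combo_design` with 59 runs and block labels
#'   `two_level` / `three_level`.
#' @seealso [verify_design()] for the balance, orthogonality and
#'   aliasing checks the design is expected to pass.
#' @export
#' @examples
#' d <- build_oacd(8)
#' nrow(d$levels)          # 59
#' table(d$block)          # 32 two-level + 27 three-level
build_oacd <- function(n_factors, drugs = NULL) {
  if (!identical(as.integer(n_factors), 8L)) {
    stop("unsupported factor count: the OACD is defined for 8 drugs",
         call. = FALSE)
  }
  if (is.null(drugs)) drugs <- paste0("drug", 1:8)
  if (length(drugs) != 8) stop("need 8 drug names", call. = FALSE)
  bind_designs(oacd_two_level_block(drugs), oacd_three_level_block(drugs))
}

#' Monotherapy runs
#'
#' One run per drug per nonzero level: each run has exactly one drug at
#' code 1 or 2 and all others at 0.
#'
#' @param n_drugs number of drugs (>= 1).
#' @param drugs optional drug names.
#' @return A `combo_design` with `2 * n_drugs` runs, block label
#'   `monotherapy`.
#' @export
monotherapy_runs <- function(n_drugs, drugs = NULL) {
  if (n_drugs < 1) stop("need at least one drug", call. = FALSE)
  if (is.null(drugs)) drugs <- paste0("drug", seq_len(n_drugs))
  m <- matrix(0L, 2L * n_drugs, n_drugs)
  for (i in seq_len(n_drugs)) {
    m[2L * i - 1L, i] <- 1L
    m[2L * i, i] <- 2L
  }
  combo_design(m, drugs, rep("monotherapy", nrow(m)))
}

#' Full factorial enumeration of the level space
#'
#' Enumerates every level-code combination, lexicographically ordered
#' with the first drug most significant. For 8 drugs at 3 levels this is
#' the 6561-combination space the fitted response surface is ranked
#' over.
#'
#' @param n_drugs number of drugs.
#' @param n_levels number of levels (>= 2); codes `0..n_levels-1`.
#' @param drugs optional drug names.
#' @param cap maximum number of runs allowed (guards against accidental
#'   combinatorial blow-up).
#' @return A `combo_design` with `n_levels ^ n_drugs` runs.
#' @export
full_factorial <- function(n_drugs, n_levels, drugs = NULL, cap = 1e6) {
  if (n_levels < 2) stop("need at least 2 levels", call. = FALSE)
  n_runs <- n_levels^n_drugs
  if (n_runs > cap) {
    stop("full factorial would have ", n_runs, " runs, above the cap of ",
         cap, call. = FALSE)
  }
  if (is.null(drugs)) drugs <- paste0("drug", seq_len(n_drugs))
  g <- expand.grid(rep(list(seq_len(n_levels) - 1L), n_drugs))
  m <- as.matrix(g[, rev(seq_len(n_drugs)), drop = FALSE])
  dimnames(m) <- NULL
  combo_design(m, drugs, rep("custom", n_runs))
}

#' Checkerboard dose ladder
#'
#' Six doses from 0 up to four times the L2 dose with twofold dilutions
#' between successive nonzero doses: `{0, L2/4, L2/2, L2, 2*L2, 4*L2}`.
#'
#' @param l2_dose the L2 concentration (> 0), in the same units the
#'   ladder should be expressed in (typically uM).
#' @param drug optional drug identifier carried along in the result.
#' @return A list of class `dose_ladder` with fields `drug` and `doses`.
#' @export
checkerboard_ladder <- function(l2_dose, drug = NA_character_) {
  if (!is.numeric(l2_dose) || length(l2_dose) != 1 || l2_dose <= 0) {
    stop("`l2_dose` must be a single positive concentration", call. = FALSE)
  }
  doses <- l2_dose * c(0, 1 / 4, 1 / 2, 1, 2, 4)
  structure(list(drug = drug, doses = doses), class = "dose_ladder")
}

#' Validate a design's balance, orthogonality and aliasing structure
#'
#' Report-only checks of the properties the screening design relies on:
#' per-column level balance, strength-2 orthogonality (for every column
#' pair, all ordered level pairs equally frequent), and -- for two-level
#' blocks -- resolution-IV aliasing (no main-effect column equal to plus
#' or minus the elementwise product of two other columns).
#'
#' @param design a `combo_design`.
#' @return A list of class `design_report`: `balance` (per-column level
#'   counts), `orthogonality_violations` (column pairs failing the
#'   equal-frequency check), `aliased` (main effect / interaction pairs
#'   found aliased in two-level columns), and logical summary flags
#'   `balanced`, `strength2`, `resolution_iv`.
#' @export
verify_design <- function(design) {
  lev <- design$levels
  k <- ncol(lev)
  balance <- lapply(seq_len(k), function(j) table(lev[, j]))
  names(balance) <- design$drugs
  balanced <- all(vapply(balance, function(tb) length(unique(tb)) == 1L,
                         logical(1)))

  viol <- list()
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        tb <- table(lev[, i], lev[, j])
        if (length(unique(as.vector(tb))) != 1L) {
          viol[[length(viol) + 1L]] <- c(design$drugs[i], design$drugs[j])
        }
      }
    }
  }

  # Resolution-IV check on columns taking exactly two levels: recode to
  # +/-1 and compare each column with every two-column product.
  aliased <- list()
  two_lev <- which(vapply(seq_len(k), function(j)
    length(unique(lev[, j])) == 2L, logical(1)))
  if (length(two_lev) >= 3) {
    pm <- lev[, two_lev, drop = FALSE]
    pm <- apply(pm, 2, function(col) {
      u <- sort(unique(col))
      ifelse(col == u[1], -1, 1)
    })
    nt <- ncol(pm)
    for (m in seq_len(nt)) {
      for (i in seq_len(nt - 1)) {
        for (j in (i + 1):nt) {
          if (m == i || m == j) next
          prod_ij <- pm[, i] * pm[, j]
          if (all(pm[, m] == prod_ij) || all(pm[, m] == -prod_ij)) {
            aliased[[length(aliased) + 1L]] <-
              c(main = design$drugs[two_lev[m]],
                int_a = design$drugs[two_lev[i]],
                int_b = design$drugs[two_lev[j]])
          }
        }
      }
    }
  }

  structure(list(balance = balance,
                 orthogonality_violations = viol,
                 aliased = aliased,
                 balanced = balanced,
                 strength2 = length(viol) == 0L,
                 resolution_iv = length(aliased) == 0L),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("design report:\n")
  cat("  balanced columns:        ", x$balanced, "\n")
  cat("  strength-2 orthogonality:", x$strength2,
      sprintf("(%d violating column pairs)\n",
              length(x$orthogonality_violations)))
  cat("  resolution IV:           ", x$resolution_iv,
      sprintf("(%d aliased main effects)\n", length(x$aliased)))
  invisible(x)
}
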