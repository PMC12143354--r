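# CSV/JSON interchange and end-to-end pipeline orchestration.
# All tables are plain UTF-8 CSV with a header row and '.' decimals.

read_pipeline_csv <- function(path, required_cols, numeric_cols = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    stop("empty input file: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    stop("empty input: ", path, " has a header but no rows",
         call. = FALSE)
  }
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), " (line 1)", call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      hint <- if (any(grepl(",", df[[col]], fixed = TRUE))) {
        " (',' decimals are not accepted; use '.')"
      } else ""
      stop("column '", col, "' in ", path,
           " is not numeric at data line ", bad, hint, call. = FALSE)
    }
  }
  df
}

write_pipeline_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write and read a combination design as CSV
#'
#' Columns: `run_id`, one level-code column per drug, `block_label`.
#'
#' @param design a `combo_design`.
#' @param path CSV file path.
#' @return `write_design_csv` returns the path invisibly;
#'   `read_design_csv` returns a `combo_design`.
#' @export
write_design_csv <- function(design, path) {
  write_pipeline_csv(as.data.frame(design), path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- read_pipeline_csv(path, c("run_id", "block_label"))
  drug_cols <- setdiff(names(df), c("run_id", "block_label"))
  lev <- as.matrix(df[drug_cols])
  if (!is.numeric(lev) || !all(lev %in% 0:2)) {
    stop("level columns in ", path, " must be codes 0/1/2",
         call. = FALSE)
  }
  combo_design(lev, drug_cols, df$block_label)
}

#' Read a dose-response table
#'
#' Expects columns `drug`, `sex`, `dose_uM`, `replicate`,
#' `response_pct` as written by [simulate_monotherapy()].
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_dose_response_csv <- function(path) {
  read_pipeline_csv(path, c("drug", "dose_uM", "replicate",
                            "response_pct"),
                    numeric_cols = c("dose_uM", "response_pct"))
}

#' Read a design-response table
#'
#' Expects one level-code column per drug plus `replicate` and
#' `response_pct` as written by [simulate_design_responses()].
#'
#' @param path CSV file path.
#' @param drugs character vector naming the level-code columns.
#' @return Data frame.
#' @export
read_design_response_csv <- function(path, drugs) {
  read_pipeline_csv(path, c(drugs, "response_pct"),
                    numeric_cols = c(drugs, "response_pct"))
}

#' Read a checkerboard table
#'
#' Expects columns `dose_a_uM`, `dose_b_uM`, `response_pct` and
#' optionally `replicate`.
#'
#' @param path CSV file path.
#' @return Data frame accepted by [score_checkerboard()].
#' @export
read_checkerboard_csv <- function(path) {
  read_pipeline_csv(path, c("dose_a_uM", "dose_b_uM", "response_pct"),
                    numeric_cols = c("dose_a_uM", "dose_b_uM",
                                     "response_pct"))
}

#' Read and validate a pipeline run configuration
#'
#' The JSON configuration lists the drugs (name, clinical `cmax`, 4PL
#' curve parameters per sex), the master seed, the noise model, the
#' stepwise thresholds, the Box-Cox candidate grid and the output
#' directory. Validation happens up front so a malformed configuration
#' fails before any stage runs.
#'
#' @param path JSON file path, or a list already parsed.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else
    jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("drugs", "seed", "out_dir")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) {
    stop("config validation error: missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  drugs <- cfg$drugs
  if (is.data.frame(drugs)) {
    drugs <- split(drugs, seq_len(nrow(drugs)))
    drugs <- lapply(drugs, as.list)
  }
  for (d in drugs) {
    if (is.null(d$name) || is.null(d$cmax) || !is.numeric(d$cmax) ||
        d$cmax <= 0) {
      stop("config validation error: every drug needs a name and a ",
           "positive cmax", call. = FALSE)
    }
  }
  cfg$drugs <- drugs
  if (is.null(cfg$well_sd)) cfg$well_sd <- 10
  if (is.null(cfg$replicates)) cfg$replicates <- 3
  if (is.null(cfg$p_enter)) cfg$p_enter <- 0.05
  if (is.null(cfg$p_remove)) cfg$p_remove <- 0.10
  if (is.null(cfg$lambda_grid)) cfg$lambda_grid <- c(-1, -0.5, 0, 0.5, 1, 2)
  if (is.null(cfg$deadband)) cfg$deadband <- 5
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

stage_seed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2147483647L

#' Run the full in-silico combination-optimization pipeline
#'
#' Orchestrates the workflow end to end on synthetic data: ground-truth
#' male/female surfaces, dose-response fitting and L1/L2 level
#' selection per drug and sex, OACD + monotherapy design, design
#' response simulation, response-surface fitting with transform
#' selection, exhaustive ranking, candidate and negative-control
#' selection, sex-bias differencing, and checkerboard synergy scoring
#' of each sex's planted interaction pair. All stage outputs are
#' written as CSV under the configured output directory together with a
#' JSON manifest recording seeds, parameters and content hashes, so a
#' rerun with the same configuration is byte-identical.
#'
#' @param config path to a JSON configuration, or a list; see
#'   [read_run_config()].
#' @return The manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  drug_names <- vapply(cfg$drugs, `[[`, character(1), "name")
  n_drugs <- length(drug_names)
  stopifnot(n_drugs == 8)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_pipeline_csv(df, path)
    files <<- c(files, path)
    path
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # stage 1: ground truth ------------------------------------------------
  pair <- run_stage("ground_truth",
                    make_sex_pair(stage_seed(cfg$seed, 1L),
                                  drugs = drug_names))

  # stage 2: dose-response and level selection ---------------------------
  levels_tab <- NULL
  curves_tab <- NULL
  run_stage("dose_response", {
    rows <- list(); crows <- list(); k <- 0L
    for (sex in c("male", "female")) {
      for (i in seq_along(cfg$drugs)) {
        d <- cfg$drugs[[i]]
        curve_true <- list(top = d$top %||% 90,
                           ec50 = d$ec50 %||% (0.2 * d$cmax),
                           hill = d$hill %||% 1.2)
        doses <- curve_true$ec50 * 10^seq(-2, 2, length.out = 8)
        nm <- noise_model(cfg$well_sd, cfg$replicates,
                          stage_seed(cfg$seed, 10L + 16L * (sex == "female") + i))
        dat <- simulate_monotherapy(curve_true, doses, nm,
                                    drug = d$name, sex = sex)
        fit <- fit_4pl(dat$dose_uM, dat$response_pct, drug = d$name,
                       sex = sex)
        ec <- function(f) tryCatch(absolute_ec(fit, f),
                                   error = function(e) NA_real_)
        # unreachable ECs never bind the min rule
        ec_bound <- function(f) { v <- ec(f); if (is.na(v)) Inf else v }
        cc50 <- 5 * d$cmax  # cytotoxicity well above the tested range
        lv <- select_levels(ec1 = ec_bound(1), cc1 = 0.05 * cc50,
                            ec2 = ec_bound(2), cc2 = 0.10 * cc50,
                            info = drug_info(d$name, d$cmax))
        k <- k + 1L
        crows[[k]] <- data.frame(drug = d$name, sex = sex,
                                 top = fit$top, ec50 = fit$ec50,
                                 hill = fit$hill, ec1 = ec(1),
                                 ec2 = ec(2), ec20 = ec(20))
        rows[[k]] <- data.frame(drug = d$name, sex = sex,
                                l1_uM = lv$l1, l2_uM = lv$l2,
                                l1_bound = lv$l1_bound,
                                l2_bound = lv$l2_bound)
      }
    }
    curves_tab <- do.call(rbind, crows)
    levels_tab <- do.call(rbind, rows)
    emit(curves_tab, "curves.csv")
    emit(levels_tab, "levels.csv")
  })

  # stage 3: design -------------------------------------------------------
  design <- run_stage("design", {
    d <- bind_designs(build_oacd(8, drugs = drug_names),
                      monotherapy_runs(8, drugs = drug_names))
    emit(as.data.frame(d), "design.csv")
    d
  })

  # stages 4-7 per sex -----------------------------------------------------
  ranked <- list()
  for (sex in c("male", "female")) {
    surface <- pair[[sex]]
    nm <- noise_model(cfg$well_sd, cfg$replicates,
                      stage_seed(cfg$seed, 100L + (sex == "female")))
    resp <- run_stage(paste0("simulate_", sex), {
      r <- simulate_design_responses(surface, design, nm)
      emit(r, paste0("responses_", sex, ".csv"))
      r
    })
    fit <- run_stage(paste0("fit_surface_", sex), {
      m <- fit_surface(as.matrix(resp[drug_names]), resp$response_pct,
                       p_enter = cfg$p_enter, p_remove = cfg$p_remove,
                       candidate_lambdas = cfg$lambda_grid)
      emit(data.frame(term = names(m$coefficients),
                      coefficient = unname(m$coefficients),
                      p_value = unname(m$p_values)),
           paste0("coefficients_", sex, ".csv"))
      m
    })
    ranked[[sex]] <- run_stage(paste0("rank_", sex), {
      rk <- predict_all(fit)
      emit(rk, paste0("ranked_", sex, ".csv"))
      tops <- do.call(rbind, lapply(2:4, function(k)
        top_k_by_drug_count(rk, k, 3)))
      ctrl <- bottom_controls(rk, 2, 2)
      emit(rbind(cbind(role = "candidate", tops),
                 cbind(role = "control", ctrl)),
           paste0("candidates_", sex, ".csv"))
      rk
    })
  }

  # stage 8: sex bias ------------------------------------------------------
  run_stage("sex_bias", {
    sb <- sex_bias_table(ranked$male, ranked$female,
                         deadband = cfg$deadband)
    emit(sb, "sex_bias.csv")
  })

  # stage 9: checkerboard synergy ------------------------------------------
  run_stage("synergy", {
    planted <- list(male = c("losartan", "SD208"),
                    female = c("LY294002", "H1152"))
    for (sex in c("male", "female")) {
      pr <- planted[[sex]]
      if (!all(pr %in% drug_names)) pr <- drug_names[1:2]
      lv <- levels_tab[levels_tab$sex == sex, ]
      l2 <- stats::setNames(lv$l2_uM, lv$drug)
      curves <- lapply(pr, function(dn) {
        ct <- curves_tab[curves_tab$drug == dn & curves_tab$sex == sex, ]
        list(top = ct$top, ec50 = ct$ec50, hill = ct$hill)
      })
      nm <- noise_model(cfg$well_sd, cfg$replicates,
                        stage_seed(cfg$seed, 200L + (sex == "female")))
      cb <- simulate_checkerboard(
        curves[[1]], curves[[2]],
        planted_bliss_excess = if (sex == "male") 20 else 20,
        ladderA = checkerboard_ladder(l2[pr[1]]),
        ladderB = checkerboard_ladder(l2[pr[2]]),
        noise = nm)
      emit(cb, paste0("checkerboard_", sex, ".csv"))
      emit(as.data.frame(score_checkerboard(cb)),
           paste0("synergy_", sex, ".csv"))
    }
  })

  manifest <- list(
    seed = cfg$seed,
    parameters = list(well_sd = cfg$well_sd,
                      replicates = cfg$replicates,
                      p_enter = cfg$p_enter, p_remove = cfg$p_remove,
                      lambda_grid = cfg$lambda_grid,
                      deadband = cfg$deadband),
    stage_order = c("ground_truth", "dose_response", "design",
                    "simulate", "fit_surface", "rank", "sex_bias",
                    "synergy"),
    outputs = lapply(files, function(f)
      list(file = basename(f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
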