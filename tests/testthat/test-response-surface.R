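test_that("the full second-order basis expands as expected", {
  d <- build_oacd(8)
  X <- expand_terms(d)
  expect_equal(ncol(X), 45)  # 1 + 8 + 8 + choose(8, 2)
  drugs <- d$drugs
  # all-L0 run
  all0 <- expand_terms(combo_design(matrix(0L, 1, 8), drugs))
  expect_equal(unname(all0[1, ]), c(1, rep(0, 44)))
  # two drugs at code 1 (coded 0.5): bilinear column is 0.25
  lv <- matrix(0L, 1, 8); lv[1, 1:2] <- 1L
  row <- expand_terms(combo_design(lv, drugs))
  expect_equal(unname(row[1, paste0(drugs[1], ":", drugs[2])]), 0.25)
  expect_equal(unname(row[1, drugs[1]]), 0.5)
  expect_equal(unname(row[1, paste0(drugs[1], "^2")]), 0.25)
})

test_that("Box-Cox selection recovers the generating exponent", {
  d <- screen_design(paste0("d", 1:8))
  X <- expand_terms(d)
  surf_lin <- 5 + 10 * rowSums(matrix(level_coding[d$levels + 1L],
                                      nrow = nrow(d$levels)))
  # responses are the square root of a linear surface: square law
  expect_equal(boxcox_select(X, sqrt(surf_lin),
                             c(0.5, 1, 2))$lambda, 2)
  # responses already linear: identity is exact
  expect_equal(boxcox_select(X, surf_lin)$lambda, 1)
  expect_warning(out <- boxcox_select(X, rep(7, nrow(X))),
                 "degenerate")
  expect_equal(out$lambda, 1)
  expect_error(boxcox_select(X, surf_lin, numeric(0)), "empty")
})

test_that("Box-Cox profile likelihood matches the MASS oracle", {
  skip_if_not_installed("MASS")
  d <- screen_design(paste0("d", 1:8))
  X <- expand_terms(d)
  set.seed(21)
  y <- (20 + 5 * X[, "d1"] + 30 * X[, "d2:d3"] + rnorm(nrow(X), 0, 2))^2
  grid <- c(0.25, 0.5, 1, 2)
  ours <- boxcox_select(X, y, grid)
  mass <- MASS::boxcox(stats::lm(y ~ X - 1, y = TRUE, qr = TRUE),
                       lambda = grid, plotit = FALSE)
  expect_equal(grid[which.max(ours$loglik)], mass$x[which.max(mass$y)])
  # log-likelihood curves agree up to an additive constant
  expect_lt(diff(range((ours$loglik - max(ours$loglik)) -
                         (mass$y - max(mass$y)))), 1e-6)
})

test_that("stepwise regression recovers a sparse noiseless truth exactly", {
  d <- screen_design()
  X <- expand_terms(d)
  y <- 2 + 3 * X[, std_drugs[1]] -
    4 * X[, paste0(std_drugs[2], ":", std_drugs[3])]
  fit <- stepwise_fit(X, y)
  expect_setequal(names(fit$coefficients),
                  c("(Intercept)", std_drugs[1],
                    paste0(std_drugs[2], ":", std_drugs[3])))
  # oracle: least squares on the true support
  oracle <- qr.solve(X[, names(fit$coefficients)], y)
  expect_equal(fit$coefficients[names(oracle)], oracle,
               tolerance = 1e-6)
  expect_equal(fit$adj_r2, 1)
})

test_that("stepwise selection is invariant to row order", {
  d <- screen_design()
  X <- expand_terms(d)
  set.seed(31)
  y <- 10 + 25 * X[, paste0(std_drugs[1], ":", std_drugs[4])] +
    rnorm(nrow(X), 0, 5)
  f1 <- stepwise_fit(X, y)
  perm <- sample(nrow(X))
  f2 <- stepwise_fit(X[perm, ], y[perm])
  expect_identical(sort(names(f1$coefficients)),
                   sort(names(f2$coefficients)))
  expect_equal(f1$coefficients[sort(names(f1$coefficients))],
               f2$coefficients[sort(names(f2$coefficients))])
})

test_that("stepwise false selections under the null are rare", {
  # Monte-Carlo null oracle: with 44 candidate terms and p_enter=0.05,
  # naive forward selection admits about 44 * 0.05 = 2.2 terms; the
  # removal pass can only prune, so the observed mean must be positive
  # and not exceed that bound by more than Monte-Carlo error.
  d <- screen_design()
  X <- expand_terms(d)
  counts <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    y <- rnorm(nrow(X), 0, 10)
    length(stepwise_fit(X, y)$coefficients) - 1L
  }, integer(1))
  expect_gt(mean(counts), 0)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(mean(counts), 44 * 0.05 + 3 * se)
})

test_that("adjusted R-squared follows its definition", {
  # hand-computed: n=4, p=2, SSE=2, SST=10 -> 1 - (2/2)/(10/3) = 0.7
  expect_equal(adjusted_r2(list(sse = 2, sst = 10, n = 4, p = 2)), 0.7)
  d <- screen_design()
  X <- expand_terms(d)
  y <- 5 + 2 * X[, std_drugs[5]]
  expect_equal(adjusted_r2(stepwise_fit(X, y)), 1)
  # intercept-only model: SSE = SST by definition, adj R^2 = 0
  expect_equal(adjusted_r2(list(sse = 10, sst = 10, n = 5, p = 1)), 0)
  expect_error(adjusted_r2(list(sse = 1, sst = 10, n = 3, p = 3)),
               "n > number of terms")
})

test_that("outlier scan flags a single corrupted run and nothing else", {
  d <- screen_design()
  X <- expand_terms(d)
  set.seed(51)
  y <- 10 + 20 * X[, paste0(std_drugs[1], ":", std_drugs[2])] +
    rnorm(nrow(X), 0, 3)
  fit <- stepwise_fit(X, y)
  expect_length(outlier_scan(fit)$flagged, 0)
  y2 <- y
  y2[17] <- y2[17] + 100  # +10 well-SD perturbation at well_sd = 10
  fit2 <- stepwise_fit(X, y2)
  scan2 <- outlier_scan(fit2)
  expect_true(17 %in% scan2$flagged)
  expect_length(outlier_scan(fit2, threshold = Inf)$flagged, 0)
  # clean noiseless fit: residuals identically zero, nothing flagged
  fit3 <- stepwise_fit(X, 1 + 2 * X[, std_drugs[1]])
  expect_length(outlier_scan(fit3)$flagged, 0)
  # refitting after removing zero flagged outliers is a no-op
  expect_equal(stepwise_fit(X, y)$coefficients, fit$coefficients)
})

test_that("transform round trip reproduces noiseless training data", {
  drugs <- paste0("d", 1:8)
  surf <- true_surface(drugs, intercept = 4, linear = rep(8, 8),
                       quadratic = rep(2, 8),
                       bilinear = data.frame(drug_a = "d1",
                                             drug_b = "d2", coef = 25),
                       transform_exponent = 2)
  d <- screen_design(drugs)
  resp <- simulate_design_responses(surf, d, noise_model(0, 1, 1))
  X <- expand_terms(as.matrix(resp[drugs]))
  fit <- stepwise_fit(X, resp$response_pct, lambda = 2)
  pred <- predict(fit, as.matrix(resp[drugs]))
  expect_equal(pred, resp$response_pct, tolerance = 1e-6)
})

test_that("fit_surface chains transform selection into the stepwise fit", {
  drugs <- paste0("d", 1:8)
  surf <- true_surface(drugs, intercept = 4, linear = rep(8, 8),
                       quadratic = rep(2, 8),
                       bilinear = data.frame(drug_a = "d3",
                                             drug_b = "d7", coef = 25),
                       transform_exponent = 2)
  d <- screen_design(drugs)
  resp <- simulate_design_responses(surf, d, noise_model(0, 1, 1))
  fit <- fit_surface(as.matrix(resp[drugs]), resp$response_pct,
                     candidate_lambdas = c(0.5, 1, 2))
  expect_equal(fit$lambda, 2)
  expect_equal(unname(fit$coefficients["d3:d7"]), 25, tolerance = 1e-6)
})

test_that("stepwise preconditions are enforced", {
  X <- cbind("(Intercept)" = rep(1, 10), a = rnorm(10))
  expect_error(stepwise_fit(X[1:2, ], rnorm(2)), "at least 3 rows")
  expect_error(stepwise_fit(X, rnorm(10), p_enter = 0.2,
                            p_remove = 0.1), "p_enter")
})
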