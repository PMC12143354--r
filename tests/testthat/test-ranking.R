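# A minimal fitted-model stand-in for ranking tests: intercept plus one
# linear term over a small drug set, on an arbitrary transform scale.
toy_model <- function(drugs, coefs, lambda = 1, shift = 0) {
  basis <- term_basis(drugs)
  sel <- match(names(coefs), basis$label)
  structure(list(drugs = drugs, terms = basis[sel, ],
                 coefficients = coefs, p_values = coefs * NA,
                 lambda = lambda, shift = shift, labels = names(coefs)),
            class = "quad_model")
}

test_that("predict_all ranks the full space as a permutation", {
  p <- make_sex_pair(2)
  d <- screen_design(p$male$drugs)
  resp <- simulate_design_responses(p$male, d, noise_model(10, 3, 12))
  fit <- fit_surface(as.matrix(resp[p$male$drugs]), resp$response_pct)
  rk <- predict_all(fit)
  expect_equal(nrow(rk), 6561)
  expect_equal(sort(rk$rank), 1:6561)
  keys <- do.call(paste, c(as.data.frame(rk[p$male$drugs]), sep = "."))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(rk$predicted_pct >= 0))
  expect_true(all(diff(rk$predicted_pct) <= 1e-12))
})

test_that("negative transformed predictions are clamped to zero efficacy", {
  expect_equal(back_transform(-4, 2), 0)
  expect_equal(back_transform(4, 2), 2)
  expect_equal(back_transform(c(-1, 0, 9), 2), c(0, 0, 3))
  # a model that predicts negative transformed values at L0
  m <- toy_model(c("a", "b"), c("(Intercept)" = -4, "a" = 100),
                 lambda = 2)
  rk <- predict_all(m, full_factorial(2, 3, drugs = c("a", "b")))
  expect_equal(min(rk$predicted_pct), 0)
  expect_true(all(rk$predicted_pct[rk$a == 0] == 0))
})

test_that("ties are broken lexicographically by level vector", {
  m <- toy_model(c("a", "b"), c("(Intercept)" = 10))
  rk <- predict_all(m, full_factorial(2, 3, drugs = c("a", "b")))
  expect_true(all(rk$predicted_pct == 10))
  expect_equal(rk$a, rep(0:2, each = 3))
  expect_equal(rk$b, rep(0:2, 3))
})

test_that("top-k selection filters by drug count", {
  p <- make_sex_pair(2)
  d <- screen_design(p$male$drugs)
  resp <- simulate_design_responses(p$male, d, noise_model(10, 3, 12))
  fit <- fit_surface(as.matrix(resp[p$male$drugs]), resp$response_pct)
  rk <- predict_all(fit)
  cand <- lapply(2:4, function(k) top_k_by_drug_count(rk, k, 3))
  expect_equal(sum(vapply(cand, nrow, integer(1))), 9)
  for (i in seq_along(cand)) {
    expect_true(all(cand[[i]]$n_drugs == i + 1))
    expect_equal(nrow(cand[[i]]), 3)
  }
  # requesting more than exist returns all with a warning
  expect_warning(out <- top_k_by_drug_count(rk[rk$n_drugs == 2, ][1:2, ],
                                            2, 5), "only 2")
  expect_equal(nrow(out), 2)
})

test_that("bottom controls are ineffective multi-drug combinations", {
  p <- make_sex_pair(2)
  d <- screen_design(p$male$drugs)
  resp <- simulate_design_responses(p$male, d, noise_model(10, 3, 12))
  fit <- fit_surface(as.matrix(resp[p$male$drugs]), resp$response_pct)
  rk <- predict_all(fit)
  ctrl <- bottom_controls(rk, 2, 2)
  expect_equal(nrow(ctrl), 2)
  expect_true(all(ctrl$n_drugs >= 2))
  tops <- top_k_by_drug_count(rk, 2, 3)
  expect_true(all(ctrl$predicted_pct <= min(tops$predicted_pct)))
  expect_error(bottom_controls(rk, 0), "at least 1")
})

test_that("sex-bias differencing is aligned, signed and classified", {
  m1 <- toy_model(c("a", "b"), c("(Intercept)" = 10, "a" = 20))
  m2 <- toy_model(c("a", "b"), c("(Intercept)" = 10))
  sp <- full_factorial(2, 3, drugs = c("a", "b"))
  r1 <- predict_all(m1, sp); r2 <- predict_all(m2, sp)
  # identical models: all differences zero, neutral
  sb0 <- sex_bias_table(r1, r1)
  expect_true(all(sb0$difference == 0))
  expect_true(all(sb0$bias_class == "neutral"))
  # antisymmetry under swapping the sexes
  sb <- sex_bias_table(r1, r2)
  sb_swapped <- sex_bias_table(r2, r1)
  key <- function(x) paste(x$a, x$b)
  idx <- match(key(sb), key(sb_swapped))
  expect_equal(sb$difference, -sb_swapped$difference[idx])
  # classification matches the sign rule outside the deadband
  expect_true(all(sb$bias_class[sb$difference > 5] == "male_biased"))
  expect_true(all(sb$bias_class[abs(sb$difference) <= 5] == "neutral"))
  # mismatched spaces are rejected
  r3 <- predict_all(toy_model("a", c("(Intercept)" = 1)),
                    full_factorial(1, 3, drugs = "a"))
  expect_error(sex_bias_table(r1, r3), "alignment")
})

test_that("the planted male interaction surfaces in the male-biased top decile", {
  p <- make_sex_pair(6)
  d <- screen_design(p$male$drugs)
  fits <- lapply(p, function(s) {
    resp <- simulate_design_responses(s, d, noise_model(0, 1, 1))
    stepwise_fit(expand_terms(as.matrix(resp[s$drugs])),
                 resp$response_pct)
  })
  sb <- sex_bias_table(predict_all(fits$male), predict_all(fits$female))
  lv <- rep(0L, 8)
  lv[match(c("losartan", "SD208"), p$male$drugs)] <- 2L
  key <- do.call(paste, c(as.list(lv), sep = "."))
  keys <- do.call(paste, c(as.data.frame(sb[p$male$drugs]), sep = "."))
  expect_lte(which(keys == key), ceiling(0.1 * nrow(sb)))
})

test_that("ranking is preserved under the monotone back-transform", {
  p <- make_sex_pair(2)
  d <- screen_design(p$male$drugs)
  resp <- simulate_design_responses(p$male, d, noise_model(10, 3, 12))
  X <- expand_terms(as.matrix(resp[p$male$drugs]))
  fit <- stepwise_fit(X, pmax(resp$response_pct, 0.1)^2, lambda = 2)
  sp <- full_factorial(8, 3, drugs = p$male$drugs)
  w <- predict(fit, sp, transformed = TRUE)
  y <- predict(fit, sp)
  pos <- w > 0
  expect_equal(order(-w[pos]), order(-y[pos]))
})

test_that("prediction validation reports correlation and line", {
  v <- validate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(v$r, 1)
  v2 <- validate_predictions(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(v2$r, -1)
  v3 <- validate_predictions(c(1, 2, 3), c(2, 4, 6))
  expect_equal(v3$r, 1)
  expect_equal(v3$slope, 2)
  expect_equal(v3$intercept, 0)
  expect_error(validate_predictions(1:2, 1:2), "length >= 3")
})
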