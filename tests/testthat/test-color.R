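# Trait-prediction models: compared OLS specs, random forest, trait
# correlations

synth_color_blues <- function(n_per_fam = 60, n_fam = 8, seed = 1,
                              beta = c(zea = 1, lut = 0.2, bcar = 0.6),
                              fam_sd = 1, noise_sd = 0.5) {
  set.seed(seed)
  fam <- rep(sprintf("F%02d", seq_len(n_fam)), each = n_per_fam)
  n <- length(fam)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, names(beta)))
  fam_off <- rnorm(n_fam, 0, fam_sd)[as.integer(factor(fam))]
  y <- drop(X %*% beta) + fam_off + rnorm(n, 0, noise_sd)
  data.frame(family = fam, kcol = y, X)
}

test_that("a duplicated response as sole predictor gives R2 = 1", {
  d <- synth_color_blues()
  d$self <- d$kcol
  cmp <- compare_linear_models(d, "kcol",
                               list(self = list(predictors = "self")))
  expect_equal(cmp$r2, 1)
})

test_that("pure-noise predictors explain essentially nothing", {
  set.seed(3)
  d <- synth_color_blues(n_per_fam = 110, n_fam = 8, beta = c(zea = 0, lut = 0, bcar = 0),
                         fam_sd = 0, noise_sd = 1)
  cmp <- compare_linear_models(d, "kcol",
                               list(noise = list(predictors = c("zea", "lut", "bcar"))))
  expect_lte(cmp$r2, 0.02)
})

test_that("a real family term wins the BIC comparison almost always", {
  wins <- vapply(1:20, function(s) {
    d <- synth_color_blues(seed = 100 + s, fam_sd = 1)
    cmp <- compare_linear_models(
      d, "kcol",
      list(with_fam = list(predictors = c("zea", "lut", "bcar"), family = TRUE),
           no_fam = list(predictors = c("zea", "lut", "bcar"), family = FALSE)))
    cmp$bic[cmp$model == "with_fam"] < cmp$bic[cmp$model == "no_fam"]
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("train R2 of a nested OLS sub-model never exceeds the full model", {
  d <- synth_color_blues(seed = 7)
  cmp <- compare_linear_models(
    d, "kcol",
    list(full = list(predictors = c("zea", "lut", "bcar"), family = TRUE),
         sub1 = list(predictors = c("zea", "lut"), family = TRUE),
         sub2 = list(predictors = "zea", family = FALSE)))
  expect_true(cmp$r2[1] >= cmp$r2[2] && cmp$r2[2] >= cmp$r2[3])
})

test_that("rank deficiency is reported per spec without failing the batch", {
  d <- synth_color_blues(seed = 9)
  d$dup <- d$zea
  expect_warning(
    cmp <- compare_linear_models(
      d, "kcol", list(ok = list(predictors = "zea"),
                      bad = list(predictors = c("zea", "dup")))),
    "rank")
  expect_equal(nrow(cmp), 2)
  expect_true(cmp$rank_deficient[cmp$model == "bad"])
})

test_that("both learners master exactly linear noiseless data", {
  d <- synth_color_blues(seed = 11, fam_sd = 0, noise_sd = 1e-9)
  rf <- fit_random_forest(d, "kcol", c("zea", "lut", "bcar"),
                          include_family = FALSE, n_trees = 300,
                          seeds = 1:2)
  expect_gte(rf$summary[["r2_lm"]], 0.99)
  expect_gte(rf$summary[["r2_rf"]], 0.85)   # forests cannot extrapolate a
                                            # hyperplane perfectly
  expect_equal(sum(rf$importance), 1, tolerance = 1e-9)
})

test_that("a constant feature receives (near) zero importance and the dominant one ranks first", {
  d <- synth_color_blues(seed = 13, beta = c(zea = 2, lut = 0.1, bcar = 0.3),
                         fam_sd = 0.2, noise_sd = 0.4)
  d$flat <- 1
  firsts <- vapply(1:5, function(s) {
    rf <- fit_random_forest(d, "kcol", c("zea", "lut", "bcar", "flat"),
                            include_family = FALSE, n_trees = 300,
                            seeds = s)
    imp <- rf$importance
    expect_lt(imp[["flat"]], 0.02)
    names(which.max(imp))
  }, "")
  expect_gte(mean(firsts == "zea"), 0.9)
})

test_that("seed-averaged metrics stabilize as seeds accumulate", {
  d <- synth_color_blues(seed = 17)
  r5 <- replicate(4, {
    sds <- sample.int(1e5, 5)
    fit_random_forest(d, "kcol", c("zea", "lut", "bcar"), n_trees = 150,
                      seeds = sds)$summary[["r2_rf"]]
  })
  r20 <- replicate(4, {
    sds <- sample.int(1e5, 20)
    fit_random_forest(d, "kcol", c("zea", "lut", "bcar"), n_trees = 150,
                      seeds = sds)$summary[["r2_rf"]]
  })
  expect_lt(sd(r20), sd(r5) + 0.02)   # shrinking (allowing sampling slack)
})

test_that("trait correlations behave at the trivial and distributional level", {
  d <- synth_color_blues(seed = 19)
  R <- trait_correlation_matrix(cbind(d, neg = -d$kcol),
                                c("kcol", "zea", "neg"))
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_equal(R["kcol", "neg"], -1)
  expect_equal(R, t(R))

  set.seed(21)
  n <- 1600
  z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, 0.7, 0.7, 1), 2))
  d2 <- data.frame(a = z[, 1], b = z[, 2])
  R2 <- trait_correlation_matrix(d2, c("a", "b"))
  expect_gt(R2["a", "b"], 0.66)
  expect_lt(R2["a", "b"], 0.74)

  d3 <- data.frame(a = rnorm(10), b = 1)
  expect_true(is.na(trait_correlation_matrix(d3, c("a", "b"))["a", "b"]))
})
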