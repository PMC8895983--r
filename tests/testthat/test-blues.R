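# DFFITS screening, BLUE extraction, Box-Cox, heritability

test_that("an injected gross outlier is flagged and clean data barely is", {
  pl <- one_way_plots(50, 3, s2g = 1, s2e = 1, seed = 5)
  structure_sel <- list(random = "ril", residual = "idh_year")
  vc_fit <- fit_mixed(pl, "t", random = "ril", residual = "idh_year")
  mk_line_fit <- function(plots) {
    fit_mixed(plots, "t", random = "ril", residual = "idh_year",
              fixed = "lines",
              vc = list(vc = vc_fit$vc, residual = as.list(vc_fit$residual)))
  }
  # clean data, conservative threshold: at most 1% flagged
  flags0 <- flag_outliers(mk_line_fit(pl), threshold = 3)
  expect_lte(nrow(flags0), ceiling(0.01 * nrow(pl)))

  pl_bad <- pl
  shift <- 10 * sd(pl$value)
  pl_bad$value[37] <- pl_bad$value[37] + shift
  flags <- flag_outliers(mk_line_fit(pl_bad), threshold = 3)
  expect_true(pl_bad$ril[37] %in% flags$ril)

  # threshold = Inf flags nothing; non-positive thresholds rejected
  expect_equal(nrow(flag_outliers(mk_line_fit(pl_bad), threshold = Inf)), 0)
  expect_error(flag_outliers(mk_line_fit(pl), threshold = 0), "positive")
})

test_that("outlier removal touches only the flagged trait's records", {
  pl <- rbind(one_way_plots(10, 2, 1, 1, seed = 6),
              transform(one_way_plots(10, 2, 1, 1, seed = 7), trait = "u"))
  flags <- data.frame(ril = "L003", year = 2009, field = "f1", row = 3,
                      range = 1, trait = "t")
  out <- remove_outliers(pl, flags)
  expect_true(is.na(out$value[out$trait == "t" & out$ril == "L003" &
                              out$range == 1]))
  expect_false(anyNA(out$value[out$trait == "u"]))
})

test_that("BLUEs reduce to per-line means in a balanced identity design", {
  pl <- one_way_plots(25, 4, s2g = 2, s2e = 1, seed = 8)
  b <- compute_blues(pl, "t", list(random = "ril", residual = "idh_year"))
  means <- tapply(pl$value, pl$ril, mean)
  expect_equal(unname(b[names(means)]), as.vector(means), tolerance = 1e-6)

  # duplicate plots with identical values give back that value
  pl2 <- one_way_plots(5, 2, 0, 1, seed = 9)
  pl2$value <- rep(c(3, 1, 4, 1, 5), each = 2)
  b2 <- compute_blues(pl2, "t", list(random = "ril", residual = "idh_year"))
  expect_equal(unname(b2), c(3, 1, 4, 1, 5))
})

test_that("BLUEs track the simulated line values at high heritability", {
  dat <- fix_plots()
  st <- blue_stage(dat$plots, "t",
                   candidate_random = list(character(0)),
                   candidate_residual = "idh_year", dffits_threshold = 3)
  gv <- genetic_values_of(dat$pop, dat$arch)[, 1]
  common <- intersect(names(st$blue), names(gv))
  expect_gte(cor(st$blue[common], gv[common], use = "complete.obs"), 0.7)
  expect_true(st$h2$estimate > 0.4 && st$h2$estimate < 0.95)
})

test_that("Box-Cox closed forms and the inverse identity hold", {
  expect_equal(boxcox_transform(5, 1), 4)
  expect_equal(boxcox_transform(exp(1), 0), 1)
  expect_equal(boxcox_transform(3, 0.5, shift = 1), 2 * (sqrt(4) - 1))
  expect_error(boxcox_transform(c(a = -2), 0.5), "non-positive")

  y <- c(0.3, 1, 2.5, 7)
  for (l in seq(-2, 2, by = 0.5))
    expect_equal(boxcox_inverse(boxcox_transform(y, l), l), y,
                 tolerance = 1e-10)

  # transform is strictly increasing
  for (l in c(-1, 0, 1.5)) {
    z <- boxcox_transform(sort(runif(20, 0.1, 5)), l)
    expect_true(all(diff(z) > 0))
  }
})

test_that("the convenient lambda is found on the grid with shift for negatives", {
  set.seed(10)
  y <- exp(rnorm(400))          # log-normal: lambda 0 is optimal
  expect_equal(choose_boxcox(y)$lambda, 0)
  y2 <- rnorm(400)              # negatives force a shift
  bc <- choose_boxcox(y2)
  expect_gt(bc$shift, -min(y2))
  expect_equal(bc$transformed,
               boxcox_transform(y2, bc$lambda, bc$shift))
})

test_that("line-mean heritability closed forms and bounds hold", {
  h <- line_mean_heritability(c(g = 1, ge = 0, e = 1), e_bar = 2, p_bar = 2)
  expect_equal(h$estimate, 2 / 3)
  expect_equal(line_mean_heritability(c(g = 0, ge = 0, e = 1), 2, 2)$estimate, 0)
  expect_error(line_mean_heritability(c(g = 0, ge = 0, e = 0), 2, 2),
               "zero total variance")
  V <- diag(c(0.1, 0, 0.1))
  hse <- line_mean_heritability(c(g = 1, ge = 0, e = 1), 2, 2, vcov = V)
  expect_gt(hse$se, 0)
})
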