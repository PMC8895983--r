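## Predicting a target trait (kernel color) from component traits
## (carotenoid BLUEs): compared linear models and a random forest, with
## feature importances and the correlation matrix of untransformed
## BLUEs.

#' Compare linear models predicting one trait from others
#'
#' Ordinary least squares per specification; rows with any missing
#' response/predictor are dropped listwise per model. The family term is
#' a categorical factor (one-hot, first level reference).
#'
#' @param blues data frame of (transformed) BLUEs with a `family`
#'   column.
#' @param response response trait column name.
#' @param model_specs named list; each element is a list with
#'   `predictors` (character vector of trait columns) and `family`
#'   (logical: include the family term).
#' @return A `model_comparison` data frame: `model`, `predictors`,
#'   `family_term`, `n`, `r2`, `adj_r2`, `aic`, `bic`, `rank_deficient`.
#' @export
compare_linear_models <- function(blues, response, model_specs) {
  rows <- lapply(names(model_specs), function(nm) {
    sp <- model_specs[[nm]]
    vars <- c(response, sp$predictors, if (isTRUE(sp$family)) "family")
    d <- blues[stats::complete.cases(blues[, vars, drop = FALSE]),
               vars, drop = FALSE]
    rhs <- c(sp$predictors, if (isTRUE(sp$family)) "family")
    f <- stats::reformulate(sprintf("`%s`", rhs), response = sprintf("`%s`", response))
    fit <- stats::lm(f, data = d)
    rd <- any(is.na(stats::coef(fit)))
    if (rd) warning("rank-deficient fit for model '", nm, "'")
    s <- summary(fit)
    data.frame(model = nm,
               predictors = paste(sp$predictors, collapse = "+"),
               family_term = isTRUE(sp$family), n = nrow(d),
               r2 = s$r.squared, adj_r2 = s$adj.r.squared,
               aic = stats::AIC(fit), bic = stats::BIC(fit),
               rank_deficient = rd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Random-forest vs linear prediction with repeated train/test splits
#'
#' Per seed: split (default 70/30), fit a regression forest
#' (`ranger`, default 1,000 trees, impurity importance) and an ordinary
#' linear model on the identical training rows, and compute on the test
#' rows: R^2, Baseline Error (mean |prediction - observed|) and Percent
#' Accuracy (per-observation `100 - 100 |pred - obs| / obs`, averaged;
#' observations with |obs| < 1e-6 are excluded from that average and
#' counted). Metrics and importances are averaged over seeds.
#'
#' @param blues data frame with `family` column, response and
#'   predictors.
#' @param response response trait name.
#' @param predictors predictor trait names.
#' @param include_family pass family to both learners (integer codes to
#'   the forest, factor to the linear model).
#' @param test_fraction test split fraction (default 0.3).
#' @param n_trees forest size (default 1000).
#' @param seeds integer vector of split seeds (default 1:30).
#' @return An `rf_report` list: `metrics` (per-seed data frame),
#'   `summary` (seed-averaged), `importance` (named, normalized to sum
#'   to 1), `n_excluded_accuracy`.
#' @export
fit_random_forest <- function(blues, response, predictors,
                              include_family = TRUE, test_fraction = 0.3,
                              n_trees = 1000, seeds = 1:30) {
  vars <- c(response, predictors, if (include_family) "family")
  d <- blues[stats::complete.cases(blues[, vars, drop = FALSE]), vars,
             drop = FALSE]
  if (!all(vapply(d[predictors], is.numeric, TRUE)))
    stop("predictors must be numeric")
  if (any(!is.finite(as.matrix(d[predictors]))))
    stop("non-finite feature values")
  d$family <- if (include_family) factor(d$family) else NULL
  feat <- c(predictors, if (include_family) "family")
  n <- nrow(d)
  imp_sum <- stats::setNames(numeric(length(feat)), feat)
  n_excl <- 0L
  met <- lapply(seeds, function(sd_) {
    set.seed(sd_)
    test <- sample.int(n, round(test_fraction * n))
    train <- setdiff(seq_len(n), test)
    dtr <- d[train, , drop = FALSE]
    dte <- d[test, , drop = FALSE]
    dtr_rf <- dtr; dte_rf <- dte
    if (include_family) {           # forest sees integer family codes
      dtr_rf$family <- as.integer(dtr$family)
      dte_rf$family <- as.integer(dte$family)
    }
    f <- stats::reformulate(sprintf("`%s`", feat), response = sprintf("`%s`", response))
    rf <- ranger::ranger(f, data = dtr_rf, num.trees = n_trees,
                         importance = "impurity", num.threads = 1,
                         seed = sd_)
    lmfit <- stats::lm(f, data = dtr)
    y <- dte[[response]]
    pred_rf <- stats::predict(rf, data = dte_rf)$predictions
    pred_lm <- unname(stats::predict(lmfit, newdata = dte))
    r2 <- function(p) 1 - sum((y - p)^2) / sum((y - mean(y))^2)
    base_err <- function(p) mean(abs(p - y))
    pacc <- function(p) {
      ok <- abs(y) >= 1e-6
      n_excl <<- n_excl + sum(!ok)
      mean(100 - 100 * abs(p[ok] - y[ok]) / y[ok])
    }
    imp <- rf$variable.importance
    imp_sum <<- imp_sum + imp / sum(imp)
    data.frame(seed = sd_, r2_rf = r2(pred_rf), r2_lm = r2(pred_lm),
               baseline_error_rf = base_err(pred_rf),
               baseline_error_lm = base_err(pred_lm),
               percent_accuracy_rf = pacc(pred_rf),
               percent_accuracy_lm = pacc(pred_lm))
  })
  met <- do.call(rbind, met)
  structure(list(metrics = met,
                 summary = colMeans(met[, -1, drop = FALSE]),
                 importance = imp_sum / length(seeds),
                 n_excluded_accuracy = n_excl,
                 n_trees = n_trees, test_fraction = test_fraction,
                 n_seeds = length(seeds)),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat("Random forest vs linear model (", x$n_trees, " trees, ",
      round(100 * (1 - x$test_fraction)), "/",
      round(100 * x$test_fraction), " split, ", x$n_seeds,
      " seeds)\n", sep = "")
  print(round(x$summary, 4))
  cat("feature importances (impurity, normalized):\n")
  print(round(sort(x$importance, decreasing = TRUE), 3))
  invisible(x)
}

#' Pairwise trait correlation matrix
#'
#' Pairwise-complete Pearson correlations of (untransformed) BLUEs;
#' symmetric with unit diagonal. Cells with fewer than 3 complete pairs
#' or a zero-variance trait are `NA`.
#'
#' @param blues data frame of BLUEs.
#' @param traits trait column names.
#' @return correlation matrix.
#' @export
trait_correlation_matrix <- function(blues, traits) {
  X <- as.matrix(blues[, traits, drop = FALSE])
  R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(X))
  R[npair < 3] <- NA
  diag(R)[diag(npair) >= 1] <- 1
  R
}
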