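#' Flag influential observations by DFFITS
#'
#' DFFITS is computed per observation from the fixed-effect projection of
#' the final (line-fixed) model, after decorrelating with the estimated
#' error covariance: with `V = L'L`, the whitened regression of
#' `L^-T y` on `L^-T X` is an ordinary least-squares problem and the
#' textbook DFFITS (externally studentized residual times
#' `sqrt(h/(1-h))`) applies.
#'
#' @param fit a `nam_mixed` fit with `fixed = "lines"`.
#' @param threshold positive cutoff; observations with
#'   `|DFFITS| > threshold` are flagged. Default `2 * sqrt(p/n)`, the
#'   conventional size-adjusted rule.
#' @return data frame of flagged observations: `ril`, `trait`, `year`,
#'   `field`, `row`, `range`, `dffits`.
#' @export
flag_outliers <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "nam_mixed"))
  if (fit$fixed != "lines")
    stop("outlier flagging uses the fixed-effect (line) projection")
  if (!is.null(threshold) && threshold <= 0)
    stop("threshold must be positive")
  L <- fit$chol_V
  Wy <- backsolve(L, fit$data$value, transpose = TRUE)
  WX <- backsolve(L, fit$X, transpose = TRUE)
  qrX <- qr(WX)
  p <- qrX$rank
  n <- length(Wy)
  if (is.null(threshold)) threshold <- 2 * sqrt(p / n)
  e <- qr.resid(qrX, Wy)
  h <- rowSums(qr.qy(qrX, diag(1, n, p))^2)
  h <- pmin(h, 1 - 1e-10)
  rss <- sum(e^2)
  df <- n - p
  s2_i <- (rss - e^2 / (1 - h)) / (df - 1)
  s2_i <- pmax(s2_i, 1e-300)
  dff <- e * sqrt(h) / (sqrt(s2_i) * (1 - h))
  bad <- which(abs(dff) > threshold)
  out <- fit$data[bad, c("ril", "year", "field", "row", "range"), drop = FALSE]
  out$trait <- rep(fit$trait, length(bad))
  out$dffits <- dff[bad]
  rownames(out) <- NULL
  out
}

#' Set flagged observations missing for their trait only
#'
#' @param plots a `plot_table`.
#' @param flags output of [flag_outliers] (possibly several traits,
#'   row-bound).
#' @return the plot table with flagged values set `NA`; records of other
#'   traits are never modified.
#' @export
remove_outliers <- function(plots, flags) {
  if (nrow(flags) == 0) return(plots)
  key <- function(d) paste(d$ril, d$trait, d$year, d$field, d$row, d$range)
  hit <- key(plots) %in% key(flags)
  plots$value[hit] <- NA
  plots
}

#' Per-line BLUEs from the sparse-fixed-line model
#'
#' Refits the selected model with one fixed effect per line (generalized
#' least squares at the REML variance parameters of the all-random fit);
#' the fixed-effect estimates are the BLUEs. Lines absent for a trait
#' come back `NA`.
#'
#' @param plots a `plot_table` (after outlier removal).
#' @param trait trait name.
#' @param structure list with `random` and `residual` (as selected by
#'   [select_structure]).
#' @param vc_fit the all-random `nam_mixed` fit supplying variance
#'   parameters; if `NULL` it is fitted here.
#' @return named numeric vector of BLUEs (all lines present in `plots`,
#'   `NA` where the trait is missing).
#' @export
compute_blues <- function(plots, trait, structure, vc_fit = NULL) {
  if (is.null(vc_fit))
    vc_fit <- fit_mixed(plots, trait, random = structure$random,
                        residual = structure$residual)
  res <- vc_fit$residual
  fit <- fit_mixed(plots, trait, random = structure$random,
                   residual = structure$residual, fixed = "lines",
                   vc = list(vc = vc_fit$vc,
                             residual = list(sigma2 = res$sigma2,
                                             rho_row = res$rho_row,
                                             rho_range = res$rho_range)))
  all_lines <- sort(unique(plots$ril))
  out <- stats::setNames(rep(NA_real_, length(all_lines)), all_lines)
  out[names(fit$beta)] <- fit$beta
  out
}

#' Box-Cox power transform
#'
#' `lambda != 0`: `((y + shift)^lambda - 1) / lambda`; `lambda == 0`:
#' `log(y + shift)`. Strictly increasing in `y` for any `lambda`.
#'
#' @param y numeric values.
#' @param lambda power.
#' @param shift location shift applied before the power (default 0).
#' @return transformed values.
#' @export
boxcox_transform <- function(y, lambda, shift = 0) {
  z <- y + shift
  bad <- which(!is.na(z) & z <= 0)
  if (length(bad))
    stop("non-positive shifted value at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (!is.null(names(y))) paste0(" (", paste(utils::head(names(y)[bad], 5),
                                                    collapse = ", "), ")"))
  if (lambda == 0) log(z) else (z^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @param x transformed values.
#' @export
boxcox_inverse <- function(x, lambda, shift = 0) {
  y <- if (lambda == 0) exp(x) else (lambda * x + 1)^(1 / lambda)
  y - shift
}

#' Choose a convenient Box-Cox lambda on a coarse grid
#'
#' The normal profile log-likelihood of the intercept-only model
#' (including the transformation Jacobian) is evaluated on the grid
#' `{-2, -1.5, ..., 2}` and the grid value with the highest profile
#' likelihood is returned. When
#' non-positive values are present, a shift of
#' `-min(y) + 0.001 * range(y)` is applied first.
#'
#' @param y numeric values (e.g. untransformed BLUEs).
#' @param grid candidate lambdas.
#' @return list `lambda`, `shift`, `transformed`.
#' @export
choose_boxcox <- function(y, grid = seq(-2, 2, by = 0.5)) {
  ok <- !is.na(y)
  shift <- 0
  if (min(y[ok]) <= 0)
    shift <- -min(y[ok]) + 0.001 * diff(range(y[ok]))
  yy <- y[ok] + shift
  n <- length(yy)
  ## normal profile log-likelihood with the transformation Jacobian
  prof <- vapply(grid, function(l) {
    z <- boxcox_transform(yy, l)
    -n / 2 * log(sum((z - mean(z))^2) / n) + (l - 1) * sum(log(yy))
  }, 1)
  lambda <- grid[which.max(prof)]
  list(lambda = lambda, shift = shift,
       transformed = ifelse(is.na(y), NA, boxcox_transform(y, lambda, shift)))
}

#' Line-mean heritability with delta-method standard error
#'
#' `h2 = s2_g / (s2_g + s2_ge / e_bar + s2_e / p_bar)` where `e_bar` and
#' `p_bar` are harmonic means of the numbers of environments and plots
#' per line. The SE is first-order delta method on the variance-component
#' covariance matrix.
#'
#' @param vc named numeric: `g` (genetic, line-within-family), `ge`
#'   (line-by-environment, 0 if absent), `e` (residual).
#' @param e_bar,p_bar harmonic mean environment and plot counts per line.
#' @param vcov optional 3x3 covariance matrix of `(g, ge, e)` estimates;
#'   if supplied an SE is returned.
#' @return list `estimate` (in `[0, 1]`), `se` (`NA` without `vcov`).
#' @export
line_mean_heritability <- function(vc, e_bar, p_bar, vcov = NULL) {
  g <- vc[["g"]]; ge <- if ("ge" %in% names(vc)) vc[["ge"]] else 0
  e <- vc[["e"]]
  denom <- g + ge / e_bar + e / p_bar
  if (denom <= 0) stop("zero total variance")
  h2 <- g / denom
  se <- NA_real_
  if (!is.null(vcov)) {
    grad <- c((denom - g) / denom^2,       # d/dg
              -g / (e_bar * denom^2),      # d/dge
              -g / (p_bar * denom^2))      # d/de
    se <- sqrt(drop(t(grad) %*% vcov %*% grad))
  }
  list(estimate = min(max(h2, 0), 1), se = se)
}

## harmonic mean
hmean <- function(x) length(x) / sum(1 / x)

## variance-component covariance from the REML fit: inverse observed
## information, numerically, on the natural (variance) scale
vc_covariance <- function(fit, which_par) {
  ll_nat <- function(theta) {
    par <- fit$par
    par[which_par] <- log(pmax(theta, 1e-12))
    fit$reml_ll(par)
  }
  theta0 <- exp(fit$par[which_par])
  H <- stats::optimHess(theta0, ll_nat)
  tryCatch(solve(-H), error = function(e)
    matrix(NA_real_, length(which_par), length(which_par)))
}

#' End-to-end BLUE stage for one trait
#'
#' Runs the full estimation protocol: two-stage BIC structure selection,
#' DFFITS outlier screening on the line-fixed projection (flagged plots
#' set missing for this trait only), re-fit, BLUE extraction, Box-Cox
#' transformation, and line-mean heritability with delta-method SE.
#'
#' @param plots a `plot_table`.
#' @param trait trait name.
#' @param candidate_random,candidate_residual candidate structures (see
#'   [select_structure]). Defaults keep the stage light: baseline-only
#'   vs. set/block extras, identity vs. AR1xAR1 residual.
#' @param dffits_threshold DFFITS cutoff (default `2 sqrt(p/n)`).
#' @param ... passed to [fit_mixed].
#' @return list: `blue` (untransformed, named by line), `transformed`,
#'   `lambda`, `shift`, `h2` (list estimate/se), `structure`, `fit`,
#'   `n_flagged`.
#' @export
blue_stage <- function(plots, trait,
                       candidate_random = list(character(0), c("set", "block")),
                       candidate_residual = c("idh_year", "ar1ar1"),
                       dffits_threshold = NULL, ...) {
  sel <- select_structure(plots, trait, candidate_random, candidate_residual, ...)
  structure_sel <- list(random = sel$random, residual = sel$residual)
  vc_fit <- sel$fit
  line_fit <- fit_mixed(plots, trait, random = sel$random,
                        residual = sel$residual, fixed = "lines",
                        vc = list(vc = vc_fit$vc,
                                  residual = as.list(vc_fit$residual)))
  flags <- flag_outliers(line_fit, threshold = dffits_threshold)
  plots2 <- remove_outliers(plots, flags)
  if (nrow(flags) > 0)
    vc_fit <- fit_mixed(plots2, trait, random = sel$random,
                        residual = sel$residual, ...)
  blue <- compute_blues(plots2, trait, structure_sel, vc_fit = vc_fit)
  bc <- choose_boxcox(blue)

  ## heritability from the all-random variance components
  d <- plots2[plots2$trait == trait & !is.na(plots2$value), ]
  e_bar <- hmean(tapply(d$year, d$ril, function(x) length(unique(x))))
  p_bar <- hmean(table(d$ril))
  g <- if ("ril" %in% names(vc_fit$vc)) vc_fit$vc[["ril"]] else 0
  ge <- if ("ril_year" %in% names(vc_fit$vc)) vc_fit$vc[["ril_year"]] else 0
  resvar <- sum(vc_fit$residual$sigma2 * vc_fit$residual$n) /
    sum(vc_fit$residual$n)
  idx_g <- match("ril", vc_fit$random)
  idx_ge <- match("ril_year", vc_fit$random)
  idx_e <- length(vc_fit$random) + 1L   # first residual block variance
  vcv <- NULL
  if (!is.na(idx_g)) {
    sel_par <- c(idx_g, idx_ge, idx_e)
    present <- !is.na(sel_par)
    Vp <- vc_covariance(vc_fit, sel_par[present])
    vcv <- matrix(0, 3, 3)
    vcv[present, present] <- Vp
  }
  h2 <- line_mean_heritability(c(g = g, ge = ge, e = resvar), e_bar, p_bar,
                               vcov = vcv)
  list(blue = blue, transformed = bc$transformed, lambda = bc$lambda,
       shift = bc$shift, h2 = h2, structure = structure_sel, fit = vc_fit,
       n_flagged = nrow(flags), selection = sel$table)
}

#' Assemble a BLUE table across traits
#'
#' @param stages named list of [blue_stage] results (one per trait).
#' @param family optional named vector mapping line to family.
#' @return `blue_table` data frame: `line`, `family`, one column per
#'   trait for untransformed BLUEs and `<trait>_bc` for transformed,
#'   with `lambda`/`shift` kept as attributes.
#' @export
blue_table <- function(stages, family = NULL) {
  lines <- sort(unique(unlist(lapply(stages, function(s) names(s$blue)))))
  out <- data.frame(line = lines, stringsAsFactors = FALSE)
  if (!is.null(family)) out$family <- unname(family[lines])
  for (tr in names(stages)) {
    out[[tr]] <- stages[[tr]]$blue[lines]
    out[[paste0(tr, "_bc")]] <- stages[[tr]]$transformed[lines]
  }
  attr(out, "lambda") <- vapply(stages, `[[`, 1, "lambda")
  attr(out, "shift") <- vapply(stages, `[[`, 1, "shift")
  class(out) <- c("blue_table", "data.frame")
  out
}

#' Write / read a BLUE table as wide TSV
#' @param blues a `blue_table`.
#' @param path file path.
#' @param ... provenance header fields.
#' @export
write_blues <- function(blues, path, ...) {
  write_stage_tsv(as.data.frame(blues), path, stage = "blues", ...)
}

#' @rdname write_blues
#' @export
read_blues <- function(path) {
  out <- read_stage_tsv(path)
  class(out) <- c("blue_table", "data.frame")
  out
}
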