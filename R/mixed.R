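## REML machinery for the plot-level mixed model
##
## y = X beta + sum_k Z_k u_k + e,  u_k ~ N(0, sigma2_k I),
## e ~ N(0, R) with R block diagonal over residual blocks (years or
## fields-in-years); an AR1 x AR1 block has
##   C_ij = sigma2_b * rho_row^|row_i - row_j| * rho_range^|range_i - range_j|
## which is the separable power model and needs no complete grid.
## Variance parameters are optimized on the log scale and AR1
## correlations via atanh, giving smooth unconstrained optimization.

RANDOM_BASELINE <- c("family", "ril", "year", "field")
RANDOM_EXTRAS <- c("plate", "set", "block", "fam_year", "ril_year")
RESIDUAL_TYPES <- c("idh_year", "idh_field", "ar1_range", "ar1_row", "ar1ar1")

term_factor <- function(plots, term) {
  f <- switch(term,
    family = plots$family,
    ril = plots$ril,
    year = plots$year,
    field = plots$field,
    set = paste(plots$field, plots$set, sep = ":"),
    block = paste(plots$field, plots$set, plots$block, sep = ":"),
    plate = plots$plate,
    fam_year = paste(plots$family, plots$year, sep = ":"),
    ril_year = paste(plots$ril, plots$year, sep = ":"),
    stop("unknown model term: ", term))
  factor(f)
}

## precomputed pieces for one residual structure
residual_blocks <- function(plots, type) {
  spatial <- grepl("^ar1", type)
  use_row <- type %in% c("ar1_row", "ar1ar1")
  use_range <- type %in% c("ar1_range", "ar1ar1")
  by <- if (type == "idh_year") plots$year else plots$field
  blocks <- lapply(split(seq_len(nrow(plots)), by), function(idx) {
    b <- list(idx = idx)
    if (spatial) {
      b$Dr <- abs(outer(as.integer(plots$row[idx]), as.integer(plots$row[idx]), "-"))
      b$Dc <- abs(outer(as.integer(plots$range[idx]), as.integer(plots$range[idx]), "-"))
      if (any(b$Dr == 0 & b$Dc == 0 & upper.tri(b$Dr)))
        stop("duplicate plot coordinates within a residual block")
    }
    b
  })
  list(type = type, blocks = blocks, spatial = spatial,
       use_row = use_row, use_range = use_range)
}

## R matrix from back-transformed residual parameters; the identity
## direction of a single-AR1 structure is a same-coordinate indicator
## (AR1(rho) x ID), i.e. rho^D with rho = 0 and 0^0 = 1
build_R <- function(res, sigma2, rho_row, rho_range, n) {
  R <- matrix(0, n, n)
  for (b in seq_along(res$blocks)) {
    bl <- res$blocks[[b]]
    if (!res$spatial) {
      R[cbind(bl$idx, bl$idx)] <- sigma2[b]
    } else {
      ## rho^D via a lookup over integer distances (D entries are small)
      pow_tab <- function(rho, D) {
        p <- rho ^ (0:max(D))
        array(p[D + 1L], dim = dim(D))
      }
      C <- (if (res$use_row) pow_tab(rho_row[b], bl$Dr) else (bl$Dr == 0)) *
           (if (res$use_range) pow_tab(rho_range[b], bl$Dc) else (bl$Dc == 0))
      R[bl$idx, bl$idx] <- sigma2[b] * C
    }
  }
  R
}

unpack_resid_par <- function(res, par) {
  nb <- length(res$blocks)
  sigma2 <- exp(par[seq_len(nb)])
  k <- nb
  rho_row <- rep(0, nb); rho_range <- rep(0, nb)
  if (res$use_row) { rho_row <- tanh(par[k + seq_len(nb)]); k <- k + nb }
  if (res$use_range) rho_range <- tanh(par[k + seq_len(nb)])
  list(sigma2 = sigma2, rho_row = rho_row, rho_range = rho_range)
}

#' Fit the plot-level linear mixed model by REML
#'
#' @param plots a `plot_table` (long format; see [simulate_traits]).
#' @param trait trait name to model.
#' @param random character vector of random terms. Baseline terms are
#'   `family`, `ril`, `year`, `field`; candidate extras are `plate`,
#'   `set`, `block`, `fam_year`, `ril_year`.
#' @param residual residual structure: `"idh_year"` (identity, one
#'   variance per year), `"idh_field"` (one variance per field-in-year),
#'   `"ar1_range"`, `"ar1_row"` or `"ar1ar1"` (separable first-order
#'   autoregressive over plot coordinates, per field-in-year).
#' @param fixed `"mean"` (grand mean only; the variance-component model)
#'   or `"lines"` (one fixed effect per RIL, for BLUE extraction).
#' @param vc optional named list `list(vc = ..., residual = ...)` of
#'   variance parameters to plug in without re-optimization (used for the
#'   sparse-fixed-line BLUE fit).
#' @param fix_rho optional named numeric, e.g. `c(row = 0)`: constrain an
#'   AR1 correlation instead of estimating it.
#' @param control list: `maxit` (default 600), `reltol`.
#' @return A `nam_mixed` object: REML log-likelihood, `bic`
#'   (`-2 logLik + k_var * log(n)`), variance components `vc`, per-block
#'   residual parameters, GLS fixed effects with SEs, and the model
#'   frame needed by downstream diagnostics.
#' @export
fit_mixed <- function(plots, trait, random = RANDOM_BASELINE,
                      residual = "idh_year", fixed = "mean", vc = NULL,
                      fix_rho = NULL, control = list()) {
  residual <- match.arg(residual, RESIDUAL_TYPES)
  stopifnot(trait %in% plots$trait)
  d <- plots[plots$trait == trait & !is.na(plots$value), , drop = FALSE]
  n <- nrow(d)
  if (n < 2) stop("not enough observations for trait ", trait)
  if (grepl("ar1", residual) && (is.null(d$row) || is.null(d$range)))
    stop("AR1 residual structures need row/range plot coordinates")
  y <- d$value

  X <- if (fixed == "mean") matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
       else {
    ril <- factor(d$ril)
    Xs <- Matrix::t(Matrix::fac2sparse(ril))
    colnames(Xs) <- levels(ril)
    as.matrix(Xs)
  }

  random <- unique(random)
  bad <- setdiff(random, c(RANDOM_BASELINE, RANDOM_EXTRAS))
  if (length(bad)) stop("unknown random term(s): ", paste(bad, collapse = ", "))
  ## a term confounded with the fixed lines is dropped from the random side
  if (fixed == "lines") random <- setdiff(random, c("family", "ril"))
  keep <- vapply(random, function(tm) nlevels(term_factor(d, tm)) >= 2, TRUE)
  random <- random[keep]
  ZZt <- lapply(random, function(tm) {
    Z <- Matrix::t(Matrix::fac2sparse(term_factor(d, tm)))
    as.matrix(Matrix::tcrossprod(Z))
  })
  names(ZZt) <- random
  K <- length(ZZt)

  res <- residual_blocks(d, residual)
  nb <- length(res$blocks)
  fix_row <- if (!is.null(fix_rho) && "row" %in% names(fix_rho)) fix_rho[["row"]] else NULL
  fix_range <- if (!is.null(fix_rho) && "range" %in% names(fix_rho)) fix_rho[["range"]] else NULL

  ## parameter vector layout: [log s2 random x K][log s2 resid x nb]
  ## [atanh rho_row x nb if free][atanh rho_range x nb if free]
  n_rho_row <- if (res$use_row && is.null(fix_row)) nb else 0L
  n_rho_range <- if (res$use_range && is.null(fix_range)) nb else 0L

  v_floor <- 1e-9 * stats::var(y)   # keeps V positive definite when a
                                    # residual variance collapses to zero
  expand_par <- function(par) {
    s2r <- exp(par[seq_len(K)])
    k <- K
    rs2 <- exp(par[k + seq_len(nb)]) + v_floor; k <- k + nb
    rr <- if (n_rho_row) tanh(par[k + seq_len(nb)]) else
      rep(if (res$use_row) fix_row else 0, nb)
    k <- k + n_rho_row
    rc <- if (n_rho_range) tanh(par[k + seq_len(nb)]) else
      rep(if (res$use_range) fix_range else 0, nb)
    list(s2r = s2r, rs2 = rs2, rr = rr, rc = rc)
  }

  build_V <- function(p) {
    V <- build_R(res, p$rs2, p$rr, p$rc, n)
    for (k in seq_len(K)) V <- V + p$s2r[k] * ZZt[[k]]
    V
  }

  reml_ll <- function(par) {
    p <- expand_par(par)
    V <- build_V(p)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(-1e10)
    Wy <- backsolve(L, y, transpose = TRUE)
    WX <- backsolve(L, X, transpose = TRUE)
    XtVX <- crossprod(WX)
    Lx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(Lx)) return(-1e10)
    Xty <- crossprod(WX, Wy)
    beta <- backsolve(Lx, backsolve(Lx, Xty, transpose = TRUE))
    yPy <- sum(Wy^2) - sum(Xty * beta)
    ll <- -0.5 * (2 * sum(log(diag(L))) + 2 * sum(log(diag(Lx))) + yPy)
    if (!is.finite(ll)) return(-1e10)
    ll
  }

  if (is.null(vc)) {
    v0 <- stats::var(y)
    init <- c(rep(log(v0 / (K + 1)), K), rep(log(v0 / 2), nb),
              rep(atanh(0.2), n_rho_row + n_rho_range))
    trace <- new.env(); trace$n <- 0L
    negll <- function(par) { trace$n <- trace$n + 1L; -reml_ll(par) }
    if (length(init) == 1) {
      opt <- stats::optim(init, negll, method = "Brent",
                          lower = init - 25, upper = init + 15)
    } else {
      ## simplex search for robustness, quasi-Newton polish for accuracy
      opt <- stats::optim(init, negll, method = "Nelder-Mead",
                          control = list(maxit = control$maxit %||% 500,
                                         reltol = control$reltol %||% 1e-8))
      opt <- stats::optim(opt$par, negll, method = "BFGS",
                          control = list(maxit = control$polish_maxit %||% 300,
                                         reltol = 1e-9))
    }
    if (opt$convergence != 0 && length(init) > 1)
      warning("REML optimization did not fully converge (code ",
              opt$convergence, ", ", trace$n, " evaluations)")
    par <- opt$par
    loglik <- -opt$value
    conv <- opt$convergence
    nev <- trace$n
  } else {
    s2r <- unlist(vc$vc)[random]
    s2r[is.na(s2r)] <- 1e-8
    rs <- vc$residual
    par <- c(log(pmax(s2r, 1e-10)), log(pmax(rep_len(rs$sigma2, nb), 1e-10)))
    if (n_rho_row) par <- c(par, atanh(rep_len(rs$rho_row %||% 0, nb)))
    if (n_rho_range) par <- c(par, atanh(rep_len(rs$rho_range %||% 0, nb)))
    loglik <- reml_ll(par)
    conv <- 0L; nev <- 1L
  }

  p <- expand_par(par)
  V <- build_V(p)
  L <- chol(V)
  Wy <- backsolve(L, y, transpose = TRUE)
  WX <- backsolve(L, X, transpose = TRUE)
  XtVX <- crossprod(WX)
  Lx <- chol(XtVX)
  Xty <- crossprod(WX, Wy)
  beta <- drop(backsolve(Lx, backsolve(Lx, Xty, transpose = TRUE)))
  names(beta) <- colnames(X)
  se <- sqrt(diag(chol2inv(Lx)))
  names(se) <- colnames(X)

  k_var <- K + nb + n_rho_row + n_rho_range
  vc_out <- stats::setNames(p$s2r, random)
  res_out <- data.frame(block = names(res$blocks), sigma2 = p$rs2,
                        rho_row = p$rr, rho_range = p$rc,
                        n = vapply(res$blocks, function(b) length(b$idx), 1L))
  structure(list(trait = trait, loglik = loglik,
                 bic = -2 * loglik + k_var * log(n),
                 vc = vc_out, residual = res_out, residual_type = residual,
                 beta = beta, se = se, fixed = fixed, n = n, k_var = k_var,
                 convergence = conv, n_eval = nev, par = par,
                 random = random, data = d, X = X, chol_V = L,
                 reml_ll = reml_ll, expand_par = expand_par),
            class = "nam_mixed")
}

#' @export
print.nam_mixed <- function(x, ...) {
  cat("Mixed model (REML) for trait '", x$trait, "', n = ", x$n, "\n", sep = "")
  cat("  logLik ", format(x$loglik), ",  BIC ", format(x$bic),
      "  (", x$k_var, " variance parameters)\n", sep = "")
  cat("  random terms:\n")
  print(round(x$vc, 5))
  cat("  residual (", x$residual_type, "):\n", sep = "")
  print(x$residual, row.names = FALSE)
  invisible(x)
}

#' @export
summary.nam_mixed <- function(object, ...) {
  print(object)
  if (object$fixed == "lines")
    cat("  fixed line effects:", length(object$beta), "lines\n")
  invisible(object)
}

#' @export
coef.nam_mixed <- function(object, ...) object$beta

#' @export
residuals.nam_mixed <- function(object, ...) {
  drop(object$data$value - object$X %*% object$beta)
}

#' @export
logLik.nam_mixed <- function(object, ...) {
  structure(object$loglik, df = object$k_var + ncol(object$X),
            class = "logLik")
}

#' Two-stage BIC selection of random and residual structures
#'
#' Stage 1 selects the random structure by minimum BIC with an identity
#' residual; stage 2 selects the residual structure by minimum BIC
#' conditional on that random structure. Ties break toward fewer variance
#' parameters; candidate order never matters.
#'
#' @param plots a `plot_table`.
#' @param trait trait name.
#' @param candidate_random list of character vectors of *extra* random
#'   terms (each combined with the baseline terms).
#' @param candidate_residual character vector of residual structures.
#' @param ... passed to [fit_mixed].
#' @return list with `random`, `residual`, the selected `fit`, and the
#'   BIC `table` of all candidates.
#' @export
select_structure <- function(plots, trait,
                             candidate_random = list(character(0)),
                             candidate_residual = "idh_year", ...) {
  if (!length(candidate_random) || !length(candidate_residual))
    stop("candidate lists must be non-empty")
  fits1 <- lapply(candidate_random, function(extra)
    tryCatch(fit_mixed(plots, trait, random = c(RANDOM_BASELINE, extra),
                       residual = "idh_year", ...),
             error = function(e) NULL))
  ok <- !vapply(fits1, is.null, TRUE)
  if (!any(ok)) stop("all random-structure candidates failed to fit")
  bic1 <- vapply(fits1, function(f) if (is.null(f)) Inf else f$bic, 1)
  kv1 <- vapply(fits1, function(f) if (is.null(f)) Inf else f$k_var, 1)
  i1 <- order(round(bic1, 6), kv1)[1]
  best_random <- c(RANDOM_BASELINE, candidate_random[[i1]])

  fits2 <- lapply(candidate_residual, function(rs)
    tryCatch(fit_mixed(plots, trait, random = best_random, residual = rs, ...),
             error = function(e) NULL))
  ok2 <- !vapply(fits2, is.null, TRUE)
  if (!any(ok2)) stop("all residual-structure candidates failed to fit")
  bic2 <- vapply(fits2, function(f) if (is.null(f)) Inf else f$bic, 1)
  kv2 <- vapply(fits2, function(f) if (is.null(f)) Inf else f$k_var, 1)
  i2 <- order(round(bic2, 6), kv2)[1]

  tab <- data.frame(
    stage = c(rep(1, length(bic1)), rep(2, length(bic2))),
    candidate = c(vapply(candidate_random, function(x)
      if (length(x)) paste(x, collapse = "+") else "(baseline)", ""),
      candidate_residual),
    bic = c(bic1, bic2), k_var = c(kv1, kv2))
  list(random = best_random, residual = candidate_residual[[i2]],
       fit = fits2[[i2]], table = tab)
}
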