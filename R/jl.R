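## Joint-linkage machinery: multi-family stepwise regression of
## transformed BLUEs on map markers, marker effects nested within family,
## the family term forced in first and never removed.
##
## The computational core exploits the structure of family-nested marker
## blocks: the columns of one marker's block live on disjoint row sets
## (one family each), so the raw block Gram matrix is diagonal and the
## partial sum of squares of a candidate block given the current model
## reduces to a small F_m x F_m solve per marker after one sparse
## cross-product with the model's Q basis.

## precompute the family-nested design for all markers; genotypes are
## mean-imputed within family (projection-based codes are continuous)
nested_design <- function(G, fam) {
  fam <- factor(fam)
  n <- nrow(G); M <- ncol(G)
  if (anyNA(G)) {
    for (f in levels(fam)) {
      rows <- which(fam == f)
      sub <- G[rows, , drop = FALSE]
      mu <- colMeans(sub, na.rm = TRUE)
      idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(idx)) sub[idx] <- mu[idx[, 2]]
      G[rows, ] <- sub
    }
  }
  ## segregating (marker, family) pairs: non-zero within-family variance
  nf <- as.vector(table(fam))
  s1 <- rowsum(G, fam, reorder = TRUE)
  s2 <- rowsum(G^2, fam, reorder = TRUE)
  fvar <- (s2 - s1^2 / nf) / pmax(nf - 1, 1)
  seg <- fvar > 1e-10          # F x M logical
  col_fam <- row(seg)[seg]
  col_marker <- col(seg)[seg]
  ord <- order(col_marker, col_fam)
  col_fam <- col_fam[ord]; col_marker <- col_marker[ord]
  fam_int <- as.integer(fam)
  ## sparse n x n_col block matrix: entry x_i in column (m, f(i))
  cols_of <- split(seq_along(col_marker), col_marker)
  rows_by_fam <- split(seq_len(n), fam_int)
  ti <- tj <- tx <- vector("list", length(col_fam))
  for (j in seq_along(col_fam)) {
    rows <- rows_by_fam[[col_fam[j]]]
    ti[[j]] <- rows
    tj[[j]] <- rep.int(j, length(rows))
    tx[[j]] <- G[rows, col_marker[j]]
  }
  Xall <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                               x = unlist(tx),
                               dims = c(n, length(col_fam)))
  list(G = G, fam = fam, Xall = Xall, col_fam = col_fam,
       col_marker = col_marker, cols_of = cols_of,
       ss = Matrix::colSums(Xall^2), n = n, M = M,
       n_seg = vapply(cols_of, length, 1L),
       markers = colnames(G))
}

## dense model matrix: family indicators + nested blocks of `markers`
jl_model_matrix <- function(nd, markers) {
  Xf <- as.matrix(Matrix::t(Matrix::fac2sparse(nd$fam)))  # works at 1 level
  colnames(Xf) <- paste0("family:", levels(nd$fam))
  if (!length(markers)) return(Xf)
  mi <- match(markers, nd$markers)
  blocks <- lapply(mi, function(m) {
    jj <- nd$cols_of[[as.character(m)]]
    B <- as.matrix(nd$Xall[, jj, drop = FALSE])
    colnames(B) <- paste0(nd$markers[m], ":", levels(nd$fam)[nd$col_fam[jj]])
    B
  })
  cbind(Xf, do.call(cbind, blocks))
}

## partial-F scan of every marker given the current model (matrix X0):
## returns p-values, SSR, df1 per marker
jl_scan <- function(y, nd, X0, exclude = integer(0)) {
  qx <- qr(X0)
  k <- qx$rank
  Q <- qr.Q(qx)[, seq_len(k), drop = FALSE]
  y_perp <- y - Q %*% crossprod(Q, y)
  sse0 <- sum(y_perp^2)
  C <- as.matrix(Matrix::crossprod(nd$Xall, Q))      # n_col x k
  d <- as.vector(Matrix::crossprod(nd$Xall, y_perp)) # n_col
  M <- nd$M
  SSR <- rep(NA_real_, M); df1 <- nd$n_seg[match(seq_len(M), as.integer(names(nd$cols_of)))]
  df1[is.na(df1)] <- 0L
  for (mc in seq_along(nd$cols_of)) {
    m <- as.integer(names(nd$cols_of)[mc])
    if (m %in% exclude) next
    jj <- nd$cols_of[[mc]]
    A <- diag(nd$ss[jj], length(jj)) - tcrossprod(C[jj, , drop = FALSE])
    r <- tryCatch({
      L <- chol(A + diag(1e-10 * max(nd$ss[jj]), length(jj)))
      v <- backsolve(L, d[jj], transpose = TRUE)
      sum(v^2)
    }, error = function(e) NA_real_)
    SSR[m] <- r
  }
  SSR <- pmin(SSR, sse0)            # numerical guard
  df2 <- nd$n - k - df1
  Fst <- (SSR / df1) / ((sse0 - SSR) / df2)
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  list(p = p, SSR = SSR, df1 = df1, sse0 = sse0, rank0 = k)
}

## vectorized null scan: min partial-F p-value over markers for each
## column of Y, against the family-only model (the permutation workhorse)
jl_null_minp <- function(Y, nd) {
  fam <- nd$fam
  G <- nd$G
  num <- matrix(0, nd$M, ncol(Y))   # sum_f (x_f' y_f)^2 / s_f
  df1 <- integer(nd$M)
  sst <- numeric(ncol(Y))
  seg_by_fam <- split(nd$col_marker, nd$col_fam)
  for (fi in seq_len(nlevels(fam))) {
    rows <- which(as.integer(fam) == fi)
    Gc <- scale(G[rows, , drop = FALSE], scale = FALSE)
    Yc <- scale(Y[rows, , drop = FALSE], scale = FALSE)
    s <- colSums(Gc^2)
    segm <- seg_by_fam[[as.character(fi)]]
    segv <- logical(nd$M); segv[segm] <- TRUE
    df1 <- df1 + segv
    cp <- crossprod(Gc, Yc)          # M x P
    cp[!segv, ] <- 0
    s[!segv] <- 1
    num <- num + cp^2 / s
    sst <- sst + colSums(Yc^2)
  }
  k <- nlevels(fam)
  df2 <- nd$n - k - df1
  ok <- df1 > 0
  minp <- vapply(seq_len(ncol(Y)), function(j) {
    Fst <- (num[ok, j] / df1[ok]) / ((sst[j] - num[ok, j]) / df2[ok])
    min(stats::pf(Fst, df1[ok], df2[ok], lower.tail = FALSE))
  }, 1)
  minp
}

## permute values within family
permute_within_family <- function(y, fam, n_perm) {
  idx <- seq_along(y)
  sapply(seq_len(n_perm), function(p) {
    pi <- idx
    for (f in levels(fam)) {
      rows <- which(fam == f)
      pi[rows] <- rows[sample.int(length(rows))]
    }
    y[pi]
  })
}

#' Permutation-derived entry threshold for joint-linkage scans
#'
#' Phenotypes are permuted within family (the family term is forced into
#' every model, so between-family structure must be preserved under the
#' null); for each permutation the minimum partial-F p-value over all
#' markers (nested within family, against the family-only model) is
#' recorded. The entry threshold at type I error `alpha` is the
#' `floor(alpha * n_perm)`-th smallest of these minima.
#'
#' @param y named numeric vector of (transformed) BLUEs.
#' @param G RIL x marker genotype matrix (rows matching `names(y)`).
#' @param fam family factor per RIL.
#' @param n_perm number of permutations (>= 20).
#' @param alpha genome-wide type I error rate.
#' @param seed integer seed.
#' @return object of class `jl_threshold`: `entry_p`, `alpha`, `minima`,
#'   and `quantile(alpha2)` giving thresholds at other levels (used for
#'   the `alpha = 0.01` support intervals).
#' @export
jl_permutation_threshold <- function(y, G, fam, n_perm = 1000, alpha = 0.05,
                                     seed = 1) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  if (n_perm * alpha < 1) stop("n_perm * alpha must be >= 1")
  fam <- factor(fam)
  keep <- !is.na(y)
  y <- y[keep]; G <- G[keep, , drop = FALSE]; fam <- droplevels(fam[keep])
  nd <- nested_design(G, fam)
  set.seed(seed)
  Y <- permute_within_family(y, fam, n_perm)
  minima <- jl_null_minp(Y, nd)
  qfun <- function(a) sort(minima)[max(1L, floor(a * length(minima)))]
  structure(list(entry_p = qfun(alpha), alpha = alpha, minima = minima,
                 quantile = qfun, n_perm = n_perm),
            class = "jl_threshold")
}

#' @export
print.jl_threshold <- function(x, ...) {
  cat("JL permutation threshold: entry p =", format(x$entry_p),
      "at alpha =", x$alpha, "from", x$n_perm, "permutations\n")
  invisible(x)
}

## (re)fit the model for a fixed marker set; returns coefficient table,
## per-marker partial SS given all others, sigma2, fitted, residuals
fit_jl_set <- function(y, nd, markers) {
  X <- jl_model_matrix(nd, markers)
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  fitted <- drop(X[, !is.na(beta), drop = FALSE] %*% beta[!is.na(beta)])
  resid <- y - fitted
  sse <- sum(resid^2)
  df_res <- nd$n - qx$rank
  ss_partial <- vapply(markers, function(m) {
    X0 <- jl_model_matrix(nd, setdiff(markers, m))
    sc <- jl_scan(y, nd, X0, exclude = integer(0))
    sc$SSR[match(m, nd$markers)]
  }, 1)
  p_partial <- vapply(markers, function(m) {
    X0 <- jl_model_matrix(nd, setdiff(markers, m))
    sc <- jl_scan(y, nd, X0)
    sc$p[match(m, nd$markers)]
  }, 1)
  list(X = X, qr = qx, beta = beta, fitted = fitted, resid = resid,
       sse = sse, df_res = df_res, ss_partial = ss_partial,
       p_partial = p_partial)
}

## deterministic tie-break: smallest p, then lower chromosome, lower cM
pick_best <- function(p, map, markers) {
  stopifnot(length(p) == length(markers))
  i <- which(p == min(p, na.rm = TRUE))
  if (length(i) > 1) {
    mi <- match(markers[i], map$marker)
    i <- i[order(map$chrom[mi], map$cM[mi])][1]
  }
  i[1]
}

#' Joint stepwise linkage regression
#'
#' Forward step: add the marker with the smallest partial-F p-value if it
#' is `<= entry_p`. Backward step: drop any included marker whose partial
#' p (given the others) exceeds `exit_p` (worst first). Iterates to a
#' fixed point. The family term is always present and never removable.
#'
#' @inheritParams jl_permutation_threshold
#' @param map a [genetic_map] covering the markers (tie-breaks and
#'   downstream intervals).
#' @param entry_p entry threshold (from [jl_permutation_threshold]).
#' @param exit_p exit threshold; default `2 * entry_p` so a marker cannot
#'   enter and exit in the same step. Must be `>= entry_p`.
#' @param trait trait label carried through outputs.
#' @param max_steps iteration cap; exceeding it is reported as an error.
#' @return A `jl_model` object.
#' @export
stepwise_jl <- function(y, G, fam, map, entry_p, exit_p = 2 * entry_p,
                        trait = "trait", max_steps = 50) {
  if (exit_p < entry_p) stop("exit_p must be >= entry_p")
  fam <- factor(fam)
  keep <- !is.na(y)
  y <- y[keep]; G <- G[keep, , drop = FALSE]; fam <- droplevels(fam[keep])
  nd <- nested_design(G, fam)
  markers <- character(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    X0 <- jl_model_matrix(nd, markers)
    sc <- jl_scan(y, nd, X0, exclude = match(markers, nd$markers))
    cand <- which(!is.na(sc$p))
    if (length(cand)) {
      best <- cand[pick_best(sc$p[cand], map, nd$markers[cand])]
      if (sc$p[best] <= entry_p) {
        markers <- c(markers, nd$markers[best])
        changed <- TRUE
      }
    }
    if (length(markers)) {
      fit <- fit_jl_set(y, nd, markers)
      worst <- which.max(fit$p_partial)
      if (fit$p_partial[worst] > exit_p) {
        markers <- markers[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
    if (step == max_steps)
      stop("stepwise selection did not reach a fixed point in ",
           max_steps, " steps")
  }
  new_jl_model(y, nd, map, markers, entry_p, exit_p, trait)
}

new_jl_model <- function(y, nd, map, markers, entry_p, exit_p, trait) {
  fit <- fit_jl_set(y, nd, markers)
  structure(list(trait = trait, y = y, nd = nd, map = map,
                 peaks = markers, entry_p = entry_p, exit_p = exit_p,
                 fit = fit),
            class = "jl_model")
}

#' @export
print.jl_model <- function(x, ...) {
  cat("Joint-linkage model for '", x$trait, "': ", length(x$peaks),
      " peak marker(s), ", nlevels(x$nd$fam), " families, n = ",
      length(x$y), "\n", sep = "")
  if (length(x$peaks)) {
    mi <- match(x$peaks, x$map$marker)
    print(data.frame(marker = x$peaks, chrom = x$map$chrom[mi],
                     cM = x$map$cM[mi],
                     partial_SS = unname(x$fit$ss_partial),
                     partial_p = unname(x$fit$p_partial)),
          row.names = FALSE)
  }
  cat("entry p <=", format(x$entry_p), "; exit p >", format(x$exit_p), "\n")
  invisible(x)
}

#' @export
summary.jl_model <- function(object, ...) {
  print(object)
  cat("model R2:", format(model_r2(object)), "\n")
  invisible(object)
}

model_r2 <- function(model) {
  1 - model$fit$sse / sum((model$y - mean(model$y))^2)
}

#' @export
coef.jl_model <- function(object, ...) allelic_effects(object)

#' @export
residuals.jl_model <- function(object, ...) object$fit$resid

#' @export
predict.jl_model <- function(object, ...) object$fit$fitted

#' Prune multicollinear peak markers
#'
#' While any pair of included markers has `|Pearson r|` of genotype
#' codes strictly greater than `r_threshold`, the member of the worst
#' pair with the lower model sum of squares (partial SS given the model
#' without the offending pair) is removed and the model refit.
#'
#' @param model a `jl_model`.
#' @param r_threshold correlation magnitude threshold (default 0.8;
#'   comparison is strict, a pair at exactly the threshold is kept).
#' @return the pruned `jl_model`.
#' @export
prune_multicollinear <- function(model, r_threshold = 0.8) {
  markers <- model$peaks
  nd <- model$nd
  repeat {
    if (length(markers) < 2) break
    Gm <- nd$G[, markers, drop = FALSE]
    r <- abs(stats::cor(Gm))
    diag(r) <- 0
    if (max(r) <= r_threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- markers[worst]
    others <- setdiff(markers, pair)
    X0 <- jl_model_matrix(nd, others)
    sc <- jl_scan(model$y, nd, X0)
    ss <- sc$SSR[match(pair, nd$markers)]
    drop_m <- pair[which.min(ss)]
    markers <- setdiff(markers, drop_m)
  }
  new_jl_model(model$y, nd, model$map, markers, model$entry_p, model$exit_p,
               model$trait)
}

#' Support interval around a peak marker
#'
#' The contiguous run of markers m (on the peak's chromosome) such that
#' substituting m for the peak leaves m's partial-F p-value at or below
#' the `alpha`-level permutation threshold; bounds are the outermost
#' qualifying markers.
#'
#' @param model a `jl_model`.
#' @param peak one of `model$peaks`.
#' @param threshold a `jl_threshold` (from [jl_permutation_threshold]).
#' @param alpha support level (default 0.01).
#' @return data frame row: `trait`, `peak`, `chrom`, `left_cM`,
#'   `right_cM`, `left_bp`, `right_bp`, `alpha`.
#' @export
support_interval <- function(model, peak, threshold, alpha = 0.01) {
  stopifnot(peak %in% model$peaks)
  p_cut <- threshold$quantile(alpha)
  nd <- model$nd
  map <- model$map
  X0 <- jl_model_matrix(nd, setdiff(model$peaks, peak))
  sc <- jl_scan(model$y, nd, X0)
  pi <- match(peak, map$marker)
  ch <- map$chrom[pi]
  on_ch <- which(map$chrom == ch & map$marker %in% nd$markers)
  on_ch <- on_ch[order(map$cM[on_ch])]
  pv <- sc$p[match(map$marker[on_ch], nd$markers)]
  qual <- !is.na(pv) & pv <= p_cut
  k <- match(pi, on_ch)
  if (!isTRUE(qual[k]))
    stop("peak ", peak, " itself fails the alpha = ", alpha, " threshold")
  left <- k; while (left > 1 && qual[left - 1]) left <- left - 1
  right <- k; while (right < length(on_ch) && qual[right + 1]) right <- right + 1
  li <- on_ch[left]; ri <- on_ch[right]
  data.frame(trait = model$trait, peak = peak, chrom = ch,
             left_cM = map$cM[li], right_cM = map$cM[ri],
             left_bp = map$bp[li], right_bp = map$bp[ri],
             alpha = alpha, stringsAsFactors = FALSE)
}

#' Re-scan peaks within their support intervals
#'
#' Iteratively substitutes each peak with the in-interval marker of
#' maximal model sum of squares (partial SS given the other peaks) until
#' every peak is a local SS maximum. Intervals are recomputed after each
#' substitution; equal-SS plateaus keep the leftmost (lowest-cM) marker.
#' A revisited model state raises an oscillation error.
#'
#' @param model a `jl_model`.
#' @param threshold a `jl_threshold` (for the interval definition).
#' @param alpha support level for intervals.
#' @return the updated `jl_model`.
#' @export
rescan_peaks <- function(model, threshold, alpha = 0.01) {
  seen <- character(0)
  repeat {
    state <- paste(sort(model$peaks), collapse = "|")
    if (state %in% seen) stop("re-scan oscillation detected")
    seen <- c(seen, state)
    changed <- FALSE
    for (peak in model$peaks) {
      ## a peak below the interval-level threshold keeps its position
      si <- tryCatch(support_interval(model, peak, threshold, alpha),
                     error = function(e) NULL)
      if (is.null(si)) next
      map <- model$map
      nd <- model$nd
      in_iv <- map$marker[map$chrom == si$chrom &
                          map$cM >= si$left_cM & map$cM <= si$right_cM]
      in_iv <- intersect(in_iv, nd$markers)
      in_iv <- setdiff(in_iv, setdiff(model$peaks, peak))
      X0 <- jl_model_matrix(nd, setdiff(model$peaks, peak))
      sc <- jl_scan(model$y, nd, X0)
      ss <- sc$SSR[match(in_iv, nd$markers)]
      ok <- !is.na(ss)
      in_iv <- in_iv[ok]; ss <- ss[ok]
      cM_iv <- map$cM[match(in_iv, map$marker)]
      best <- in_iv[order(-ss, cM_iv)][1]
      cur_ss <- ss[match(peak, in_iv)]
      if (!identical(best, peak) && ss[match(best, in_iv)] > cur_ss + 1e-12) {
        peaks <- model$peaks
        peaks[peaks == peak] <- best
        model <- new_jl_model(model$y, nd, map, peaks, model$entry_p,
                              model$exit_p, model$trait)
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  model
}

#' Family-nested allelic effect estimates at the model peaks
#'
#' One estimate (and SE) per (peak, family); families in which the
#' marker does not segregate come back `NA`. Effects are on the 0/1
#' parental-origin coding: the estimate is the difference between the
#' alternate- and common-parent genotype-class means in that family.
#'
#' @param model a `jl_model`.
#' @param y optional replacement phenotype (same lines; used by the
#'   pleiotropy cross-fit). Defaults to the model's own phenotype.
#' @return data frame: `trait`, `marker`, `family`, `effect`, `se`.
#' @export
allelic_effects <- function(model, y = NULL) {
  nd <- model$nd
  yy <- if (is.null(y)) model$y else y
  X <- model$fit$X
  qx <- qr(X)
  beta <- qr.coef(qx, yy)
  res <- qr.resid(qx, yy)
  s2 <- sum(res^2) / (length(yy) - qx$rank)
  R <- qr.R(qx)[, order(qx$pivot), drop = FALSE]
  XtX_inv_diag <- tryCatch(diag(chol2inv(chol(crossprod(X)))),
                           error = function(e) rep(NA_real_, ncol(X)))
  se <- sqrt(s2 * XtX_inv_diag)
  fams <- levels(nd$fam)
  out <- expand.grid(family = fams, marker = model$peaks,
                     stringsAsFactors = FALSE)[, 2:1]
  cn <- paste0(out$marker, ":", out$family)
  out$effect <- beta[match(cn, colnames(X))]
  out$se <- se[match(cn, colnames(X))]
  data.frame(trait = model$trait, out, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Phenotypic variance explained per peak
#'
#' Uses observed within-family allele frequencies (not the Mendelian
#' 0.5), so segregation distortion is accounted for:
#' `var_q = sum_f w_f p_f (1 - p_f) s_f^2` with `w_f = n_f / N` and
#' `s_f` the family-nested effect (class-difference scale; equivalently
#' `p(1-p)(2a)^2` with `a = s/2` the allelic substitution effect). PVE is
#' `var_q` divided by the total variance of the transformed BLUEs.
#'
#' @param model a `jl_model`.
#' @return data frame `trait`, `marker`, `pve`, plus attributes
#'   `total_pve` (sum) and `model_r2`.
#' @export
pve <- function(model) {
  vy <- stats::var(model$y)
  if (vy <= 0) stop("zero phenotypic variance")
  eff <- allelic_effects(model)
  nd <- model$nd
  w <- as.vector(table(nd$fam)) / length(nd$fam)
  names(w) <- levels(nd$fam)
  out <- data.frame(trait = model$trait, marker = model$peaks,
                    pve = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(model$peaks)) {
    m <- model$peaks[i]
    pf_ <- tapply(nd$G[, m], nd$fam, mean)
    ef <- eff$effect[eff$marker == m]
    names(ef) <- eff$family[eff$marker == m]
    fams <- names(ef)[!is.na(ef)]
    out$pve[i] <- sum(w[fams] * pf_[fams] * (1 - pf_[fams]) * ef[fams]^2) / vy
  }
  attr(out, "total_pve") <- sum(out$pve)
  attr(out, "model_r2") <- model_r2(model)
  out
}

#' Full joint-linkage stage for one trait
#'
#' Threshold permutations, stepwise selection, multicollinearity pruning,
#' peak re-scan, support intervals, allelic effects and PVE.
#'
#' @inheritParams stepwise_jl
#' @param n_perm permutations for the entry threshold.
#' @param alpha entry type I error rate.
#' @param interval_alpha support interval level.
#' @param r_threshold multicollinearity pruning threshold.
#' @param seed integer seed (permutations).
#' @return list: `model`, `threshold`, `intervals`, `effects`, `pve`.
#' @export
jl_stage <- function(y, G, fam, map, trait = "trait", n_perm = 1000,
                     alpha = 0.05, interval_alpha = 0.01, r_threshold = 0.8,
                     seed = 1) {
  thr <- jl_permutation_threshold(y, G, fam, n_perm = n_perm, alpha = alpha,
                                  seed = seed)
  model <- stepwise_jl(y, G, fam, map, entry_p = thr$entry_p, trait = trait)
  model <- prune_multicollinear(model, r_threshold = r_threshold)
  if (length(model$peaks)) model <- rescan_peaks(model, thr, interval_alpha)
  ivs <- if (length(model$peaks))
    do.call(rbind, lapply(model$peaks, function(pk)
      tryCatch(support_interval(model, pk, thr, interval_alpha),
               error = function(e) NULL)))
  else NULL
  list(model = model, threshold = thr, intervals = ivs,
       effects = if (length(model$peaks)) allelic_effects(model) else NULL,
       pve = if (length(model$peaks)) pve(model) else NULL)
}
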