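## Resampling GWAS on projected dense variants, scored by the resample
## model inclusion probability (RMIP). Single-variant tests follow the
## joint-linkage conventions: family-nested dosage slope, partial F
## against the family(-plus-included-variants) model.

#' Chromosome-specific residual phenotypes from a joint-linkage model
#'
#' For the focal chromosome, the joint-linkage model is refit with all
#' peaks EXCEPT those on that chromosome (family term retained); its
#' residuals carry the focal chromosome's signal and none of the
#' other chromosomes'. With no peaks at all the residuals are the BLUEs
#' minus family means, identical across chromosomes.
#'
#' @param model a `jl_model`.
#' @param chrom focal chromosome.
#' @return named numeric residual vector (one per line).
#' @export
chromosome_residuals <- function(model, chrom) {
  map <- model$map
  on_focal <- model$peaks[map$chrom[match(model$peaks, map$marker)] == chrom]
  keep <- setdiff(model$peaks, on_focal)
  fit <- fit_jl_set(model$y, model$nd, keep)
  stats::setNames(fit$resid, names(model$y))
}

## full p-value matrix (variant x column-of-Y) for single-variant
## family-nested partial F against the family-only model
gwas_scan_p <- function(Y, nd) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  fam <- nd$fam
  num <- matrix(0, nd$M, ncol(Y))
  df1 <- integer(nd$M)
  sst <- numeric(ncol(Y))
  seg_by_fam <- split(nd$col_marker, nd$col_fam)
  for (fi in seq_len(nlevels(fam))) {
    rows <- which(as.integer(fam) == fi)
    Gc <- scale(nd$G[rows, , drop = FALSE], scale = FALSE)
    Yc <- scale(Y[rows, , drop = FALSE], scale = FALSE)
    s <- colSums(Gc^2)
    segm <- seg_by_fam[[as.character(fi)]]
    segv <- logical(nd$M); segv[segm] <- TRUE
    df1 <- df1 + segv
    cp <- crossprod(Gc, Yc)
    cp[!segv, ] <- 0
    s[!segv] <- 1
    num <- num + cp^2 / s
    sst <- sst + colSums(Yc^2)
  }
  k <- nlevels(fam)
  df2 <- nd$n - k - df1
  P <- matrix(1, nd$M, ncol(Y))
  ok <- df1 > 0 & df2 > 0
  for (j in seq_len(ncol(Y))) {
    Fst <- (num[ok, j] / df1[ok]) / (pmax(sst[j] - num[ok, j], 0) / df2[ok])
    P[ok, j] <- stats::pf(Fst, df1[ok], df2[ok], lower.tail = FALSE)
  }
  P
}

#' Permutation-based GWAS significance threshold at a target FDR
#'
#' Residuals are permuted within family; each permutation yields a full
#' single-variant scan (per chromosome against that chromosome's
#' residuals). The threshold is the largest observed p-value `t` such
#' that the empirical-null false-positive estimate
#' `mean over permutations of #(p_perm <= t)` divided by the observed
#' count `#(p_obs <= t)` is at most `fdr`. `fdr = 1` passes everything
#' (threshold 1); the threshold is monotone non-increasing as `fdr`
#' decreases.
#'
#' @param residuals_by_chrom named list (chromosome -> residual vector
#'   from [chromosome_residuals]).
#' @param pv a `projected_variants` object.
#' @param fam family factor per RIL.
#' @param n_perm number of permutations (>= 20).
#' @param fdr target false discovery rate.
#' @param seed integer seed.
#' @return list `threshold`, `fdr`, `p_obs` (named by variant),
#'   `n_perm`.
#' @export
gwas_threshold <- function(residuals_by_chrom, pv, fam, n_perm = 1000,
                           fdr = 0.05, seed = 1) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  fam <- factor(fam)
  chroms <- intersect(names(residuals_by_chrom),
                      as.character(unique(pv$info$chrom)))
  p_obs <- numeric(0)
  p_perm <- NULL
  set.seed(seed)
  for (ch in chroms) {
    res <- residuals_by_chrom[[ch]]
    if (stats::sd(res) < 1e-12) stop("degenerate (constant) residuals")
    vsel <- which(pv$info$chrom == as.integer(ch))
    nd <- nested_design(pv$dosage[, vsel, drop = FALSE], fam)
    po <- gwas_scan_p(res, nd)[, 1]
    names(po) <- pv$info$variant[vsel]
    p_obs <- c(p_obs, po)
    Y <- permute_within_family(res, fam, n_perm)
    p_perm <- rbind(p_perm, gwas_scan_p(Y, nd))
  }
  if (fdr >= 1) {
    thr <- 1
  } else {
    cand <- sort(p_obs)
    n_obs <- seq_along(cand)
    efp <- vapply(cand, function(t) sum(p_perm <= t) / n_perm, 1)
    pass <- which(efp / n_obs <= fdr)
    thr <- if (length(pass)) cand[max(pass)] else 0
  }
  list(threshold = thr, fdr = fdr, p_obs = p_obs, n_perm = n_perm)
}

#' Resampling GWAS scored by model inclusion probability
#'
#' In each of `n_iter` iterations, `ceiling(subsample * N)` RILs are
#' drawn (with replacement by default); per chromosome, forward
#' selection against that chromosome's joint-linkage residuals adds the
#' variant with the smallest family-nested partial-F p-value while it is
#' at or below `threshold`. RMIP is the number of iterations in which a
#' variant entered the final model (on the conventional 0-100 scale when
#' `n_iter = 100`).
#'
#' @inheritParams gwas_threshold
#' @param threshold per-trait significance threshold (from
#'   [gwas_threshold]).
#' @param n_iter iterations; values other than 100 are allowed but
#'   flagged with a warning since the RMIP scale assumes 100.
#' @param subsample fraction of RILs per iteration, in (0, 1].
#' @param replace bootstrap sampling with replacement (default) or
#'   subsampling without.
#' @param max_steps forward-selection cap per chromosome per iteration.
#' @param rmip_report reporting cutoff (default 5).
#' @param trait trait label.
#' @return An `rmip_table` data frame: `trait`, `variant`, `chrom`,
#'   `bp`, `rmip`, `reported`.
#' @export
rmip_scan <- function(residuals_by_chrom, pv, fam, threshold, n_iter = 100,
                      subsample = 0.8, replace = TRUE, seed = 1,
                      max_steps = 25, rmip_report = 5, trait = "trait") {
  if (subsample <= 0 || subsample > 1) stop("subsample must be in (0, 1]")
  if (n_iter != 100)
    warning("RMIP scale assumes 100 iterations; got ", n_iter)
  fam <- factor(fam)
  N <- nrow(pv$dosage)
  chroms <- intersect(names(residuals_by_chrom),
                      as.character(unique(pv$info$chrom)))
  counts <- stats::setNames(integer(ncol(pv$dosage)), colnames(pv$dosage))
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(N, ceiling(subsample * N), replace = replace)
    fam_it <- droplevels(fam[idx])
    for (ch in chroms) {
      res <- residuals_by_chrom[[ch]][idx]
      vsel <- which(pv$info$chrom == as.integer(ch))
      G_it <- pv$dosage[idx, vsel, drop = FALSE]
      nd <- nested_design(G_it, fam_it)
      chosen <- character(0)
      for (s in seq_len(max_steps)) {
        X0 <- jl_model_matrix(nd, chosen)
        sc <- jl_scan(res, nd, X0, exclude = match(chosen, nd$markers))
        cand <- which(!is.na(sc$p))
        if (!length(cand)) break
        ## order-stable tie-break: variant id after the p-value
        best <- cand[order(sc$p[cand], nd$markers[cand])][1]
        if (sc$p[best] > threshold) break
        chosen <- c(chosen, nd$markers[best])
      }
      counts[chosen] <- counts[chosen] + 1L
    }
  }
  out <- data.frame(trait = trait, variant = pv$info$variant,
                    chrom = pv$info$chrom, bp = pv$info$bp,
                    rmip = as.integer(counts[pv$info$variant]),
                    stringsAsFactors = FALSE)
  out$reported <- out$rmip >= rmip_report
  class(out) <- c("rmip_table", "data.frame")
  attr(out, "n_iter") <- n_iter
  attr(out, "rmip_report") <- rmip_report
  out
}

#' @export
print.rmip_table <- function(x, ...) {
  cat("RMIP table:", nrow(x), "variants;",
      sum(x$reported), "reported (RMIP >=",
      attr(x, "rmip_report"), ") over", attr(x, "n_iter"), "iterations\n")
  if (any(x$reported))
    print(utils::head(as.data.frame(x)[order(-x$rmip), ], 10),
          row.names = FALSE)
  invisible(x)
}

#' Full GWAS stage for one trait
#'
#' Chromosome residuals from the joint-linkage model, permutation FDR
#' threshold, and the resampling scan.
#'
#' @param model a `jl_model`.
#' @param pv a `projected_variants`.
#' @param n_perm,fdr,n_iter,subsample,replace,seed,rmip_report see
#'   [gwas_threshold] and [rmip_scan].
#' @return list: `rmip` (an `rmip_table`), `threshold`, `residuals`.
#' @export
gwas_stage <- function(model, pv, n_perm = 1000, fdr = 0.05, n_iter = 100,
                       subsample = 0.8, replace = TRUE, seed = 1,
                       rmip_report = 5) {
  ## align variants with the model's line set (lines can drop out of the
  ## BLUE stage)
  lines <- names(model$y)
  if (!all(lines %in% rownames(pv$dosage)))
    stop("projected variants lack ", sum(!lines %in% rownames(pv$dosage)),
         " of the model's lines")
  if (!identical(rownames(pv$dosage), lines))
    pv <- structure(list(info = pv$info,
                         dosage = pv$dosage[lines, , drop = FALSE]),
                    class = "projected_variants")
  chroms <- sort(unique(pv$info$chrom))
  res_by <- stats::setNames(
    lapply(chroms, function(ch) chromosome_residuals(model, ch)),
    as.character(chroms))
  thr <- gwas_threshold(res_by, pv, model$nd$fam, n_perm = n_perm,
                        fdr = fdr, seed = derive_seed(seed, 101))
  rmip <- rmip_scan(res_by, pv, model$nd$fam, thr$threshold, n_iter = n_iter,
                    subsample = subsample, replace = replace,
                    seed = derive_seed(seed, 202),
                    rmip_report = rmip_report, trait = model$trait)
  list(rmip = rmip, threshold = thr, residuals = res_by)
}

#' Write an RMIP table as TSV
#' @param rmip an `rmip_table`.
#' @param path file path.
#' @param ... provenance header fields.
#' @export
write_rmip <- function(rmip, path, ...) {
  write_stage_tsv(as.data.frame(rmip), path, stage = "gwas_rmip", ...)
}
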