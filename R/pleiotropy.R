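#' Cross-fit a joint-linkage model with another trait's phenotype
#'
#' Fits trait A's final model terms (family + A's peak blocks) to trait
#' B's transformed BLUEs on the intersection of lines, and returns the
#' family-nested allelic effects of B at A's peaks.
#'
#' @param model trait A's `jl_model`.
#' @param y_other named numeric vector of trait B's transformed BLUEs.
#' @return data frame as from [allelic_effects] (trait = B implied by
#'   the caller).
#' @export
cross_fit <- function(model, y_other) {
  common <- intersect(names(model$y), names(y_other)[!is.na(y_other)])
  if (!length(common)) stop("no lines shared between the two traits")
  if (length(common) == length(model$y) &&
      all(common == names(model$y))) {
    return(allelic_effects(model, y = unname(y_other[names(model$y)])))
  }
  ## line sets differ: rebuild the design on the intersection
  keep <- names(model$y) %in% common
  nd <- nested_design(model$nd$G[keep, , drop = FALSE],
                      droplevels(model$nd$fam[keep]))
  sub <- new_jl_model(unname(y_other[names(model$y)[keep]]), nd, model$map,
                      model$peaks, model$entry_p, model$exit_p, model$trait)
  allelic_effects(sub)
}

#' Correlate allelic effects between two traits
#'
#' Pearson correlation over paired (peak x family) allelic-effect
#' estimates, the operational definition of pleiotropy: at trait A's
#' QTL, do the family-nested effects on trait B line up with those on A?
#' Tested per scope (a common interval, or genome-wide over all peaks).
#'
#' @param effects_a,effects_b effect tables ([allelic_effects] /
#'   [cross_fit]) with matching `marker`/`family` rows.
#' @param scope label for the tested scope.
#' @param trait_a,trait_b trait labels.
#' @param sd_a,sd_b optional trait SDs (of transformed BLUEs) used to
#'   standardize effects before correlating, so traits on different
#'   Box-Cox scales are comparable; standardization does not change r.
#' @return one-row data frame: `trait_a`, `trait_b`, `scope`, `r`, `p`,
#'   `n_effects`, `sign`, `untestable`.
#' @export
effect_correlation <- function(effects_a, effects_b, scope = "genome-wide",
                               trait_a = "A", trait_b = "B",
                               sd_a = 1, sd_b = 1) {
  key_a <- paste(effects_a$marker, effects_a$family)
  key_b <- paste(effects_b$marker, effects_b$family)
  common <- intersect(key_a, key_b)
  ea <- effects_a$effect[match(common, key_a)] / sd_a
  eb <- effects_b$effect[match(common, key_b)] / sd_b
  ok <- !is.na(ea) & !is.na(eb)   # monomorphic families dropped pairwise
  ea <- ea[ok]; eb <- eb[ok]
  n <- length(ea)
  out <- data.frame(trait_a = trait_a, trait_b = trait_b, scope = scope,
                    r = NA_real_, p = NA_real_, n_effects = n,
                    sign = NA_character_, untestable = FALSE,
                    stringsAsFactors = FALSE)
  if (n < 3 || stats::sd(ea) < 1e-12 || stats::sd(eb) < 1e-12) {
    out$untestable <- TRUE
    return(out)
  }
  ct <- stats::cor.test(ea, eb)
  out$r <- unname(ct$estimate)
  out$p <- ct$p.value
  out$sign <- if (out$r >= 0) "positive" else "negative"
  out
}

#' Pleiotropy stage across a set of traits
#'
#' For every ordered trait pair (A, B), trait A's final model is
#' cross-fit with B's phenotype and effects correlated genome-wide and
#' within each common interval containing at least one of A's peaks.
#' Benjamini-Hochberg adjustment is applied across the whole batch;
#' significance at `q <= 0.05`. Both model directions are reported
#' separately, never averaged.
#'
#' @param jl_models named list of `jl_model` objects (one per trait).
#' @param blues_mat matrix/data.frame of transformed BLUEs, lines x
#'   traits (rownames = line ids).
#' @param common_intervals optional `common_intervals` object (see
#'   [merge_intervals]) defining interval scopes.
#' @param standardize divide effects by the trait SD of transformed
#'   BLUEs (default TRUE).
#' @param q_cut significance level on BH-adjusted p (default 0.05).
#' @return A `pleiotropy_result` data frame with columns of
#'   [effect_correlation] plus `q` and `significant`.
#' @export
pleiotropy_stage <- function(jl_models, blues_mat, common_intervals = NULL,
                             standardize = TRUE, q_cut = 0.05) {
  traits <- names(jl_models)
  blues_mat <- as.matrix(blues_mat[, traits, drop = FALSE])
  sds <- if (standardize) apply(blues_mat, 2, stats::sd, na.rm = TRUE)
         else stats::setNames(rep(1, length(traits)), traits)
  rows <- list()
  for (a in traits) {
    ma <- jl_models[[a]]
    if (!length(ma$peaks)) next
    eff_a <- allelic_effects(ma)
    for (b in setdiff(traits, a)) {
      yb <- blues_mat[, b]
      names(yb) <- rownames(blues_mat)
      eff_b <- cross_fit(ma, yb)
      rows[[length(rows) + 1]] <-
        effect_correlation(eff_a, eff_b, "genome-wide", a, b,
                           sds[[a]], sds[[b]])
      if (!is.null(common_intervals)) {
        mi <- match(ma$peaks, ma$map$marker)
        pk_df <- data.frame(marker = ma$peaks, chrom = ma$map$chrom[mi],
                            bp = ma$map$bp[mi])
        for (iv in seq_len(nrow(common_intervals$intervals))) {
          ivr <- common_intervals$intervals[iv, ]
          in_iv <- pk_df$marker[pk_df$chrom == ivr$chrom &
                                pk_df$bp >= ivr$start_bp &
                                pk_df$bp <= ivr$end_bp]
          if (!length(in_iv)) next
          sel_a <- eff_a[eff_a$marker %in% in_iv, ]
          sel_b <- eff_b[eff_b$marker %in% in_iv, ]
          rows[[length(rows) + 1]] <-
            effect_correlation(sel_a, sel_b, sprintf("interval_%d", iv),
                               a, b, sds[[a]], sds[[b]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  testable <- !out$untestable
  out$q[testable] <- stats::p.adjust(out$p[testable], method = "BH")
  out$significant <- !is.na(out$q) & out$q <= q_cut
  class(out) <- c("pleiotropy_result", "data.frame")
  out
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat("Pleiotropy:", nrow(x), "tests;", sum(x$significant), "significant\n")
  sig <- as.data.frame(x)[x$significant, ]
  if (nrow(sig)) print(utils::head(sig[order(sig$q), ], 12), row.names = FALSE)
  invisible(x)
}

#' Export a pleiotropy edge list for network plotting
#' @param result a `pleiotropy_result`.
#' @param path file path.
#' @param ... provenance header fields.
#' @export
write_pleiotropy <- function(result, path, ...) {
  edges <- as.data.frame(result)[, c("trait_a", "trait_b", "scope", "r",
                                     "q", "sign")]
  write_stage_tsv(edges, path, stage = "pleiotropy", ...)
}
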