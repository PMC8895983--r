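#' Simulate a dense founder variant panel
#'
#' Generates biallelic variants along the physical map with allele
#' assignments for the common parent and every alternate parent. Variant
#' count per chromosome is Poisson with the requested density; positions
#' are uniform. Founder alleles are drawn Bernoulli with a variant-
#' specific frequency, and variants monomorphic across all founders are
#' dropped (they can never segregate in any family).
#'
#' @param pop a [nam_population] (supplies founders and the bp span).
#' @param density_per_Mb expected variants per megabase (> 0).
#' @param causal_spec optional data frame of planted causal variants:
#'   columns `variant`, `chrom`, `bp`, `carriers` (comma-separated
#'   founder ids carrying the alternate allele).
#' @param seed integer seed.
#' @return data frame: `variant`, `chrom`, `bp`, then one 0/1 allele
#'   column per founder (common parent first).
#' @export
simulate_dense_variants <- function(pop, density_per_Mb, causal_spec = NULL,
                                    seed = 1) {
  if (density_per_Mb <= 0) stop("density_per_Mb must be positive")
  set.seed(seed)
  founders <- c(pop$common_parent, unname(pop$parents))
  out <- list()
  for (ch in unique(pop$map$chrom)) {
    sub <- pop$map[pop$map$chrom == ch, ]
    span <- max(sub$bp) - min(sub$bp)
    n <- stats::rpois(1, density_per_Mb * span / 1e6)
    if (n == 0) next
    bp <- sort(sample(seq(min(sub$bp), max(sub$bp)), n))
    p <- stats::runif(n, 0.1, 0.9)
    alle <- matrix(stats::rbinom(n * length(founders), 1, rep(p, length(founders))),
                   nrow = n)
    colnames(alle) <- founders
    out[[length(out) + 1]] <- data.frame(
      variant = sprintf("v%d_%d", ch, seq_len(n)), chrom = ch, bp = bp,
      alle, stringsAsFactors = FALSE, check.names = FALSE)
  }
  vt <- do.call(rbind, out)
  if (!is.null(causal_spec)) {
    for (k in seq_len(nrow(causal_spec))) {
      carriers <- trimws(strsplit(causal_spec$carriers[k], ",")[[1]])
      row <- data.frame(variant = causal_spec$variant[k],
                        chrom = causal_spec$chrom[k], bp = causal_spec$bp[k],
                        stringsAsFactors = FALSE)
      for (f in founders) row[[f]] <- as.integer(f %in% carriers)
      vt <- rbind(vt, row)
    }
    vt <- vt[order(vt$chrom, vt$bp), ]
  }
  keep <- apply(vt[, founders, drop = FALSE], 1, function(a) length(unique(a)) > 1)
  vt <- vt[keep, , drop = FALSE]
  rownames(vt) <- NULL
  vt
}

#' Project founder variants onto RILs
#'
#' Within each family the RIL dosage at a variant is obtained by linear
#' interpolation (on the cM scale) of the parental-origin codes at the
#' flanking map markers, pushed through the two founders' alleles:
#' `dosage = code * allele_alt + (1 - code) * allele_common`, so a
#' variant colinear with a map marker reproduces that marker's codes
#' exactly when the founders differ. Variants monomorphic across the
#' whole panel are dropped.
#'
#' @param variants founder variant table (see [simulate_dense_variants]).
#' @param pop a [nam_population].
#' @return A `projected_variants` object: list with `info` (variant,
#'   chrom, bp) and `dosage` (RIL x variant matrix in `[0, 1]`).
#' @export
project_variants <- function(variants, pop) {
  map <- pop$map
  fam <- as.character(pop$family)
  founders <- c(pop$common_parent, unname(pop$parents))
  missing_f <- setdiff(founders, names(variants))
  if (length(missing_f))
    stop("variant table lacks founder column(s): ",
         paste(missing_f, collapse = ", "))
  N <- nrow(pop$geno)
  dos <- matrix(NA_real_, N, nrow(variants),
                dimnames = list(rownames(pop$geno), variants$variant))
  for (ch in unique(variants$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (nrow(sub) == 0) stop("variant chromosome ", ch, " not on map")
    if (is.unsorted(sub$cM, strictly = TRUE)) stop("unordered map")
    vsel <- which(variants$chrom == ch)
    vcM <- map_bp_to_cM(map, ch, variants$bp[vsel])
    li <- findInterval(vcM, sub$cM, all.inside = TRUE)
    ri <- li + 1L
    gap <- sub$cM[ri] - sub$cM[li]
    w <- ifelse(gap > 0, (vcM - sub$cM[li]) / gap, 0)
    w <- pmin(pmax(w, 0), 1)
    Gl <- pop$geno[, sub$marker[li], drop = FALSE]
    Gr <- pop$geno[, sub$marker[ri], drop = FALSE]
    code <- sweep(Gl, 2, 1 - w, "*") + sweep(Gr, 2, w, "*")
    for (f in levels(pop$family)) {
      rows <- fam == f
      a_com <- as.numeric(variants[vsel, pop$common_parent])
      a_alt <- as.numeric(variants[vsel, pop$parents[[f]]])
      d <- a_alt - a_com
      dos[rows, vsel] <- sweep(code[rows, , drop = FALSE], 2, d, "*") +
        matrix(a_com, sum(rows), length(vsel), byrow = TRUE)
    }
  }
  poly <- apply(dos, 2, function(x) stats::var(x) > 1e-12)
  structure(list(info = variants[poly, c("variant", "chrom", "bp")],
                 dosage = dos[, poly, drop = FALSE]),
            class = "projected_variants")
}

#' @export
print.projected_variants <- function(x, ...) {
  cat("Projected variants:", ncol(x$dosage), "polymorphic variants x",
      nrow(x$dosage), "RILs\n")
  invisible(x)
}

#' Read founder variants from an uncompressed VCF
#'
#' Founder genotypes (one sample per founder) are collapsed to 0/1 allele
#' calls: any alternate allele present counts as 1. Multiallelic records
#' are dropped with a message.
#'
#' @param path VCF file path.
#' @return founder variant table as from [simulate_dense_variants].
#' @export
read_founder_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF founder panels requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    message("dropping ", sum(multi), " multiallelic record(s)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v)
  alle <- apply(gt, 2, function(g) as.integer(grepl("1", g)))
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- sprintf("v%s_%s", fix[noid, "CHROM"], fix[noid, "POS"])
  out <- data.frame(variant = id, chrom = as.integer(fix[, "CHROM"]),
                    bp = as.numeric(fix[, "POS"]), alle,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
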