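#' NAM population objects
#'
#' A `nam_population` holds the recombinant inbred line (RIL) genotypes of
#' one or more biparental families that share a common parent, coded by
#' parental origin: 0 = common-parent allele, 1 = alternate-parent allele,
#' 0.5 = heterozygous/uncertain, `NA` = missing. Continuous codes in
#' `[0, 1]` arise after projection of dense variants and are accepted.
#'
#' @param geno numeric RIL x marker matrix with RIL ids as rownames and
#'   marker ids (matching `map$marker`) as colnames.
#' @param family factor/character of length `nrow(geno)` assigning each
#'   RIL to exactly one family.
#' @param map a [genetic_map] covering the genotyped markers.
#' @param parents optional named character vector: alternate parent id per
#'   family level.
#' @param common_parent id of the shared parent (default "B73").
#' @param dense_variants optional founder variant table (see
#'   [simulate_dense_variants]).
#' @return A `nam_population` list object.
#' @export
nam_population <- function(geno, family, map, parents = NULL,
                           common_parent = "B73", dense_variants = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) stop("geno needs RIL ids as rownames")
  family <- factor(family)
  if (length(family) != nrow(geno))
    stop("family must assign every RIL to exactly one family")
  if (!all(colnames(geno) %in% map$marker))
    stop("all genotyped markers must be on the map")
  rng <- range(geno, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("genotype codes must lie in [0, 1]")
  ## order marker columns along the map
  ord <- match(map$marker[map$marker %in% colnames(geno)], colnames(geno))
  geno <- geno[, ord, drop = FALSE]
  structure(list(geno = geno, family = family, map = map,
                 parents = parents, common_parent = common_parent,
                 dense_variants = dense_variants),
            class = "nam_population")
}

#' @export
print.nam_population <- function(x, ...) {
  cat("NAM population:", nrow(x$geno), "RILs in", nlevels(x$family),
      "family(ies);", ncol(x$geno), "mapped markers\n")
  print(table(x$family))
  invisible(x)
}

## one Haldane meiosis at marker resolution: Poisson crossovers on the cM
## scale, no interference
meiosis_gamete <- function(h1, h2, pos, len) {
  n_xo <- stats::rpois(1L, len / 100)
  seg <- if (n_xo > 0L) findInterval(pos, sort(stats::runif(n_xo, 0, len)))
         else integer(length(pos))
  use1 <- (seg + sample.int(2L, 1L)) %% 2L == 0L
  ifelse(use1, h1, h2)
}

## self one individual (two marker-level haplotypes) to fixation
self_to_fixation <- function(pos, len, n_gen) {
  h1 <- integer(length(pos))       # common-parent chromosome
  h2 <- rep(1L, length(pos))       # alternate-parent chromosome
  for (g in seq_len(n_gen)) {
    g1 <- meiosis_gamete(h1, h2, pos, len)
    g2 <- meiosis_gamete(h1, h2, pos, len)
    h1 <- g1; h2 <- g2
    if (all(h1 == h2)) break
  }
  het <- h1 != h2
  if (any(het)) {                  # force residual heterozygosity
    pick1 <- stats::runif(1) < 0.5
    h1[het] <- if (pick1) h1[het] else h2[het]
  }
  h1
}

#' Simulate one biparental RIL family
#'
#' Each RIL is produced by explicit repeated selfing from the F1 (Haldane
#' meioses: Poisson crossovers on the cM scale, no interference), with
#' residual heterozygosity after `n_gen` generations forced to fixation.
#' This generative construction reproduces the classical two-locus RIL
#' recombination fraction R = 2r/(1+2r) (r the Haldane gamete value) and
#' the two-fold RIL map expansion without any ad hoc rate adjustment.
#'
#' @param map a [genetic_map].
#' @param n_ril number of RILs (>= 1).
#' @param seed integer seed; identical seed gives bit-identical output.
#' @param n_gen selfing generations before forcing fixation (default 10,
#'   i.e. beyond S5; residual heterozygosity < 0.1%).
#' @param distortion optional segregation distortion spec: a data frame
#'   with columns `marker` and `freq` (target alternate-allele frequency).
#'   Implemented as viability selection: an oversized cohort is simulated
#'   and RILs are sampled from the allele classes at the distorted
#'   marker(s) to hit the target frequency, so linked markers show the
#'   expected decaying distortion.
#' @return integer 0/1 matrix, `n_ril` x markers.
#' @export
simulate_family <- function(map, n_ril, seed, n_gen = 10, distortion = NULL) {
  if (nrow(map) == 0) stop("empty map")
  if (n_ril < 1) stop("n_ril must be >= 1")
  set.seed(seed)
  chroms <- unique(map$chrom)
  n_sim <- if (is.null(distortion)) n_ril else max(3L * n_ril, n_ril + 50L)
  geno <- matrix(0L, n_sim, nrow(map),
                 dimnames = list(NULL, map$marker))
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    pos <- map$cM[sel]
    len <- max(pos)
    if (len <= 0) len <- 1e-9   # single-marker chromosome: no crossovers
    for (i in seq_len(n_sim))
      geno[i, sel] <- self_to_fixation(pos, len, n_gen)
  }
  if (!is.null(distortion)) {
    keep <- seq_len(n_sim)
    for (k in seq_len(nrow(distortion))) {
      m <- distortion$marker[k]
      p <- distortion$freq[k]
      carrier <- geno[keep, m] == 1L
      n1 <- min(round(n_ril * p), sum(carrier))
      n1 <- max(n1, n_ril - sum(!carrier))
      keep <- c(sample(keep[carrier], n1),
                sample(keep[!carrier], n_ril - n1))
    }
    geno <- geno[sort(keep[seq_len(n_ril)]), , drop = FALSE]
  } else {
    geno <- geno[seq_len(n_ril), , drop = FALSE]
  }
  geno
}

#' Simulate a full NAM panel
#'
#' Builds `n_families` biparental RIL families sharing a common parent.
#' Defaults mirror a 10-family panel of ~170 RILs per family (~1,700
#' lines total).
#'
#' @param map a [genetic_map].
#' @param n_families number of families.
#' @param n_ril RILs per family (recycled).
#' @param seed integer seed.
#' @param parents alternate-parent ids (defaults to the 10 yellow-to-
#'   orange grain NAM founders).
#' @param distortion optional named list: per family id, a distortion spec
#'   as in [simulate_family].
#' @inheritParams simulate_family
#' @return A [nam_population].
#' @export
simulate_nam_population <- function(map, n_families = 10, n_ril = 170, seed = 1,
                                    parents = c("B97", "CML228", "CML52",
                                                "Hp301", "Ki11", "Ki3", "NC350",
                                                "NC358", "Oh7B", "Tx303"),
                                    n_gen = 10, distortion = NULL) {
  n_ril <- rep_len(n_ril, n_families)
  if (length(parents) < n_families)
    parents <- sprintf("AP%02d", seq_len(n_families))
  parents <- parents[seq_len(n_families)]
  fam_ids <- sprintf("Z%03d", seq_len(n_families))
  names(parents) <- fam_ids
  gl <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    g <- simulate_family(map, n_ril[f], seed = derive_seed(seed, f),
                         distortion = distortion[[fam_ids[f]]])
    rownames(g) <- sprintf("%sE%04d", fam_ids[f], seq_len(n_ril[f]))
    gl[[f]] <- g
  }
  geno <- do.call(rbind, gl)
  family <- rep(fam_ids, n_ril)
  nam_population(geno, family, map, parents = parents)
}

#' Per-family alternate-allele frequencies
#'
#' @param pop a [nam_population].
#' @return family x marker matrix of within-family mean genotype codes.
#' @export
family_allele_freq <- function(pop) {
  t(sapply(levels(pop$family), function(f)
    colMeans(pop$geno[pop$family == f, , drop = FALSE], na.rm = TRUE)))
}

#' Write / read RIL genotypes as TSV
#'
#' Wide layout: one row per RIL with `ril` and `family` columns followed
#' by one column per marker.
#'
#' @param pop a [nam_population].
#' @param path file path.
#' @param map a [genetic_map] used to re-validate markers on read.
#' @param ... provenance header fields.
#' @export
write_genotypes <- function(pop, path, ...) {
  df <- data.frame(ril = rownames(pop$geno), family = as.character(pop$family),
                   pop$geno, check.names = FALSE)
  write_stage_tsv(df, path, stage = "genotypes", ...)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, map) {
  df <- read_stage_tsv(path)
  geno <- as.matrix(df[, setdiff(names(df), c("ril", "family")), drop = FALSE])
  rownames(geno) <- df$ril
  nam_population(geno, df$family, map)
}
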