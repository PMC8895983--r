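## Locus resolution: merging QTL support intervals across traits,
## LD profiling around associated variants, and candidate-gene
## resolution by the triple criterion (association search space,
## same-trait JL interval, a priori evidence).
##
## All interval arithmetic is 1-based closed, via IRanges/GenomicRanges;
## BED input (0-based half-open) is converted on read.

#' Merge physically overlapping intervals across traits
#'
#' Sweep-line union of intervals sharing at least one bp (closed
#' convention: `[1,5]` and `[6,8]` do NOT overlap), per chromosome.
#' Member (trait, interval) pairs are recorded per merged interval.
#'
#' @param intervals data frame with columns `trait`, `chrom`,
#'   `left_bp`, `right_bp` (e.g. row-bound [support_interval] outputs,
#'   with `start_bp`/`end_bp` accepted as aliases).
#' @return A `common_intervals` object: `intervals` (data frame
#'   `interval_id`, `chrom`, `start_bp`, `end_bp`, `n_members`) and
#'   `members` (data frame `interval_id`, `trait`, `chrom`,
#'   `start_bp`, `end_bp`).
#' @export
merge_intervals <- function(intervals) {
  iv <- as.data.frame(intervals)
  if ("left_bp" %in% names(iv)) {
    iv$start_bp <- iv$left_bp; iv$end_bp <- iv$right_bp
  }
  if (any(iv$start_bp > iv$end_bp)) stop("interval start > end")
  gr <- GenomicRanges::GRanges(as.character(iv$chrom),
                               IRanges::IRanges(iv$start_bp, iv$end_bp))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  mtab <- data.frame(
    interval_id = S4Vectors::subjectHits(hits),
    trait = iv$trait[S4Vectors::queryHits(hits)],
    chrom = iv$chrom[S4Vectors::queryHits(hits)],
    start_bp = iv$start_bp[S4Vectors::queryHits(hits)],
    end_bp = iv$end_bp[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  out <- data.frame(
    interval_id = seq_along(merged),
    chrom = as.integer(as.character(GenomicRanges::seqnames(merged))),
    start_bp = GenomicRanges::start(merged),
    end_bp = GenomicRanges::end(merged),
    n_members = as.vector(table(factor(mtab$interval_id,
                                       levels = seq_along(merged)))))
  structure(list(intervals = out, members = mtab),
            class = "common_intervals")
}

#' @export
print.common_intervals <- function(x, ...) {
  cat("Common support intervals:", nrow(x$intervals), "merged from",
      nrow(x$members), "member interval(s)\n")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' LD profile around associated variants, against a random-variant null
#'
#' Squared Pearson correlation of dosages between each focal variant and
#' every variant within `window_bp`, compared with the same statistic
#' for a random draw of variants (the null). Zero-variance columns are
#' skipped and counted.
#'
#' @param focal character vector of focal variant ids (e.g. reported
#'   GWAS variants).
#' @param pv a `projected_variants` (dosage source for all variants).
#' @param window_bp half-window in bp (default 250000).
#' @param n_null number of random null focal variants (default 50000,
#'   capped at the number available).
#' @param seed integer seed.
#' @return list: `observed`, `null` (numeric r^2 vectors), `n_skipped`,
#'   `window_bp`.
#' @export
ld_profile <- function(focal, pv, window_bp = 250000, n_null = 50000,
                       seed = 1) {
  info <- pv$info
  dos <- pv$dosage
  sds <- apply(dos, 2, stats::sd)
  skipped <- sum(sds < 1e-12)
  r2_around <- function(ids) {
    out <- list()
    for (v in ids) {
      i <- match(v, info$variant)
      if (is.na(i) || sds[i] < 1e-12) next
      nb <- which(info$chrom == info$chrom[i] &
                  abs(info$bp - info$bp[i]) <= window_bp &
                  info$variant != v & sds >= 1e-12)
      if (!length(nb)) next
      out[[v]] <- drop(stats::cor(dos[, i], dos[, nb, drop = FALSE]))^2
    }
    unlist(out, use.names = FALSE)
  }
  obs <- r2_around(focal)
  set.seed(seed)
  null_ids <- sample(info$variant, min(n_null, nrow(info)))
  nul <- r2_around(null_ids)
  list(observed = obs, null = nul, n_skipped = skipped,
       window_bp = window_bp)
}

#' Read gene annotations from BED or GFF3
#'
#' BED (0-based half-open) is converted to 1-based closed coordinates on
#' read; GFF3 `gene` features are used as-is. Falls back to a plain TSV
#' with columns `gene`, `chrom`, `start_bp`, `end_bp`.
#'
#' @param path annotation file (`.bed`, `.gff`/`.gff3`, or TSV).
#' @return data frame `gene`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_gene_annotations <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bed", "gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading ", ext, " needs the rtracklayer package")
    gr <- rtracklayer::import(path)
    if (ext %in% c("gff", "gff3")) {
      gr <- gr[gr$type == "gene"]
      ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
    } else ids <- gr$name
    data.frame(gene = as.character(ids),
               chrom = as.integer(as.character(GenomicRanges::seqnames(gr))),
               start_bp = GenomicRanges::start(gr),
               end_bp = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
  } else {
    read_stage_tsv(path)
  }
}

#' Resolve candidate genes by the triple criterion
#'
#' A gene qualifies iff (i) its span intersects the search space
#' `[variant - window_bp, variant + window_bp]` of at least one reported
#' association, (ii) its span overlaps an individual-trait JL support
#' interval for at least one of the SAME traits, and (iii) it is on the
#' a priori candidate list. Supporting traits, variants and intervals
#' are recorded per gene.
#'
#' @param common_intervals a `common_intervals` object (supplies the
#'   member individual-trait intervals).
#' @param rmip an `rmip_table` (reported associations only are used).
#' @param genes gene annotation data frame (see
#'   [read_gene_annotations]).
#' @param apriori character vector of a priori candidate gene ids.
#' @param window_bp association search-space half-window (default
#'   250000).
#' @param containment `"overlap"` (default) or `"within"`: whether a
#'   gene must merely overlap or lie fully inside the JL interval.
#' @return data frame of candidate genes: `gene`, `chrom`, `start_bp`,
#'   `end_bp`, `traits`, `variants`, `max_rmip`, `interval_ids`.
#' @export
resolve_genes <- function(common_intervals, rmip, genes, apriori,
                          window_bp = 250000, containment = "overlap") {
  containment <- match.arg(containment, c("overlap", "within"))
  assoc <- as.data.frame(rmip)[rmip$reported, , drop = FALSE]
  mem <- common_intervals$members
  if (length(setdiff(genes$chrom, mem$chrom)) &&
      !any(genes$chrom %in% c(mem$chrom, assoc$chrom)))
    warning("no shared chromosomes between annotations and intervals")
  out <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (!(g$gene %in% apriori)) next                     # (iii)
    hit_assoc <- assoc[assoc$chrom == g$chrom &
                       assoc$bp + window_bp >= g$start_bp &
                       assoc$bp - window_bp <= g$end_bp, , drop = FALSE]
    if (!nrow(hit_assoc)) next                           # (i)
    in_iv <- if (containment == "overlap")
      mem[mem$chrom == g$chrom & mem$end_bp >= g$start_bp &
          mem$start_bp <= g$end_bp, , drop = FALSE]
    else
      mem[mem$chrom == g$chrom & mem$start_bp <= g$start_bp &
          mem$end_bp >= g$end_bp, , drop = FALSE]
    shared <- intersect(unique(hit_assoc$trait), unique(in_iv$trait))
    if (!length(shared)) next                            # (ii), same trait
    keep_assoc <- hit_assoc[hit_assoc$trait %in% shared, ]
    out[[g$gene]] <- data.frame(
      gene = g$gene, chrom = g$chrom, start_bp = g$start_bp,
      end_bp = g$end_bp,
      traits = paste(sort(shared), collapse = ","),
      variants = paste(unique(keep_assoc$variant), collapse = ","),
      max_rmip = max(keep_assoc$rmip),
      interval_ids = paste(sort(unique(
        in_iv$interval_id[in_iv$trait %in% shared])), collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(0), chrom = integer(0),
               start_bp = numeric(0), end_bp = numeric(0),
               traits = character(0), variants = character(0),
               max_rmip = integer(0), interval_ids = character(0))
  rownames(res) <- NULL
  res
}
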