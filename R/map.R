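#' Genetic map objects
#'
#' A `genetic_map` is a data frame with one row per marker and columns
#' `marker` (unique id), `chrom` (integer chromosome), `cM` (genetic
#' position, strictly increasing within chromosome) and `bp` (physical
#' position, strictly increasing within chromosome). It is the mapping
#' backbone shared by the RIL simulator, the joint-linkage scan and
#' variant projection.
#'
#' @param markers character vector of unique marker ids.
#' @param chrom integer chromosome per marker.
#' @param cM numeric genetic position in centiMorgans.
#' @param bp integer physical position in base pairs.
#' @return A `genetic_map` object (a validated data frame).
#' @export
genetic_map <- function(markers, chrom, cM, bp) {
  map <- data.frame(marker = as.character(markers),
                    chrom = as.integer(chrom),
                    cM = as.numeric(cM),
                    bp = as.numeric(bp),
                    stringsAsFactors = FALSE)
  validate_genetic_map(map)
}

validate_genetic_map <- function(map) {
  stopifnot(all(c("marker", "chrom", "cM", "bp") %in% names(map)))
  if (anyDuplicated(map$marker))
    stop("marker ids must be unique")
  if (any(map$cM < 0) || any(map$bp < 0))
    stop("map positions must be non-negative")
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (is.unsorted(sub$cM, strictly = TRUE))
      stop("cM positions must be strictly increasing within chromosome ", ch)
    if (is.unsorted(sub$bp, strictly = TRUE))
      stop("bp positions must be strictly increasing within chromosome ", ch)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Simulate an evenly spaced genetic map
#'
#' Places markers at `0, step_cM, 2*step_cM, ...` up to `length_cM` on each
#' chromosome, with physical positions `bp = round(cM * bp_per_cM)`. An
#' even 0.1 cM grid over 10 chromosomes is the backbone used for
#' joint-linkage scans of NAM panels; coarser grids are convenient for
#' simulation studies.
#'
#' @param n_chrom number of chromosomes.
#' @param length_cM chromosome length in cM.
#' @param step_cM marker spacing in cM.
#' @param bp_per_cM physical bases per cM (default 1e6, of the order of
#'   cereal genome averages). Must give strictly increasing bp.
#' @return A [genetic_map].
#' @examples
#' map <- simulate_map(1, 100, 0.1)
#' nrow(map)  # 1001
#' @export
simulate_map <- function(n_chrom, length_cM, step_cM, bp_per_cM = 1e6) {
  if (n_chrom < 1 || length_cM <= 0 || step_cM <= 0 || bp_per_cM <= 0)
    stop("all arguments must be positive")
  if (step_cM > length_cM)
    stop("step_cM must not exceed length_cM")
  n_steps <- floor(length_cM / step_cM + 1e-9)
  pos <- seq(0, by = step_cM, length.out = n_steps + 1)
  per_chrom <- length(pos)
  chrom <- rep(seq_len(n_chrom), each = per_chrom)
  cM <- rep(pos, n_chrom)
  idx <- rep(seq_len(per_chrom), n_chrom)
  genetic_map(markers = sprintf("m%d_%d", chrom, idx),
              chrom = chrom, cM = cM, bp = round(cM * bp_per_cM))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", nrow(x), "markers on", length(unique(x$chrom)),
      "chromosome(s)\n")
  spans <- tapply(x$cM, x$chrom, max)
  cat("  chromosome span(s) cM:", paste(format(spans), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a genetic map as 4-column TSV
#'
#' @param map a [genetic_map].
#' @param path file path.
#' @param ... passed to the provenance header writer (`stage`, `seed`,
#'   `config_hash`).
#' @return `read_map` returns a [genetic_map]; rows are sorted on load
#'   (with a warning if the file was unsorted).
#' @export
write_map <- function(map, path, ...) {
  write_stage_tsv(as.data.frame(map), path, stage = "map", ...)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- read_stage_tsv(path)
  ord <- order(df$chrom, df$cM)
  if (any(ord != seq_len(nrow(df)))) {
    warning("map rows were not sorted; sorting on load")
    df <- df[ord, , drop = FALSE]
  }
  genetic_map(df$marker, df$chrom, df$cM, df$bp)
}

## linear cM <-> bp interpolation within a chromosome, used by variant
## projection; extrapolation is clamped to the terminal markers
map_bp_to_cM <- function(map, chrom, bp) {
  sub <- map[map$chrom == chrom, ]
  if (nrow(sub) == 0) stop("chromosome ", chrom, " not on map")
  stats::approx(sub$bp, sub$cM, xout = pmin(pmax(bp, min(sub$bp)), max(sub$bp)),
                ties = "ordered")$y
}
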