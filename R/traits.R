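#' Field design specification for the plot-level trait simulator
#'
#' Emulates an augmented incomplete-block sets design evaluated over
#' multiple years: within each year every line is grown once; each family
#' forms one set within a field; sets are cut into incomplete blocks laid
#' out consecutively on a row x range grid, one grid per field. Variance
#' components of the design strata are expressed as fractions of the
#' realized within-family genetic variance, so the generator adapts to
#' whatever architecture it is given.
#'
#' @param years year labels; each year contributes one plot per line.
#' @param fields_per_year integer number of fields per year (families are
#'   split evenly across a year's fields). Default `c(2, 1)`: three
#'   fields over two years.
#' @param block_size plots per incomplete block.
#' @param n_range ranges (columns) per field grid; rows fill row-major.
#' @param v_year,v_field,v_set,v_block,v_plate,v_fam_year variance of the
#'   corresponding random stratum as a fraction of genetic variance.
#'   `v_fam_year` is the family-by-year (genotype-by-environment) stratum
#'   entering the heritability denominator.
#' @param rho_row,rho_range AR1 correlations of the spatial plot error in
#'   the row and range directions (separable AR1 x AR1 per field).
#' @param plate_size plots per autosampler plate (assay batching).
#' @param family_means optional named numeric vector of family intercepts
#'   (trait units); if `NULL`, drawn once per call from
#'   N(0, v_family * sigma2_g).
#' @param v_family variance fraction for drawn family intercepts.
#' @return A `field_design` list.
#' @export
field_design <- function(years = c(2009, 2010), fields_per_year = c(2, 1),
                         block_size = 20, n_range = 20,
                         v_year = 0.3, v_field = 0.15, v_set = 0.1,
                         v_block = 0.1, v_plate = 0, v_fam_year = 0,
                         rho_row = 0.4, rho_range = 0.4,
                         plate_size = 90, family_means = NULL, v_family = 0.5) {
  structure(list(years = years,
                 fields_per_year = rep_len(fields_per_year, length(years)),
                 block_size = block_size, n_range = n_range,
                 v_year = v_year, v_field = v_field, v_set = v_set,
                 v_block = v_block, v_plate = v_plate,
                 v_fam_year = v_fam_year,
                 rho_row = rho_row, rho_range = rho_range,
                 plate_size = plate_size, family_means = family_means,
                 v_family = v_family),
            class = "field_design")
}

#' Line genetic values implied by a trait architecture
#'
#' Sums the family-nested QTL effects over each RIL's genotype, per
#' trait. These are the noise-free line values the phenotype simulator
#' builds on, and the natural truth reference in simulation studies.
#'
#' @param pop a [nam_population].
#' @param arch a [trait_architecture].
#' @return RIL x trait matrix of genetic values.
#' @export
genetic_values <- function(pop, arch) {
  traits <- names(arch$h2)
  gv <- matrix(0, nrow(pop$geno), length(traits),
               dimnames = list(rownames(pop$geno), traits))
  eff <- arch$effects
  if (is.null(eff) || nrow(eff) == 0) return(gv)
  if (!all(eff$marker %in% colnames(pop$geno)))
    stop("all QTL must reference markers on the map/genotypes")
  fam <- as.character(pop$family)
  for (k in seq_len(nrow(eff))) {
    rows <- fam == eff$family[k]
    gv[rows, eff$trait[k]] <- gv[rows, eff$trait[k]] +
      eff$effect[k] * pop$geno[rows, eff$marker[k]]
  }
  gv
}

## lay out the plots of one year: returns data.frame of design factors
layout_year <- function(pop, design, year, n_fields) {
  fams <- levels(pop$family)
  field_of_fam <- rep(seq_len(n_fields), length.out = length(fams))
  names(field_of_fam) <- fams
  out <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    fams_f <- fams[field_of_fam == f]
    rows <- which(as.character(pop$family) %in% fams_f)
    if (!length(rows)) next    # more fields than families

    ril <- rownames(pop$geno)[rows]
    fam <- as.character(pop$family)[rows]
    ord <- order(fam)      # one set (= family) at a time, blocks within
    ril <- ril[ord]; fam <- fam[ord]
    n <- length(ril)
    idx <- seq_len(n)
    blk_in_field <- ceiling(idx / design$block_size)
    plot_row <- ceiling(idx / design$n_range)
    plot_range <- ((idx - 1L) %% design$n_range) + 1L
    out[[f]] <- data.frame(ril = ril, family = fam, year = year,
                           field = sprintf("%s_f%d", year, f),
                           set = fam,   # sets design: one set per family
                           block = sprintf("b%d", blk_in_field),
                           row = plot_row, range = plot_range,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## AR1 x AR1 unit-variance field noise on the plots of one field
ar1_field_noise <- function(rowi, rangei, rho_row, rho_range) {
  nr <- max(rowi); nc <- max(rangei)
  ar1_chol <- function(n, rho) {
    if (n == 1) return(matrix(1, 1, 1))
    C <- rho ^ abs(outer(seq_len(n), seq_len(n), "-"))
    chol(C)
  }
  Lr <- ar1_chol(nr, rho_row)
  Lc <- ar1_chol(nc, rho_range)
  Z <- matrix(stats::rnorm(nr * nc), nr, nc)
  E <- t(Lr) %*% Z %*% Lc
  E[cbind(rowi, rangei)]
}

#' Simulate plot-level phenotypes over a multi-year field design
#'
#' The plot value for line i, trait t is
#' `sum_q a_{f(i),q,t} * genotype + family intercept + year + field + set
#'  + block (+ plate, + family-by-year) random draws + AR1xAR1 spatial
#'  residual`. The residual variance is calibrated from the realized
#' (pooled within-family) genetic variance so the target line-mean
#' heritability holds:
#' `sigma2_e = p_bar * (sigma2_g (1 - h2)/h2 - sigma2_ge / e_bar)` with
#' `e_bar`, `p_bar` the harmonic mean numbers of environments and plots
#' per line.
#'
#' @param pop a [nam_population].
#' @param arch a [trait_architecture].
#' @param design a [field_design].
#' @param seed integer seed.
#' @return A `plot_table` data frame in long format: `ril`, `family`,
#'   `year`, `field`, `set`, `block`, `row`, `range`, `plate`, `trait`,
#'   `value`.
#' @export
simulate_traits <- function(pop, arch, design = field_design(), seed = 1) {
  if (any(arch$h2 <= 0 | arch$h2 > 1)) stop("h2 targets must lie in (0, 1]")
  set.seed(seed)
  gv <- genetic_values(pop, arch)
  traits <- colnames(gv)
  fam <- as.character(pop$family)

  plots <- do.call(rbind, lapply(seq_along(design$years), function(y)
    layout_year(pop, design, design$years[y], design$fields_per_year[y])))
  plots$plate <- sprintf("p%d", ceiling(seq_len(nrow(plots)) / design$plate_size))

  e_bar <- length(design$years)                 # environments per line
  p_bar <- length(design$years)                 # one plot per line per year

  long <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    g <- gv[, tr][plots$ril]
    ## pooled within-family genetic variance of line values
    s2g <- mean(tapply(gv[, tr], fam, stats::var))
    if (!is.finite(s2g) || s2g == 0) s2g_scale <- 1 else s2g_scale <- s2g
    h2 <- arch$h2[[tr]]
    s2ge <- design$v_fam_year * s2g_scale
    s2e <- p_bar * (s2g_scale * (1 - h2) / h2 - s2ge / e_bar)
    if (s2g == 0) s2e <- if (h2 == 1) 0 else s2e
    s2e <- max(s2e, 0)

    draw <- function(f, v) {
      u <- stats::rnorm(length(unique(f)), 0, sqrt(v * s2g_scale))
      names(u) <- unique(f)
      u[f]
    }
    fm <- design$family_means
    if (is.null(fm)) {
      fm <- stats::rnorm(nlevels(pop$family), 0, sqrt(design$v_family * s2g_scale))
      names(fm) <- levels(pop$family)
    }
    val <- g + fm[plots$family] +
      draw(as.character(plots$year), design$v_year) +
      draw(plots$field, design$v_field) +
      draw(paste(plots$field, plots$set), design$v_set) +
      draw(paste(plots$field, plots$set, plots$block), design$v_block) +
      draw(plots$plate, design$v_plate) +
      draw(paste(plots$family, plots$year), design$v_fam_year)
    ## spatial residual per field
    eps <- numeric(nrow(plots))
    for (fd in unique(plots$field)) {
      sel <- plots$field == fd
      eps[sel] <- ar1_field_noise(plots$row[sel], plots$range[sel],
                                  design$rho_row, design$rho_range)
    }
    val <- val + sqrt(s2e) * eps
    long[[ti]] <- data.frame(plots, trait = tr, value = unname(val),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, long)
  rownames(out) <- NULL
  class(out) <- c("plot_table", "data.frame")
  out
}

#' Write / read a plot table as long-format TSV
#' @param plots a `plot_table`.
#' @param path file path.
#' @param ... provenance header fields.
#' @export
write_plot_table <- function(plots, path, ...) {
  write_stage_tsv(as.data.frame(plots), path, stage = "plots", ...)
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  out <- read_stage_tsv(path)
  class(out) <- c("plot_table", "data.frame")
  out
}
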