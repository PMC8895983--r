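## Orchestration: configuration, typed loaders, and the end-to-end
## synthetic-validation workflow binding all stages.

#' Pipeline configuration
#'
#' Collects the stage parameters of the full workflow with the
#' conventional defaults: 1,000 permutations at alpha = 0.05 for entry
#' thresholds, alpha = 0.01 support intervals, 100 GWAS iterations at
#' 80% bootstrap subsampling, RMIP reporting cutoff 5, 250 kb search
#' windows, multicollinearity pruning at |r| > 0.8, GWAS FDR 0.05,
#' 1,000-tree forests with 70/30 splits over 30 seeds.
#'
#' @param paths named list of input paths (`map`, `genotypes`,
#'   `variants`, `plots` or `blues`, `annotations`, `apriori`); unused
#'   in synthetic-validation mode.
#' @param mode `"synthetic-validation"` or `"real-data"`.
#' @param n_perm,alpha,interval_alpha,n_iter,subsample,rmip_report,window_bp,r_threshold,fdr,n_trees,test_fraction,seeds
#'   stage parameters (see the stage functions).
#' @param dffits_threshold DFFITS cutoff for outlier screening
#'   (`NULL` = the `2 sqrt(p/n)` default).
#' @param candidate_random,candidate_residual candidate structures for
#'   the BLUE stage (see [select_structure]).
#' @param sim list of synthetic-data settings (`n_families`, `n_ril`,
#'   `n_chrom`, `length_cM`, `step_cM`, `density_per_Mb`, `h2`).
#' @param seed master seed; all stage seeds derive from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(paths = list(), mode = "synthetic-validation",
                            n_perm = 1000, alpha = 0.05,
                            interval_alpha = 0.01, n_iter = 100,
                            subsample = 0.8, rmip_report = 5,
                            window_bp = 250000, r_threshold = 0.8,
                            fdr = 0.05, n_trees = 1000, test_fraction = 0.3,
                            seeds = 1:30, dffits_threshold = 3,
                            candidate_random = list(character(0),
                                                    c("set", "block")),
                            candidate_residual = c("idh_year", "ar1ar1"),
                            sim = list(), seed = 1) {
  mode <- match.arg(mode, c("synthetic-validation", "real-data"))
  probs <- c(alpha = alpha, interval_alpha = interval_alpha,
             subsample = subsample, fdr = fdr,
             test_fraction = test_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  counts <- c(n_perm = n_perm, n_iter = n_iter, rmip_report = rmip_report,
              window_bp = window_bp, n_trees = n_trees)
  if (any(counts <= 0)) stop("counts must be positive")
  sim_def <- list(n_families = 5, n_ril = 100, n_chrom = 2, length_cM = 120,
                  step_cM = 1, bp_per_cM = 1e6, density_per_Mb = 2,
                  h2 = 0.8, n_traits = 3)
  sim_def[names(sim)] <- sim
  structure(list(paths = paths, mode = mode, n_perm = n_perm, alpha = alpha,
                 interval_alpha = interval_alpha, n_iter = n_iter,
                 subsample = subsample, rmip_report = rmip_report,
                 window_bp = window_bp, r_threshold = r_threshold,
                 fdr = fdr, n_trees = n_trees,
                 test_fraction = test_fraction, seeds = seeds,
                 dffits_threshold = dffits_threshold,
                 candidate_random = candidate_random,
                 candidate_residual = candidate_residual, sim = sim_def,
                 seed = seed),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$candidate_random))
    y$candidate_random <- lapply(y$candidate_random, as.character)
  if (!is.null(y$candidate_residual))
    y$candidate_residual <- as.character(y$candidate_residual)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Typed loaders with invariants enforced on load
#'
#' `load_map` reads a 4-column TSV map (sorting unsorted rows with a
#' warning); `load_genotypes` reads a wide genotype TSV against a map;
#' `load_blues` reads a wide BLUE table.
#'
#' @param path file path.
#' @param map a [genetic_map] (for `load_genotypes`).
#' @return the corresponding typed object.
#' @export
load_map <- function(path) read_map(path)

#' @rdname load_map
#' @export
load_genotypes <- function(path, map) read_genotypes(path, map)

#' @rdname load_map
#' @export
load_blues <- function(path) read_blues(path)

## default synthetic trait architecture used by the validation workflow:
## three correlated traits sharing one pleiotropic QTL plus one
## trait-specific QTL each, mirroring a branchpoint-like architecture
default_sim_architecture <- function(pop, sim, seed) {
  map <- pop$map
  fams <- levels(pop$family)
  mk <- function(chrom, frac) {
    sub <- map[map$chrom == chrom, ]
    sub$marker[round(frac * (nrow(sub) - 1)) + 1]
  }
  traits <- sprintf("trait%d", seq_len(sim$n_traits))
  eff <- rbind(
    pleiotropic_qtl(mk(1, 0.5), traits, fams, mean_effect = 1,
                    sd_effect = 0.3, rho = 0.8, seed = derive_seed(seed, 11)),
    do.call(rbind, lapply(seq_along(traits), function(i)
      pleiotropic_qtl(mk((i %% sim$n_chrom) + 1, 0.25 + 0.1 * i), traits[i],
                      fams, mean_effect = 0.8, sd_effect = 0.25, rho = 1,
                      seed = derive_seed(seed, 20 + i)))))
  h2 <- stats::setNames(rep_len(sim$h2, length(traits)), traits)
  trait_architecture(eff, h2)
}

#' Run the end-to-end workflow
#'
#' Executes the stages in order (simulate where in synthetic-validation
#' mode, then BLUEs, joint linkage, GWAS, pleiotropy, locus resolution,
#' trait-prediction models), writing one TSV per stage into `out_dir`
#' together with a provenance manifest (stage, seed, config hash,
#' record counts, wall time). A failed stage halts with its name; a
#' missing a priori list downgrades the locus stage to a warning.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with all stage objects and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("namqtl_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- config_hash(unclass(config))
  manifest <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest[[name]] <<- list(stage = name,
                              seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    val
  }
  wr <- function(df, file, stage) {
    write_stage_tsv(as.data.frame(df), file.path(out_dir, file), stage = stage,
                    seed = config$seed, config_hash = ch)
    manifest[[stage]]$records <<- nrow(df)
  }
  sim <- config$sim

  dat <- t_stage("simulate", {
    map <- simulate_map(sim$n_chrom, sim$length_cM, sim$step_cM, sim$bp_per_cM)
    pop <- simulate_nam_population(map, n_families = sim$n_families,
                                   n_ril = sim$n_ril,
                                   seed = derive_seed(config$seed, 1))
    arch <- default_sim_architecture(pop, sim, config$seed)
    plots <- simulate_traits(pop, arch, field_design(),
                             seed = derive_seed(config$seed, 2))
    variants <- simulate_dense_variants(pop, sim$density_per_Mb,
                                        seed = derive_seed(config$seed, 3))
    pv <- project_variants(variants, pop)
    list(map = map, pop = pop, arch = arch, plots = plots, pv = pv)
  })
  wr(dat$map, "map.tsv", "simulate")
  write_genotypes(dat$pop, file.path(out_dir, "genotypes.tsv"),
                  seed = config$seed, config_hash = ch)
  write_plot_table(dat$plots, file.path(out_dir, "plots.tsv"),
                   seed = config$seed, config_hash = ch)

  traits <- names(dat$arch$h2)
  fam_of <- stats::setNames(as.character(dat$pop$family),
                            rownames(dat$pop$geno))

  stages <- t_stage("blues", {
    out <- lapply(traits, function(tr)
      blue_stage(dat$plots, tr,
                 candidate_random = config$candidate_random,
                 candidate_residual = config$candidate_residual,
                 dffits_threshold = config$dffits_threshold))
    names(out) <- traits
    out
  })
  blues <- blue_table(stages, family = fam_of)
  wr(blues, "blues.tsv", "blues")
  herit <- data.frame(trait = traits,
                      h2 = vapply(stages, function(s) s$h2$estimate, 1),
                      se = vapply(stages, function(s) s$h2$se, 1))
  wr(herit, "heritability.tsv", "blues")

  jl <- t_stage("joint_linkage", {
    out <- lapply(traits, function(tr) {
      y <- stats::setNames(blues[[paste0(tr, "_bc")]], blues$line)
      jl_stage(y, dat$pop$geno, dat$pop$family[match(blues$line, rownames(dat$pop$geno))],
               dat$map, trait = tr, n_perm = config$n_perm,
               alpha = config$alpha, interval_alpha = config$interval_alpha,
               r_threshold = config$r_threshold,
               seed = derive_seed(config$seed, 4))
    })
    names(out) <- traits
    out
  })
  ivs <- do.call(rbind, lapply(jl, `[[`, "intervals"))
  effs <- do.call(rbind, lapply(jl, `[[`, "effects"))
  pves <- do.call(rbind, lapply(jl, `[[`, "pve"))
  if (!is.null(ivs)) wr(ivs, "jl_intervals.tsv", "joint_linkage")
  if (!is.null(effs)) wr(effs, "jl_effects.tsv", "joint_linkage")
  if (!is.null(pves)) wr(pves, "jl_pve.tsv", "joint_linkage")

  gw <- t_stage("gwas", {
    out <- lapply(traits, function(tr)
      gwas_stage(jl[[tr]]$model, dat$pv, n_perm = max(100, config$n_perm %/% 5),
                 fdr = config$fdr, n_iter = config$n_iter,
                 subsample = config$subsample,
                 seed = derive_seed(config$seed, 5),
                 rmip_report = config$rmip_report))
    names(out) <- traits
    out
  })
  rmip_all <- do.call(rbind, lapply(gw, function(g) as.data.frame(g$rmip)))
  wr(rmip_all, "gwas_rmip.tsv", "gwas")

  common <- if (!is.null(ivs)) merge_intervals(ivs) else NULL

  plei <- t_stage("pleiotropy", {
    models <- lapply(jl, `[[`, "model")
    bm <- as.matrix(blues[, paste0(traits, "_bc"), drop = FALSE])
    colnames(bm) <- traits
    rownames(bm) <- blues$line
    pleiotropy_stage(models, bm, common_intervals = common)
  })
  write_pleiotropy(plei, file.path(out_dir, "pleiotropy.tsv"),
                   seed = config$seed, config_hash = ch)

  loci <- t_stage("loci", {
    if (is.null(common)) NULL else {
      apriori <- config$paths$apriori
      genes <- config$paths$annotations
      if (is.null(apriori) || is.null(genes)) {
        warning("no annotation/a priori inputs; locus resolution skipped")
        list(common = common, genes = NULL)
      } else {
        gtab <- read_gene_annotations(genes)
        alist <- read_stage_tsv(apriori)$gene
        rg <- resolve_genes(common,
                            structure(rmip_all,
                                      class = c("rmip_table", "data.frame")),
                            gtab, alist, window_bp = config$window_bp)
        list(common = common, genes = rg)
      }
    }
  })
  if (!is.null(common)) wr(common$intervals, "common_intervals.tsv", "loci")
  if (!is.null(loci$genes)) wr(loci$genes, "candidate_genes.tsv", "loci")

  color <- t_stage("color_model", {
    response <- traits[1]
    preds <- setdiff(traits, response)
    bdf <- data.frame(family = blues$family,
                      stats::setNames(as.data.frame(
                        blues[, paste0(traits, "_bc"), drop = FALSE]), traits))
    specs <- list(full = list(predictors = preds, family = TRUE),
                  no_family = list(predictors = preds, family = FALSE))
    cmp <- compare_linear_models(bdf, response, specs)
    rf <- fit_random_forest(bdf, response, preds,
                            n_trees = config$n_trees,
                            test_fraction = config$test_fraction,
                            seeds = config$seeds)
    list(comparison = cmp, rf = rf)
  })
  wr(color$comparison, "model_comparison.tsv", "color_model")
  wr(color$rf$metrics, "rf_metrics.tsv", "color_model")

  mdf <- do.call(rbind, lapply(manifest, function(m)
    data.frame(stage = m$stage, seconds = m$seconds,
               records = m$records %||% NA)))
  write_stage_tsv(mdf, file.path(out_dir, "manifest.tsv"), stage = "manifest",
                  seed = config$seed, config_hash = ch)
  invisible(list(data = dat, blues = blues, heritability = herit,
                 jl = jl, gwas = gw, pleiotropy = plei, common = common,
                 loci = loci, color = color, manifest = mdf,
                 out_dir = out_dir))
}
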