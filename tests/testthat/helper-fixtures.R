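# Shared fixtures, built once per test run. Sizes are kept small enough
# for interactive use while preserving the statistical structure the
# assertions rely on.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_cache))
    assign(name, builder(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# 2 chromosomes x 101 markers at 1 cM
fix_map <- function() fixture("map", function() simulate_map(2, 100, 1))

# 5 families x 80 RILs on fix_map
fix_pop <- function() fixture("pop", function()
  simulate_nam_population(fix_map(), n_families = 5, n_ril = 80, seed = 42))

# a QTL on chr1 mid plus a trait-A-specific QTL on chr2, phenotypes at
# moderate noise; returns list(yA, yB, arch, thr, modA)
fix_jl <- function() fixture("jl", function() {
  pop <- fix_pop()
  fams <- levels(pop$family)
  set.seed(7)
  eff <- rbind(
    pleiotropic_qtl("m1_51", c("tA", "tB"), fams, mean_effect = 1,
                    sd_effect = 0.3, rho = 0.9, seed = 2),
    pleiotropic_qtl("m2_31", "tA", fams, mean_effect = 0.8, rho = 1, seed = 3))
  arch <- trait_architecture(eff, h2 = c(tA = 0.8, tB = 0.8))
  gv <- genetic_values_of(pop, arch)
  yA <- gv[, "tA"] + rnorm(nrow(gv), 0, sd(gv[, "tA"]) * 0.7)
  yB <- gv[, "tB"] + rnorm(nrow(gv), 0, sd(gv[, "tB"]) * 0.7)
  names(yA) <- names(yB) <- rownames(pop$geno)
  thr <- jl_permutation_threshold(yA, pop$geno, pop$family, n_perm = 100,
                                  seed = 4)
  modA <- stepwise_jl(yA, pop$geno, pop$family, fix_map(), thr$entry_p,
                      trait = "tA")
  modA <- rescan_peaks(prune_multicollinear(modA), thr)
  list(yA = yA, yB = yB, arch = arch, thr = thr, modA = modA, gv = gv)
})

# truth reference for simulation-based assertions
genetic_values_of <- function(pop, arch) genetic_values(pop, arch)

# plot table on a small dedicated population (rapid mixed-model tests):
# 3 families x 50 RILs, two years
fix_plots <- function() fixture("plots", function() {
  map <- simulate_map(1, 60, 2)
  pop <- simulate_nam_population(map, n_families = 3, n_ril = 50, seed = 11)
  fams <- levels(pop$family)
  eff <- pleiotropic_qtl("m1_16", "t", fams, mean_effect = 1,
                         sd_effect = 0.3, rho = 1, seed = 5)
  arch <- trait_architecture(eff, h2 = c(t = 0.7))
  list(pop = pop, arch = arch,
       plots = simulate_traits(pop, arch, field_design(), seed = 8))
})

# balanced one-way layout: g lines x r reps, single year/field
one_way_plots <- function(g, r, s2g, s2e, seed = 1) {
  set.seed(seed)
  ril <- rep(sprintf("L%03d", seq_len(g)), each = r)
  y <- rep(rnorm(g, 0, sqrt(s2g)), each = r) + rnorm(g * r, 0, sqrt(s2e))
  structure(data.frame(ril = ril, family = "F1", year = 2009, field = "f1",
                       set = "s", block = "b",
                       row = rep(seq_len(g), each = r),
                       range = rep(seq_len(r), g),
                       plate = "p1", trait = "t", value = y),
            class = c("plot_table", "data.frame"))
}
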