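# Joint-linkage mapping: thresholds, stepwise selection, pruning,
# re-scan, support intervals, effects, PVE

test_that("the permutation threshold is the stated order statistic", {
  jl <- fix_jl()
  thr <- jl$thr
  expect_equal(thr$entry_p, sort(thr$minima)[floor(0.05 * 100)])
  expect_equal(thr$quantile(1), max(thr$minima))
  expect_error(jl_permutation_threshold(jl$yA, fix_pop()$geno,
                                        fix_pop()$family, n_perm = 10),
               ">= 20")
  expect_error(jl_permutation_threshold(jl$yA, fix_pop()$geno,
                                        fix_pop()$family, n_perm = 50,
                                        alpha = 0.01), "alpha")
})

test_that("stepwise finds the planted QTL and is deterministic", {
  jl <- fix_jl()
  map <- fix_map()
  peaks <- jl$modA$peaks
  mi <- match(peaks, map$marker)
  # one peak within 5 cM of each planted QTL (m1_51 at 50 cM chr1,
  # m2_31 at 30 cM chr2)
  expect_true(any(map$chrom[mi] == 1 & abs(map$cM[mi] - 50) <= 5))
  expect_true(any(map$chrom[mi] == 2 & abs(map$cM[mi] - 30) <= 5))

  # identical phenotype -> identical model
  pop <- fix_pop()
  m2 <- stepwise_jl(jl$yA, pop$geno, pop$family, map, jl$thr$entry_p,
                    trait = "copy")
  m1 <- stepwise_jl(jl$yA, pop$geno, pop$family, map, jl$thr$entry_p,
                    trait = "orig")
  expect_identical(m1$peaks, m2$peaks)

  expect_error(stepwise_jl(jl$yA, pop$geno, pop$family, map,
                           entry_p = 1e-4, exit_p = 1e-5), "exit_p")
})

test_that("a pure-noise trait at the calibrated threshold stays mostly empty", {
  pop <- fix_pop()
  map <- fix_map()
  set.seed(31)
  y <- rnorm(nrow(pop$geno))
  names(y) <- rownames(pop$geno)
  thr <- jl_permutation_threshold(y, pop$geno, pop$family, n_perm = 100,
                                  seed = 13)
  mod <- stepwise_jl(y, pop$geno, pop$family, map, thr$entry_p)
  expect_lte(length(mod$peaks), 1)
})

test_that("the family term is always present and model SS never decreases", {
  jl <- fix_jl()
  X <- jl$modA$fit$X
  expect_true(all(paste0("family:", levels(fix_pop()$family)) %in%
                  colnames(X)))
  # forward path: refit models with growing peak sets; SS non-decreasing
  nd <- jl$modA$nd
  sse_prev <- Inf
  for (k in seq_along(jl$modA$peaks)) {
    fit <- namqtl:::fit_jl_set(jl$modA$y, nd, jl$modA$peaks[seq_len(k)])
    expect_lte(fit$sse, sse_prev + 1e-9)
    sse_prev <- fit$sse
  }
})

test_that("multicollinearity pruning keeps one of a duplicated pair and respects the strict threshold", {
  pop <- fix_pop()
  map <- fix_map()
  # duplicate m1_51 as its neighbour: correlation 1 within the model
  G <- pop$geno
  G[, "m1_52"] <- G[, "m1_51"]
  jl <- fix_jl()
  nd <- namqtl:::nested_design(G, pop$family)
  mod <- namqtl:::new_jl_model(jl$yA, nd, map, c("m1_51", "m1_52"),
                               0.01, 0.02, "tA")
  pruned <- prune_multicollinear(mod)
  expect_equal(length(pruned$peaks), 1)
  expect_true(pruned$peaks %in% c("m1_51", "m1_52"))

  # a pair correlated below the threshold is kept (strict >)
  r_actual <- abs(cor(pop$geno[, "m1_51"], pop$geno[, "m1_60"]))
  expect_lt(r_actual, 0.8)   # 9 cM apart: r ~ 0.7 in RILs
  mod2 <- namqtl:::new_jl_model(jl$yA,
                                namqtl:::nested_design(pop$geno, pop$family),
                                map, c("m1_51", "m1_60"), 0.01, 0.02, "tA")
  pruned2 <- prune_multicollinear(mod2, r_threshold = r_actual)
  expect_equal(length(pruned2$peaks), 2)
})

test_that("iterative pruning of mutually collinear markers keeps the max-SS member", {
  pop <- fix_pop()
  map <- fix_map()
  jl <- fix_jl()
  G <- pop$geno
  # three near-copies of the QTL marker with decreasing signal fidelity
  set.seed(17)
  G[, "m1_49"] <- G[, "m1_51"]
  G[, "m1_53"] <- G[, "m1_51"]
  flip <- sample(nrow(G), 12)
  G[flip, "m1_53"] <- 1 - G[flip, "m1_53"]
  nd <- namqtl:::nested_design(G, pop$family)
  trio <- c("m1_49", "m1_51", "m1_53")
  mod <- namqtl:::new_jl_model(jl$yA, nd, map, trio, 0.01, 0.02, "tA")
  pruned <- prune_multicollinear(mod, r_threshold = 0.6)
  expect_equal(length(pruned$peaks), 1)
  # independent oracle: the max single-marker SS member of the trio
  X0 <- namqtl:::jl_model_matrix(nd, character(0))
  sc <- namqtl:::jl_scan(jl$yA, nd, X0)
  ss <- sc$SSR[match(trio, nd$markers)]
  expect_equal(pruned$peaks, trio[which.max(ss)])
})

test_that("re-scan moves an off-peak marker to the local SS maximum and is a fixed point there", {
  jl <- fix_jl()
  pop <- fix_pop()
  map <- fix_map()
  nd <- jl$modA$nd
  true_peak <- jl$modA$peaks[grepl("^m1", jl$modA$peaks)]
  other <- setdiff(jl$modA$peaks, true_peak)
  # seed the model 2 markers off the selected chr1 peak
  off <- sprintf("m1_%d", as.integer(sub("m1_", "", true_peak)) + 2)
  mod_off <- namqtl:::new_jl_model(jl$yA, nd, map, c(off, other),
                                   jl$modA$entry_p, jl$modA$exit_p, "tA")
  rescanned <- rescan_peaks(mod_off, jl$thr)
  # exhaustive oracle: max partial SS within the support interval
  si <- support_interval(rescanned, rescanned$peaks[1], jl$thr)
  X0 <- namqtl:::jl_model_matrix(nd, other)
  sc <- namqtl:::jl_scan(jl$yA, nd, X0)
  in_iv <- map$marker[map$chrom == si$chrom & map$cM >= si$left_cM &
                      map$cM <= si$right_cM]
  ss_iv <- sc$SSR[match(intersect(in_iv, nd$markers), nd$markers)]
  best_ss <- max(ss_iv, na.rm = TRUE)
  got <- sc$SSR[match(rescanned$peaks[1], nd$markers)]
  expect_equal(got, best_ss, tolerance = 1e-9)

  # already at the local max: unchanged
  again <- rescan_peaks(rescanned, jl$thr)
  expect_identical(again$peaks, rescanned$peaks)
})

test_that("support intervals stay on the peak's chromosome and cover the planted QTL", {
  jl <- fix_jl()
  map <- fix_map()
  for (pk in jl$modA$peaks) {
    si <- support_interval(jl$modA, pk, jl$thr)
    expect_equal(si$chrom, map$chrom[match(pk, map$marker)])
    expect_lte(si$left_cM, map$cM[match(pk, map$marker)])
    expect_gte(si$right_cM, map$cM[match(pk, map$marker)])
  }
  si1 <- support_interval(jl$modA,
                          jl$modA$peaks[grepl("^m1", jl$modA$peaks)], jl$thr)
  expect_true(si1$left_cM <= 50 && si1$right_cM >= 50)
})

test_that("allelic effects recover the simulated family effects and flag monomorphic families", {
  map <- simulate_map(1, 40, 4)
  pop <- simulate_nam_population(map, n_families = 3, n_ril = 120, seed = 19)
  # family Z003 monomorphic at the QTL: overwrite with constant
  G <- pop$geno
  G[as.character(pop$family) == "Z003", "m1_6"] <- 0
  pop2 <- nam_population(G, pop$family, map, parents = pop$parents)
  eff <- data.frame(marker = "m1_6", trait = "t",
                    family = c("Z001", "Z002"), effect = c(1, -1))
  gv <- genetic_values_of(pop2, trait_architecture(eff, h2 = c(t = 0.9)))
  y <- gv[, 1]; names(y) <- rownames(G)   # noiseless
  nd <- namqtl:::nested_design(G, pop2$family)
  mod <- namqtl:::new_jl_model(y, nd, map, "m1_6", 0.01, 0.02, "t")
  ae <- allelic_effects(mod)
  expect_equal(ae$effect[ae$family == "Z001"], 1, tolerance = 1e-8)
  expect_equal(ae$effect[ae$family == "Z002"], -1, tolerance = 1e-8)
  expect_true(is.na(ae$effect[ae$family == "Z003"]))
})

test_that("PVE uses observed allele frequencies and detects no signal in null markers", {
  map <- simulate_map(1, 40, 4)
  pop <- simulate_nam_population(map, n_families = 1, n_ril = 400, seed = 23)
  eff <- data.frame(marker = "m1_6", trait = "t", family = "Z001", effect = 1)
  arch <- trait_architecture(eff, h2 = c(t = 0.9))
  gv <- genetic_values_of(pop, arch)[, 1]
  set.seed(3)
  y <- gv + rnorm(length(gv), 0, sd(gv))
  names(y) <- rownames(pop$geno)
  nd <- namqtl:::nested_design(pop$geno, pop$family)
  mod <- namqtl:::new_jl_model(y, nd, map, "m1_6", 0.01, 0.02, "t")
  tab <- pve(mod)
  p <- mean(pop$geno[, "m1_6"])
  ae <- allelic_effects(mod)
  expected <- p * (1 - p) * ae$effect[1]^2 / var(y)
  expect_equal(tab$pve, expected, tolerance = 1e-8)
  expect_gt(tab$pve, 0.3)   # ~half the variance is genetic here

  # an unlinked null marker carries (almost) no PVE
  mod0 <- namqtl:::new_jl_model(y, nd, map, "m1_11", 0.01, 0.02, "t")
  y_null <- sample(y)
  names(y_null) <- names(y)
  mod_null <- namqtl:::new_jl_model(y_null, nd, map, "m1_11", 0.01, 0.02, "t")
  expect_lte(pve(mod_null)$pve, 0.01)
})

test_that("the closed-form PVE example holds", {
  # single family, p = 0.5, class-difference effect 2 (allelic effect 1),
  # trait variance 2 -> PVE = 0.25 * 4 / 2 = 0.5
  n <- 400
  g <- rep(c(0, 1), each = n / 2)
  y <- 2 * g
  # bring var(y) to exactly 2 with a genotype-orthogonal component
  extra <- rep(c(-1, 1), n / 2)
  extra <- extra - mean(extra)
  y <- y + extra * sqrt((2 - var(2 * g)) / var(extra))
  expect_equal(var(y), 2, tolerance = 1e-12)
  map <- genetic_map(c("q", "z"), c(1, 1), c(0, 10), c(1, 2))
  G <- cbind(q = g, z = rep(c(0, 1, 1, 0), n / 4))
  rownames(G) <- sprintf("r%03d", seq_len(n))
  y <- setNames(y, rownames(G))
  nd <- namqtl:::nested_design(G, rep("f1", n))
  mod <- namqtl:::new_jl_model(y, nd, map, "q", 0.01, 0.02, "t")
  tab <- pve(mod)
  expect_equal(tab$pve, 0.5, tolerance = 0.01)
})
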