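# Chromosome residuals, permutation FDR thresholds, RMIP scans

fix_gwas <- function() fixture("gwas", function() {
  pop <- fix_pop()
  jl <- fix_jl()
  causal <- data.frame(variant = "causal_q1", chrom = 1,
                       bp = fix_map()$bp[fix_map()$marker == "m1_51"],
                       carriers = paste(unname(pop$parents), collapse = ","))
  vt <- simulate_dense_variants(pop, density_per_Mb = 1, causal_spec = causal,
                                seed = 29)
  pv <- project_variants(vt, pop)
  list(pop = pop, jl = jl, pv = pv)
})

test_that("a model without peaks yields family-mean residuals identical across chromosomes", {
  pop <- fix_pop()
  jl <- fix_jl()
  nd <- jl$modA$nd
  empty <- namqtl:::new_jl_model(jl$yA, nd, fix_map(), character(0),
                                 0.01, 0.02, "tA")
  r1 <- chromosome_residuals(empty, 1)
  r2 <- chromosome_residuals(empty, 2)
  expect_equal(r1, r2)
  fm <- tapply(jl$yA, pop$family, mean)
  expect_equal(unname(r1),
               as.vector(jl$yA - fm[as.character(pop$family)]),
               tolerance = 1e-10)
})

test_that("focal-chromosome residuals retain that chromosome's signal only", {
  g <- fix_gwas()
  mod <- g$jl$modA         # peaks on chr1 and chr2
  r1 <- chromosome_residuals(mod, 1)   # chr2 peak regressed out
  r2 <- chromosome_residuals(mod, 2)
  q1 <- g$pop$geno[, "m1_51"]
  q2 <- g$pop$geno[, "m2_31"]
  # chr1 signal present in chr1 residuals, absent from chr2 residuals
  expect_gt(abs(cor(r1, q1)), 0.25)
  expect_lt(abs(cor(r2, q1)), 0.1)
  expect_gt(abs(cor(r2, q2)), 0.2)
  # residuals orthogonal to the retained model columns
  keep <- setdiff(mod$peaks, mod$peaks[fix_map()$chrom[
    match(mod$peaks, fix_map()$marker)] == 1])
  X <- namqtl:::jl_model_matrix(mod$nd, keep)
  expect_lt(max(abs(crossprod(X, r1))), 1e-8)
})

test_that("the FDR threshold honors its trivial and monotonicity properties", {
  g <- fix_gwas()
  mod <- g$jl$modA
  res_by <- list(`1` = chromosome_residuals(mod, 1),
                 `2` = chromosome_residuals(mod, 2))
  thr1 <- gwas_threshold(res_by, g$pv, g$pop$family, n_perm = 40, fdr = 1,
                         seed = 5)
  expect_equal(thr1$threshold, 1)
  t05 <- gwas_threshold(res_by, g$pv, g$pop$family, n_perm = 40, fdr = 0.05,
                        seed = 5)$threshold
  t20 <- gwas_threshold(res_by, g$pv, g$pop$family, n_perm = 40, fdr = 0.20,
                        seed = 5)$threshold
  expect_lte(t05, t20)
  const <- lapply(res_by, function(r) r * 0)
  expect_error(gwas_threshold(const, g$pv, g$pop$family, n_perm = 40),
               "degenerate")
})

test_that("RMIP values are integral in [0, n_iter] with the reported set at the cutoff", {
  g <- fix_gwas()
  mod <- g$jl$modA
  res_by <- list(`1` = chromosome_residuals(mod, 1),
                 `2` = chromosome_residuals(mod, 2))
  thr <- gwas_threshold(res_by, g$pv, g$pop$family, n_perm = 40, seed = 6)
  rm <- rmip_scan(res_by, g$pv, g$pop$family, thr$threshold, n_iter = 100,
                  seed = 7)
  expect_true(all(rm$rmip == floor(rm$rmip)))
  expect_true(all(rm$rmip >= 0 & rm$rmip <= 100))
  expect_equal(rm$reported, rm$rmip >= 5)
  # the planted causal variant dominates the scan
  expect_gte(rm$rmip[rm$variant == "causal_q1"], 50)
})

test_that("deterministic full-sample scans give all-or-nothing RMIP", {
  g <- fix_gwas()
  mod <- g$jl$modA
  res_by <- list(`1` = chromosome_residuals(mod, 1),
                 `2` = chromosome_residuals(mod, 2))
  thr <- gwas_threshold(res_by, g$pv, g$pop$family, n_perm = 40, seed = 8)
  rm <- suppressWarnings(
    rmip_scan(res_by, g$pv, g$pop$family, thr$threshold, n_iter = 20,
              subsample = 1, replace = FALSE, seed = 9))
  expect_true(all(rm$rmip %in% c(0, 20)))
  expect_warning(
    rmip_scan(res_by, g$pv, g$pop$family, 1e-10, n_iter = 2, subsample = 1,
              replace = FALSE, seed = 9),
    "100 iterations")
  expect_error(
    rmip_scan(res_by, g$pv, g$pop$family, 0.1, subsample = 0), "subsample")
})

test_that("scan results do not depend on variant ordering", {
  g <- fix_gwas()
  mod <- g$jl$modA
  res_by <- list(`1` = chromosome_residuals(mod, 1),
                 `2` = chromosome_residuals(mod, 2))
  thr <- gwas_threshold(res_by, g$pv, g$pop$family, n_perm = 30, seed = 10)
  perm <- sample(ncol(g$pv$dosage))
  pv2 <- structure(list(info = g$pv$info[perm, ],
                        dosage = g$pv$dosage[, perm]),
                   class = "projected_variants")
  r1 <- rmip_scan(res_by, g$pv, g$pop$family, thr$threshold, n_iter = 100,
                  seed = 11)
  r2 <- rmip_scan(res_by, pv2, g$pop$family, thr$threshold, n_iter = 100,
                  seed = 11)
  m <- match(r1$variant, r2$variant)
  expect_equal(r1$rmip, r2$rmip[m])
})
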