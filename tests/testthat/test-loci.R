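# Interval merging, LD profiles, candidate-gene resolution

test_that("closed-interval merging follows the shared-bp rule", {
  m <- merge_intervals(data.frame(trait = c("a", "b"), chrom = 1,
                                  start_bp = c(1, 4), end_bp = c(5, 8)))
  expect_equal(nrow(m$intervals), 1)
  expect_equal(m$intervals$start_bp, 1)
  expect_equal(m$intervals$end_bp, 8)
  expect_equal(m$intervals$n_members, 2)

  m2 <- merge_intervals(data.frame(trait = c("a", "b"), chrom = 1,
                                   start_bp = c(1, 6), end_bp = c(5, 8)))
  expect_equal(nrow(m2$intervals), 2)

  expect_error(merge_intervals(data.frame(trait = "a", chrom = 1,
                                          start_bp = 9, end_bp = 2)),
               "start > end")
})

test_that("merging matches the brute-force transitive closure and is idempotent", {
  # oracle: union-find over pairwise overlaps
  closure_sizes <- function(iv) {
    n <- nrow(iv)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (iv$chrom[i] == iv$chrom[j] &&
          iv$start_bp[i] <= iv$end_bp[j] && iv$start_bp[j] <= iv$end_bp[i])
        parent[find(i)] <- find(j)
    }
    comp <- vapply(seq_len(n), find, 1L)
    agg <- lapply(split(seq_len(n), comp), function(ix)
      c(iv$chrom[ix[1]], min(iv$start_bp[ix]), max(iv$end_bp[ix])))
    do.call(rbind, agg)
  }
  set.seed(53)
  iv <- data.frame(trait = sprintf("t%d", 1:100),
                   chrom = sample(1:3, 100, TRUE),
                   start_bp = sample(1e6, 100))
  iv$end_bp <- iv$start_bp + sample(5e4, 100)
  got <- merge_intervals(iv)$intervals
  # closure can chain overlaps transitively; compare sorted spans
  want <- as.data.frame(closure_sizes(iv))
  names(want) <- c("chrom", "start_bp", "end_bp")
  ord <- function(d) d[order(d$chrom, d$start_bp), c("chrom", "start_bp", "end_bp")]
  expect_equal(unname(as.matrix(ord(got))), unname(as.matrix(ord(want))))

  again <- merge_intervals(transform(got, trait = "x"))
  expect_equal(again$intervals[, c("chrom", "start_bp", "end_bp")],
               got[, c("chrom", "start_bp", "end_bp")])
  # merged intervals pairwise disjoint per chromosome
  by_ch <- split(got, got$chrom)
  for (d in by_ch) if (nrow(d) > 1) {
    d <- d[order(d$start_bp), ]
    expect_true(all(d$start_bp[-1] > d$end_bp[-nrow(d)]))
  }
})

test_that("LD around focal variants behaves as expected", {
  pop <- fix_pop()
  vt <- simulate_dense_variants(pop, density_per_Mb = 0.6, seed = 59)
  pv <- project_variants(vt, pop)
  # a duplicated focal column gives r2 = 1 with its copy
  dup <- pv
  dup$info <- rbind(dup$info,
                    data.frame(variant = "copy", chrom = dup$info$chrom[1],
                               bp = dup$info$bp[1] + 1))
  dup$dosage <- cbind(dup$dosage, copy = dup$dosage[, 1])
  ld <- ld_profile(dup$info$variant[1], dup, window_bp = 10, n_null = 5,
                   seed = 3)
  expect_equal(max(ld$observed), 1)

  # distant, unlinked variants: mean r2 near the finite-sample floor
  set.seed(61)
  n <- 200
  # block variants clustered at 1-10 kb; the rest isolated far away
  bp <- c((1:10) * 1000, 1e6 + (1:30) * 1e5)
  ind <- list(info = data.frame(variant = sprintf("x%d", 1:40), chrom = 1,
                                bp = bp),
              dosage = matrix(rbinom(n * 40, 1, 0.5), n, 40,
                              dimnames = list(NULL, sprintf("x%d", 1:40))))
  class(ind) <- "projected_variants"
  ld2 <- ld_profile(ind$info$variant, ind, window_bp = 1e8, n_null = 40,
                    seed = 5)
  expect_lt(abs(mean(ld2$observed) - 1 / (n - 1)), 0.004)

  # a tight LD block (near-copies of one column) dominates the null
  blk <- ind
  for (k in 2:10) blk$dosage[, k] <- ifelse(runif(n) < 0.05,
                                            1 - blk$dosage[, 1],
                                            blk$dosage[, 1])
  ld3 <- ld_profile(sprintf("x%d", 1:10), blk, window_bp = 2e4, n_null = 5,
                    seed = 7)
  expect_gt(mean(ld3$observed > 0.5), 0.5)
  expect_gt(mean(ld3$observed), mean(ld2$null) + 0.3)
})

test_that("gene resolution enforces all three criteria", {
  ci <- merge_intervals(data.frame(
    trait = c("kcol", "zea", "lut"),
    chrom = c(1, 1, 2),
    start_bp = c(10e6, 12e6, 30e6),
    end_bp = c(15e6, 18e6, 35e6)))
  rmip <- structure(data.frame(
    trait = c("kcol", "zea", "lut", "kcol"),
    variant = c("v1", "v2", "v3", "v4"),
    chrom = c(1, 1, 2, 2),
    bp = c(11e6, 13e6, 31e6, 31.2e6),
    rmip = c(40, 22, 9, 3)), class = c("rmip_table", "data.frame"))
  rmip$reported <- rmip$rmip >= 5
  genes <- data.frame(
    gene = c("hit", "far", "not_apriori"),
    chrom = c(1, 1, 1),
    start_bp = c(11.1e6, 80e6, 11.1e6),
    end_bp = c(11.2e6, 80.1e6, 11.3e6))
  apriori <- c("hit", "far")

  got <- resolve_genes(ci, rmip, genes, apriori)
  # "hit": within 250 kb of v1 (kcol), inside the kcol interval
  expect_true("hit" %in% got$gene)
  expect_false("far" %in% got$gene)          # megabases from everything
  expect_false("not_apriori" %in% got$gene)  # fails criterion (iii)

  # same-trait clause: an association of trait X within reach, but the
  # gene sits only in a trait-Y interval
  rmip2 <- rmip
  rmip2$trait <- c("zea", "zea", "zea", "zea")   # all associations zea
  ci2 <- merge_intervals(data.frame(trait = "kcol", chrom = 1,
                                    start_bp = 10e6, end_bp = 15e6))
  got2 <- resolve_genes(ci2, rmip2, genes["hit" == genes$gene, ], "hit")
  expect_equal(nrow(got2), 0)

  # monotone in window_bp
  w1 <- resolve_genes(ci, rmip, genes, apriori, window_bp = 1e4)
  w2 <- resolve_genes(ci, rmip, genes, apriori, window_bp = 5e6)
  expect_true(all(w1$gene %in% w2$gene))
})

test_that("gene annotations read from BED convert to 1-based closed coordinates", {
  skip_if_not_installed("rtracklayer")
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tgeneA\t0\t+",
               "2\t5000\t5100\tgeneB\t0\t-"), f)
  g <- read_gene_annotations(f)
  expect_equal(g$start_bp, c(1000, 5001))
  expect_equal(g$end_bp, c(2000, 5100))
  expect_equal(g$gene, c("geneA", "geneB"))

  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=geneC",
               "1\ttest\texon\t1000\t1500\t.\t+\t.\tID=exonC"), f2)
  g2 <- read_gene_annotations(f2)
  expect_equal(g2$gene, "geneC")
  expect_equal(g2$start_bp, 1000)
})
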