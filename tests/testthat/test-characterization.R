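# Characterization statistics: direction index, HR correlations, minor
# allele enrichment, region classification, linkage pruning, variant-pair
# independence, and driver association.

mk_res <- function(vid, cz, lhr, p = 0.01) {
  data.frame(variant_id = vid, stratum = cz, log_hr = lhr, hr = exp(lhr),
             p = p, converged = TRUE, stringsAsFactors = FALSE)
}

test_that("direction index follows the max-ratio formula", {
  # significant with the same direction in five cancers: index exactly 1
  res <- do.call(rbind, lapply(1:5, function(i) mk_res("v1", paste0("C", i), 0.4)))
  out <- direction_index_stats(res, min_cancers = 3)
  expect_identical(out$indices$index, 1)
  expect_identical(out$expected_index, 1)
  # 2 poor + 1 favorable: index 2/3
  res2 <- rbind(mk_res("v2", "C1", 0.4), mk_res("v2", "C2", 0.3),
                mk_res("v2", "C3", -0.2))
  out2 <- direction_index_stats(res2, min_cancers = 3)
  expect_equal(out2$indices$index, 2 / 3)
  # index bounds hold whenever a variant qualifies
  set.seed(2)
  res3 <- do.call(rbind, lapply(1:30, function(v) {
    k <- sample(3:6, 1)
    do.call(rbind, lapply(1:k, function(i) {
      mk_res(paste0("w", v), paste0("C", i), sample(c(-0.3, 0.3), 1))
    }))
  }))
  out3 <- direction_index_stats(res3, min_cancers = 3)
  expect_true(all(out3$indices$index >= 0.5 & out3$indices$index <= 1))
})

test_that("mean index under random 50/50 directions matches enumeration", {
  # exact enumeration for k = 3: E[max(B, 3-B)/3], B ~ Binomial(3, 1/2)
  e3 <- sum(pmax(0:3, 3 - (0:3)) / 3 * dbinom(0:3, 3, 0.5))
  expect_equal(e3, 0.75)
  set.seed(6)
  res <- do.call(rbind, lapply(1:4000, function(v) {
    do.call(rbind, lapply(1:3, function(i) {
      mk_res(paste0("v", v), paste0("C", i), sample(c(-0.5, 0.5), 1))
    }))
  }))
  out <- direction_index_stats(res, min_cancers = 3)
  se <- sd(out$indices$index) / sqrt(nrow(out$indices))
  expect_lt(abs(mean(out$indices$index) - e3), 4 * se)
})

test_that("HR pair correlation pools within-variant pairs; partial form matches oracle", {
  # identical HRs within variant, varying across variants: perfect correlation
  res <- do.call(rbind, lapply(1:8, function(v) {
    do.call(rbind, lapply(1:3, function(i) mk_res(paste0("v", v), paste0("C", i),
                                                  0.1 * v)))
  }))
  out <- hr_pair_correlation(res, "poor")
  expect_equal(out$rho, 1, tolerance = 1e-12)
  expect_equal(out$n_pairs, 8 * 3)
  # partial Spearman against the residual-regression oracle
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    expect_equal(partial_spearman(x, y, z)$rho, oracle_partial_spearman(x, y, z),
                 tolerance = 1e-10)
  }
  # independent HRs: rho near zero
  set.seed(13)
  resn <- do.call(rbind, lapply(1:200, function(v) {
    do.call(rbind, lapply(1:3, function(i) {
      mk_res(paste0("v", v), paste0("C", i), runif(1, 0.05, 1))
    }))
  }))
  outn <- hr_pair_correlation(resn, "poor")
  expect_lt(abs(outn$rho), 4 / sqrt(outn$n_pairs))
})

test_that("minor-allele enrichment equals the hypergeometric closed form", {
  hits <- data.frame(log_hr = c(rep(0.5, 10), rep(-0.5, 10)),
                     population_af = c(rep(0.1, 10), rep(0.9, 10)))
  out <- minor_allele_risk_test(hits)
  # perfectly separated 10/10 table: p = 1/choose(20, 10)
  expect_equal(out$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(out$p, oracle_fisher_greater(out$table), tolerance = 1e-12)
  # all alleles minor: degenerate margin, p = 1
  hits2 <- data.frame(log_hr = c(0.5, -0.5), population_af = c(0.1, 0.2))
  expect_equal(minor_allele_risk_test(hits2)$p, 1)
  # random tables match the direct summation oracle
  set.seed(3)
  for (i in 1:25) {
    h <- data.frame(log_hr = rnorm(30), population_af = runif(30))
    out <- minor_allele_risk_test(h)
    expect_equal(out$p, oracle_fisher_greater(out$table), tolerance = 1e-12)
  }
})

test_that("effect size / AF correlation flags degenerate input", {
  hits <- data.frame(log_hr = log(seq(4, 1.2, length.out = 10)),
                     population_af = seq(0.05, 0.5, length.out = 10))
  out <- effect_size_af_correlation(hits)
  expect_equal(out$rho, -1, tolerance = 1e-12)
  expect_true(is.na(effect_size_af_correlation(
    data.frame(log_hr = rnorm(5), population_af = rep(0.2, 5)))$rho))
})

test_that("linkage pruning keeps the first variant by position, order-free", {
  set.seed(8)
  base <- rbinom(100, 2, 0.3)
  g <- cbind(var0001 = base, var0002 = base, var0003 = rbinom(100, 2, 0.3))
  hits <- data.frame(variant_id = c("var0002", "var0001", "var0003"),
                     chrom = "chr1", pos = c(200, 100, 5000))
  out <- ld_prune(hits, g, 0.8)
  expect_setequal(out$variant_id, c("var0001", "var0003"))
  out_rev <- ld_prune(hits[3:1, ], g, 0.8)
  expect_setequal(out_rev$variant_id, c("var0001", "var0003"))
  # three mutually linked variants leave exactly one survivor
  g3 <- cbind(var0001 = base, var0002 = base, var0003 = base)
  hits3 <- data.frame(variant_id = paste0("var000", 1:3), chrom = "chr1",
                      pos = c(300, 100, 200))
  expect_equal(ld_prune(hits3, g3, 0.8)$variant_id, "var0002")
  # nothing linked: identity
  gu <- cbind(var0001 = rbinom(100, 2, 0.3), var0002 = rbinom(100, 2, 0.3))
  hitsu <- data.frame(variant_id = c("var0001", "var0002"), chrom = "chr1",
                      pos = c(1, 2))
  expect_equal(nrow(ld_prune(hitsu, gu, 0.8)), 2)
})

test_that("region classification is strand-aware and multi-transcript", {
  gmod <- data.frame(
    tx_id = c("txA", "txB"), chrom = "chr1", strand = c("+", "-"),
    tx_start = c(1000, 1500), tx_end = c(3000, 3800),
    cds_start = c(1200, 1700), cds_end = c(2800, 3600),
    exon_starts = c("1000,2000", "1500,3000"),
    exon_ends = c("1400,3000", "2000,3800"), stringsAsFactors = FALSE)
  # inside txA's CDS exon
  expect_true("exonic" %in% classify_region("chr1", 1300, gmod))
  # 500 bp 5' of txA start: upstream within the 1 kb window (the same
  # position also sits in txB's downstream window on the minus strand)
  expect_true("upstream" %in% classify_region("chr1", 500, gmod))
  expect_identical(classify_region("chr1", 10, gmod,
                                   flank = 100), "intergenic")
  # exon of txA, intron of txB: both labels
  lab <- classify_region("chr1", 2100, gmod)
  expect_true(all(c("exonic", "intronic") %in% lab))
  # before CDS on + strand: 5' UTR; past a minus-strand end: upstream
  expect_true("5utr" %in% classify_region("chr1", 1100, gmod))
  expect_true("upstream" %in% classify_region("chr1", 3900, gmod))
  # far away: intergenic
  expect_identical(classify_region("chr1", 100000, gmod), "intergenic")
  expect_identical(classify_region("chr2", 1300, gmod), "intergenic")
})

test_that("pair independence test sees multiplicative effects and nulls", {
  set.seed(40)
  n <- 800
  g <- cbind(var0001 = rbinom(n, 2, 0.25), var0002 = rbinom(n, 2, 0.25))
  tt <- sim_ph_times(log(2) * (g[, 1] >= 1) + log(2) * (g[, 2] >= 1))
  cohort <- data.frame(time = tt, event = 1L)
  hits <- data.frame(variant_id = c("var0001", "var0002"))
  out <- pair_independence_test(hits, g, cohort)
  expect_equal(out$n_pairs, 1)
  expect_gt(out$pairs$hr_both, out$pairs$hr_one)
  # all-reference second variant: pair skipped
  g2 <- g; g2[, 2] <- 0L
  out2 <- pair_independence_test(hits, g2, cohort)
  expect_equal(out2$n_pairs, 0)
  expect_equal(out2$n_skipped, 1)
})

test_that("driver association respects the five-mutated-patients rule", {
  set.seed(50)
  n <- 400
  g <- cbind(var0001 = rbinom(n, 2, 0.3), var0002 = rbinom(n, 2, 0.3))
  rownames(g) <- sprintf("p%03d", 1:n)
  carrier <- g[, 1] >= 1
  dr <- cbind(D1 = rbinom(n, 1, ifelse(carrier, 0.35, 0.08)),
              D2 = rbinom(n, 1, 0.1),
              D_rare = c(rep(1L, 4), rep(0L, n - 4)))   # only 4 mutated
  rownames(dr) <- rownames(g)
  hits <- data.frame(variant_id = "var0001", log_hr = 0.5)
  allr <- data.frame(variant_id = c("var0001", "var0002"), log_hr = c(0.5, 0.2))
  out <- driver_association_scan(hits, allr, g, dr)
  expect_false("D_rare" %in% out$pair_tests$driver_gene)
  strong <- out$pair_tests[out$pair_tests$driver_gene == "D1" &
                             out$pair_tests$variant_id == "var0001", ]
  expect_lt(strong$fdr, 0.10)
  expect_equal(out$n_prognostic_associated, 1)
  # Fisher p equals the direct hypergeometric summation
  tab <- table(factor(carrier, levels = c(TRUE, FALSE)),
               factor(dr[, "D1"] == 1, levels = c(TRUE, FALSE)))
  expect_equal(strong$p, oracle_fisher_greater(tab), tolerance = 1e-12)
})
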