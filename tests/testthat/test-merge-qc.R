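# Merge precedence, depth masking, strict three-way concordance, cohort
# allele frequency, and the three discovery filters.

test_that("depth masking hides exactly the low-coverage calls", {
  g <- gm(rep(1L, 6), 3, 2)
  d <- matrix(c(30, 9, 10, 0, 12, 11), 3, 2, dimnames = dimnames(g))
  cs <- source_call_set("WXS_NORMAL", g, d)
  m <- mask_low_depth(cs, 10)
  expect_true(is.na(m$genotypes[2, 1]))  # 9 reads: fewer than 10
  expect_false(is.na(m$genotypes[3, 1])) # exactly 10 reads kept
  expect_true(is.na(m$genotypes[1, 2]))  # 0 reads
  # min_depth 0 is the identity
  expect_identical(mask_low_depth(cs, 0)$genotypes, g)
  # all depths above threshold: identity
  cs2 <- source_call_set("WXS_TUMOR", g, matrix(50, 3, 2, dimnames = dimnames(g)))
  expect_identical(mask_low_depth(cs2, 10)$genotypes, g)
})

test_that("merge uses normal-then-tumor-then-RNA precedence with provenance", {
  n <- gm(c(NA, 0, NA, NA), 2, 2)
  t_ <- gm(c(1, 2, NA, NA), 2, 2)
  r <- gm(c(2, 2, 1, NA), 2, 2)
  mk <- function(x) source_call_set("WXS_NORMAL", x, matrix(30, 2, 2, dimnames = dimnames(x)))
  m <- merge_calls(mk(n), mk(t_), mk(r))
  expect_equal(unname(m$genotypes[1, 1]), 1)       # tumor wins over RNA
  expect_equal(m$provenance[1, 1], "WXS_TUMOR")
  expect_equal(unname(m$genotypes[2, 1]), 0)       # normal wins everywhere known
  expect_equal(m$provenance[2, 1], "WXS_NORMAL")
  expect_equal(unname(m$genotypes[1, 2]), 1)       # only RNA knows
  expect_equal(m$provenance[1, 2], "RNA_TUMOR")
  expect_true(is.na(m$genotypes[2, 2]))            # all unknown stays unknown
  expect_equal(m$provenance[2, 2], "UNKNOWN")
})

test_that("merge is idempotent and normal-dominant", {
  set.seed(1)
  g1 <- gm(sample(c(0:2, NA), 60, replace = TRUE), 6, 10)
  g2 <- gm(sample(c(0:2, NA), 60, replace = TRUE), 6, 10)
  g3 <- gm(sample(c(0:2, NA), 60, replace = TRUE), 6, 10)
  mk <- function(x, s) source_call_set(s, x, matrix(30, 6, 10, dimnames = dimnames(x)))
  m <- merge_calls(mk(g1, "WXS_NORMAL"), mk(g2, "WXS_TUMOR"), mk(g3, "RNA_TUMOR"))
  m2 <- merge_calls(mk(m$genotypes, "WXS_NORMAL"), mk(m$genotypes, "WXS_TUMOR"),
                    mk(m$genotypes, "RNA_TUMOR"))
  expect_identical(m2$genotypes, m$genotypes)
  known <- !is.na(g1)
  expect_identical(m$genotypes[known], g1[known])
})

test_that("concordance counts strict three-way agreement over all patients", {
  g <- gm(rep(1L, 20), 20, 1)
  sets <- make_clean_sets(g)
  expect_equal(unname(concordance_percent(sets$WXS_NORMAL, sets$WXS_TUMOR,
                                          sets$RNA_TUMOR)), 100)
  # 18 of 20 concordant is exactly 90.0
  g2 <- g; g2[1:2, 1] <- 0L
  sets2 <- sets; sets2$RNA_TUMOR <- source_call_set("RNA_TUMOR", g2,
                                                    sets$RNA_TUMOR$depth)
  expect_equal(unname(concordance_percent(sets2$WXS_NORMAL, sets2$WXS_TUMOR,
                                          sets2$RNA_TUMOR)), 90)
  # one source fully unknown: nobody is concordant under the strict rule
  g3 <- g; g3[] <- NA_integer_
  sets3 <- sets; sets3$WXS_TUMOR <- source_call_set("WXS_TUMOR", g3, sets$WXS_TUMOR$depth)
  expect_equal(unname(concordance_percent(sets3$WXS_NORMAL, sets3$WXS_TUMOR,
                                          sets3$RNA_TUMOR)), 0)
  expect_error(concordance_percent(sets$WXS_NORMAL, sets$WXS_TUMOR,
                                   sets$RNA_TUMOR, patients = character()),
               "zero patients")
})

test_that("cohort allele frequency averages dosages over known calls", {
  expect_equal(unname(cohort_allele_frequency(gm(rep(1L, 4), 4, 1))), 0.5)
  expect_equal(unname(cohort_allele_frequency(gm(c(0L, 0L, 1L, 2L), 4, 1))), 3 / 8)
  g <- gm(c(NA, NA, NA, NA), 4, 1)
  expect_true(is.na(cohort_allele_frequency(g)))
  # unknowns excluded from the denominator
  expect_equal(unname(cohort_allele_frequency(gm(c(2L, NA, NA, NA), 4, 1))), 1)
})

test_that("the three discovery filters use the stated strict cutoffs", {
  # 30 patients, 6 variants; one variant fails each filter, three pass
  n <- 30
  g <- gm(rep(1L, n * 6), n, 6)
  g[15:n, 2] <- 0L                      # var0002: 14 carriers only
  sets <- make_clean_sets(g)
  rna <- sets$RNA_TUMOR$genotypes
  rna[1:3, 3] <- 0L                     # var0003: 27/30 = 90% concordant, not > 90
  sets$RNA_TUMOR <- source_call_set("RNA_TUMOR", rna, sets$RNA_TUMOR$depth)
  ann <- data.frame(variant_id = colnames(g),
                    population_af = c(0.04, rep(0.3, 5)))  # var0001 fails AF
  merged <- merge_calls(sets$WXS_NORMAL, sets$WXS_TUMOR, sets$RNA_TUMOR)
  qc <- qc_filter(merged, sets, ann, qc_thresholds(), rep("CAN1", n))
  expect_equal(sum(qc$pass), 3)
  expect_equal(unname(attr(qc, "exclusions")), c(1, 1, 1))
  # boundary semantics: population AF exactly 5% is excluded
  ann2 <- ann; ann2$population_af[1] <- 0.05
  qc2 <- qc_filter(merged, sets, ann2, qc_thresholds(), rep("CAN1", n))
  expect_false(qc2$pass[qc2$variant_id == "var0001"])
  # concordance exactly 90 is excluded, 15 carriers are enough
  expect_false(qc$pass[qc$variant_id == "var0003"])
  expect_equal(qc$carriers[qc$variant_id == "var0002"], 14)
  # all-zero thresholds pass everything
  qc0 <- qc_filter(merged, sets, ann, qc_thresholds(0, 0, 0, 0), rep("CAN1", n))
  expect_true(all(qc0$pass))
})

test_that("raising any threshold never increases the survivor count", {
  set.seed(7)
  n <- 60
  truth <- gm(rbinom(n * 30, 2, 0.25), n, 30)
  sets <- corrupt_to_call_sets(truth, 0.03, list(dist = "poisson", mean = 14), seed = 3)
  masked <- lapply(sets, mask_low_depth, min_depth = 10)
  merged <- merge_calls(masked$WXS_NORMAL, masked$WXS_TUMOR, masked$RNA_TUMOR)
  ann <- data.frame(variant_id = colnames(truth),
                    population_af = runif(30, 0.03, 0.4))
  cz <- rep("CAN1", n)
  base <- sum(qc_filter(merged, masked, ann, qc_thresholds(10, 0.05, 10, 70), cz)$pass)
  for (thr in list(qc_thresholds(10, 0.10, 10, 70), qc_thresholds(10, 0.05, 20, 70),
                   qc_thresholds(10, 0.05, 10, 90))) {
    expect_lte(sum(qc_filter(merged, masked, ann, thr, cz)$pass), base)
  }
})

test_that("cross-source AF correlations match a rank-then-Pearson oracle", {
  set.seed(5)
  truth <- gm(rbinom(50 * 50, 2, runif(50, 0.1, 0.5)[rep(1:50, each = 50)]), 50, 50)
  sets <- corrupt_to_call_sets(truth, c(0, 0.1, 0.2),
                               list(dist = "constant", value = 30), seed = 8)
  merged <- merge_calls(sets$WXS_NORMAL, sets$WXS_TUMOR, sets$RNA_TUMOR)
  rho <- cross_source_af_correlation(sets, merged)
  expect_equal(unname(diag(rho)), rep(1, 4))
  af_n <- cohort_allele_frequency(sets$WXS_NORMAL$genotypes)
  af_r <- cohort_allele_frequency(sets$RNA_TUMOR$genotypes)
  expect_equal(rho["WXS_NORMAL", "RNA_TUMOR"],
               stats::cor(rank(af_n), rank(af_r)), tolerance = 1e-12)
  # identical call sets correlate perfectly; rank reversal gives -1
  sets0 <- make_clean_sets(truth)
  merged0 <- merge_calls(sets0$WXS_NORMAL, sets0$WXS_TUMOR, sets0$RNA_TUMOR)
  rho0 <- cross_source_af_correlation(sets0, merged0)
  expect_true(all(abs(rho0 - 1) < 1e-12))
})

test_that("zero-corruption deep-coverage round trip reproduces the truth", {
  set.seed(3)
  truth <- gm(rbinom(40 * 25, 2, 0.3), 40, 25)
  sets <- corrupt_to_call_sets(truth, 0, list(dist = "constant", value = 30), seed = 1)
  masked <- lapply(sets, mask_low_depth, min_depth = 10)
  merged <- merge_calls(masked$WXS_NORMAL, masked$WXS_TUMOR, masked$RNA_TUMOR)
  expect_identical(merged$genotypes, truth)
  conc <- concordance_percent(masked$WXS_NORMAL, masked$WXS_TUMOR, masked$RNA_TUMOR)
  expect_true(all(conc == 100))
})

test_that("VCF writing and reading round-trips genotypes and depths", {
  set.seed(9)
  truth <- gm(c(rbinom(59, 2, 0.4), NA), 10, 6)
  depth <- matrix(rpois(60, 25), 10, 6, dimnames = dimnames(truth))
  ann <- data.frame(variant_id = colnames(truth), chrom = "chr1",
                    pos = seq(100, 600, 100), ref = "A", alt = "G")
  cs <- source_call_set("WXS_NORMAL", truth, depth)
  f <- tempfile(fileext = ".vcf")
  write_vcf(cs, ann, f)
  back <- read_vcf_calls(f, "WXS_NORMAL")
  expect_equal(unname(back$genotypes), unname(truth))
  expect_equal(unname(back$depth), unname(depth))
  expect_equal(attr(back, "variants")$pos, ann$pos)
})
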