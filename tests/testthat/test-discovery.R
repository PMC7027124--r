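# Discovery scans: per-cancer and pooled-group Cox designs, BH family
# bookkeeping, recurrence filtering, and CADD restriction.

test_that("per-cancer scan finds a strong planted variant and labels direction", {
  st <- make_study(400, "CAN1", 60, variant_effects = c(var0005 = log(4)), seed = 31)
  res <- per_cancer_scan(st$merged, st$cohort, st$covariates_per_cancer, st$qc)
  expect_true("var0005" %in% res$variant_id[res$hit])
  row <- res[res$variant_id == "var0005", ]
  expect_equal(row$direction, "poor")
  expect_gt(row$log_hr, 0)
  # direction labelling is hr > 1 <=> poor everywhere
  expect_true(all((res$log_hr > 0) == (res$direction == "poor")))
  # fdr never below p
  ok <- !is.na(res$fdr)
  expect_true(all(res$fdr[ok] >= res$p[ok] - 1e-12))
  # every fit is reproducible in isolation
  idx <- which(st$cohort$cancer == "CAN1")
  refit <- cox_fit(cbind(variant = st$merged$genotypes[idx, "var0005"],
                         age = st$cohort$age[idx]),
                   st$cohort$time[idx], st$cohort$event[idx])
  expect_equal(row$log_hr, refit$log_hr[1], tolerance = 1e-8)
})

test_that("the BH family equals the eligible variant count per cancer", {
  st <- make_study(300, c("CAN1", "CAN2"), 40, seed = 5)
  res <- per_cancer_scan(st$merged, st$cohort, st$covariates_per_cancer, st$qc)
  for (cz in c("CAN1", "CAN2")) {
    n_elig <- sum(st$qc$pass & st$qc$cancer == cz)
    expect_equal(sum(res$stratum == cz & res$converged), n_elig)
  }
})

test_that("the CADD-restricted scan tests only high-CADD variants", {
  st <- make_study(300, "CAN1", 50, seed = 12)
  res <- per_cancer_scan(st$merged, st$cohort, st$covariates_per_cancer, st$qc,
                         annotations = st$variants, cadd_filter = TRUE)
  high <- st$variants$variant_id[st$variants$cadd_score > 25]
  expect_true(all(res$variant_id %in% high))
  # no high-CADD variants at all: empty scan
  ann0 <- st$variants; ann0$cadd_score <- 1
  res0 <- per_cancer_scan(st$merged, st$cohort, st$covariates_per_cancer, st$qc,
                          annotations = ann0, cadd_filter = TRUE)
  expect_equal(nrow(res0), 0)
})

test_that("recurrence filter demands one shared direction across cancers", {
  mk <- function(vid, cz, lhr, p) data.frame(variant_id = vid, stratum = cz,
                                             log_hr = lhr, p = p, converged = TRUE)
  # significant with HR > 1 in 7 cancers: retained at min 7
  res <- do.call(rbind, lapply(1:7, function(i) mk("v1", paste0("C", i), 0.5, 0.01)))
  out <- recurrence_filter(res, min_cancers = 7)
  expect_true(out$retained[out$variant_id == "v1"])
  # 4 poor + 3 favorable, all significant: max same-direction is 4, dropped
  res2 <- rbind(do.call(rbind, lapply(1:4, function(i) mk("v2", paste0("C", i), 0.5, 0.01))),
                do.call(rbind, lapply(5:7, function(i) mk("v2", paste0("C", i), -0.5, 0.01))))
  out2 <- recurrence_filter(res2, min_cancers = 7)
  expect_false(out2$retained[out2$variant_id == "v2"])
  expect_equal(out2$n_poor, 4)
  expect_equal(out2$n_favorable, 3)
  # min_cancers 1 retains anything significant once
  out3 <- recurrence_filter(mk("v3", "C1", 0.2, 0.04), min_cancers = 1)
  expect_true(out3$retained)
  # non-significant rows never count
  out4 <- recurrence_filter(mk("v4", "C1", 0.2, 0.2), min_cancers = 1)
  expect_equal(nrow(out4), 0)
})

test_that("the pooled design has dummies plus per-cancer interactions", {
  cohort <- data.frame(patient_id = sprintf("p%02d", 1:6),
                       cancer = rep(c("X", "Y"), each = 3),
                       A = c(1, 2, 3, 4, 5, 6), B = c(9, 8, 7, 6, 5, 4))
  grp <- group_spec("G", c("X", "Y"))
  bd <- build_group_design(grp, cohort, list(X = "A", Y = "B"))
  expect_identical(colnames(bd$design), c("X_status", "X:A", "Y:B"))
  expect_equal(bd$design[, "X_status"], c(1, 1, 1, 0, 0, 0))
  expect_equal(bd$design[, "X:A"], c(1, 2, 3, 0, 0, 0))   # zero outside X
  expect_equal(bd$design[, "Y:B"], c(0, 0, 0, 6, 5, 4))
  # shared covariate selected in both cancers: two separate columns
  bd2 <- build_group_design(grp, cohort, list(X = "A", Y = "A"))
  expect_identical(colnames(bd2$design), c("X_status", "X:A", "Y:A"))
  # single-cancer group: no dummies, interactions collapse to covariates
  bd3 <- build_group_design(group_spec("G1", "X"), cohort, list(X = "A"))
  expect_identical(colnames(bd3$design), "X:A")
  expect_equal(unname(bd3$design[, 1]), c(1, 2, 3))
})

test_that("a single-cancer group scan reproduces the per-cancer scan", {
  st <- make_study(250, "CAN1", 25, variant_effects = c(var0003 = log(2)), seed = 77)
  res_pc <- per_cancer_scan(st$merged, st$cohort, st$covariates_per_cancer, st$qc)
  res_gr <- group_scan(list(group_spec("G1", "CAN1")), st$merged, st$cohort,
                       st$covariates_per_cancer,
                       scan_config(group_min_carriers = 0))
  m <- match(res_pc$variant_id, res_gr$variant_id)
  expect_true(all(!is.na(m)))
  expect_equal(res_pc$p, res_gr$p[m], tolerance = 1e-8)
  expect_equal(res_pc$log_hr, res_gr$log_hr[m], tolerance = 1e-8)
})

test_that("group carrier eligibility uses the pooled 15-patient rule", {
  st <- make_study(300, c("CAN1", "CAN2"), 30, seed = 41)
  g <- st$merged$genotypes
  carriers <- colSums(g >= 1, na.rm = TRUE)
  res <- group_scan(list(group_spec("G", c("CAN1", "CAN2"))), st$merged,
                    st$cohort, st$covariates_per_cancer, scan_config())
  tested <- unique(res$variant_id)
  expect_true(all(carriers[tested] >= 15))
  expect_false(any(names(carriers)[carriers < 15] %in% tested))
})

test_that("overlapping-group duplicates resolve to the largest group", {
  res <- data.frame(variant_id = c("v1", "v1", "v2"),
                    stratum = c("G_small", "G_big", "G_small"),
                    n_group_patients = c(100, 300, 100))
  out <- dedupe_group_hits(res)
  expect_equal(out$stratum[out$variant_id == "v1"], "G_big")
  expect_equal(nrow(out), 2)
})

test_that("a sensitivity rerun with an extra covariate leaves HRs correlated", {
  st <- make_study(400, "CAN1", 30, variant_effects = c(var0002 = log(2)), seed = 13)
  st$cohort$noise <- rnorm(nrow(st$cohort))
  base <- per_cancer_scan(st$merged, st$cohort, list(CAN1 = "age"), st$qc)
  sens <- per_cancer_scan(st$merged, st$cohort, list(CAN1 = c("age", "noise")), st$qc)
  out <- hr_sensitivity_correlation(base, sens)
  expect_gt(out$rho, 0.9)
  expect_equal(out$n, nrow(base))
})
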