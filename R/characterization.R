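# Post-discovery characterization: direction-concordance index, hazard-ratio
# pair correlations (plain and AF-partialled Spearman), minor-allele risk
# enrichment, effect-size/allele-frequency correlation, genomic region
# classification, linkage pruning, variant-pair independence, and somatic
# driver-mutation association.

#' Direction-concordance index of recurrent prognostic variants
#'
#' For every variant associated with outcome (unadjusted p below
#' `p_threshold`) in at least `min_cancers` cancers, counts the poor
#' (HR > 1) and favorable (HR < 1) associations and computes
#' max(poor, favorable) / (poor + favorable). A perfectly concordant
#' variant scores 1. The expected index under no per-variant concordance is
#' estimated empirically as max(total poor, total favorable) / total, and
#' the observed indices are compared to it with a one-sample Wilcoxon test.
#'
#' @param results full per-cancer scan results.
#' @param min_cancers minimum qualifying cancers per variant (default 3).
#' @param p_threshold unadjusted p cut (default 0.05).
#' @return list: `indices` data.frame (variant_id, n_poor, n_favorable,
#'   index), `expected_index`, `p` (Wilcoxon), `n_variants`.
#' @export
direction_index_stats <- function(results, min_cancers = 3, p_threshold = 0.05) {
  res <- results[results$converged & !is.na(results$p) & results$p < p_threshold, ]
  if (!nrow(res)) return(list(indices = NULL, expected_index = NA_real_,
                              p = NA_real_, n_variants = 0L))
  tab <- stats::aggregate(cbind(n_poor = res$log_hr > 0,
                                n_favorable = res$log_hr < 0),
                          by = list(variant_id = res$variant_id), FUN = sum)
  tab <- tab[tab$n_poor + tab$n_favorable >= min_cancers, , drop = FALSE]
  if (!nrow(tab)) return(list(indices = NULL, expected_index = NA_real_,
                              p = NA_real_, n_variants = 0L))
  tab$index <- pmax(tab$n_poor, tab$n_favorable) / (tab$n_poor + tab$n_favorable)
  tot_poor <- sum(tab$n_poor); tot_fav <- sum(tab$n_favorable)
  expected <- max(tot_poor, tot_fav) / (tot_poor + tot_fav)
  p <- if (nrow(tab) >= 2 && stats::sd(tab$index) > 0) {
    suppressWarnings(stats::wilcox.test(tab$index, mu = expected)$p.value)
  } else NA_real_
  list(indices = tab, expected_index = expected, p = p, n_variants = nrow(tab))
}

#' Correlation of a variant's hazard ratios across cancers
#'
#' Restricts to variants significant in the same direction in at least
#' `min_cancers` cancers (favorable and poor sets are analyzed separately),
#' forms every within-variant pair of hazard ratios, and reports the
#' Spearman correlation over all pairs. With `control_af = TRUE` a
#' first-order partial Spearman correlation is computed instead, ranking
#' the two hazard-ratio vectors and the variant allele frequencies and
#' partialling the AF ranks out:
#' r12.3 = (r12 - r13 r23) / sqrt((1 - r13^2)(1 - r23^2)).
#'
#' @param results full per-cancer scan results.
#' @param direction "poor" or "favorable".
#' @param af optional named vector of per-variant allele frequencies
#'   (required when `control_af`).
#' @param min_cancers minimum same-direction significant cancers (default 3).
#' @param p_threshold unadjusted p cut (default 0.05).
#' @param control_af partial out allele frequency.
#' @return list: rho, p, n_pairs.
#' @export
hr_pair_correlation <- function(results, direction = c("poor", "favorable"),
                                af = NULL, min_cancers = 3, p_threshold = 0.05,
                                control_af = FALSE) {
  direction <- match.arg(direction)
  sgn <- if (direction == "poor") 1 else -1
  res <- results[results$converged & !is.na(results$p) & results$p < p_threshold &
                   sgn * results$log_hr > 0, ]
  counts <- table(res$variant_id)
  keep <- names(counts)[counts >= min_cancers]
  h1 <- numeric(); h2 <- numeric(); vid <- character()
  for (v in keep) {
    hrs <- res$hr[res$variant_id == v]
    cmb <- utils::combn(length(hrs), 2)
    h1 <- c(h1, hrs[cmb[1, ]]); h2 <- c(h2, hrs[cmb[2, ]])
    vid <- c(vid, rep(v, ncol(cmb)))
  }
  if (length(h1) < 3) return(list(rho = NA_real_, p = NA_real_, n_pairs = length(h1)))
  if (!control_af) {
    ct <- suppressWarnings(stats::cor.test(h1, h2, method = "spearman"))
    return(list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = length(h1)))
  }
  if (is.null(af)) .stopf("allele frequencies required when control_af = TRUE")
  out <- partial_spearman(h1, h2, af[vid])
  c(out, list(n_pairs = length(h1)))
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms the three vectors and returns the partial correlation of
#' the first two given the third, with the usual t-approximation p-value on
#' n - 3 degrees of freedom.
#'
#' @param x,y,z numeric vectors of equal length.
#' @return list with rho and p.
#' @export
partial_spearman <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r12 <- stats::cor(rx, ry); r13 <- stats::cor(rx, rz); r23 <- stats::cor(ry, rz)
  rho <- (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  n <- length(x)
  tstat <- rho * sqrt((n - 3) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 3))
}

#' Is the minor allele enriched for poor-outcome associations?
#'
#' Classifies each hit's alternate allele as minor (allele frequency below
#' 0.5) or major, and its association direction as poor (HR > 1) or
#' favorable, then runs a one-sided Fisher's exact test for enrichment of
#' the minor & poor cell.
#'
#' @param hits data.frame with log_hr (or hr) and an allele-frequency
#'   column named `population_af` (preferred) or `cohort_af`.
#' @return list: p, odds ratio estimate, and the 2x2 table
#'   (minor/major x poor/favorable).
#' @export
minor_allele_risk_test <- function(hits) {
  af <- hits$population_af %||% hits$cohort_af
  if (is.null(af)) .stopf("hits need a population_af or cohort_af column")
  minor <- factor(af < 0.5, levels = c(TRUE, FALSE), labels = c("minor", "major"))
  poor <- factor(hits$log_hr > 0, levels = c(TRUE, FALSE), labels = c("poor", "favorable"))
  tab <- table(minor, poor)
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Spearman correlation of effect size with allele frequency
#'
#' Effect size is |ln(HR)|; the correlation is computed over (linkage-
#' pruned) hits against their allele frequency.
#'
#' @param hits data.frame with log_hr and population_af/cohort_af columns.
#' @return list: rho, p; rho is NA (flagged) when either vector is constant.
#' @export
effect_size_af_correlation <- function(hits) {
  af <- hits$population_af %||% hits$cohort_af
  es <- abs(hits$log_hr)
  if (length(unique(af)) < 2 || length(unique(es)) < 2) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(es, af, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Prune linked variants, keeping the first by genomic position
#'
#' Among hits whose genotype correlation r-squared exceeds the threshold
#' (transitively), only the variant with the smallest (chrom, pos) is
#' retained. The result does not depend on the input row order.
#'
#' @param hits data.frame with variant_id, chrom, pos.
#' @param genotypes dosage matrix containing the hit variants.
#' @param r2_threshold linkage cut (default 0.8).
#' @return the pruned hits.
#' @export
ld_prune <- function(hits, genotypes, r2_threshold = 0.8) {
  vids <- unique(hits$variant_id)
  if (length(vids) < 2) return(hits)
  ann <- hits[!duplicated(hits$variant_id), c("variant_id", "chrom", "pos")]
  ann <- ann[order(ann$chrom, ann$pos, ann$variant_id), ]
  r2 <- suppressWarnings(stats::cor(genotypes[, ann$variant_id, drop = FALSE],
                                    use = "pairwise.complete.obs"))^2
  keep <- character()
  for (v in ann$variant_id) {
    linked <- length(keep) && any(r2[v, keep] > r2_threshold, na.rm = TRUE)
    if (!linked) keep <- c(keep, v)
  }
  hits[hits$variant_id %in% keep, , drop = FALSE]
}

#' Classify a variant position into genic regions
#'
#' Interval lookup against a transcript model. Each overlapping transcript
#' contributes a label (exonic, intronic, 5' UTR, 3' UTR); positions within
#' the flank window of a transcript end contribute upstream/downstream
#' (strand-aware); a position hitting nothing is intergenic. A variant may
#' carry several labels across transcripts.
#'
#' @param chrom,pos 1-based variant position.
#' @param gene_model data.frame of transcripts: tx_id, chrom, strand,
#'   tx_start, tx_end, cds_start, cds_end, exon_starts, exon_ends (the exon
#'   columns are comma-separated 1-based inclusive coordinates).
#' @param flank upstream/downstream window in bp (default 1000).
#' @return character vector of unique region labels.
#' @export
classify_region <- function(chrom, pos, gene_model, flank = 1000) {
  labels <- character()
  gm <- gene_model[gene_model$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(gm))) {
    tx <- gm[i, ]
    if (pos >= tx$tx_start && pos <= tx$tx_end) {
      es <- as.numeric(strsplit(as.character(tx$exon_starts), ",")[[1]])
      ee <- as.numeric(strsplit(as.character(tx$exon_ends), ",")[[1]])
      in_exon <- any(pos >= es & pos <= ee)
      if (!in_exon) {
        labels <- c(labels, "intronic")
      } else if (pos >= tx$cds_start && pos <= tx$cds_end) {
        labels <- c(labels, "exonic")
      } else {
        before_cds <- pos < tx$cds_start
        labels <- c(labels,
                    if (xor(before_cds, tx$strand == "-")) "5utr" else "3utr")
      }
    } else if (tx$strand == "+" && pos < tx$tx_start && pos >= tx$tx_start - flank) {
      labels <- c(labels, "upstream")
    } else if (tx$strand == "+" && pos > tx$tx_end && pos <= tx$tx_end + flank) {
      labels <- c(labels, "downstream")
    } else if (tx$strand == "-" && pos > tx$tx_end && pos <= tx$tx_end + flank) {
      labels <- c(labels, "upstream")
    } else if (tx$strand == "-" && pos < tx$tx_start && pos >= tx$tx_start - flank) {
      labels <- c(labels, "downstream")
    }
  }
  if (!length(labels)) "intergenic" else unique(labels)
}

#' Test whether paired prognostic variants act at least partly independently
#'
#' For each pair of poor-direction (linkage-pruned) variants within a
#' cancer: exclude patients homozygous for either variant, form group 1
#' (homozygous reference for both), group 2 (heterozygous for exactly one),
#' and group 3 (heterozygous for both), and fit one Cox model with the two
#' group indicators plus the clinical covariates. If the effects combine,
#' the hazard ratio of group 3 vs 1 exceeds that of group 2 vs 1; a paired
#' one-sided Wilcoxon signed-rank test across pairs tests this.
#'
#' @param hits poor-direction hits for one cancer (variant_id column).
#' @param genotypes dosage matrix for the cancer's patients.
#' @param cohort cohort rows for those patients (time, event, covariates).
#' @param covariates covariate column names to control for.
#' @param pairs optional 2-column matrix of variant-id pairs; all pairs of
#'   distinct hit variants by default.
#' @return list: `pairs` data.frame (variant_a, variant_b, hr_one, hr_both),
#'   `p` (paired one-sided signed-rank), `n_pairs`, `n_skipped`.
#' @export
pair_independence_test <- function(hits, genotypes, cohort, covariates = character(),
                                   pairs = NULL) {
  vids <- unique(hits$variant_id)
  if (is.null(pairs)) {
    if (length(vids) < 2) return(list(pairs = NULL, p = NA_real_, n_pairs = 0L,
                                      n_skipped = 0L))
    cmb <- utils::combn(vids, 2)
    pairs <- t(cmb)
  }
  cv <- as.matrix(cohort[, covariates, drop = FALSE])
  out <- list(); k <- 0L; skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    va <- pairs[i, 1]; vb <- pairs[i, 2]
    ga <- genotypes[, va]; gb <- genotypes[, vb]
    ok <- !is.na(ga) & !is.na(gb) & ga < 2 & gb < 2   # drop homozygous alt
    grp <- ifelse(ga[ok] == 0 & gb[ok] == 0, 1L,
                  ifelse(ga[ok] == 1 & gb[ok] == 1, 3L, 2L))
    if (!all(1:3 %in% grp)) { skipped <- skipped + 1L; next }
    x <- cbind(one = as.numeric(grp == 2L), both = as.numeric(grp == 3L),
               cv[ok, , drop = FALSE])
    core <- tryCatch(.cox_core(x, cohort$time[ok], cohort$event[ok]),
                     error = function(e) NULL)
    if (is.null(core) || !core$converged) { skipped <- skipped + 1L; next }
    k <- k + 1L
    out[[k]] <- data.frame(variant_a = va, variant_b = vb,
                           hr_one = exp(core$coef[1]), hr_both = exp(core$coef[2]),
                           stringsAsFactors = FALSE)
  }
  if (!k) return(list(pairs = NULL, p = NA_real_, n_pairs = 0L, n_skipped = skipped))
  tab <- do.call(rbind, out)
  p <- suppressWarnings(stats::wilcox.test(tab$hr_both, tab$hr_one, paired = TRUE,
                                           alternative = "greater")$p.value)
  list(pairs = tab, p = p, n_pairs = k, n_skipped = skipped)
}

#' Association of prognostic variants with somatic driver mutations
#'
#' Per (variant, driver gene): 2x2 table of risk-allele carriage (carriers
#' of the poor-direction allele vs the protective allele) against somatic
#' mutation, one-sided Fisher's exact test, BH-adjusted within each
#' variant's scan. Driver genes with fewer than `min_mutated` mutated
#' patients are not tested. A global one-sided Fisher test then asks whether
#' prognostic variants are associated (any pair with FDR below
#' `fdr_threshold`) more often than the other tested variants.
#'
#' @param hits prognostic hits (variant_id, log_hr).
#' @param all_results all tested variants (variant_id, log_hr) defining the
#'   comparison pool; must contain the hits.
#' @param genotypes dosage matrix.
#' @param driver_table patients x driver-genes 0/1 matrix.
#' @param min_mutated minimum mutated patients per driver gene (default 5).
#' @param fdr_threshold per-pair FDR cut for "associated" (default 0.10).
#' @return list: `pair_tests` data.frame, `n_prognostic_associated`,
#'   `global` (list with p, odds_ratio, table).
#' @export
driver_association_scan <- function(hits, all_results, genotypes, driver_table,
                                    min_mutated = 5, fdr_threshold = 0.10) {
  eligible_drivers <- colnames(driver_table)[colSums(driver_table) >= min_mutated]
  scan_variant <- function(v, log_hr) {
    g <- genotypes[, v]
    risk_carrier <- if (log_hr > 0) !is.na(g) & g >= 1 else !is.na(g) & g == 0
    known <- !is.na(g)
    rows <- lapply(eligible_drivers, function(dg) {
      tab <- table(factor(risk_carrier[known], levels = c(TRUE, FALSE)),
                   factor(driver_table[known, dg] == 1, levels = c(TRUE, FALSE)))
      data.frame(variant_id = v, driver_gene = dg,
                 p = stats::fisher.test(tab, alternative = "greater")$p.value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  run_pool <- function(res) {
    rows <- mapply(scan_variant, res$variant_id, res$log_hr, SIMPLIFY = FALSE)
    tab <- do.call(rbind, rows)
    if (is.null(tab)) return(NULL)
    tab$fdr <- stats::ave(tab$p, tab$variant_id, FUN = bh_fdr)
    tab
  }
  uniq <- function(d) d[!duplicated(d$variant_id), c("variant_id", "log_hr")]
  hits_u <- uniq(hits); all_u <- uniq(all_results)
  pair_tests <- run_pool(all_u)
  associated <- tapply(pair_tests$fdr < fdr_threshold, pair_tests$variant_id, any)
  is_hit <- names(associated) %in% hits_u$variant_id
  tab <- table(factor(is_hit, levels = c(TRUE, FALSE),
                      labels = c("prognostic", "other")),
               factor(associated, levels = c(TRUE, FALSE),
                      labels = c("associated", "not")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(pair_tests = pair_tests[pair_tests$variant_id %in% hits_u$variant_id, ],
       n_prognostic_associated = sum(associated[is_hit]),
       global = list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab))
}
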