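# Merging of the three per-source genotype call sets with source precedence,
# low-depth masking, strict three-way concordance, cohort allele frequency,
# and the three discovery filters (population AF, per-cancer carrier count,
# per-cancer concordance).

#' Mask genotype calls covered by too few reads
#'
#' Calls at positions covered by fewer than `min_depth` reads are set to
#' unknown (NA); everything else is untouched.
#'
#' @param calls a [source_call_set()].
#' @param min_depth minimum read depth to keep a call (default 10).
#' @return the call set with low-depth entries set to NA.
#' @export
mask_low_depth <- function(calls, min_depth = 10) {
  stopifnot(inherits(calls, "source_call_set"))
  g <- calls$genotypes
  g[calls$depth < min_depth] <- NA_integer_
  source_call_set(calls$source, g, calls$depth)
}

.check_aligned <- function(normal, tumor, rna) {
  d <- dim(normal$genotypes)
  if (!identical(d, dim(tumor$genotypes)) || !identical(d, dim(rna$genotypes)) ||
      !identical(dimnames(normal$genotypes), dimnames(tumor$genotypes)) ||
      !identical(dimnames(normal$genotypes), dimnames(rna$genotypes))) {
    .stopf("the three call sets must share patient and variant indices")
  }
}

#' Merge the three per-source call sets by source precedence
#'
#' Per entry, the merged genotype is the first known call in the order
#' normal exome, tumor exome, tumor RNA; the source used is recorded as
#' provenance. An entry unknown in all three sources stays unknown.
#'
#' @param normal,tumor,rna [source_call_set()]s sharing indices
#'   (WXS_NORMAL, WXS_TUMOR, RNA_TUMOR respectively).
#' @return a `merged_call_set`: list with `genotypes`, `provenance`
#'   (character matrix), and `cohort_af` (per-variant alternate-allele
#'   frequency over known calls).
#' @export
merge_calls <- function(normal, tumor, rna) {
  .check_aligned(normal, tumor, rna)
  g <- normal$genotypes
  prov <- matrix("WXS_NORMAL", nrow(g), ncol(g), dimnames = dimnames(g))
  miss <- is.na(g)
  g[miss] <- tumor$genotypes[miss]
  prov[miss] <- "WXS_TUMOR"
  miss <- is.na(g)
  g[miss] <- rna$genotypes[miss]
  prov[miss] <- "RNA_TUMOR"
  prov[is.na(g)] <- "UNKNOWN"
  structure(list(genotypes = g, provenance = prov,
                 cohort_af = cohort_allele_frequency(g)),
            class = "merged_call_set")
}

#' Per-variant three-way call concordance percentage
#'
#' A patient is concordant for a variant iff all three sources carry the
#' exact same known genotype class (homozygous reference, heterozygous, or
#' homozygous alternate). The percentage is concordant patients divided by
#' all patients considered, times 100; a patient with any unknown source
#' call counts as not concordant.
#'
#' @param normal,tumor,rna aligned [source_call_set()]s.
#' @param patients optional subset of patient row names (e.g. one cancer's
#'   patients); all rows by default.
#' @return named numeric vector of percentages in \[0, 100\] per variant.
#' @export
concordance_percent <- function(normal, tumor, rna, patients = NULL) {
  .check_aligned(normal, tumor, rna)
  g1 <- normal$genotypes; g2 <- tumor$genotypes; g3 <- rna$genotypes
  if (!is.null(patients)) {
    g1 <- g1[patients, , drop = FALSE]
    g2 <- g2[patients, , drop = FALSE]
    g3 <- g3[patients, , drop = FALSE]
  }
  if (nrow(g1) == 0L) .stopf("concordance is undefined with zero patients")
  conc <- !is.na(g1) & !is.na(g2) & !is.na(g3) & g1 == g2 & g2 == g3
  100 * colSums(conc) / nrow(g1)
}

#' Cohort alternate-allele frequency per variant
#'
#' Sum of alternate-allele dosages over known calls divided by twice the
#' number of known calls; NA (flagged missing) for a variant with no known
#' call.
#'
#' @param genotypes dosage matrix (or a `merged_call_set`).
#' @return named numeric vector of allele frequencies.
#' @export
cohort_allele_frequency <- function(genotypes) {
  if (inherits(genotypes, "merged_call_set")) genotypes <- genotypes$genotypes
  known <- colSums(!is.na(genotypes))
  af <- colSums(genotypes, na.rm = TRUE) / (2 * known)
  af[known == 0L] <- NA_real_
  af
}

#' Quality-control thresholds for the discovery filters
#'
#' Defaults follow the study design: calls below 10 reads masked, variants
#' kept only with population allele frequency above 5%, at least 15 carriers
#' in a cancer ("more than 14"), and per-cancer call concordance above 90%.
#'
#' @param min_depth,min_population_af,min_carriers,min_concordance_pct
#'   thresholds; population-AF and concordance cuts are strict inequalities.
#' @export
qc_thresholds <- function(min_depth = 10, min_population_af = 0.05,
                          min_carriers = 15, min_concordance_pct = 90) {
  stopifnot(min_depth >= 0, min_population_af >= 0, min_carriers >= 0,
            min_concordance_pct >= 0, min_concordance_pct <= 100)
  structure(list(min_depth = min_depth, min_population_af = min_population_af,
                 min_carriers = min_carriers,
                 min_concordance_pct = min_concordance_pct),
            class = "qc_thresholds")
}

#' Apply the three discovery filters per cancer
#'
#' A (variant, cancer) pair survives iff the variant's population allele
#' frequency exceeds `min_population_af` (strict), at least `min_carriers`
#' patients of that cancer carry one or more alternate alleles in the merged
#' calls, and the three-way call concordance within that cancer exceeds
#' `min_concordance_pct` (strict).
#'
#' @param merged a `merged_call_set`.
#' @param call_sets the list of three masked [source_call_set()]s (used for
#'   per-cancer concordance).
#' @param annotations annotation data.frame covering all variants
#'   (variant_id, population_af).
#' @param thresholds a [qc_thresholds()].
#' @param cancer named factor/character vector per patient (rownames of the
#'   genotype matrix must be its names or match its order).
#' @return data.frame with one row per (variant, cancer): pass/fail flags
#'   per filter, carriers, concordance_pct, and overall `pass`; per-filter
#'   exclusion counts are attached as attribute `exclusions` (a variant
#'   fails a cancer's exclusion count once per filter it violates).
#' @export
qc_filter <- function(merged, call_sets, annotations, thresholds = qc_thresholds(),
                      cancer) {
  g <- merged$genotypes
  vids <- colnames(g)
  if (!all(vids %in% annotations$variant_id)) .stopf("annotations must cover all variants")
  pop_af <- annotations$population_af[match(vids, annotations$variant_id)]
  cancers <- sort(unique(as.character(cancer)))
  res <- vector("list", length(cancers))
  for (i in seq_along(cancers)) {
    rows <- which(as.character(cancer) == cancers[i])
    carriers <- colSums(g[rows, , drop = FALSE] >= 1, na.rm = TRUE)
    conc <- concordance_percent(call_sets$WXS_NORMAL, call_sets$WXS_TUMOR,
                                call_sets$RNA_TUMOR,
                                patients = rownames(g)[rows])
    res[[i]] <- data.frame(
      variant_id = vids, cancer = cancers[i],
      population_af = pop_af, carriers = carriers, concordance_pct = conc,
      pass_population_af = pop_af > thresholds$min_population_af,
      pass_carriers = carriers >= thresholds$min_carriers,
      pass_concordance = conc > thresholds$min_concordance_pct,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- do.call(rbind, res)
  out$pass <- out$pass_population_af & out$pass_carriers & out$pass_concordance
  attr(out, "exclusions") <- c(
    population_af = sum(!out$pass_population_af),
    carriers = sum(!out$pass_carriers),
    concordance = sum(!out$pass_concordance)
  )
  out
}

#' Spearman correlation of per-variant allele frequencies across sources
#'
#' Pairwise Spearman rank correlation among the per-variant allele-frequency
#' vectors of the three sources and the merged calls.
#'
#' @param call_sets list of the three [source_call_set()]s.
#' @param merged a `merged_call_set`.
#' @return 4x4 matrix of Spearman rho.
#' @export
cross_source_af_correlation <- function(call_sets, merged) {
  afs <- cbind(
    WXS_NORMAL = cohort_allele_frequency(call_sets$WXS_NORMAL$genotypes),
    WXS_TUMOR = cohort_allele_frequency(call_sets$WXS_TUMOR$genotypes),
    RNA_TUMOR = cohort_allele_frequency(call_sets$RNA_TUMOR$genotypes),
    MERGED = merged$cohort_af
  )
  stats::cor(afs, method = "spearman", use = "pairwise.complete.obs")
}
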