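# cis-eQTL triage of prognostic variants: carrier-status expression test,
# covariate-adjusted Cox on gene expression, and the direction-concordance
# chain that must close for a candidate to be retained.

#' Carrier-status expression test
#'
#' Splits patients by carriage of at least one alternate allele and compares
#' the gene's expression between the groups with a Wilcoxon rank-sum test.
#'
#' @param dosage variant dosage vector (NA = unknown).
#' @param expression expression values aligned to `dosage`.
#' @return list: p, direction (+1 carriers higher, -1 lower), n_carriers.
#'   p is NA (flagged) when either group is empty.
#' @export
carrier_expression_test <- function(dosage, expression) {
  ok <- !is.na(dosage) & !is.na(expression)
  carrier <- dosage[ok] >= 1
  if (!any(carrier) || all(carrier)) {
    return(list(p = NA_real_, direction = NA_real_, n_carriers = sum(carrier)))
  }
  p <- suppressWarnings(stats::wilcox.test(expression[ok][carrier],
                                           expression[ok][!carrier])$p.value)
  dir <- sign(stats::median(expression[ok][carrier]) -
                stats::median(expression[ok][!carrier]))
  list(p = p, direction = dir, n_carriers = sum(carrier))
}

#' Triage prognostic variants acting as concordant cis-eQTLs
#'
#' For each hit with an annotated gene: (1) carrier-status expression test;
#' (2) Cox regression of outcome on the gene's standardized expression,
#' controlling the clinical covariates. A candidate is retained when both
#' p-values fall below `p_threshold` (a relaxed cut, since the two results
#' must additionally be concordant) and the direction chain closes: a
#' risk variant whose carriers have higher expression must see expression
#' itself carry HR above 1 (and each sign flip must propagate), i.e.
#' sign(variant log HR) x expression direction x sign(expression log HR) > 0.
#'
#' @param hits scan hits with variant_id, stratum (cancer), log_hr.
#' @param expression genes x patients matrix.
#' @param genotypes dosage matrix (patients x variants).
#' @param cohort cohort data.frame (time, event, covariates, cancer).
#' @param covariates_per_cancer named list of covariates per cancer.
#' @param annotations annotation table mapping variant_id to gene_id.
#' @param p_threshold relaxed per-test cut (default 0.10).
#' @return data.frame of candidates with the component statistics and a
#'   `concordant` flag; retained candidates have `retained = TRUE`.
#' @export
concordant_eqtl_scan <- function(hits, expression, genotypes, cohort,
                                 covariates_per_cancer, annotations,
                                 p_threshold = 0.10) {
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(hits))) {
    v <- hits$variant_id[i]; cz <- hits$stratum[i]
    gene <- annotations$gene_id[match(v, annotations$variant_id)]
    if (is.na(gene) || !gene %in% rownames(expression)) next
    idx <- which(cohort$cancer == cz)
    dos <- genotypes[idx, v]
    expr <- expression[gene, idx]
    et <- carrier_expression_test(dos, expr)
    if (is.na(et$p)) next
    z <- as.numeric(scale(expr))
    covars <- covariates_per_cancer[[cz]] %||% character()
    x <- cbind(expr = z, as.matrix(cohort[idx, covars, drop = FALSE]))
    core <- tryCatch(.cox_core(x, cohort$time[idx], cohort$event[idx]),
                     error = function(e) NULL)
    if (is.null(core) || !core$converged) next
    chain <- sign(hits$log_hr[i]) * et$direction * sign(core$coef[1])
    k <- k + 1L
    rows[[k]] <- data.frame(
      variant_id = v, gene_id = gene, cancer = cz,
      variant_log_hr = hits$log_hr[i],
      expression_p = et$p, expression_direction = et$direction,
      expression_log_hr = core$coef[1], expression_cox_p = core$p[1],
      concordant = is.finite(chain) && chain > 0,
      stringsAsFactors = FALSE)
  }
  if (!k) {
    return(data.frame(variant_id = character(), gene_id = character(),
                      cancer = character(), variant_log_hr = numeric(),
                      expression_p = numeric(), expression_direction = numeric(),
                      expression_log_hr = numeric(), expression_cox_p = numeric(),
                      concordant = logical(), retained = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$retained <- out$concordant & out$expression_p < p_threshold &
    out$expression_cox_p < p_threshold
  out
}
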