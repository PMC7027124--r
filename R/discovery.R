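# The six discovery analyses: per-cancer Cox scans (1, 4), recurrence
# filters across cancers (2, 5), and pooled-group scans with per-cancer
# covariate interaction designs (3, 6). Analyses 4-6 restrict the tested
# family to high-CADD variants.

#' Scan configuration
#'
#' @param fdr_threshold FDR cut for a hit (default 0.10).
#' @param per_cancer_p unadjusted p threshold used by the recurrence
#'   analyses (default 0.05).
#' @param recurrence_min_cancers minimum same-direction cancers: 7 for the
#'   all-variant recurrence analysis, 5 for the high-CADD one.
#' @param cadd_threshold CADD score cut for analyses 4-6 (strict, default 25).
#' @param genotype_coding "additive" (dosage 0/1/2) or "dominant"
#'   (carrier 0/1).
#' @param group_min_carriers minimum pooled carriers for a variant to enter
#'   a group scan (default 15).
#' @export
scan_config <- function(fdr_threshold = 0.10, per_cancer_p = 0.05,
                        recurrence_min_cancers = 7, cadd_threshold = 25,
                        genotype_coding = c("additive", "dominant"),
                        group_min_carriers = 15) {
  genotype_coding <- match.arg(genotype_coding)
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1, per_cancer_p > 0,
            per_cancer_p <= 1, recurrence_min_cancers >= 1, group_min_carriers >= 0)
  structure(list(fdr_threshold = fdr_threshold, per_cancer_p = per_cancer_p,
                 recurrence_min_cancers = recurrence_min_cancers,
                 cadd_threshold = cadd_threshold,
                 genotype_coding = genotype_coding,
                 group_min_carriers = group_min_carriers),
            class = "scan_config")
}

.code_genotype <- function(dosage, coding) {
  if (coding == "dominant") as.integer(dosage >= 1) else dosage
}

# One variant's Cox fit inside a stratum: variant term first, then the
# covariate block. Patients with unknown genotype at this variant are
# dropped from this fit only.
.scan_one <- function(dosage, covar, times, events, coding) {
  keep <- !is.na(dosage)
  x <- cbind(variant = .code_genotype(dosage[keep], coding),
             covar[keep, , drop = FALSE])
  times <- times[keep]; events <- events[keep]
  if (length(times) == 0L || sum(events) == 0L) return(NULL)
  sds <- apply(x, 2, stats::sd)
  if (sds[1] == 0) return(NULL)          # monomorphic in stratum
  x <- x[, sds > 0, drop = FALSE]        # drop covariates constant here
  core <- tryCatch(.cox_core(x, times, events), error = function(e) NULL)
  if (is.null(core)) return(NULL)
  list(log_hr = core$coef[1], se = core$se[1], p = core$p[1], n = core$n,
       n_events = core$n_events, n_carriers = sum(dosage[keep] >= 1),
       converged = core$converged)
}

.finish_scan <- function(rows, fdr_threshold) {
  if (!length(rows)) {
    return(data.frame(variant_id = character(), stratum = character(),
                      log_hr = numeric(), se = numeric(), hr = numeric(),
                      p = numeric(), fdr = numeric(), n = integer(),
                      n_events = integer(), n_carriers = integer(),
                      converged = logical(), direction = character(),
                      hit = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$hr <- exp(out$log_hr)
  # BH within each stratum over the converged fits only; non-converged
  # fits are kept in the table (fdr NA) but leave the BH family
  out$fdr <- NA_real_
  for (s in unique(out$stratum)) {
    fam <- which(out$stratum == s & out$converged)
    out$fdr[fam] <- bh_fdr(out$p[fam])
  }
  out$direction <- ifelse(out$log_hr > 0, "poor", "favorable")
  out$hit <- !is.na(out$fdr) & out$fdr < fdr_threshold
  rownames(out) <- NULL
  out
}

#' Per-cancer prognostic variant scan
#'
#' Fits one Cox model per (variant, cancer) — variant genotype plus the
#' cancer's selected clinical covariates — over the patients of that cancer,
#' and adjusts p-values by Benjamini-Hochberg within each cancer. With
#' `cadd_filter = TRUE` only variants with CADD score above the configured
#' threshold enter, and the BH family is that subset.
#'
#' @param merged a `merged_call_set` (rows aligned to `cohort`).
#' @param cohort data.frame with cancer, covariates, time, event.
#' @param covariates_per_cancer named list: covariate column names selected
#'   for each cancer (may be empty).
#' @param eligibility output of [qc_filter()]; only passing (variant,
#'   cancer) pairs are tested.
#' @param config a [scan_config()].
#' @param annotations annotation table (required when `cadd_filter`).
#' @param cadd_filter restrict to high-CADD variants (analyses 4-6 style).
#' @return data.frame of per-(variant, cancer) results with columns
#'   variant_id, stratum, log_hr, se, hr, p, fdr, n, n_events, n_carriers,
#'   converged, direction, hit.
#' @export
per_cancer_scan <- function(merged, cohort, covariates_per_cancer, eligibility,
                            config = scan_config(), annotations = NULL,
                            cadd_filter = FALSE) {
  g <- merged$genotypes
  stopifnot(nrow(g) == nrow(cohort))
  elig <- eligibility[eligibility$pass, c("variant_id", "cancer")]
  if (cadd_filter) {
    if (is.null(annotations)) .stopf("annotations required for the CADD-restricted scan")
    high <- annotations$variant_id[annotations$cadd_score > config$cadd_threshold]
    elig <- elig[elig$variant_id %in% high, , drop = FALSE]
  }
  rows <- list(); k <- 0L
  for (cz in unique(elig$cancer)) {
    idx <- which(cohort$cancer == cz)
    if (!length(idx)) next
    covars <- covariates_per_cancer[[cz]] %||% character()
    cv <- as.matrix(cohort[idx, covars, drop = FALSE])
    times <- cohort$time[idx]; events <- cohort$event[idx]
    for (v in elig$variant_id[elig$cancer == cz]) {
      fit <- .scan_one(g[idx, v], cv, times, events, config$genotype_coding)
      if (is.null(fit)) next
      k <- k + 1L
      rows[[k]] <- data.frame(variant_id = v, stratum = cz,
                              log_hr = fit$log_hr, se = fit$se, p = fit$p,
                              n = fit$n, n_events = fit$n_events,
                              n_carriers = fit$n_carriers,
                              converged = fit$converged,
                              stringsAsFactors = FALSE)
    }
  }
  .finish_scan(rows, config$fdr_threshold)
}

#' Recurrently associated variants across cancers
#'
#' A variant qualifies when the number of cancers in which it is associated
#' (unadjusted p below `p_threshold`) with the *same* hazard-ratio direction
#' reaches `min_cancers`.
#'
#' @param results full per-cancer scan results (all tested fits, not only
#'   hits).
#' @param min_cancers minimum count of same-direction significant cancers.
#' @param p_threshold unadjusted p cut (default 0.05).
#' @return data.frame: variant_id, n_poor, n_favorable, direction (of the
#'   majority), retained.
#' @export
recurrence_filter <- function(results, min_cancers, p_threshold = 0.05) {
  res <- results[results$converged & !is.na(results$p) & results$p < p_threshold, ]
  if (!nrow(res)) {
    return(data.frame(variant_id = character(), n_poor = integer(),
                      n_favorable = integer(), direction = character(),
                      retained = logical(), stringsAsFactors = FALSE))
  }
  tab <- stats::aggregate(cbind(n_poor = res$log_hr > 0,
                                n_favorable = res$log_hr < 0),
                          by = list(variant_id = res$variant_id), FUN = sum)
  tab$direction <- ifelse(tab$n_poor >= tab$n_favorable, "poor", "favorable")
  tab$retained <- pmax(tab$n_poor, tab$n_favorable) >= min_cancers
  tab
}

#' Specify a pooled cancer group
#'
#' @param group_id label.
#' @param cancers member cancer codes (two or more for a true pooled group).
#' @export
group_spec <- function(group_id, cancers) {
  stopifnot(length(cancers) >= 1)
  structure(list(group_id = group_id, cancers = sort(unique(cancers))),
            class = "group_spec")
}

#' Build the pooled-group Cox design (cancer dummies + interactions)
#'
#' Columns are cancer-membership dummies (the last member in sorted order is
#' the reference, so a two-cancer group {X, Y} carries the dummy `X_status`
#' as in the pooled model), plus one interaction column per (cancer,
#' selected covariate) pair — the covariate's value inside that cancer and
#' zero outside it. The variant column is appended by the scan.
#'
#' @param group a [group_spec()].
#' @param cohort the cohort restricted or not; only member-cancer patients
#'   are used.
#' @param covariates_per_cancer named list of selected covariates per cancer.
#' @return list: `design` (matrix), `rows` (cohort row indices used).
#' @export
build_group_design <- function(group, cohort, covariates_per_cancer) {
  members <- group$cancers
  present <- members[members %in% cohort$cancer]
  if (length(present) < length(members)) {
    warning("dropping empty cancers from group: ",
            paste(setdiff(members, present), collapse = ", "))
  }
  members <- present
  rows <- which(cohort$cancer %in% members)
  sub <- cohort[rows, , drop = FALSE]
  cols <- list()
  if (length(members) > 1L) {
    for (cz in utils::head(members, -1L)) {
      cols[[paste0(cz, "_status")]] <- as.numeric(sub$cancer == cz)
    }
  }
  for (cz in members) {
    for (cov in covariates_per_cancer[[cz]] %||% character()) {
      cols[[paste0(cz, ":", cov)]] <- as.numeric(sub$cancer == cz) * sub[[cov]]
    }
  }
  design <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = length(rows), ncol = 0)
  list(design = design, rows = rows)
}

#' Pooled-group prognostic variant scan
#'
#' For each group, variants carried by at least `group_min_carriers` pooled
#' patients are fitted on the interaction design of
#' [build_group_design()] with the variant genotype appended; BH adjustment
#' is within group. Cancer-dummy and interaction coefficients are nuisance
#' terms and are not reported.
#'
#' @param groups list of [group_spec()]s.
#' @param merged a `merged_call_set`.
#' @param cohort cohort data.frame.
#' @param covariates_per_cancer named list of selected covariates per cancer.
#' @param config a [scan_config()].
#' @param annotations,cadd_filter as in [per_cancer_scan()].
#' @param variants optional restriction of the tested variant set (e.g. the
#'   QC-passing union); all genotyped variants by default.
#' @return data.frame as in [per_cancer_scan()] with `stratum` = group id
#'   and an extra `n_group_patients` column.
#' @export
group_scan <- function(groups, merged, cohort, covariates_per_cancer,
                       config = scan_config(), annotations = NULL,
                       cadd_filter = FALSE, variants = NULL) {
  g <- merged$genotypes
  stopifnot(nrow(g) == nrow(cohort))
  vids <- variants %||% colnames(g)
  if (cadd_filter) {
    if (is.null(annotations)) .stopf("annotations required for the CADD-restricted scan")
    vids <- intersect(vids, annotations$variant_id[annotations$cadd_score > config$cadd_threshold])
  }
  rows <- list(); k <- 0L
  for (grp in groups) {
    bd <- build_group_design(grp, cohort, covariates_per_cancer)
    if (!length(bd$rows)) next
    times <- cohort$time[bd$rows]; events <- cohort$event[bd$rows]
    gg <- g[bd$rows, , drop = FALSE]
    carriers <- colSums(gg[, vids, drop = FALSE] >= 1, na.rm = TRUE)
    for (v in vids[carriers >= config$group_min_carriers]) {
      fit <- .scan_one(gg[, v], bd$design, times, events, config$genotype_coding)
      if (is.null(fit)) next
      k <- k + 1L
      rows[[k]] <- data.frame(variant_id = v, stratum = grp$group_id,
                              log_hr = fit$log_hr, se = fit$se, p = fit$p,
                              n = fit$n, n_events = fit$n_events,
                              n_carriers = fit$n_carriers,
                              converged = fit$converged,
                              n_group_patients = length(bd$rows),
                              stringsAsFactors = FALSE)
    }
  }
  .finish_scan(rows, config$fdr_threshold)
}

#' Keep one row per variant across overlapping groups (largest group wins)
#'
#' When a variant is reported in several overlapping groups, downstream
#' characterization uses the fit from the group containing the most
#' patients.
#'
#' @param group_results output of [group_scan()].
#' @return the results restricted to the largest group per variant.
#' @export
dedupe_group_hits <- function(group_results) {
  if (!nrow(group_results)) return(group_results)
  ord <- order(group_results$variant_id, -group_results$n_group_patients)
  res <- group_results[ord, ]
  res[!duplicated(res$variant_id), ]
}

#' Hazard-ratio agreement between a scan and a sensitivity rerun
#'
#' Generic covariate-sensitivity check: rerun a scan with an extra covariate
#' block (e.g. adding race composition back) and report the Spearman
#' correlation of the per-(variant, stratum) log hazard ratios.
#'
#' @param results,results_sensitivity two scan result tables.
#' @return list with `rho` and `p` from a Spearman correlation test.
#' @export
hr_sensitivity_correlation <- function(results, results_sensitivity) {
  key <- function(d) paste(d$variant_id, d$stratum)
  m <- match(key(results), key(results_sensitivity))
  ok <- !is.na(m)
  ct <- suppressWarnings(stats::cor.test(results$log_hr[ok],
                                         results_sensitivity$log_hr[m[ok]],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
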