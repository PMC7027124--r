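# Orchestration: one configuration drives simulate -> merge-qc -> covariate
# selection -> scans 1-6 -> characterization -> AUC evaluation -> eQTL
# triage -> power analysis, writing a reproducible TSV/JSON report bundle.
# Every table carries the configuration hash and master seed in a leading
# comment line.

#' Default pipeline configuration
#'
#' Returns the demo-scale configuration: three cancers, Hardy-Weinberg
#' genotypes at annotated frequencies, a handful of planted prognostic,
#' eQTL, and driver effects, moderate censoring, and all analyses enabled.
#' Any element can be overridden by the matching argument.
#'
#' @param seed master seed; every stage derives named child streams from it.
#' @param ... overrides merged over the defaults (shallow, by name).
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    simulate = list(
      n_patients = 900,
      cancer_codes = c("CAN1", "CAN2", "CAN3"),
      cancer_props = c(1, 1, 1),
      covariate_spec = list(age = list(dist = "normal", mean = 60, sd = 10),
                            stage = list(dist = "binary", prob = 0.4)),
      n_variants = 300,
      af_range = c(0.05, 0.5),
      frac_high_cadd = 0.15,
      n_genes = 60,
      variant_effects = c(var0001 = log(3), var0002 = log(2.5),
                          var0003 = -log(2.5), var0010 = log(2)),
      covariate_effects = c(age = 0.03, stage = 0.6),
      # gene_id "cis" resolves to the variant's annotated gene at run time
      eqtl_effects = list(var0001 = list(gene_id = "cis", shift = 1.5)),
      driver_assoc = list(var0002 = list(driver_gene = "DRV1", or = 4)),
      baseline_scale = 0.05, baseline_shape = 1, censoring_rate = 0.3,
      discordance_rate = 0.01,
      depth = list(dist = "poisson", mean = 30),
      driver_genes = paste0("DRV", 1:5),
      driver_background_rate = 0.1
    ),
    qc = list(min_depth = 10, min_population_af = 0.05, min_carriers = 15,
              min_concordance_pct = 90),
    scan = list(fdr_threshold = 0.10, per_cancer_p = 0.05,
                cadd_threshold = 25, genotype_coding = "additive",
                group_min_carriers = 15),
    groups = list(list(group_id = "G1", cancers = c("CAN1", "CAN2", "CAN3")),
                  list(group_id = "G2", cancers = c("CAN1", "CAN2"))),
    analyses = 1:6,
    recurrence_min_cancers = 7,
    recurrence_min_cancers_cadd = 5,
    power_hrs = c(2, 3, 4, 5, 10, 15, 20),
    power_sample = 10000,
    max_auc_variants = 10
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys override the defaults of
#' [default_config()].
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config(seed = y$seed %||% 1L)
  for (nm in setdiff(names(y), "seed")) {
    blk <- y[[nm]]
    # named blocks merge over the defaults; lists like `groups` and scalar
    # settings replace them outright
    cfg[[nm]] <- if (is.list(blk) && !is.null(names(blk)) && all(names(blk) != "")) {
      utils::modifyList(cfg[[nm]] %||% list(), blk)
    } else blk
  }
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Fails fast with the offending field named.
#'
#' @param config a `run_config`.
#' @export
validate_config <- function(config) {
  need <- function(block, field) {
    if (is.null(config[[block]][[field]])) {
      .stopf("config validation: missing required field '%s$%s'", block, field)
    }
  }
  if (is.null(config$seed)) .stopf("config validation: missing required field 'seed'")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    .stopf("config validation: provide either a 'simulate' block or an 'inputs' block")
  }
  if (!is.null(config$simulate)) {
    for (f in c("n_patients", "cancer_codes", "covariate_spec", "n_variants")) {
      need("simulate", f)
    }
    if (config$simulate$n_patients < 1) .stopf("config validation: simulate$n_patients must be >= 1")
  }
  invisible(TRUE)
}

# Small stable FNV-1a hash of the deparsed configuration for provenance
# stamping of output tables.
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 19661366
  for (k in utf8ToInt(s)) h <- (bitwXor(as.integer(h), k) * 16777619) %% 2147483647
  sprintf("%08x", h)
}

.stamp_tsv <- function(x, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# germscan config_hash=%s seed=%d", hash, seed), con)
  close(con)
  suppressWarnings(utils::write.table(x, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full discovery pipeline
#'
#' Executes the requested stages in dependency order from one configuration
#' and writes the report bundle (TSVs plus a JSON summary) to `out_dir`.
#' With identical configuration and seed the bundle is byte-identical across
#' reruns.
#'
#' @param config a `run_config` from [default_config()] / [read_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  say <- function(...) if (!quiet) message(sprintf("[germscan] %s", sprintf(...)))
  stamp <- function(x, name) .stamp_tsv(x, file.path(out_dir, name), hash, seed)

  ## -- simulate -------------------------------------------------------
  sim <- config$simulate
  say("simulate: n=%d patients, %d variants", sim$n_patients, sim$n_variants)
  variants <- generate_variant_table(sim$n_variants, sim$af_range,
                                     sim$frac_high_cadd, sim$n_genes, seed = seed)
  cohort <- generate_baseline_cohort(sim$n_patients, sim$cancer_codes,
                                     sim$covariate_spec, sim$cancer_props, seed = seed)
  truth <- generate_genotypes(variants, sim$n_patients, seed = seed)
  plan <- effect_plan(variant_effects = unlist(sim$variant_effects),
                      covariate_effects = unlist(sim$covariate_effects),
                      eqtl_effects = sim$eqtl_effects,
                      driver_assoc = sim$driver_assoc,
                      baseline_scale = sim$baseline_scale,
                      baseline_shape = sim$baseline_shape,
                      censoring_rate = sim$censoring_rate)
  # planted eQTLs are cis by construction: the shifted gene is the variant's
  # annotated proximate gene, whatever placeholder the config carried
  for (v in names(plan$eqtl_effects)) {
    plan$eqtl_effects[[v]]$gene_id <-
      variants$gene_id[match(v, variants$variant_id)]
  }
  cohort <- simulate_outcomes(cohort, truth, plan, seed = seed)
  call_sets <- corrupt_to_call_sets(truth, sim$discordance_rate, sim$depth,
                                    seed = seed)
  expression <- simulate_expression(truth, plan, sim$n_genes, seed = seed)
  drivers <- simulate_driver_mutations(truth, plan, sim$driver_genes,
                                       sim$driver_background_rate, seed = seed)
  for (src in names(call_sets)) {
    write_vcf(call_sets[[src]], variants,
              file.path(out_dir, paste0(tolower(src), ".vcf")))
  }
  stamp(cohort, "clinical.tsv")
  stamp(variants, "annotations.tsv")
  write_matrix_tsv(expression, file.path(out_dir, "expression.tsv"), "gene_id")
  write_matrix_tsv(drivers, file.path(out_dir, "drivers.tsv"), "patient_id")
  write_truth(plan, file.path(out_dir, "truth.json"))

  ## -- merge & QC -----------------------------------------------------
  say("merge-qc")
  thr <- do.call(qc_thresholds, config$qc)
  masked <- lapply(call_sets, mask_low_depth, min_depth = thr$min_depth)
  merged <- merge_calls(masked$WXS_NORMAL, masked$WXS_TUMOR, masked$RNA_TUMOR)
  qc <- qc_filter(merged, masked, variants, thr, cohort$cancer)
  stamp(qc, "qc_report.tsv")
  af_cor <- cross_source_af_correlation(masked, merged)

  ## -- covariate selection -------------------------------------------
  say("covariate selection (Lasso)")
  covar_cols <- setdiff(names(cohort), c("patient_id", "cancer", "time", "event"))
  covariates_per_cancer <- list()
  for (cz in sort(unique(cohort$cancer))) {
    idx <- cohort$cancer == cz
    cand <- covar_cols[vapply(covar_cols, function(v) stats::sd(cohort[[v]][idx]) > 0, TRUE)]
    covariates_per_cancer[[cz]] <- if (length(cand)) {
      lasso_select_covariates(cohort[idx, cand, drop = FALSE],
                              cohort$time[idx], cohort$event[idx],
                              seed = child_seed(seed, paste0("lasso_", cz)))
    } else character()
  }

  ## -- scans ----------------------------------------------------------
  scfg <- do.call(scan_config, c(config$scan,
                                 list(recurrence_min_cancers = config$recurrence_min_cancers)))
  groups <- lapply(config$groups, function(gs) group_spec(gs$group_id, gs$cancers))
  results <- list()
  if (1 %in% config$analyses) {
    say("analysis 1: per-cancer scan")
    results$a1 <- per_cancer_scan(merged, cohort, covariates_per_cancer, qc, scfg)
    stamp(results$a1, "analysis1.tsv")
  }
  if (2 %in% config$analyses && !is.null(results$a1)) {
    results$a2 <- recurrence_filter(results$a1, config$recurrence_min_cancers,
                                    scfg$per_cancer_p)
    stamp(results$a2, "analysis2.tsv")
  }
  if (3 %in% config$analyses) {
    say("analysis 3: pooled-group scan")
    results$a3 <- group_scan(groups, merged, cohort, covariates_per_cancer, scfg,
                             variants = unique(qc$variant_id[qc$pass]))
    stamp(results$a3, "analysis3.tsv")
  }
  if (4 %in% config$analyses) {
    results$a4 <- per_cancer_scan(merged, cohort, covariates_per_cancer, qc, scfg,
                                  annotations = variants, cadd_filter = TRUE)
    stamp(results$a4, "analysis4.tsv")
  }
  if (5 %in% config$analyses && !is.null(results$a4)) {
    results$a5 <- recurrence_filter(results$a4, config$recurrence_min_cancers_cadd,
                                    scfg$per_cancer_p)
    stamp(results$a5, "analysis5.tsv")
  }
  if (6 %in% config$analyses) {
    results$a6 <- group_scan(groups, merged, cohort, covariates_per_cancer, scfg,
                             annotations = variants, cadd_filter = TRUE,
                             variants = unique(qc$variant_id[qc$pass]))
    stamp(results$a6, "analysis6.tsv")
  }

  ## -- characterization ----------------------------------------------
  say("characterization")
  chars <- list()
  if (!is.null(results$a1) && nrow(results$a1)) {
    chars$direction <- direction_index_stats(results$a1)
    hits1 <- results$a1[results$a1$hit, , drop = FALSE]
    if (nrow(hits1)) {
      hits1$population_af <- variants$population_af[match(hits1$variant_id,
                                                          variants$variant_id)]
      hits1$chrom <- variants$chrom[match(hits1$variant_id, variants$variant_id)]
      hits1$pos <- variants$pos[match(hits1$variant_id, variants$variant_id)]
      pruned <- ld_prune(hits1, merged$genotypes)
      chars$minor_allele <- minor_allele_risk_test(pruned)
      chars$effect_af <- effect_size_af_correlation(pruned)
      chars$driver <- driver_association_scan(pruned, results$a1,
                                              merged$genotypes, drivers)
      stamp(pruned, "hits_analysis1_pruned.tsv")
    }
  }

  ## -- AUC evaluation -------------------------------------------------
  auc_rows <- list()
  if (!is.null(results$a1) && any(results$a1$hit)) {
    say("delta-AUC evaluation")
    hits <- results$a1[results$a1$hit, ]
    hits <- utils::head(hits[order(hits$fdr), ], config$max_auc_variants)
    for (i in seq_len(nrow(hits))) {
      cz <- hits$stratum[i]
      idx <- which(cohort$cancer == cz)
      s <- delta_auc_series(cohort[idx, ], covariates_per_cancer[[cz]],
                            merged$genotypes[idx, hits$variant_id[i]],
                            coding = scfg$genotype_coding)
      auc_rows[[i]] <- data.frame(variant_id = hits$variant_id[i], cancer = cz,
                                  mean_delta = s$mean_delta, se_delta = s$se_delta,
                                  improvement_p = auc_improvement_test(s),
                                  n_times = length(s$eval_times),
                                  stringsAsFactors = FALSE)
    }
    stamp(do.call(rbind, auc_rows), "delta_auc.tsv")
  }

  ## -- eQTL triage ----------------------------------------------------
  eqtl_tab <- NULL
  if (!is.null(results$a1) && any(results$a1$hit)) {
    say("eQTL triage")
    eqtl_tab <- concordant_eqtl_scan(results$a1[results$a1$hit, ], expression,
                                     merged$genotypes, cohort,
                                     covariates_per_cancer, variants)
    stamp(eqtl_tab, "eqtl_candidates.tsv")
  }

  ## -- power analysis -------------------------------------------------
  say("power analysis")
  power_rows <- list(); k <- 0L
  for (cz in sort(unique(cohort$cancer))) {
    elig <- qc$variant_id[qc$pass & qc$cancer == cz]
    if (!length(elig)) next
    set.seed(child_seed(seed, paste0("power_", cz)))
    samp <- if (length(elig) > config$power_sample) {
      sample(elig, config$power_sample)
    } else elig
    idx <- cohort$cancer == cz
    n_cz <- sum(idx)
    ev_rate <- mean(cohort$event[idx])
    alpha <- scan_alpha(length(elig))
    carrier_frac <- colMeans(merged$genotypes[idx, samp, drop = FALSE] >= 1,
                             na.rm = TRUE)
    carrier_frac <- pmin(pmax(carrier_frac, 1e-6), 1 - 1e-6)
    for (hr in config$power_hrs) {
      pw <- cox_power(n_cz, ev_rate, carrier_frac, hr, alpha)
      k <- k + 1L
      power_rows[[k]] <- data.frame(cancer = cz, hr = hr,
                                    n_variants = length(samp),
                                    alpha = alpha,
                                    mean_power = mean(pw),
                                    frac_above_80 = mean(pw > 0.8),
                                    stringsAsFactors = FALSE)
    }
  }
  power_tab <- do.call(rbind, power_rows)
  stamp(power_tab, "power.tsv")

  ## -- summary --------------------------------------------------------
  hit_counts <- lapply(results, function(r) {
    if ("hit" %in% names(r)) sum(r$hit) else sum(r$retained)
  })
  summary <- list(
    config_hash = hash, seed = seed,
    n_patients = nrow(cohort), n_variants = ncol(truth),
    qc_pass_pairs = sum(qc$pass),
    exclusions = as.list(attr(qc, "exclusions")),
    hits = hit_counts,
    expected_direction_index = chars$direction$expected_index %||% NA,
    minor_allele_p = chars$minor_allele$p %||% NA,
    af_correlation_merged_vs_normal = unname(af_cor["MERGED", "WXS_NORMAL"]),
    power_frac_above_80 = if (!is.null(power_tab)) {
      hrs <- sort(unique(power_tab$hr))
      stats::setNames(lapply(hrs, function(h) {
        mean(power_tab$frac_above_80[power_tab$hr == h])
      }), paste0("hr", hrs))
    } else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %s", out_dir)
  invisible(list(variants = variants, cohort = cohort, truth = truth,
                 plan = plan, merged = merged, qc = qc,
                 covariates_per_cancer = covariates_per_cancer,
                 results = results, characterization = chars,
                 auc = auc_rows, eqtl = eqtl_tab, power = power_tab,
                 af_correlation = af_cor))
}
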