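# Independent brute-force oracles, kept deliberately naive and separate
# from the package implementations they check.

# BH step-up by definition: adj_i = min_{j >= i} (m * p_(j) / j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  adj
}

# One-sided (greater) Fisher p for a 2x2 table by direct hypergeometric
# summation over at-least-as-extreme tables.
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  hi <- min(m, k)
  sum(vapply(a:hi, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, 0))
}

# Partial correlation of rank-transformed vectors by residual regression.
oracle_partial_spearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::resid(stats::lm(rx ~ rz))
  ey <- stats::resid(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}

# Product-limit survival by looping over risk sets.
oracle_km <- function(times, events) {
  tt <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    d <- sum(times == tt[i] & events == 1)
    r <- sum(times >= tt[i])
    s <- s * (1 - d / r)
    out[i] <- s
  }
  data.frame(time = tt, surv = out)
}

# Unweighted fraction of concordant case/control marker pairs (ties = 1/2)
# at an evaluation time, valid only without censoring.
oracle_auc_nocensor <- function(marker, times, eval_time) {
  case <- which(times <= eval_time)
  ctrl <- which(times > eval_time)
  num <- 0
  for (i in case) for (j in ctrl) {
    num <- num + (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
  }
  num / (length(case) * length(ctrl))
}

# Weibull proportional-hazards event times for a linear predictor.
sim_ph_times <- function(lp, scale = 0.1, shape = 1) {
  u <- stats::runif(length(lp))
  (-log(u) / (scale * exp(lp)))^(1 / shape)
}

# A small aligned trio of uncorrupted call sets around a truth matrix.
make_clean_sets <- function(truth, depth = 30L) {
  d <- matrix(depth, nrow(truth), ncol(truth), dimnames = dimnames(truth))
  list(WXS_NORMAL = source_call_set("WXS_NORMAL", truth, d),
       WXS_TUMOR = source_call_set("WXS_TUMOR", truth, d),
       RNA_TUMOR = source_call_set("RNA_TUMOR", truth, d))
}

# Genotype matrix with dimnames from plain values.
gm <- function(values, n, m) {
  matrix(as.integer(values), n, m,
         dimnames = list(sprintf("pt%05d", seq_len(n)), sprintf("var%04d", seq_len(m))))
}

# One-call synthetic study: annotation, cohort with outcomes, clean call
# sets, merged genotypes and a fully permissive QC table.
make_study <- function(n_patients, cancers, n_variants, variant_effects = numeric(),
                       covariate_effects = c(age = 0.3), censoring = 0.3,
                       af_range = c(0.1, 0.4), seed = 1) {
  variants <- generate_variant_table(n_variants, af_range, seed = seed)
  cohort <- generate_baseline_cohort(
    n_patients, cancers, list(age = list(dist = "normal", mean = 0, sd = 1)),
    seed = seed)
  g <- generate_genotypes(variants, n_patients, seed = seed)
  plan <- effect_plan(variant_effects = variant_effects,
                      covariate_effects = covariate_effects,
                      censoring_rate = censoring)
  cohort <- simulate_outcomes(cohort, g, plan, seed = seed)
  sets <- make_clean_sets(g)
  merged <- merge_calls(sets$WXS_NORMAL, sets$WXS_TUMOR, sets$RNA_TUMOR)
  qc <- qc_filter(merged, sets, variants,
                  qc_thresholds(min_depth = 0, min_population_af = 0,
                                min_carriers = 0, min_concordance_pct = 0),
                  cohort$cancer)
  covars <- stats::setNames(rep(list("age"), length(cancers)), cancers)
  list(variants = variants, cohort = cohort, genotypes = g, merged = merged,
       qc = qc, sets = sets, covariates_per_cancer = covars, plan = plan)
}
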