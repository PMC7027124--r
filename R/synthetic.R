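# Synthetic cohort generator: Hardy-Weinberg genotypes, three corruptible
# per-source call sets with read depths, Weibull proportional-hazards
# outcomes with planted effects, cis-eQTL expression shifts, and planted
# variant/driver-mutation associations. Planted truth is carried alongside
# every output so downstream estimates can be compared to it.

#' Construct an effect plan for a synthetic cohort
#'
#' The effect plan is the ground truth of a simulation: per-variant log
#' hazard ratios, per-covariate log hazard ratios, cis-eQTL expression
#' shifts, variant-driver mutation odds ratios, the Weibull baseline hazard,
#' and the target censoring fraction.
#'
#' @param variant_effects named numeric vector, log hazard ratio per
#'   variant id (additive per alternate-allele copy). Empty by default.
#' @param covariate_effects named numeric vector, log hazard ratio per
#'   covariate column.
#' @param eqtl_effects named list, `variant_id = list(gene_id =, shift =)`
#'   with the shift in within-gene standard-deviation units for carriers.
#' @param driver_assoc named list, `variant_id = list(driver_gene =, or =)`
#'   with a carrier odds ratio for somatic mutation of the driver gene.
#' @param baseline_scale,baseline_shape Weibull baseline hazard
#'   \eqn{h_0(t) = scale \cdot shape \cdot t^{shape-1}}; shape 1 is the
#'   exponential special case.
#' @param censoring_rate target fraction of patients censored, in \[0, 1\].
#' @return an object of class `effect_plan`.
#' @export
effect_plan <- function(variant_effects = numeric(),
                        covariate_effects = numeric(),
                        eqtl_effects = list(),
                        driver_assoc = list(),
                        baseline_scale = 0.1,
                        baseline_shape = 1,
                        censoring_rate = 0.3) {
  stopifnot(censoring_rate >= 0, censoring_rate <= 1,
            baseline_scale > 0, baseline_shape > 0)
  for (d in driver_assoc) {
    if (!is.null(d$or) && d$or <= 0) .stopf("driver odds ratios must be > 0")
  }
  structure(list(variant_effects = variant_effects,
                 covariate_effects = covariate_effects,
                 eqtl_effects = eqtl_effects,
                 driver_assoc = driver_assoc,
                 baseline_scale = baseline_scale,
                 baseline_shape = baseline_shape,
                 censoring_rate = censoring_rate),
            class = "effect_plan")
}

#' Generate a synthetic variant annotation table
#'
#' @param n_variants number of variants.
#' @param af_range population allele-frequency range to draw from
#'   (uniform); frequencies are the alternate-allele population AF.
#' @param frac_high_cadd fraction of variants given a CADD score above 25
#'   (drawn in 25-40); the rest are drawn in 0-25.
#' @param n_genes number of gene ids to assign variants to.
#' @param seed integer seed.
#' @return data.frame with columns variant_id, chrom, pos, ref, alt,
#'   population_af, cadd_score, gene_id, strand.
#' @export
generate_variant_table <- function(n_variants, af_range = c(0.05, 0.5),
                                   frac_high_cadd = 0.1, n_genes = max(10L, ceiling(n_variants / 5)),
                                   seed = 1L) {
  stopifnot(n_variants >= 1)
  set.seed(child_seed(seed, "variants"))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  high <- runif(n_variants) < frac_high_cadd
  data.frame(
    variant_id = sprintf("var%04d", seq_len(n_variants)),
    chrom = sample(paste0("chr", 1:22), n_variants, replace = TRUE),
    pos = sort(sample.int(5e7, n_variants)),
    ref = ref, alt = alt,
    population_af = runif(n_variants, af_range[1], af_range[2]),
    cadd_score = ifelse(high, runif(n_variants, 25.5, 40), runif(n_variants, 0, 24.5)),
    gene_id = sprintf("gene%04d", sample.int(n_genes, n_variants, replace = TRUE)),
    strand = sample(c("+", "-"), n_variants, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate baseline clinical data for a synthetic cohort
#'
#' Draws per-patient covariates independently from the named distributions
#' and assigns cancer codes by the requested proportions. Outcomes are added
#' separately by [simulate_outcomes()].
#'
#' @param n_patients cohort size.
#' @param cancer_codes character vector of cancer codes.
#' @param covariate_spec named list; each element describes one covariate as
#'   `list(dist = "normal", mean =, sd =)`, `list(dist = "uniform", min =,
#'   max =)`, `list(dist = "binary", prob =)`, or `list(dist = "constant",
#'   value =)`.
#' @param cancer_props optional proportions (recycled/normalized); equal by
#'   default.
#' @param seed integer seed.
#' @return data.frame with patient_id, cancer, and one column per covariate.
#' @export
generate_baseline_cohort <- function(n_patients, cancer_codes,
                                     covariate_spec = list(age = list(dist = "normal", mean = 60, sd = 10)),
                                     cancer_props = NULL, seed = 1L) {
  stopifnot(n_patients >= 1, length(cancer_codes) >= 1)
  set.seed(child_seed(seed, "cohort"))
  props <- cancer_props %||% rep(1, length(cancer_codes))
  props <- props / sum(props)
  cancer <- sample(cancer_codes, n_patients, replace = TRUE, prob = props)
  out <- data.frame(patient_id = sprintf("pt%05d", seq_len(n_patients)),
                    cancer = cancer, stringsAsFactors = FALSE)
  for (nm in names(covariate_spec)) {
    sp <- covariate_spec[[nm]]
    out[[nm]] <- switch(sp$dist,
      normal   = stats::rnorm(n_patients, sp$mean %||% 0, sp$sd %||% 1),
      uniform  = stats::runif(n_patients, sp$min %||% 0, sp$max %||% 1),
      binary   = stats::rbinom(n_patients, 1L, sp$prob %||% 0.5),
      constant = rep(sp$value %||% 0, n_patients),
      .stopf("unknown covariate distribution '%s' for covariate '%s'", sp$dist, nm)
    )
  }
  out
}

#' Draw Hardy-Weinberg genotypes at annotated population allele frequencies
#'
#' Each entry is an alternate-allele dosage drawn independently with
#' genotype probabilities \eqn{p^2, 2pq, q^2} where q is the variant's
#' population allele frequency.
#'
#' @param variants annotation data.frame from [generate_variant_table()]
#'   (needs variant_id and population_af).
#' @param n_patients number of patients (rows).
#' @param seed integer seed.
#' @return integer matrix patients x variants of dosages in 0:2.
#' @export
generate_genotypes <- function(variants, n_patients, seed = 1L) {
  q <- variants$population_af
  if (any(q <= 0 | q >= 1)) .stopf("population_af must lie strictly in (0, 1)")
  set.seed(child_seed(seed, "genotypes"))
  m <- length(q)
  # two independent allele draws per patient per variant
  g <- matrix(stats::rbinom(n_patients * m, 2L, rep(q, each = n_patients)),
              nrow = n_patients, ncol = m)
  dimnames(g) <- list(sprintf("pt%05d", seq_len(n_patients)), variants$variant_id)
  g
}

#' Simulate proportional-hazards outcomes with planted effects
#'
#' Event times follow a Weibull proportional-hazards model with linear
#' predictor \eqn{\sum \beta_c x_c + \sum \beta_v d_v} over the plan's
#' covariate and variant effects (dosage-additive). Independent uniform
#' administrative censoring is calibrated by bisection so the realized
#' censoring fraction matches the plan's target in expectation.
#'
#' @param cohort baseline cohort from [generate_baseline_cohort()].
#' @param genotypes dosage matrix aligned to the cohort rows.
#' @param plan an [effect_plan()].
#' @param seed integer seed.
#' @param extra_lp optional additional per-patient linear-predictor term
#'   (used e.g. to make outcome depend on simulated expression).
#' @return the cohort with `time` and `event` columns appended.
#' @export
simulate_outcomes <- function(cohort, genotypes, plan, seed = 1L, extra_lp = NULL) {
  n <- nrow(cohort)
  if (!is.null(genotypes) && nrow(genotypes) != n) .stopf("cohort/genotype dimension mismatch")
  lp <- rep(0, n)
  for (nm in names(plan$covariate_effects)) {
    if (!nm %in% names(cohort)) .stopf("covariate '%s' in plan but not in cohort", nm)
    lp <- lp + plan$covariate_effects[[nm]] * cohort[[nm]]
  }
  for (nm in names(plan$variant_effects)) {
    if (!nm %in% colnames(genotypes)) .stopf("variant '%s' in plan but not in genotypes", nm)
    lp <- lp + plan$variant_effects[[nm]] * genotypes[, nm]
  }
  if (!is.null(extra_lp)) lp <- lp + extra_lp
  set.seed(child_seed(seed, "outcomes"))
  u <- stats::runif(n)
  # inverse-CDF draw: S(t|x) = exp(-scale * t^shape * exp(lp))
  t_event <- (-log(u) / (plan$baseline_scale * exp(lp)))^(1 / plan$baseline_shape)
  if (plan$censoring_rate <= 0) {
    cohort$time <- t_event
    cohort$event <- 1L
    return(cohort)
  }
  cmax <- .calibrate_censoring(t_event, plan$censoring_rate)
  cens <- stats::runif(n, 0, cmax)
  cohort$time <- pmin(t_event, cens)
  cohort$event <- as.integer(t_event <= cens)
  cohort
}

# Bisection on the upper bound of U(0, c) censoring so that the expected
# censored fraction over the realized event times equals the target.
.calibrate_censoring <- function(t_event, target) {
  frac <- function(cmax) mean(pmin(t_event / cmax, 1))  # P(U < T) per patient
  lo <- min(t_event) / 1e6
  hi <- max(t_event) * 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (frac(mid) > target) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) break
  }
  sqrt(lo * hi)
}

#' Corrupt a true genotype matrix into three per-source call sets
#'
#' Emulates the raw inputs of the merge step: a normal-exome, tumor-exome,
#' and tumor-RNA call set, each equal to the truth except that every entry
#' is independently flipped (to a uniformly chosen wrong genotype class)
#' with the per-source discordance probability, plus a per-source read-depth
#' matrix.
#'
#' @param truth true dosage matrix.
#' @param discordance_rate scalar or length-3 vector of per-source flip
#'   probabilities (order WXS_NORMAL, WXS_TUMOR, RNA_TUMOR).
#' @param depth_model list: `dist` one of "poisson" or "constant";
#'   `mean` scalar or length-3 per-source mean (poisson) or `value` for
#'   constant depth.
#' @param seed integer seed.
#' @return named list of three `source_call_set` objects
#'   (WXS_NORMAL, WXS_TUMOR, RNA_TUMOR), each `list(source, genotypes,
#'   depth)`, with the truth attached as attribute `truth`.
#' @export
corrupt_to_call_sets <- function(truth, discordance_rate = 0,
                                 depth_model = list(dist = "poisson", mean = 30),
                                 seed = 1L) {
  .assert_genotype_matrix(truth)
  rate <- rep(discordance_rate, length.out = 3L)
  if (any(rate < 0 | rate > 1)) .stopf("discordance_rate must be in [0, 1]")
  sources <- c("WXS_NORMAL", "WXS_TUMOR", "RNA_TUMOR")
  out <- vector("list", 3L)
  names(out) <- sources
  for (k in 1:3) {
    set.seed(child_seed(seed, paste0("corrupt_", sources[k])))
    g <- truth
    flip <- stats::runif(length(g)) < rate[k] & !is.na(g)
    if (any(flip)) {
      # wrong genotype uniformly among the other two classes
      step <- sample(1:2, sum(flip), replace = TRUE)
      g[flip] <- (g[flip] + step[seq_len(sum(flip))]) %% 3L
    }
    set.seed(child_seed(seed, paste0("depth_", sources[k])))
    dist <- depth_model$dist %||% "poisson"
    depth <- switch(dist,
      poisson = matrix(stats::rpois(length(g), rep(depth_model$mean, length.out = 3L)[k]),
                       nrow = nrow(g)),
      constant = matrix(rep(depth_model$value, length.out = 3L)[k], nrow(g), ncol(g)),
      .stopf("unknown depth model '%s'", dist))
    dimnames(depth) <- dimnames(g)
    out[[k]] <- source_call_set(sources[k], g, depth)
  }
  attr(out, "truth") <- truth
  out
}

#' Construct a per-source call set
#'
#' @param source one of WXS_NORMAL, WXS_TUMOR, RNA_TUMOR.
#' @param genotypes dosage matrix (NA = unknown).
#' @param depth non-negative integer read-depth matrix, same shape.
#' @export
source_call_set <- function(source, genotypes, depth) {
  source <- match.arg(source, c("WXS_NORMAL", "WXS_TUMOR", "RNA_TUMOR"))
  .assert_genotype_matrix(genotypes)
  stopifnot(identical(dim(genotypes), dim(depth)))
  if (any(depth < 0, na.rm = TRUE)) .stopf("depths must be non-negative")
  structure(list(source = source, genotypes = genotypes, depth = depth),
            class = "source_call_set")
}

#' Simulate a gene-by-patient expression matrix with planted cis-eQTLs
#'
#' Baseline expression is standard normal per gene; carriers (dosage >= 1)
#' of a planted eQTL variant have the linked gene shifted by the planted
#' number of standard deviations.
#'
#' @param genotypes dosage matrix.
#' @param plan an [effect_plan()] whose `eqtl_effects` name the planted
#'   (variant, gene, shift) triples.
#' @param n_genes number of genes; gene ids `gene0001...` match
#'   [generate_variant_table()].
#' @param seed integer seed.
#' @return numeric matrix genes x patients.
#' @export
simulate_expression <- function(genotypes, plan, n_genes, seed = 1L) {
  set.seed(child_seed(seed, "expression"))
  n <- nrow(genotypes)
  expr <- matrix(stats::rnorm(n_genes * n), nrow = n_genes, ncol = n,
                 dimnames = list(sprintf("gene%04d", seq_len(n_genes)), rownames(genotypes)))
  for (v in names(plan$eqtl_effects)) {
    eff <- plan$eqtl_effects[[v]]
    if (!v %in% colnames(genotypes)) .stopf("eQTL variant '%s' not in genotypes", v)
    if (!eff$gene_id %in% rownames(expr)) .stopf("eQTL gene '%s' out of range", eff$gene_id)
    carrier <- !is.na(genotypes[, v]) & genotypes[, v] >= 1
    expr[eff$gene_id, carrier] <- expr[eff$gene_id, carrier] + eff$shift
  }
  expr
}

#' Simulate a patient-by-driver-gene somatic mutation table
#'
#' Every patient mutates each driver gene with the background probability;
#' carriers of a planted associated variant have their odds multiplied by
#' the planted odds ratio.
#'
#' @param genotypes dosage matrix.
#' @param plan an [effect_plan()] with `driver_assoc` entries.
#' @param driver_genes character vector of driver gene names.
#' @param background_rate baseline mutation probability per (patient, gene).
#' @param seed integer seed.
#' @return integer 0/1 matrix patients x driver genes.
#' @export
simulate_driver_mutations <- function(genotypes, plan, driver_genes,
                                      background_rate = 0.1, seed = 1L) {
  stopifnot(background_rate >= 0, background_rate <= 1)
  set.seed(child_seed(seed, "drivers"))
  n <- nrow(genotypes)
  pr <- matrix(background_rate, n, length(driver_genes),
               dimnames = list(rownames(genotypes), driver_genes))
  for (v in names(plan$driver_assoc)) {
    d <- plan$driver_assoc[[v]]
    if (!d$driver_gene %in% driver_genes) next
    carrier <- !is.na(genotypes[, v]) & genotypes[, v] >= 1
    odds <- background_rate / (1 - background_rate) * d$or
    pr[carrier, d$driver_gene] <- odds / (1 + odds)
  }
  mut <- matrix(as.integer(stats::runif(length(pr)) < pr), n, length(driver_genes),
                dimnames = dimnames(pr))
  mut
}
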