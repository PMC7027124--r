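# Statistical kernel: Kaplan-Meier, Cox partial-likelihood fitting (Efron
# ties by default), Lasso-based clinical covariate selection, BH false
# discovery control, the scan-wide significance level, and survival power.

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @return data.frame with columns time, n_risk, n_event, surv; the
#'   right-continuous step function starts at S(0) = 1.
#' @export
km_estimate <- function(times, events) {
  stopifnot(all(times >= 0), length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

# Fast Cox core over a plain design matrix, used by the scans. Returns
# coefficients, standard errors, Wald p-values and a convergence flag.
.cox_core <- function(x, times, events, ties = "efron") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  keep <- stats::complete.cases(x) & !is.na(times) & !is.na(events)
  x <- x[keep, , drop = FALSE]
  times <- times[keep]; events <- events[keep]
  n <- nrow(x)
  if (n == 0L || sum(events) == 0L) .stopf("Cox fit requires at least one event")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) .stopf("constant column(s) in Cox design: %s",
                            paste(colnames(x)[sds == 0], collapse = ", "))
  fit <- tryCatch(suppressWarnings(
    survival::coxph.fit(x, survival::Surv(times, events), strata = NULL,
                        offset = NULL, init = NULL,
                        control = survival::coxph.control(),
                        weights = NULL, method = ties, rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) {
    return(list(coef = rep(NA_real_, ncol(x)), se = rep(NA_real_, ncol(x)),
                p = rep(NA_real_, ncol(x)), n = n, n_events = sum(events),
                converged = FALSE))
  }
  beta <- fit$coefficients
  se <- sqrt(diag(as.matrix(fit$var)))
  # monotone-likelihood / separation heuristics: runaway coefficients or
  # exploding variance mean the Wald statistic is meaningless
  converged <- all(is.finite(beta)) && all(is.finite(se)) &&
    all(abs(beta) < 15) && all(se < 50)
  p <- 2 * stats::pnorm(-abs(beta / se))
  list(coef = beta, se = se, p = p, n = n, n_events = sum(events),
       converged = converged)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the partial likelihood over a numeric design matrix and reports
#' per-term Wald statistics. Fits showing signs of monotone likelihood
#' (separation) are flagged as non-converged rather than reported.
#'
#' @param design numeric matrix or data.frame of covariates (no constant
#'   columns).
#' @param times,events follow-up times and 0/1 event indicators.
#' @param ties "efron" (default) or "breslow".
#' @return a `cox_result` data.frame: term, log_hr, se, hr, p, n, n_events,
#'   converged.
#' @export
cox_fit <- function(design, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  design <- as.matrix(design)
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(ncol(design)))
  core <- .cox_core(design, times, events, ties)
  structure(data.frame(term = colnames(design), log_hr = core$coef, se = core$se,
                       hr = exp(core$coef), p = core$p, n = core$n,
                       n_events = core$n_events, converged = core$converged,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("cox_result", "data.frame"))
}

#' Select prognostic clinical covariates by L1-penalized Cox regression
#'
#' Fits the Lasso path for a Cox model over the candidate covariates and
#' keeps those with nonzero coefficients at the largest penalty whose
#' cross-validated partial-likelihood deviance is within one standard error
#' of the minimum (the parsimonious standard choice; the bare minimum-
#' deviance penalty admits too many null covariates to serve covariate
#' selection).
#'
#' @param covariates data.frame/matrix of candidate covariates.
#' @param times,events outcome.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @return character vector of selected covariate names (possibly empty).
#' @export
lasso_select_covariates <- function(covariates, times, events, cv_folds = 10, seed = 1L) {
  x <- as.matrix(covariates)
  keep <- stats::complete.cases(x) & !is.na(times) & !is.na(events)
  x <- x[keep, , drop = FALSE]; times <- times[keep]; events <- events[keep]
  if (ncol(x) < 2L) {
    # glmnet needs >= 2 columns; test the lone candidate directly
    fit <- cox_fit(x, times, events)
    return(if (fit$converged[1] && fit$p[1] < 0.05) colnames(x) else character())
  }
  set.seed(child_seed(seed, "lasso_folds"))
  foldid <- sample(rep_len(seq_len(cv_folds), nrow(x)))
  cv <- glmnet::cv.glmnet(x, survival::Surv(times, events), family = "cox",
                          foldid = foldid, nlambda = 100)
  beta <- as.matrix(stats::coef(cv, s = "lambda.1se"))
  rownames(beta)[beta[, 1] != 0]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Scan-wide significance level for the power analysis
#'
#' The power analysis evaluates detection at a Bonferroni-style level of
#' 0.10 divided by the number of variants tested in the cancer, a threshold
#' as stringent or slightly more stringent than BH control at 0.10.
#'
#' @param n_tested number of variants tested.
#' @return significance level.
#' @export
scan_alpha <- function(n_tested) {
  stopifnot(n_tested >= 1)
  0.10 / n_tested
}

#' Analytic power of a two-sided Cox test of a binary exposure
#'
#' Schoenfeld's formula with variance inflation for correlated covariates:
#' \deqn{power = \Phi(|\ln hr| \sqrt{D\, p (1-p) (1-R^2)} - z_{1-\alpha/2})}
#' with D = n * event_rate expected events and p the exposed fraction.
#'
#' @param n sample size.
#' @param event_rate expected fraction of patients with an event.
#' @param exposed_fraction fraction carrying the exposure, in (0, 1).
#' @param hr hazard ratio to detect.
#' @param alpha two-sided significance level.
#' @param r2_other_covariates squared multiple correlation of the exposure
#'   with the other model covariates (0 = uncorrelated).
#' @return power in \[0, 1\].
#' @export
cox_power <- function(n, event_rate, exposed_fraction, hr, alpha = 0.05,
                      r2_other_covariates = 0) {
  if (any(event_rate < 0 | event_rate > 1) || any(exposed_fraction <= 0) ||
      any(exposed_fraction >= 1) || r2_other_covariates < 0 ||
      r2_other_covariates >= 1 || alpha <= 0 || alpha >= 1 || any(hr <= 0)) {
    .stopf("invalid power-analysis arguments")
  }
  d <- n * event_rate
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(abs(log(hr)) *
                 sqrt(d * exposed_fraction * (1 - exposed_fraction) *
                        (1 - r2_other_covariates)) - z)
}
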