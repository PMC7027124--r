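# Internal helpers shared across modules.

#' Derive a child random seed from a master seed and a stream name
#'
#' All stochastic generators in the package draw their seed from a master
#' seed through a named stream, so adding a new generator to a pipeline never
#' perturbs the draws of existing ones. The derivation is a small string hash
#' folded into the master seed, kept inside the 32-bit signed integer range.
#'
#' @param seed master seed (integer).
#' @param stream character stream name.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_genotype_matrix <- function(g) {
  stopifnot(is.matrix(g))
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype matrix entries must be 0, 1, 2 or NA (unknown)")
  }
  invisible(g)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
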