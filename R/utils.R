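#' Derive an independent RNG substream seed
#'
#' Every stochastic stage of the package derives its own seed from a master
#' seed and a stream index, so stages (and resampling replicates) are
#' individually reproducible and mutually independent. The derivation is a
#' fixed multiplicative hash kept inside the 32-bit signed integer range.
#'
#' @param seed Master seed (integer).
#' @param stream Non-negative stream index.
#' @return An integer seed usable with [set.seed()].
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(as.double(seed)) %% m)
  # two rounds of a Lehmer-style mix so adjacent streams decorrelate
  s <- (s * 48271 + as.double(stream) * 16807 + 1) %% m
  s <- (s * 48271 + 12345) %% m
  as.integer(s)
}

# run `code` under a temporary seed without disturbing the caller's RNG state
with_stream_seed <- function(seed, stream, code) {
  withr::with_seed(derive_seed(seed, stream), code)
}

stop_pcitr <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pcitr_error"))
}

# clamped log-likelihood epsilon (documented contract: probabilities are
# clamped to [eps, 1 - eps] before taking logs)
PCIT_EPS <- 1e-12

logistic <- function(x) plogis(x)

# numerically safe fractional-Bernoulli log-likelihood contributions
frac_bernoulli_ll <- function(y, p) {
  p <- pmin(pmax(p, PCIT_EPS), 1 - PCIT_EPS)
  y * log(p) + (1 - y) * log(1 - p)
}

# log-sum-exp for normalizing importance weights
log_sum_exp <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lw - m)))
}

# weighted quantile, type-1 step interpolation on the weight CDF
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord])
  cw <- cw / cw[length(cw)]
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}
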