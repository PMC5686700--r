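#' Plug-in (maximum likelihood) entropy of a count table
#'
#' Computes \eqn{-\sum_i p_i \log_2 p_i} with \eqn{p_i = n_i/n}. Empty bins
#' contribute nothing. Used as the bias-uncorrected reference against the
#' Bayesian estimator and for exact chain-rule identities.
#'
#' @param counts nonnegative integer vector of bin counts.
#' @return entropy in bits.
#' @export
plugin_entropy <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

## Map from the Dirichlet concentration parameter beta to the prior expected
## entropy xi(beta) = psi(K*beta + 1) - psi(beta + 1), in nats.
.nsb_xi <- function(beta, K) digamma(K * beta + 1) - digamma(beta + 1)

## Invert xi -> beta on a log-spaced grid by monotone interpolation.
## xi is strictly increasing in beta from 0 to log(K).
.nsb_beta_of_xi <- function(xi, K) {
  log_beta <- seq(log(1e-8), log(1e8), length.out = 4000)
  xig <- .nsb_xi(exp(log_beta), K)
  ok <- !duplicated(xig)
  exp(stats::approx(xig[ok], log_beta[ok], xout = xi, rule = 2)$y)
}

## Log evidence of the counts under a symmetric Dirichlet(beta) prior,
## up to a beta-independent constant. Bins with zero counts cancel.
.nsb_log_evidence <- function(beta, counts_nz, n, K) {
  lgamma(K * beta) - lgamma(n + K * beta) +
    sum(lgamma(counts_nz + beta)) - length(counts_nz) * lgamma(beta)
}

## First and second posterior moments of the entropy (nats) under a
## Dirichlet posterior with parameters lambda (given as unique values `lam`
## with multiplicities `mult`), following the closed forms of Wolpert & Wolf.
.dirichlet_entropy_moments <- function(lam, mult, L0) {
  m1 <- digamma(L0 + 1) - sum(mult * lam * digamma(lam + 1)) / L0

  psiL2 <- digamma(L0 + 2)
  tpsiL2 <- trigamma(L0 + 2)
  J <- (digamma(lam + 2) - psiL2)^2 + trigamma(lam + 2) - tpsiL2
  t1 <- sum(mult * lam * (lam + 1) * J)
  u <- digamma(lam + 1) - psiL2
  A <- sum(mult * lam * u)
  B <- sum(mult * lam^2 * u^2)
  S2 <- sum(mult * lam^2)
  cross <- A^2 - B - tpsiL2 * (L0^2 - S2)
  m2 <- (t1 + cross) / (L0 * (L0 + 1))
  c(m1, m2)
}

#' NSB Bayesian entropy estimate of a discrete count table
#'
#' Posterior mean and standard deviation of the Shannon entropy under the
#' Nemenman-Shafee-Bialek prior: a mixture of symmetric Dirichlet priors
#' whose mixing density is flat in the prior expected entropy, so that the
#' estimate is close to unbiased over a wide range of true entropies even
#' when the sample undersamples the alphabet. The mixture is integrated
#' numerically on a grid over the prior expected entropy
#' \eqn{\xi \in (0, \log K)}, with log-weights stabilised by subtracting
#' their maximum.
#'
#' @param counts nonnegative integer vector of observed bin counts. Bins that
#'   were never observed must still be present (as zeros) or accounted for
#'   via `alphabet_size`.
#' @param alphabet_size total number of bins K of the discretisation
#'   (defaults to `length(counts)`; may exceed it, the difference is treated
#'   as extra empty bins).
#' @param n_grid number of integration nodes over the prior expected entropy.
#' @return list with `entropy` (posterior mean, bits) and `sd` (posterior
#'   standard deviation, bits).
#' @export
nsb_entropy <- function(counts, alphabet_size = length(counts), n_grid = 1000) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite nonnegative integers")
  K <- alphabet_size
  if (K < length(counts)) stop("alphabet_size smaller than the count vector")
  n <- sum(counts)
  if (n < 1) stop("empty sample: no observations to estimate entropy from")
  if (K == 1) return(list(entropy = 0, sd = 0))

  counts_nz <- counts[counts > 0]
  ## compress equal counts; zero bins enter only through K
  tab <- table(counts_nz)
  vals <- as.numeric(names(tab))
  mults <- as.numeric(tab)
  n_zero <- K - length(counts_nz)

  xi <- (seq_len(n_grid) - 0.5) / n_grid * log(K)
  beta <- .nsb_beta_of_xi(xi, K)

  logw <- vapply(beta, .nsb_log_evidence, numeric(1),
                 counts_nz = counts_nz, n = n, K = K)
  w <- exp(logw - max(logw))
  w <- w / sum(w)

  mom <- vapply(beta, function(b) {
    lam <- c(vals + b, if (n_zero > 0) b)
    mult <- c(mults, if (n_zero > 0) n_zero)
    .dirichlet_entropy_moments(lam, mult, n + K * b)
  }, numeric(2))

  m1 <- sum(w * mom[1, ])
  m2 <- sum(w * mom[2, ])
  v <- max(m2 - m1^2, 0)
  list(entropy = m1 / log(2), sd = sqrt(v) / log(2))
}
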