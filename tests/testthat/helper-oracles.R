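# Independent oracles, coded separately from the package implementations.

# --- NSB oracle: adaptive quadrature over the Dirichlet concentration ------
# Integrates over beta directly (not the entropy reparameterisation used by
# the package), weighting by the flat-in-expected-entropy prior density
# d xi / d beta, with plain O(K^2) double-sum moment formulas.

oracle_dirichlet_moments <- function(lambda) {
  L0 <- sum(lambda)
  m1 <- digamma(L0 + 1) - sum(lambda / L0 * digamma(lambda + 1))
  K <- length(lambda)
  m2 <- 0
  for (i in seq_len(K)) {
    Ji <- (digamma(lambda[i] + 2) - digamma(L0 + 2))^2 +
      trigamma(lambda[i] + 2) - trigamma(L0 + 2)
    m2 <- m2 + lambda[i] * (lambda[i] + 1) / (L0 * (L0 + 1)) * Ji
    for (j in seq_len(K)) {
      if (i == j) next
      Iij <- (digamma(lambda[i] + 1) - digamma(L0 + 2)) *
        (digamma(lambda[j] + 1) - digamma(L0 + 2)) - trigamma(L0 + 2)
      m2 <- m2 + lambda[i] * lambda[j] / (L0 * (L0 + 1)) * Iij
    }
  }
  c(m1 = m1, m2 = m2)
}

oracle_nsb <- function(counts, K = length(counts)) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (K == 1) return(list(entropy = 0, sd = 0))
  full <- c(counts, rep(0, K - length(counts)))
  log_ev <- function(beta)
    lgamma(K * beta) - lgamma(n + K * beta) +
      sum(lgamma(full + beta)) - K * lgamma(beta)
  prior <- function(beta) K * trigamma(K * beta + 1) - trigamma(beta + 1)
  # locate the evidence maximum on a log grid for stable normalisation
  bg <- exp(seq(log(1e-7), log(1e7), length.out = 400))
  lev <- vapply(bg, log_ev, numeric(1))
  c0 <- max(lev)
  integrand <- function(b, fun) {
    vapply(b, function(bb) {
      w <- exp(log_ev(bb) - c0) * prior(bb)
      if (!is.finite(w) || w == 0) return(0)
      w * fun(bb)
    }, numeric(1))
  }
  # split the infinite range for robustness
  quad <- function(fun) {
    stats::integrate(integrand, 0, 1, fun = fun, rel.tol = 1e-10,
                     subdivisions = 500L)$value +
      stats::integrate(integrand, 1, Inf, fun = fun, rel.tol = 1e-10,
                       subdivisions = 500L)$value
  }
  z <- quad(function(b) 1)
  m1 <- quad(function(b) oracle_dirichlet_moments(full + b)[1]) / z
  m2 <- quad(function(b) oracle_dirichlet_moments(full + b)[2]) / z
  list(entropy = m1 / log(2), sd = sqrt(max(m2 - m1^2, 0)) / log(2))
}

# --- plug-in information quantities on discretised data ---------------------

oracle_plugin_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  hx <- plugin_entropy(rowSums(tab))
  hy <- plugin_entropy(colSums(tab))
  hxy <- plugin_entropy(as.vector(tab))
  hx + hy - hxy
}

# --- exhaustive matching oracle for the tracker -----------------------------
# Enumerates every injective partial matching between frames a and b and
# returns the best score under the exponential-distance likelihood.

oracle_best_matching <- function(a, b, lambda, penalty) {
  D <- as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                           nrow(a) + seq_len(nrow(b)), drop = FALSE]
  nA <- nrow(a); nB <- nrow(b)
  best <- -Inf
  rec <- function(i, usedB, score, nmatch) {
    if (i > nA) {
      tot <- score - penalty * ((nA - nmatch) + (nB - nmatch))
      if (tot > best) best <<- tot
      return(invisible())
    }
    rec(i + 1, usedB, score, nmatch)          # leave i unmatched
    for (j in seq_len(nB)) {
      if (!usedB[j]) {
        usedB[j] <- TRUE
        rec(i + 1, usedB, score - D[i, j] / lambda, nmatch + 1)
        usedB[j] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, nB), 0, 0)
  best
}
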