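#' @title Mutual-information estimates between stimulus and single-cell responses
#' @description
#' All estimators work on a data frame with one row per cell: a categorical
#' stimulus column (e.g. GnRH concentration) and one to three numeric response
#' columns. Responses are discretised on a pooled alphabet (see
#' [bin_spec()]) and entropies are estimated with the NSB Bayesian estimator
#' ([nsb_entropy()]), giving every information quantity a posterior standard
#' deviation. Quantities are reported in bits and are not clamped at zero:
#' estimator noise can make a true-zero MI slightly negative, and clamping
#' would bias averages across simulation sweeps.
#' @name mi-estimation
NULL

.mi_estimate <- function(value, sd, n, bins, components, method) {
  structure(list(value = value, sd = sd, n = n, bins = bins,
                 components = components, method = method),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f bits (posterior sd %.4f, n = %d, bins = %s)\n",
              x$method, x$value, x$sd, x$n,
              paste(x$bins, collapse = "x")))
  invisible(x)
}

.check_sample <- function(data, stimulus, responses) {
  stopifnot(is.data.frame(data), stimulus %in% names(data),
            all(responses %in% names(data)))
  s <- as.character(data[[stimulus]])
  if (anyNA(s)) stop("missing stimulus labels")
  for (r in responses) {
    bad <- which(!is.finite(data[[r]]))
    if (length(bad) > 0)
      stop("non-finite response '", r, "' at record(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  levels_s <- unique(s)
  list(s = s, levels = levels_s)
}

## Discretise response columns on the pooled range; returns flattened
## 0-based symbols and the product alphabet size.
.pooled_symbols <- function(data, responses, n_bins) {
  n_bins <- rep_len(n_bins, length(responses))
  idx <- vector("list", length(responses))
  for (d in seq_along(responses)) {
    idx[[d]] <- discretize(data[[responses[d]]], bin_spec(n_bins = n_bins[d]))
  }
  list(sym = .joint_index(idx, n_bins), K = prod(n_bins), bins = n_bins)
}

## H(Z) and H(Z|S) with NSB on a shared alphabet; sds combined in quadrature.
.entropy_decomposition <- function(sym, K, s, levels_s) {
  hz <- nsb_entropy(.count_table(sym, K), K)
  n <- length(sym)
  hz_s <- 0; var_s <- 0
  for (lev in levels_s) {
    sel <- s == lev
    ns <- sum(sel)
    if (ns == 0) stop("stimulus level with zero records: ", lev)
    h <- nsb_entropy(.count_table(sym[sel], K), K)
    w <- ns / n
    hz_s <- hz_s + w * h$entropy
    var_s <- var_s + (w * h$sd)^2
  }
  list(hz = hz$entropy, hz_sd = hz$sd, hzs = hz_s, hzs_sd = sqrt(var_s))
}

#' Conditional entropy H(Z|S) of a response given the stimulus
#'
#' Weighted average \eqn{\sum_s (n_s/n) H_{NSB}(Z | S=s)} with all levels
#' binned on the pooled alphabet; the posterior sd is combined in quadrature
#' across levels.
#'
#' @param data data frame of per-cell records.
#' @param stimulus name of the categorical stimulus column.
#' @param response name of the numeric response column.
#' @param n_bins bins for the response alphabet.
#' @return list with `value` and `sd` in bits.
#' @export
conditional_entropy <- function(data, stimulus = "stimulus", response = "z1",
                                n_bins = 30) {
  chk <- .check_sample(data, stimulus, response)
  ps <- .pooled_symbols(data, response, n_bins)
  dec <- .entropy_decomposition(ps$sym, ps$K, chk$s, chk$levels)
  list(value = dec$hzs, sd = dec$hzs_sd)
}

.mi_core <- function(data, stimulus, responses, n_bins, method) {
  chk <- .check_sample(data, stimulus, responses)
  if (length(chk$levels) < 2)
    stop("MI requires at least 2 distinct stimulus levels")
  ps <- .pooled_symbols(data, responses, n_bins)
  dec <- .entropy_decomposition(ps$sym, ps$K, chk$s, chk$levels)
  .mi_estimate(value = dec$hz - dec$hzs,
               sd = sqrt(dec$hz_sd^2 + dec$hzs_sd^2),
               n = nrow(data), bins = ps$bins,
               components = list(H_Z = dec$hz, H_Z_sd = dec$hz_sd,
                                 H_Z_given_S = dec$hzs,
                                 H_Z_given_S_sd = dec$hzs_sd),
               method = method)
}

#' Mutual information I(Z;S) between stimulus and a scalar response
#'
#' \eqn{I(Z;S) = H(Z) - H(Z|S)} with NSB entropies on a shared 30-bin
#' (by default) alphabet over the pooled observed range.
#'
#' @inheritParams conditional_entropy
#' @return an object of class `mi_estimate`.
#' @export
mutual_information <- function(data, stimulus = "stimulus", response = "z1",
                               n_bins = 30) {
  stopifnot(length(response) == 1)
  .mi_core(data, stimulus, response, n_bins, "I(Z;S)")
}

#' Joint mutual information between stimulus and a 2-D response vector
#'
#' Each response dimension is discretised separately; the joint alphabet is
#' the Cartesian product (default 30 x 30) and the MI of the product symbol
#' against the stimulus is estimated. Note that at typical cohort sizes
#' (~10^3 cells per level) a 30 x 30 alphabet is sparsely sampled; the NSB
#' estimator is designed for this regime but per-dimension bins can be
#' lowered via `n_bins`.
#'
#' @inheritParams conditional_entropy
#' @param responses names of the two response columns.
#' @param n_bins bins per dimension (scalar or length 2).
#' @export
joint_mi <- function(data, stimulus = "stimulus", responses = c("z1", "z2"),
                     n_bins = 30) {
  stopifnot(length(responses) == 2)
  .mi_core(data, stimulus, responses, n_bins, "I(Z1,Z2;S)")
}

#' Trajectory mutual information (three time points) against the stimulus
#'
#' The response trajectory is represented by the response at three time
#' points and treated as a 3-D vector on a product alphabet. With the
#' default 30 bins per dimension the 27000-cell alphabet is very sparse at
#' n ~ 10^3; consider `n_bins = 8` for trajectory estimates on small cohorts.
#'
#' @inheritParams joint_mi
#' @param responses names of the three response columns (one per time point).
#' @export
trajectory_mi <- function(data, stimulus = "stimulus",
                          responses = c("z1", "z2", "z3"), n_bins = 30) {
  stopifnot(length(responses) == 3)
  .mi_core(data, stimulus, responses, n_bins, "I(Z(t1,t2,t3);S)")
}

#' Mutual information between two responses (no stimulus conditioning)
#'
#' \eqn{I(Z_1;Z_2) = H(Z_1) + H(Z_2) - H(Z_1,Z_2)} with NSB entropies,
#' pooling all records; used e.g. for the MI between pulse-1 and pulse-2
#' responses across a cohort.
#'
#' @inheritParams joint_mi
#' @export
mi_between <- function(data, responses = c("z1", "z2"), n_bins = 30) {
  stopifnot(length(responses) == 2)
  for (r in responses) {
    if (any(!is.finite(data[[r]]))) stop("non-finite response '", r, "'")
  }
  n_bins <- rep_len(n_bins, 2)
  i1 <- discretize(data[[responses[1]]], bin_spec(n_bins[1]))
  i2 <- discretize(data[[responses[2]]], bin_spec(n_bins[2]))
  h1 <- nsb_entropy(.count_table(i1, n_bins[1]), n_bins[1])
  h2 <- nsb_entropy(.count_table(i2, n_bins[2]), n_bins[2])
  h12 <- nsb_entropy(.count_table(.joint_index(list(i1, i2), n_bins),
                                  prod(n_bins)), prod(n_bins))
  .mi_estimate(value = h1$entropy + h2$entropy - h12$entropy,
               sd = sqrt(h1$sd^2 + h2$sd^2 + h12$sd^2),
               n = nrow(data), bins = n_bins,
               components = list(H_Z1 = h1$entropy, H_Z2 = h2$entropy,
                                 H_Z1Z2 = h12$entropy),
               method = "I(Z1;Z2)")
}

#' Conditional mutual information I(Z1;Z2|S)
#'
#' \eqn{\sum_s (n_s/n) I(Z_1;Z_2 | S=s)}, each conditional MI computed from
#' NSB entropies on alphabets shared across levels (pooled ranges).
#'
#' @inheritParams joint_mi
#' @export
conditional_mi <- function(data, stimulus = "stimulus",
                           responses = c("z1", "z2"), n_bins = 30) {
  stopifnot(length(responses) == 2)
  chk <- .check_sample(data, stimulus, responses)
  n_bins <- rep_len(n_bins, 2)
  i1 <- discretize(data[[responses[1]]], bin_spec(n_bins[1]))
  i2 <- discretize(data[[responses[2]]], bin_spec(n_bins[2]))
  i12 <- .joint_index(list(i1, i2), n_bins)
  n <- nrow(data)
  val <- 0; var_tot <- 0
  for (lev in chk$levels) {
    sel <- chk$s == lev
    ns <- sum(sel)
    if (ns == 0) stop("stimulus level with zero records: ", lev)
    h1 <- nsb_entropy(.count_table(i1[sel], n_bins[1]), n_bins[1])
    h2 <- nsb_entropy(.count_table(i2[sel], n_bins[2]), n_bins[2])
    h12 <- nsb_entropy(.count_table(i12[sel], prod(n_bins)), prod(n_bins))
    w <- ns / n
    val <- val + w * (h1$entropy + h2$entropy - h12$entropy)
    var_tot <- var_tot + w^2 * (h1$sd^2 + h2$sd^2 + h12$sd^2)
  }
  .mi_estimate(value = val, sd = sqrt(var_tot), n = n, bins = n_bins,
               components = NULL, method = "I(Z1;Z2|S)")
}

#' Additional information carried by a second response beyond a first
#'
#' The information a second-pulse response adds about the stimulus given the
#' first-pulse response, via the chain-rule identity
#' \deqn{I(Z_2;S|Z_1) = I(Z_2;S) - I(Z_1;Z_2) + I(Z_1;Z_2|S).}
#' When the second response is an exact copy of the first this is zero (the
#' second pulse is fully predicted); when the first response is independent
#' of both the second and the stimulus it reduces to \eqn{I(Z_2;S)}.
#'
#' @inheritParams joint_mi
#' @param responses names of the first- and second-pulse response columns,
#'   in that order (`c(z1, z2)`).
#' @return an `mi_estimate`; `components` holds the three constituent terms.
#' @export
additional_information <- function(data, stimulus = "stimulus",
                                   responses = c("z1", "z2"), n_bins = 30) {
  stopifnot(length(responses) == 2)
  i_z2_s <- mutual_information(data, stimulus, responses[2], n_bins)
  i_z1_z2 <- mi_between(data, responses, n_bins)
  i_z1_z2_s <- conditional_mi(data, stimulus, responses, n_bins)
  .mi_estimate(value = i_z2_s$value - i_z1_z2$value + i_z1_z2_s$value,
               sd = sqrt(i_z2_s$sd^2 + i_z1_z2$sd^2 + i_z1_z2_s$sd^2),
               n = nrow(data), bins = rep_len(n_bins, 2),
               components = list(I_Z2_S = i_z2_s$value,
                                 I_Z1_Z2 = i_z1_z2$value,
                                 I_Z1_Z2_given_S = i_z1_z2_s$value),
               method = "I(Z2;S|Z1)")
}
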