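#' Binning specification for response discretisation
#'
#' Responses are discretised into `n_bins` bins before entropy estimation.
#' The default, matching standard practice for single-cell information
#' estimates, is 30 equal-width bins over the pooled observed range
#' (minimum to maximum across all stimulus levels), so that conditional and
#' unconditional entropies share one alphabet. An equal-count (quantile)
#' strategy is available as an option.
#'
#' @param n_bins number of bins (per response dimension).
#' @param strategy "equal-width" (default) or "equal-count".
#' @param range optional fixed `c(lo, hi)`; `NULL` means pooled observed
#'   range. Values outside a fixed range are clamped into the edge bins.
#' @return an object of class `bin_spec`.
#' @export
bin_spec <- function(n_bins = 30, strategy = c("equal-width", "equal-count"),
                     range = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n_bins >= 1, n_bins == round(n_bins))
  if (!is.null(range)) {
    stopifnot(length(range) == 2, is.finite(range), range[1] < range[2])
  }
  structure(list(n_bins = as.integer(n_bins), strategy = strategy,
                 range = range), class = "bin_spec")
}

#' Discretise real values into bin indices
#'
#' Equal-width bins are half-open `[e_i, e_{i+1})` with the top bin closed,
#' so a value exactly on an interior edge goes to the upper bin and the
#' global maximum joins the top bin. A degenerate zero-range input (all
#' values identical) collapses to a single bin: every index is 0 and the
#' downstream entropy is exactly zero, rather than an error, so constant
#' (information-free) responses pass through pipelines.
#'
#' @param values numeric vector, all finite.
#' @param spec a [bin_spec()], or a bin count for convenience.
#' @return integer vector of 0-based bin indices in `[0, n_bins)`.
#' @export
discretize <- function(values, spec = bin_spec()) {
  if (is.numeric(spec) && length(spec) == 1) spec <- bin_spec(n_bins = spec)
  if (length(values) == 0) stop("no values to discretise")
  bad <- which(!is.finite(values))
  if (length(bad) > 0)
    stop("non-finite response value at record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  K <- spec$n_bins
  if (spec$strategy == "equal-count") {
    edges <- unique(stats::quantile(values, probs = seq(0, 1, length.out = K + 1),
                                    names = FALSE))
    if (length(edges) < 2) return(rep(0L, length(values)))
    idx <- findInterval(values, edges, rightmost.closed = TRUE,
                        all.inside = TRUE) - 1L
    return(idx)
  }
  rng <- if (is.null(spec$range)) range(values) else spec$range
  lo <- rng[1]; hi <- rng[2]
  if (hi <= lo) return(rep(0L, length(values)))
  w <- (hi - lo) / K
  idx <- floor((values - lo) / w)
  idx[values >= hi] <- K - 1
  idx <- pmin(pmax(idx, 0), K - 1)
  as.integer(idx)
}

## bin counts on an alphabet of size K from 0-based indices
.count_table <- function(idx, K) tabulate(idx + 1L, nbins = K)

## flatten several 0-based index vectors to a product-alphabet symbol
.joint_index <- function(idx_list, K_vec) {
  sym <- idx_list[[1]]
  if (length(idx_list) > 1) {
    for (d in 2:length(idx_list)) sym <- sym * K_vec[d] + idx_list[[d]]
  }
  sym
}
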