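#' @title Cell tracking by MCMC nucleus matching
#' @description
#' Frame-to-frame matching of nucleus centroids: candidate pairings are
#' scored by a likelihood that decays exponentially with Euclidean distance,
#' unmatched centroids pay a fixed log-likelihood penalty (allowing cells to
#' enter or leave the field), and the most likely injective partial matching
#' is found by Metropolis Markov chain Monte Carlo over matchings, keeping
#' the best state visited (MAP). Chained pairwise matchings link per-cell
#' tracks through a time stack.
#' @name cell-tracking
NULL

#' Tracker parameters
#'
#' @param lambda_px exponential distance scale, pixels; `NULL` (default)
#'   self-scales to twice the median nearest-neighbour displacement between
#'   the two frames.
#' @param unmatched_penalty log-likelihood cost per unmatched centroid
#'   (default 3: leaving two centroids unmatched costs as much as matching
#'   them at distance 6 lambda).
#' @param n_iterations Metropolis steps per frame pair.
#' @param seed RNG seed (matching is deterministic given the seed).
#' @param p_add,p_remove,p_swap proposal mix.
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(lambda_px = NULL, unmatched_penalty = 3,
                            n_iterations = 10000, seed = 1,
                            p_add = 0.4, p_remove = 0.2, p_swap = 0.4) {
  stopifnot(is.null(lambda_px) || lambda_px > 0, n_iterations >= 1,
            unmatched_penalty >= 0,
            abs(p_add + p_remove + p_swap - 1) < 1e-9)
  structure(list(lambda_px = lambda_px, unmatched_penalty = unmatched_penalty,
                 n_iterations = as.integer(n_iterations), seed = seed,
                 p_add = p_add, p_remove = p_remove, p_swap = p_swap),
            class = "tracking_params")
}

.frame_xy <- function(frame) {
  if (is.matrix(frame)) return(frame)
  as.matrix(frame[, c("x", "y"), drop = FALSE])
}

## score of a matching: sum of -d/lambda over matched pairs minus the
## penalty per unmatched centroid on either side
.matching_score <- function(m, D, lambda, penalty) {
  matched <- which(m > 0L)
  nB <- ncol(D)
  -sum(D[cbind(matched, m[matched])]) / lambda -
    penalty * ((length(m) - length(matched)) + (nB - length(matched)))
}

#' Match nucleus centroids between two frames
#'
#' Metropolis MCMC over injective partial matchings with add/remove/swap
#' proposals, greedy nearest-neighbour initialisation, and best-state
#' tracking. The returned matching is the best (maximum a posteriori) state
#' visited.
#'
#' @param a,b frames: matrices or data frames with columns `x`, `y`
#'   (pixels).
#' @param params a [tracking_params()].
#' @param record_trace store the best score after every iteration (for
#'   diagnostics).
#' @return list of class `matching`: `pairs` (data frame `a`, `b`, `dist`),
#'   `m` (for each A index, the matched B index or 0), `score`,
#'   `lambda_px`, and optionally `best_trace`.
#' @export
match_pair <- function(a, b, params = tracking_params(),
                       record_trace = FALSE) {
  A <- .frame_xy(a); B <- .frame_xy(b)
  nA <- nrow(A); nB <- nrow(B)
  stopifnot(nA >= 1, nB >= 1)
  D <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
  lambda <- params$lambda_px
  if (is.null(lambda)) {
    nn <- apply(D, 1, min)
    lambda <- max(2 * stats::median(nn), 1e-3)
  }
  pen <- params$unmatched_penalty
  set.seed(params$seed)

  # greedy nearest-neighbour initialisation: accept matches that beat
  # leaving both centroids unmatched
  m <- integer(nA)
  usedB <- logical(nB)
  ord <- order(D)
  for (k in ord) {
    i <- (k - 1L) %% nA + 1L
    j <- (k - 1L) %/% nA + 1L
    if (m[i] == 0L && !usedB[j] && D[i, j] / lambda < 2 * pen) {
      m[i] <- j; usedB[j] <- TRUE
    }
  }

  score <- .matching_score(m, D, lambda, pen)
  best_m <- m; best_score <- score
  n_it <- params$n_iterations
  trace <- if (record_trace) numeric(n_it) else NULL
  thr <- c(params$p_add, params$p_add + params$p_remove)
  u_move <- stats::runif(n_it)
  u_acc <- log(stats::runif(n_it))

  for (it in seq_len(n_it)) {
    if (u_move[it] < thr[1]) {           # add
      free_a <- which(m == 0L)
      free_b <- which(!usedB)
      if (length(free_a) > 0 && length(free_b) > 0) {
        i <- free_a[sample.int(length(free_a), 1L)]
        j <- free_b[sample.int(length(free_b), 1L)]
        delta <- -D[i, j] / lambda + 2 * pen
        if (u_acc[it] < delta) {
          m[i] <- j; usedB[j] <- TRUE; score <- score + delta
        }
      }
    } else if (u_move[it] < thr[2]) {    # remove
      matched <- which(m > 0L)
      if (length(matched) > 0) {
        i <- matched[sample.int(length(matched), 1L)]
        delta <- D[i, m[i]] / lambda - 2 * pen
        if (u_acc[it] < delta) {
          usedB[m[i]] <- FALSE; m[i] <- 0L; score <- score + delta
        }
      }
    } else {                             # swap partners of two matched rows
      matched <- which(m > 0L)
      if (length(matched) >= 2) {
        ij <- matched[sample.int(length(matched), 2L)]
        i1 <- ij[1]; i2 <- ij[2]
        delta <- (D[i1, m[i1]] + D[i2, m[i2]] -
                    D[i1, m[i2]] - D[i2, m[i1]]) / lambda
        if (u_acc[it] < delta) {
          tmp <- m[i1]; m[i1] <- m[i2]; m[i2] <- tmp
          score <- score + delta
        }
      }
    }
    if (score > best_score) {
      best_score <- score; best_m <- m
    }
    if (record_trace) trace[it] <- best_score
  }

  matched <- which(best_m > 0L)
  out <- list(
    pairs = data.frame(a = matched, b = best_m[matched],
                       dist = D[cbind(matched, best_m[matched])]),
    m = best_m, score = best_score, lambda_px = lambda)
  if (record_trace) out$best_trace <- trace
  structure(out, class = "matching")
}

#' Link per-cell tracks through a frame stack
#'
#' Chains pairwise matchings across consecutive frames. A track ends when
#' its centroid goes unmatched; centroids in a later frame that are not
#' matched to any existing track start new tracks.
#'
#' @param frames a `frame_stack` (list of data frames with `x`, `y` and
#'   optionally ground-truth `id`).
#' @param params a [tracking_params()]; the seed is advanced per frame pair.
#' @return data frame `(track_id, frame, cell_idx, x, y)` where `cell_idx`
#'   is the row index within the frame.
#' @export
link_tracks <- function(frames, params = tracking_params()) {
  stopifnot(length(frames) >= 2)
  n_frames <- length(frames)
  track_of <- seq_len(nrow(.frame_xy(frames[[1]])))  # track id per row
  next_track <- length(track_of) + 1L
  rows <- list()
  xy <- .frame_xy(frames[[1]])
  rows[[1]] <- data.frame(track_id = track_of, frame = 1L,
                          cell_idx = seq_len(nrow(xy)),
                          x = xy[, 1], y = xy[, 2])
  for (f in seq_len(n_frames - 1)) {
    pp <- params
    pp$seed <- params$seed + f
    mt <- match_pair(frames[[f]], frames[[f + 1]], pp)
    nB <- nrow(.frame_xy(frames[[f + 1]]))
    new_track_of <- integer(nB)
    new_track_of[mt$pairs$b] <- track_of[mt$pairs$a]
    unmatched_b <- which(new_track_of == 0L)
    if (length(unmatched_b) > 0) {
      new_track_of[unmatched_b] <- next_track:(next_track +
                                                 length(unmatched_b) - 1L)
      next_track <- next_track + length(unmatched_b)
    }
    track_of <- new_track_of
    xy <- .frame_xy(frames[[f + 1]])
    rows[[f + 1]] <- data.frame(track_id = track_of, frame = f + 1L,
                                cell_idx = seq_len(nB),
                                x = xy[, 1], y = xy[, 2])
  }
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$frame), ]
}
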