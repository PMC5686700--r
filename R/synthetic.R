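#' @title Synthetic single-cell cohorts
#' @description
#' Generators for wet-lab-like single-cell datasets so that every estimation
#' stage is testable without imaging data: fixed-cell snapshot cohorts
#' (full eight-concentration dose responses with lognormal cell-to-cell
#' heterogeneity), tracked live-cell cohorts (hybrid-model NFAT-NF time
#' series with measurement noise and the time-0 quality gate), and nucleus
#' centroid frame stacks with known ground-truth identities for the cell
#' tracker. All generators are deterministic given their seed.
#' @name synthetic-cohorts
NULL

## four-parameter log-logistic response in [0, 1]; zero at c = 0
.hill_response <- function(conc, log10_ec50, hill) {
  ifelse(conc <= 0, 0,
         1 / (1 + 10^(hill * (log10_ec50 - log10(conc)))))
}

#' Generate a fixed-cell snapshot cohort
#'
#' One row per cell: a ppERK-like readout in arbitrary fluorescence units
#' (AFU, floor near the imaging background of ~135 AFU) and an NFAT-NF-like
#' readout in \[0,1\], both following four-parameter log-logistic population
#' dose-response curves. Cell-to-cell heterogeneity enters through lognormal
#' per-cell basal and amplitude factors; the amplitude factor is shared
#' between the two readouts, making them correlated within a condition (as
#' co-measured pathway readouts are). Gaussian measurement noise is added on
#' top. MI estimates on the cohort are invariant to the affine AFU scale.
#'
#' @param concentrations GnRH levels, molar (default the eight-level design:
#'   0 and 1e-12 to 1e-6 M in decade steps).
#' @param n_per_level cells per concentration.
#' @param time_min nominal stimulation time recorded in the table, minutes.
#' @param basal_afu,amplitude_afu ppERK-like baseline and dynamic range, AFU.
#' @param log10_ec50,hill ppERK-like potency (default -8.24, the fitted
#'   5-minute value) and slope.
#' @param nfat_basal,nfat_amplitude,nfat_log10_ec50,nfat_hill the NFAT-NF
#'   readout's curve; values are clipped to \[0,1\].
#' @param cv_basal,cv_amplitude lognormal CVs of the per-cell basal and
#'   (shared) amplitude factors.
#' @param noise_sd_afu,noise_sd_nf additive measurement noise.
#' @param seed RNG seed.
#' @return data frame `(cell_id, concentration, time_min, ppERK, nfat_nf)`.
#' @export
generate_snapshot_cohort <- function(concentrations = c(0, 10^seq(-12, -6)),
                                     n_per_level = 1000, time_min = 5,
                                     basal_afu = 135, amplitude_afu = 300,
                                     log10_ec50 = -8.24, hill = 1,
                                     nfat_basal = 0.47, nfat_amplitude = 0.25,
                                     nfat_log10_ec50 = -8.5, nfat_hill = 1,
                                     cv_basal = 0.3, cv_amplitude = 0.3,
                                     noise_sd_afu = 20, noise_sd_nf = 0.02,
                                     seed = 1) {
  stopifnot(amplitude_afu >= 0, hill > 0, nfat_hill > 0,
            cv_basal >= 0, cv_amplitude >= 0)
  set.seed(seed)
  rln <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
  }
  n_tot <- length(concentrations) * n_per_level
  conc <- rep(concentrations, each = n_per_level)
  basal_f <- rln(n_tot, cv_basal)
  amp_f <- rln(n_tot, cv_amplitude)  # shared across readouts
  f_erk <- .hill_response(conc, log10_ec50, hill)
  f_nf <- .hill_response(conc, nfat_log10_ec50, nfat_hill)
  pperk <- basal_afu * basal_f + amplitude_afu * amp_f * f_erk +
    stats::rnorm(n_tot, 0, noise_sd_afu)
  nf <- nfat_basal * basal_f + nfat_amplitude * amp_f * f_nf +
    stats::rnorm(n_tot, 0, noise_sd_nf)
  data.frame(cell_id = seq_len(n_tot),
             concentration = conc,
             stimulus = sprintf("%g", conc),
             time_min = time_min,
             ppERK = pperk,
             nfat_nf = pmin(pmax(nf, 0), 1))
}

#' Generate a tracked live-cell cohort
#'
#' Runs the hybrid model under a single-pulse design at each concentration
#' and adds Gaussian measurement noise to the NFAT-NF series (clipped to
#' \[0,1\]). Time-0 values are distributed around the unstimulated steady
#' state (per-cell, through the sampled calmodulin level) plus noise, so the
#' time-0 quality gate removes a realistic, small fraction of cells.
#'
#' @inheritParams during_after_analysis
#' @param n_per_level cells per concentration.
#' @param duration_min pulse (and recording) length, minutes.
#' @param noise_sd additive measurement noise on NFAT-NF.
#' @param out_dt sampling interval of the recorded series, minutes.
#' @return long data frame `(cell_id, stimulus, concentration, t_min,
#'   nfat_nf)`; one series per cell on a shared grid.
#' @export
generate_tracked_cohort <- function(params = default_parameters(),
                                    concentrations = c(0, 1e-11, 1e-9, 1e-7),
                                    n_per_level = 100, duration_min = 60,
                                    fl = 10000, cv = default_effector_cv(),
                                    noise_sd = 0.01, seed = 1,
                                    out_dt = 2.5, dt = 0.05) {
  set.seed(seed + 211)  # measurement-noise stream
  out <- vector("list", length(concentrations))
  for (j in seq_along(concentrations)) {
    run <- hybrid_simulate(params, pulse_protocol(duration_min,
                                                  concentrations[j]),
                           t_end = duration_min, n_cells = n_per_level,
                           fl = fl, cv_R = cv, cv_M = cv, seed = seed,
                           cell_offset = (j - 1) * n_per_level,
                           dt = dt, out_dt = out_dt)
    noisy <- run$nfat_nf +
      matrix(stats::rnorm(length(run$nfat_nf), 0, noise_sd),
             nrow = nrow(run$nfat_nf))
    noisy <- pmin(pmax(noisy, 0), 1)
    out[[j]] <- data.frame(
      cell_id = rep(seq_len(n_per_level) + (j - 1) * n_per_level,
                    times = length(run$t)),
      stimulus = sprintf("%g", concentrations[j]),
      concentration = concentrations[j],
      t_min = rep(run$t, each = n_per_level),
      nfat_nf = as.vector(noisy))
  }
  do.call(rbind, out)
}

#' Quality filter on time-0 NFAT nuclear fraction
#'
#' Removes cells whose time-0 NFAT-NF is below `lower` or above `upper`
#' (strict inequalities: cells exactly at 0.40 or 0.55 are kept, as the gate
#' is printed).
#'
#' @param cohort long data frame as from [generate_tracked_cohort()]
#'   (columns `cell_id`, `t_min`, `nfat_nf`).
#' @param lower,upper gate bounds on the time-0 value.
#' @return list with `kept` (filtered cohort), `removed` (number of cells
#'   removed) and `removed_ids`.
#' @export
qc_filter <- function(cohort, lower = 0.4, upper = 0.55) {
  stopifnot(all(c("cell_id", "t_min", "nfat_nf") %in% names(cohort)))
  t0 <- cohort[cohort$t_min == min(cohort$t_min), ]
  if (anyNA(t0$nfat_nf)) stop("missing time-0 NFAT-NF values")
  bad <- t0$cell_id[t0$nfat_nf < lower | t0$nfat_nf > upper]
  list(kept = cohort[!(cohort$cell_id %in% bad), , drop = FALSE],
       removed = length(bad),
       removed_ids = bad)
}

#' Generate synthetic nucleus-centroid frame stacks
#'
#' Gaussian random-walk centroids with known ground-truth identities,
#' optional cell births (Poisson per frame) and deaths (per-cell hazard per
#' frame), as a fixture for the tracker.
#'
#' @param n_cells initial number of nuclei.
#' @param n_frames number of frames.
#' @param width,height field of view, pixels.
#' @param displacement_px per-frame random-walk standard deviation, pixels.
#' @param birth_rate expected new nuclei per frame.
#' @param death_rate per-nucleus disappearance probability per frame.
#' @param seed RNG seed.
#' @return list of class `frame_stack`: one data frame per frame with
#'   columns `id` (ground truth), `x`, `y` (0-based pixel coordinates).
#' @export
generate_frames <- function(n_cells = 50, n_frames = 10, width = 500,
                            height = 500, displacement_px = 2,
                            birth_rate = 0, death_rate = 0, seed = 1) {
  stopifnot(n_cells >= 1, n_frames >= 1)
  set.seed(seed)
  pos <- data.frame(id = seq_len(n_cells),
                    x = stats::runif(n_cells, 0, width),
                    y = stats::runif(n_cells, 0, height))
  next_id <- n_cells + 1L
  frames <- vector("list", n_frames)
  frames[[1]] <- pos
  for (f in seq_len(n_frames - 1)) {
    if (death_rate > 0 && nrow(pos) > 0)
      pos <- pos[stats::runif(nrow(pos)) > death_rate, , drop = FALSE]
    n_new <- if (birth_rate > 0) stats::rpois(1, birth_rate) else 0L
    if (n_new > 0) {
      pos <- rbind(pos, data.frame(id = next_id:(next_id + n_new - 1L),
                                   x = stats::runif(n_new, 0, width),
                                   y = stats::runif(n_new, 0, height)))
      next_id <- next_id + n_new
    }
    pos$x <- pmin(pmax(pos$x + stats::rnorm(nrow(pos), 0, displacement_px),
                       0), width)
    pos$y <- pmin(pmax(pos$y + stats::rnorm(nrow(pos), 0, displacement_px),
                       0), height)
    frames[[f + 1]] <- pos
  }
  structure(frames, class = "frame_stack")
}
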