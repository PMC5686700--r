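#' @title Pulse protocols, response summaries and information analyses
#' @description
#' GnRH is secreted in pulses; these functions build the pulse designs used
#' throughout, reduce simulated (or tracked) NFAT-NF time courses to scalar
#' responses, and run the two information analyses: sensing during vs after
#' a single pulse, and sensing two consecutive pulses across effector
#' stabilities.
#'
#' Area-under-curve responses are computed on baseline-corrected traces
#' (NFAT-NF minus the cell's time-0 value), the standard live-cell reading
#' of a translocation *response*; maxima are taken on the raw traces.
#' @name pulse-analysis
NULL

#' Two-pulse stimulus design
#'
#' The canonical design: a 15-minute pulse terminated by washing, a
#' 135-minute interval, then a 60-minute pulse at the same concentration,
#' applied at 0, 1e-11, 1e-9 and 1e-7 M GnRH. (A shorter variant with a
#' 120-minute interval and 30-minute second pulse can be built by changing
#' the arguments.)
#'
#' @param pulse1_min,interval_min,pulse2_min durations, minutes.
#' @param concentrations GnRH levels, molar.
#' @return an object of class `pulse_design`.
#' @export
pulse_design <- function(pulse1_min = 15, interval_min = 135,
                         pulse2_min = 60,
                         concentrations = c(0, 1e-11, 1e-9, 1e-7)) {
  stopifnot(pulse1_min > 0, pulse2_min > 0, interval_min >= 0,
            length(concentrations) >= 2, all(concentrations >= 0))
  structure(list(pulse1_min = pulse1_min, interval_min = interval_min,
                 pulse2_min = pulse2_min, concentrations = concentrations),
            class = "pulse_design")
}

## trapezoidal AUC of each row of Y over the grid times within [from, to]
.auc_rows <- function(t, Y, from, to) {
  sel <- which(t >= from - 1e-9 & t <= to + 1e-9)
  if (length(sel) < 2) stop("AUC window [", from, ", ", to,
                            "] contains fewer than 2 grid points")
  tt <- t[sel]
  apply(Y[, sel, drop = FALSE], 1, function(y) pracma::trapz(tt, y))
}

#' Summarise one trajectory to a scalar (or 3-vector) response
#'
#' @param t time grid, minutes.
#' @param y NFAT-NF values on the grid.
#' @param kind one of `"snapshot"` (value at the grid time nearest `at`),
#'   `"auc"` (trapezoidal integral over `window`, minutes; baseline
#'   subtracted first when `baseline_correct`), `"max"` (maximum in
#'   `window`), `"trajectory"` (values at the three grid times nearest
#'   `at`).
#' @param window `c(start, end)` minutes, within the trajectory span.
#' @param at time point(s) for snapshot/trajectory kinds.
#' @param baseline_correct subtract `y` at time 0 before integrating
#'   (AUC only).
#' @return scalar, or length-3 vector for `kind = "trajectory"`.
#' @export
summarize_trajectory <- function(t, y, kind = c("snapshot", "auc", "max",
                                                "trajectory"),
                                 window = NULL, at = NULL,
                                 baseline_correct = FALSE) {
  kind <- match.arg(kind)
  if (kind %in% c("auc", "max")) {
    stopifnot(!is.null(window), length(window) == 2)
    if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9)
      stop("window outside the trajectory span")
  }
  switch(kind,
    snapshot = {
      stopifnot(length(at) == 1)
      y[which.min(abs(t - at))]
    },
    auc = {
      yy <- if (baseline_correct) y - y[1] else y
      drop(.auc_rows(t, matrix(yy, nrow = 1), window[1], window[2]))
    },
    max = {
      sel <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
      max(y[sel])
    },
    trajectory = {
      stopifnot(length(at) == 3)
      vapply(at, function(a) y[which.min(abs(t - a))], numeric(1))
    })
}

## Run one hybrid population per concentration and return responses.
## summarise: function(t, Y_baseline_raw) -> data.frame of response columns.
.population_sweep <- function(params, make_protocol, t_end, concentrations,
                              n_cells, fl, cv, seed, dt, summarise) {
  out <- vector("list", length(concentrations))
  for (j in seq_along(concentrations)) {
    run <- hybrid_simulate(params, make_protocol(concentrations[j]), t_end,
                           n_cells = n_cells, fl = fl, cv_R = cv, cv_M = cv,
                           seed = seed, dt = dt,
                           cell_offset = (j - 1) * n_cells)
    resp <- summarise(run$t, run$nfat_nf)
    resp$stimulus <- sprintf("%g", concentrations[j])
    resp$cell_id <- seq_len(n_cells) + (j - 1) * n_cells
    out[[j]] <- resp
  }
  do.call(rbind, out)
}

#' Information transfer during and immediately after a single GnRH pulse
#'
#' Simulates 15-minute pulses at the four canonical concentrations with the
#' hybrid model, reduces each cell to the baseline-corrected AUC of its
#' NFAT-NF trace during the pulse (`z_during`, over \[0, 15\] min) and in
#' the following 15 minutes (`z_after`, over \[15, 30\] min), plus the
#' 15-minute snapshot, and estimates \eqn{I(Z_{during};S)},
#' \eqn{I(Z_{after};S)}, the snapshot MI, and the additional information
#' \eqn{I(Z_{after};S|Z_{during})} by the chain rule.
#'
#' @param params model parameters.
#' @param fl effector fluctuation lifetime, minutes.
#' @param cv shared effector CV ([default_effector_cv()]).
#' @param n_cells cells per concentration.
#' @param concentrations GnRH levels, molar.
#' @param seed population seed.
#' @param n_bins response bins for the NSB estimation.
#' @param dt integration step, minutes.
#' @return list with `cells` (per-cell response table) and the
#'   `mi_estimate`s `I_during`, `I_after`, `I_snapshot`, `additional`.
#' @export
during_after_analysis <- function(params = default_parameters(), fl,
                                  cv = default_effector_cv(),
                                  n_cells = 1000,
                                  concentrations = c(0, 1e-11, 1e-9, 1e-7),
                                  seed = 1, n_bins = 30, dt = 0.05) {
  pulse <- 15
  cells <- .population_sweep(
    params, function(cc) pulse_protocol(pulse, cc), t_end = 2 * pulse,
    concentrations, n_cells, fl, cv, seed, dt,
    summarise = function(t, Y) {
      B <- Y - Y[, 1]
      data.frame(
        z_during = .auc_rows(t, B, 0, pulse),
        z_after = .auc_rows(t, B, pulse, 2 * pulse),
        z_snapshot = Y[, which.min(abs(t - pulse))])
    })
  list(
    cells = cells,
    fl = fl, cv = cv, seed = seed,
    I_during = mutual_information(cells, "stimulus", "z_during", n_bins),
    I_after = mutual_information(cells, "stimulus", "z_after", n_bins),
    I_snapshot = mutual_information(cells, "stimulus", "z_snapshot", n_bins),
    additional = additional_information(cells, "stimulus",
                                        c("z_during", "z_after"), n_bins))
}

#' Information transfer from sensing two GnRH pulses across effector stabilities
#'
#' For each fluctuation lifetime on `fls`, simulates the two-pulse design
#' with the hybrid model and computes, per the canonical readouts:
#' \itemize{
#'   \item `I_z1_s`, `I_z2_s`: MI between GnRH and the baseline-corrected
#'     AUC over the first 15 minutes of each pulse;
#'   \item `additional`: the chain-rule additional information from the
#'     second-pulse AUC response given the first;
#'   \item `I_z1_z2`, `I_z1_z2_cond`: MI (and its GnRH-conditioned version)
#'     between the pulse-1 and pulse-2 maxima of the raw NFAT-NF trace,
#'     pooled over concentrations.
#' }
#'
#' @inheritParams during_after_analysis
#' @param fls fluctuation lifetimes to sweep, minutes.
#' @param design a [pulse_design()].
#' @return list with `table` (one row per `fl`, values and posterior sds)
#'   and `cells` (per-cell responses, all `fl`s stacked).
#' @export
two_pulse_analysis <- function(params = default_parameters(),
                               fls = c(10, 100, 1000, 10000),
                               design = pulse_design(),
                               cv = default_effector_cv(), n_cells = 1000,
                               seed = 1, n_bins = 30, dt = 0.05) {
  p1 <- design$pulse1_min
  t2start <- p1 + design$interval_min
  t_end <- t2start + design$pulse2_min
  auc_win <- min(15, design$pulse1_min, design$pulse2_min)
  rows <- vector("list", length(fls))
  all_cells <- vector("list", length(fls))
  for (i in seq_along(fls)) {
    cells <- .population_sweep(
      params, function(cc) two_pulse_protocol(cc, p1, design$interval_min,
                                              design$pulse2_min),
      t_end, design$concentrations, n_cells, fls[i], cv, seed, dt,
      summarise = function(t, Y) {
        # each pulse's AUC response is corrected by the baseline at that
        # pulse's onset, so slow baseline drift between pulses does not
        # masquerade as a second-pulse response
        B1 <- Y - Y[, 1]
        B2 <- Y - Y[, which.min(abs(t - t2start))]
        data.frame(
          z1_max = apply(Y[, t <= p1 + 1e-9, drop = FALSE], 1, max),
          z2_max = apply(Y[, t >= t2start - 1e-9, drop = FALSE], 1, max),
          z1_auc = .auc_rows(t, B1, 0, auc_win),
          z2_auc = .auc_rows(t, B2, t2start, t2start + auc_win))
      })
    cells$fl <- fls[i]
    all_cells[[i]] <- cells
    i1 <- mutual_information(cells, "stimulus", "z1_auc", n_bins)
    i2 <- mutual_information(cells, "stimulus", "z2_auc", n_bins)
    add <- additional_information(cells, "stimulus",
                                  c("z1_auc", "z2_auc"), n_bins)
    izz <- mi_between(cells, c("z1_max", "z2_max"), n_bins)
    izzc <- conditional_mi(cells, "stimulus", c("z1_max", "z2_max"), n_bins)
    rows[[i]] <- data.frame(
      fl = fls[i],
      I_z1_s = i1$value, I_z1_s_sd = i1$sd,
      I_z2_s = i2$value, I_z2_s_sd = i2$sd,
      additional = add$value, additional_sd = add$sd,
      I_z1_z2 = izz$value, I_z1_z2_sd = izz$sd,
      I_z1_z2_cond = izzc$value, I_z1_z2_cond_sd = izzc$sd)
  }
  list(table = do.call(rbind, rows), cells = do.call(rbind, all_cells),
       cv = cv, seed = seed, design = design)
}

#' Snapshot, AUC and trajectory information for a single sustained pulse
#'
#' Mirrors the live-cell single-pulse analysis: MI between GnRH and the
#' NFAT-NF value at each requested time point, the baseline-corrected AUC
#' over the whole pulse, and the three-time-point trajectory.
#'
#' @inheritParams during_after_analysis
#' @param duration_min pulse length, minutes.
#' @param snapshot_times times for snapshot MI, minutes.
#' @param trajectory_times the three time points of the trajectory readout.
#' @param trajectory_bins bins per dimension for the trajectory MI (the
#'   3-D product alphabet is sparse at n ~ 10^3, so fewer bins than the
#'   1-D default are advisable).
#' @return list with `cells`, `snapshots` (data frame time/value/sd),
#'   `I_auc`, `I_trajectory`.
#' @export
single_pulse_information <- function(params = default_parameters(), fl,
                                     cv = default_effector_cv(),
                                     n_cells = 1000,
                                     concentrations = c(0, 1e-11, 1e-9, 1e-7),
                                     duration_min = 60,
                                     snapshot_times = c(15, 30, 60),
                                     trajectory_times = c(15, 30, 60),
                                     seed = 1, n_bins = 30,
                                     trajectory_bins = 8, dt = 0.05) {
  cells <- .population_sweep(
    params, function(cc) pulse_protocol(duration_min, cc),
    t_end = duration_min, concentrations, n_cells, fl, cv, seed, dt,
    summarise = function(t, Y) {
      B <- Y - Y[, 1]
      resp <- data.frame(auc = .auc_rows(t, B, 0, duration_min))
      for (tp in unique(c(snapshot_times, trajectory_times)))
        resp[[sprintf("snap_%g", tp)]] <- Y[, which.min(abs(t - tp))]
      resp
    })
  snaps <- do.call(rbind, lapply(snapshot_times, function(tp) {
    est <- mutual_information(cells, "stimulus", sprintf("snap_%g", tp),
                              n_bins)
    data.frame(time_min = tp, mi = est$value, sd = est$sd)
  }))
  list(
    cells = cells, fl = fl, cv = cv, seed = seed,
    snapshots = snaps,
    I_auc = mutual_information(cells, "stimulus", "auc", n_bins),
    I_trajectory = trajectory_mi(cells, "stimulus",
                                 sprintf("snap_%g", trajectory_times),
                                 trajectory_bins))
}
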