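#' Mean-squared displacement of a trajectory
#'
#' Ensemble- and time-origin-averaged MSD at the requested snapshot lags,
#' computed from unwrapped positions. For each particle the MSD at lag
#' \eqn{\ell} is averaged over all time origins; the reported standard error
#' is over the particle ensemble.
#'
#' Reference closed forms (2D): a passive particle obeys
#' \eqn{MSD(t) = 4 D_t t} with \eqn{D_t = k_B T / \gamma_t}; an active
#' Brownian particle with speed \eqn{v = F^{act}/\gamma_t} and persistence
#' time \eqn{\tau_r = \gamma_r / k_B T} obeys
#' \deqn{MSD(t) = 4 D_t t + 2 v^2 \tau_r^2 \left[t/\tau_r +
#'   e^{-t/\tau_r} - 1\right].}
#'
#' @param traj a [trajectory_record()] (>= 2 snapshots).
#' @param lags integer snapshot lags (>= 1).
#' @return data frame with columns `lag`, `lag_time`, `msd`, `se`, `n`.
#' @export
analyze_msd <- function(traj, lags) {
  S <- n_snapshots(traj)
  if (S < 2) stop("at least 2 snapshots required")
  lags <- as.integer(lags)
  stopifnot(all(lags >= 1), all(lags < S))
  pos <- traj$positions_unwrapped
  N <- dim(pos)[2]
  out <- lapply(lags, function(l) {
    origins <- seq_len(S - l)
    # per-particle time-origin average
    acc <- matrix(0, length(origins), N)
    for (oi in seq_along(origins)) {
      d <- pos[origins[oi] + l, , ] - pos[origins[oi], , ]
      acc[oi, ] <- rowSums(d^2)
    }
    per_particle <- colMeans(acc)
    data.frame(lag = l,
               lag_time = traj$time[1 + l] - traj$time[1],
               msd = mean(per_particle),
               se = stats::sd(per_particle) / sqrt(N),
               n = N)
  })
  do.call(rbind, out)
}

#' Orientation autocorrelation of a trajectory
#'
#' Ensemble- and time-origin-averaged director autocorrelation
#' \eqn{\langle \hat e(t_0 + t) \cdot \hat e(t_0) \rangle} at the requested
#' snapshot lags. For a freely rotating 2D particle this decays as
#' \eqn{\exp(-D_r t)} with \eqn{D_r = k_B T / \gamma_r}.
#'
#' @inheritParams analyze_msd
#' @return data frame with columns `lag`, `lag_time`, `acf`, `se`, `n`.
#' @export
analyze_orientation_acf <- function(traj, lags) {
  S <- n_snapshots(traj)
  if (S < 2) stop("at least 2 snapshots required")
  lags <- as.integer(lags)
  stopifnot(all(lags >= 1), all(lags < S))
  dirs <- traj$directors
  N <- dim(dirs)[2]
  out <- lapply(lags, function(l) {
    origins <- seq_len(S - l)
    acc <- matrix(0, length(origins), N)
    for (oi in seq_along(origins)) {
      acc[oi, ] <- rowSums(dirs[origins[oi] + l, , ] * dirs[origins[oi], , ])
    }
    per_particle <- colMeans(acc)
    data.frame(lag = l,
               lag_time = traj$time[1 + l] - traj$time[1],
               acf = mean(per_particle),
               se = stats::sd(per_particle) / sqrt(N),
               n = N)
  })
  do.call(rbind, out)
}

#' Closed-form active Brownian particle MSD (2D)
#'
#' @param t time (vector ok).
#' @param v propulsion speed \eqn{F^{act}/\gamma_t}.
#' @param D_t translational diffusion coefficient \eqn{k_B T/\gamma_t}.
#' @param tau_r persistence time \eqn{\gamma_r / k_B T}.
#' @return theoretical MSD values.
#' @export
abp_msd_theory <- function(t, v, D_t, tau_r) {
  4 * D_t * t + 2 * v^2 * tau_r^2 * (t / tau_r + exp(-t / tau_r) - 1)
}
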