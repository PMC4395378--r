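#' Simulate a propagating action potential on the cable
#'
#' Advances the modified Hodgkin--Huxley cable equation with time-varying
#' capacitance using the staggered backward-Euler scheme of Hines: the
#' voltage update is implicit (one tridiagonal solve per step) and the
#' gates are advanced on staggered half steps by the exact exponential
#' update of the linear gate equation.  Ends are sealed (zero axial flux).
#' The stimulus is applied to the first compartment as a current density
#' `stim_amp / (2 pi radius dx)` for `stim_dur` ms.
#'
#' @param params a [cable_params()] object.
#' @param cond a [conductances()] object (with fitted `V_L`).
#' @param record_at positions along the cable to record, cm.  Each is
#'   mapped to the nearest compartment centre `(i - 1/2) dx`.
#' @param stim_amp,stim_dur,t_total optional overrides of the stimulus
#'   amplitude (uA), duration (ms) and total simulated time (ms).
#' @param stop_at_spike optional position, cm: terminate the run as soon
#'   as the voltage there crosses 0 mV (used by threshold searches).
#' @param v_init initial (and target resting) potential, mV.
#'
#' @return An object of class `"axon_sim"`: a list with `time` (ms), the
#'   voltage matrix `v` (one column per recording position, mV), gate
#'   matrices `m`, `h`, `n` at the same positions, the realised recording
#'   `positions` (cm), the final state of every compartment, and the
#'   `params`/`cond` used.
#' @examples
#' p <- cable_params(TC = 18.5, t_total = 10)
#' sim <- simulate_axon(p, conductances(120, 36, p))
#' ap_metrics(sim)
#' @export
simulate_axon <- function(params, cond,
                          record_at = c(2.5, 5, 7.5, 9.5),
                          stim_amp = NULL, stim_dur = NULL, t_total = NULL,
                          stop_at_spike = NULL, v_init = -65) {
  stopifnot(inherits(params, "cable_params"), inherits(cond, "conductances"))
  if (is.null(stim_amp)) stim_amp <- params$stim_amp
  if (is.null(stim_dur)) stim_dur <- params$stim_dur
  if (is.null(t_total)) t_total <- params$t_total
  nx <- round(params$L / params$dx)
  idx <- pos_to_index(record_at, params$dx, nx)
  stop_idx <- if (is.null(stop_at_spike)) -1L else
    pos_to_index(stop_at_spike, params$dx, nx)
  res <- .cpp_cable_solve(params$L, params$radius, params$R_a, params$G_L,
                          params$E_Na, params$E_K, params$C0, params$Cg_max,
                          params$G_Na_ref, params$TC, params$dt, params$dx,
                          cond$G_Na, cond$G_K, cond$V_L,
                          stim_amp, stim_dur, t_total,
                          idx, stop_idx, v_init)
  pos <- (idx - 0.5) * params$dx
  for (nm in c("v", "m", "h", "n")) colnames(res[[nm]]) <- format(pos)
  structure(list(time = res$time, v = res$v, m = res$m, h = res$h,
                 n = res$n, positions = pos,
                 final = list(v = res$v_final, n = res$n_final,
                              m = res$m_final, h = res$h_final),
                 stopped_early = res$stopped_early,
                 stim = list(amp = stim_amp, dur = stim_dur),
                 params = params, cond = cond),
            class = "axon_sim")
}

pos_to_index <- function(x, dx, nx) {
  idx <- as.integer(pmin(pmax(round(x / dx + 0.5), 1), nx))
  idx
}

#' @export
print.axon_sim <- function(x, ...) {
  cat(sprintf(
    "Axon simulation: G_Na = %g, G_K = %g mS/cm2 at %g C; %.3g ms simulated\n",
    x$cond$G_Na, x$cond$G_K, x$params$TC, max(x$time)))
  cat(sprintf("  recorded at %s cm; peak voltage %.1f mV%s\n",
              paste(format(x$positions), collapse = ", "), max(x$v),
              if (x$stopped_early) " (stopped at first distal spike)" else ""))
  invisible(x)
}

#' @export
plot.axon_sim <- function(x, ...) {
  matplot(x$time, x$v, type = "l", lty = 1, xlab = "time (ms)",
          ylab = "membrane potential (mV)", ...)
  legend("topright", legend = sprintf("%.2f cm", x$positions),
         col = seq_along(x$positions), lty = 1, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.axon_sim <- function(x, ...) {
  out <- data.frame(time_ms = x$time, x$v, check.names = FALSE)
  names(out) <- c("time_ms", sprintf("v_%s_cm", format(x$positions)))
  out
}

# time of the first upward crossing of `level`, linearly interpolated;
# NA if none
upcross_time <- function(t, v, level = 0) {
  above <- v >= level
  k <- which(!above[-length(above)] & above[-1])
  if (!length(k)) return(NA_real_)
  k <- k[1]
  t[k] + (level - v[k]) / (v[k + 1] - v[k]) * (t[k + 1] - t[k])
}

upcross_count <- function(v, level = 0) {
  above <- v >= level
  sum(!above[-length(above)] & above[-1])
}

# sub-sample peak time and value by quadratic interpolation around the
# maximum of the FIRST suprathreshold episode (an axon can re-fire late
# in a run; conduction metrics refer to the first passing wave)
peak_time <- function(t, v, level = 0) {
  up <- which(v >= level)
  if (!length(up)) {
    i <- which.max(v)
  } else {
    k0 <- up[1]
    after <- which(t > t[k0] & v < level)
    k1 <- if (length(after)) after[1] else length(v)
    i <- (k0:k1)[which.max(v[k0:k1])]
  }
  if (i == 1 || i == length(v)) return(list(t = t[i], v = v[i], i = i))
  dt <- t[2] - t[1]
  y0 <- v[i - 1]; y1 <- v[i]; y2 <- v[i + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (denom == 0) 0 else 0.5 * (y0 - y2) / denom
  list(t = t[i] + delta * dt,
       v = y1 - 0.25 * (y0 - y2) * delta, i = i)
}

column_at <- function(sim, pos) {
  j <- which.min(abs(sim$positions - pos))
  if (abs(sim$positions[j] - pos) > sim$params$dx)
    stop(sprintf("no recording near %g cm (have %s)", pos,
                 paste(format(sim$positions), collapse = ", ")))
  j
}

#' Physiological metrics of one simulated action potential
#'
#' Operational definitions: the axon `conducted` if the voltage crosses
#' 0 mV upward at the distal recording site within the run; `velocity` is
#' the distance between the quarter- and three-quarter-length sites
#' divided by the difference of their (quadratically interpolated) action
#' potential peak times; `na_flux` is the time integral of the sodium
#' current `G_Na m^3 h (V - E_Na)` at mid-axon over the action potential
#' (from the upward -55 mV crossing until the voltage falls back below
#' -55 mV), reported as inward charge per membrane area; `apd50`/`apd90`
#' are the durations from the mid-axon peak to 50% and 90% repolarization
#' toward the resting potential; `spike_count` is the number of upward
#' 0 mV crossings at mid-axon.
#'
#' @param sim an [simulate_axon()] result recorded (at least) at the
#'   `proximal`, `mid` and `distal` sites.
#' @param distal position of the conduction-success site, cm.
#' @param proximal,far velocity-measurement sites, cm.
#' @param mid position used for flux, duration and spike count, cm.
#' @param v_rest resting potential used for repolarization levels, mV.
#' @return An object of class `"ap_metrics"` with fields `conducted`,
#'   `velocity` (m/s, `NA` when conduction failed), `na_flux` (nC/cm2),
#'   `apd50`, `apd90` (ms), `spike_count`.
#' @export
ap_metrics <- function(sim, distal = 9.5, proximal = 2.5, far = 7.5,
                       mid = 5, v_rest = -65) {
  stopifnot(inherits(sim, "axon_sim"))
  t <- sim$time
  vd <- sim$v[, column_at(sim, distal)]
  conducted <- is.finite(upcross_time(t, vd, 0))

  velocity <- NA_real_
  if (conducted) {
    j1 <- column_at(sim, proximal); j2 <- column_at(sim, far)
    p1 <- peak_time(t, sim$v[, j1]); p2 <- peak_time(t, sim$v[, j2])
    dist_cm <- sim$positions[j2] - sim$positions[j1]
    velocity <- dist_cm / (p2$t - p1$t) * 10   # cm/ms -> m/s
  }

  jm <- column_at(sim, mid)
  vm <- sim$v[, jm]
  spike_count <- upcross_count(vm, 0)

  na_flux <- apd50 <- apd90 <- NA_real_
  if (any(vm >= 0)) {
    pk <- peak_time(t, vm)
    # AP window at mid-axon: -55 mV upward crossing to return below -55 mV
    on <- upcross_time(t, vm, -55)
    below <- which(t > pk$t & vm < -55)
    off <- if (length(below)) t[below[1]] else max(t)
    w <- t >= on & t <= off
    i_na <- sim$cond$G_Na * sim$m[, jm] ^ 3 * sim$h[, jm] *
      (vm - sim$params$E_Na)                       # uA/cm2, inward < 0
    dt <- t[2] - t[1]
    na_flux <- -sum(i_na[w]) * dt                  # nC/cm2 (uA ms = nC)
    for (frac in c(0.5, 0.9)) {
      lev <- pk$v - frac * (pk$v - v_rest)
      after <- which(t > pk$t & vm <= lev)
      val <- if (length(after)) {
        k <- after[1]
        tc <- t[k - 1] + (lev - vm[k - 1]) / (vm[k] - vm[k - 1]) * dt
        tc - pk$t
      } else NA_real_
      if (frac == 0.5) apd50 <- val else apd90 <- val
    }
  } else {
    na_flux <- 0
  }
  structure(list(conducted = conducted, velocity = velocity,
                 na_flux = na_flux, apd50 = apd50, apd90 = apd90,
                 spike_count = spike_count),
            class = "ap_metrics")
}

#' @export
print.ap_metrics <- function(x, ...) {
  cat("Action potential metrics\n")
  cat(sprintf("  conducted: %s\n", x$conducted))
  cat(sprintf("  velocity:  %s\n",
              if (is.na(x$velocity)) "undefined (conduction failed)"
              else sprintf("%.2f m/s", x$velocity)))
  cat(sprintf("  Na flux:   %.1f nC/cm2 per AP\n", x$na_flux))
  cat(sprintf("  APD50/90:  %.3f / %.3f ms\n", x$apd50, x$apd90))
  cat(sprintf("  spikes at mid-axon: %d\n", x$spike_count))
  invisible(x)
}
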