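#' Cable geometry, passive properties and numerical settings
#'
#' Bundles everything that defines one axon simulation except the pair of
#' voltage-gated conductances: geometry, passive electrical properties,
#' kinetics temperature, discretization and the stimulus protocol.
#' Defaults are the squid giant-axon values used throughout:
#' a 10 cm cable of radius 238 um, axial resistivity 0.0354 kOhm cm,
#' leak conductance 0.3 mS/cm2, intrinsic capacitance 0.88 uF/cm2 and a
#' gating capacitance that peaks at 0.13 uF/cm2 when `G_Na` equals the
#' reference 120 mS/cm2.
#'
#' @param L cable length, cm.
#' @param radius axon radius, cm.
#' @param R_a axial (cytoplasmic) resistivity, kOhm cm.
#' @param G_L specific leak conductance, mS/cm2.
#' @param E_Na,E_K sodium and potassium reversal potentials, mV.
#' @param C0 intrinsic (bilayer) membrane capacitance, uF/cm2.
#' @param Cg_max gating-capacitance maximum at `G_Na_ref`, uF/cm2.
#' @param G_Na_ref reference sodium conductance for the gating capacitance,
#'   mS/cm2.
#' @param TC temperature, degrees C.  Rate constants scale with
#'   `Q10 = 3^((TC - 6.3)/10)`.
#' @param dt time step, ms.
#' @param dx space step, cm.  Must divide `L`.
#' @param stim_amp stimulus amplitude, uA, delivered to the first
#'   compartment as a current density `stim_amp / (2 pi radius dx)`.
#' @param stim_dur stimulus duration, ms.
#' @param t_total total simulated time, ms.
#'
#' @return An object of class `"cable_params"`.
#' @examples
#' p <- cable_params(TC = 18.5)
#' p
#' @seealso [conductances()], [simulate_axon()]
#' @export
cable_params <- function(L = 10, radius = 238e-4, R_a = 0.0354, G_L = 0.3,
                         E_Na = 50, E_K = -77, C0 = 0.88, Cg_max = 0.13,
                         G_Na_ref = 120, TC = 18.5, dt = 1e-3, dx = 1e-2,
                         stim_amp = 20, stim_dur = 0.1, t_total = 20) {
  stopifnot(L > 0, radius > 0, R_a > 0, G_L > 0, C0 > 0, Cg_max >= 0,
            G_Na_ref > 0, dt > 0, dx > 0, stim_dur >= 0, t_total > 0)
  nx <- round(L / dx)
  if (abs(nx * dx - L) > 1e-9 * L)
    stop("`dx` must divide the cable length `L`")
  structure(list(L = L, radius = radius, R_a = R_a, G_L = G_L,
                 E_Na = E_Na, E_K = E_K, C0 = C0, Cg_max = Cg_max,
                 G_Na_ref = G_Na_ref, TC = TC, dt = dt, dx = dx,
                 stim_amp = stim_amp, stim_dur = stim_dur,
                 t_total = t_total),
            class = "cable_params")
}

#' @export
print.cable_params <- function(x, ...) {
  cat("Axon cable parameters\n")
  cat(sprintf("  geometry: L = %g cm, radius = %g cm, R_a = %g kOhm cm\n",
              x$L, x$radius, x$R_a))
  cat(sprintf("  passive:  G_L = %g mS/cm2, E_Na = %g mV, E_K = %g mV\n",
              x$G_L, x$E_Na, x$E_K))
  cat(sprintf("  capacitance: C0 = %g, Cg_max = %g uF/cm2 (ref G_Na = %g)\n",
              x$C0, x$Cg_max, x$G_Na_ref))
  cat(sprintf("  temperature: %g C (Q10 factor %.3f)\n",
              x$TC, 3 ^ ((x$TC - 6.3) / 10)))
  cat(sprintf("  grid: dt = %g ms, dx = %g cm (%d compartments, %d steps)\n",
              x$dt, x$dx, round(x$L / x$dx), round(x$t_total / x$dt)))
  cat(sprintf("  stimulus: %g uA for %g ms; total time %g ms\n",
              x$stim_amp, x$stim_dur, x$t_total))
  invisible(x)
}

#' Voltage-dependent rate constants of the gating variables
#'
#' The six rate constants of the modified Hodgkin--Huxley kinetics, in 1/ms,
#' each scaled by `Q10 = 3^((TC - 6.3)/10)`.  The potassium deactivation
#' rate uses the Clay form `beta_n = 0.125 exp(-(V+65)/19.7)`, which gives
#' the axon its Type 3 excitability, and the inactivation recovery rate is
#' `beta_h = 1.8 / (1 + exp(-(V+16)/10))`.  The removable singularities of
#' `alpha_n` (at -55 mV) and `alpha_m` (at -40 mV) are evaluated by their
#' analytic limits.
#'
#' @param V membrane potential, mV (vectorized).
#' @param TC temperature, degrees C.
#' @return A matrix with one row per element of `V` and columns
#'   `alpha_n`, `beta_n`, `alpha_m`, `beta_m`, `alpha_h`, `beta_h`.
#' @examples
#' rate_constants(-55, TC = 6.3)[, "alpha_n"]  # 0.1, by the analytic limit
#' @export
rate_constants <- function(V, TC = 6.3) {
  stopifnot(is.numeric(V), all(is.finite(V)))
  .cpp_rate_constants(as.numeric(V), TC)
}

#' Steady-state gating variables
#'
#' `x_inf = alpha_x / (alpha_x + beta_x)` for the three gates.  The Q10
#' factor cancels, so the steady states are temperature independent.
#'
#' @inheritParams rate_constants
#' @return A matrix with columns `n`, `m`, `h`, values in \[0, 1\].
#' @export
steady_state_gates <- function(V, TC = 6.3) {
  r <- rate_constants(V, TC)
  out <- cbind(n = r[, "alpha_n"] / (r[, "alpha_n"] + r[, "beta_n"]),
               m = r[, "alpha_m"] / (r[, "alpha_m"] + r[, "beta_m"]),
               h = r[, "alpha_h"] / (r[, "alpha_h"] + r[, "beta_h"]))
  out
}

#' Fit the leak reversal potential for a stationary resting state
#'
#' Solves the steady-state current balance at the resting potential,
#' `G_K n_inf^4 (V_rest - E_K) + G_Na m_inf^3 h_inf (V_rest - E_Na) +
#' G_L (V_rest - V_L) = 0`, for `V_L`.  With gates at their steady state
#' the balance is linear in `V_L`, so the solution is closed form; an
#' unstimulated simulation then holds the membrane at `V_rest`.
#'
#' @param G_Na,G_K peak conductances, mS/cm2.
#' @param G_L leak conductance, mS/cm2 (must be positive).
#' @param V_rest target resting potential, mV.
#' @param E_Na,E_K reversal potentials, mV.
#' @return The leak reversal potential `V_L`, mV.
#' @examples
#' solve_leak_potential(0, 0, 0.3)      # leak-only axon rests at V_L
#' solve_leak_potential(120, 36, 0.3)
#' @export
solve_leak_potential <- function(G_Na, G_K, G_L = 0.3, V_rest = -65,
                                 E_Na = 50, E_K = -77) {
  if (G_L <= 0)
    stop("`G_L` must be positive: a zero leak cannot pin the resting state")
  g <- steady_state_gates(V_rest)
  i_k <- G_K * g[, "n"] ^ 4 * (V_rest - E_K)
  i_na <- G_Na * g[, "m"] ^ 3 * g[, "h"] * (V_rest - E_Na)
  unname(V_rest + (i_k + i_na) / G_L)
}

#' A (G_Na, G_K) phenotype point with its fitted leak potential
#'
#' @param G_Na,G_K peak sodium and potassium conductances, mS/cm2.
#' @param params a [cable_params()] object supplying `G_L` and the
#'   reversal potentials used to fit `V_L`.
#' @param V_rest resting potential the leak is fitted to, mV.
#' @return An object of class `"conductances"` with fields `G_Na`, `G_K`
#'   and the fitted `V_L`.
#' @export
conductances <- function(G_Na, G_K, params = cable_params(),
                         V_rest = -65) {
  stopifnot(G_Na >= 0, G_K >= 0)
  v_l <- solve_leak_potential(G_Na, G_K, G_L = params$G_L, V_rest = V_rest,
                              E_Na = params$E_Na, E_K = params$E_K)
  structure(list(G_Na = G_Na, G_K = G_K, V_L = v_l, V_rest = V_rest),
            class = "conductances")
}

#' @export
print.conductances <- function(x, ...) {
  cat(sprintf(
    "Conductances: G_Na = %g, G_K = %g mS/cm2 (V_L = %.3f mV for rest at %g mV)\n",
    x$G_Na, x$G_K, x$V_L, x$V_rest))
  invisible(x)
}

#' Sodium-channel gating capacitance
#'
#' `C_g = Cg_max (G_Na / G_Na_ref) (1 - m)`: the gating charge of closed
#' sodium channels behaves as an extra membrane capacitance, proportional
#' to the closed fraction `1 - m` and to the channel density.  Total
#' membrane capacitance is `C0 + C_g`.
#'
#' @param m sodium activation gate value(s) in \[0, 1\].
#' @param G_Na peak sodium conductance, mS/cm2.
#' @param Cg_max capacitance at `m = 0` and `G_Na = G_Na_ref`, uF/cm2.
#' @param G_Na_ref reference conductance, mS/cm2.
#' @return Gating capacitance, uF/cm2.
#' @export
gating_capacitance <- function(m, G_Na, Cg_max = 0.13, G_Na_ref = 120) {
  stopifnot(all(m >= 0), all(m <= 1), G_Na >= 0)
  Cg_max * (G_Na / G_Na_ref) * (1 - m)
}
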