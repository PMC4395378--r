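#' Classify axonal excitability as Type 2 or Type 3
#'
#' Protocol: a sustained current step is injected into the first
#' compartment of the full cable and spikes are counted at mid-axon.
#' The just-threshold amplitude (smallest sustained current that elicits
#' at least one propagated spike) is located by bisection to a relative
#' tolerance of 1%, then a step of twice that amplitude is applied for the
#' full duration.  Two or more spikes at the recording site mean the axon
#' fires repetitively under sustained drive (Type 2 excitability); a
#' single spike followed by silence is Type 3.  Classification is done at
#' low temperature (6.3 C) by default, where the distinction is sharpest;
#' the boundary itself is relatively temperature independent.
#'
#' @param cond a [conductances()] object; must lie inside the excitable
#'   region (a spike must be elicitable).
#' @param params a [cable_params()] object.  The default uses 6.3 C and a
#'   100 ms sustained step.
#' @param step_dur duration of the sustained current, ms.
#' @param record_pos spike-counting position, cm.
#' @param bracket optional starting bracket `c(lo, hi)` for the threshold
#'   current, uA; it is expanded automatically if it does not straddle the
#'   threshold.
#' @param rel_tol relative tolerance of the threshold bisection.
#' @param threshold_floor just-threshold currents below this (uA) mark a
#'   phenotype whose resting state is effectively unstable (it fires on
#'   a vanishing perturbation, orders of magnitude below the normal
#'   rheobase).  Such hyperexcitable phenotypes are classified on the
#'   repetitive-firing (`"type2"`) side of the dichotomy and flagged
#'   `spontaneous = TRUE`.
#' @return An object of class `"excitability"`: list with `type`
#'   (`"type3"` or `"type2"`), `threshold` (just-threshold current, uA),
#'   `spike_count` at twice threshold, `spontaneous`, and the protocol
#'   settings.
#' @examples
#' \donttest{
#' p <- cable_params(TC = 6.3, t_total = 100)
#' classify_excitability(conductances(120, 36, p), p)  # Type 3
#' }
#' @export
classify_excitability <- function(cond,
                                  params = cable_params(TC = 6.3,
                                                        t_total = 100),
                                  step_dur = 100, record_pos = 5,
                                  bracket = c(0.5, 8), rel_tol = 0.01,
                                  threshold_floor = 1e-3) {
  stopifnot(inherits(cond, "conductances"))
  t_run <- max(params$t_total, step_dur)

  spikes_at <- function(amp, stop_early = TRUE) {
    sim <- simulate_axon(params, cond, record_at = record_pos,
                         stim_amp = amp, stim_dur = step_dur,
                         t_total = t_run,
                         stop_at_spike = if (stop_early) record_pos else NULL)
    if (stop_early) as.integer(sim$stopped_early)
    else upcross_count(sim$v[, 1], 0)
  }

  lo <- max(bracket[1], 0)
  hi <- max(bracket[2], 2e-3)
  # expand until the bracket straddles the threshold
  tries <- 0
  while (spikes_at(hi) == 0L) {
    lo <- hi; hi <- hi * 2; tries <- tries + 1
    if (hi > 1e3)
      stop("no spike elicited up to ", hi,
           " uA: phenotype outside the excitable region")
  }
  while (lo > 0 && spikes_at(lo) >= 1L) {
    hi <- lo; lo <- lo / 2
    if (lo < 1e-4) { lo <- 0; break }
  }
  while ((hi - lo) / hi > rel_tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid) >= 1L) hi <- mid else lo <- mid
  }
  threshold <- hi

  if (threshold < threshold_floor) {
    # unstable rest: fires on a vanishing perturbation, so the phenotype
    # is on the hyperexcitable side of the Type 3 / Type 2 dichotomy
    return(structure(list(type = "type2", threshold = threshold,
                          spike_count = NA_integer_, spontaneous = TRUE,
                          step_dur = step_dur, record_pos = record_pos,
                          TC = params$TC, cond = cond),
                     class = "excitability"))
  }
  n_spikes <- spikes_at(2 * threshold, stop_early = FALSE)
  if (n_spikes == 0L)
    stop("no spike at twice the just-threshold current: ",
         "phenotype outside the excitable region")
  structure(list(type = if (n_spikes >= 2L) "type2" else "type3",
                 threshold = threshold, spike_count = n_spikes,
                 spontaneous = FALSE,
                 step_dur = step_dur, record_pos = record_pos,
                 TC = params$TC, cond = cond),
            class = "excitability")
}

#' @export
print.excitability <- function(x, ...) {
  cat(sprintf(
    "%s excitability at G_Na = %g, G_K = %g mS/cm2 (%g C):\n",
    if (x$type == "type3") "Type 3" else "Type 2",
    x$cond$G_Na, x$cond$G_K, x$TC))
  if (isTRUE(x$spontaneous))
    cat("  unstable resting state: fires on a vanishing perturbation\n")
  else
    cat(sprintf(
      "  just-threshold current %.3g uA; %d spike(s) in %g ms at 2x threshold\n",
      x$threshold, x$spike_count, x$step_dur))
  invisible(x)
}
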