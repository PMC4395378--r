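#' Fitness functions over channel-expression phenotypes
#'
#' A fitness function maps a phenotype -- one conductance (mS/cm2) or a
#' (G_Na, G_K) pair -- to a survival probability in \[0, 1\].  The
#' constructors below build the forms used in the evolutionary runs:
#' step discontinuities at physiological failure boundaries ("fitness
#' cliffs"), graded selection on conduction velocity (with or without a
#' linear metabolic cost), graded selection on action-potential duration,
#' and the 2D indicator of the viable region.
#'
#' `fitness_fn` objects are plain R functions carrying a `domain`
#' attribute (`"1d"` or `"2d"`) and a descriptive `tag`.  1D functions
#' take a numeric vector of phenotypes; 2D functions take a two-column
#' matrix `cbind(g_na, g_k)`.
#'
#' @name fitness
NULL

new_fitness_fn <- function(f, domain, tag) {
  structure(f, class = "fitness_fn", domain = domain, tag = tag)
}

#' @export
print.fitness_fn <- function(x, ...) {
  cat(sprintf("Fitness function (%s): %s\n", attr(x, "domain"),
              attr(x, "tag")))
  invisible(x)
}

#' Step fitness at a functional discontinuity
#'
#' Survival probability 1 on the surviving side of the threshold
#' (inclusive) and 0 on the other.  The plateau value of 1 is a
#' computational convenience; only the location of the step matters for
#' the selection-mutation balance.
#'
#' @param threshold phenotype at the cliff edge, mS/cm2.
#' @param side `"above"`: phenotypes `>= threshold` survive (conduction
#'   or excitability cliffs); `"below"`: phenotypes `<= threshold`
#'   survive.
#' @return A `fitness_fn`.
#' @examples
#' f <- fitness_cliff(81)
#' f(c(80, 81, 85))  # 0 1 1
#' @export
fitness_cliff <- function(threshold, side = c("above", "below")) {
  stopifnot(threshold >= 0)
  side <- match.arg(side)
  f <- if (side == "above") function(x) as.numeric(x >= threshold)
       else function(x) as.numeric(x <= threshold)
  new_fitness_fn(f, "1d", sprintf("cliff: survive %s %g mS/cm2",
                                  if (side == "above") ">=" else "<=",
                                  threshold))
}

# shared scaffolding: piecewise-linear metric -> [floor, 1] rescale,
# composed with a conduction cliff
rescaled_curve_fitness <- function(g, metric, floor, cliff, tag,
                                   invert = FALSE) {
  if (floor < 0 || floor >= 1)
    stop("`floor` must lie in [0, 1): the rescaled fitness would leave [0, 1]")
  ok <- is.finite(metric)
  g <- g[ok]; metric <- metric[ok]
  if (invert) metric <- -metric
  lo <- min(metric); hi <- max(metric)
  if (hi <= lo) stop("metric curve is flat; cannot rescale")
  mfun <- approxfun(g, metric, rule = 2)
  f <- function(x) {
    val <- floor + (1 - floor) * (mfun(x) - lo) / (hi - lo)
    val <- pmin(pmax(val, 0), 1)
    val * (x >= cliff)
  }
  new_fitness_fn(f, "1d", tag)
}

#' Graded fitness proportional to conduction velocity
#'
#' Affinely rescales a tabulated velocity curve onto `[floor, 1]` and
#' composes it with the conduction cliff: phenotypes below the cliff die,
#' and above it survival rises with conduction velocity.  A `floor`
#' close to 1 models weak positive selection for speed (the
#' selection-mutation balance is then dominated by drift and mutation
#' pressure); the rescaling slope is a free calibration constant.
#'
#' @param curve a [velocity_curve()] result (or data frame with the swept
#'   conductance in its first flagged axis column and
#'   `velocity_m_per_s`).
#' @param floor fitness at the slowest conducting phenotype, in \[0, 1).
#' @param cliff conduction-failure threshold, mS/cm2.
#' @return A `fitness_fn`.
#' @export
fitness_velocity <- function(curve, floor = 0.95, cliff) {
  swept <- sweep_axis_values(curve)
  keep <- curve$conducted & swept >= cliff
  rescaled_curve_fitness(swept[keep], curve$velocity_m_per_s[keep],
                         floor, cliff,
                         sprintf("velocity selection (floor %g, cliff %g)",
                                 floor, cliff))
}

#' Fitness from conduction velocity minus a linear expression cost
#'
#' Subtracts a metabolic cost growing linearly with sodium conductance
#' from the velocity curve, renormalizes the difference onto
#' `[floor, 1]` (so the interior optimum has fitness 1) and composes
#' with the conduction cliff.  With `cost_slope = 0` this reduces to
#' [fitness_velocity()].
#'
#' @inheritParams fitness_velocity
#' @param cost_slope cost per mS/cm2, in velocity units (m/s per mS/cm2).
#' @return A `fitness_fn`.
#' @export
fitness_velocity_cost <- function(curve, cost_slope, floor = 0, cliff) {
  stopifnot(cost_slope >= 0)
  swept <- sweep_axis_values(curve)
  keep <- curve$conducted & swept >= cliff
  net <- curve$velocity_m_per_s[keep] - cost_slope * swept[keep]
  rescaled_curve_fitness(swept[keep], net, floor, cliff,
                         sprintf("velocity - cost (slope %g, cliff %g)",
                                 cost_slope, cliff))
}

#' Fitness favouring brief action potentials
#'
#' Inverts a tabulated action-potential-duration curve (shorter spikes
#' are fitter), rescales onto `[floor, 1]` and composes with the
#' repolarization-failure cliff at low potassium conductance.
#'
#' @param curve a [velocity_curve()] sweep along the potassium axis with
#'   `apd90_ms` tabulated.
#' @param floor fitness at the longest-duration conducting phenotype.
#' @param cliff conduction-failure threshold, mS/cm2 (default 3, the
#'   repolarization-failure edge).
#' @param measure which duration column to invert.
#' @return A `fitness_fn`.
#' @export
fitness_apd <- function(curve, floor = 0.95, cliff = 3,
                        measure = c("apd90_ms", "apd50_ms")) {
  measure <- match.arg(measure)
  swept <- sweep_axis_values(curve)
  keep <- curve$conducted & swept >= cliff
  rescaled_curve_fitness(swept[keep], curve[[measure]][keep], floor, cliff,
                         sprintf("short-APD selection (%s, floor %g)",
                                 measure, floor),
                         invert = TRUE)
}

sweep_axis_values <- function(curve) {
  ax <- attr(curve, "axis")
  if (is.null(ax)) {
    # fall back: the axis is whichever column varies
    ax <- if (length(unique(curve$g_na)) > 1) "na" else "k"
  }
  if (ax == "na") curve$g_na else curve$g_k
}

#' Indicator fitness of the 2D viable region
#'
#' Survival 1 for (G_Na, G_K) phenotypes that both conduct at the test
#' temperature and show Type 3 excitability, 0 elsewhere.  Membership is
#' evaluated against piecewise-linear [region_boundaries()], so no cable
#' simulation is needed per phenotype.  Phenotypes outside the anchored
#' conductance range are evaluated against the nearest boundary segment
#' (constant extrapolation) with a one-time warning.
#'
#' @param boundaries a [region_boundaries()] object built with
#'   `type3 = TRUE`.
#' @return A `fitness_fn` with domain `"2d"`; call it with
#'   `cbind(g_na, g_k)`.
#' @export
fitness_region2d <- function(boundaries) {
  stopifnot(inherits(boundaries, "region_boundaries"))
  if (is.null(boundaries$k_type3))
    stop("boundaries were built without the Type 3 edge; ",
         "rebuild with type3 = TRUE")
  warned <- FALSE
  rng_na <- range(boundaries$gna_anchors)
  rng_gk <- range(boundaries$gk_anchors)
  f <- function(x) {
    x <- rbind(x)
    gna <- pmax(x[, 1], 0); gk <- pmax(x[, 2], 0)
    if (!warned && (any(gna > rng_na[2]) || any(gk > rng_gk[2]))) {
      warned <<- TRUE
      warning("phenotypes outside the anchored landscape range; ",
              "boundaries extrapolated as constant")
    }
    as.numeric(gna >= boundaries$na_min(gk) &
               gk >= boundaries$k_min(gna) &
               gk <= boundaries$k_max(gna) &
               gk >= boundaries$k_type3(gna))
  }
  new_fitness_fn(f, "2d",
                 sprintf("2D region: conducts at %g C and Type 3",
                         boundaries$TC))
}

#' Tabulate a fitness function for inspection or export
#'
#' @param f a `fitness_fn`.
#' @param phenotypes numeric vector (1D) or two-column matrix (2D).
#' @return Data frame of phenotypes and fitness values, ready for
#'   `write.csv()`.
#' @export
tabulate_fitness <- function(f, phenotypes) {
  stopifnot(inherits(f, "fitness_fn"))
  if (attr(f, "domain") == "2d") {
    phenotypes <- rbind(phenotypes)
    data.frame(g_na = phenotypes[, 1], g_k = phenotypes[, 2],
               fitness = f(phenotypes))
  } else {
    data.frame(phenotype = phenotypes, fitness = f(phenotypes))
  }
}
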