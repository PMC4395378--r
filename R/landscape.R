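#' Locate a functional boundary along one conductance axis
#'
#' Bisects a predicate (action-potential conduction, or Type 3
#' excitability) along the sodium or potassium conductance axis, holding
#' the other conductance fixed.  The search runs on an integer grid of
#' `granularity` mS/cm2 (matching the precision at which the boundaries
#' are reported), so the result is identical to a brute-force scan at
#' that step: the smallest (side `"lower"`) or largest (side `"upper"`)
#' conductance at which the predicate holds.
#'
#' @param axis `"na"` or `"k"`: the conductance being varied.
#' @param fixed the value of the other conductance, mS/cm2.
#' @param predicate `"conducts"` (an action potential crosses 0 mV at the
#'   distal site within the window) or `"type3"` (single-spike response
#'   to a sustained 2x-threshold current).
#' @param TC temperature for the predicate, degrees C.  Conduction tests
#'   default to 26 (the warmest water the squid encounters); excitability
#'   is classified at 6.3.
#' @param bracket `c(lo, hi)`: conductances straddling the boundary.  For
#'   side `"lower"` the predicate must fail at `lo` and hold at `hi`;
#'   for `"upper"` the reverse.
#' @param side which edge of the region the bracket straddles.
#' @param expand widen the bracket automatically (up to a few doublings)
#'   when the predicate does not change across it, instead of erroring.
#' @param granularity reporting grid, mS/cm2.
#' @param t_total simulation window for conduction tests, ms.
#' @param params optional [cable_params()] override.
#' @return The boundary conductance, mS/cm2.
#' @examples
#' \donttest{
#' # minimum G_Na sustaining conduction at 26 C with G_K = 36
#' find_threshold("na", fixed = 36, predicate = "conducts", TC = 26,
#'                bracket = c(40, 150))
#' }
#' @export
find_threshold <- function(axis = c("na", "k"), fixed,
                           predicate = c("conducts", "type3"),
                           TC = if (match.arg(predicate) == "type3") 6.3 else 26,
                           bracket, side = c("lower", "upper"),
                           expand = FALSE,
                           granularity = 1, t_total = 30, params = NULL) {
  axis <- match.arg(axis)
  predicate <- match.arg(predicate)
  side <- match.arg(side)
  if (is.null(params))
    params <- cable_params(TC = TC,
                           t_total = if (predicate == "type3") 100 else t_total)
  test <- boundary_predicate(axis, fixed, predicate, params)

  lo <- round(bracket[1] / granularity) * granularity
  hi <- round(bracket[2] / granularity) * granularity
  p_lo <- test(lo); p_hi <- test(hi)
  tries <- 0
  while (p_lo == p_hi && expand && tries < 4 && hi > lo) {
    width <- hi - lo
    if ((side == "lower") == p_lo) {        # boundary lies below lo
      if (side == "lower" && p_lo && lo <= 0)
        return(lo)                          # predicate holds down to zero
      hi <- lo; p_hi <- p_lo
      lo <- max(0, lo - width); p_lo <- test(lo)
    } else {                                # boundary lies above hi
      lo <- hi; p_lo <- p_hi
      hi <- hi + width; p_hi <- test(hi)
    }
    tries <- tries + 1
  }
  if (p_lo == p_hi) {
    if (expand && side == "lower" && p_lo && lo <= 0) return(lo)
    stop("predicate does not change across the bracket [",
         lo, ", ", hi, "]")
  }
  want_hi_pass <- (side == "lower")
  if (p_hi != want_hi_pass)
    stop(sprintf("for side = \"%s\" the predicate must %s at the upper end",
                 side, if (want_hi_pass) "hold" else "fail"))
  while (hi - lo > granularity) {
    mid <- round((lo + hi) / (2 * granularity)) * granularity
    if (test(mid) == want_hi_pass) hi <- mid else lo <- mid
  }
  if (side == "lower") hi else lo
}

boundary_predicate <- function(axis, fixed, predicate, params) {
  force(params)
  pair <- function(g) if (axis == "na") c(g, fixed) else c(fixed, g)
  if (predicate == "conducts") {
    function(g) {
      p <- pair(g)
      sim <- simulate_axon(params, conductances(p[1], p[2], params),
                           record_at = 9.5, stop_at_spike = 9.5)
      isTRUE(sim$stopped_early) || any(sim$v >= 0)
    }
  } else {
    thr_hint <- new.env()
    thr_hint$bracket <- c(0.05, 1)
    function(g) {
      p <- pair(g)
      ex <- classify_excitability(conductances(p[1], p[2], params), params,
                                  bracket = thr_hint$bracket)
      # warm-start the next threshold search: thresholds vary smoothly
      # (floored: a nearly spontaneously firing phenotype must not
      # collapse the bracket for its neighbours)
      thr_hint$bracket <- c(max(ex$threshold * 0.7, 1e-3),
                            max(ex$threshold * 1.3, 2e-3))
      ex$type == "type3"
    }
  }
}

#' Conduction velocity (or other metric) along a conductance sweep
#'
#' Simulates the axon at each grid point along one conductance axis and
#' tabulates the action-potential metrics.  Non-conducting points are
#' kept in the table and flagged in the `conducted` column rather than
#' silently dropped.
#'
#' @inheritParams find_threshold
#' @param range `c(from, to)` sweep limits, mS/cm2.
#' @param step grid step, mS/cm2.
#' @param TC simulation temperature (default 18.5).
#' @param t_total simulation window per point, ms.
#' @return A data frame of class `"conductance_sweep"` with columns `g_na`,
#'   `g_k`, `conducted`, `velocity_m_per_s`, `na_flux_nc_per_cm2`,
#'   `apd50_ms`, `apd90_ms`, `spike_count`.  The attribute `"peak"` holds
#'   the grid location of maximum velocity.
#' @export
velocity_curve <- function(axis = c("na", "k"), fixed, range, step = 5,
                           TC = 18.5, t_total = 16, params = NULL) {
  axis <- match.arg(axis)
  if (is.null(params)) params <- cable_params(TC = TC, t_total = t_total)
  gs <- seq(range[1], range[2], by = step)
  rows <- lapply(gs, function(g) {
    p <- if (axis == "na") c(g, fixed) else c(fixed, g)
    met <- ap_metrics(simulate_axon(params, conductances(p[1], p[2], params)))
    data.frame(g_na = p[1], g_k = p[2], conducted = met$conducted,
               velocity_m_per_s = met$velocity,
               na_flux_nc_per_cm2 = met$na_flux,
               apd50_ms = met$apd50, apd90_ms = met$apd90,
               spike_count = met$spike_count)
  })
  out <- do.call(rbind, rows)
  if (any(!out$conducted))
    warning("sweep includes non-conducting points (flagged in `conducted`)")
  swept <- if (axis == "na") out$g_na else out$g_k
  ok <- out$conducted
  attr(out, "peak") <- if (any(ok)) swept[ok][which.max(out$velocity_m_per_s[ok])]
                       else NA_real_
  attr(out, "axis") <- axis
  class(out) <- c("conductance_sweep", "data.frame")
  out
}

#' Continuous location of the conduction-velocity peak
#'
#' Fits a quadratic to the velocity curve around its grid maximum and
#' returns the vertex, refining the peak location below the grid step.
#'
#' @param curve a [velocity_curve()] result.
#' @param window half-width (in grid points) of the quadratic fit.
#' @return List with `g` (refined peak location, mS/cm2), `velocity`
#'   (fitted peak velocity, m/s) and `g_grid` (the grid argmax).
#' @export
velocity_peak <- function(curve, window = 5) {
  stopifnot(inherits(curve, "conductance_sweep"))
  swept <- if (attr(curve, "axis") == "na") curve$g_na else curve$g_k
  v <- curve$velocity_m_per_s
  i <- which.max(v)
  sel <- max(1, i - window):min(length(v), i + window)
  fit <- lm(v[sel] ~ swept[sel] + I(swept[sel]^2))
  b <- coef(fit)
  g_hat <- if (is.na(b[3]) || b[3] >= 0) swept[i] else -b[2] / (2 * b[3])
  list(g = unname(g_hat),
       velocity = unname(b[1] + b[2] * g_hat + b[3] * g_hat^2),
       g_grid = swept[i])
}

#' Sweep a rectangular (G_Na, G_K) grid and tabulate the landscape
#'
#' Evaluates the action-potential metrics (and optionally the
#' excitability class) at every point of a rectangular conductance grid.
#' The result can be cached to disk as a CSV with a JSON metadata
#' sidecar; a reload with identical grid and parameters is bit-identical,
#' and any mismatch between requested and cached parameters triggers a
#' recompute with a warning.
#'
#' @param g_na,g_k grid vectors, mS/cm2.
#' @param TC simulation temperature for the metrics.
#' @param classify also run the (slow) Type 2/3 classification per point.
#' @param cache_dir optional directory for the CSV + JSON cache.
#' @param t_total simulation window per point, ms.
#' @return A data frame of class `"landscape"` with one row per grid point
#'   and the metric columns of [velocity_curve()] plus (optionally)
#'   `excitability`; metadata in `attr(, "meta")`.
#' @export
build_landscape <- function(g_na, g_k, TC = 18.5, classify = FALSE,
                            cache_dir = NULL, t_total = 16) {
  meta <- list(g_na = as.numeric(g_na), g_k = as.numeric(g_k), TC = TC,
               classify = classify, t_total = t_total,
               version = as.character(utils::packageVersion("axevolve")))
  if (!is.null(cache_dir)) {
    cached <- read_landscape_cache(cache_dir, meta)
    if (!is.null(cached)) return(cached)
  }
  if (length(g_na) == 0L || length(g_k) == 0L) {
    out <- empty_landscape()
    attr(out, "meta") <- meta
    return(out)
  }
  params <- cable_params(TC = TC, t_total = t_total)
  ex_params <- if (classify) cable_params(TC = 6.3, t_total = 100)
  grid <- expand.grid(g_na = as.numeric(g_na), g_k = as.numeric(g_k))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gna <- grid$g_na[i]; gk <- grid$g_k[i]
    met <- ap_metrics(simulate_axon(params, conductances(gna, gk, params)))
    exc <- NA_character_
    if (classify && met$conducted)
      exc <- classify_excitability(conductances(gna, gk, ex_params),
                                   ex_params)$type
    data.frame(g_na = gna, g_k = gk, conducted = met$conducted,
               velocity_m_per_s = met$velocity,
               na_flux_nc_per_cm2 = met$na_flux, apd50_ms = met$apd50,
               apd90_ms = met$apd90, spike_count = met$spike_count,
               excitability = exc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("landscape", "data.frame")
  attr(out, "meta") <- meta
  if (!is.null(cache_dir)) write_landscape_cache(cache_dir, out, meta)
  out
}

empty_landscape <- function() {
  out <- data.frame(g_na = numeric(), g_k = numeric(), conducted = logical(),
                    velocity_m_per_s = numeric(),
                    na_flux_nc_per_cm2 = numeric(), apd50_ms = numeric(),
                    apd90_ms = numeric(), spike_count = integer(),
                    excitability = character(), stringsAsFactors = FALSE)
  class(out) <- c("landscape", "data.frame")
  out
}

landscape_cache_paths <- function(cache_dir) {
  list(csv = file.path(cache_dir, "landscape.csv"),
       meta = file.path(cache_dir, "landscape_meta.json"))
}

read_landscape_cache <- function(cache_dir, meta) {
  p <- landscape_cache_paths(cache_dir)
  if (!file.exists(p$csv) || !file.exists(p$meta)) return(NULL)
  stored <- jsonlite::read_json(p$meta, simplifyVector = TRUE)
  same <- isTRUE(all.equal(stored[sort(names(stored))],
                           lapply(meta, identity)[sort(names(meta))],
                           tolerance = 1e-12, check.attributes = FALSE))
  if (!same) {
    warning("landscape cache parameters differ from request; recomputing")
    return(NULL)
  }
  out <- read.csv(p$csv, stringsAsFactors = FALSE,
                  colClasses = c(excitability = "character"))
  class(out) <- c("landscape", "data.frame")
  attr(out, "meta") <- meta
  out
}

write_landscape_cache <- function(cache_dir, landscape, meta) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  p <- landscape_cache_paths(cache_dir)
  write.csv(as.data.frame(landscape), p$csv, row.names = FALSE)
  jsonlite::write_json(meta, p$meta, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' @export
print.landscape <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Conductance landscape: %d points at %g C (%d conducting)\n",
              nrow(x), if (is.null(m)) NA else m$TC, sum(x$conducted)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Piecewise-linear boundaries of the viable (G_Na, G_K) region
#'
#' Locates, by 1D bisection at a set of anchor values, the conduction
#' boundaries at the test temperature (minimum G_Na as a function of
#' G_K; minimum and maximum G_K as a function of G_Na) and optionally the
#' Type 3 excitability boundary (minimum G_K for single-spike firing,
#' classified at 6.3 C).  Between anchors the boundaries are interpolated
#' linearly; fitness evaluation at arbitrary phenotypes then needs no
#' further cable simulation.
#'
#' @param gk_anchors G_K values at which the minimum conducting G_Na is
#'   located.
#' @param gna_anchors G_Na values at which the G_K conduction window and
#'   (optionally) the Type 3 boundary are located.
#' @param TC conduction-test temperature, degrees C.
#' @param type3 also locate the Type 3/Type 2 boundary (slow).
#' @param na_bracket,k_low_bracket,k_high_bracket,type3_bracket bisection
#'   brackets, mS/cm2.
#' @return An object of class `"region_boundaries"`: interpolating
#'   functions `na_min(g_k)`, `k_min(g_na)`, `k_max(g_na)` and (if
#'   requested) `k_type3(g_na)`, plus the anchor tables.
#' @seealso [fitness_region2d()]
#' @export
region_boundaries <- function(gk_anchors = c(20, 36, 52),
                              gna_anchors = c(90, 120, 160, 200),
                              TC = 26, type3 = TRUE,
                              na_bracket = c(40, 150),
                              k_low_bracket = c(-0.5, 10),
                              k_high_bracket = c(60, 200),
                              type3_bracket = c(10, 40)) {
  na_min <- vapply(gk_anchors, function(gk)
    find_threshold("na", fixed = gk, predicate = "conducts", TC = TC,
                   bracket = na_bracket), numeric(1))
  p26 <- cable_params(TC = TC, t_total = 30)
  conducts_at <- function(gna, gk) {
    sim <- simulate_axon(p26, conductances(gna, gk, p26), record_at = 9.5,
                         stop_at_spike = 9.5)
    isTRUE(sim$stopped_early) || any(sim$v >= 0)
  }
  ref_gk <- max(min(gk_anchors), 5)
  k_window <- vapply(gna_anchors, function(gna) {
    # a G_Na line entirely outside the conducting region has no window
    if (!conducts_at(gna, ref_gk)) return(c(NA_real_, NA_real_))
    lo <- if (conducts_at(gna, max(k_low_bracket[1], 0)))
      max(k_low_bracket[1], 0)
    else find_threshold("k", fixed = gna, predicate = "conducts", TC = TC,
                        bracket = c(max(k_low_bracket[1], 0), ref_gk),
                        side = "lower")
    hi <- if (conducts_at(gna, k_high_bracket[2])) k_high_bracket[2]
    else find_threshold("k", fixed = gna, predicate = "conducts", TC = TC,
                        bracket = c(ref_gk, k_high_bracket[2]),
                        side = "upper")
    c(lo, hi)
  }, numeric(2))
  k_min <- k_window[1, ]; k_max <- k_window[2, ]
  k_t3 <- if (type3) vapply(gna_anchors, function(gna)
    find_threshold("k", fixed = gna, predicate = "type3",
                   bracket = type3_bracket, expand = TRUE),
    numeric(1)) else NULL
  ok <- !is.na(k_min)
  if (sum(ok) < 2)
    stop("fewer than two G_Na anchors intersect the conducting region")
  out <- list(
    gk_anchors = gk_anchors, gna_anchors = gna_anchors, TC = TC,
    na_min_tab = na_min, k_min_tab = k_min, k_max_tab = k_max,
    k_type3_tab = k_t3,
    na_min = approxfun(gk_anchors, na_min, rule = 2),
    k_min = approxfun(gna_anchors[ok], k_min[ok], rule = 2),
    k_max = approxfun(gna_anchors[ok], k_max[ok], rule = 2),
    k_type3 = if (type3) approxfun(gna_anchors, k_t3, rule = 2))
  class(out) <- "region_boundaries"
  out
}

#' @export
print.region_boundaries <- function(x, ...) {
  cat(sprintf("Viable-region boundaries (conduction at %g C):\n", x$TC))
  cat("  min G_Na at G_K anchors: ",
      paste(sprintf("%g->%g", x$gk_anchors, x$na_min_tab), collapse = ", "),
      "\n")
  cat("  G_K window at G_Na anchors: ",
      paste(sprintf("%g->[%g,%g]", x$gna_anchors, x$k_min_tab, x$k_max_tab),
            collapse = ", "), "\n")
  if (!is.null(x$k_type3_tab))
    cat("  Type 3 boundary: ",
        paste(sprintf("%g->%g", x$gna_anchors, x$k_type3_tab),
              collapse = ", "), "\n")
  invisible(x)
}
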