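test_that("bisection matches a brute-force integer scan of the same predicate", {
  # narrow window around the sodium conduction edge at 26 C keeps the
  # brute-force oracle affordable
  thr <- find_threshold("na", fixed = 36, predicate = "conducts", TC = 26,
                        bracket = c(62, 74))
  p <- params_26()
  conducts <- vapply(62:74, function(g) {
    sim <- simulate_axon(p, conductances(g, 36, p), record_at = 9.5,
                         stop_at_spike = 9.5)
    isTRUE(sim$stopped_early) || any(sim$v >= 0)
  }, logical(1))
  expect_equal(thr, (62:74)[which(conducts)[1]])
  # the conducting side is contiguous along the scan line
  expect_true(all(diff(conducts) >= 0))
})

test_that("find_threshold rejects brackets that do not straddle the edge", {
  expect_error(find_threshold("na", fixed = 36, predicate = "conducts",
                              TC = 26, bracket = c(100, 140)),
               "does not change")
})

test_that("velocity curve flags non-conducting points and finds its peak", {
  expect_warning(
    curve <- velocity_curve("na", fixed = 36, range = c(55, 105), step = 10,
                            TC = 26, t_total = 30),
    "non-conducting")
  expect_true(any(!curve$conducted))
  expect_true(all(is.na(curve$velocity_m_per_s[!curve$conducted])))

  curve <- velocity_curve("k", fixed = 120, range = c(10, 80), step = 10)
  expect_true(all(curve$conducted))
  # velocity declines steadily with increasing potassium conductance
  expect_true(all(diff(curve$velocity_m_per_s) < 0))
})

test_that("sodium flux per action potential rises with sodium conductance", {
  curve <- velocity_curve("na", fixed = 36, range = c(85, 300), step = 43)
  expect_true(all(diff(curve$na_flux_nc_per_cm2) > 0))
})

test_that("velocity_peak refines the grid argmax quadratically", {
  g <- seq(100, 200, by = 10)
  fake <- data.frame(g_na = g, g_k = 36, conducted = TRUE,
                     velocity_m_per_s = 25 - (g - 143)^2 / 1000)
  attr(fake, "axis") <- "na"
  class(fake) <- c("conductance_sweep", "data.frame")
  pk <- velocity_peak(fake)
  expect_equal(pk$g_grid, 140)
  expect_equal(pk$g, 143, tolerance = 1e-6)
})

test_that("landscape tables cache losslessly and recompute on mismatch", {
  cache <- withr::local_tempdir()
  ls1 <- build_landscape(c(100, 120), c(30, 40), TC = 18.5, t_total = 8,
                         cache_dir = cache)
  expect_s3_class(ls1, "landscape")
  expect_equal(nrow(ls1), 4)
  expect_true(all(ls1$conducted))

  ls2 <- build_landscape(c(100, 120), c(30, 40), TC = 18.5, t_total = 8,
                         cache_dir = cache)
  expect_equal(as.data.frame(ls1), as.data.frame(ls2))

  expect_warning(
    ls3 <- build_landscape(c(100, 120), c(30, 45), TC = 18.5, t_total = 8,
                           cache_dir = cache),
    "cache")
  expect_equal(sort(unique(ls3$g_k)), c(30, 45))

  expect_equal(nrow(build_landscape(numeric(0), numeric(0))), 0)
})
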