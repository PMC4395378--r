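# a smooth stand-in velocity curve: rises from the cliff, plateaus, dips
fake_na_curve <- function() {
  g <- seq(85, 500, by = 5)
  v <- 21 + 4 * (1 - exp(-(g - 85) / 120)) - ((g - 465) / 400)^2
  out <- data.frame(g_na = g, g_k = 36, conducted = TRUE,
                    velocity_m_per_s = v)
  attr(out, "axis") <- "na"
  class(out) <- c("conductance_sweep", "data.frame")
  out
}

fake_k_curve <- function() {
  g <- seq(4, 80, by = 2)
  out <- data.frame(g_na = 120, g_k = g, conducted = TRUE,
                    velocity_m_per_s = 22 - 0.05 * g,
                    apd90_ms = 0.3 + 6 / g, apd50_ms = 0.15 + 3 / g)
  attr(out, "axis") <- "k"
  class(out) <- c("conductance_sweep", "data.frame")
  out
}

test_that("fitness cliffs are step functions with inclusive survival", {
  f <- fitness_cliff(81)
  expect_equal(f(c(80, 81, 85)), c(0, 1, 1))
  expect_equal(f(c(-10, 0)), c(0, 0))
  f24 <- fitness_cliff(24)
  expect_equal(f24(c(22, 24, 36)), c(0, 1, 1))
  f_below <- fitness_cliff(88, side = "below")
  expect_equal(f_below(c(88, 90)), c(1, 0))
})

test_that("velocity fitness is a rescaled monotone curve over the cliff", {
  f <- fitness_velocity(fake_na_curve(), floor = 0.95, cliff = 85)
  expect_equal(f(80), 0)
  g <- seq(85, 465, by = 5)
  vals <- f(g)
  expect_true(all(vals >= 0.95 & vals <= 1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_error(fitness_velocity(fake_na_curve(), floor = 1.2, cliff = 85),
               "floor")
})

test_that("velocity-minus-cost has a single interior optimum at fitness 1", {
  curve <- fake_na_curve()
  f <- fitness_velocity_cost(curve, cost_slope = 0.012, floor = 0,
                             cliff = 85)
  g <- seq(85, 500, by = 1)
  vals <- f(g)
  expect_true(all(vals >= 0 & vals <= 1))
  i <- which.max(vals)
  expect_gt(g[i], 85); expect_lt(g[i], 465)
  expect_equal(vals[i], 1, tolerance = 1e-9)
  # single interior maximum: rises then falls
  expect_true(all(diff(vals[seq_len(i)]) >= -1e-9))
  expect_true(all(diff(vals[i:length(vals)]) <= 1e-9))

  # zero cost slope reduces to the velocity fitness
  f0 <- fitness_velocity_cost(curve, cost_slope = 0, floor = 0.95,
                              cliff = 85)
  fv <- fitness_velocity(curve, floor = 0.95, cliff = 85)
  expect_equal(f0(seq(85, 500, 7)), fv(seq(85, 500, 7)), tolerance = 1e-12)
})

test_that("APD fitness rewards brief spikes above the repolarization cliff", {
  f <- fitness_apd(fake_k_curve(), floor = 0.9, cliff = 3)
  expect_equal(f(2), 0)
  g <- seq(4, 80, by = 2)
  vals <- f(g)
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= 0.9 & vals <= 1))
})

test_that("all fitness values stay in [0, 1], including negative phenotypes", {
  fns <- list(fitness_cliff(81),
              fitness_velocity(fake_na_curve(), 0.95, 85),
              fitness_velocity_cost(fake_na_curve(), 0.012, 0, 85),
              fitness_apd(fake_k_curve(), 0.9, 3))
  x <- c(-50, -1, 0, 2.5, 81, 120, 465, 1e4)
  for (f in fns) {
    v <- f(x)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("cliff-plus-noise survival matches the exact binomial tail", {
  # genotype k noise-sd units above the cliff: survival probability is
  # the upper tail of the (zero-centred, step-scaled) binomial
  threshold <- 85
  step <- 5; n_noise <- 28
  f <- fitness_cliff(threshold)
  set.seed(31)
  for (d_steps in c(0, 1, 3)) {
    geno <- threshold + d_steps * step
    ph <- phenotype_value(rep(geno / (2 * step), 4e4),
                          rep(geno / (2 * step), 4e4),
                          step = step, n_noise = n_noise)
    surv <- mean(f(ph))
    # survive iff Binomial(28, 1/2) >= 14 - d_steps
    exact <- 1 - pbinom(14 - d_steps - 1, n_noise, 0.5)
    expect_equal(surv, exact, tolerance = 4 * sqrt(exact * (1 - exact) / 4e4) + 1e-3)
  }
})

test_that("2D region fitness is the indicator of the viable region", {
  bnd <- structure(list(
    gk_anchors = c(10, 60), gna_anchors = c(60, 200), TC = 26,
    na_min_tab = c(70, 66), k_min_tab = c(2, 2), k_max_tab = c(120, 122),
    k_type3_tab = c(14, 34),
    na_min = approxfun(c(10, 60), c(70, 66), rule = 2),
    k_min = approxfun(c(60, 200), c(2, 2), rule = 2),
    k_max = approxfun(c(60, 200), c(120, 122), rule = 2),
    k_type3 = approxfun(c(60, 200), c(14, 34), rule = 2)),
    class = "region_boundaries")
  f <- fitness_region2d(bnd)
  expect_equal(f(cbind(120, 36)), 1)          # inside
  expect_equal(f(cbind(120, 10)), 0)          # Type 2 side
  expect_equal(f(cbind(0, 36)), 0)            # conduction failure
  expect_equal(f(cbind(c(120, 0), c(36, 36))), c(1, 0))
  expect_warning(v <- f(cbind(120, 150)), "outside")  # above the K window
  expect_equal(v, 0)
})

test_that("fitness functions tabulate for export", {
  f <- fitness_cliff(24)
  tab <- tabulate_fitness(f, c(20, 24, 30))
  expect_named(tab, c("phenotype", "fitness"))
  expect_equal(tab$fitness, c(0, 1, 1))
})
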