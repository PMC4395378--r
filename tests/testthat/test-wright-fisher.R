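test_that("initial population is centred on the starting mean with binomial spread", {
  cfg <- evolution_config(list(wf_locus("na", 5, 120)), N = 4000)
  set.seed(42)
  pop <- init_population(cfg)
  a <- pop[[1]]
  expect_length(a, 8000)
  expect_true(all(a >= 0))
  # mean allele 12, spread Binomial(6, 1/2) centred -> sd sqrt(1.5)
  expect_equal(mean(a), 12, tolerance = 0.02)
  expect_equal(sd(a), sqrt(6 * 0.25), tolerance = 0.05)
  # mean phenotype 120 mS/cm2
  expect_equal(mean(genotype_phenotypes(pop, cfg, 1)), 120, tolerance = 1)

  # zero spread variant: every allele identical
  cfg0 <- evolution_config(list(wf_locus("k", 2, 36)), N = 100,
                           init_spread_n = 0)
  pop0 <- init_population(cfg0)
  expect_true(all(pop0[[1]] == 9L))
  expect_equal(unique(genotype_phenotypes(pop0, cfg0, 1)), 36)
})

test_that("mutation moves alleles one step with the printed bias and floor", {
  a <- rep(5L, 1e5)
  expect_identical(mutate_alleles(a, mu = 0), a)

  set.seed(7)
  b <- mutate_alleles(a, mu = 0.01, bias = 0.9)
  expect_true(all(abs(b - a) <= 1))
  # expected displacement mu (0.1 - 0.9) = -0.008 steps per generation
  expect_lt(abs(mean(b - a) + 0.008), 0.002)
  expect_lt(abs(mean(b != a) - 0.01), 0.002)

  # the floor absorbs down-mutations at 0
  z <- mutate_alleles(rep(0L, 1e4), mu = 1, bias = 1)
  expect_true(all(z == 0L))
})

test_that("phenotype mapping sums alleles and adds calibrated binomial noise", {
  expect_equal(phenotype_value(12, 12, step = 5), 120)
  expect_equal(phenotype_value(18, 18, step = 2), 72)
  expect_equal(phenotype_value(c(0, 3), c(0, 4), step = 5), c(0, 35))

  set.seed(11)
  # sodium noise n = 28: sd = 5 sqrt(28/4) = 13.2 mS/cm2
  ph <- phenotype_value(rep(12, 2e4), rep(12, 2e4), step = 5, n_noise = 28)
  expect_equal(mean(ph), 120, tolerance = 0.5)
  expect_equal(sd(ph), 13.2, tolerance = 0.3)
  # potassium noise n = 16: sd = 2 sqrt(16/4) = 4.0 mS/cm2
  ph <- phenotype_value(rep(9, 2e4), rep(9, 2e4), step = 2, n_noise = 16)
  expect_equal(sd(ph), 4.0, tolerance = 0.1)
  # clamped at zero
  expect_true(all(phenotype_value(rep(0, 1e3), rep(0, 1e3), 5, 28) >= 0))
  expect_error(wf_locus("na", 5, 120, n_noise = 7), "even")
})

test_that("allele counts are conserved and runs are seed deterministic", {
  cfg <- evolution_config(list(wf_locus("na", 5, 60)), N = 300)
  r1 <- run_evolution(cfg, fitness_cliff(40), generations = 40, seed = 5)
  expect_length(r1$final[[1]], 600)
  expect_true(all(r1$final[[1]] >= 0))
  expect_equal(nrow(r1$trajectory), 41)

  r2 <- run_evolution(cfg, fitness_cliff(40), generations = 40, seed = 5)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final, r2$final)
  r3 <- run_evolution(cfg, fitness_cliff(40), generations = 40, seed = 6)
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("neutral evolution declines at the mutation-pressure rate", {
  # expected change in mean allele: mu (0.1 - 0.9) = -0.008 steps/gen,
  # i.e. -0.08 mS/cm2 per generation for the two-allele sodium phenotype
  cfg <- evolution_config(list(wf_locus("na", 5, 120)), N = 2000)
  run <- run_evolution(cfg, fitness_flat(), generations = 250, seed = 2)
  tr <- run$trajectory
  slope <- coef(lm(mean_na ~ generation, tr))[2]
  expect_lt(abs(unname(slope) + 0.08), 0.025)
})

test_that("loci are inherited and evolve independently", {
  f_na_only <- structure(function(x) as.numeric(rbind(x)[, 1] >= 100),
                         class = "fitness_fn", domain = "2d",
                         tag = "cliff on locus 1 only")
  cfg <- evolution_config(list(wf_locus("na", 5, 120),
                               wf_locus("k", 2, 36)), N = 1000)
  k_slopes <- vapply(3:5, function(s) {
    run <- run_evolution(cfg, f_na_only, generations = 250, seed = s)
    tr <- run$trajectory
    # locus 1 is held up by its cliff throughout
    expect_gt(tr$mean_na[nrow(tr)], 100)
    unname(coef(lm(mean_k ~ generation, tr))[2])
  }, numeric(1))
  # locus 2 decays by pure mutation pressure, as if neutral
  expect_lt(abs(mean(k_slopes) + 0.032), 0.015)
})

test_that("an unreachable fitness requirement aborts as extinction", {
  cfg <- evolution_config(list(wf_locus("na", 5, 20)), N = 50)
  expect_error(
    run_evolution(cfg, fitness_cliff(5000), generations = 2, seed = 1),
    "extinction")
})

test_that("replicate summaries average the final means", {
  cfg <- evolution_config(list(wf_locus("na", 5, 50)), N = 200)
  rep <- replicate_evolution(cfg, fitness_cliff(30), generations = 50,
                             replicates = 3, seed_base = 10)
  expect_equal(dim(rep$finals), c(3, 1))
  expect_equal(unname(rep$mean["na"]), mean(rep$finals[, "na"]))
  expect_true(rep$sd["na"] >= 0)
})

test_that("final histograms reflect genotype and noise-inclusive phenotypes", {
  cfg <- evolution_config(list(wf_locus("na", 5, 80, n_noise = 28)), N = 400)
  run <- run_evolution(cfg, fitness_flat(), generations = 5, seed = 9)
  h0 <- final_histogram(run, "na", noise = FALSE)
  expect_equal(sum(h0$count), 400)
  expect_true(all(h0$phenotype %% 5 == 0))   # genotype grid only
  set.seed(1)
  h1 <- final_histogram(run, "na", noise = TRUE)
  expect_equal(sum(h1$count), 400)
  expect_gt(sd(rep(h1$phenotype, h1$count)), sd(rep(h0$phenotype, h0$count)))
})
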