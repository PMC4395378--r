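test_that("transition probabilities are a proper distribution", {
  d <- exact_transition_distribution(c("1" = 2, "2" = 3, "3" = 1), step = 5,
                                     mu = 0.01, bias = 0.9,
                                     fitness = fitness_cliff(15))
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_true(all(d$prob > 0))
  counts <- as.matrix(d[grep("^n_", names(d))])
  expect_true(all(rowSums(counts) == 6))
  q <- attr(d, "pair_distribution")
  expect_equal(sum(q$prob), 1, tolerance = 1e-12)
})

test_that("neutral no-mutation case matches brute-force pair enumeration", {
  # independent oracle: enumerate every ordered draw of N = 2 offspring
  # pairs explicitly
  counts <- c("0" = 1, "1" = 2, "2" = 1)
  vals <- as.integer(names(counts))
  two_n <- sum(counts)
  copies <- rep(vals, counts)
  states <- new.env(parent = emptyenv())
  for (i in seq_len(two_n)) for (j in seq_len(two_n)) {
    if (j == i) next
    for (k in seq_len(two_n)) for (l in seq_len(two_n)) {
      if (l == k) next
      tab <- integer(3)
      for (a in copies[c(i, j, k, l)]) tab[a + 1] <- tab[a + 1] + 1
      key <- paste(tab, collapse = ",")
      states[[key]] <- (if (is.null(states[[key]])) 0 else states[[key]]) +
        1 / (two_n * (two_n - 1))^2
    }
  }
  d <- exact_transition_distribution(counts, step = 5, mu = 0, bias = 0.9,
                                     fitness = fitness_flat())
  for (r in seq_len(nrow(d))) {
    key <- paste(d$n_0[r], d$n_1[r], d$n_2[r], sep = ",")
    expect_equal(d$prob[r], states[[key]], tolerance = 1e-12)
  }
  expect_equal(attr(d, "acceptance"), 1)
})

test_that("selection renormalizes the accepted-pair distribution", {
  # a cliff that only the (2,2) pair survives
  d <- exact_transition_distribution(c("1" = 4, "2" = 2), step = 5, mu = 0,
                                     bias = 0.9,
                                     fitness = fitness_cliff(20))
  # every offspring must be the homozygous pair of the two allele-2 copies
  expect_equal(nrow(d), 1)
  expect_equal(d$n_2, 6)
  expect_equal(d$prob, 1)
  # acceptance probability: P(draw both 2-copies) = (2/6)(1/5)
  expect_equal(attr(d, "acceptance"), 2 / 6 * 1 / 5, tolerance = 1e-12)
})

test_that("enumeration guards reject intractable states", {
  big <- setNames(rep(2L, 2), c("1", "2"))
  expect_error(exact_transition_distribution(setNames(20L, "1"), 5, 0.01),
               "N <= 6")
  expect_error(exact_transition_distribution(c("1" = 2), 5, 0.01,
                                             fitness = fitness_cliff(1e4)),
               "positive fitness")
  expect_silent(exact_transition_distribution(big, 5, 0.01))
})

test_that("Monte-Carlo one-generation frequencies match the exact law", {
  # moderate replication here; the full-scale comparison runs in the
  # acceptance suite
  counts <- c("2" = 3, "3" = 2, "4" = 1)
  cfg <- evolution_config(list(wf_locus("na", 5, 30)), N = 3, mu = 0.05)
  f <- fitness_cliff(25)
  d <- exact_transition_distribution(counts, step = 5, mu = 0.05, bias = 0.9,
                                     fitness = f)
  pop0 <- structure(list(na = rep(c(2L, 3L, 4L), c(3, 2, 1))),
                    class = "wf_population", N = 3L)
  set.seed(17)
  n_rep <- 2e4
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(n_rep)) {
    nxt <- next_generation(pop0, cfg, f)
    tab <- table(factor(nxt[[1]], levels = 0:8))
    key <- paste(tab, collapse = ",")
    seen[[key]] <- (if (is.null(seen[[key]])) 0 else seen[[key]]) + 1
  }
  vals_all <- 0:8
  for (r in seq_len(nrow(d))) {
    if (d$prob[r] < 5e-3) next
    cnt <- integer(9)
    for (nm in grep("^n_", names(d), value = TRUE))
      cnt[match(as.integer(sub("n_", "", nm)), vals_all)] <- d[[nm]][r]
    key <- paste(cnt, collapse = ",")
    obs <- (if (is.null(seen[[key]])) 0 else seen[[key]]) / n_rep
    se <- sqrt(d$prob[r] * (1 - d$prob[r]) / n_rep)
    expect_lt(abs(obs - d$prob[r]), 4 * se + 1e-4)
  }
})
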