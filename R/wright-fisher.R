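#' One channel locus of the regulatory-evolution model
#'
#' An allele is a non-negative integer summarizing the combined strength
#' of the promoter and cis-regulatory modules of one channel-gene copy.
#' An allele of strength `n` contributes `step * n` mS/cm2 of peak
#' conductance (step 5 for the sodium channel, 2 for potassium); the two
#' alleles of a diploid individual are summed.  Phenotypic noise, when
#' present, is a zero-centred binomial added on the conductance scale:
#' `step * (Binomial(n_noise, 1/2) - n_noise/2)`, with standard deviation
#' `step * sqrt(n_noise) / 2`.
#'
#' @param name locus label (e.g. `"na"`, `"k"`).
#' @param step conductance per allele unit, mS/cm2.
#' @param start_mean initial population-mean phenotype, mS/cm2.  The mean
#'   allele value is `start_mean / (2 * step)`.
#' @param n_noise number of trials of the zero-centred binomial noise
#'   (even; 0 disables noise).
#' @return A `wf_locus` list.
#' @export
wf_locus <- function(name, step, start_mean, n_noise = 0) {
  stopifnot(step > 0, start_mean >= 0, n_noise >= 0,
            n_noise == round(n_noise))
  if (n_noise %% 2 != 0)
    stop("`n_noise` must be even so the noise is integer-centred")
  structure(list(name = name, step = step, start_mean = start_mean,
                 n_noise = as.integer(n_noise)), class = "wf_locus")
}

#' Configuration of one evolutionary run
#'
#' Defaults follow the standard simulation conditions: population size
#' 5000, per-allele mutation rate 1e-2 per generation, and a 0.9
#' probability that a mutation weakens regulatory function (one allele
#' step down) versus 0.1 that it strengthens it.  Initial allelic
#' variation is `Binomial(6, 1/2)` centred on the starting mean allele.
#'
#' @param loci list of [wf_locus()] objects (one or two loci; loci are
#'   inherited independently).
#' @param N diploid population size.
#' @param mu per-allele mutation probability per generation.
#' @param bias probability that a mutation decreases allele strength
#'   (must exceed 1/2 and be below 1).
#' @param init_spread_n,init_spread_p binomial parameters of the initial
#'   allele spread around the starting mean.
#' @return An `evolution_config` object.
#' @examples
#' cfg <- evolution_config(list(wf_locus("na", 5, 120)))
#' @export
evolution_config <- function(loci, N = 5000, mu = 1e-2, bias = 0.9,
                             init_spread_n = 6, init_spread_p = 0.5) {
  if (inherits(loci, "wf_locus")) loci <- list(loci)
  stopifnot(length(loci) >= 1,
            all(vapply(loci, inherits, logical(1), "wf_locus")),
            N >= 2, mu > 0 || mu == 0, mu < 1, bias > 0.5, bias < 1)
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  structure(list(loci = loci, N = as.integer(N), mu = mu, bias = bias,
                 init_spread_n = init_spread_n,
                 init_spread_p = init_spread_p),
            class = "evolution_config")
}

#' @export
print.evolution_config <- function(x, ...) {
  cat(sprintf("Evolution configuration: N = %d, mu = %g, downward bias = %g\n",
              x$N, x$mu, x$bias))
  for (l in x$loci)
    cat(sprintf(
      "  locus %s: step %g mS/cm2, start mean %g mS/cm2, noise n = %d (sd %.2f)\n",
      l$name, l$step, l$start_mean, l$n_noise,
      l$step * sqrt(l$n_noise) / 2))
  invisible(x)
}

#' Initialize the allele pool
#'
#' Each of the `2N` allele copies per locus is drawn as
#' `mean_allele - n p + Binomial(n, p)` (defaults `n = 6`, `p = 1/2`),
#' clamped at 0, so the pool is centred on the starting mean with
#' pre-existing regulatory variation.
#'
#' @param config an [evolution_config()].
#' @return A `wf_population`: a list with one integer vector of length
#'   `2N` per locus (copies `2i-1` and `2i` belong to individual `i`).
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "evolution_config"))
  pool <- lapply(config$loci, function(l) {
    mean_allele <- round(l$start_mean / (2 * l$step))
    centre <- round(config$init_spread_n * config$init_spread_p)
    draws <- rbinom(2L * config$N, config$init_spread_n,
                    config$init_spread_p)
    pmax(0L, as.integer(mean_allele - centre + draws))
  })
  structure(pool, class = "wf_population", N = config$N)
}

#' Mutate a vector of alleles
#'
#' Each allele independently mutates with probability `mu`; a mutation
#' moves the allele one step down with probability `bias` (weakened
#' regulatory function) or one step up otherwise.  Down-mutations at 0
#' are absorbed (regulatory strength cannot go negative).
#'
#' @param alleles integer vector of allele strengths.
#' @param mu per-allele mutation probability.
#' @param bias probability that a mutation is a down step.
#' @return Mutated integer vector.
#' @export
mutate_alleles <- function(alleles, mu, bias = 0.9) {
  if (mu == 0) return(alleles)
  n <- length(alleles)
  hit <- runif(n) < mu
  if (!any(hit)) return(alleles)
  dir <- ifelse(runif(sum(hit)) < bias, -1L, 1L)
  alleles[hit] <- pmax(0L, alleles[hit] + dir)
  alleles
}

#' Phenotype of an allele pair
#'
#' `step * (a1 + a2)` plus, when `n_noise > 0`, the zero-centred binomial
#' phenotypic noise on the conductance scale, clamped at 0 (conductance
#' cannot be negative).
#'
#' @param a1,a2 allele strengths (vectors).
#' @param step conductance per allele unit, mS/cm2.
#' @param n_noise binomial noise trials (even; 0 = deterministic map).
#' @return Conductance phenotype(s), mS/cm2.
#' @export
phenotype_value <- function(a1, a2, step, n_noise = 0) {
  ph <- step * (a1 + a2)
  if (n_noise > 0)
    ph <- ph + step * (rbinom(length(ph), n_noise, 0.5) - n_noise / 2)
  pmax(ph, 0)
}

#' Advance the population one generation
#'
#' The reproduction cycle: two allele copies per locus are drawn for each
#' candidate offspring from the parental gamete pool without replacement
#' of the same copy (the pool is restored between candidates); the drawn
#' alleles are mutated; the phenotype (with fresh phenotypic noise per
#' candidate) is computed; and the candidate survives with probability
#' equal to its fitness.  Rejected candidates are discarded entirely and
#' redrawn; the cycle repeats until `N` offspring survive.  Loci are
#' inherited independently.
#'
#' @param pop a `wf_population`.
#' @param config the [evolution_config()].
#' @param fitness a `fitness_fn` (domain `"1d"` for one locus, `"2d"`
#'   for two loci in the order of `config$loci`).
#' @return The next-generation `wf_population`.
#' @export
next_generation <- function(pop, config, fitness) {
  N <- config$N
  two_n <- 2L * N
  n_loci <- length(config$loci)
  twod <- attr(fitness, "domain") == "2d"
  if (twod && n_loci != 2L)
    stop("2D fitness requires exactly two loci")

  kept <- vector("list", n_loci)
  for (j in seq_len(n_loci)) kept[[j]] <- vector("list", 0L)
  got <- 0L
  tried <- 0L
  batch <- N + ceiling(N / 4)
  while (got < N) {
    draw <- vector("list", n_loci)
    ph <- vector("list", n_loci)
    for (j in seq_len(n_loci)) {
      pool <- pop[[j]]
      i1 <- sample.int(two_n, batch, replace = TRUE)
      i2 <- sample.int(two_n - 1L, batch, replace = TRUE)
      i2 <- i2 + (i2 >= i1)
      a1 <- mutate_alleles(pool[i1], config$mu, config$bias)
      a2 <- mutate_alleles(pool[i2], config$mu, config$bias)
      draw[[j]] <- list(a1 = a1, a2 = a2)
      ph[[j]] <- phenotype_value(a1, a2, config$loci[[j]]$step,
                                 config$loci[[j]]$n_noise)
    }
    w <- if (twod) fitness(cbind(ph[[1]], ph[[2]])) else fitness(ph[[1]])
    acc <- which(runif(batch) < w)
    tried <- tried + batch
    if (length(acc)) {
      take <- acc[seq_len(min(length(acc), N - got))]
      for (j in seq_len(n_loci))
        kept[[j]][[length(kept[[j]]) + 1L]] <-
          rbind(draw[[j]]$a1[take], draw[[j]]$a2[take])
      got <- got + length(take)
    }
    if ((got == 0L && tried >= 2e5) ||
        (tried >= 2e6 && got / tried < 1e-6))
      stop("population extinction: acceptance probability below 1e-6 -- ",
           "fitness function incompatible with reachable phenotypes")
    rate <- max(got / tried, 0.02)
    batch <- min(ceiling((N - got) / rate * 1.1) + 16L, 8L * N)
  }
  out <- vector("list", n_loci)
  for (j in seq_len(n_loci)) {
    mat <- do.call(cbind, kept[[j]])     # 2 x N matrix of allele pairs
    out[[j]] <- as.integer(mat)          # interleaves a1, a2 per individual
  }
  names(out) <- names(pop)
  structure(out, class = "wf_population", N = N)
}

#' Run the evolutionary simulation
#'
#' Iterates [next_generation()] for the requested number of generations,
#' recording the per-generation mean and standard deviation of the
#' genotype-determined phenotype (conductance without phenotypic noise)
#' at each locus.  Given a seed the trajectory is fully reproducible.
#'
#' @param config an [evolution_config()].
#' @param fitness a `fitness_fn`; use `fitness_flat()` for neutral runs.
#' @param generations number of generations to simulate.
#' @param seed optional RNG seed for the run.
#' @param keep_every record the trajectory every this many generations
#'   (generation 0 and the final generation are always recorded).
#' @return An object of class `"wf_evolution"`: the trajectory data
#'   frame (`generation`, then `mean_` and `sd_` columns per locus), the
#'   final population, and the configuration.
#' @examples
#' cfg <- evolution_config(list(wf_locus("na", 5, 120)), N = 200)
#' run <- run_evolution(cfg, fitness_cliff(81), generations = 100, seed = 1)
#' coef(run)
#' @export
run_evolution <- function(config, fitness, generations, seed = NULL,
                          keep_every = 1L) {
  stopifnot(inherits(config, "evolution_config"),
            inherits(fitness, "fitness_fn"), generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  pop <- init_population(config)
  rec_gens <- unique(c(seq(0L, generations, by = keep_every), generations))
  n_loci <- length(config$loci)
  traj <- matrix(NA_real_, nrow = length(rec_gens), ncol = 1 + 2 * n_loci)
  rec_row <- function(row, gen) {
    stats <- unlist(lapply(seq_len(n_loci), function(j) {
      ph <- genotype_phenotypes(pop, config, j)
      c(mean(ph), sd(ph))
    }))
    traj[row, ] <<- c(gen, stats)
  }
  rec_row(1L, 0L)
  row <- 2L
  for (gen in seq_len(generations)) {
    pop <- next_generation(pop, config, fitness)
    if (gen == rec_gens[row]) {
      rec_row(row, gen)
      row <- row + 1L
    }
  }
  traj <- as.data.frame(traj)
  names(traj) <- c("generation",
                   unlist(lapply(names(config$loci), function(nm)
                     paste0(c("mean_", "sd_"), nm))))
  structure(list(trajectory = traj, final = pop, config = config,
                 fitness_tag = attr(fitness, "tag"), seed = seed,
                 generations = generations),
            class = "wf_evolution")
}

# phenotypes implied by the genotype alone (no noise), per individual
genotype_phenotypes <- function(pop, config, j) {
  a <- pop[[j]]
  config$loci[[j]]$step * (a[c(TRUE, FALSE)] + a[c(FALSE, TRUE)])
}

#' Neutral (flat) fitness
#'
#' Survival probability 1 everywhere: evolution under mutation and drift
#' only.
#' @param domain `"1d"` or `"2d"`.
#' @return A `fitness_fn`.
#' @export
fitness_flat <- function(domain = "1d") {
  f <- if (domain == "2d") function(x) rep(1, nrow(rbind(x)))
       else function(x) rep(1, length(x))
  new_fitness_fn(f, domain, "neutral (no selection)")
}

#' @export
print.wf_evolution <- function(x, ...) {
  cat(sprintf(
    "Wright-Fisher run: N = %d, %d generations, mu = %g (bias %g)\n",
    x$config$N, x$generations, x$config$mu, x$config$bias))
  cat(sprintf("  selection: %s\n", x$fitness_tag))
  fin <- coef(x)
  cat("  final mean phenotype (mS/cm2):",
      paste(sprintf("%s = %.2f", names(fin), fin), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.wf_evolution <- function(object, ...) {
  tr <- object$trajectory
  fin <- tr[nrow(tr), grep("^mean_", names(tr)), drop = FALSE]
  setNames(as.numeric(fin), sub("^mean_", "", names(fin)))
}

#' @export
summary.wf_evolution <- function(object, tail_frac = 0.5, ...) {
  tr <- object$trajectory
  tail_rows <- tr$generation >= (1 - tail_frac) * max(tr$generation)
  mean_cols <- grep("^mean_", names(tr), value = TRUE)
  out <- list(final = coef(object),
              tail_mean = colMeans(tr[tail_rows, mean_cols, drop = FALSE]),
              tail_sd = vapply(tr[tail_rows, mean_cols, drop = FALSE], sd,
                               numeric(1)),
              generations = object$generations, N = object$config$N,
              fitness_tag = object$fitness_tag)
  class(out) <- "summary.wf_evolution"
  out
}

#' @export
print.summary.wf_evolution <- function(x, ...) {
  cat(sprintf("Wright-Fisher summary (N = %d, %d generations; %s)\n",
              x$N, x$generations, x$fitness_tag))
  for (nm in names(x$final))
    cat(sprintf(
      "  %s: final mean %.2f mS/cm2; late-run mean %.2f (sd of mean %.2f)\n",
      nm, x$final[nm], x$tail_mean[paste0("mean_", nm)],
      x$tail_sd[paste0("mean_", nm)]))
  invisible(x)
}

#' @export
plot.wf_evolution <- function(x, ...) {
  tr <- x$trajectory
  mean_cols <- grep("^mean_", names(tr), value = TRUE)
  matplot(tr$generation, tr[mean_cols], type = "l", lty = 1,
          xlab = "generation", ylab = "mean conductance (mS/cm2)", ...)
  legend("topright", legend = sub("^mean_", "", mean_cols),
         col = seq_along(mean_cols), lty = 1, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.wf_evolution <- function(x, ...) x$trajectory

#' Final-population phenotype histogram
#'
#' Counts of the phenotype distribution of the final population, either
#' mapped directly from genotype or with one draw of phenotypic noise
#' added per individual (the distribution that selection acts on).
#'
#' @param run a `wf_evolution` object.
#' @param locus locus name or index.
#' @param noise add one phenotypic-noise draw per individual.
#' @return Data frame with `phenotype` and `count`.
#' @export
final_histogram <- function(run, locus = 1, noise = FALSE) {
  stopifnot(inherits(run, "wf_evolution"))
  j <- if (is.character(locus)) match(locus, names(run$config$loci))
       else locus
  l <- run$config$loci[[j]]
  a <- run$final[[j]]
  ph <- if (noise)
    phenotype_value(a[c(TRUE, FALSE)], a[c(FALSE, TRUE)], l$step, l$n_noise)
  else genotype_phenotypes(run$final, run$config, j)
  tab <- table(ph)
  data.frame(phenotype = as.numeric(names(tab)),
             count = as.integer(tab))
}

#' Replicated evolutionary runs
#'
#' Runs [run_evolution()] `replicates` times with seeds `seed_base + 1 :
#' replicates` and summarizes the final means.
#'
#' @inheritParams run_evolution
#' @param replicates number of independent runs.
#' @param seed_base seeds are `seed_base + replicate index`.
#' @return List with per-replicate final means (`finals`, a matrix with
#'   one row per replicate), their across-replicate `mean` and `sd`, and
#'   the individual runs (invisibly heavy; only trajectories retained).
#' @export
replicate_evolution <- function(config, fitness, generations, replicates = 3,
                                seed_base = 0, keep_every = 10L) {
  finals <- NULL
  trajs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    run <- run_evolution(config, fitness, generations,
                         seed = seed_base + r, keep_every = keep_every)
    finals <- rbind(finals, coef(run))
    trajs[[r]] <- run$trajectory
  }
  list(finals = finals, mean = colMeans(finals),
       sd = apply(finals, 2, sd), trajectories = trajs)
}
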