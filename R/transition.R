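#' Exact one-generation transition distribution (small populations)
#'
#' For a single locus without phenotypic noise, enumerates the exact
#' probability distribution of the next generation's allele-count vector
#' under the full reproduction cycle: the first allele copy is drawn from
#' the parental pool, the second from the pool minus that copy (without
#' replacement of the same copy), both are mutated (one step down with
#' probability `bias * mu`, up with `(1 - bias) * mu`, down-mutations at
#' 0 absorbed), and the pair is accepted with probability equal to the
#' fitness of its phenotype.  The `N` surviving offspring are independent
#' draws from the accepted-pair distribution, so the next-generation
#' counts are the sum of `N` i.i.d. pair contributions, enumerated
#' exactly.  This distribution is the oracle against which the
#' Monte-Carlo simulator ([next_generation()]) is validated.
#'
#' Only small states are tractable: the enumeration is guarded at
#' `N <= 6` and at most 6 distinct allele values (after mutation).
#'
#' @param counts named integer vector: number of copies of each allele
#'   value in the current pool.  Names are the allele strengths (e.g.
#'   `c("3" = 2, "4" = 4)`); the total must be `2N`.
#' @param step conductance per allele unit, mS/cm2.
#' @param mu per-allele mutation probability.
#' @param bias probability that a mutation is a down step.
#' @param fitness a 1D `fitness_fn` applied to `step * (a1 + a2)`.
#' @return A data frame with one row per reachable next-generation state:
#'   columns `n_<value>` (copy counts per allele value) and `prob`.
#'   Probabilities sum to 1.  The attribute `"pair_distribution"` holds
#'   the accepted-pair probabilities; `"acceptance"` the per-candidate
#'   acceptance probability.
#' @examples
#' f <- fitness_flat()
#' d <- exact_transition_distribution(c("1" = 2, "2" = 4), step = 5,
#'                                    mu = 0, bias = 0.9, fitness = f)
#' sum(d$prob)  # 1
#' @export
exact_transition_distribution <- function(counts, step, mu, bias = 0.9,
                                          fitness = fitness_flat()) {
  stopifnot(inherits(fitness, "fitness_fn"),
            attr(fitness, "domain") == "1d",
            all(counts >= 0), sum(counts) %% 2 == 0)
  vals <- as.integer(names(counts))
  if (anyNA(vals)) stop("`counts` must be named by allele value")
  counts <- as.integer(counts)
  two_n <- sum(counts)
  N <- two_n / 2L
  if (N > 6) stop("exact enumeration is guarded at N <= 6")

  # mutation outcome distribution for one allele of value a
  mut_dist <- function(a) {
    if (a == 0L) {
      # a down-mutation at 0 is absorbed at 0
      v <- c(0L, 1L); p <- c(1 - mu + bias * mu, (1 - bias) * mu)
    } else {
      v <- c(a - 1L, a, a + 1L)
      p <- c(bias * mu, 1 - mu, (1 - bias) * mu)
    }
    keep <- p > 0
    list(v = v[keep], p = p[keep])
  }

  # joint distribution over ordered post-mutation pairs, weighted by
  # draw probabilities and fitness acceptance
  pair_prob <- new.env(parent = emptyenv())
  add_pair <- function(u, v, p) {
    key <- paste(sort(c(u, v)), collapse = ",")
    pair_prob[[key]] <- (if (is.null(pair_prob[[key]])) 0
                         else pair_prob[[key]]) + p
  }
  accept_total <- 0
  for (i in seq_along(vals)) {
    if (counts[i] == 0L) next
    p1 <- counts[i] / two_n
    m1 <- mut_dist(vals[i])
    for (j in seq_along(vals)) {
      c2 <- counts[j] - (i == j)
      if (c2 <= 0L) next
      p2 <- c2 / (two_n - 1L)
      m2 <- mut_dist(vals[j])
      for (u in seq_along(m1$v)) for (w in seq_along(m2$v)) {
        a1 <- m1$v[u]; a2 <- m2$v[w]
        p <- p1 * p2 * m1$p[u] * m2$p[w]
        f <- fitness(step * (a1 + a2))
        if (f > 0) {
          add_pair(a1, a2, p * f)
          accept_total <- accept_total + p * f
        }
      }
    }
  }
  if (accept_total <= 0)
    stop("no allele pair has positive fitness: population cannot reproduce")
  pair_keys <- ls(pair_prob)
  q <- vapply(pair_keys, function(k) pair_prob[[k]], numeric(1)) /
    accept_total
  pairs <- lapply(strsplit(pair_keys, ","), as.integer)
  all_vals <- sort(unique(unlist(pairs)))
  if (length(all_vals) > 6)
    stop("more than 6 distinct allele values; enumeration guard")

  # compositions of N over the pair types -> exact multinomial sum
  P <- length(q)
  state_prob <- new.env(parent = emptyenv())
  log_fact <- lgamma(seq_len(N + 1))
  recurse <- function(idx, left, cnt) {
    if (idx == P) {
      cnt[P] <- left
      lp <- log_fact[N + 1] - sum(log_fact[cnt + 1]) +
        sum(cnt * log(q))
      contrib <- integer(length(all_vals))
      for (k in seq_len(P)) {
        if (cnt[k] == 0L) next
        for (a in pairs[[k]])
          contrib[match(a, all_vals)] <- contrib[match(a, all_vals)] + cnt[k]
      }
      key <- paste(contrib, collapse = ",")
      state_prob[[key]] <- (if (is.null(state_prob[[key]])) 0
                            else state_prob[[key]]) + exp(lp)
      return()
    }
    for (c_k in 0:left) {
      cnt[idx] <- c_k
      recurse(idx + 1L, left - c_k, cnt)
    }
  }
  recurse(1L, N, integer(P))

  keys <- ls(state_prob)
  mat <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  out <- as.data.frame(mat)
  names(out) <- paste0("n_", all_vals)
  out$prob <- vapply(keys, function(k) state_prob[[k]], numeric(1))
  out <- out[order(-out$prob), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair_distribution") <-
    data.frame(pair = pair_keys, prob = q)
  attr(out, "acceptance") <- accept_total
  out
}
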