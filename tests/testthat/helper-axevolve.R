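# shared fixtures: short simulation windows keep unit tests fast
params_185 <- function(t_total = 12) cable_params(TC = 18.5, t_total = t_total)
params_26 <- function(t_total = 30) cable_params(TC = 26, t_total = t_total)

default_sim <- function(t_total = 12, g_na = 120, g_k = 36, ...) {
  p <- params_185(t_total)
  simulate_axon(p, conductances(g_na, g_k, p), ...)
}

# direct evaluation of the printed rate expressions: the independent
# oracle for the tabulated/compiled path
rates_reference <- function(V, TC) {
  q10 <- 3 ^ ((TC - 6.3) / 10)
  vtrap <- function(x, k) ifelse(abs(x) < 1e-9, k, x / (1 - exp(-x / k)))
  cbind(alpha_n = 0.01 * vtrap(V + 55, 10) * q10,
        beta_n = 0.125 * exp(-(V + 65) / 19.7) * q10,
        alpha_m = 0.1 * vtrap(V + 40, 10) * q10,
        beta_m = 4 * exp(-(V + 65) / 18) * q10,
        alpha_h = 0.07 * exp(-(V + 65) / 20) * q10,
        beta_h = 1.8 / (1 + exp(-(V + 16) / 10)) * q10)
}

# one-generation allele-count tally of a wf_population locus
locus_counts <- function(pop, j = 1) {
  tab <- table(pop[[j]])
  setNames(as.integer(tab), names(tab))
}
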