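# Small fixture networks used across tests

# a single neutral species that is itself the reactive channel
single_reactive_network <- function(rate = 1e-5) {
  microspecies_network(
    data.frame(label = "only", n_protons = 0L, charge = 0L, log_beta = 0,
               reactive = TRUE, rate_s = rate),
    molecule = "degenerate")
}

# neutral + one anion at micro-pK = -log_beta; optionally reactive anion
two_species_network <- function(log_beta_anion = -7, anion_rate = NA_real_) {
  microspecies_network(
    data.frame(label = c("neutral", "anion"),
               n_protons = c(0L, -1L), charge = c(0L, -1L),
               log_beta = c(0, log_beta_anion),
               reactive = c(FALSE, is.finite(anion_rate)),
               rate_s = c(NA_real_, anion_rate)),
    molecule = "two-species")
}

# independent brute-force oracle for mole fractions: direct term-by-term
# evaluation of beta * [H+]^n on the linear scale (no log-sum-exp)
brute_force_fractions <- function(network, ph) {
  sp <- network$species
  h <- 10^(-ph)
  terms <- 10^sp$log_beta * h^sp$n_protons
  stats::setNames(terms / sum(terms), sp$label)
}

# brute-force oracle for the observed rate: sum of k_r * x_r
brute_force_k_obs <- function(network, ph) {
  sp <- network$species
  x <- brute_force_fractions(network, ph)
  sum(sp$rate_s[sp$reactive] * x[sp$label[sp$reactive]])
}
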