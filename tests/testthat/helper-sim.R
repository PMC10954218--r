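# Shared fixtures: small simulator configs used across test files.

small_sim_config <- function(seed = 1, ...) {
  sim_config(n_samples_per_genotype = 2, n_cells_per_sample = 150,
             n_genes = 220, n_program = 20, n_decoys = 20,
             seed = seed, ...)
}

# seven well-separated populations: delegate to the package benchmark
seven_pop_config <- function(seed = 1, n_cells_per_sample = 220, ...) {
  seven_population_config(seed = seed,
                          n_cells_per_sample = n_cells_per_sample, ...)
}

# brute-force two-sided Mann-Whitney p by enumerating all rank assignments
brute_force_mw <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  pooled <- c(xa, xb)
  idx <- utils::combn(na + nb, na)
  mu <- na * nb / 2
  u_obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
  us <- apply(idx, 2, function(a) {
    r <- rank(pooled)
    sum(r[a]) - na * (na + 1) / 2
  })
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}
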