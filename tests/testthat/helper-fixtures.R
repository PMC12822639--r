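# Shared fixture builders. Everything is generated in code; no data files.

default_grid <- function() seq(650, 4000, by = 4)

# A deterministic noise-free profile: pure band sum, no jitter/baseline.
noise_free_profile <- function(base = default_profiles()$Fungi) {
  base$band_cv <- 0
  base$silica_cv <- 0
  base$baseline_scale <- 0
  base$noise_sd <- 0
  base$jitter_sd <- 0
  base
}

# Closed-form band sum for a profile on a grid (the generator's noise-free
# limit), built independently from the generator's own loop.
band_sum <- function(profile, grid) {
  gb <- ftirtax:::GEN_BANDS
  a <- numeric(length(grid))
  for (i in seq_len(nrow(gb)))
    a <- a + profile$band_means[[i]] *
      exp(-(grid - gb$center[i])^2 / (2 * gb$sd[i]^2))
  a + profile$silica_mean *
    exp(-(grid - ftirtax:::SILICA_CENTER)^2 / (2 * ftirtax:::SILICA_SD^2))
}

# Small labelled two-class dataset of generated spectra.
small_two_class <- function(n_pos = 6, n_neg = 10, seed = 1) {
  d <- study_design(counts = c(Fungi = n_neg, Prototaxites = n_pos),
                    seed = seed)
  generate_dataset(d)
}

# Independent chi-square inertia of a non-negative matrix (CA total
# inertia), used as the CCA oracle.
chisq_inertia <- function(Y) {
  P <- Y / sum(Y)
  r <- rowSums(P); cw <- colSums(P)
  E <- outer(r, cw)
  sum((P - E)^2 / E)
}
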