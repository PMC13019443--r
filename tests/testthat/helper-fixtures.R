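# Shared fixtures: small analytic spectra and toy spectra collections,
# all built in code.

# a short axis keeps I/O and small-model tests fast
toy_axis <- function(n = 40) wavenumber_axis(seq(800, 1800, length.out = n))

gauss_on <- function(axis, center, sigma, amp = 1) {
  amp * exp(-(as.numeric(axis) - center)^2 / (2 * sigma^2))
}

lorentz_on <- function(axis, center, gamma, amp = 1) {
  amp * gamma^2 / ((as.numeric(axis) - center)^2 + gamma^2)
}

# deterministic pseudo-random spectrum with metadata
toy_spectrum <- function(axis, subject = "S01", position = 0, offset = 6,
                         tissue = "transcutaneous", seed = 1) {
  set.seed(seed)
  raman_spectrum(axis, abs(stats::rnorm(length(axis))) + 0.5,
                 acquisition_meta(subject, "D2P1", position, offset,
                                  tissue))
}

# matched transcutaneous/bone collections over subjects x positions
toy_collections <- function(subjects = c("S01", "S02"),
                            positions = c(-5, 0, 5), axis = toy_axis()) {
  k <- 0
  trans <- list(); bone <- list()
  for (s in subjects) for (p in positions) {
    k <- k + 1
    trans[[k]] <- toy_spectrum(axis, s, p, 6, "transcutaneous", seed = k)
    bone[[k]] <- toy_spectrum(axis, s, p, 3, "exposed_bone",
                              seed = 100 + k)
  }
  list(trans = trans, bone = bone)
}

# noise-free generator config: bone passes straight through at 6 mm
identity_config <- function() {
  generator_config(
    bone_fraction_by_offset = c("0" = 1, "3" = 1, "6" = 1),
    baseline_coeffs = 0, baseline_jitter_sdlog = 0, noise_sd = 0,
    jitter_sdlog = 0)
}
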