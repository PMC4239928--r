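# Shared fixtures. Everything is generated in code; "fast" variants use a
# coarser probe grid and smaller sets to keep unit tests quick while the
# full default configurations are exercised in test-acceptance.R.

fast_probe <- function(noise_sd = 5e-4) {
  instrument_spec("probe", seq(700, 1800, by = 10), optical_path = 2,
                  photometric_noise_sd = noise_sd, mode = "transflectance")
}

fast_hetero_cfg <- function(seed = 1L, noise = assay_noise_model(),
                            n_cal = 40, n_val = 12, ...) {
  study_config(organism_heterolactic("cluster"), fast_probe(),
               method = "PLS", n_calibration = n_cal, n_validation = n_val,
               noise = noise, hydro = hydrodynamic_state(400, 0.3),
               seed = seed, ...)
}

fast_homo_cfg <- function(seed = 1L, noise = assay_noise_model(),
                          n_cal = 30, n_val = 12) {
  study_config(organism_homolactic(), instrument_filter19(),
               method = "MLR", n_calibration = n_cal, n_validation = n_val,
               noise = noise,
               hydro = hydrodynamic_state(120, 0), seed = seed)
}

# low-rank latent-structure matrix for screening / PLS tests
latent_matrix <- function(n, p, k = 3, noise = 1e-6, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    T_ <- matrix(rnorm(n * k), n, k) %*% diag(sqrt(seq(k, 1)), k)
    L <- matrix(rnorm(p * k), p, k)
    T_ %*% t(L) + noise * matrix(rnorm(n * p), n, p)
  })
}
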