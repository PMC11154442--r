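# Shared fixture builders. Everything is generated in code; no files.

# single-condition dataset straight from flux/rejection vectors
make_dataset <- function(v_w, r_obs, id = "c1", pH = 7, ionic = 0,
                         replicate = 1) {
  rejection_data(data.frame(
    condition_id = id, pH = pH, ionic_strength_M = ionic,
    tmp_bar = NA_real_, flux_m_per_s = v_w, replicate = replicate,
    r_obs = r_obs, stringsAsFactors = FALSE
  ))
}

# noiseless single-condition dataset from the advection forward model
make_advection_dataset <- function(sigma, k_dbl, v_w, ...) {
  make_dataset(v_w, rejection_advection(sigma, v_w / k_dbl), ...)
}

# microscopic parameters reproducing given lumped (sigma, Pe_d, Pe_m) at v_w
make_microscopic <- function(sigma, pe_d, pe_m, v_w = 1e-5,
                             K_c = 1, K_d = 1, D_i = 1e-10, D_m = 1e-11) {
  microscopic_parameters(
    K_c = K_c, K_d = K_d, D_m = D_m, D_i = D_i,
    delta_mem = pe_m * K_d * D_m / (K_c * v_w),
    delta_pol = pe_d * D_i / v_w,
    phi = (1 - sigma) / K_c
  )
}

# fluxes used across the inference tests: Pe_d from ~0.14 to ~2 at the
# reference k_dbl of 7.34e-6 m/s
ref_fluxes <- function(n = 10) seq(1e-6, 1.5e-5, length.out = n)
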