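# Closed-form solution-friction transport: Peclet numbers, sieving/partition
# coefficients and the rejection equations with and without pore diffusion.

# exp(-pe) underflows to subnormals near 745; treat pe > .pe_overflow as the
# analytic limit exp(-pe) = 0 so downstream ratios never hit 0/0.
.pe_overflow <- 709

.exp_neg <- function(pe) {
  out <- exp(-pe)
  out[pe > .pe_overflow] <- 0
  out
}

#' Membrane Peclet number
#'
#' Ratio of advective to diffusive solute transport inside the membrane pores,
#' `Pe_m = v_w / k_m`, where `k_m = K_d * D_m / (K_c * delta_mem)` lumps the
#' hindered pore diffusivity and active-layer thickness into a single
#' mass-transfer coefficient. `Pe_m >= 10` marks the advection-dominated
#' regime in which pore diffusion is negligible.
#'
#' @param v_w water velocity / volumetric flux (m/s), `>= 0`.
#' @param k_m membrane mass-transfer coefficient (m/s), `> 0`.
#' @return Dimensionless Peclet number, `0` at zero flux.
#' @seealso [peclet_polarization()], [rejection_general()]
#' @export
#' @examples
#' peclet_membrane(2e-5, 2e-6) # deep in the advection-dominated regime
peclet_membrane <- function(v_w, k_m) {
  if (any(!is.finite(k_m)) || any(k_m <= 0)) {
    stop("`k_m` must be strictly positive", call. = FALSE)
  }
  if (any(v_w < 0)) stop("`v_w` must be non-negative", call. = FALSE)
  v_w / k_m
}

#' Polarization-layer Peclet number
#'
#' `Pe_d = v_w / k_dbl = v_w * delta_pol / D`, the ratio of advective
#' drag towards the membrane to back-diffusion across the concentration
#' polarization layer. Large `Pe_d` means strong polarization and hence a
#' lower observed rejection at a given sieving coefficient.
#'
#' @param v_w water velocity / volumetric flux (m/s), `>= 0`.
#' @param k_dbl polarization-layer mass-transfer coefficient (m/s), `> 0`.
#' @return Dimensionless Peclet number.
#' @export
peclet_polarization <- function(v_w, k_dbl) {
  if (any(!is.finite(k_dbl)) || any(k_dbl <= 0)) {
    stop("`k_dbl` must be strictly positive", call. = FALSE)
  }
  if (any(v_w < 0)) stop("`v_w` must be non-negative", call. = FALSE)
  v_w / k_dbl
}

#' Sieving coefficient from hindrance and partitioning
#'
#' `sigma = 1 - K_c * Phi`: the fraction of solute held back at vanishing flux,
#' combining the advective hindrance factor `K_c` with the partition
#' coefficient `Phi` (concentration just inside the pore over concentration at
#' the membrane surface). Equals the observed rejection in the limit
#' `v_w -> 0`.
#'
#' @param K_c advective hindrance factor (dimensionless, `>= 0`).
#' @param phi partition coefficient (dimensionless, `>= 0`).
#' @return Sieving coefficient; values below 0 (when `K_c * phi > 1`) are
#'   returned with a warning since they are algebraically defined but
#'   unphysical.
#' @export
sieving_coefficient <- function(K_c, phi) {
  if (any(K_c < 0) || any(phi < 0)) {
    stop("`K_c` and `phi` must be non-negative", call. = FALSE)
  }
  sigma <- 1 - K_c * phi
  if (any(sigma < 0)) {
    warning("K_c * phi > 1 gives a negative sieving coefficient", call. = FALSE)
  }
  sigma
}

#' Ferry steric partition coefficient
#'
#' Purely geometric partitioning of a spherical solute of radius `r_s` into a
#' cylindrical pore of radius `r_p`: `(1 - r_s/r_p)^2`. For `r_s >= r_p` the
#' solute cannot enter and the coefficient is 0 (the squared form would
#' otherwise turn positive again past `r_s = 2 r_p`).
#'
#' @param r_s solute radius (m), `>= 0`.
#' @param r_p pore radius (m), `> 0`.
#' @return Partition coefficient in `[0, 1]`.
#' @export
#' @examples
#' ferry_partition(3.48e-9, 5.69e-9) # BSA in a 300 kDa-MWCO pore, ~0.15
ferry_partition <- function(r_s, r_p) {
  if (any(r_p <= 0)) stop("`r_p` must be strictly positive", call. = FALSE)
  if (any(r_s < 0)) stop("`r_s` must be non-negative", call. = FALSE)
  lambda <- pmin(r_s / r_p, 1)
  (1 - lambda)^2
}

#' Partition coefficient with solute-membrane interaction energy
#'
#' Steric (Ferry) partitioning scaled by a Boltzmann factor for the total
#' solute-membrane interaction energy `E_T`:
#' `Phi = (1 - r_s/r_p)^2 * exp(-E_T / kT)`. A repulsive interaction
#' (`E_T > 0`, e.g. like-charged solute and pore wall at low ionic strength)
#' depresses partitioning below the steric value; `E_T = 0` recovers
#' [ferry_partition()].
#'
#' @inheritParams ferry_partition
#' @param E_T total interaction energy (J); may be negative (attraction).
#' @param kT thermal energy `k_B * T` (J), `> 0`. Default is 25 degrees C.
#' @return Partition coefficient, `>= 0`.
#' @export
smith_deen_partition <- function(r_s, r_p, E_T = 0, kT = 1.380649e-23 * 298.15) {
  if (any(kT <= 0)) stop("`kT` must be strictly positive", call. = FALSE)
  ferry_partition(r_s, r_p) * exp(-E_T / kT)
}

#' Observed rejection from concentrations
#'
#' `R_obs = 1 - c_permeate / c_retentate`, the experimentally accessible
#' retention of a solute.
#'
#' @param c_retentate retentate (bulk) concentration, `> 0`; any unit shared
#'   with `c_permeate`.
#' @param c_permeate permeate concentration, `>= 0`.
#' @return Observed rejection; negative values (permeate enrichment) are
#'   returned with a warning.
#' @export
observed_rejection <- function(c_retentate, c_permeate) {
  if (any(!is.finite(c_retentate)) || any(c_retentate <= 0)) {
    stop("`c_retentate` must be strictly positive", call. = FALSE)
  }
  if (any(c_permeate < 0)) stop("`c_permeate` must be non-negative", call. = FALSE)
  if (any(c_permeate > c_retentate)) {
    warning("permeate concentration exceeds retentate: negative rejection",
            call. = FALSE)
  }
  1 - c_permeate / c_retentate
}

# validation-free kernels for the optimizer's residual evaluations, where
# sigma may legitimately step outside [0, 1] on the way to the optimum
.rej_adv_core <- function(sigma, pe_d) {
  out <- 1 - (1 - sigma) / ((1 - sigma) + .exp_neg(pe_d) * sigma)
  out[sigma == 1] <- 1
  out
}

.rej_gen_core <- function(sigma, pe_d, pe_m) {
  denom <- (1 - sigma) + .exp_neg(pe_d) * (1 - .exp_neg(pe_m)) * sigma
  out <- 1 - (1 - sigma) / denom
  out[sigma == 1] <- 1
  out[pe_m == 0] <- 0
  out
}

.check_sigma <- function(sigma, strict) {
  if (strict && (any(sigma < 0) || any(sigma > 1))) {
    stop("`sigma` outside [0, 1] (strict mode)", call. = FALSE)
  }
  if (!strict && (any(sigma < 0) || any(sigma > 1))) {
    warning("`sigma` outside [0, 1]", call. = FALSE)
  }
  invisible(sigma)
}

#' Generalized rejection equation (advection + pore diffusion)
#'
#' Observed rejection of a neutral solute including concentration polarization
#' and diffusion through the membrane:
#' \deqn{R_{obs} = 1 - \frac{1-\sigma}{(1-\sigma) +
#'   e^{-Pe_d}\,(1 - e^{-Pe_m})\,\sigma}}
#' As `Pe_m -> Inf` (no pore diffusion) this reduces to
#' [rejection_advection()]; at `Pe_m = 0` the membrane is infinitely
#' diffusive and rejection vanishes.
#'
#' @param sigma sieving coefficient.
#' @param pe_d polarization-layer Peclet number, `>= 0`.
#' @param pe_m membrane Peclet number, `>= 0`.
#' @param strict if `TRUE`, error when `sigma` leaves `[0, 1]`; default warns
#'   only, since unconstrained fits may legitimately step slightly outside.
#' @return Observed rejection. Numerically stable up to `Pe` of at least 700,
#'   beyond which the exponentials take their analytic limit 0.
#' @export
#' @examples
#' rejection_general(0.9, pe_d = 2, pe_m = 1)
rejection_general <- function(sigma, pe_d, pe_m, strict = FALSE) {
  .check_sigma(sigma, strict)
  if (any(pe_d < 0) || any(pe_m < 0)) {
    stop("Peclet numbers must be non-negative", call. = FALSE)
  }
  n <- max(length(sigma), length(pe_d), length(pe_m))
  sigma <- rep_len(sigma, n); pe_d <- rep_len(pe_d, n); pe_m <- rep_len(pe_m, n)
  # 0/0 corners resolved in the kernel: full sieving passes nothing; a
  # membrane with Pe_m = 0 is infinitely diffusive and passes everything
  .rej_gen_core(sigma, pe_d, pe_m)
}

#' Advection-dominated rejection equation
#'
#' The `Pe_m -> Inf` limit of [rejection_general()], appropriate for open
#' membranes at high flux where pore diffusion is negligible:
#' \deqn{R_{obs} = 1 - \frac{1-\sigma}{(1-\sigma) + e^{-Pe_d}\,\sigma}}
#' At `Pe_d = 0` (vanishing flux) the observed rejection equals the sieving
#' coefficient `sigma`, its maximum.
#'
#' @inheritParams rejection_general
#' @return Observed rejection.
#' @export
rejection_advection <- function(sigma, pe_d, strict = FALSE) {
  .check_sigma(sigma, strict)
  if (any(pe_d < 0)) stop("`pe_d` must be non-negative", call. = FALSE)
  n <- max(length(sigma), length(pe_d))
  sigma <- rep_len(sigma, n); pe_d <- rep_len(pe_d, n)
  .rej_adv_core(sigma, pe_d)
}

#' Solute flux through the membrane
#'
#' Integrated hindered advection-diffusion flux across the active layer,
#' `J = K_c * Phi * v_w * (c_p e^{-Pe_m} - c_m) / (e^{-Pe_m} - 1)`, positive
#' towards the permeate. The expression is singular at `Pe_m = 0`; there the
#' diffusive limit is returned (finite only when `c_m == c_p`) with a warning.
#'
#' @param c_m concentration at the membrane surface, retentate side (mol/m^3).
#' @param c_p permeate concentration (mol/m^3).
#' @param v_w water velocity (m/s).
#' @param K_c advective hindrance factor.
#' @param phi partition coefficient.
#' @param pe_m membrane Peclet number, `>= 0`.
#' @return Solute flux (mol m^-2 s^-1).
#' @export
solute_flux_membrane <- function(c_m, c_p, v_w, K_c, phi, pe_m) {
  if (any(pe_m < 0)) stop("`pe_m` must be non-negative", call. = FALSE)
  n <- max(length(c_m), length(c_p), length(pe_m))
  c_m <- rep_len(c_m, n); c_p <- rep_len(c_p, n); pe_m <- rep_len(pe_m, n)
  e <- .exp_neg(pe_m)
  out <- K_c * phi * v_w * (c_p * e - c_m) / (e - 1)
  sing <- pe_m == 0
  if (any(sing)) {
    warning("pe_m = 0: membrane flux is the pure-diffusion limit", call. = FALSE)
    out[sing] <- ifelse(c_m[sing] == c_p[sing],
                        (K_c * phi * v_w * c_m)[sing],
                        Inf * sign(c_m[sing] - c_p[sing]))
  }
  out
}

#' Solute flux across the polarization layer
#'
#' Integrated advection-diffusion flux across the polarization layer
#' (friction-free, bulk diffusivity):
#' `J = v_w * (c_m e^{-Pe_d} - c_b) / (e^{-Pe_d} - 1)`. With `c_b = c_m`
#' there is no gradient and the flux collapses to pure advective
#' carry-through `v_w * c_b` for any `Pe_d`.
#'
#' @param c_b bulk retentate concentration (mol/m^3).
#' @param c_m concentration at the membrane surface (mol/m^3).
#' @param v_w water velocity (m/s).
#' @param pe_d polarization-layer Peclet number, `>= 0`.
#' @return Solute flux (mol m^-2 s^-1).
#' @export
solute_flux_polarization <- function(c_b, c_m, v_w, pe_d) {
  if (any(pe_d < 0)) stop("`pe_d` must be non-negative", call. = FALSE)
  n <- max(length(c_b), length(c_m), length(pe_d))
  c_b <- rep_len(c_b, n); c_m <- rep_len(c_m, n); pe_d <- rep_len(pe_d, n)
  e <- .exp_neg(pe_d)
  out <- v_w * (c_m * e - c_b) / (e - 1)
  sing <- pe_d == 0
  if (any(sing)) {
    warning("pe_d = 0: polarization flux is the pure-diffusion limit",
            call. = FALSE)
    out[sing] <- ifelse(c_b[sing] == c_m[sing], (v_w * c_b)[sing],
                        Inf * sign(c_b[sing] - c_m[sing]))
  }
  out
}
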