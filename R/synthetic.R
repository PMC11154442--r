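# Synthetic flux-rejection data with the statistical structure of a
# pilot-scale crossflow study: a grid of solution conditions and
# transmembrane pressures, duplicate concentration measurements, and
# rejections produced by the forward rejection model plus multiplicative
# measurement noise on the concentrations.

#' Pilot-scale crossflow study design
#'
#' The default grid: six solution conditions (pH 7 at 0, 0.08, 0.15 and
#' 0.2 M NaCl; pH 4.9 at 0 and 0.2 M NaCl), transmembrane pressures of 0.2,
#' 0.5, 0.8, 1.5 and 3 bar, duplicate concentration measurements, a
#' 0.5% (w/v) protein feed and a crossflow velocity of 0.167 m/s.
#'
#' @param conditions data frame with columns `pH` and `ionic_strength_M`.
#' @param pressures transmembrane pressures (bar), strictly positive and
#'   increasing.
#' @param replicates concentration measurements per condition x pressure.
#' @param protein_conc feed protein concentration, mass fraction (w/v) in %.
#' @param crossflow crossflow velocity (m/s).
#' @return An object of class `"study_design"`; conditions get ids of the
#'   form `"pH7_0.08M"`.
#' @export
study_design <- function(conditions, pressures, replicates = 2,
                         protein_conc = 0.5, crossflow = 0.167) {
  stopifnot(is.data.frame(conditions),
            all(c("pH", "ionic_strength_M") %in% names(conditions)),
            replicates >= 1, all(pressures > 0),
            !is.unsorted(pressures, strictly = TRUE))
  conditions$condition_id <- sprintf("pH%g_%gM", conditions$pH,
                                     conditions$ionic_strength_M)
  structure(list(conditions = conditions, pressures = pressures,
                 replicates = as.integer(replicates),
                 protein_conc = protein_conc, crossflow = crossflow),
            class = "study_design")
}

#' @rdname study_design
#' @export
default_design <- function() {
  study_design(
    conditions = data.frame(
      pH = c(7, 7, 7, 7, 4.9, 4.9),
      ionic_strength_M = c(0, 0.08, 0.15, 0.2, 0, 0.2)
    ),
    pressures = c(0.2, 0.5, 0.8, 1.5, 3)
  )
}

#' Ground truth for the synthetic study
#'
#' Per-condition transport parameters plus the flux law and noise level the
#' generator uses. The default sieving coefficients (0.9993, 0.9935, 0.9686,
#' 0.9646, 0.9977, 0.9916, in the order of [default_design()]) and the
#' shared `k_dbl = 7.34e-6` m/s are representative of BSA on an open
#' 300 kDa-MWCO membrane; the linear flux law (`v_w = permeability * TMP`,
#' default 5e-6 m/s/bar) is a stand-in for measured fluxes that keeps
#' `Pe_d` in the 0.1-2 working range, valid below cake-layer formation.
#'
#' @param sigma per-condition sieving coefficients, recycled to the number
#'   of design conditions when needed; may be named by condition id.
#' @param k_dbl shared polarization-layer mass-transfer coefficient (m/s).
#' @param k_m membrane mass-transfer coefficient (m/s) or `NULL`; only used
#'   when simulating from the general model.
#' @param permeability flux per unit transmembrane pressure (m/s/bar).
#' @param noise_sd_conc relative standard deviation of the multiplicative
#'   Gaussian noise on each concentration measurement (default 1%).
#' @param seed integer seed making the simulation reproducible.
#' @return An object of class `"ground_truth"`.
#' @export
default_ground_truth <- function(sigma = c(0.9993, 0.9935, 0.9686, 0.9646,
                                           0.9977, 0.9916),
                                 k_dbl = 7.34e-6, k_m = NULL,
                                 permeability = 5e-6, noise_sd_conc = 0.01,
                                 seed = 20240126) {
  stopifnot(k_dbl > 0, permeability > 0, noise_sd_conc >= 0,
            is.null(k_m) || k_m > 0)
  structure(list(sigma = sigma, k_dbl = k_dbl, k_m = k_m,
                 permeability = permeability,
                 noise_sd_conc = noise_sd_conc, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Volumetric flux from transmembrane pressure
#'
#' Linear flux law `v_w = permeability * tmp`, appropriate below the
#' limiting-flux regime (no cake layer).
#'
#' @param tmp transmembrane pressure (bar), `>= 0`.
#' @param permeability membrane permeability (m/s/bar), `> 0`.
#' @return Volumetric flux (m/s).
#' @export
flux_from_pressure <- function(tmp, permeability) {
  stopifnot(all(tmp >= 0), permeability > 0)
  permeability * tmp
}

#' Simulate a flux-rejection dataset
#'
#' For every condition x pressure x replicate cell: the flux follows from
#' the linear flux law; the true rejection from the forward model
#' ([rejection_advection()] or [rejection_general()]); the retentate
#' concentration is the nominal feed and the permeate concentration
#' `(1 - R) * c_ret`; both concentrations are then perturbed by independent
#' multiplicative Gaussian noise with relative sd `noise_sd_conc`, and the
#' recorded rejection is [observed_rejection()] of the noisy pair --
#' mirroring how rejections are actually measured. Bit-reproducible for a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param design a [study_design()] object.
#' @param truth a [default_ground_truth()] object supplying parameters for
#'   every design condition.
#' @param model forward model, `"advection"` (default) or `"general"`
#'   (requires `truth$k_m`).
#' @param seed overrides `truth$seed` when given.
#' @return A [rejection_data()] data frame with one row per measurement and
#'   columns `condition_id`, `pH`, `ionic_strength_M`, `tmp_bar`,
#'   `flux_m_per_s`, `replicate`, `c_retentate`, `c_permeate`, `r_obs`.
#' @export
simulate_dataset <- function(design, truth, model = c("advection", "general"),
                             seed = truth$seed) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"))
  model <- match.arg(model)
  if (model == "general" && is.null(truth$k_m)) {
    stop("simulating from the general model requires `truth$k_m`",
         call. = FALSE)
  }
  conds <- design$conditions
  m <- nrow(conds)
  sigma <- truth$sigma
  if (!is.null(names(sigma))) {
    if (!all(conds$condition_id %in% names(sigma))) {
      stop("`truth$sigma` lacks values for some design conditions",
           call. = FALSE)
    }
    sigma <- sigma[conds$condition_id]
  } else {
    if (length(sigma) != m && length(sigma) != 1) {
      stop("`truth$sigma` must supply one value per design condition",
           call. = FALSE)
    }
    sigma <- rep_len(sigma, m)
  }

  grid <- expand.grid(replicate = seq_len(design$replicates),
                      tmp_bar = design$pressures,
                      cond = seq_len(m))
  v_w <- flux_from_pressure(grid$tmp_bar, truth$permeability)
  pe_d <- peclet_polarization(v_w, truth$k_dbl)
  r_true <- if (model == "advection") {
    rejection_advection(sigma[grid$cond], pe_d)
  } else {
    rejection_general(sigma[grid$cond], pe_d,
                      peclet_membrane(v_w, truth$k_m))
  }

  # feed concentration in kg/m^3 (0.5% w/v = 5 kg/m^3)
  c_ret <- rep(design$protein_conc * 10, nrow(grid))
  c_per <- (1 - r_true) * c_ret

  n <- nrow(grid)
  noisy <- .with_seed(seed, {
    eps <- stats::rnorm(2 * n, mean = 0, sd = truth$noise_sd_conc)
    list(ret = c_ret * (1 + eps[seq_len(n)]),
         per = c_per * (1 + eps[n + seq_len(n)]))
  })

  rejection_data(data.frame(
    condition_id = conds$condition_id[grid$cond],
    pH = conds$pH[grid$cond],
    ionic_strength_M = conds$ionic_strength_M[grid$cond],
    tmp_bar = grid$tmp_bar,
    flux_m_per_s = v_w,
    replicate = grid$replicate,
    c_retentate = noisy$ret,
    c_permeate = noisy$per,
    r_obs = suppressWarnings(observed_rejection(noisy$ret, noisy$per)),
    stringsAsFactors = FALSE
  ))
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
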