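# Containers for lumped transport parameters and flux-rejection observations.

#' Lumped transport parameters
#'
#' The three lumped coefficients that fully determine a predicted rejection
#' curve: the sieving coefficient `sigma` (rejection limit at vanishing
#' flux), the polarization-layer mass-transfer coefficient `k_dbl`, and, for
#' the model that retains pore diffusion, the membrane mass-transfer
#' coefficient `k_m`. Leaving `k_m` absent selects the advection-dominated
#' model.
#'
#' @param sigma sieving coefficient; physically in `[0, 1]`, but values
#'   slightly outside arise from unconstrained fits and are accepted with a
#'   warning unless `strict = TRUE`.
#' @param k_dbl polarization-layer mass-transfer coefficient (m/s), `> 0`.
#' @param k_m membrane mass-transfer coefficient (m/s), `> 0`, or `NULL`.
#' @param strict error (rather than warn) when `sigma` leaves `[0, 1]`.
#' @return An object of class `"transport_parameters"`.
#' @export
transport_parameters <- function(sigma, k_dbl, k_m = NULL, strict = FALSE) {
  .check_sigma(sigma, strict)
  if (!is.numeric(k_dbl) || k_dbl <= 0) {
    stop("`k_dbl` must be strictly positive", call. = FALSE)
  }
  if (!is.null(k_m) && (!is.numeric(k_m) || k_m <= 0)) {
    stop("`k_m` must be strictly positive when supplied", call. = FALSE)
  }
  structure(list(sigma = sigma, k_dbl = k_dbl, k_m = k_m),
            class = "transport_parameters")
}

#' Predict observed rejection from transport parameters
#'
#' Evaluates the advection-dominated rejection equation, or the generalized
#' one when the parameters carry a membrane mass-transfer coefficient, at the
#' given volumetric fluxes.
#'
#' @param params a [transport_parameters()] object.
#' @param v_w volumetric flux / water velocity (m/s), vectorized.
#' @param model `"advection"` or `"general"`; defaults to `"general"` exactly
#'   when `params$k_m` is present.
#' @return Predicted observed rejection, same length as `v_w`.
#' @export
predict_rejection <- function(params, v_w,
                              model = if (is.null(params$k_m)) "advection"
                                      else "general") {
  stopifnot(inherits(params, "transport_parameters"))
  model <- match.arg(model, c("advection", "general"))
  pe_d <- peclet_polarization(v_w, params$k_dbl)
  if (model == "advection") {
    rejection_advection(params$sigma, pe_d)
  } else {
    if (is.null(params$k_m)) {
      stop("the general model requires `k_m`", call. = FALSE)
    }
    rejection_general(params$sigma, pe_d, peclet_membrane(v_w, params$k_m))
  }
}

.dataset_cols <- c("condition_id", "pH", "ionic_strength_M", "tmp_bar",
                   "flux_m_per_s", "replicate", "r_obs")

#' Flux-rejection dataset
#'
#' Validates a data frame of replicated flux-rejection observations grouped
#' by solution condition and stamps it with class `"rejection_data"`.
#' Required columns: `condition_id`, `pH`, `ionic_strength_M`,
#' `flux_m_per_s`, `replicate`, `r_obs`; `tmp_bar` and the concentration
#' pair `c_retentate`/`c_permeate` are carried through when present.
#'
#' @param df a data frame of observations.
#' @return `df` with class `c("rejection_data", "data.frame")`.
#' @export
rejection_data <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- setdiff(.dataset_cols, c("tmp_bar"))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("dataset has no observations", call. = FALSE)
  bad_flux <- which(!is.finite(df$flux_m_per_s) | df$flux_m_per_s <= 0)
  if (length(bad_flux)) {
    stop("non-positive flux in rows: ", paste(bad_flux, collapse = ", "),
         call. = FALSE)
  }
  bad_r <- which(!is.finite(df$r_obs) | df$r_obs > 1)
  if (length(bad_r)) {
    stop("r_obs missing or > 1 in rows: ", paste(bad_r, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("rejection_data", "data.frame")
  df
}

#' Split a dataset by solution condition
#'
#' @param data a [rejection_data()] object.
#' @return Named list of single-condition `rejection_data` objects, in order
#'   of first appearance.
#' @export
split_conditions <- function(data) {
  stopifnot(inherits(data, "rejection_data"))
  ids <- unique(data$condition_id)
  out <- lapply(ids, function(id) {
    d <- data[data$condition_id == id, , drop = FALSE]
    class(d) <- c("rejection_data", "data.frame")
    d
  })
  names(out) <- ids
  out
}
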