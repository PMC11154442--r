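# Nonlinear least-squares estimation of sieving and mass-transfer
# coefficients from flux-rejection data, and nested-model comparison.
#
# All fits run Levenberg-Marquardt (minpack.lm::nls.lm) on the residuals
# R_obs - R_pred. Rate coefficients are fitted on the log scale, which keeps
# them positive without hard bounds and conditions the problem across the
# 1e-6 m/s magnitude; sigma is fitted untransformed and unbounded, since
# real fits can land marginally above 1.

.fit_control <- function(maxiter = 500) {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, gtol = 1e-10,
                             maxiter = maxiter)
}

#' Residual sum of squares of a rejection model
#'
#' `sum((R_obs - R_pred(v_w))^2)` over all observations, the objective every
#' fit minimizes. Invariant under permutation of the observations.
#'
#' @param params a [transport_parameters()] object; `k_m` is required for
#'   the general model.
#' @param data a single-condition [rejection_data()] object.
#' @param model `"advection"` or `"general"`.
#' @return Residual sum of squares.
#' @export
residual_ss <- function(params, data, model = c("advection", "general")) {
  stopifnot(inherits(data, "rejection_data"))
  model <- match.arg(model)
  if (model == "general" && is.null(params$k_m)) {
    stop("the general model requires `k_m`", call. = FALSE)
  }
  sum((data$r_obs - predict_rejection(params, data$flux_m_per_s, model))^2)
}

# map an unconstrained parameter vector to predictions for one condition
.pred_from_par <- function(par, v_w, model) {
  sigma <- par[["sigma"]]
  pe_d <- v_w / exp(par[["log_k_dbl"]])
  if (model == "advection") {
    .rej_adv_core(rep_len(sigma, length(pe_d)), pe_d)
  } else {
    .rej_gen_core(rep_len(sigma, length(pe_d)), pe_d,
                  v_w / exp(par[["log_k_m"]]))
  }
}

.default_init <- function(data, model) {
  s0 <- max(data$r_obs)
  if (s0 <= 0) s0 <- 0.5
  k0 <- stats::median(data$flux_m_per_s) # puts Pe_d near 1
  par <- c(sigma = s0, log_k_dbl = log(k0))
  if (model == "general") par <- c(par, log_k_m = log(k0))
  par
}

# Linearized (Jacobian-based) standard errors on the internal scale,
# delta-methoded back to (sigma, k_dbl, k_m). nls.lm's hessian is the
# Gauss-Newton J'J of the residual vector.
.fit_se <- function(fit, df) {
  ss <- fit$deviance
  s2 <- if (df > 0) ss / df else NA_real_
  covmat <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
  if (is.null(covmat)) {
    return(rep(NA_real_, length(fit$par)))
  }
  sqrt(pmax(diag(covmat), 0))
}

.adj_r2 <- function(ss_res, r_obs, n_par) {
  n <- length(r_obs)
  ss_tot <- sum((r_obs - mean(r_obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - (ss_res / (n - n_par)) / (ss_tot / (n - 1))
}

.make_fit_result <- function(estimate, se, ci95, ss_res, df, adj_r2, n_obs,
                             model, converged, message, niter, condition_id,
                             fitted_names) {
  structure(list(
    params = transport_parameters(
      sigma = unname(estimate[["sigma"]]),
      k_dbl = unname(estimate[["k_dbl"]]),
      k_m = if ("k_m" %in% names(estimate)) unname(estimate[["k_m"]]) else NULL
    ),
    estimate = estimate, se = se, ci95 = ci95,
    ss_res = ss_res, df = df, adj_r2 = adj_r2, n_obs = n_obs,
    model = model, converged = converged, message = message, niter = niter,
    condition_id = condition_id, fitted = fitted_names
  ), class = "uf_fit")
}

#' Fit a rejection model to one solution condition
#'
#' Minimizes [residual_ss()] over `(sigma, k_dbl)` (advection-dominated
#' model) or `(sigma, k_dbl, k_m)` (general model) by Levenberg-Marquardt.
#' 95% confidence half-widths come from the linearized parameter covariance
#' with t quantiles at the residual degrees of freedom; rate coefficients
#' fitted on the log scale are delta-methoded back.
#'
#' @param data a single-condition [rejection_data()] object.
#' @param model `"advection"` (default) or `"general"`.
#' @param init optional [transport_parameters()] starting values. The
#'   default starts `sigma` at the largest observed rejection (its
#'   vanishing-flux limit) and both rate coefficients at the median flux,
#'   which places `Pe` near 1.
#' @param conf_level confidence level for the reported intervals.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return An object of class `"uf_fit"`: `params`
#'   ([transport_parameters()]), `estimate`, `se` and `ci95` (half-widths)
#'   named vectors, `ss_res`, `df`, `adj_r2`, `n_obs`, `model`, `converged`.
#' @export
#' @examples
#' design <- default_design()
#' truth <- default_ground_truth(noise_sd_conc = 0)
#' sim <- simulate_dataset(design, truth)
#' fit_condition(split_conditions(sim)[[1]])
fit_condition <- function(data, model = c("advection", "general"),
                          init = NULL, conf_level = 0.95, maxiter = 500) {
  stopifnot(inherits(data, "rejection_data"))
  model <- match.arg(model)
  if (length(unique(data$condition_id)) != 1) {
    stop("`fit_condition` expects a single condition; see `fit_shared_kdbl`",
         call. = FALSE)
  }
  n_par <- if (model == "advection") 2L else 3L
  if (nrow(data) < n_par + 1) {
    stop("need at least ", n_par + 1, " observations to fit ", n_par,
         " parameters", call. = FALSE)
  }
  par0 <- if (is.null(init)) .default_init(data, model) else {
    p <- c(sigma = init$sigma, log_k_dbl = log(init$k_dbl))
    if (model == "general") {
      if (is.null(init$k_m)) stop("`init` lacks `k_m` for the general model",
                                  call. = FALSE)
      p <- c(p, log_k_m = log(init$k_m))
    }
    p
  }

  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(par) data$r_obs - .pred_from_par(par, data$flux_m_per_s, model),
    control = .fit_control(maxiter)
  )

  n <- nrow(data)
  df <- n - n_par
  se_int <- .fit_se(fit, df)
  est_int <- fit$par
  # exp() of a log-scale estimate pushed to the k -> 0 boundary can
  # underflow; the smallest positive double preserves "advection limit"
  back <- function(lk) max(exp(lk), .Machine$double.xmin)
  estimate <- c(sigma = unname(est_int[["sigma"]]),
                k_dbl = back(est_int[["log_k_dbl"]]))
  se <- c(sigma = se_int[[1]],
          k_dbl = estimate[["k_dbl"]] * se_int[[2]])
  if (model == "general") {
    estimate <- c(estimate, k_m = back(est_int[["log_k_m"]]))
    se <- c(se, k_m = estimate[["k_m"]] * se_int[[3]])
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  suppressWarnings(.make_fit_result(
    estimate = estimate, se = se, ci95 = tq * se,
    ss_res = fit$deviance, df = df,
    adj_r2 = .adj_r2(fit$deviance, data$r_obs, n_par),
    n_obs = n, model = model,
    converged = fit$info %in% 1:4, message = fit$message, niter = fit$niter,
    condition_id = data$condition_id[[1]],
    fitted_names = names(estimate)
  ))
}

#' Fit per-condition sieving with one shared mass-transfer coefficient
#'
#' Simultaneous least squares over several solution conditions under the
#' advection-dominated model, with one sieving coefficient per condition and
#' a single `k_dbl` common to all of them -- the assumption that mass
#' transfer in the polarization layer does not depend on pH or ionic
#' strength. With a single condition this reduces exactly to
#' [fit_condition()].
#'
#' @param data a multi-condition [rejection_data()] object (or a list of
#'   single-condition ones).
#' @param init optional list with `sigma` (named by condition) and `k_dbl`.
#' @inheritParams fit_condition
#' @return An object of class `"uf_shared_fit"`: named vectors `sigma`,
#'   `sigma_se`, `sigma_ci95`, scalars `k_dbl`, `k_dbl_se`, `k_dbl_ci95`,
#'   plus `estimate`/`ci95` across all parameters, `ss_res`, `df`,
#'   `adj_r2`, `n_obs`, `converged`.
#' @export
fit_shared_kdbl <- function(data, init = NULL, conf_level = 0.95,
                            maxiter = 500) {
  if (is.list(data) && !is.data.frame(data)) {
    data <- do.call(rbind, lapply(data, as.data.frame))
    data <- rejection_data(data)
  }
  stopifnot(inherits(data, "rejection_data"))
  ids <- unique(data$condition_id)
  m <- length(ids)
  n <- nrow(data)
  if (n < m + 2) {
    stop("need at least n_conditions + 2 observations", call. = FALSE)
  }
  idx <- match(data$condition_id, ids)

  if (is.null(init)) {
    s0 <- vapply(ids, function(id) max(data$r_obs[data$condition_id == id]),
                 numeric(1))
    s0[s0 <= 0] <- 0.5
    par0 <- c(s0, log(stats::median(data$flux_m_per_s)))
  } else {
    par0 <- c(init$sigma[ids], log(init$k_dbl))
  }
  names(par0) <- c(paste0("sigma.", ids), "log_k_dbl")

  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(par) {
      pe_d <- data$flux_m_per_s / exp(par[[m + 1]])
      data$r_obs - .rej_adv_core(par[idx], pe_d)
    },
    control = .fit_control(maxiter)
  )

  n_par <- m + 1L
  df <- n - n_par
  se_int <- .fit_se(fit, df)
  sigma <- fit$par[seq_len(m)]
  names(sigma) <- ids
  k_dbl <- exp(fit$par[[m + 1]])
  sigma_se <- se_int[seq_len(m)]
  names(sigma_se) <- ids
  k_dbl_se <- k_dbl * se_int[[m + 1]]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)

  estimate <- c(stats::setNames(sigma, paste0("sigma.", ids)), k_dbl = k_dbl)
  se_all <- c(stats::setNames(sigma_se, paste0("sigma.", ids)),
              k_dbl = k_dbl_se)
  structure(list(
    sigma = sigma, sigma_se = sigma_se, sigma_ci95 = tq * sigma_se,
    k_dbl = k_dbl, k_dbl_se = k_dbl_se, k_dbl_ci95 = tq * k_dbl_se,
    estimate = estimate, se = se_all, ci95 = tq * se_all,
    ss_res = fit$deviance, df = df,
    adj_r2 = .adj_r2(fit$deviance, data$r_obs, n_par),
    n_obs = n, model = "advection",
    converged = fit$info %in% 1:4, message = fit$message, niter = fit$niter,
    condition_ids = ids
  ), class = "uf_shared_fit")
}

#' Fit the sieving coefficient with a frozen mass-transfer coefficient
#'
#' One-parameter fit of `sigma` under the advection-dominated model with
#' `k_dbl` held at a supplied value, e.g. an average fitted coefficient or a
#' Sherwood-correlation estimate (see [estimate_kdbl()]). Freezing `k_dbl`
#' below its true value over-states polarization and biases `sigma` upward.
#'
#' @param data a single-condition [rejection_data()] object with at least
#'   2 observations.
#' @param k_dbl frozen polarization-layer mass-transfer coefficient (m/s).
#' @inheritParams fit_condition
#' @return An object of class `"uf_fit"` with `sigma` as the only fitted
#'   parameter (`k_dbl` reported but carrying no uncertainty).
#' @export
fit_fixed_kdbl <- function(data, k_dbl, conf_level = 0.95, maxiter = 500) {
  stopifnot(inherits(data, "rejection_data"))
  if (!is.numeric(k_dbl) || k_dbl <= 0) {
    stop("`k_dbl` must be strictly positive", call. = FALSE)
  }
  if (length(unique(data$condition_id)) != 1) {
    stop("`fit_fixed_kdbl` expects a single condition", call. = FALSE)
  }
  if (nrow(data) < 2) stop("need at least 2 observations", call. = FALSE)

  pe_d <- data$flux_m_per_s / k_dbl
  s0 <- max(data$r_obs); if (s0 <= 0) s0 <- 0.5
  fit <- minpack.lm::nls.lm(
    par = c(sigma = s0),
    fn = function(par) data$r_obs -
      .rej_adv_core(rep_len(par[["sigma"]], length(pe_d)), pe_d),
    control = .fit_control(maxiter)
  )

  n <- nrow(data)
  df <- n - 1L
  se <- c(sigma = .fit_se(fit, df)[[1]], k_dbl = 0)
  estimate <- c(sigma = unname(fit$par[["sigma"]]), k_dbl = k_dbl)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  suppressWarnings(.make_fit_result(
    estimate = estimate, se = se, ci95 = tq * se,
    ss_res = fit$deviance, df = df,
    adj_r2 = .adj_r2(fit$deviance, data$r_obs, 1L),
    n_obs = n, model = "advection",
    converged = fit$info %in% 1:4, message = fit$message, niter = fit$niter,
    condition_id = data$condition_id[[1]],
    fitted_names = "sigma"
  ))
}

#' Compare nested rejection-model fits by F test
#'
#' `F = ((SS1 - SS2) / (df1 - df2)) / (SS2 / df2)`, where model 1 has fewer
#' parameters (larger residual sum of squares `SS1`, more degrees of freedom
#' `df1`) than model 2. The p value is the upper tail of the F distribution
#' with `df1 - df2` and `df2` degrees of freedom. When the larger model
#' fails to improve the fit the statistic can come out at or below zero; it
#' is reported as computed and the p value is set to 1.
#'
#' @param fit_small the fit with fewer parameters (`"uf_fit"`).
#' @param fit_large the fit with more parameters, on the same data.
#' @return An object of class `"uf_ftest"` with `F`, `p`, `ss1`, `ss2`,
#'   `df1`, `df2`.
#' @export
f_test <- function(fit_small, fit_large) {
  ss1 <- fit_small$ss_res; df1 <- fit_small$df
  ss2 <- fit_large$ss_res; df2 <- fit_large$df
  if (df1 <= df2) {
    stop("`fit_small` must have more residual degrees of freedom",
         call. = FALSE)
  }
  if (!is.null(fit_small$n_obs) && !is.null(fit_large$n_obs) &&
      fit_small$n_obs != fit_large$n_obs) {
    stop("fits were not performed on the same dataset", call. = FALSE)
  }
  Fstat <- if (ss2 == 0) {
    if (ss1 > 0) Inf else 0
  } else {
    ((ss1 - ss2) / (df1 - df2)) / (ss2 / df2)
  }
  p <- if (Fstat <= 0) 1 else stats::pf(Fstat, df1 - df2, df2,
                                        lower.tail = FALSE)
  structure(list(F = Fstat, p = p, ss1 = ss1, ss2 = ss2,
                 df1 = df1, df2 = df2),
            class = "uf_ftest")
}

#' Adjusted coefficient of determination
#'
#' `1 - (ss_res / (n - p)) / (ss_tot / (n - 1))` with the total sum of
#' squares about the mean observed rejection. Can be negative when the model
#' predicts worse than the mean. Undefined (NA, with a warning) when the
#' observations have zero variance.
#'
#' @param fit a `"uf_fit"` or `"uf_shared_fit"` object.
#' @param data the [rejection_data()] the fit was computed on.
#' @return Adjusted r-squared.
#' @export
adjusted_r2 <- function(fit, data) {
  stopifnot(inherits(data, "rejection_data"))
  n_par <- if (inherits(fit, "uf_shared_fit")) {
    length(fit$sigma) + 1L
  } else {
    length(fit$fitted)
  }
  out <- .adj_r2(fit$ss_res, data$r_obs, n_par)
  if (is.na(out)) warning("zero total variance: adjusted r2 undefined",
                          call. = FALSE)
  out
}

#' @export
print.uf_fit <- function(x, ...) {
  cat(sprintf("Rejection fit (%s model) for condition '%s'\n",
              x$model, x$condition_id))
  tab <- data.frame(estimate = x$estimate,
                    ci95 = x$ci95[names(x$estimate)])
  print(signif(tab, 6))
  cat(sprintf("ss_res = %.4g on %d df, adj-r2 = %.3f, %s\n",
              x$ss_res, x$df, x$adj_r2,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.uf_shared_fit <- function(x, ...) {
  cat("Shared-k_dbl rejection fit (advection model)\n")
  tab <- data.frame(sigma = x$sigma, ci95 = x$sigma_ci95)
  print(signif(tab, 6))
  cat(sprintf("k_dbl = %.4g +/- %.2g m/s (95%% CI)\n", x$k_dbl, x$k_dbl_ci95))
  cat(sprintf("ss_res = %.4g on %d df, adj-r2 = %.3f, %s\n",
              x$ss_res, x$df, x$adj_r2,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.uf_ftest <- function(x, ...) {
  cat(sprintf(
    "F test: F = %.4g on (%d, %d) df, p = %.3g\n  SS1 = %.4g (df %d), SS2 = %.4g (df %d)\n",
    x$F, x$df1 - x$df2, x$df2, x$p, x$ss1, x$df1, x$ss2, x$df2))
  invisible(x)
}
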