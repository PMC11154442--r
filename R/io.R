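# Delimited-text dataset reader/writer, YAML run configuration, and report
# writers tying the pipeline together. Files carry TMP in bar and ionic
# strength in mol/L (reporting units); everything is SI internally
# (1 bar = 1e5 Pa exactly).

.schema_required <- c("condition_id", "pH", "ionic_strength_M", "tmp_bar",
                      "flux_m_per_s", "replicate")

#' Read a flux-rejection dataset from CSV
#'
#' Expects a comma-separated file with header columns `condition_id`, `pH`,
#' `ionic_strength_M`, `tmp_bar`, `flux_m_per_s`, `replicate`, and either
#' `r_obs` or the concentration pair `c_retentate`/`c_permeate` (rejections
#' are then computed via [observed_rejection()]). When both are present the
#' `r_obs` column takes precedence and any disagreement beyond 1e-6 is
#' reported. Row-level validation failures are reported with their line
#' numbers.
#'
#' @param path CSV file path.
#' @return A [rejection_data()] object.
#' @export
read_rejection_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty data section in ", path, call. = FALSE)
  missing_cols <- setdiff(.schema_required, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_r <- "r_obs" %in% names(df)
  has_conc <- all(c("c_retentate", "c_permeate") %in% names(df))
  if (!has_r && !has_conc) {
    stop("need an `r_obs` column or the pair `c_retentate`/`c_permeate`",
         call. = FALSE)
  }
  if (has_conc) {
    r_from_conc <- suppressWarnings(
      observed_rejection(df$c_retentate, df$c_permeate))
    if (has_r) {
      off <- which(abs(df$r_obs - r_from_conc) > 1e-6)
      if (length(off)) {
        message("r_obs and concentration columns disagree (> 1e-6) on rows: ",
                paste(off, collapse = ", "), "; keeping r_obs")
      }
    } else {
      df$r_obs <- r_from_conc
    }
  }

  # row-level validation with data line numbers (header is line 1)
  problems <- character(0)
  bad <- which(!is.finite(df$flux_m_per_s) | df$flux_m_per_s <= 0)
  if (length(bad)) {
    problems <- c(problems, paste0("non-positive flux on lines: ",
                                   paste(bad + 1, collapse = ", ")))
  }
  bad <- which(!is.finite(df$r_obs) | df$r_obs > 1)
  if (length(bad)) {
    problems <- c(problems, paste0("r_obs missing or > 1 on lines: ",
                                   paste(bad + 1, collapse = ", ")))
  }
  if (length(problems)) {
    stop("schema errors in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  rejection_data(df)
}

#' Write a flux-rejection dataset to CSV
#'
#' Floating-point columns are serialized with 6 significant digits, enough
#' for a lossless fit round trip at measurement precision.
#'
#' @param data a [rejection_data()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_data <- function(data, path) {
  stopifnot(inherits(data, "rejection_data"))
  df <- as.data.frame(data)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_keys <- c("geometry", "solution", "model", "fit_strategy",
                  "fixed_kdbl_value", "sherwood_correlation", "seed",
                  "output_dir")
.geometry_keys <- c("h", "eps", "S_vp", "L")
.solution_keys <- c("rho", "eta", "D", "v_r")

#' Read a run configuration
#'
#' Parses a YAML configuration with strict unknown-key rejection. Known
#' top-level keys: `geometry` (`h`, `eps`, `S_vp`, `L`), `solution` (`rho`,
#' `eta`, `D`, `v_r`), `model` (`advection`/`general`), `fit_strategy`
#' (`per_condition`/`shared_kdbl`/`fixed_kdbl`), `fixed_kdbl_value`,
#' `sherwood_correlation`, `seed`, `output_dir`. The `fixed_kdbl` strategy
#' requires either `fixed_kdbl_value` or a `sherwood_correlation` to derive
#' one from.
#'
#' @param path YAML file path.
#' @return A list of class `"run_config"` with `geometry` and `solution`
#'   replaced by [module_geometry()] / [solution_properties()] objects.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$geometry)) {
    unknown <- setdiff(names(cfg$geometry), .geometry_keys)
    if (length(unknown)) {
      stop("unknown geometry keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg$geometry <- do.call(module_geometry, lapply(cfg$geometry, as.numeric))
  } else {
    cfg$geometry <- default_module_geometry()
  }
  if (!is.null(cfg$solution)) {
    unknown <- setdiff(names(cfg$solution), .solution_keys)
    if (length(unknown)) {
      stop("unknown solution keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg$solution <- do.call(solution_properties,
                            lapply(cfg$solution, as.numeric))
  } else {
    cfg$solution <- default_solution_properties()
  }
  cfg$model <- match.arg(cfg$model %||% "advection", c("advection", "general"))
  cfg$fit_strategy <- match.arg(cfg$fit_strategy %||% "per_condition",
                                c("per_condition", "shared_kdbl",
                                  "fixed_kdbl"))
  if (cfg$fit_strategy == "fixed_kdbl" &&
      is.null(cfg$fixed_kdbl_value) && is.null(cfg$sherwood_correlation)) {
    stop("fixed_kdbl strategy requires `fixed_kdbl_value` or ",
         "`sherwood_correlation`", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed %||% 20240126)
  cfg$output_dir <- cfg$output_dir %||% "."
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write fit and comparison reports
#'
#' Writes a parameter table (`parameters.csv`: condition, estimates with
#' 95% CI half-widths, residual sum of squares, df, adjusted r-squared), a
#' model-comparison table (`comparison.csv`: adjusted r-squared of both
#' models, F and p) when comparisons are supplied, and a machine-readable
#' `summary.json`. All floating-point values carry 6 significant digits.
#'
#' @param fits list of `"uf_fit"` objects (one per condition).
#' @param comparisons optional list of `"uf_ftest"` objects named like
#'   `fits`, each optionally carrying `adj_r2_general`/`adj_r2_advection`.
#' @param dir output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(fits, comparisons = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  get_par <- function(f, what, name) {
    v <- f[[what]]
    if (name %in% names(v)) unname(v[[name]]) else NA_real_
  }
  par_tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      condition_id = f$condition_id, model = f$model,
      sigma = get_par(f, "estimate", "sigma"),
      sigma_ci95 = get_par(f, "ci95", "sigma"),
      k_dbl = get_par(f, "estimate", "k_dbl"),
      k_dbl_ci95 = get_par(f, "ci95", "k_dbl"),
      k_m = get_par(f, "estimate", "k_m"),
      k_m_ci95 = get_par(f, "ci95", "k_m"),
      ss_res = f$ss_res, df = f$df, adj_r2 = f$adj_r2,
      stringsAsFactors = FALSE
    )
  }))
  num <- vapply(par_tab, is.double, logical(1))
  par_tab[num] <- lapply(par_tab[num], signif, digits = 6)
  params_path <- file.path(dir, "parameters.csv")
  utils::write.csv(par_tab, params_path, row.names = FALSE, quote = FALSE)
  written <- c(parameters = params_path)

  if (!is.null(comparisons) && length(comparisons)) {
    cmp_tab <- do.call(rbind, lapply(names(comparisons), function(id) {
      cm <- comparisons[[id]]
      data.frame(
        condition_id = id,
        adj_r2_general = cm$adj_r2_general %||% NA_real_,
        adj_r2_advection = cm$adj_r2_advection %||% NA_real_,
        F = cm$F, p = cm$p, stringsAsFactors = FALSE
      )
    }))
    num <- vapply(cmp_tab, is.double, logical(1))
    cmp_tab[num] <- lapply(cmp_tab[num], signif, digits = 6)
    cmp_path <- file.path(dir, "comparison.csv")
    utils::write.csv(cmp_tab, cmp_path, row.names = FALSE, quote = FALSE)
    written <- c(written, comparison = cmp_path)
  } else {
    message("no model comparisons supplied; comparison table omitted")
  }

  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(parameters = par_tab,
         comparisons = if (!is.null(comparisons) && length(comparisons)) {
           lapply(comparisons, unclass)
         } else NULL),
    summary_path, auto_unbox = TRUE, digits = 6, null = "null")
  written <- c(written, summary = summary_path)
  invisible(written)
}
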