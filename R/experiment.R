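# High-level simulation study: fit the synthetic grid at several SNR levels
# with either engine and collect per-voxel errors, the basis of the accuracy
# and precision comparisons.

#' Run the synthetic accuracy/precision study
#'
#' Generates (or takes) a ground-truth grid, synthesizes clean signals on the
#' protocol, fits the noiseless data and `n_instances` Rician replicates per
#' finite SNR with the chosen engine, and returns per-voxel errors for every
#' parameter and for the offset-Gaussian objective f_obj (whose "truth" value
#' is the objective evaluated at the true parameters against the same data).
#'
#' @param engine `"amico"` or `"nlls"`.
#' @param protocol A `pgse_protocol`.
#' @param grid Ground-truth tibble; defaults to the full 13,050-voxel grid.
#' @param snr_levels SNR levels to run (include `Inf` for noiseless).
#' @param n_instances Noise replicates per finite SNR.
#' @param seed Base seed for noise generation and LM starts.
#' @param lambda Tikhonov weight (amico engine).
#' @param n_starts,max_iter Non-linear engine controls.
#' @param nlls_sigma Noise scale assumed by the non-linear engine's
#'   offset-Gaussian objective across all conditions, emulating the original
#'   pipeline whose noise floor is calibrated once from the acquisition
#'   (default 1/20, the clinical b0 SNR). The linear engine's f_obj uses the
#'   per-condition 1/SNR.
#' @param free_d_ees Use the extended dictionary / free d_EES fit.
#' @return A `verdict_study`: list with long `errors` tibble (columns `snr`,
#'   `instance`, `voxel`, `parameter`, `truth`, `estimate`, `error`,
#'   `abs_error`), the `truth` grid, and the run configuration.
#' @export
run_simulation_study <- function(engine = c("amico", "nlls"),
                                 protocol = verdict_protocol(),
                                 grid = NULL,
                                 snr_levels = c(20, Inf),
                                 n_instances = 10, seed = 1,
                                 lambda = 0.001, n_starts = 10,
                                 max_iter = 100, nlls_sigma = 1 / 20,
                                 free_d_ees = FALSE) {
  engine <- match.arg(engine)
  if (is.null(grid)) grid <- verdict_parameter_grid()
  clean <- simulate_signals(grid, protocol)
  dict <- if (engine == "amico") verdict_dictionary(protocol, free_d_ees)
          else NULL
  fit_one <- function(signals, sigma, fit_seed) {
    if (engine == "amico") {
      fit_amico(signals, dict, lambda = lambda, sigma = sigma)
    } else {
      fit_nlls(signals, protocol, n_starts = n_starts, seed = fit_seed,
               sigma = nlls_sigma, free_d_ees = free_d_ees,
               max_iter = max_iter)
    }
  }
  fobj_truth <- function(observed, sigma) {
    s <- clean
    if (sigma == 0) return(rowSums((observed - s)^2))
    rowSums((observed - sqrt(s^2 + sigma^2))^2) / sigma^2
  }
  collect <- function(fit, observed, sigma, snr, instance) {
    e <- estimation_errors(fit$params, grid, instance = instance)
    ft <- fobj_truth(observed, sigma)
    fe <- tibble(voxel = seq_len(nrow(grid)), instance = instance,
                 parameter = "f_obj", truth = ft,
                 estimate = fit$params$f_obj,
                 error = fit$params$f_obj - ft)
    fe$abs_error <- abs(fe$error)
    e <- dplyr::bind_rows(e, fe)
    e$snr <- snr
    e
  }
  errors <- list()
  for (snr in snr_levels) {
    if (is.infinite(snr)) {
      obj_sigma <- if (engine == "nlls") nlls_sigma else 0
      fit <- fit_one(clean, 0, seed)
      errors[[length(errors) + 1]] <- collect(fit, clean, obj_sigma, Inf, 1L)
    } else {
      sigma <- 1 / snr
      obj_sigma <- if (engine == "nlls") nlls_sigma else sigma
      reps <- add_rician_noise(clean, snr, n_instances,
                               seed + 1000L * match(snr, snr_levels))
      for (i in seq_along(reps)) {
        fit <- fit_one(reps[[i]], sigma, seed + i)
        errors[[length(errors) + 1]] <- collect(fit, reps[[i]], obj_sigma,
                                                snr, i)
      }
    }
  }
  structure(list(errors = dplyr::bind_rows(errors), truth = grid,
                 engine = engine,
                 config = list(snr_levels = snr_levels,
                               n_instances = n_instances, seed = seed,
                               lambda = lambda, n_starts = n_starts,
                               nlls_sigma = nlls_sigma,
                               free_d_ees = free_d_ees)),
            class = "verdict_study")
}

#' @export
print.verdict_study <- function(x, ...) {
  cat(sprintf("<verdict_study> engine = %s, %d voxels, SNR levels: %s\n",
              x$engine, nrow(x$truth),
              paste(x$config$snr_levels, collapse = ", ")))
  invisible(x)
}

#' Precision ratios from a simulation study
#'
#' SD-of-error ratio between a finite-SNR condition and the infinite-SNR
#' reference, per parameter.
#'
#' @param study A `verdict_study` run with both `snr` and `Inf` among its
#'   SNR levels.
#' @param snr Finite SNR for the numerator (default 20).
#' @return Tibble from [precision_ratio()].
#' @export
study_precision_ratios <- function(study, snr = 20) {
  stopifnot(inherits(study, "verdict_study"))
  en <- dplyr::filter(study$errors, .data$snr == !!snr)
  er <- dplyr::filter(study$errors, is.infinite(.data$snr))
  if (nrow(en) == 0 || nrow(er) == 0) {
    abort("study must contain both the requested SNR and the infinite-SNR reference")
  }
  precision_ratio(en, er)
}

#' Mean absolute error by SNR from a simulation study
#'
#' @param study A `verdict_study`.
#' @return Tibble with one row per (snr, parameter): pooled mean and SD of
#'   absolute errors.
#' @export
study_error_by_snr <- function(study) {
  stopifnot(inherits(study, "verdict_study"))
  dplyr::summarise(
    dplyr::group_by(study$errors, .data$snr, .data$parameter),
    mean_abs_error = mean(.data$abs_error, na.rm = TRUE),
    sd_abs_error = stats::sd(.data$abs_error, na.rm = TRUE),
    .groups = "drop")
}

#' Uniformly subsample the parameter grid
#'
#' Deterministic, evenly spaced subsample used for the slower non-linear
#' engine.
#'
#' @param grid Tibble from [verdict_parameter_grid()].
#' @param n Target number of voxels.
#' @return Tibble with `n` rows.
#' @export
subsample_grid <- function(grid, n) {
  if (n >= nrow(grid)) return(grid)
  idx <- unique(round(seq(1, nrow(grid), length.out = n)))
  grid[idx, , drop = FALSE]
}
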