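# Synthetic-data generator: the (f_IC, f_EES, R) ground-truth grid, clean
# forward-model signals on the five-shell protocol, and Rician-noise
# replicates at stated b = 0 SNR levels.

#' Ground-truth parameter grid
#'
#' 30 equally spaced values for f_IC and f_EES on [0, 1] and 30 radii equally
#' spaced from 0.02 to 15 um. Fraction pairs are kept when f_IC > 0 and
#' f_IC + f_EES <= 1 (435 pairs), each crossed with the 30 radii:
#' 13,050 voxels in total. Diffusivities are fixed at d_IC = d_EES = 2e-9
#' and P = 8e-9 m^2/s; f_VASC = 1 - f_IC - f_EES.
#'
#' @return Tibble with one row per voxel: `f_ic`, `f_ees`, `f_vasc`,
#'   `radius` (m), `d_ic`, `d_ees`, `p`.
#' @export
verdict_parameter_grid <- function() {
  fr <- seq(0, 1, length.out = 30)
  pairs <- tidyr::expand_grid(f_ic = fr, f_ees = fr)
  pairs <- dplyr::filter(pairs, .data$f_ic > 0,
                         .data$f_ic + .data$f_ees <= 1 + 1e-12)
  radii <- seq(0.02e-6, 15e-6, length.out = 30)
  grid <- tidyr::expand_grid(pairs, radius = radii)
  dplyr::mutate(grid,
                f_vasc = pmax(1 - .data$f_ic - .data$f_ees, 0),
                d_ic = D_IC_FIXED, d_ees = D_EES_FIXED, p = P_VASC_FIXED)[
    , c("f_ic", "f_ees", "f_vasc", "radius", "d_ic", "d_ees", "p")]
}

#' Synthesize clean VERDICT signals for a parameter grid
#'
#' Evaluates the three-compartment forward model for every grid row on the
#' given protocol. Sphere signals are computed once per unique radius.
#'
#' @param grid Tibble from [verdict_parameter_grid()] (or any tibble with
#'   `f_ic`, `f_ees`, `f_vasc`, `radius`, `d_ees` columns).
#' @param protocol A `pgse_protocol`.
#' @param n_roots GPD series truncation.
#' @return Matrix (n_voxels x N_d) of clean signals; b = 0 columns are 1.
#' @export
simulate_signals <- function(grid, protocol = verdict_protocol(),
                             n_roots = 100) {
  stopifnot(inherits(protocol, "pgse_protocol"))
  radii <- sort(unique(grid$radius))
  sph <- vapply(radii, function(r) sphere_signal(protocol, r, D_IC_FIXED,
                                                 n_roots),
                numeric(nrow(protocol)))
  d_vals <- sort(unique(grid$d_ees))
  bl <- vapply(d_vals, function(d) ball_signal(protocol$b, d),
               numeric(nrow(protocol)))
  astro <- astrosticks_signal(protocol$b, P_VASC_FIXED)
  ri <- match(grid$radius, radii)
  di <- match(grid$d_ees, d_vals)
  s <- t(sph[, ri, drop = FALSE]) * grid$f_ic +
    t(bl[, di, drop = FALSE]) * grid$f_ees +
    matrix(astro, nrow(grid), nrow(protocol), byrow = TRUE) * grid$f_vasc
  s[, protocol$is_b0] <- 1
  s
}

#' Add Rician noise to signal vectors
#'
#' Each measurement S is replaced by sqrt((S + e1)^2 + e2^2) with e1, e2
#' independent zero-mean Gaussians of standard deviation 1/snr (SNR is
#' defined on the normalized b = 0 signal, which equals 1). Noise is applied
#' to all measurements including the b = 0 entries; no re-normalization is
#' performed. `snr = Inf` returns the input unchanged.
#'
#' @param signals Matrix of clean signals (voxels x measurements).
#' @param snr b = 0 signal-to-noise ratio (> 0; may be `Inf`).
#' @param n_instances Number of independent noise replicates.
#' @param seed Integer seed; replicate i uses a stream derived from
#'   (seed, i), so the set is reproducible and instances are independent.
#' @return List of `n_instances` noisy matrices.
#' @export
add_rician_noise <- function(signals, snr, n_instances = 1, seed = 1) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  if (is.na(snr) || snr <= 0) abort("snr must be positive (or Inf)")
  if (n_instances < 1) abort("n_instances must be >= 1")
  if (is.infinite(snr)) {
    return(lapply(seq_len(n_instances), function(i) signals))
  }
  sigma <- 1 / snr
  lapply(seq_len(n_instances), function(i) {
    withr::with_seed(seed + i - 1L, {
      e1 <- matrix(stats::rnorm(length(signals), sd = sigma), nrow(signals))
      e2 <- matrix(stats::rnorm(length(signals), sd = sigma), nrow(signals))
      sqrt((signals + e1)^2 + e2^2)
    })
  })
}

#' Generate the full synthetic study dataset
#'
#' Ground-truth grid, clean signals, and Rician replicates at each requested
#' SNR (10 instances each at SNR 20 and 50 by default; infinite SNR is the
#' clean data itself).
#'
#' @param protocol A `pgse_protocol`.
#' @param snr_levels Numeric SNR levels (may include `Inf`).
#' @param n_instances Replicates per finite SNR.
#' @param seed Base seed; each SNR level uses an offset stream.
#' @param grid Optional pre-built (possibly subsampled) truth grid.
#' @return A `verdict_simulation`: list with `truth`, `clean`, `noisy`
#'   (named list per SNR of replicate lists), `snr_levels`, `seeds`,
#'   `protocol`.
#' @export
simulate_verdict_dataset <- function(protocol = verdict_protocol(),
                                     snr_levels = c(20, 50, Inf),
                                     n_instances = 10, seed = 1,
                                     grid = NULL) {
  if (is.null(grid)) grid <- verdict_parameter_grid()
  clean <- simulate_signals(grid, protocol)
  noisy <- list()
  seeds <- list()
  for (k in seq_along(snr_levels)) {
    snr <- snr_levels[k]
    if (is.infinite(snr)) next
    snr_seed <- seed + 1000L * k
    noisy[[as.character(snr)]] <- add_rician_noise(clean, snr, n_instances,
                                                   snr_seed)
    seeds[[as.character(snr)]] <- snr_seed + seq_len(n_instances) - 1L
  }
  structure(list(truth = grid, clean = clean, noisy = noisy,
                 snr_levels = snr_levels, seeds = seeds, protocol = protocol),
            class = "verdict_simulation")
}

#' @export
print.verdict_simulation <- function(x, ...) {
  cat(sprintf("<verdict_simulation> %d voxels, %d measurements; SNR levels: %s\n",
              nrow(x$truth), ncol(x$clean),
              paste(x$snr_levels, collapse = ", ")))
  invisible(x)
}

#' Export a synthetic dataset as plain-text files
#'
#' Writes `truth.csv` (fractions and R in um), `clean_signals.txt` and one
#' `signals_snr<level>_<instance>.txt` per replicate, plus a JSON manifest of
#' seeds and sizes.
#'
#' @param dataset A `verdict_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- dplyr::mutate(dataset$truth, radius_um = .data$radius * 1e6,
                         radius = NULL)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.table(dataset$clean, file.path(dir, "clean_signals.txt"),
                     row.names = FALSE, col.names = FALSE)
  for (snr in names(dataset$noisy)) {
    reps <- dataset$noisy[[snr]]
    for (i in seq_along(reps)) {
      utils::write.table(
        reps[[i]],
        file.path(dir, sprintf("signals_snr%s_%02d.txt", snr, i)),
        row.names = FALSE, col.names = FALSE)
    }
  }
  manifest <- list(n_voxels = nrow(dataset$truth),
                   n_measurements = ncol(dataset$clean),
                   snr_levels = dataset$snr_levels, seeds = dataset$seeds)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
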