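#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
NULL

#' Proton gyromagnetic ratio
#'
#' The gyromagnetic ratio of the proton in rad s^-1 T^-1, used throughout for
#' b-value computation and signal synthesis.
#' @export
GAMMA_PROTON <- 2.675153e8

#' Compute the PGSE b-value
#'
#' Computes b = (Delta - delta/3) * (gamma * delta * |G|)^2 for a pulsed
#' gradient spin echo measurement. All arguments are in SI units; the result
#' is in s/m^2 (divide by 1e6 for the conventional s/mm^2).
#'
#' @param big_delta Gradient separation Delta (s).
#' @param small_delta Gradient duration delta (s).
#' @param gradient Gradient strength |G| (T/m).
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1).
#' @return Numeric vector of b-values (s/m^2); zero exactly where |G| = 0.
#' @examples
#' # the 2000 s/mm^2 shell of the built-in prostate protocol
#' compute_bvalue(34.3e-3, 14.4e-3, 67.7e-3) / 1e6
#' @export
compute_bvalue <- function(big_delta, small_delta, gradient,
                           gamma = GAMMA_PROTON) {
  if (any(!is.finite(big_delta)) || any(!is.finite(small_delta)) ||
      any(!is.finite(gradient))) {
    abort("timings and gradient strengths must be finite")
  }
  if (any(big_delta <= 0) || any(small_delta <= 0)) {
    abort("pulse timings must be positive")
  }
  if (any(small_delta >= big_delta)) {
    abort("gradient duration delta must be smaller than separation Delta")
  }
  if (any(gradient < 0)) abort("gradient strength must be nonnegative")
  (big_delta - small_delta / 3) * (gamma * small_delta * gradient)^2
}

#' Construct a PGSE protocol
#'
#' Validates a table of pulsed-gradient spin-echo measurements and attaches
#' derived b-values. One row per measurement with columns `gx`, `gy`, `gz`
#' (unit direction; zero for b = 0 rows), `gradient` (|G|, T/m), `big_delta`
#' (s), `small_delta` (s), `te` (s) and optionally `tr` (s).
#'
#' @param measurements A data frame with the columns above.
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1).
#' @return A tibble of class `pgse_protocol` with added columns `b` (s/m^2)
#'   and `is_b0`.
#' @export
pgse_protocol <- function(measurements, gamma = GAMMA_PROTON) {
  m <- as_tibble(measurements)
  needed <- c("gx", "gy", "gz", "gradient", "big_delta", "small_delta", "te")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0) {
    abort(paste0("protocol is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"tr" %in% names(m)) m$tr <- NA_real_
  bad <- which(m$big_delta <= 0 | m$small_delta <= 0 | m$te <= 0 |
                 m$small_delta >= m$big_delta | m$gradient < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid timings (need 0 < delta < Delta, te > 0, |G| >= 0) in measurement %s",
      paste(bad, collapse = ", ")))
  }
  nrm <- sqrt(m$gx^2 + m$gy^2 + m$gz^2)
  bad_dir <- which(m$gradient > 0 & abs(nrm - 1) > 1e-6)
  if (length(bad_dir) > 0) {
    abort(sprintf("non-unit gradient direction in measurement %s",
                  paste(bad_dir, collapse = ", ")))
  }
  m$b <- compute_bvalue(m$big_delta, m$small_delta, m$gradient, gamma)
  m$is_b0 <- m$gradient == 0
  attr(m, "gamma") <- gamma
  class(m) <- c("pgse_protocol", class(m))
  m
}

# Table of the five-shell prostate acquisition (nominal b in s/mm^2, timings
# in ms, |G| in mT/m): one row per shell with its TE-matched b = 0 image.
prostate_shell_table <- function() {
  tibble(
    b_nominal   = c(90, 500, 1500, 2000, 3000),
    big_delta   = c(23.8, 31.3, 43.8, 34.3, 38.8) * 1e-3,
    small_delta = c(3.9, 11.4, 23.9, 14.4, 18.9) * 1e-3,
    gradient    = c(61.2, 44.3, 32.0, 67.7, 60.0) * 1e-3,
    te          = c(50, 65, 90, 71, 80) * 1e-3,
    tr          = c(2482, 2482, 2482, 3945, 3349) * 1e-3
  )
}

#' Built-in five-shell prostate VERDICT protocol
#'
#' The optimized prostate acquisition: five diffusion shells at nominal
#' b = 90, 500, 1500, 2000 and 3000 s/mm^2, each measured along the three
#' coordinate axes, plus one b = 0 measurement per shell (per echo time),
#' giving 20 normalized measurements per voxel.
#'
#' @return A `pgse_protocol` tibble with 20 rows (15 diffusion-weighted,
#'   5 b = 0), diffusion-weighted rows first in shell order.
#' @export
verdict_protocol <- function() {
  sh <- prostate_shell_table()
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  dw <- do.call(rbind, lapply(seq_len(nrow(sh)), function(i) {
    tibble(gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3],
           gradient = sh$gradient[i], big_delta = sh$big_delta[i],
           small_delta = sh$small_delta[i], te = sh$te[i], tr = sh$tr[i])
  }))
  b0 <- tibble(gx = 0, gy = 0, gz = 0, gradient = 0,
               big_delta = sh$big_delta, small_delta = sh$small_delta,
               te = sh$te, tr = sh$tr)
  pgse_protocol(rbind(dw, b0))
}

#' Look up a built-in protocol by name
#'
#' @param name Protocol name; currently only `"prostate-verdict-5shell"`.
#' @return A `pgse_protocol`.
#' @export
builtin_protocol <- function(name = "prostate-verdict-5shell") {
  switch(name,
         "prostate-verdict-5shell" = verdict_protocol(),
         abort(sprintf("unknown built-in protocol '%s'", name)))
}

SCHEME_HEADER <- "VERSION: STEJSKALTANNER"

#' Read and write PGSE scheme files
#'
#' Plain-text scheme dialect: a header line `VERSION: STEJSKALTANNER`
#' followed by one measurement per line with whitespace-separated columns
#' `gx gy gz |G| Delta delta TE`, all in SI units (T/m and s).
#'
#' @param path File path.
#' @param protocol A `pgse_protocol`.
#' @return `load_scheme` returns a `pgse_protocol`; `save_scheme` returns
#'   `path` invisibly.
#' @export
load_scheme <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2) abort("scheme file has no measurement rows")
  if (trimws(lines[1]) != SCHEME_HEADER) {
    abort(sprintf("line 1: expected header '%s'", SCHEME_HEADER))
  }
  rows <- lapply(seq_along(lines[-1]), function(i) {
    fields <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 7 || any(is.na(vals))) {
      abort(sprintf("line %d: expected 7 numeric columns (gx gy gz |G| Delta delta TE)",
                    i + 1))
    }
    if (vals[5] <= 0 || vals[6] <= 0 || vals[7] <= 0 || vals[6] >= vals[5]) {
      abort(sprintf("line %d: non-physical timings (need 0 < delta < Delta, TE > 0)",
                    i + 1))
    }
    if (vals[4] > 0 && abs(sqrt(sum(vals[1:3]^2)) - 1) > 1e-6) {
      abort(sprintf("line %d: gradient direction is not a unit vector", i + 1))
    }
    vals
  })
  m <- do.call(rbind, rows)
  out <- tryCatch(
    pgse_protocol(tibble(gx = m[, 1], gy = m[, 2], gz = m[, 3],
                         gradient = m[, 4], big_delta = m[, 5],
                         small_delta = m[, 6], te = m[, 7])),
    error = function(e) {
      abort(sprintf("scheme validation failed: %s (line numbers are row + 1)",
                    conditionMessage(e)))
    })
  out
}

#' @rdname load_scheme
#' @export
save_scheme <- function(protocol, path) {
  stopifnot(inherits(protocol, "pgse_protocol"))
  body <- sprintf("%.10g %.10g %.10g %.10g %.10g %.10g %.10g",
                  protocol$gx, protocol$gy, protocol$gz, protocol$gradient,
                  protocol$big_delta, protocol$small_delta, protocol$te)
  writeLines(c(SCHEME_HEADER, body), path)
  invisible(path)
}
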