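# The VERDICT-AMICO signal dictionary: precomputed compartment signal
# vectors (atoms) stacked as columns of Phi = [Phi_r | Phi_e | Phi_v].

#' Build a VERDICT-AMICO signal dictionary
#'
#' Constructs the dictionary matrix for a protocol. The original dictionary
#' has 17 sphere atoms with radii linearly spaced from 0.01 to 15.1 um at
#' fixed d_IC = 2e-9 m^2/s, one ball atom at d_EES = 2e-9 m^2/s and one
#' astrosticks atom at P = 8e-9 m^2/s (19 atoms). The free-d_EES variant has
#' 13 sphere atoms over the same radius range, 5 ball atoms at d_EES in
#' {1.1, 1.6, 2.1, 2.6, 3.1}e-9 m^2/s and one astrosticks atom (19 atoms).
#'
#' Atoms are raw normalized signals (no column rescaling) so fitted weights
#' are directly volume fractions.
#'
#' @param protocol A `pgse_protocol`.
#' @param free_d_ees Build the extended dictionary with multiple EES
#'   diffusivities?
#' @param n_roots GPD series truncation for the sphere atoms.
#' @return A `verdict_dictionary`: list with matrix `phi` (N_d x N_k), atom
#'   label tibble `atoms` (columns `compartment`, `radius`, `d`), partition
#'   sizes `n_r`, `n_e`, `n_v`, and the protocol.
#' @export
verdict_dictionary <- function(protocol, free_d_ees = FALSE, n_roots = 100) {
  stopifnot(inherits(protocol, "pgse_protocol"))
  if (free_d_ees) {
    radii <- seq(R_MIN, R_MAX, length.out = 13)
    d_ees <- c(1.1, 1.6, 2.1, 2.6, 3.1) * 1e-9
  } else {
    radii <- seq(R_MIN, R_MAX, length.out = 17)
    d_ees <- D_EES_FIXED
  }
  n_d <- nrow(protocol)
  n_r <- length(radii); n_e <- length(d_ees); n_v <- 1L
  n_k <- n_r + n_e + n_v
  if (n_k > n_d) {
    abort(sprintf(
      "dictionary has %d atoms but only %d measurements; the simple Tikhonov regularizer needs N_k <= N_d",
      n_k, n_d))
  }
  phi_r <- vapply(radii, function(r) {
    s <- sphere_signal(protocol, r, D_IC_FIXED, n_roots)
    s[protocol$is_b0] <- 1
    s
  }, numeric(n_d))
  phi_e <- vapply(d_ees, function(d) {
    s <- ball_signal(protocol$b, d)
    s[protocol$is_b0] <- 1
    s
  }, numeric(n_d))
  phi_v <- {
    s <- astrosticks_signal(protocol$b, P_VASC_FIXED)
    s[protocol$is_b0] <- 1
    matrix(s, ncol = 1)
  }
  atoms <- tibble(
    compartment = c(rep("IC", n_r), rep("EES", n_e), "VASC"),
    radius = c(radii, rep(NA_real_, n_e + n_v)),
    d = c(rep(D_IC_FIXED, n_r), d_ees, P_VASC_FIXED))
  out <- list(phi = cbind(phi_r, phi_e, phi_v), atoms = atoms,
              n_r = n_r, n_e = n_e, n_v = n_v, free_d_ees = free_d_ees,
              protocol = protocol)
  class(out) <- "verdict_dictionary"
  out
}

#' @export
print.verdict_dictionary <- function(x, ...) {
  cat(sprintf("<verdict_dictionary> %d x %d (N_r = %d sphere, N_e = %d ball, N_v = %d astrosticks)\n",
              nrow(x$phi), ncol(x$phi), x$n_r, x$n_e, x$n_v))
  invisible(x)
}

#' Export / import a dictionary as plain text
#'
#' Writes the matrix as whitespace-delimited text and the atom labels as a
#' sidecar CSV (`<path>.atoms.csv`).
#'
#' @param dict A `verdict_dictionary`.
#' @param path Matrix file path.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary_matrix`
#'   returns a list with `phi` and `atoms`.
#' @export
write_dictionary <- function(dict, path) {
  utils::write.table(dict$phi, path, row.names = FALSE, col.names = FALSE)
  utils::write.csv(dict$atoms, paste0(path, ".atoms.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary_matrix <- function(path) {
  phi <- as.matrix(utils::read.table(path))
  dimnames(phi) <- NULL
  atoms <- as_tibble(utils::read.csv(paste0(path, ".atoms.csv")))
  list(phi = phi, atoms = atoms)
}
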