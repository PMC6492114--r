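# Shared fixtures and independent oracles, built in code at test time.

# Cached built-ins (construction is deterministic).
the <- new.env()

fix_protocol <- function() {
  if (is.null(the$protocol)) the$protocol <- verdict_protocol()
  the$protocol
}

fix_dictionary <- function(free_d_ees = FALSE) {
  key <- if (free_d_ees) "dict_free" else "dict"
  if (is.null(the[[key]])) the[[key]] <- verdict_dictionary(fix_protocol(),
                                                            free_d_ees)
  the[[key]]
}

# A small protocol: two shells (b = 500 and 2000 rows of the prostate
# acquisition) x 3 directions + 2 b0 rows.
small_protocol <- function() {
  p <- fix_protocol()
  pgse_protocol(p[c(4:6, 10:12, 17, 19), setdiff(names(p), c("b", "is_b0"))])
}

# Independent accelerated projected-gradient (FISTA) solver for
# min_{x>=0} 1/2 ||phi x - y||^2 + lambda ||x||^2, used as a generic convex
# QP oracle against the active-set implementation.
qp_oracle_objective <- function(phi, y, lambda, iters = 8000) {
  L <- max(eigen(crossprod(phi), symmetric = TRUE,
                 only.values = TRUE)$values) + 2 * lambda
  x <- z <- numeric(ncol(phi))
  tk <- 1
  for (k in seq_len(iters)) {
    g <- crossprod(phi, phi %*% z - y) + 2 * lambda * z
    xn <- pmax(z - g / L, 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- xn + (tk - 1) / tn * (xn - x)
    x <- xn
    tk <- tn
  }
  0.5 * sum((phi %*% x - y)^2) + lambda * sum(x^2)
}

rnnls_objective <- function(phi, y, lambda, x) {
  0.5 * sum((phi %*% x - y)^2) + lambda * sum(x^2)
}
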