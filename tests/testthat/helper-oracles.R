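# Independent numeric oracles used across tests.

# MI of a channel whose conditional laws are normal with the given means
# and SDs and whose input takes each component with weight w: brute-force
# continuous quadrature of the MI integral, independent of the package's
# discretized-grid pipeline.
gaussian_channel_mi_oracle <- function(mus, sigmas,
                                       w = rep(1 / length(mus),
                                               length(mus))) {
  f <- function(y) {
    px <- vapply(seq_along(mus),
                 function(i) dnorm(y, mus[i], sigmas[i]),
                 numeric(length(y)))
    if (is.null(dim(px))) px <- matrix(px, nrow = length(y))
    pm <- drop(px %*% w)
    acc <- numeric(length(y))
    for (i in seq_along(mus)) {
      v <- px[, i] * log2(px[, i] / pm)
      v[!is.finite(v)] <- 0
      acc <- acc + w[i] * v
    }
    acc
  }
  integrate(f, min(mus) - 12 * max(sigmas), max(mus) + 12 * max(sigmas),
            subdivisions = 2000, rel.tol = 1e-10)$value
}

# central finite differences of propensities with respect to the state
numeric_propensity_jacobian <- function(net, z, x = 0, h = 1e-4) {
  M <- nrow(net$nu)
  N <- length(net$species)
  jac <- matrix(0, M, N)
  for (k in seq_len(N)) {
    zp <- z; zp[k] <- z[k] + h
    zm <- z; zm[k] <- z[k] - h
    jac[, k] <- (propensities(net, zp, x) - propensities(net, zm, x)) /
      (2 * h)
  }
  jac
}

# hand-built two-species dose surface with normal conditionals, used to
# exercise the joint-MI machinery without a reaction network
manual_surface <- function(doses, times, mu1, mu2, v1, v2, c12) {
  nd <- length(doses)
  nt <- length(times)
  mu <- array(0, c(nd, nt, 2), dimnames = list(NULL, NULL, c("Y1r", "Y2")))
  cv <- array(0, c(nd, nt, 2, 2),
              dimnames = list(NULL, NULL, c("Y1r", "Y2"), c("Y1r", "Y2")))
  for (d in seq_len(nd)) {
    for (t in seq_len(nt)) {
      mu[d, t, ] <- c(mu1[d], mu2[d])
      cv[d, t, , ] <- matrix(c(v1[d], c12[d], c12[d], v2[d]), 2)
    }
  }
  structure(list(doses = doses, times_min = times,
                 species = c("Y1r", "Y2"), mu = mu, cov = cv),
            class = "dose_surface")
}
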