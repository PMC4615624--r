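# Reconstruction of conditional output laws from the first two moments.
# Low-mean, over-dispersed states get a moment-matched negative binomial
# (the natural stationary family for linear transcription), high-mean
# states a normal; the boundary C == mu degenerates to Poisson, and a
# vanishing variance to a point mass.

#' Build a distribution model from mean and variance
#'
#' Applies the reconstruction rule used throughout the package: when
#' `mu < 3 * sqrt(C)` the law is a moment-matched negative binomial
#' (`size = mu^2 / (C - mu)`, reproducing mean `mu` and variance `C`
#' exactly), degenerating to Poisson when `C <= mu`; when
#' `mu >= 3 * sqrt(C)` the negative binomial is indistinguishable from a
#' normal and a normal(mu, C) is used. A vanishing mean or variance yields
#' a point mass.
#'
#' @param mu mean (>= 0).
#' @param C variance (> 0, or 0 for a point mass).
#' @param label optional label naming the upstream moment state, used in
#'   error messages.
#' @return Object of class `dist_model`: list with `family` (one of
#'   `"negative-binomial"`, `"normal"`, `"poisson"`, `"point"`), `mu`, `C`,
#'   and family parameters.
#' @export
#' @examples
#' dist_from_moments(100, 400)$family  # "normal": 3*sqrt(400) = 60 < 100
#' dist_from_moments(10, 25)$family    # "negative-binomial"
dist_from_moments <- function(mu, C, label = NULL) {
  if (!is.finite(mu) || !is.finite(C) || mu < 0 || C < 0) {
    stop("invalid moments (mu = ", mu, ", C = ", C, ")",
         if (!is.null(label)) paste0(" from ", label), call. = FALSE)
  }
  eps <- 1e-12
  if (C <= eps || mu <= eps) {
    return(structure(list(family = "point", mu = mu, C = 0,
                          at = max(mu, 0)), class = "dist_model"))
  }
  if (mu < 3 * sqrt(C)) {
    if (C > mu) {
      size <- mu^2 / (C - mu)
      structure(list(family = "negative-binomial", mu = mu, C = C,
                     size = size, p = mu / C), class = "dist_model")
    } else {
      structure(list(family = "poisson", mu = mu, C = mu),
                class = "dist_model")
    }
  } else {
    structure(list(family = "normal", mu = mu, C = C),
              class = "dist_model")
  }
}

#' @export
print.dist_model <- function(x, ...) {
  cat("<dist_model>", x$family, " mu =", signif(x$mu, 6),
      " var =", signif(x$C, 6), "\n")
  invisible(x)
}

dist_density <- function(d, y) {
  switch(d$family,
    point = as.numeric(abs(y - d$at) < 0.5),
    poisson = dpois(round(y), d$mu),
    `negative-binomial` = dnbinom(round(y), size = d$size, mu = d$mu),
    normal = dnorm(y, d$mu, sqrt(d$C))
  )
}

dist_upper <- function(d, tail = 1e-10) {
  switch(d$family,
    point = d$at,
    poisson = qpois(tail, d$mu, lower.tail = FALSE),
    `negative-binomial` = qnbinom(tail, size = d$size, mu = d$mu,
                                  lower.tail = FALSE),
    normal = d$mu + 8 * sqrt(d$C)
  )
}

#' Discretized probability mass of a distribution model
#'
#' Evaluates the reconstructed law on a discrete support suitable for the
#' mutual-information sums. Count families use their integer support
#' truncated where the upper-tail mass falls below `tail`; a normal is
#' discretized on `mu +/- 8*sqrt(C)` with bin width at most `sqrt(C)/20`
#' (and at most `dx_max`). Probabilities are renormalized to sum to one.
#'
#' @param d a `dist_model`.
#' @param tail tail mass at which integer supports are truncated.
#' @param dx_max upper bound on the bin width (default 1 molecule).
#' @return List with `support`, bin width `dx`, and probabilities `p`
#'   summing to 1.
#' @export
dist_pmf <- function(d, tail = 1e-10, dx_max = 1) {
  if (d$family == "point") {
    return(list(support = d$at, dx = 1, p = 1))
  }
  if (d$family == "normal") {
    sdv <- sqrt(d$C)
    dx <- min(sdv / 20, dx_max)
    support <- seq(max(d$mu - 8 * sdv, 0) , d$mu + 8 * sdv, by = dx)
    p <- dnorm(support, d$mu, sdv)
  } else {
    support <- 0:max(dist_upper(d, tail), 2)
    dx <- 1
    p <- dist_density(d, support)
  }
  list(support = support, dx = dx, p = p / sum(p))
}

#' Multivariate normal distribution model
#'
#' Joint laws (for simultaneous reporter/output measurements) are always
#' modeled as multivariate normal, matching the regime in which the joint
#' computations are performed (high copy number, approximately gaussian
#' marginals).
#'
#' @param mu mean vector.
#' @param C covariance matrix; symmetrized, must be positive semi-definite.
#' @export
joint_normal <- function(mu, C) {
  C <- as.matrix(C)
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  structure(list(family = "mvnormal", mu = mu, C = C),
            class = "dist_model")
}

#' Conditional law of the second coordinate of a bivariate normal
#'
#' @param d a bivariate `joint_normal` model.
#' @param y1 conditioning values (vectorized).
#' @param var_floor lower bound applied to the conditional variance, which
#'   guards the perfectly correlated limit on a discretized grid.
#' @return List with vectors `mean` (per `y1`) and scalar `var`.
#' @export
conditional_normal <- function(d, y1, var_floor = 0.25) {
  stopifnot(d$family == "mvnormal", length(d$mu) == 2)
  s11 <- d$C[1, 1]; s22 <- d$C[2, 2]; s12 <- d$C[1, 2]
  if (s11 <= 0) {
    return(list(mean = rep(d$mu[2], length(y1)),
                var = max(s22, var_floor)))
  }
  rho2 <- min(s12^2 / (s11 * s22), 0.9999)
  list(mean = d$mu[2] + s12 / s11 * (y1 - d$mu[1]),
       var = max(s22 * (1 - rho2), var_floor))
}
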