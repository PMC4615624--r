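# Time-dependent mutual information between a step input and snapshot
# readouts. A dose-response surface stores per-dose, per-time moments of
# all species; conditional output laws are reconstructed from the moments,
# the input is treated as uniform over the dose range through a finely
# interpolated dose grid, and the information sums run over the shared
# discrete support of the reconstructed laws.

#' Build a time-dependent dose-response surface
#'
#' Propagates the network moments from a common initial condition once per
#' dose (the step turning on at t = 0) and stores means and covariances of
#' all species at the requested output times. The t = 0 entry is
#' dose-independent by construction.
#'
#' @param net a [reaction_network()].
#' @param doses step amplitudes (nM), at least 2, sorted internally.
#' @param times_min output times (minutes).
#' @param init a [moment_state()] shared by all doses (see
#'   [make_initial()]).
#' @param rtol,atol integrator tolerances passed to [integrate_moments()].
#' @return Object of class `dose_surface`: list with `doses`, `times_min`,
#'   `species`, `mu` (doses x times x species), `cov`
#'   (doses x times x species x species).
#' @export
build_surface <- function(net, doses, times_min, init, rtol = 1e-8,
                          atol = 1e-8) {
  stopifnot(length(doses) >= 2, !anyDuplicated(doses))
  doses <- sort(doses)
  N <- length(net$species)
  mu <- array(NA_real_, c(length(doses), length(times_min), N),
              dimnames = list(NULL, NULL, net$species))
  cv <- array(NA_real_, c(length(doses), length(times_min), N, N),
              dimnames = list(NULL, NULL, net$species, net$species))
  for (d in seq_along(doses)) {
    tr <- tryCatch(
      integrate_moments(net, init, times_min, x = doses[d], rtol = rtol,
                        atol = atol),
      error = function(e) {
        stop("moment propagation failed at dose ", doses[d], " nM: ",
             conditionMessage(e), call. = FALSE)
      })
    mu[d, , ] <- tr$mean
    cv[d, , , ] <- aperm(tr$cov, c(3, 1, 2))
  }
  structure(list(doses = doses, times_min = times_min,
                 species = net$species, mu = mu, cov = cv),
            class = "dose_surface")
}

#' @export
print.dose_surface <- function(x, ...) {
  cat("<dose_surface>", length(x$doses), "doses x", length(x$times_min),
      "times;", length(x$species), "species\n")
  invisible(x)
}

surface_time_index <- function(surface, time_min) {
  i <- match(time_min, surface$times_min)
  if (is.na(i)) stop("time ", time_min, " min not on the surface",
                     call. = FALSE)
  i
}

#' Interpolate surface moments at an arbitrary dose
#'
#' Means and central moments are interpolated linearly between the
#' bracketing sampled doses; queries outside the sampled range are an
#' error.
#'
#' @param surface a `dose_surface`.
#' @param x dose (nM) within the sampled range.
#' @param time_min one of the surface times.
#' @param observables species subset (default all).
#' @return List with mean vector `mu` and covariance `C`.
#' @export
interpolate_surface <- function(surface, x, time_min,
                                observables = surface$species) {
  if (x < min(surface$doses) || x > max(surface$doses)) {
    stop("dose ", x, " nM outside the sampled range", call. = FALSE)
  }
  ti <- surface_time_index(surface, time_min)
  d <- surface$doses
  hi <- findInterval(x, d, rightmost.closed = TRUE) + 1L
  hi <- min(max(hi, 2L), length(d))
  lo <- hi - 1L
  w <- (x - d[lo]) / (d[hi] - d[lo])
  ob <- match(observables, surface$species)
  mu <- (1 - w) * surface$mu[lo, ti, ob] + w * surface$mu[hi, ti, ob]
  C <- (1 - w) * surface$cov[lo, ti, ob, ob] +
    w * surface$cov[hi, ti, ob, ob]
  list(mu = setNames(as.vector(mu), observables),
       C = matrix(C, length(ob), length(ob),
                  dimnames = list(observables, observables)))
}

fine_moments <- function(surface, time_min, observable, n_grid) {
  ti <- surface_time_index(surface, time_min)
  k <- match(observable, surface$species)
  if (is.na(k)) stop("unknown observable: ", observable, call. = FALSE)
  xs <- seq(min(surface$doses), max(surface$doses), length.out = n_grid)
  mu <- pmax(approx(surface$doses, surface$mu[, ti, k], xs)$y, 0)
  C <- pmax(approx(surface$doses, surface$cov[, ti, k, k], xs)$y, 0)
  list(xs = xs, mu = mu, C = C)
}

mi_from_moment_sets <- function(mu, C, w = NULL, tail = 1e-10) {
  n <- length(mu)
  if (is.null(w)) w <- rep(1 / n, n)
  mu <- pmax(mu, 0)
  C <- pmax(C, 0)
  dists <- lapply(seq_len(n), function(i) dist_from_moments(mu[i], C[i]))
  ymax <- max(vapply(dists, dist_upper, numeric(1), tail = tail), 2)
  ygrid <- 0:ceiling(ymax)
  pmix <- numeric(length(ygrid))
  hc <- 0
  for (i in seq_len(n)) {
    p <- dist_density(dists[[i]], ygrid)
    s <- sum(p)
    if (s <= 0) next
    p <- p / s
    pmix <- pmix + w[i] * p
    nz <- p > 0
    hc <- hc + w[i] * sum(p[nz] * log2(p[nz]))
  }
  nz <- pmix > 0
  max(hc - sum(pmix[nz] * log2(pmix[nz])), 0)
}

#' Time-dependent mutual information of a single readout
#'
#' Evaluates I(x+; y, t) for a uniform input over the sampled dose range:
#' the per-dose moments are linearly interpolated onto a fine dose grid,
#' conditional laws are reconstructed with [dist_from_moments()], and the
#' information sum runs over the shared integer support of all conditional
#' laws (counts being the native support of the reconstructed
#' distributions).
#'
#' @param surface a `dose_surface`.
#' @param times_min surface time(s) at which to evaluate.
#' @param observable species name of the readout.
#' @param n_grid number of interpolated doses representing the continuous
#'   uniform input (default 501).
#' @param tail tail mass at which supports are truncated.
#' @return Numeric vector of MI values in bits, one per time.
#' @export
mutual_information <- function(surface, times_min, observable,
                               n_grid = 501, tail = 1e-10) {
  vapply(times_min, function(tm) {
    fm <- fine_moments(surface, tm, observable, n_grid)
    if (tm > 0 && all(fm$C <= 0)) {
      if (max(fm$mu) - min(fm$mu) < 1e-9) return(0)
      stop("degenerate zero-variance output distribution at t = ", tm,
           " min", call. = FALSE)
    }
    mi_from_moment_sets(fm$mu, fm$C, tail = tail)
  }, numeric(1))
}

#' Mutual-information time course as a tidy data frame
#'
#' @inheritParams mutual_information
#' @param conditioning label recorded in the output (e.g. `"S1"`,
#'   `"population"`).
#' @export
mi_curve <- function(surface, times_min = surface$times_min, observable,
                     n_grid = 501, conditioning = "population") {
  data.frame(time_min = times_min, conditioning = conditioning,
             observable = observable,
             bits = mutual_information(surface, times_min, observable,
                                       n_grid = n_grid))
}

#' Select the number of dose-sampled experiments for converged MI
#'
#' Computes MI with increasing numbers N of log-spaced step doses (the
#' nested protocols of [log_step_protocol()]) and applies a three-point
#' geometric extrapolation to the last three values: with increments
#' assumed to shrink geometrically at rate r, the limiting value is
#' `MI(N) + d * ratio / (1 - ratio)`, with `d = MI(N) - MI(N-1)` and
#' `ratio` the quotient of the last two increments. The smallest N within
#' `rel_tol` of the extrapolated bound is selected; a non-contracting ratio
#' (r >= 1) defers the decision to larger N.
#'
#' @param net a [reaction_network()].
#' @param init shared initial condition.
#' @param time_min evaluation time (minutes).
#' @param xmax maximum dose (nM).
#' @param observable readout species.
#' @param candidates increasing consecutive candidate values of N (>= 3
#'   entries).
#' @param ratio geometric dose spacing ratio.
#' @param n_grid fine-grid size for each MI evaluation.
#' @param rel_tol relative convergence criterion (default 1 percent).
#' @return List with `N` (chosen count, `NA` if never met), `converged`,
#'   `mi` (data frame of N and bits), `mi_inf` (last extrapolated bound).
#' @export
choose_N <- function(net, init, time_min, xmax = 250, observable = "Y2",
                     candidates = 4:24, ratio = 2 / 3, n_grid = 501,
                     rel_tol = 0.01) {
  stopifnot(length(candidates) >= 3, !is.unsorted(candidates),
            all(diff(candidates) == 1))
  n_max <- max(candidates)
  all_doses <- log_step_protocol(xmax, n_max, ratio)$amplitudes
  surface <- build_surface(net, all_doses, c(0, time_min), init)
  mi_n <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    n <- candidates[i]
    doses_n <- c(0, xmax * ratio^((n - 2):0))
    sub <- subset_surface(surface, doses_n)
    mi_n[i] <- mutual_information(sub, time_min, observable,
                                  n_grid = n_grid)
  }
  sel <- select_converged_n(candidates, mi_n, rel_tol)
  if (!sel$converged) {
    warning("convergence criterion not met within candidate range; ",
            "returning best available N")
  }
  c(sel, list(mi = data.frame(N = candidates, bits = mi_n)))
}

# three-point geometric (Aitken-style) extrapolation over consecutive
# sample counts; returns the smallest N within rel_tol of the bound
select_converged_n <- function(candidates, mi_n, rel_tol = 0.01) {
  chosen <- NA_integer_
  mi_inf <- NA_real_
  converged <- FALSE
  for (i in 3:length(candidates)) {
    d1 <- mi_n[i - 1] - mi_n[i - 2]
    d2 <- mi_n[i] - mi_n[i - 1]
    if (abs(d2) < 1e-12) {                    # flat: already converged
      chosen <- candidates[i]; mi_inf <- mi_n[i]; converged <- TRUE
      break
    }
    r <- d2 / d1
    if (!is.finite(r) || r >= 1 || r <= 0) next
    extr <- mi_n[i] + d2 * r / (1 - r)
    mi_inf <- extr
    if (abs(mi_n[i] - extr) <= rel_tol * abs(extr)) {
      chosen <- candidates[i]; converged <- TRUE
      break
    }
  }
  if (is.na(chosen)) chosen <- max(candidates)
  list(N = chosen, converged = converged, mi_inf = mi_inf)
}

subset_surface <- function(surface, doses) {
  idx <- match(doses, surface$doses)
  if (anyNA(idx)) stop("doses not on the surface", call. = FALSE)
  idx <- sort(idx)
  structure(list(doses = surface$doses[idx], times_min = surface$times_min,
                 species = surface$species,
                 mu = surface$mu[idx, , , drop = FALSE],
                 cov = surface$cov[idx, , , , drop = FALSE]),
            class = "dose_surface")
}

#' Joint mutual information of two simultaneous readouts
#'
#' Evaluates I(x+; [y1 y2], t) treating the per-dose conditional law of the
#' readout pair as bivariate normal (the regime in which joint measurements
#' are modeled). Returns the direct double-sum result together with the
#' chain-rule decomposition I(x; y1) + E[I(x; y2 | y1)], computed by a
#' distinct summation path over the same grids, so the two can be checked
#' against each other.
#'
#' @param surface a `dose_surface`.
#' @param time_min evaluation time.
#' @param observables the two readout species, conditioning variable first.
#' @param n_grid interpolated dose-grid size.
#' @param ny grid points per readout axis.
#' @param var_floor variance floor (molecules^2) guarding degenerate
#'   conditionals on the discretized grid.
#' @return List with `bits` (joint MI), `marginal1` (I(x; y1)),
#'   `expected_conditional` (E[I(x; y2 | y1)]), `chain` (their sum).
#' @export
joint_mi <- function(surface, time_min, observables = c("Y1r", "Y2"),
                     n_grid = 501, ny = 161, var_floor = 0.25) {
  stopifnot(length(observables) == 2)
  ti <- surface_time_index(surface, time_min)
  ob <- match(observables, surface$species)
  if (anyNA(ob)) stop("unknown observables", call. = FALSE)
  d <- surface$doses
  xs <- seq(min(d), max(d), length.out = n_grid)
  mu1 <- approx(d, surface$mu[, ti, ob[1]], xs)$y
  mu2 <- approx(d, surface$mu[, ti, ob[2]], xs)$y
  s11 <- pmax(approx(d, surface$cov[, ti, ob[1], ob[1]], xs)$y, var_floor)
  s22 <- pmax(approx(d, surface$cov[, ti, ob[2], ob[2]], xs)$y, var_floor)
  s12 <- approx(d, surface$cov[, ti, ob[1], ob[2]], xs)$y
  rho <- pmin(pmax(s12 / sqrt(s11 * s22), -0.9999), 0.9999)
  s12 <- rho * sqrt(s11 * s22)

  y1 <- seq(max(min(mu1 - 8 * sqrt(s11)), 0), max(mu1 + 8 * sqrt(s11)),
            length.out = ny)
  y2 <- seq(max(min(mu2 - 8 * sqrt(s22)), 0), max(mu2 + 8 * sqrt(s22)),
            length.out = ny)

  pmix1 <- numeric(ny)
  h1 <- 0
  A <- matrix(0, ny, ny)      # joint mixture
  B <- matrix(0, ny, ny)      # sum_d w p1 p2|1 log2 p2|1
  hjoint <- 0
  w <- 1 / n_grid
  for (i in seq_len(n_grid)) {
    p1 <- dnorm(y1, mu1[i], sqrt(s11[i]))
    p1 <- p1 / sum(p1)
    cvar <- max(s22[i] * (1 - rho[i]^2), var_floor)
    cmean <- mu2[i] + s12[i] / s11[i] * (y1 - mu1[i])
    P2 <- outer(cmean, y2, function(m, yy) dnorm(yy, m, sqrt(cvar)))
    P2 <- P2 / pmax(rowSums(P2), .Machine$double.xmin)
    Pj <- p1 * P2
    A <- A + w * Pj
    L2 <- ifelse(P2 > 0, log2(pmax(P2, .Machine$double.xmin)), 0)
    B <- B + w * Pj * L2
    nzj <- Pj > 0
    hjoint <- hjoint + w * sum(Pj[nzj] * log2(Pj[nzj]))
    pmix1 <- pmix1 + w * p1
    nz1 <- p1 > 0
    h1 <- h1 + w * sum(p1[nz1] * log2(p1[nz1]))
  }
  nz <- A > 0
  bits <- max(hjoint - sum(A[nz] * log2(A[nz])), 0)
  nz1 <- pmix1 > 0
  marginal1 <- max(h1 - sum(pmix1[nz1] * log2(pmix1[nz1])), 0)
  # E[I(x; y2 | y1)] by its own summation path
  denom <- matrix(pmix1, ny, ny)
  nzc <- A > 0 & denom > 0
  e_cond <- sum(B[nzc]) - sum(A[nzc] * log2(A[nzc] / denom[nzc]))
  e_cond <- max(e_cond, 0)
  list(bits = bits, marginal1 = marginal1, expected_conditional = e_cond,
       chain = marginal1 + e_cond)
}

#' Expected conditional MI over the slow-variable population (Eq. of the
#' slow-conditioning identity)
#'
#' For a slowly fluctuating global variable the population joint MI over
#' (readout, G) decomposes into the expectation over the stationary law of
#' G of the MI conditioned on G. Each conditional term propagates the
#' network with G pinned at a grid node, starting from the conditional
#' stationary state at that node.
#'
#' @param net network with the global variable.
#' @param doses step amplitudes.
#' @param times_min evaluation times.
#' @param observable readout species.
#' @param grid quadrature grid from [g_grid()]; defaults to the network's
#'   `gspec` with 1e-6 tail coverage.
#' @param n_grid fine dose-grid size per conditional MI.
#' @return List with `bits` (length of `times_min`), `per_node` (matrix
#'   nodes x times), `grid`.
#' @export
expected_conditional_mi <- function(net, doses, times_min,
                                    observable = "Y2", grid = NULL,
                                    n_grid = 201) {
  stopifnot("G" %in% net$species)
  if (is.null(grid)) grid <- g_grid(net$gspec, coverage_tail = 1e-6)
  cm <- g_conditional_moments(net, doses, times_min, observable, grid)
  per_node <- matrix(0, nrow(grid), length(times_min))
  for (k in seq_len(nrow(grid))) {
    for (j in seq_along(times_min)) {
      fm <- fine_dose_interp(doses, cm$mu[k, , j], cm$C[k, , j], n_grid)
      per_node[k, j] <- mi_from_moment_sets(fm$mu, fm$C)
    }
  }
  list(bits = as.vector(crossprod(grid$w, per_node)), per_node = per_node,
       grid = grid)
}

# per-node (pinned-G), per-dose, per-time moments of one observable
g_conditional_moments <- function(net, doses, times_min, observable,
                                  grid) {
  run_times <- sort(unique(c(0, times_min)))
  ti <- match(times_min, run_times)
  mu <- array(0, c(nrow(grid), length(doses), length(times_min)))
  C <- array(0, c(nrow(grid), length(doses), length(times_min)))
  for (k in seq_len(nrow(grid))) {
    g <- grid$g[k]
    pinned <- pin_global(net, g)
    init <- conditional_initial(net, g)
    ob <- match(observable, pinned$species)
    for (d in seq_along(doses)) {
      tr <- integrate_moments(pinned, init, run_times, x = doses[d])
      mu[k, d, ] <- tr$mean[ti, ob]
      C[k, d, ] <- pmax(tr$cov[ob, ob, ti], 0)
    }
  }
  list(mu = mu, C = C)
}

fine_dose_interp <- function(doses, mu, C, n_grid) {
  xs <- seq(min(doses), max(doses), length.out = n_grid)
  list(xs = xs, mu = pmax(approx(doses, mu, xs)$y, 0),
       C = pmax(approx(doses, C, xs)$y, 0))
}

#' Slow-variable decomposition of the population joint MI
#'
#' For a slowly fluctuating global variable, the joint MI between the
#' input and the pair (readout, G) equals the expectation over the
#' stationary law of G of the MI conditioned on G. This function evaluates
#' both sides from the same G-pinned conditional laws but by different
#' summation paths — the left side as the literal double sum over the
#' (G, y) support, the right side as the weighted average of per-node MI
#' values on per-node supports — so their agreement validates the
#' conditioning machinery and the quadrature.
#'
#' @inheritParams expected_conditional_mi
#' @return List with `joint_bits`, `expected_bits` (each per time),
#'   `per_node`, `grid`.
#' @export
slow_g_identity <- function(net, doses, times_min, observable = "Y2",
                            grid = NULL, n_grid = 201) {
  stopifnot("G" %in% net$species)
  if (is.null(grid)) grid <- g_grid(net$gspec, coverage_tail = 1e-6)
  cm <- g_conditional_moments(net, doses, times_min, observable, grid)
  nk <- nrow(grid)
  per_node <- matrix(0, nk, length(times_min))
  joint <- numeric(length(times_min))
  for (j in seq_along(times_min)) {
    # right side: E_G[ I(x; y | G) ], each node on its own support
    fms <- lapply(seq_len(nk), function(k) {
      fine_dose_interp(doses, cm$mu[k, , j], cm$C[k, , j], n_grid)
    })
    for (k in seq_len(nk)) {
      per_node[k, j] <- mi_from_moment_sets(fms[[k]]$mu, fms[[k]]$C)
    }
    # left side: I(x; [G y]) as a double sum on the union support, with
    # p(g, y | x) = p(g) p(y | g, x)
    dists <- lapply(seq_len(nk), function(k) {
      lapply(seq_len(n_grid), function(i) {
        dist_from_moments(fms[[k]]$mu[i], fms[[k]]$C[i])
      })
    })
    ymax <- max(vapply(seq_len(nk), function(k) {
      max(vapply(dists[[k]], dist_upper, numeric(1)), 2)
    }, numeric(1)))
    yg <- 0:ceiling(ymax)
    Amix <- matrix(0, nk, length(yg))     # sum_x w_x p(g) p(y|g,x)
    hc <- 0
    wx <- 1 / n_grid
    for (i in seq_len(n_grid)) {
      P <- matrix(0, nk, length(yg))
      for (k in seq_len(nk)) {
        p <- dist_density(dists[[k]][[i]], yg)
        s <- sum(p)
        if (s > 0) P[k, ] <- grid$w[k] * p / s
      }
      Amix <- Amix + wx * P
      nz <- P > 0
      hc <- hc + wx * sum(P[nz] * log2(P[nz]))
    }
    nz <- Amix > 0
    joint[j] <- max(hc - sum(Amix[nz] * log2(Amix[nz])), 0)
  }
  list(joint_bits = joint,
       expected_bits = as.vector(crossprod(grid$w, per_node)),
       per_node = per_node, grid = grid)
}

#' MI between the slow variable and a readout at fixed input
#'
#' Evaluates I(y; G, t | x+): how much a snapshot of the readout reveals
#' about the cell's slow global state under a given step amplitude — a
#' measure of the response diversity that cell-to-cell variability in G
#' induces. Conditional laws per G node are propagated with G pinned.
#'
#' @param net network with the global variable.
#' @param x step amplitude (nM).
#' @param times_min evaluation times.
#' @param observable readout species.
#' @param grid quadrature grid from [g_grid()].
#' @param tail support truncation mass.
#' @return Numeric vector of MI values (bits) per time.
#' @export
conditional_mi_given_input <- function(net, x, times_min,
                                       observable = "Y2", grid = NULL,
                                       tail = 1e-10) {
  stopifnot("G" %in% net$species)
  if (is.null(grid)) grid <- g_grid(net$gspec, coverage_tail = 1e-6)
  cm <- g_conditional_moments(net, x, times_min, observable, grid)
  vapply(seq_along(times_min), function(j) {
    mi_from_moment_sets(cm$mu[, 1, j], cm$C[, 1, j], w = grid$w,
                        tail = tail)
  }, numeric(1))
}

#' Equalize the reporter means across doses
#'
#' Sets the reporter mean at every dose to its zero-dose value while
#' rescaling the reporter variance so the noise (SD over mean) at each dose
#' is preserved; covariances with every other species are rescaled by the
#' same factor, preserving all correlation coefficients. By construction
#' the reporter alone then carries (essentially) no information about the
#' dose.
#'
#' @param surface a `dose_surface` whose lowest dose is 0.
#' @param reporter reporter species name.
#' @return The transformed `dose_surface`.
#' @export
equalize_reporter_means <- function(surface, reporter = "Y1r") {
  k <- match(reporter, surface$species)
  if (is.na(k)) stop("unknown reporter: ", reporter, call. = FALSE)
  if (surface$doses[1] != 0) {
    stop("mean equalization requires a zero-dose column", call. = FALSE)
  }
  out <- surface
  for (ti in seq_along(surface$times_min)) {
    mu0 <- surface$mu[1, ti, k]
    if (mu0 <= 0) {
      if (all(abs(surface$mu[, ti, k]) < 1e-12)) next
      stop("zero reporter mean at zero dose (t = ",
           surface$times_min[ti], " min)", call. = FALSE)
    }
    for (d in seq_along(surface$doses)) {
      mud <- surface$mu[d, ti, k]
      if (mud <= 0) next
      s <- mu0 / mud
      out$mu[d, ti, k] <- mu0
      out$cov[d, ti, k, ] <- surface$cov[d, ti, k, ] * s
      out$cov[d, ti, , k] <- surface$cov[d, ti, , k] * s
      out$cov[d, ti, k, k] <- surface$cov[d, ti, k, k] * s^2
    }
  }
  out
}
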