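# Moment propagation of the chemical master equation under the locally
# affine propensity expansion: propensities are replaced by their first-order
# Taylor expansion about the current mean, which closes the mean/covariance
# ODE system exactly for affine networks and approximately otherwise.

#' Create a moment state
#'
#' @param mean named mean copy-number vector.
#' @param cov covariance matrix (molecules^2); defaults to zero.
#' @param time_min timestamp in minutes.
#' @export
moment_state <- function(mean, cov = NULL, time_min = 0) {
  n <- length(mean)
  if (is.null(cov)) cov <- matrix(0, n, n)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == n, ncol(cov) == n)
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(names(mean), names(mean))
  structure(list(mean = mean, cov = cov, time_min = time_min),
            class = "moment_state")
}

#' @export
print.moment_state <- function(x, ...) {
  cat("<moment_state> t =", x$time_min, "min\n")
  print(data.frame(mean = x$mean, variance = diag(x$cov)))
  invisible(x)
}

#' Linearize propensities about a mean state
#'
#' Returns exact propensity values and analytic state-gradients at the
#' (clipped non-negative) mean vector `z`, for every reaction of the
#' network, including the Hill transcription term and bilinear
#' G-coupled translation terms.
#'
#' @param net a [reaction_network()].
#' @param z mean copy-number vector.
#' @param x input amplitude.
#' @return List with `a` (length-M propensity vector) and `jac` (M-by-N
#'   matrix of partial derivatives).
#' @export
linearize_propensities <- function(net, z, x = 0) {
  z <- state_vector(net, z)
  if (any(!is.finite(z))) stop("non-finite mean state", call. = FALSE)
  z <- pmax(z, 0)
  M <- nrow(net$nu)
  N <- length(net$species)
  a <- numeric(M)
  jac <- matrix(0, M, N, dimnames = dimnames(net$nu))
  for (j in seq_len(M)) {
    r <- net$reactions[[j]]
    switch(r$kind,
      const = {
        a[j] <- r$rate
      },
      lin = {
        coef <- if (r$x_scaled) r$rate * x else r$rate
        a[j] <- coef * z[[r$species]]
        jac[j, r$species] <- coef
      },
      bilin = {
        coef <- if (r$x_scaled) r$rate * x else r$rate
        s1 <- r$species[1]; s2 <- r$species[2]
        a[j] <- coef * z[[s1]] * z[[s2]]
        jac[j, s1] <- jac[j, s1] + coef * z[[s2]]
        jac[j, s2] <- jac[j, s2] + coef * z[[s1]]
      },
      hill = {
        a[j] <- hill_value(r$hill, z[[r$species]])
        jac[j, r$species] <- hill_grad(r$hill, z[[r$species]])
      },
      adh1 = {
        a[j] <- adh1_value(r$adh1, x)
      }
    )
  }
  list(a = setNames(a, rownames(net$nu)), jac = jac)
}

vech_idx <- function(n) which(lower.tri(matrix(0, n, n), diag = TRUE))

pack_moments <- function(z, C) c(z, C[vech_idx(length(z))])

unpack_moments <- function(state, n) {
  z <- state[seq_len(n)]
  C <- matrix(0, n, n)
  C[lower.tri(C, diag = TRUE)] <- state[-seq_len(n)]
  C <- C + t(C) - diag(diag(C), n)
  list(z = z, C = C)
}

#' Expected propensities under the normal closure
#'
#' Evaluates E[a_j(y)] for a state with mean `z` and covariance `C` as
#' `a_j(z) + 0.5 * tr(H_j C)` with `H_j` the propensity Hessian: exact for
#' constant, linear and bilinear propensities, and the leading curvature
#' correction for the Hill form (important at low copy numbers, where the
#' Hill term is strongly convex). Results are clipped at zero.
#'
#' @param net a [reaction_network()].
#' @param z mean vector.
#' @param C covariance matrix (species x species, named or in species
#'   order).
#' @param x input amplitude.
#' @export
expected_propensities <- function(net, z, C, x = 0) {
  lin <- linearize_propensities(net, z, x)
  a <- lin$a
  zc <- pmax(state_vector(net, z), 0)
  C <- as.matrix(C)
  if (is.null(dimnames(C))) dimnames(C) <- list(net$species, net$species)
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (r$kind == "bilin") {
      coef <- if (r$x_scaled) r$rate * x else r$rate
      a[j] <- a[j] + coef * C[r$species[1], r$species[2]]
    } else if (r$kind == "hill" && zc[[r$species]] > 0) {
      h <- r$hill
      yv <- zc[[r$species]]
      yn <- yv^h$n
      Kn <- h$K^h$n
      den <- yn + Kn
      d2 <- h$b * h$n * Kn * yv^(h$n - 2) *
        ((h$n - 1) * den - 2 * h$n * yn) / den^3
      a[j] <- a[j] + 0.5 * d2 * C[r$species, r$species]
    }
  }
  pmax(a, 0)
}

moment_rhs <- function(t, state, parms) {
  net <- parms$net
  n <- length(net$species)
  m <- unpack_moments(state, n)
  lin <- linearize_propensities(net, m$z, parms$x)
  a <- expected_propensities(net, m$z, m$C, parms$x)
  nu <- net$nu
  dz <- drop(crossprod(nu, a))
  A <- crossprod(nu, lin$jac)           # N x N drift Jacobian
  B <- crossprod(nu, nu * a)            # diffusion matrix
  dC <- A %*% m$C + m$C %*% t(A) + B
  dC <- (dC + t(dC)) / 2
  list(c(dz, dC[vech_idx(n)]))
}

#' Integrate the mean/covariance moment equations
#'
#' Solves the coupled first/second-moment ODEs of the network under the
#' affine closure with a stiff-capable integrator. The step input is applied
#' from the first requested time onward (`x(t) = x` for `t >= 0`). For
#' networks whose propensities are affine in the state the result carries no
#' closure error. Negative transient means are clipped to zero only inside
#' propensity evaluation, never in the state itself, and the covariance is
#' re-symmetrized at each output time.
#'
#' @param net a [reaction_network()].
#' @param init a [moment_state()] (or named mean vector, taken with zero
#'   covariance).
#' @param times_min output times in minutes, strictly increasing, >= 0.
#' @param x step-input amplitude (nM).
#' @param rtol,atol integrator tolerances; the defaults accommodate rate
#'   constants spanning several orders of magnitude while not forcing the
#'   integrator to resolve sub-molecule covariance components.
#' @return A `moment_trajectory`: list with `times_min`, `mean`
#'   (times-by-species matrix), `cov` (species-by-species-by-times array),
#'   and `species`.
#' @export
#' @examples
#' bd <- birth_death_network(beta = 0.5, gamma = 0.01)
#' tr <- integrate_moments(bd, moment_state(c(X = 0)), times_min = c(0, 5))
#' tr$mean  # Poisson transient: mean == variance
integrate_moments <- function(net, init, times_min, x = 0,
                              rtol = 1e-8, atol = 1e-8) {
  if (!inherits(init, "moment_state")) init <- moment_state(init)
  z0 <- state_vector(net, init$mean)
  C0 <- init$cov
  if (is.null(dimnames(C0)) && length(z0) == nrow(C0)) {
    dimnames(C0) <- list(net$species, net$species)
  }
  C0 <- C0[net$species, net$species, drop = FALSE]
  stopifnot(all(times_min >= 0), !is.unsorted(times_min, strictly = TRUE))
  n <- length(net$species)
  times_s <- times_min * 60
  solver_times <- if (times_s[1] > 0) c(0, times_s) else times_s
  enc <- encode_network(net, x)
  rhs <- function(t, state, parms) {
    list(moment_rhs_cpp(state, enc$nu, enc$kind, enc$coef, enc$i1,
                        enc$i2, enc$hb0, enc$hb, enc$hn, enc$hK))
  }
  sol <- suppressWarnings(deSolve::vode(
    y = pack_moments(z0, C0), times = solver_times, func = rhs,
    parms = NULL, rtol = rtol, atol = atol, mf = 22, maxsteps = 100000
  ))
  if (attr(sol, "istate")[1] < 0) {
    # a frozen (pinned) direction can trip BDF error control; retry with
    # the switching lsoda integrator before giving up
    sol <- suppressWarnings(deSolve::lsoda(
      y = pack_moments(z0, C0), times = solver_times, func = rhs,
      parms = NULL, rtol = rtol, atol = atol, maxsteps = 100000
    ))
  }
  if (attr(sol, "istate")[1] < 0) {
    reached <- max(sol[, 1]) / 60
    stop(sprintf(
      "moment integration failed (reached t = %.3f min of %.3f)",
      reached, max(times_min)), call. = FALSE)
  }
  keep <- match(times_s, sol[, 1])
  means <- matrix(sol[keep, 1 + seq_len(n), drop = FALSE],
                  nrow = length(keep), ncol = n,
                  dimnames = list(NULL, net$species))
  covs <- array(0, dim = c(n, n, length(keep)),
                dimnames = list(net$species, net$species, NULL))
  for (i in seq_along(keep)) {
    m <- unpack_moments(sol[keep[i], -1], n)
    covs[, , i] <- (m$C + t(m$C)) / 2
  }
  structure(list(times_min = times_min, mean = means, cov = covs,
                 species = net$species),
            class = "moment_trajectory")
}

#' Extract the moment state at one trajectory time
#'
#' @param traj a `moment_trajectory`.
#' @param time_min a time present in the trajectory.
#' @export
state_at <- function(traj, time_min) {
  i <- match(time_min, traj$times_min)
  if (is.na(i)) stop("time not in trajectory", call. = FALSE)
  moment_state(setNames(traj$mean[i, ], traj$species),
               traj$cov[, , i], time_min)
}

#' Tidy data frame of a moment trajectory
#'
#' @param x a `moment_trajectory`.
#' @param ... unused.
#' @return Data frame with columns `time_min`, `species`, `mean`,
#'   `variance`.
#' @export
as.data.frame.moment_trajectory <- function(x, ...) {
  n <- length(x$species)
  Ti <- length(x$times_min)
  data.frame(
    time_min = rep(x$times_min, each = n),
    species = rep(x$species, times = Ti),
    mean = as.vector(t(x$mean)),
    variance = as.vector(apply(x$cov, 3, diag))
  )
}

dynamic_species <- function(net) {
  which(colSums(abs(net$nu)) > 0)
}

slowest_rate <- function(net) {
  rates <- vapply(net$reactions, function(r) {
    if (r$kind != "lin" || r$x_scaled || r$rate <= 0) return(NA_real_)
    ch <- r$change[r$species]
    if (length(ch) == 1 && !is.na(ch) && ch < 0) r$rate else NA_real_
  }, numeric(1))
  rates <- rates[is.finite(rates)]
  if (length(rates) == 0) 1e-4 else min(rates)
}

#' Stationary moments of a network
#'
#' Finds the fixed point of the affine moment equations at a constant input:
#' the means are integrated to near-stationarity and polished with Newton
#' steps on the deterministic rate equations, and the covariance solves the
#' associated Lyapunov equation exactly. Species not changed by any
#' reaction (e.g. a pinned global variable) keep their initial value with
#' zero variance.
#'
#' @param net a [reaction_network()].
#' @param x constant input amplitude (nM).
#' @param init optional starting mean vector (defaults to all-zero, with a
#'   pinned G started at its pinning value).
#' @param tol relative residual tolerance on the stationary means.
#' @return A [moment_state()] at the fixed point.
#' @export
#' @examples
#' g <- birth_death_network(1.5e-6, 3e-8, name = "G")
#' st <- stationary_moments(g)
#' c(st$mean, st$cov)  # mean 50, variance 50: Poisson
stationary_moments <- function(net, x = 0, init = NULL, tol = 1e-9) {
  n <- length(net$species)
  z <- setNames(numeric(n), net$species)
  if (!is.null(init)) z[names(init)] <- init
  if ("G" %in% net$species && is.null(init)) {
    g0 <- attr(net, "pinned_at")
    if (is.null(g0) && !is.null(net$gspec)) g0 <- net$gspec$gbar
    if (!is.null(g0)) z[["G"]] <- g0
  }
  dyn <- dynamic_species(net)
  if (length(dyn) == 0) return(moment_state(z))

  # coarse mean relaxation over a log time grid, means only (the affine mean
  # equations do not involve the covariance)
  mean_rhs <- function(t, zz, p) {
    lin <- linearize_propensities(net, zz, x)
    list(drop(crossprod(net$nu, lin$a)))
  }
  t_max <- 20 / slowest_rate(net)
  times <- c(0, 10^seq(0, log10(t_max), length.out = 200))
  sol <- deSolve::lsoda(z, times, mean_rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
  z <- setNames(sol[nrow(sol), -1], net$species)

  nd <- length(dyn)
  lyap_solve <- function(Ad, Bd) {
    K <- kronecker(diag(nd), Ad) + kronecker(Ad, diag(nd))
    Cd <- matrix(solve(K, -as.vector(Bd)), nd, nd)
    (Cd + t(Cd)) / 2
  }
  C <- matrix(0, n, n, dimnames = list(net$species, net$species))
  # alternate Newton steps on the means (with covariance-corrected
  # expected propensities) and Lyapunov solves for the covariance
  for (iter in 1:80) {
    lin <- linearize_propensities(net, z, x)
    aeff <- expected_propensities(net, z, C, x)
    dz <- drop(crossprod(net$nu, aeff))
    A <- crossprod(net$nu, lin$jac)
    Ad <- A[dyn, dyn, drop = FALSE]
    Bd <- crossprod(net$nu, net$nu * aeff)[dyn, dyn, drop = FALSE]
    Cnew <- C
    Cnew[dyn, dyn] <- lyap_solve(Ad, Bd)
    dC <- max(abs(Cnew - C)) / (max(abs(Cnew)) + 1)
    C <- Cnew
    rel <- sqrt(sum(dz[dyn]^2)) / (sqrt(sum(z[dyn]^2)) + 1)
    if (rel < tol && dC < 1e-10) break
    step <- tryCatch(solve(Ad, dz[dyn]), error = function(e) NULL)
    if (is.null(step)) {
      stop("stationary point not found: singular drift Jacobian",
           call. = FALSE)
    }
    z[dyn] <- pmax(z[dyn] - step, 0)
    if (iter == 80 && (rel >= tol || dC >= 1e-10)) {
      stop("stationary moments did not converge", call. = FALSE)
    }
  }
  moment_state(z, C)
}
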