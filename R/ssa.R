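# Exact stochastic simulation (Gillespie direct method), the brute-force
# oracle against which the moment closure and distribution reconstructions
# are validated.

encode_network <- function(net, x) {
  M <- nrow(net$nu)
  kind <- integer(M); coef <- numeric(M)
  i1 <- integer(M); i2 <- integer(M)
  hb0 <- numeric(M); hb <- numeric(M); hn <- numeric(M); hK <- numeric(M)
  idx <- function(s) match(s, net$species) - 1L
  for (j in seq_len(M)) {
    r <- net$reactions[[j]]
    if (r$kind == "const") {
      kind[j] <- 0L; coef[j] <- r$rate
    } else if (r$kind == "adh1") {
      kind[j] <- 0L; coef[j] <- adh1_value(r$adh1, x)
    } else if (r$kind == "lin") {
      kind[j] <- 1L
      coef[j] <- if (r$x_scaled) r$rate * x else r$rate
      i1[j] <- idx(r$species)
    } else if (r$kind == "bilin") {
      kind[j] <- 2L
      coef[j] <- if (r$x_scaled) r$rate * x else r$rate
      i1[j] <- idx(r$species[1]); i2[j] <- idx(r$species[2])
    } else if (r$kind == "hill") {
      kind[j] <- 3L
      i1[j] <- idx(r$species)
      hb0[j] <- r$hill$b0; hb[j] <- r$hill$b
      hn[j] <- r$hill$n; hK[j] <- r$hill$K
    } else {
      stop("unknown propensity kind: ", r$kind, call. = FALSE)
    }
  }
  list(nu = net$nu, kind = kind, coef = coef, i1 = i1, i2 = i2,
       hb0 = hb0, hb = hb, hn = hn, hK = hK)
}

#' Exact stochastic simulation of a reaction network
#'
#' Samples statistically exact trajectories of the chemical master equation
#' with the Gillespie direct method (compiled). The step input is applied
#' for the whole simulated window (`x(t) = x` for `t >= 0`).
#'
#' @param net a [reaction_network()].
#' @param init integer initial copy numbers (named or in species order).
#' @param times_min recording times in minutes (>= 0, increasing); the
#'   state is recorded at each.
#' @param x step-input amplitude (nM).
#' @param n_runs number of independent sample paths.
#' @param seed optional integer seed (`set.seed` is called when supplied);
#'   fixed seeds give bit-identical output.
#' @return Object of class `ssa_ensemble`: list with `times_min`, `states`
#'   (array runs x times x species), `species`, `jumps` (reaction count per
#'   run), `x`.
#' @export
#' @examples
#' bd <- birth_death_network(0.5, 0.01)
#' sim <- simulate_ssa(bd, c(X = 0), times_min = c(0, 5, 10), n_runs = 100,
#'                     seed = 1)
#' colMeans(sim$states[, , 1])
simulate_ssa <- function(net, init, times_min, x = 0, n_runs = 1,
                         seed = NULL) {
  stopifnot(n_runs >= 1, all(times_min >= 0),
            !is.unsorted(times_min, strictly = TRUE))
  y0 <- state_vector(net, init)
  if (any(y0 < 0) || any(y0 != round(y0))) {
    stop("initial state must be non-negative integers", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_network(net, x)
  res <- ssa_run_cpp(enc$nu, enc$kind, enc$coef, enc$i1, enc$i2, enc$hb0,
                     enc$hb, enc$hn, enc$hK, as.integer(round(y0)),
                     times_min * 60, as.integer(n_runs))
  states <- res$states
  dimnames(states) <- list(NULL, NULL, net$species)
  structure(list(times_min = times_min, states = states,
                 species = net$species, jumps = res$jumps, x = x),
            class = "ssa_ensemble")
}

#' Empirical moments and histograms of an SSA ensemble
#'
#' Summarizes an ensemble of exact sample paths into per-time empirical
#' means and covariances (an empirical counterpart of a moment trajectory)
#' plus max-normalized histograms per species.
#'
#' @param net a [reaction_network()].
#' @param init integer state, or a function `(n)` returning an n-by-species
#'   matrix of sampled integer initial states.
#' @param n_runs number of paths (>= 2).
#' @param times_min recording times (minutes).
#' @param x input amplitude.
#' @param seed optional integer seed.
#' @param binwidth histogram bin width in molecules (single value or named
#'   per species).
#' @return List with `times_min`, `mean`, `cov` (as in a moment
#'   trajectory), `histograms` (per time, per species: data frame of bin
#'   `mid`, `count`, `p` and max-normalized `p_norm`), and `states`.
#' @export
ensemble_summary <- function(net, init, n_runs, times_min, x = 0,
                             seed = NULL, binwidth = 1) {
  stopifnot(n_runs >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.function(init)) {
    inits <- init(n_runs)
    sims <- vector("list", n_runs)
    states <- array(0, dim = c(n_runs, length(times_min),
                               length(net$species)),
                    dimnames = list(NULL, NULL, net$species))
    jumps <- numeric(n_runs)
    for (i in seq_len(n_runs)) {
      s <- simulate_ssa(net, inits[i, ], times_min, x = x, n_runs = 1)
      states[i, , ] <- s$states[1, , ]
      jumps[i] <- s$jumps
    }
    sim <- list(times_min = times_min, states = states,
                species = net$species, jumps = jumps, x = x)
  } else {
    sim <- simulate_ssa(net, init, times_min, x = x, n_runs = n_runs)
  }
  Tn <- length(times_min)
  N <- length(net$species)
  means <- matrix(0, Tn, N, dimnames = list(NULL, net$species))
  covs <- array(0, dim = c(N, N, Tn),
                dimnames = list(net$species, net$species, NULL))
  histograms <- vector("list", Tn)
  for (ti in seq_len(Tn)) {
    S <- sim$states[, ti, , drop = TRUE]
    if (is.null(dim(S))) S <- matrix(S, ncol = N)
    means[ti, ] <- colMeans(S)
    covs[, , ti] <- stats::cov(S)
    histograms[[ti]] <- lapply(setNames(seq_len(N), net$species),
                               function(k) {
      bw <- if (length(binwidth) > 1) binwidth[[net$species[k]]] else binwidth
      ssa_histogram(S[, k], bw)
    })
  }
  list(times_min = times_min, mean = means, cov = covs,
       histograms = histograms, states = sim$states)
}

#' Max-normalized histogram of sampled copy numbers
#'
#' @param x sampled values.
#' @param binwidth bin width (molecules).
#' @return Data frame with bin midpoints `mid`, `count`, probability `p`
#'   and `p_norm = p / max(p)`.
#' @export
ssa_histogram <- function(x, binwidth = 1) {
  lo <- floor(min(x) / binwidth) * binwidth
  breaks <- seq(lo - binwidth / 2, max(x) + binwidth, by = binwidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  data.frame(mid = h$mids, count = h$counts, p = p, p_norm = p / max(p))
}

#' Sup-distance between sampled and reconstructed distributions
#'
#' Compares an SSA sample against a reconstructed distribution model the way
#' the validation overlays are read: both the empirical probability mass and
#' the model mass are evaluated on the integer support, smoothed with the
#' same discrete Gaussian kernel, max-normalized, and their largest absolute
#' difference returned. The kernel bandwidth (default half the model SD)
#' sets the resolution at which disagreement is measured and suppresses
#' Monte-Carlo roughness by the same amount on both curves.
#'
#' @param samples integer samples from the SSA ensemble.
#' @param d a `dist_model` reconstructed from the matching moments.
#' @param bandwidth Gaussian kernel SD in molecules; default
#'   `sqrt(d$C) / 2`.
#' @return The sup-norm distance between the two max-normalized smoothed
#'   curves.
#' @export
distribution_sup_distance <- function(samples, d, bandwidth = NULL) {
  if (is.null(bandwidth)) bandwidth <- max(sqrt(d$C) / 2, 0.5)
  lo <- floor(min(samples, d$mu - 8 * sqrt(d$C)))
  hi <- ceiling(max(samples, d$mu + 8 * sqrt(d$C)))
  grid <- max(lo, 0):hi
  emp <- tabulate(round(samples) - grid[1] + 1L, nbins = length(grid))
  emp <- emp / sum(emp)
  mod <- dist_density(d, grid)
  mod <- mod / sum(mod)
  kw <- ceiling(4 * bandwidth)
  kern <- dnorm(-kw:kw, 0, bandwidth)
  kern <- kern / sum(kern)
  smooth <- function(p) {
    out <- stats::filter(c(numeric(kw), p, numeric(kw)), kern,
                         sides = 2)
    as.numeric(out[(kw + 1):(kw + length(p))])
  }
  es <- smooth(emp)
  ms <- smooth(mod)
  max(abs(es / max(es) - ms / max(ms)), na.rm = TRUE)
}
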