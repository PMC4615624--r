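# Initial-condition regimes for a network carrying the slow global
# variable G: homogeneous point states at prescribed G values, the
# intrinsic-spread state Sg, the full heterogeneous stationary population,
# and the integer quadrature grid over the stationary law of G used for
# conditional mutual-information identities.

#' Construct an initial condition regime
#'
#' * `S1`, `S2`, `S3`: homogeneous point states (zero covariance) with G at
#'   `gbar`, `gbar - sqrt(gbar)`, `gbar + sqrt(gbar)` respectively and all
#'   other species at their conditional stationary means given that G.
#' * `Sg`: G pinned at `gbar` with zero G-variance, while the other species
#'   carry their conditional stationary covariance (intrinsic spread).
#' * `heterogeneous`: the full stationary moment state of the network,
#'   including the Poisson spread of G (for a network without G, simply its
#'   intrinsic stationary state).
#'
#' @param kind one of `"S1"`, `"S2"`, `"S3"`, `"Sg"`, `"heterogeneous"`.
#' @param net a [reaction_network()]; the S-states and `Sg` require the
#'   global variable.
#' @param x input amplitude at which the pre-stimulus stationary state is
#'   computed (0 for a step protocol).
#' @return A [moment_state()] with attribute `kind`.
#' @export
#' @examples
#' net <- attach_global_variable(build_simple_cascade(), global_spec())
#' s2 <- make_initial("S2", net)
#' s2$mean[["G"]]  # 50 - sqrt(50)
make_initial <- function(kind = c("S1", "S2", "S3", "Sg", "heterogeneous"),
                         net, x = 0) {
  kind <- match.arg(kind)
  has_g <- "G" %in% net$species
  if (!has_g && kind != "heterogeneous") {
    stop("initial condition '", kind,
         "' requires a network with the global variable G", call. = FALSE)
  }
  if (kind == "heterogeneous") {
    st <- stationary_moments(net, x = x)
  } else {
    gbar <- net$gspec$gbar
    g0 <- switch(kind, S1 = gbar, S2 = gbar - sqrt(gbar),
                 S3 = gbar + sqrt(gbar), Sg = gbar)
    st <- conditional_initial(net, g0)
    if (kind != "Sg") {
      st <- moment_state(st$mean)             # point state, no spread
    }
  }
  attr(st, "kind") <- kind
  st
}

#' Conditional stationary state given a pinned global variable
#'
#' Stationary means and intrinsic covariance of all species when G is held
#' at `g` (G itself has zero variance). Under the stationary
#' proportionality of G-coupled synthesis, conditional protein means scale
#' as `g / gbar`.
#'
#' @param net network containing G.
#' @param g value at which G is pinned.
#' @param x input amplitude.
#' @export
conditional_initial <- function(net, g, x = 0) {
  pinned <- pin_global(net, g)
  st <- stationary_moments(pinned, x = x)
  mean_full <- setNames(numeric(length(net$species)), net$species)
  mean_full[pinned$species] <- st$mean
  mean_full[["G"]] <- g
  cov_full <- matrix(0, length(net$species), length(net$species),
                     dimnames = list(net$species, net$species))
  cov_full[pinned$species, pinned$species] <- st$cov
  moment_state(mean_full, cov_full)
}

#' Integer quadrature grid over the stationary law of G
#'
#' Nodes are integer copy numbers of G weighted by the stationary Poisson
#' law with mean `gbar`, truncated to the requested coverage (weight-sorted
#' when a fixed node count is requested) and renormalized. Conditional
#' initial states for each node come from [conditional_initial()].
#'
#' @param gspec a [global_spec()].
#' @param n_nodes optional fixed number of nodes: the `n_nodes` most
#'   probable integers are kept. By default all integers covering at least
#'   `1 - coverage_tail` of the mass are kept.
#' @param coverage_tail tail mass excluded by the default truncation.
#' @return Data frame with integer `g` and normalized weight `w`.
#' @export
#' @examples
#' grid <- g_grid(global_spec(gbar = 50, gamma_g = 3e-8))
#' sum(grid$w)              # 1
#' sum(grid$g * grid$w)     # 50 (to quadrature accuracy)
g_grid <- function(gspec, n_nodes = NULL, coverage_tail = 1e-10) {
  gbar <- gspec$gbar
  lo <- qpois(coverage_tail / 2, gbar)
  hi <- qpois(coverage_tail / 2, gbar, lower.tail = FALSE)
  g <- lo:hi
  w <- dpois(g, gbar)
  if (!is.null(n_nodes)) {
    stopifnot(n_nodes >= 1)
    keep <- order(w, decreasing = TRUE)[seq_len(min(n_nodes, length(g)))]
    keep <- sort(keep)
    g <- g[keep]; w <- w[keep]
  }
  data.frame(g = g, w = w / sum(w))
}

#' Calibrate the global-variable mean from reporter noise
#'
#' Under Poissonian statistics for the slow variable, a measured reporter
#' noise (SD over mean) of `eta` dominated by global fluctuations implies a
#' mean copy number `1 / eta^2` for G.
#'
#' @param noise reporter noise (SD/mean).
#' @return Implied mean of G (not rounded).
#' @export
#' @examples
#' calibrate_gbar(0.155)  # about 42
calibrate_gbar <- function(noise) {
  stopifnot(noise > 0)
  1 / noise^2
}
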