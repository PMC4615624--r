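#' @useDynLib stochmi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx dnbinom dnorm dpois qnbinom qnorm qpois rnorm
#'   rpois rmultinom runif setNames integrate sd var cov qchisq pchisq
#' @importFrom utils write.csv modifyList
NULL

# ---------------------------------------------------------------------------
# Parameter sets
# ---------------------------------------------------------------------------

#' Rate constants for the two-step signaling cascade
#'
#' Returns the nominal parameter set of the in-silico cascade in which a step
#' input `x` converts an inactive factor Y1* (`Y1s`) to its active form `Y1`,
#' which in turn activates transcription of the output gene `Y2` (mRNA
#' `My2`). All rates are in molecules and seconds; public time arguments
#' elsewhere in the package are in minutes.
#'
#' @param ... named overrides of individual rate constants.
#' @return Named list of rate constants:
#'   `beta_y1s` (mol/s, synthesis of Y1*), `gamma_y1s` = `gamma_y1` (1/s,
#'   decay of Y1* and Y1), `theta_x` (1/mol/s, input-dependent activation),
#'   `theta_y1` (1/s, deactivation), `n1` and `y1_0` (Hill exponent and
#'   half-saturation, in molecules, of Y1-driven transcription), `beta_m2s`
#'   (mol/s, basal transcription), `beta_m2` (mol/s, activated
#'   transcription), `gamma_m2` (1/s), `beta_y2` (1/s, translation per
#'   mRNA), `gamma_y2` (1/s).
#' @seealso [build_simple_cascade()]
#' @export
#' @examples
#' p <- cascade_params()
#' p$beta_y1s / p$gamma_y1s  # mean total Y1, about 1500 molecules
cascade_params <- function(...) {
  p <- list(
    beta_y1s = 0.01,
    gamma_y1s = 0.0000067,
    gamma_y1 = 0.0000067,
    theta_x = 0.001,
    theta_y1 = 1.5,
    n1 = 3,
    y1_0 = 85,
    beta_m2s = 0.0083,
    beta_m2 = 0.1583,
    gamma_m2 = 0.00083,
    beta_y2 = 0.0014,
    gamma_y2 = 0.00014
  )
  override_params(p, list(...))
}

#' Rate constants for the estradiol-inducible synthetic circuit
#'
#' Parameter sets for the model of the synthetic transcriptional circuit in
#' which a constitutively transcribed mRNA `M1` is translated into the
#' estradiol-responsive factor Y1* and into a co-expressed fluorescent
#' reporter `Y1r`; active `Y1` drives transcription of the output `Y2`.
#' The `"global"` variant is meant to be combined with a slowly fluctuating
#' translation-capacity variable G ([attach_global_variable()] /
#' [build_synthetic_circuit()]); the `"intrinsic"` variant models the same
#' circuit with purely intrinsic fluctuations and a low-copy Y1 pool.
#'
#' @param variant `"global"` or `"intrinsic"`.
#' @param ... named overrides.
#' @return Named list of rate constants; in addition to the cascade symbols
#'   it contains `beta_m1`, `gamma_m1` (ADH1 mRNA synthesis/decay),
#'   `beta_y1s` reinterpreted as a per-mRNA translation rate (1/s),
#'   `gamma_y1r` (reporter decay), and the estradiol-repression constants
#'   `alpha_x`, `x_e`, `n_x` of the ADH1 promoter.
#' @export
circuit_params <- function(variant = c("global", "intrinsic"), ...) {
  variant <- match.arg(variant)
  p <- list(
    beta_m1 = 0.667,
    gamma_m1 = 0.00067,
    beta_y1s = 0.0000139,
    gamma_y1s = 0.0000463,
    gamma_y1 = 0.0000463,
    gamma_y1r = 0.0000463,
    theta_x = 0.002,
    theta_y1 = 1.5,
    n1 = 1.5,
    y1_0 = 85,
    beta_m2s = 0,
    beta_m2 = 0.083,
    gamma_m2 = 0.00083,
    beta_y2 = 0.0014,
    gamma_y2 = 0.0000463,
    alpha_x = 0.35,
    x_e = 45,
    n_x = 2
  )
  if (variant == "intrinsic") {
    p$beta_y1s <- 0.0000019
    p$y1_0 <- 1
  }
  override_params(p, list(...))
}

override_params <- function(p, dots) {
  if (length(dots) == 0L) return(p)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  modifyList(p, dots)
}

check_params <- function(params, required) {
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rates <- unlist(params[required])
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rate constants must be finite and non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Reaction and network constructors
# ---------------------------------------------------------------------------

# A reaction couples a stoichiometric change to a parametric propensity form:
#   const : a = rate                      (rate may be x-dependent, see adh1)
#   lin   : a = rate * y[i]        (rate multiplied by input x if x_scaled)
#   bilin : a = rate * y[i] * y[j]
#   hill  : a = b0 + b * y[i]^n / (y[i]^n + K^n)
#   adh1  : a = bm1 * ((1 - ax) + ax * xe^nx / (xe^nx + x^nx))
reaction <- function(name, change, kind, rate = NULL, species = character(),
                     x_scaled = FALSE, hill = NULL, adh1 = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  list(name = name, change = change, kind = kind, rate = rate,
       species = species, x_scaled = isTRUE(x_scaled), hill = hill,
       adh1 = adh1)
}

#' Construct a chemical reaction network
#'
#' Low-level constructor used by the model builders; also useful for small
#' bespoke networks in tests and examples. Propensities are restricted to
#' the parametric forms the package knows how to linearize exactly:
#' constants (optionally estradiol-repressed), mass-action linear terms
#' (optionally scaled by the external input), bilinear terms, and Hill
#' activation.
#'
#' @param species character vector of species names.
#' @param reactions list of reactions built with the internal `reaction()`
#'   helper (see [birth_death_network()] for a worked example via source).
#' @param params parameter list retained for serialization.
#' @param model free-form model label.
#' @param gspec optional global-variable specification ([global_spec()]).
#' @return An object of class `reaction_network` with elements `species`,
#'   `reactions`, `nu` (reactions-by-species stoichiometric matrix),
#'   `params`, `model`, `gspec`.
#' @export
reaction_network <- function(species, reactions, params = list(),
                             model = "custom", gspec = NULL) {
  stopifnot(is.character(species), length(species) >= 1L,
            !anyDuplicated(species))
  nu <- matrix(0L, nrow = length(reactions), ncol = length(species),
               dimnames = list(vapply(reactions, `[[`, "", "name"), species))
  for (j in seq_along(reactions)) {
    ch <- reactions[[j]]$change
    bad <- setdiff(names(ch), species)
    if (length(bad) > 0) {
      stop("reaction '", reactions[[j]]$name, "' changes unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    nu[j, names(ch)] <- as.integer(ch)
    dep <- reactions[[j]]$species
    if (length(dep) > 0 && !all(dep %in% species)) {
      stop("reaction '", reactions[[j]]$name,
           "' depends on unknown species", call. = FALSE)
    }
  }
  structure(list(species = species, reactions = reactions, nu = nu,
                 params = params, model = model, gspec = gspec),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> model:", x$model, "\n")
  cat("  species  (", length(x$species), "): ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  reactions(", nrow(x$nu), "): ",
      paste(rownames(x$nu), collapse = ", "), "\n", sep = "")
  if (!is.null(x$gspec)) {
    cat("  global variable G: mean", x$gspec$gbar, "rate gamma_g",
        x$gspec$gamma_g, if (isTRUE(attr(x, "pinned"))) "(pinned)" else "",
        "\n")
  }
  invisible(x)
}

#' Simple birth/death network
#'
#' One species produced at constant rate `beta` and degraded at per-capita
#' rate `gamma`; its stationary law is Poisson with mean `beta/gamma`.
#' Used throughout as an analytically solvable fixture.
#'
#' @param beta birth rate (mol/s).
#' @param gamma death rate (1/s).
#' @param name species name.
#' @export
birth_death_network <- function(beta, gamma, name = "X") {
  reaction_network(
    species = name,
    reactions = list(
      reaction("birth", setNames(1L, name), "const", rate = beta),
      reaction("death", setNames(-1L, name), "lin", rate = gamma,
               species = name)
    ),
    params = list(beta = beta, gamma = gamma),
    model = "birth_death"
  )
}

# ---------------------------------------------------------------------------
# Model builders
# ---------------------------------------------------------------------------

#' Build the two-step signaling cascade
#'
#' Species are `Y1s` (inactive Y1*), `Y1` (active), `My2` (output mRNA) and
#' `Y2` (output protein). The external input `x` enters only through the
#' activation propensity `theta_x * x * Y1s`; transcription of `My2` follows
#' the Hill form `beta_m2s + beta_m2 * y1^n1 / (y1^n1 + y1_0^n1)`.
#'
#' @param params parameter list as from [cascade_params()].
#' @return A [reaction_network()].
#' @export
#' @examples
#' net <- build_simple_cascade()
#' propensities(net, c(Y1s = 1500, Y1 = 0, My2 = 10, Y2 = 100), x = 250)
build_simple_cascade <- function(params = cascade_params()) {
  check_params(params, c("beta_y1s", "gamma_y1s", "gamma_y1", "theta_x",
                         "theta_y1", "n1", "y1_0", "beta_m2s", "beta_m2",
                         "gamma_m2", "beta_y2", "gamma_y2"))
  p <- params
  reactions <- list(
    reaction("syn_y1s", c(Y1s = 1L), "const", rate = p$beta_y1s),
    reaction("deg_y1s", c(Y1s = -1L), "lin", rate = p$gamma_y1s,
             species = "Y1s"),
    reaction("act", c(Y1s = -1L, Y1 = 1L), "lin", rate = p$theta_x,
             species = "Y1s", x_scaled = TRUE),
    reaction("deact", c(Y1 = -1L, Y1s = 1L), "lin", rate = p$theta_y1,
             species = "Y1"),
    reaction("deg_y1", c(Y1 = -1L), "lin", rate = p$gamma_y1,
             species = "Y1"),
    reaction("tx_my2", c(My2 = 1L), "hill", species = "Y1",
             hill = list(b0 = p$beta_m2s, b = p$beta_m2, n = p$n1,
                         K = p$y1_0)),
    reaction("deg_my2", c(My2 = -1L), "lin", rate = p$gamma_m2,
             species = "My2"),
    reaction("tl_y2", c(Y2 = 1L), "lin", rate = p$beta_y2,
             species = "My2"),
    reaction("deg_y2", c(Y2 = -1L), "lin", rate = p$gamma_y2,
             species = "Y2")
  )
  reaction_network(c("Y1s", "Y1", "My2", "Y2"), reactions, params = params,
                   model = "simple_cascade")
}

#' Specify a global translation-capacity variable
#'
#' The global variable G follows a memoryless birth/death process with birth
#' rate `beta_g` and per-capita death rate `gamma_g`, so its stationary law
#' is Poisson with mean `gbar = beta_g / gamma_g` and coefficient of
#' variation `1/sqrt(gbar)`. Coupled protein-synthesis propensities are
#' multiplied by `G / gbar`, leaving their means unchanged while adding slow
#' extrinsic fluctuations.
#'
#' @param gbar target mean of G (molecules).
#' @param gamma_g death rate (1/s); `3e-8` makes G much slower than the
#'   cascade, `3e-6` is the slow-global default for the synthetic circuit.
#' @param beta_g birth rate; defaults to `gbar * gamma_g`.
#' @param coupled names of the protein-creation reactions to couple; `NULL`
#'   lets the model builders pick their translation reactions.
#' @export
#' @examples
#' gs <- global_spec(gbar = 50, gamma_g = 3e-8)
#' gs$beta_g   # 1.5e-6
#' gs$eta_g    # 1/sqrt(50)
global_spec <- function(gbar = 50, gamma_g = 3e-8, beta_g = gbar * gamma_g,
                        coupled = NULL) {
  stopifnot(gamma_g > 0, beta_g >= 0)
  gbar <- beta_g / gamma_g
  list(beta_g = beta_g, gamma_g = gamma_g, gbar = gbar,
       eta_g = 1 / sqrt(gbar), coupled = coupled)
}

#' Attach a global fluctuating variable to a network
#'
#' Adds the species `G` with its birth/death reactions and rewrites each
#' coupled propensity `a` to `a * G / gbar`: a constant synthesis rate
#' becomes linear in G and a mass-action translation term becomes bilinear
#' in (mRNA, G). With G pinned at `gbar` all propensities reduce to their
#' nominal values.
#'
#' @param net a [reaction_network()] without a global variable.
#' @param gspec a [global_spec()]; if its `coupled` field is `NULL`, all
#'   `const`- and `lin`-kind synthesis reactions whose name starts with
#'   `syn_` or `tl_` are coupled.
#' @export
attach_global_variable <- function(net, gspec) {
  stopifnot(inherits(net, "reaction_network"))
  if ("G" %in% net$species) stop("network already has a global variable")
  coupled <- gspec$coupled
  if (is.null(coupled)) {
    coupled <- grep("^(syn|tl)_", rownames(net$nu), value = TRUE)
  }
  unknown <- setdiff(coupled, rownames(net$nu))
  if (length(unknown) > 0) {
    stop("unknown coupled reaction(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  gbar <- gspec$gbar
  reactions <- lapply(net$reactions, function(r) {
    if (!(r$name %in% coupled)) return(r)
    if (r$kind == "const") {
      reaction(r$name, r$change, "lin", rate = r$rate / gbar, species = "G")
    } else if (r$kind == "lin") {
      reaction(r$name, r$change, "bilin", rate = r$rate / gbar,
               species = c(r$species, "G"), x_scaled = r$x_scaled)
    } else {
      stop("cannot couple propensity of kind '", r$kind, "' to G",
           call. = FALSE)
    }
  })
  reactions <- c(reactions, list(
    reaction("syn_g", c(G = 1L), "const", rate = gspec$beta_g),
    reaction("deg_g", c(G = -1L), "lin", rate = gspec$gamma_g, species = "G")
  ))
  gspec$coupled <- coupled
  reaction_network(c(net$species, "G"), reactions, params = net$params,
                   model = paste0(net$model, "_global"), gspec = gspec)
}

#' Build the synthetic estradiol-inducible circuit
#'
#' The circuit extends the simple cascade with an mRNA step for Y1*: `M1`
#' (ADH1 mRNA) is transcribed at the estradiol-repressed rate
#' `beta_m1 * ((1 - alpha_x) + alpha_x * x_e^n_x / (x_e^n_x + x^n_x))`
#' (a constant `beta_m1` when `adh1_estradiol = FALSE`), and is translated
#' both into Y1* (`Y1s`) and into the co-expressed fluorescent reporter
#' `Y1r`. Downstream of `Y1` the network is identical to the cascade. The
#' `"global"` variant couples the three translation reactions to a slow
#' global variable G (default mean 42, `gamma_g = 3e-6`, the slow-global
#' fluctuation or SGF model); the `"intrinsic"` variant has no G.
#'
#' @param params parameter list, defaults to [circuit_params()] for the
#'   chosen variant.
#' @param variant `"global"` or `"intrinsic"`.
#' @param adh1_estradiol include the modest estradiol-dependent repression
#'   of ADH1 transcription (`TRUE`, the default) or hold it constant.
#' @param gspec global-variable spec for the `"global"` variant; defaults
#'   to `global_spec(gbar = 42, gamma_g = 3e-6)`.
#' @export
#' @examples
#' sgf <- build_synthetic_circuit()              # slow-global-fluctuation
#' intr <- build_synthetic_circuit(variant = "intrinsic")
build_synthetic_circuit <- function(params = NULL,
                                    variant = c("global", "intrinsic"),
                                    adh1_estradiol = TRUE, gspec = NULL) {
  variant <- match.arg(variant)
  if (is.null(params)) params <- circuit_params(variant)
  check_params(params, c("beta_m1", "gamma_m1", "beta_y1s", "gamma_y1s",
                         "gamma_y1", "gamma_y1r", "theta_x", "theta_y1",
                         "n1", "y1_0", "beta_m2s", "beta_m2", "gamma_m2",
                         "beta_y2", "gamma_y2", "alpha_x", "x_e", "n_x"))
  p <- params
  tx_m1 <- if (adh1_estradiol) {
    reaction("tx_m1", c(M1 = 1L), "adh1",
             adh1 = list(bm1 = p$beta_m1, ax = p$alpha_x, xe = p$x_e,
                         nx = p$n_x))
  } else {
    reaction("tx_m1", c(M1 = 1L), "const", rate = p$beta_m1)
  }
  reactions <- list(
    tx_m1,
    reaction("deg_m1", c(M1 = -1L), "lin", rate = p$gamma_m1,
             species = "M1"),
    reaction("tl_y1s", c(Y1s = 1L), "lin", rate = p$beta_y1s,
             species = "M1"),
    reaction("tl_y1r", c(Y1r = 1L), "lin", rate = p$beta_y1s,
             species = "M1"),
    reaction("deg_y1s", c(Y1s = -1L), "lin", rate = p$gamma_y1s,
             species = "Y1s"),
    reaction("deg_y1r", c(Y1r = -1L), "lin", rate = p$gamma_y1r,
             species = "Y1r"),
    reaction("act", c(Y1s = -1L, Y1 = 1L), "lin", rate = p$theta_x,
             species = "Y1s", x_scaled = TRUE),
    reaction("deact", c(Y1 = -1L, Y1s = 1L), "lin", rate = p$theta_y1,
             species = "Y1"),
    reaction("deg_y1", c(Y1 = -1L), "lin", rate = p$gamma_y1,
             species = "Y1"),
    reaction("tx_my2", c(My2 = 1L), "hill", species = "Y1",
             hill = list(b0 = p$beta_m2s, b = p$beta_m2, n = p$n1,
                         K = p$y1_0)),
    reaction("deg_my2", c(My2 = -1L), "lin", rate = p$gamma_m2,
             species = "My2"),
    reaction("tl_y2", c(Y2 = 1L), "lin", rate = p$beta_y2,
             species = "My2"),
    reaction("deg_y2", c(Y2 = -1L), "lin", rate = p$gamma_y2,
             species = "Y2")
  )
  net <- reaction_network(c("M1", "Y1s", "Y1", "Y1r", "My2", "Y2"),
                          reactions, params = params,
                          model = paste0("circuit_", variant))
  if (variant == "global") {
    if (is.null(gspec)) gspec <- global_spec(gbar = 42, gamma_g = 3e-6)
    gspec$coupled <- c("tl_y1s", "tl_y1r", "tl_y2")
    net <- attach_global_variable(net, gspec)
    net$model <- "circuit_global"
  } else if (!is.null(gspec)) {
    stop("the intrinsic variant takes no global-variable spec",
         call. = FALSE)
  }
  net
}

#' Pin the global variable at a fixed copy number
#'
#' Conditions the network on G = `g`: the `G / gbar` factor of every
#' coupled propensity is replaced by the constant `g / gbar` and the G
#' species (with its birth/death reactions) is removed, leaving the
#' conditional network whose translation rates are scaled by `g / gbar`.
#' Used for conditioning on the slow variable.
#'
#' @param net network containing `G`.
#' @param g copy number at which G is held (recorded as attribute
#'   `pinned_at`).
#' @export
pin_global <- function(net, g = net$gspec$gbar) {
  stopifnot("G" %in% net$species)
  gbar <- net$gspec$gbar
  keep <- !(rownames(net$nu) %in% c("syn_g", "deg_g"))
  reactions <- lapply(net$reactions[keep], function(r) {
    if (!("G" %in% r$species)) return(r)
    if (r$kind == "lin" && r$species == "G") {
      reaction(r$name, r$change, "const", rate = r$rate * g)
    } else if (r$kind == "bilin") {
      other <- setdiff(r$species, "G")
      reaction(r$name, r$change, "lin", rate = r$rate * g,
               species = other, x_scaled = r$x_scaled)
    } else {
      stop("cannot pin propensity of kind '", r$kind, "'", call. = FALSE)
    }
  })
  out <- reaction_network(setdiff(net$species, "G"), reactions,
                          params = net$params, model = net$model,
                          gspec = net$gspec)
  attr(out, "pinned") <- TRUE
  attr(out, "pinned_at") <- g
  out
}

# ---------------------------------------------------------------------------
# Propensity evaluation
# ---------------------------------------------------------------------------

hill_value <- function(h, y) {
  if (y <= 0) return(h$b0)
  yn <- y^h$n
  h$b0 + h$b * yn / (yn + h$K^h$n)
}

hill_grad <- function(h, y) {
  if (y <= 0) {
    if (h$n > 1) return(0)
    if (h$n == 1) return(h$b / h$K)
    return(Inf)
  }
  yn <- y^h$n
  Kn <- h$K^h$n
  h$b * h$n * Kn * y^(h$n - 1) / (yn + Kn)^2
}

adh1_value <- function(a, x) {
  a$bm1 * ((1 - a$ax) + a$ax * a$xe^a$nx / (a$xe^a$nx + x^a$nx))
}

#' Evaluate reaction propensities at a state
#'
#' @param net a [reaction_network()].
#' @param y named (or ordered) state vector, molecules; negative entries
#'   are clipped to zero before evaluation.
#' @param x external input amplitude (nM).
#' @return Named vector of propensities (1/s), one per reaction.
#' @export
propensities <- function(net, y, x = 0) {
  y <- state_vector(net, y)
  y <- pmax(y, 0)
  a <- vapply(net$reactions, function(r) {
    switch(r$kind,
      const = r$rate,
      lin = {
        coef <- if (r$x_scaled) r$rate * x else r$rate
        coef * y[[r$species]]
      },
      bilin = {
        coef <- if (r$x_scaled) r$rate * x else r$rate
        coef * y[[r$species[1]]] * y[[r$species[2]]]
      },
      hill = hill_value(r$hill, y[[r$species]]),
      adh1 = adh1_value(r$adh1, x),
      stop("unknown propensity kind: ", r$kind)
    )
  }, numeric(1))
  names(a) <- rownames(net$nu)
  a
}

state_vector <- function(net, y) {
  if (!is.null(names(y))) {
    missing <- setdiff(net$species, names(y))
    if (length(missing) > 0) {
      stop("state is missing species: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    y <- y[net$species]
  } else if (length(y) != length(net$species)) {
    stop("state length does not match species count", call. = FALSE)
  }
  setNames(as.numeric(y), net$species)
}

#' Estradiol-repressed ADH1 transcription rate
#'
#' `beta_m1 * ((1 - alpha_x) + alpha_x * x_e^n_x / (x_e^n_x + x^n_x))`:
#' equals `beta_m1` at zero estradiol and `beta_m1 * (1 - alpha_x)` at
#' saturating doses.
#'
#' @param x estradiol (nM), vectorized.
#' @param params circuit parameter list.
#' @export
adh1_rate <- function(x, params = circuit_params()) {
  p <- params
  p$beta_m1 * ((1 - p$alpha_x) +
                 p$alpha_x * p$x_e^p$n_x / (p$x_e^p$n_x + x^p$n_x))
}

#' Hill transcription propensity of the output gene
#'
#' @param y1 active Y1 copy number, vectorized.
#' @param params parameter list with `beta_m2s`, `beta_m2`, `n1`, `y1_0`.
#' @export
hill_activation <- function(y1, params = cascade_params()) {
  p <- params
  yn <- pmax(y1, 0)^p$n1
  p$beta_m2s + p$beta_m2 * yn / (yn + p$y1_0^p$n1)
}

# ---------------------------------------------------------------------------
# Input protocols
# ---------------------------------------------------------------------------

#' Step-input protocols
#'
#' A step protocol applies `x(t) = 0` for `t < 0` and `x(t) = x_plus` for
#' `t >= 0`, with the amplitude drawn uniformly from a finite dose set.
#' `estradiol_protocol()` returns the 12-well series used for the synthetic
#' circuit: doses `100 * (2/3)^(c - 1)` nM for wells `c = 1..11` plus a
#' zero-estradiol well. `log_step_protocol()` generalizes it to `n` doses
#' below an arbitrary maximum, which is how finite dose-sample counts are
#' generated when studying convergence of the mutual-information estimate.
#'
#' @param amplitudes dose amplitudes (nM).
#' @param xmax maximum dose; defaults to `max(amplitudes)`.
#' @return List with `amplitudes` (sorted ascending), `xmax`, and uniform
#'   probabilities `p`.
#' @export
step_protocol <- function(amplitudes, xmax = max(amplitudes)) {
  stopifnot(length(amplitudes) >= 1, all(amplitudes >= 0),
            all(amplitudes <= xmax))
  amplitudes <- sort(unique(amplitudes))
  list(amplitudes = amplitudes, xmax = xmax,
       p = rep(1 / length(amplitudes), length(amplitudes)))
}

#' @rdname step_protocol
#' @export
estradiol_protocol <- function() {
  step_protocol(c(0, 100 * (2 / 3)^(10:0)), xmax = 100)
}

#' @rdname step_protocol
#' @param n total number of doses including the zero dose.
#' @param ratio geometric spacing ratio of the nonzero doses.
#' @export
log_step_protocol <- function(xmax, n, ratio = 2 / 3) {
  stopifnot(n >= 2, ratio > 0, ratio < 1)
  step_protocol(c(0, xmax * ratio^((n - 2):0)), xmax = xmax)
}
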