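# stochmi

Time-dependent mutual information in stochastic biochemical networks.

## The problem

How many bits does a snapshot of a pathway output carry about the input a
cell received? Population-level estimates of this mutual information (MI)
from dose-response experiments are routinely low — about one bit — and
`stochmi` implements the modeling machinery to ask why: cells enter the
experiment with different initial states and with different slowly
fluctuating global factors (e.g. translation capacity), so the population
is a mixture of distinct, individually much cleaner channels. The package
is aimed at quantitative/systems biologists who want to decompose
population MI into its single-cell and extrinsic components, and to decide
from time-resolved cytometry-style data which noise regime dominates a
circuit.

## What it computes

For a well-stirred reaction network with state `y`, reactions `r_j`
(stoichiometry `nu_j`, propensity `a_j(y)`), the chemical master equation
governs `P(y, t | x)`. The package propagates its first two moments under
a second-moment (normal) closure,

    dz/dt = nu' E[a],        E[a_j] = a_j(z) + (1/2) tr(H_j C)
    dC/dt = A C + C A' + B,  A = nu' (da/dy)|_z,  B = nu' diag(E[a]) nu

rebuilds conditional output laws from `(mu, C)` — negative binomial where
`mu < 3 sqrt(C)`, normal otherwise — and evaluates the time-dependent MI
of a step-input protocol with a uniform input over the dose range,

    I(x+; y, t) = sum_x sum_y p(y,t|x+) p_u(x+) log2[ p(y,t|x+) / p(y,t) ]

together with joint MI of simultaneous readouts (chain-rule decomposition
included), the expectation of MI conditioned on a slow global variable G
(a birth/death process multiplying translation rates by `G / gbar`), and
the diversity metric `I(y; G, t | x)`. An exact Gillespie simulator
(compiled) validates the closure, and a synthetic flow-cytometry generator
emulates per-cell reporter tables for three noise regimes (slow-global,
fast-global, intrinsic) with a classifier that recovers the regime from
the summary statistics.

## Worked example

```r
library(stochmi)

# Two-step signaling cascade: input x converts Y1* to Y1, which drives
# transcription of the output Y2.
casc <- build_simple_cascade()
st <- stationary_moments(casc, x = 0)
round(st$mean, 1)
#>    Y1s     Y1    My2     Y2
#> 1492.5    0.0   10.0  100.0     # total Y1 = 0.01 / 6.7e-6 ~ 1500

# Add a slow global variable (mean 50, relaxation 3e-8 1/s) coupled to
# the translation rates, and compare population vs single-cell MI.
net   <- attach_global_variable(casc, global_spec(gbar = 50, gamma_g = 3e-8))
doses <- log_step_protocol(250, 13)$amplitudes
times <- c(0, 165, 330, 750)
het <- make_initial("heterogeneous", net)   # full stationary population
s1  <- make_initial("S1", net)              # one cell at the mean state
mi_pop <- mutual_information(build_surface(net, doses, times, het),
                             times, "Y2", n_grid = 201)
mi_s1  <- mutual_information(build_surface(net, doses, times, s1),
                             times, "Y2", n_grid = 201)
round(rbind(population = mi_pop, S1 = mi_s1), 3)
#>             [,1]  [,2]  [,3]  [,4]
#> population     0 1.220 1.261 1.270
#> S1             0 2.727 2.941 2.974
```

A cell whose slow state is known transmits ~1.7 bits more than the pooled
population at 750 min: population averaging, not the pathway, hides the
information. The slow-variable identity makes this exact — the joint MI
over (output, G) equals the average of G-conditioned MI values:

```r
id <- slow_g_identity(net, doses, c(165, 330, 750), "Y2", n_grid = 201)
round(id$expected_bits, 3)
#> [1] 2.622 2.827 2.888
max(abs(id$joint_bits - id$expected_bits))
#> [1] 3.996803e-15
```

For the estradiol-inducible synthetic circuit (slow-global-fluctuation
model: `gbar = 42` calibrated from the measured reporter noise 0.155,
`gamma_g = 3e-6`), the emulated cytometry experiment recovers its own
generating regime:

```r
cells <- generate_cells("SGF", n_cells = 3000, seed = 11)
s <- summarize_cells(cells)
subset(s, channel == "y1r" & dose_nM == 0 & time_min == 580)$noise
#> [1] 0.1575798                      # the calibration target, 0.155
classify_variability(s)
#> [1] "slow-global"
```

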