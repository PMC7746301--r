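# loopstate

Structural and bifurcation analysis of a positive-feedback-loop model of
ALS pathogenesis.

## The problem

In the SOD1-linked form of amyotrophic lateral sclerosis, misfolded mutant
SOD1 accumulates on motor-neuron mitochondria and impairs oxidative
phosphorylation (OXPHOS).  That single insult propagates through three
overlapping feedback loops: energy stress activates AMPK, AMPK activates
the glycolytic driver PFK3, PFK3 shifts glucose catabolism away from the
pentose phosphate pathway (PPP), the loss of PPP-derived reducing power
worsens oxidative stress and glutamate excitotoxicity, and both feed back
onto mitochondria and onto PFK3 expression (via APC^Cdh1^ inhibition).
Every one of those cycles contains an even number of inhibitions, so each
is a *positive* loop — the classic architecture of a bistable switch
between a healthy state (high OXPHOS/PPP, low AMPK/PFK3/glutamate) and a
pathological one.

`loopstate` is for systems biologists who want that argument as executable,
tested code rather than as a figure: every printed sign matrix, loop count
and equilibrium-count claim in the analysis is an automated assertion.

## The model

Each functional agent `x_i ∈ {a (AMPK), k (PFK3), c (APC^Cdh1^), m
(OXPHOS), p (PPP), g (glutamate)}` follows

    τ_i ẋ_i + x_i = Σ_{j→i} r_ji(x_j)

with monotone Hill responses `f(x) = αxⁿ/(1+βxⁿ)` (activation) and
`h(x) = γ/(1+δxⁿ)` (inhibition) and a constant input `u` (mutant SOD1)
inhibiting the OXPHOS equation.  The strength of the PFK3 → PPP
inhibition — the one edge shared by all three loops — is scaled by a
bifurcation parameter `μ`, so the effective term is `μ·h₅(k)`.

The analysis stack:

* **Structural (parameter-free):** interaction matrix `S = sign(J)`, input
  sign vector, simple-loop census with signs, candidate-multistationarity
  test, monotone gauge detection (variable flips making the pattern
  Metzler), structural influence matrix `sign(adj(−J))` at a stable
  equilibrium, input–output influence vector.
* **Numerical:** adaptive RK45 simulation, multistart damped-Newton
  equilibrium finding with stability classification and healthy /
  pathological labelling, numerical verification of every influence sign.
* **Bifurcation:** μ sweeps with fold bisection, hysteresis runs, edge
  knockouts with the loop-free closed-form steady state.
* **Scenario:** seeded random parameterizations and a bistable-regime
  search; the shipped reference fixture is one pinned bistable instance.

## Worked example

```r
library(loopstate)

net <- als_network()
S <- interaction_matrix(net)
enumerate_feedback_loops(S)
#> loop a-k-p-m-a (positive, 2 inhibitory edges)
#> loop c-k-p-g-c (positive, 4 inhibitory edges)
#> loop a-k-p-g-m-a (positive, 4 inhibitory edges)

find_monotone_gauge(S)
#> gauge (D and -D equivalent; canonical: flip(m) = +1):
#>   a:-  k:-  c:+  m:+  p:+  g:-

structural_influence_matrix(S)
#>              AMPK PFK3 APC^Cdh1 OXPHOS PPP GLUTAMATE
#> on AMPK      +    +    -        -      -   +
#> on PFK3      +    +    -        -      -   +
#> on APC^Cdh1  -    -    +        +      +   -
#> on OXPHOS    -    -    +        +      +   -
#> on PPP       -    -    +        +      +   -
#> on GLUTAMATE +    +    -        -      -   +
```

The influence matrix says: a persistent push on any of {AMPK, PFK3,
glutamate} raises all three and lowers {APC^Cdh1^, OXPHOS, PPP} at the new
steady state — regardless of parameter values — and vice versa.  The two
blocks are the disease-promoting and disease-preventing halves of the
network.

Dynamics on the pinned bistable fixture:

```r
params <- reference_parameterization()   # mu at mid-window, ~14.6
eqs <- classify_health(find_equilibria(params, n_starts = 40, seed = 1))
for (e in eqs) print(e)
#> equilibrium (stable, label: healthy)
#>   a=0.349358  k=0.614499  c=1.11362  m=2.26714  p=9.24438  g=0.00437637
#> ...
#> equilibrium (unstable, label: unclassified)
#>   a=0.984444  k=2.19905  c=1.08876  m=1.15838  p=1.43436  g=0.156344
#> ...
#> equilibrium (stable, label: pathological)
#>   a=2.31104  k=6.03366  c=0.591749  m=0.377511  p=0.205426  g=0.971342
```

Two stable states separated by a saddle: the healthy one has high OXPHOS
(m) and PPP (p) with AMPK/PFK3/glutamate low, the pathological one the
reverse.  Sweeping the key interaction strength:

```r
d <- sweep_mu(params, exp(seq(log(1e-2), log(1e2), length.out = 60)), seed = 1)
print(d)
#> bifurcation_diagram over mu: 60 grid points in [0.01, 100]
#>   stable-count pattern: 1 -> 2 -> 1
#>   folds near: 7.276, 28.15
#>   bistable window: [8.227, 24.54]
```

One caution on reading the μ axis: μ scales the whole production term
`μ·h₅(k)` of PPP, so *larger* μ means more PPP production and lower
steady-state PFK3 — the pathological high-PFK3 state is the unique
equilibrium at *small* μ, and "strengthening the PFK3 → PPP suppression"
moves leftward on this axis (see the methods vignette for why this is
forced by the influence matrix).

Knocking out the shared PFK3 → PPP edge collapses the switch:

```r
ko <- knockout_edge(params, "h5")
length(enumerate_feedback_loops(interaction_matrix(ko$network)))  # 0
length(find_equilibria(ko, n_starts = 30, seed = 1))              # 1
knockout_equilibrium_closed_form(ko)$state[["p"]]                 # exactly 0
```

which is the model's therapeutic punchline: every loop runs through PFK3,
so keeping PFK3 activity low removes the bistability entirely.

One command reruns the whole analysis with every claim asserted:

```r
reproduce_paper(output_dir = "reproduction", seed = 1)
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/loopstate.R", package="loopstate"))') \
    structure --builtin als --out structure.json
```

Subcommands: `structure`, `simulate`, `equilibria`, `bifurcate`,
`knockout`, `hysteresis`, `verify-influence`, `search-bistable`,
`reproduce`.  Model specs are JSON (`write_model_spec()` /
`load_model_spec()`).

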