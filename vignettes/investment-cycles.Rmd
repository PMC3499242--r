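---
title: "Investment cycles, phase polymorphism and spatial bubbles in two-guild mutualisms"
author: "mutualsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Investment cycles, phase polymorphism and spatial bubbles in two-guild mutualisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutualsim)
```

## The model

Two mutualist guilds — think host plants and their rhizobial or mycorrhizal
symbionts, or ants and the aphids they tend — exchange costly investments
over repeated rounds. Each individual carries two non-negative heritable
traits:

* the **initial offer** $o$: the unconditional investment made in the first
  round, before any feedback from the partner;
* the **reward rate** $r$: the slope with which the *previous round's own
  net payoff* is converted into the next investment.

An individual paired with a partner from the other guild invests $I(1) = o$
in round one and

$$I(t) = \max\{0,\; o + r\,P(t-1)\}, \qquad t = 2, \dots, T,$$

afterwards, where $P(t-1)$ is its own net payoff from the previous round.
A round pays the benefit of the partner's investment minus the cost of
one's own:

$$P(t) = B(I_\mathrm{partner}(t)) - C(I_\mathrm{own}(t)),$$

with the saturating benefit $B(x) = B_0\,(1 - e^{-B_1 x})$ and linear cost
$C(x) = K x$. Total payoffs sum the $T$ rounds. The benefit saturates —
each extra unit received helps less — while costs do not, which is what
makes unconditional generosity exploitable.

The functional forms are a modelling choice constrained by structure:
$B(0)=0$, smooth saturation toward an asymptote $B_0$, initial slope
$B'(0)=B_0 B_1$, and a cost linear at the origin with slope $K$. Any pair
of functions with these properties yields the same qualitative picture;
`model_params()` accepts custom `benefit_fn`/`cost_fn` closures for the
pure-R game path (`play_interaction()`), while the grid scans and the
individual-based model use the built-in family for speed.

### Parameters and defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `B0` | asymptotic benefit | payoff | 5 |
| `B1` | benefit saturation rate | 1/investment | 1 |
| `K` | cost slope | payoff/investment | 1 |
| `T` | rounds per interaction | — | 20 |

The defaults give a linearised benefit-to-cost ratio $r_0 = B_0 B_1 / K = 5$,
a generously profitable mutualism of the kind the threshold and cycle
phenomena are most clearly expressed in. $r_0$ is an upper bound: the
saturating benefit drives the realised benefit-to-cost ratio below it for
any positive investment, and no investment can ever pay when $r_0 \le 1$.

## The reciprocation threshold

For vanishing investments the game linearises. One extra unit of own
investment costs $C'(0) = K$ and raises the partner's payoff by
$B'(0) = B_0 B_1$; a payoff-reactive partner converts that into
$r\,B'(0)$ extra investment next round, worth $r\,B'(0)^2$ in benefit.
Reciprocation therefore pays exactly when

$$r > \beta^{*} = \frac{C'(0)}{B'(0)^2} = \frac{K}{(B_0 B_1)^2}.$$

Note the square: the reward rate has units of investment per payoff, so the
benefit slope enters twice (once converting own investment into the
partner's payoff, once converting the partner's response back into own
benefit). In a finite game the last round's investment earns no return,
which shifts the measured sign change upward by a factor of roughly
$1 + 2/T$; with the default $T = 20$ the flip sits about 11% above
$\beta^*$, converging onto it for longer games. For slope ratios close to
one (roughly $r_0 \lesssim 2.5$) the window of rewards in which
reciprocation is profitable before the interaction destabilises becomes so
narrow that no sign change is numerically detectable; the threshold is a
small-investment, comfortably-profitable-regime concept.

```{r threshold}
p <- model_params()
reciprocation_threshold(p)
```

## Best responses and the investment cycle

No closed form exists for the best response, so `best_response()` scans a
strategy grid (default $201 \times 201$ over $[0,5]^2$, ties broken toward
smaller traits for determinism). The best response to no investment is no
investment, and an exhaustive pair scan finds no other mutual
best-response pair — a coarse grid can host spurious fixed points wherever
the best-response map moves a strategy by less than one grid step, so
`find_mutual_best_responses()` verifies every candidate on a finer grid
before reporting it.

```{r br}
find_mutual_best_responses(p, grid_spec(5, 5, 21, 21))
```

Iterating best responses (`best_response_dynamics()`) from any start
reaches the no-investment pair; starts just above the threshold first
*increase* reciprocation and offers before the collapse. The deterministic
skeleton of the same story is the gradient flow: both guilds' traits
follow their monomorphic selection gradients (`selection_gradient()`,
central finite differences with step $h = 10^{-4}$, one-sided at the zero
boundary), integrated by explicit Euler steps. Euler is sufficient here
because gradients are cheap and only the qualitative cycle shape is of
interest; a step-halving check (peak offer moves by far less than 2% when
the step is halved) guards the accuracy of that choice.

```{r cycle}
beta <- reciprocation_threshold(p)
fl <- gradient_flow(list(c(0.01, 1.5 * beta), c(0.01, 1.5 * beta)), p,
                    step_size = 1e-3, n_steps = 20000)
print(fl)
```

The trajectory is the **investment cycle**: both traits rise (phase I,
gradient pointing up-right), the reward rate peaks and declines while
offers still grow (phase II), then both collapse to zero (phase III).
Phases are the clockwise angle of the gradient vector from the positive
reward axis — offer on the horizontal axis, reward on the vertical, which
makes the narrated phase order I &rarr; II &rarr; III match the quadrant
order of the angle. A zero gradient has no phase; it is reported as
`undefined` and excluded from histograms.

## The individual-based model

`run_simulation()` evolves two populations of such strategies, either on
two matched $N \times N$ toroidal lattices (partners occupy matching
sites; competition is among the Moore-8 neighbours) or as well-mixed pools
(random partner per payoff evaluation; competitors drawn at random).
Toroidal wrap avoids edge artifacts. One generation is population-size
single-site updates (asynchronous, the default) or one simultaneous sweep
(synchronous). Each update refreshes the payoffs of the interacting pair
— and, by default, of every competitor entering the competition
(`payoff_refresh = "full"`; `"focal_only"` keeps stale competitor caches) —
then applies the competition rule on both lattices at the site, then
mutates the written strategies.

Two competition rules are available: *best-takes-over* (deterministic
imitation of the highest-payoff contender, exact ties resolved uniformly
at random) and the *pairwise-comparison* (Fermi) rule, replacement with
probability $1/(1 + e^{-\Delta P / K_\mathrm{sel}})$ against one random
competitor, $K_\mathrm{sel} = 0.1$ by default. Two mutation kernels
matter: with a **constant CV** the mutational standard deviation is
proportional to the current trait value, so zero is absorbing — a guild
that loses a trait entirely can never regain it; with **constant sigma**
variation regenerates everywhere. This one switch controls most of the
spatial-versus-well-mixed contrast below.

Reported payoffs are normalised by `max_potential_payoff()` — the payoff a
pair would accrue if both played the symmetric per-round optimum, found by
bounded scalar maximisation. Below the profitability boundary
($r_0 \le 1$) that optimum is zero; the costless bound $T B_0$ is used as
the normaliser there so the column stays defined (payoffs are then
non-positive and the normalised value is ~0).

## What the simulations show, and at what sizes

The package's tests exercise the model at sizes chosen once to make each
phenomenon detectable within minutes on one core; they are stated here as
the package's study conditions.

* **Diversity threshold** (well-mixed, constant sigma, 900 individuals per
  guild, 2000 generations, pairwise-comparison updating, 5 replicates):
  at $\sigma = 0.005$ the community never ignites (normalised payoff
  below 0.05); at $\sigma = 0.1$ a stable mutualistic community holds
  around 0.45. The transition is abrupt; beyond it the payoff declines
  mildly with $\sigma$ as the cycle amplitude shrinks, which is why the
  high-diversity reference point is $\sigma = 0.1$ rather than a larger
  value.
* **Spatial facilitation** (constant CV, synchronous best-takes-over,
  $50 \times 50$ versus well-mixed at matched parameters, 2000
  generations, 5 replicates): runs start from homogeneous traits 0.1 —
  just above the threshold, so the cycle ignites immediately — because
  the contrast concerns the *maintenance* of mutualism: under constant-CV
  mutation the lattice holds mean investments around 0.26 while the
  well-mixed community decays to ~0.01. Starting at the conventional
  0.01 instead, neither structure ignites within thousands of
  generations (the reward trait must drift across the threshold with
  mutation steps proportional to a tiny trait value), which is a
  statement about ignition time, not about maintenance.
* **Interface logic**: strategy-pair duels are constructed by seeded
  random search and classified by `classify_interface()`; the predicted
  outcome is checked against `two_bubble_experiment()` (mutation-free
  $40 \times 40$ lattices, synchronous best-takes-over, 200 generations).
  For straight vertical fronts the two-dimensional dynamics reduce
  exactly to a ring of columns (`rehearse_interface()`), which is what
  makes a purely static payoff-ordering classifier predictive. Under
  synchronous updating a blocked interface *flickers* — the mismatched
  cross-pairing forms in one sweep and is repelled in the next — so the
  experiment inspects the final two generations and reports interface
  statistics from the phase that carries the stripe.

## Numerical choices and degenerate inputs

* Grid scans start exactly at zero and break payoff ties toward smaller
  offers, then smaller rewards, so `(0, r)` responses that are
  payoff-ties of no-investment collapse onto `(0, 0)`.
* Finite differences use $h = 10^{-4}$ with one-sided fallback at the
  trait boundary. The truncation $\max\{0, \cdot\}$ in the investment
  rule makes payoffs piecewise smooth; finite differences across a kink
  can produce locally misleading gradients at large traits in
  unprofitable regimes, which is why threshold statements are made in the
  small-investment regime.
* `classify_interface()` reports any exact payoff tie among the used
  comparisons as `degenerate` (ties cannot move a deterministic front).
* Exact zeros matter in the mutation kernel: under constant CV a zero
  trait draws sd 0 and stays exactly zero, by design.
* Euler integration caps traits at 50 (configurable) purely as a
  divergence guard; trajectories of interest never approach it.

## What the generator does not emulate

The simulated communities are idealisations: exactly two guilds, one
partner per individual per evaluation, matched lattice sites, no
demography (constant population, death–birth replacement only), no
sexual reproduction, no environmental heterogeneity, and mutation kernels
that are Gaussian by fiat. Passing tests therefore show that the
*mechanisms* — threshold, cycle, phase polymorphism, bubble dynamics —
operate as described in this model class, not that any particular natural
mutualism is quantitatively captured.

## Known limitations

* The threshold formula is a small-investment limit; its finite-$T$ shift
  (~$1 + 2/T$) and its breakdown near $r_0 = 1$ are documented above.
* Long-run payoff levels in the stochastic runs depend on population
  size, horizon and update rule; the package asserts the qualitative
  contrasts, not absolute levels.
* Bubble detection thresholds trait distances at `epsilon = 0.1` by
  default (configurable); there is no canonical operational definition of
  a bubble and genealogies of bubbles across snapshots are out of scope.
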