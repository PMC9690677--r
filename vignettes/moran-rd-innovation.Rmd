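---
title: "Moran-process dynamics of pharmaceutical R&D innovation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moran-process dynamics of pharmaceutical R&D innovation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morangame)
```

## The model

A market of $N$ pharmaceutical enterprises produces one drug. Each
enterprise plays one of two strategies: **R&D innovation** ($I$) — invest
in improving the drug, at cost $C_{ph}$ for revenue $R_I$ if the R&D
succeeds — or **non-R&D innovation** ($T$) — keep producing as before, at
cost $C_{pl}$ for revenue $R_T$. Two policy levers shape the payoffs:

* **Industry cooperation.** Two innovators can pool R&D with universities
  and institutes, raising the success probability to $\eta_1$; an
  innovator paired with a non-innovator succeeds alone with probability
  $\eta_2$ (normally $\eta_1 \ge \eta_2$).
* **Tax incentives.** Innovators are exempted the fraction
  $\lambda R_T$ of the traditional revenue; non-innovators pay it.

The pairwise payoffs are therefore $a_{II} = \eta_1 R_I - C_{ph}$,
$a_{IT} = \eta_2 R_I - C_{ph}$ and, for the non-innovator against either
opponent, $a_{TT} = a_{TI} = R_T - \lambda R_T - C_{pl}$. With $i$
innovators present, averaging over the other $N-1$ group members gives
the expected revenues

$$E_{iI} = \frac{(i-1)a_{II} + (N-i)a_{IT}}{N-1}, \qquad
  E_{iT} = a_{TT},$$

so $E_{iI}$ is affine in $i$ (increasing when $\eta_1 > \eta_2$) and
$E_{iT}$ is flat — the non-innovator's payoff does not depend on its
opponent.

The tax convention deserves a note: one printed form of the
non-innovator's revenue elsewhere reads $\lambda R_I$, but the payoff
table, the model hypotheses and every downstream coefficient use
$\lambda R_T$; the package implements $R_T - \lambda R_T - C_{pl}$
throughout.

## Selection regimes

Revenue maps to reproductive fitness through a selection intensity
$\xi \ge 0$, which measures how much strategy choice is driven by payoff
rather than by external factors (policy shocks, public-health events):

* **neutral** ($\xi = 0$): $e = 1$; drift only.
* **linear** ($0 < \xi \le 1$): $e = 1 - \xi + \xi E$. The
  expected-revenue regime; $\xi = 1$ is pure expected-revenue dominance.
* **exponential** ($\xi > 1$, available for any $\xi > 0$):
  $e = \exp(\xi E)$. The super-expected-revenue regime, where payoff
  differences are amplified.

`resolve_regime()` applies exactly this rule for `regime = "auto"`. The
linear map can produce $e \le 0$ when $\xi$ is large and revenues are
strongly negative (the baseline scenario at $\xi = 1$ has
$e_{1I} = \eta_2 R_I - C_{ph} = -4$). Invasion analysis only uses fitness
*differences*, so it accepts any sign; chain computations require
positive fitness and raise a classed error
(`morangame_nonpositive_fitness`) advising the exponential map. The two
maps agree on fitness differences and ratios to $O(\xi^2)$, which is why
all weak-selection results below are regime-independent at first order.

## The Moran chain and fixation

Each step, one enterprise is picked to reproduce with probability
proportional to fitness and one uniformly at random is replaced, so the
innovator count $i$ performs a birth–death walk on $\{0, \dots, N\}$ with

$$Z_{i,i+1} = \frac{i e_{iI}}{i e_{iI} + (N-i) e_{iT}}\cdot\frac{N-i}{N},
  \qquad
  Z_{i,i-1} = \frac{(N-i) e_{iT}}{i e_{iI} + (N-i) e_{iT}}\cdot\frac{i}{N},$$

and absorbing ends at $0$ and $N$. Standard birth–death absorption gives
the rooting (fixation) probabilities from a single mutant,

$$\rho_I = \Big(1 + \sum_{k=1}^{N-1}\prod_{n=1}^{k}
  \frac{e_{nT}}{e_{nI}}\Big)^{-1}, \qquad
  \rho_T = \Big(1 + \sum_{k=1}^{N-1}\prod_{i=k}^{N-1}
  \frac{e_{iI}}{e_{iT}}\Big)^{-1},$$

with the full absorption vector $q_i$ interpolating between $q_0 = 0$
and $q_N = 1$. Under neutrality $\rho_I = \rho_T = 1/N$, the classic
benchmark: selection *favours* a strategy when its $\rho$ exceeds $1/N$.

### Numerical choices

All sums-of-products are accumulated as log-sum-exp over cumulative log
fitness ratios, so exponential-regime runs with $|\xi E|$ in the
hundreds neither overflow nor underflow ($\rho$ is finally recovered as
`plogis(-logsumexp(...))`). `fixation_linear_solve()` is an intentionally
independent second route — it assembles the absorption equations as a
row-normalized (jump-chain) tridiagonal system, solves densely and
applies one step of iterative refinement — and is used in the tests as an
oracle against the closed form. The dense route is limited by
conditioning once the cumulative fitness-ratio products span more than
roughly $e^{20}$; the log-space recursive route has no such limit, so the
equivalence tests bound the spread of the random draws they feed the
oracle while the recursive engine is separately exercised at
$\xi = 30$, $N = 40$. Monotonicity of $q$ is asserted after computation,
never assumed.

## Weak selection: the $1/N$ rule

As $\xi \to 0$ both fitness maps give

$$\rho_I \approx \frac1N + \frac{\xi}{6N}(\alpha + N\beta), \qquad
  \rho_T \approx \frac1N + \frac{\xi}{6N}(\gamma + N\delta),$$

with

$$\alpha = \delta = (-2\eta_1-\eta_2)R_I + 3(1-\lambda)R_T + 3C_{ph} - 3C_{pl},$$
$$\beta = (\eta_1+2\eta_2)R_I - 3(1-\lambda)R_T - 3C_{ph} + 3C_{pl}, \quad
  \gamma = (4\eta_1-\eta_2)R_I - 3(1-\lambda)R_T - 3C_{ph} + 3C_{pl}.$$

These are exact first-order coefficients: the tests differentiate the
exact $\rho$ numerically at $\xi \to 0$ and verify a log–log error slope
of 2 against the expansion. A sufficient condition for weak selection to
favour the innovators at *every* group size is a positive invasion
margin $\eta_2 R_I - C_{ph} - (R_T - \lambda R_T - C_{pl}) > 0$ together
with $\eta_1 > \eta_2$ (`proposition1_condition()`): the margin is the
excess of a lone innovator's payoff over a non-innovator's, and the
cooperation premise makes $\alpha + N\beta$ increasing in $N$.

`classify_weak()` compares exact $\rho_I$ and $\rho_T$ with $1/N$ by
default and only uses the Taylor form on request, because realistic
study settings ($\xi = 0.1$) are not asymptotically small; ties are
declared within $10^{-12}$.

## Strong and super-strong selection: invasion thresholds

At $\xi = 1$ the decision quantities are the boundary fitness
differences

$$h_1 = \eta_2 R_I + \lambda R_T + C_{pl} - C_{ph} - R_T, \qquad
  h_{N-1} = \tfrac{N-2}{N-1}\eta_1 R_I + \tfrac{1}{N-1}\eta_2 R_I
            + \lambda R_T + C_{pl} - C_{ph} - R_T.$$

Sign pairs classify the dynamics: $(+,+)$ innovation replaces
tradition; $(-,-)$ the reverse; $(+,-)$ neither pure state resists the
other's rare mutant, so the strategies coexist. The fourth combination
$(-,+)$ — each pure state resists invasion — is not covered by the
expected-revenue case list in the source analysis, but it occurs for
realistic parameters (the baseline with $\lambda = 0.3$ at large $N$),
so `classify_strong()` labels it `bistable` rather than leaving it
undefined.

Treating $N$ as real, $h_{N-1}$ crosses zero at

$$N_0 = \frac{2\eta_1 R_I - \eta_2 R_I + \lambda R_T - R_T - C_{ph} + C_{pl}}
             {\eta_1 R_I + \lambda R_T - R_T - C_{ph} + C_{pl}},$$

reported by `threshold_N0()` as a real number together with the
applicability sign $\eta_2 R_I + \lambda R_T - R_T - (C_{ph}-C_{pl})$
(which equals $h_1$). Integer group sizes are classified by strict
inequality on either side of $N_0$; a size falling numerically on the
boundary is resolved by evaluating $h_{N-1}$ directly. The monotone
reading "above $N_0$ the innovators win when the sign is positive"
additionally requires $\eta_1 \ge \eta_2$, since
$\partial h/\partial N - h_1 = (\eta_1 - \eta_2) R_I$; the package
documents and tests the threshold under that cooperation premise.
When the denominator vanishes, $h_{N-1}$ is independent of $N$ and a
`degenerate-threshold` error is raised instead of a spurious number.

Under exponential fitness the same information arrives as ratios
$f = \exp(\xi h)$ against 1 (and $g = f - 1$, the plotted form). Since
$\exp$ is monotone, $\operatorname{sign}(f-1) = \operatorname{sign}(h)$
for every $\xi > 0$: `classify_super()` always agrees with
`classify_strong()` and the threshold is unchanged ($N_1 = N_0$),
which the tests check over a thousand random draws at
$\xi \in \{1.1, 1.5, 5\}$. Amplifying revenue changes the speed of
selection, not its direction.

## Monte Carlo validation

`simulate_fixation()` steps the chain literally — sampling up, down or
stay from the exact one-step probabilities — until absorption, and
estimates fixation as the absorbed-at-$N$ fraction with a binomial
standard error. A `jump_chain = TRUE` variant conditions each step on
leaving the current state; absorption probabilities are invariant to
removing self-loops, so both estimators target the same quantity and
the jump form is much faster near weak selection, where the chain
spends most steps idling. One RNG stream seeded once makes runs
bit-reproducible. The generator is deliberately the same
`transition_row()` the analytic engine uses — the simulation validates
the absorption algebra end-to-end, not the transition formulas
themselves, which have their own direct tests.

What the simulator emulates is exactly the model's stochastic update:
it does not add measurement noise, heterogeneous firms, entry/exit, or
strategy mutation, so agreement between simulation and formula shows
internal consistency of the dynamics, not realism of the market model.

## The simulation study as sweeps

`builtin_scenarios()` packages the study's market: non-R&D cost 13 and
revenue 22, R&D cost 18 and revenue 35, with the per-panel bindings
(`fig1a`/`fig1b`: $\xi = 0.1$, $\eta_1 = 0.8$, $\eta_2 = 0.4$,
$\lambda = 0.1$ vs $0.3$; `fig2`: $\xi = 0.01$, $\lambda = 0.2$,
$N = 50$; `fig3a`/`fig3b`: $\xi = 1$, $\eta_2 = 0.3$, $\eta_1 = 0.7$ vs
$0.5$; `fig4`: $\xi = 1.5$). Group size and success-rate defaults for
the unbound fields are the values each panel varies around.

```{r fig1b}
sw <- run_sweep(builtin_scenarios()$fig1b,
                axis1 = list(name = "N", values = 2:12),
                outputs = c("N_rho_I", "N_rho_T"))
sw[, c("N", "N_rho_T")]
max(sw$N[sw$N_rho_T > 1])
```

With the high tax incentive ($\lambda = 0.3$) the non-R&D strategy's
scaled rooting probability $N\rho_T$ stays above the neutral line 1
only up to $N^{*} = 4$: in small markets tradition can still take over,
in larger ones it cannot. The first-order Taylor form locates the same
integer crossing (largest $N$ with $\gamma + N\delta > 0$;
$36.8/8.8 \approx 4.18$). The surrounding narrative regions sometimes
attached to this curve for $4 \le N \le 6$ and $N > 6$ do not follow
unambiguously from direct evaluation of the printed fixation formulas
under either fitness map, so the package reproduces what the equations
give and anchors on the robust $N^{*} = 4$ crossing.

Sweeps are deterministic (identical spec, identical rows), record
per-point errors in an `error` column instead of dropping grid points,
and export to RFC-4180 CSV with a single comment header carrying the
metadata, so the data rows are byte-stable. `plot_sweep()` draws the
curves with the conventional reference line; the plot is a view over
the CSV-shaped table and contains no computation of its own.

## Problem sizes and runtime

Everything here is desk scale. Exact fixation at $N = 200$ is
instantaneous ($O(N)$ for the recursive form, $O(N^3)$ worst case for
the dense oracle at test sizes $N \le 25$); the test suite's heaviest
pieces are the $21 \times 21$ success-rate grid at $N = 50$ (441 exact
fixations, about a second) and the Monte Carlo validation (20,000
replicates at $N = 8$ plus twenty 5,000-replicate draws, a few
seconds with the jump chain). Those sizes were chosen as comfortable
desk-scale settings that still leave the statistical checks sharp.

## Limitations

* Two strategies, homogeneous firms, well-mixed group: no structure,
  no mutation, no entry/exit, no per-firm parameters.
* The mixed/coexistence outcomes are classified, not located: the
  package does not compute interior quasi-stationary distributions.
* The weak-selection expansion is first order only; at $\xi = 0.1$ it
  is useful but visibly off the exact curve (both are available, so
  compare them).
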