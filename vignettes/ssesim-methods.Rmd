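---
title: "ssesim: model, parameters, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ssesim: model, parameters, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ssesim` is a discrete-time agent-based model of occupational safety in
small-scale enterprises (SSEs). One period represents three months. Three
agent groups interact with a population of profit-seeking firms.

### The firm

Each firm chooses a per-period safety investment $K$. The true safety level
of production responds with saturating returns:

$$ s = \frac{\beta K}{1 + \beta K}, \qquad \beta = 0.33 . $$

Safety levels map to a four-class taxonomy at boundaries 0.8 / 0.7 / 0.6 of
the normalized scale: class 1 (high), class 2 (medium), class 3 (meets the
standard), class 4 (below standard). At the defaults these boundaries
coincide with the government's evaluation thresholds
$T_2 = 0.8 > T_1 = 0.7 > T_0 = 0.6$.

Per-period profit is

$$ F = (1 - t)\,PV - C + \text{transfer}, $$

where $PV = FP \cdot T \cdot \overline{SV} \cdot EN \cdot PS_{\text{eff}}
\cdot \text{scale}$ is the gross production value (product price, months per
period, mean workforce efficiency, headcount, effective demand fraction, and
a productivity calibration factor), and
$C = LC + K \cdot \kappa + PC$ sums the wage bill, the
currency cost of the safety investment ($\kappa$ = `K_cost_scale`), and a
fixed production cost. Firms start with working capital
(`initial_capital`) and exit permanently once their cumulative position has
been negative for `exit_periods = 3` consecutive periods. The population is
conserved as active + exited; there is no market entry.

### Employees

Each of the $EN_0 = 40$ employees perceives the safety level through a
cognitive-bias coefficient $\theta \sim U[0.8, 1.2]$: the perceived OSH level
is $\theta s$. Production efficiency responds linearly:

$$ SV = M \cdot (\theta s) \cdot \eta + \delta
      = 0.22 \cdot \theta s \cdot 0.4 + 0.6 , $$

so efficiency runs from 0.6 (no perceived safety) to about 0.71. An employee
whose perceived OSH level falls below `action_threshold = 0.6` is
dissatisfied and — depending on the scenario — may expose conditions to the
public (probability `expose_prob`), blow the whistle to the regulator
(probability `whistle_prob`), or, in scenario 5, leave or demand a raise.

### The public

Every firm carries a reputation value $SC \in [0, 1]$. When a firm is exposed,
$SC$ drops to the mean perceived OSH level of the exposing employees (never
rising on exposure); with no exposures it recovers additively at
`recovery_rate` per period. Sales respond piecewise: the demand fraction
$PS$ is carried forward unchanged while $SC \ge 0.8$, and is multiplied by
$SC \cdot 0.5 + 0.6$ on $[0.6, 0.8)$ or $SC \cdot 0.167 + 0.8$ below, so a
reputation shock compounds over consecutive disreputable periods. While
reputation is intact, demand recovers additively at `sales_recovery_rate`.

The market has fixed total size: a fraction `demand_redistribution` of the
demand lost by disreputable firms is captured, evenly, by the firms whose
reputation is at or above 0.8, capped at `demand_cap` times normal demand
per firm. This market-clearing step is what makes reputation economically
double-edged — exposure is both a stick (lost sales) and, for clean
competitors, a carrot (captured sales).

### The government

The regulator evaluates a firm with certainty in the period after a whistle,
with probability `expose_eval_prob` after a media exposure, and with
probability `inspection_prob = 0.1` otherwise. An evaluation reads the true
safety level and applies a banded transfer
($-10000$ below 0.6, $0$ on $[0.6, 0.7)$, $+5000$ on $[0.7, 0.8)$,
$+50000$ at or above 0.8) and a safety-graded tax rate
(0.2 / 0.15 / 0.1 / 0.05 across the same bands). The tax persists until the
next evaluation; never-evaluated firms pay `default_tax_rate = 0.15`. A
whistleblowing employee whose report is confirmed (evaluation below 0.6)
receives a reward proportional to their efficiency plus 0.1; the reward is a
government-to-employee payment and does not enter the firm's profit.

### Self-learning

Firms are boundedly rational. Each keeps a probability vector
$(p_d, p_i, p_c)$ over cutting, raising, or keeping the investment,
initialised uniform. After each period the vector shifts by
$\varepsilon$-scaled amounts chosen by the signs of last period's investment
change and profit change: a move followed by a profit increase is reinforced
(its probability gains $\varepsilon$, the other two lose $\varepsilon/2$
each); otherwise it is suppressed symmetrically. Profit changes smaller than
`profit_tol` (1 currency unit) in absolute value count as "no increase".
Components are clipped to $[p_{\text{floor}}, 1 - p_{\text{floor}}]$ and
renormalised, so no strategy is ever extinguished. Step sizes are
class-dependent: well-invested classes cut in larger and add in smaller
relative moves than low classes.

### Event timing

Actions taken in period $t$ reach the system in period $t+1$: exposures move
reputation, sales, and (possibly) the regulator next period; whistles trigger
next period's evaluation. This one-period information lag keeps each period's
computation acyclic. Within a period the order is: classify → perceive →
act → reputation/sales → evaluation → production/profit → turnover →
learning → exit.

### Scenarios

1. silence — employees take no action;
2. public exposure only;
3. whistleblowing only;
4. exposure and whistleblowing;
5. exposure, whistleblowing, and turnover/raise demands. Dissatisfied
   employees of firms that kept investment flat for
   `silent_periods_trigger = 2` periods leave with probability `leave_prob`
   or stay with a `raise_rate` wage raise; vacancies refill with
   class-dependent probability (0.9 / 0.7 / 0.5 / 0.2), so unsafe firms
   struggle to recruit.

## Parameters and units

Currency amounts (transfers, wages, prices, costs) share one nominal unit.
All probabilities are per period (3 months), per firm or per employee as
noted. `default_config()` documents every key; configurations round-trip
through flat YAML (`load_config()` / `write_config()`) and each key can be
overridden on the command line with `--set key=value`.

## Calibration rationale

The behavioural and regulatory constants above are structural. The economic
closure — how much production a unit of efficiency earns and what safety
investment costs — is the package's own calibration, chosen so that the
model's qualitative regularities emerge at the committed defaults:

* `productivity_scale = 24` and `K_cost_scale = 5000` place the unregulated
  profit optimum at a sub-standard safety level: cutting safety is always
  tempting in the short run, but a regulated, reputation-sensitive firm can
  profitably sustain high safety. `PC = 72000` fixes overheads at 20% of the
  initial wage bill.
* `epsilon = 0.15`: the learner must stay responsive. At small step sizes
  firms lock into the cut-investment strategy during the early profitable
  cutting phase and cannot escape the subsequent losses; at 0.15 a sustained
  run of losses homogenises the probability vector quickly enough for firms
  to change course within the horizon.
* `expose_prob = 0.025` per dissatisfied employee-period keeps media
  exposure rare but consequential (with 40 employees, an unsafe firm is
  exposed roughly every couple of periods). Larger values push the exposure
  scenarios into mass bankruptcy.
* `recovery_rate = 0.5` and `sales_recovery_rate = 0.12` let a firm that
  cleans up regain reputation within a period and demand within a couple of
  quarters, so the reputation channel rewards improvement rather than merely
  scarring.
* `demand_redistribution = 0.5` with `demand_cap = 1.25` gives clean firms a
  genuine upside from competitors' disgrace. Without this channel exposure is
  a pure deadweight drain and the exposure scenarios could not be both safer
  *and* more profitable — which they are empirically.
* `leave_prob = 0.3` and `raise_rate = 0.02` make scenario 5's labour
  pressure a smooth, persistent drain (hard-to-replace departures, creeping
  wage costs) that the myopic learner can actually follow, rather than a
  lumpy shock it cannot attribute.
* `initial_capital = 60000` (about one period of moderate losses) and
  `init_s_min = 0.5` start the census solvent and contested: every class is
  populated and no firm is born already bankrupt.

A deliberate property of the learning rule is that it reacts to the *sign*
of profit changes, not their size. Episodic punishments (a fine, a one-off
exposure) land on whatever move the firm happened to make that period and
therefore teach little; persistent gradients (demand share, wage drift,
recurring taxes) teach reliably. The calibration leans on the second kind of
signal wherever an incentive is meant to be learnable.

## Generator realism and validation

The model is a stylised generator, not a fitted one. Its intended outputs are
qualitative regularities, which the test suite checks at the committed
defaults (50 firms, 60 periods, 20 replicates per scenario, fixed seed
ladder):

* under silence, the high-safety class empties out and mean safety decays to
  the bottom of the scenario ranking;
* whistleblowing alone enforces the legal floor but little more — firms
  hover near the penalty threshold;
* exposure outranks whistleblowing on safety through the reputation–sales
  channel;
* the combined scenarios reach the highest safety levels, with turnover
  pressure on top;
* late-horizon profit is lowest in scenarios 1 and 3: under regulation plus
  reputation, safety pays;
* in scenario 1, bankruptcies thin the population while the survivors
  under-invest.

`validate_scenarios()` scores each scenario on the late-horizon (last
quarter of the run) active-population-weighted mean safety level, ranks the
five scores onto the ordinal scale Very low … Very high, and compares the
labels with the stored reference (`survey_reference()`), which also records
survey-item means and standard deviations on a 1–5 agreement scale.
Scenario 5 carries no survey value — departed employees could not be
surveyed — and is marked unverifiable. The stored survey means are
non-monotone in the ordinal labels (scenario 2 "Medium" has a lower item
mean than scenario 3 "Low"); the package records these constants verbatim
and validates against the model-label column only.

```{r}
library(ssesim)
v <- validate_scenarios(default_config())
v$labels
write_reports(v$agreement, "reports/")
```

## Limitations

* The exact trajectories depend on the economic closure; only the ordinal
  scenario comparisons are validated, not currency-level magnitudes.
* The learner is deliberately myopic (one-period lookback, sign-only
  feedback); it does not anticipate evaluations or discount the future.
* No market entry: bankrupt firms are not replaced, so long horizons select
  on survivors.
* Demand redistribution treats the market as a single homogeneous pool with
  even capture by all reputable firms.
* One-period lag structure is fixed; simultaneous-response variants are out
  of scope.

## Problem sizes

The default experiment (5 scenarios × 20 replicates × 50 SSEs × 60 periods
× 40 employees) runs in about 20 seconds on one CPU; a single simulation in
well under a second. Memory stays in the tens of megabytes; all state is
vectorised per period (one numeric vector or matrix slot per firm).
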