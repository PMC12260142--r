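# posdesign

Decision-theoretic probability of success (PoS) and sample size
determination for superiority trials analysed with a one-sided z-test.

## The problem

At the planning stage of a trial the true treatment effect θ is unknown.
The classical power calculation conditions on a single design value θ_d;
the hybrid frequentist–Bayesian approach instead expresses design-stage
uncertainty with a proper *design prior* π(θ) and averages the power
function over it. But "probability of success" is not a single quantity.
For the test of H0: θ ≤ θ0 against H1: θ > θ0, with power function
η_n(θ) = Φ(√n (θ − θ0)/σ − z₁₋α), `posdesign` computes four measures:

- **u (u-PoS)** — the Bayes utility of the test under 0–1 utility, i.e. the
  expected probability of choosing the **true** hypothesis, whichever it is:
  u_n = p₀·u_{n0} + p₁·u_{n1}, where p₀ = P(Θ ≤ θ0), p₁ = 1 − p₀,
  u_{n0} = E[1 − η_n(Θ) | Θ ≤ θ0] and u_{n1} = E[η_n(Θ) | Θ > θ0];
- **e^a** — the joint probability of rejecting H0 *and* Θ lying in the
  alternative: e^a_n = p₁·u_{n1};
- **e^b** — the expected power conditional on the alternative:
  e^b_n = u_{n1};
- **e^c (assurance)** — the marginal probability of rejection:
  e^c_n = p₀(1 − u_{n0}) + p₁·u_{n1}.

Only u and e^b tend to 1 as n → ∞; e^a and e^c tend to p₁, which caps the
feasible thresholds of sample-size criteria built on them. When the design
prior puts non-negligible mass on the null (consensus or bimodal priors),
u-PoS credits correct acceptance of H0 and therefore asks for markedly
smaller trials than the rejection-based measures.

Design priors: point-mass, normal, skew-normal (CDF via an in-house Owen's
T function), truncated-normal and two-component normal mixtures, each
parameterised by a location θ_d and a design-prior sample size n_d (scale
σ/√n_d), plus an optional inverse-gamma prior on σ². In the log-odds-ratio
application σ² = 4, so n counts total events across both arms.

Each measure is evaluated by deterministic adaptive quadrature (the
reference), by Monte Carlo with one common seeded draw set for all four
measures and all sample sizes, or — for assurance under a normal prior —
in closed form: e^c_n = 1 − Φ((θ0 − θ_d + (σ/√n) z₁₋α)/ξ_d) with
ξ_d = σ√(1/n_d + 1/n).

## Worked example

```r
library(posdesign)
tst <- one_sided_test(theta0 = 0, alpha = 0.05, sigma = 2)
pri <- normal_prior(theta_d = 0.198, n_d = 46)  # skeptical effect, moderate confidence
summary(pos(tst, pri, n = 100))
#> Probability of success at n = 100 (quadrature)
#>      u    e_a    e_b    e_c 
#> 0.6002 0.3529 0.4711 0.3566 
#> 
#> Decomposition: p0 = 0.251, p1 = 0.749, u_n0 = 0.9853, u_n1 = 0.4711
```

With 100 events, a trial designed under this prior has a 60% chance of
reaching the correct conclusion (u-PoS), but only a 36% chance of rejecting
H0 (assurance): a quarter of the prior mass sits on the null, where the
correct outcome is acceptance — which assurance counts as failure.
The impact on the required trial size:

```r
pos_ssd(tst, pri, measure = "u", epsilon = 0.8)
#> Sample size for measure 'u' at threshold 0.8 (quadrature)
#>   n* = 441  (measure = 0.8001, limit = 1.0000)
pos_ssd(tst, pri, measure = "b", epsilon = 0.8)
#> Sample size for measure 'b' at threshold 0.8 (quadrature)
#>   n* = 747  (measure = 0.8001, limit = 1.0000)
pos_ssd(tst, normal_prior(0.198, 15), measure = "c", epsilon = 0.8)
#> Sample size for measure 'c' at threshold 0.8 (quadrature)
#>   infeasible: threshold 0.8 >= limiting value 0.6493
```

The u-PoS criterion needs 441 events where conditional expected power needs
747; an assurance threshold of 0.8 is provably unreachable under a prior
with p₁ = 0.65, which `pos_ssd()` reports without searching.

Whole scenario grids (several priors × sample sizes × measures) run from a
JSON config via `run_compute()`, `run_ssd()` and `run_curves()`; see
`inst/extdata/unimodal_scenario.json` for the schema and `inst/cli/upos.R`
for a thin command-line wrapper
(`Rscript inst/cli/upos.R compute --config scenario.json --out table.csv`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the headline quantities of the package's reference design
scenarios from scratch with the installed package — frequentist optimal
sample sizes under point-mass priors, Monte Carlo (M = 10⁶) values of u-PoS
and conditional expected power under normal / truncated / mixture priors,
the exact skew-normal null mass, and the quadrature-based u-PoS optimal
sample size — and writes them as a JSON object keyed by target id.

## Documentation

The methods vignette (`vignettes/pos-measures.Rmd`) describes the model,
the prior family, the numerical schemes and their accuracy, threshold
feasibility, and known limitations, including exactly how fast each measure
approaches its large-sample limit.
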