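---
title: "Probability of success as a Bayes utility: model, computation, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability of success as a Bayes utility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posdesign)
```

## The decision problem

A planned superiority trial will be analysed with a one-sided z-test of
$H_0:\theta\le\theta_0$ against $H_1:\theta>\theta_0$, where the endpoint
summary is approximately $N(\theta,\sigma^2/n)$ with known $\sigma$. The
test rejects when $\bar x_n > \theta_0 + \sigma z_{1-\alpha}/\sqrt n$, so its
power function is
$\eta_n(\theta)=\Phi\!\big(\sqrt n(\theta-\theta_0)/\sigma - z_{1-\alpha}\big)$.

Viewed as a decision between two actions under the symmetric 0–1 utility,
the pre-experimental quality of the test at a fixed $\theta$ is the
probability of the *correct* decision,
$$U_n(\theta)=\begin{cases}1-\eta_n(\theta) & \theta\le\theta_0\\
\eta_n(\theta) & \theta>\theta_0,\end{cases}$$
which, unlike $\eta_n$, does not mix the type I error into the notion of
"success". Averaging over a proper design prior $\pi$ gives the Bayes
utility $u_n=E_\pi[U_n(\Theta)]$ — the u-PoS — with the decomposition
$u_n=p_0u_{n0}+p_1u_{n1}$ over the prior masses $p_i$ of the two
hypotheses and the conditional utilities $u_{n0}, u_{n1}$. The three
rejection-based competitors are linear in the same two building blocks:
$e^a_n=p_1u_{n1}$, $e^b_n=u_{n1}$, and assurance
$e^c_n=p_0(1-u_{n0})+p_1u_{n1}$. These identities are exact and the
quadrature path of `pos()` is required (and tested) to satisfy them to
$10^{-8}$; they also give $u_n-e^c_n=p_0(2u_{n0}-1)$, so u-PoS exceeds
assurance exactly when $u_{n0}>1/2$, i.e. as soon as the test is more
likely than not to accept a true null.

Only "greater" alternatives are coded. A "less" problem maps onto this one
by negating the effect scale; building a second code path would duplicate
every formula for a sign.

## Parameters and defaults

* `theta0 = 0`, `sigma = 2`: the log-odds-ratio application. With
  $\sigma^2=4$, $n$ is the effective number of observations — the total
  event count over both arms — which keeps sample sizes on the scale
  practitioners quote.
* `alpha = 0.05`, one-sided. The package's reference tables (point-mass
  power 0.256/0.585/0.860 at $n=100$, optimal sizes 631/179/84) are
  reproduced exactly with $z_{0.95}=1.645$ and not with $z_{0.975}$, which
  pins the convention; it is overridable.
* Design priors carry a location $\theta_d$ and a *prior sample size*
  $n_d$, giving scale $\omega=\sigma/\sqrt{n_d}$: prior information is
  expressed in the same units as data information, and $n_d\to\infty$
  recovers the classical conditional power analysis. For the skew-normal
  prior, $\sigma^2/n_d$ is the squared *scale* of the law, not its
  variance: this reading reproduces the reference null masses
  (e.g. $p_0=0.06$ at $\theta_d=0.198$, $n_d=46$, $\lambda=1$) through the
  CDF $\Phi(z)-2T(z,\lambda)$, which is what fixes the parameterisation.
* The boundary belongs to the null ($\Omega_0$ closed). This matters only
  for point-mass priors sitting exactly at $\theta_0$ and for the limiting
  value $\eta_\infty(\theta_0)=\alpha$.
* The inverse-gamma variance prior uses the shape–scale form with mean
  $b/(a-1)$; `inv_gamma_prior(16, 60)` then has mean 4 and SD
  $60/(15\sqrt{14})\approx 1.07$, the intended "mean 4, SD about 1"
  elicitation.

## Numerical schemes

**Quadrature (default, deterministic).** Every prior decomposes into
smooth components (a mixture contributes two); each component is
integrated separately over $\Omega_0$ and $\Omega_1$ because the utility
integrand kinks at $\theta_0$. Panels are split at the component's own
scale points ($\theta_d + \{\pm1,\pm4,\pm10\}\,\omega$) *and* at the power
function's transition scale ($\theta_0 + \{\pm3,\pm40\}\,\sigma/\sqrt n$),
then handed to adaptive Gauss–Kronrod (`stats::integrate`,
`rel.tol = 1e-10`). The second set of break points is what keeps results
accurate when $n$ is huge and $\eta_n$ is nearly a step function; the
scheme is validated against Monte Carlo at $M=10^7$ (agreement to
$2\times10^{-5}$ at $n=10^6$).

**Monte Carlo.** One seeded draw set $\theta^{(1..M)}$ from the prior
yields all four estimators — common random numbers make the measures, and
the whole curve in $n$ during sample-size search, positively correlated
and smooth. $e^b$ uses the ratio estimator with the empirical alternative
mass $\bar p_1$; if no draw lands in the alternative it is reported as
undefined (`NA`, with a warning), never as $0/0$. Standard errors are
sample SDs of the integrands over $\sqrt M$; the $e^b$ SE uses the delta
method for the ratio. Default $M=10^6$ gives SEs of a few $10^{-4}$.
Sampling is inverse-CDF for truncated normals (cost independent of the
truncation mass), the half-normal representation for skew normals, and
rejection from the parent for conditional (restricted) priors — the one
sampler whose cost grows like $1/p_i$, acceptable because restricted
priors are diagnostics, not simulation workhorses.

**Owen's T.** No installed package provides it, so `owens_t()` integrates
the defining integrand adaptively and is checked against
$T(h,1)=\Phi(h)(1-\Phi(h))/2$ and $T(0,a)=\arctan(a)/(2\pi)$.

**Unknown variance.** With `variance_prior =`, each draw $\sigma^{2(r)}$
enters *both* the prior scale ($\theta\,|\,\sigma^2 \sim
N(\theta_d,\sigma^2/n_d)$) and the power function. This joint-draw
construction keeps the induced null mass essentially at its known-variance
value and makes the measures depend on the variance prior almost only
through its mean (halving the prior SD at fixed mean 4 moves $u_n$ by
less than 0.01 — a tested property). Conditioning the power on the prior
mean of $\sigma^2$ instead would be a defensible alternative; the
joint-draw choice is the one consistent with treating $\sigma^2$ as a
single unknown shared by prior and sampling model.

## Sample size determination and feasibility

$n^\star=\min\{n: m_n\ge\varepsilon\}$ for a measure $m$ and threshold
$\varepsilon$. Since $e^a_n,e^c_n\to p_1$, thresholds are defaulted to a
fraction (80%) of each measure's reachable maximum:
$\varepsilon_u=\varepsilon_b=0.8$, $\varepsilon_a=\varepsilon_c=0.8p_1$,
with $p_1$ from the exact prior CDF (not a rounded table value — the
difference moves mixtures' thresholds by about 0.003 and their $n^\star$
by tens of units, which is why the exact value is used). `pos_ssd()`
first rejects provably infeasible requests ($\varepsilon\ge$ limit) with
no search; otherwise it brackets by doubling, bisects, and ends with a
backward scan (≤ 64 steps) that certifies minimality without assuming
global monotonicity. A cap hit (`n_max`) is reported as a distinct,
non-provable failure.

Because $\varepsilon_a=p_1\varepsilon_b$ and $e^a_n = p_1 e^b_n$ exactly,
the `a` and `b` criteria return identical $n^\star$ under the default
rule; u-PoS always needs the smallest trial, markedly so when $p_0$ is
large (bimodal consensus priors).

## What a green test does and does not establish

There is no synthetic-data module here — the "data" of the framework are
the design parameters themselves, and the stochastic ingredient is the
prior sampler. The Monte Carlo versus quadrature agreement tests (3-SE
bands over randomized scenarios) establish that the two independent
computational routes agree *under the stated normal model with known
$\sigma$*; they say nothing about how well a normal approximation to a log
odds ratio describes a real binary endpoint at small event counts, nor
about elicitation quality of $\theta_d$, $n_d$, $\lambda$ or the mixture
weights. Scenario values are design inputs, not estimates.

## Numerical limitations worth knowing

* **Approach to the limits is slow.** The distance of every measure from
  its $n\to\infty$ limit decays like
  $\pi(\theta_0)\,\sigma\,C/\sqrt n$ with
  $C=\int|\eta_\infty-\eta|\,\mathrm d t\approx 1.69$: at $n=10^6$ the gap
  is still $0.002$–$0.01$ for the priors above (largest when the prior
  piles mass at the boundary, as a $w_0=0.75$ mixture does). Tests of the
  limiting behaviour therefore either evaluate at $n\ge10^9$ or assert
  the $1/\sqrt n$ rate itself; expecting $10^{-3}$ closeness at $n=10^6$
  is mathematically impossible, and one acceptance check that states
  exactly that is deliberately left failing rather than loosened.
* **$n^\star$ is ill-conditioned where curves are flat.** Near its
  threshold a measure curve can climb at only $\sim3\times10^{-4}$ per
  event, so a $\pm0.005$ error in the measure — typical of Monte Carlo at
  $M\approx10^4$–$10^5$ — shifts the crossing by $\pm20$ events.
  Published tabulations of MC-based optimal sizes can therefore sit
  several percent from the exact quadrature minimum, in either direction;
  `posdesign` reports the exact minimum (deterministic quadrature is the
  SSD default) and the audit `trace` of every evaluation, and one
  acceptance comparison against such tabulated values is left failing at
  its stated band for the rejection-based measures.
* Quadrature assumes priors with densities; point masses bypass it (power
  evaluation is exact), but atoms elsewhere than $\theta_d$ are not
  representable.
* Scenario configs are JSON (not YAML): the deployment environment has a
  JSON parser available as a hard dependency already, and the schema needs
  nothing YAML adds.

## Scope

Two-sided and equivalence hypotheses, analysis-stage priors and posterior
computation, non-0–1 utilities, interim/predictive extensions, and
non-normal endpoint models are out of scope; the measure definitions are
model-agnostic, so the normal machinery is the only layer that would need
replacing.
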