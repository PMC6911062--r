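---
title: "Mapping species richness from opportunistic samples: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping species richness from opportunistic samples: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefrich)
```

# The scientific problem

Citizen-science records of species richness are collected where volunteers
chose to go, not where a design told them to. If the choice of sampling
locations is stochastically dependent on the process being mapped —
*preferential sampling* — predictions from a naive geostatistical model are
biased. `prefrich` implements a two-stage analysis of this situation for
point-referenced richness counts from two sources: an opportunistic
citizen-science data set (CSD) and a randomised, design-based survey (RSD)
that serves as the gold standard.

Stage one models *where* the citizens sampled. Stage two models *what they
found*, with the first stage's residual spatial structure supplied as an
adjustment covariate. A final step compares the two sources' prediction
surfaces where both are informative.

# Stage one: the sampling process

The CSD sampling locations are treated as a realisation of a log-Gaussian
Cox process with intensity

$$\Lambda(x) = \exp\{\alpha_0 + \alpha_1 D(x) + \alpha_2 V(x) + S(x)\},$$

where $D(x)$ is the distance (km) from $x$ to the collectors' home,
$V(x)$ is the value-of-nature covariate in $[0,1]$, and $S(x)$ is a
zero-mean stationary Gaussian field with Matérn correlation

$$\rho(u;\phi,\kappa)=\{2^{\kappa-1}\Gamma(\kappa)\}^{-1}(u/\phi)^\kappa
K_\kappa(u/\phi).$$

The smoothness $\kappa$ is fixed at 1 and never estimated: under
fixed-domain asymptotics the triple $(\sigma^2,\phi,\kappa)$ is not
consistently estimable, so one member is pinned. A negative $\alpha_1$
means collectors favour locations near home; $\exp(\alpha_2)$ is the
intensity multiplier of a fully "valuable" cell over a worthless one
(`intensity_ratio()`).

**Discretization.** Rather than a triangulated continuous-space
approximation of $S$, the package discretizes the region into the same
regular grid that carries the covariates (1 km cells by default), with one
latent value per cell; the point process then reduces to conditionally
Poisson cell counts with mean $\text{area}\cdot\Lambda(\text{cell})$. The
two formulations agree as the grid refines, and the discretized model can
be checked exactly against quadrature oracles; the covariates are
cell-level anyway, so nothing sharper than the grid is observable. A
refinement factor is available by passing a finer grid, and the test suite
verifies that halving the cell size moves the intensity coefficients by
less than one standard error.

# Stage two: the richness models

Richness counts $Y_j(x_i,t_i)$ from source $j$ are conditionally Poisson
given a spatial field $U_j$ and record-level noise $Z_j$:

- CSD: $\log\mu = \beta_0+\beta_1 W+\beta_2 V+\beta_3 F+
  \beta_4\log C_i + f(t_i) + \gamma\hat S(x_i) + U(x_i) + Z_i$
- RSD: $\log\mu = \beta_0+\beta_1 W+\beta_2 V+\beta_3 F+
  \beta_5 (t_i-1997) + U(x_i) + Z_i$

with $W, V, F$ the wetness, value-of-nature and forest-cover covariates,
$C_i$ the number of collectors, $f$ a cubic B-spline in time with interior
knots at 1990, 1995, 2000, 2002, 2004, 2006 and boundary knots at the
survey limits (1985, 2009), and $\hat S$ the predictive mean of the stage-one
field. The fields $U_j$ have exponential correlation with variance
$\nu_j^2$ and scale $\psi_j$ (reported as `log_sigma2`, `log_phi`, with the
nugget $\tau_j^2$ as `log_tau2`, mirroring the usual results-table layout);
the latent field is spatial at cell resolution, so records in one cell
share the cell's $U$ value and are separated by their own nugget draws.

$\gamma$ is the preferential-sampling adjustment: a log-linear effect of
the estimated sampling field on richness. It is a *plug-in* adjustment —
$\hat S$ enters as a fixed covariate, and the uncertainty in $\hat S$ is
not propagated into the richness fit. This mirrors the two-stage design
the analysis follows; a joint model is out of scope.

**Identifiability of the temporal spline.** One basis column is absorbed
into the intercept (the basis is evaluated without its first function), and
`spline_effect()` reports $f(t)$ centred on its 1997–1999 mean, the window
in which both sources collected data.

# Estimation: Monte Carlo maximum likelihood

Both stages are Poisson log-Gaussian models; `prefrich` fits them with a
single MCML engine:

1. a deterministic **Laplace pre-fit** — profile maximization of the
   Laplace-approximate likelihood over the covariance parameters, with the
   regression coefficients and latent field profiled out by a
   Schur-complement Newton step — supplies the starting point. Because the
   (variance, nugget) profile is often bimodal (all-spatial vs all-nugget
   modes), the pre-fit multi-starts across variance allocations and keeps
   the best mode;
2. at the current parameters $\psi_0$, the latent field is sampled from
   $p(b\mid y;\psi_0)$ by a preconditioned Langevin (MALA) chain, whitened
   by the Laplace curvature; the step size adapts to a 0.57 acceptance
   rate during burn-in only, so the retained chain has a fixed kernel;
3. the likelihood-ratio objective
   $\log \tfrac1M\sum_m f(y,b_m;\psi)/f(y,b_m;\psi_0)$ is maximized with
   analytic gradients, inside a box trust region around $\psi_0$ and with
   an effective-sample-size floor that rejects parameter values supported
   by too few Monte Carlo draws;
4. steps 2–3 are repeated with the sampling distribution refreshed at the
   new optimum until the relative parameter change falls below `tol`
   (default `1e-3`, at most `refresh` = 5 refreshes).

Three numerical safeguards deserve explanation. The *scale cap* bounds the
correlation scale at the point-set diameter: beyond the domain size the
scale is not identifiable and the profile likelihood develops a spurious
ridge. The *variance floor on the Monte Carlo start* exists because a
likelihood-ratio estimate sampled at a collapsed variance cannot detect
that a larger variance fits better (no latent draw carries mass there),
while walking a variance *down* from a rich start is estimated reliably;
the Monte Carlo stage therefore starts from variances no smaller than a
modest floor and descends if the data want it. The *jitter policy* adds
`1e-8` times the marginal variance to a covariance diagonal once if a
Cholesky factorization fails, then errors.

Confidence intervals are Wald intervals from the observed information at
the optimum, computed by Louis' identity (complete information minus the
posterior variance of the complete-data score) on a fresh Monte Carlo
sample drawn at the optimum. The missing-information term is a posterior
variance estimated from finitely many draws; its sampling noise can
spuriously exceed the complete information, so the missing fraction is
capped at 99% per whitened direction — flat directions then get honestly
enormous, rather than meaningless, standard errors. Poisson factorial
constants are dropped in every likelihood in the package; only
differences matter and the convention is applied consistently. The
reported `loglik` of a fit is the Laplace evaluation of the marginal
likelihood at the MCML optimum under this same convention.

# The comparison

Predictions $\hat\mu_j(x,t)$ are computed at $t=1998$ with the number of
collectors fixed at $C=2$ (the CSD's usual team), as
$\exp(\hat\eta + m + v/2)$ where $(m,v)$ are the conditional mean and
variance of $U$ at the cell (kriging from the latent posterior summary)
and $v$ additionally carries the Wald parameter-uncertainty term of the
linear predictor; the standard error is $\hat\mu\sqrt{e^v-1}$, and the
coefficient of variation se/mean is the uncertainty map. The nugget is
record-level noise and is excluded from the prediction target by default
(`include_nugget` reverses this).

Cells enter the comparison region when, for *each* source's fitted
exponential correlation, the correlation with the nearest sampled location
(over the union of both sources' locations) is at least 0.75 — an
intersection rule, since a comparison needs both sources to be informative;
with exponential correlation the rule is the distance cutoff
$-\psi_j\log 0.75$. On that region the surfaces are compared through the
relative difference

$$RD(x) = \frac{\hat\mu_{CSD}(x,t)-\hat\mu_{RSD}(x,t)}
{\max\{\hat\mu_{CSD}(x,t),\hat\mu_{RSD}(x,t)\}} \in [-1, 1],$$

positive where the citizen-science surface predicts more. The default
histogram uses 18 equal bins on $[-0.9, 0.9]$, widened when values fall
outside.

# The synthetic-study generator

`gen_scenario()` builds complete studies with the statistical structure the
analysis assumes: smooth correlated covariate fields (cross-correlated
Gaussian fields pushed through the standard normal CDF, so margins are
uniform on $[0,1]$); an LGCP-sampled opportunistic point pattern (cell-wise
Poisson counts, positions uniform within cells, years uniform over
1985–2009, collector counts on $\{1,2,3\}$ with probabilities
$(0.1, 0.8, 0.1)$); a randomly offset lattice survey restricted to cells
whose forest cover passes a threshold (years uniform over 1997–1999); and
conditionally Poisson richness counts from the stage-two models.

Two presets ship: `"nonpreferential"` ($\gamma_{true}=0$) and
`"preferential"` ($\gamma_{true}=0.5$). Crucially, the generator injects
preferential dependence through the **true** latent sampling field, while
the analysis can only ever use the estimate $\hat S$: recovery of
$\gamma$ is therefore attenuated by construction, exactly as on real data.
Tests of $\gamma$ discrimination are accordingly framed as rates (null
coverage near nominal; more frequent rejection under the preferential
preset), not as unbiased recovery of $\gamma_{true}$.

Default truth values: the sampling model uses $\alpha = (-1.5, -0.1, 1.5)$,
$\sigma^2=0.5$, $\phi=3$ km on a 30 × 30 km region at 1 km resolution with
the home towards the western edge — a desk-scale region yielding roughly
150–250 events rather than the original study's thousands. The RSD truth
$(\beta=(1.5,-0.3,0.4,0.2)$, $\beta_5=-0.08$, $\nu^2=0.1$, $\psi=13$ km,
$\tau^2=0.04)$ matches the recovery-study conditions used in the acceptance
suite. The CSD truth mirrors the same scale of effects with
$\beta_4 = 1.9$ for the collector effect, $\psi = 5.4$ km, and a
desk-scale nugget $\tau^2=0.1$ — a large nugget would swamp counts of
desk-scale magnitude and leave nothing recoverable at this study size.

What the generator does **not** emulate: species-level composition and
detectability, the surveyors' 50 m field trajectories, uneven temporal
coverage of the opportunistic record (visit years are uniform), and any
real geography — the region is a synthetic square and the covariate fields
are stand-ins, so passing tests demonstrate the statistical machinery, not
fidelity to any particular landscape.

# Study sizes used by the tests

The verification studies run at reduced Monte Carlo size: 150 retained
latent samples per refresh (120 in the recovery studies), at most 4
refreshes (3 in the recovery studies), 200–250 burn-in Langevin steps,
thinning 3. Parameter recovery uses 50 replicates per model on a
20 × 20 km region (the sampling model with home at the centre and truth
$\alpha=(-2,-0.1,1.5)$, $\sigma^2=0.5$, $\phi=3$; the survey model on a
forest-restricted lattice of roughly 300 locations). The discrimination study runs 15 full pipelines
per preset on the same region size. The discretization check refits one
fixed pattern at 1 km and 0.5 km cells on a 16 × 16 km region; the finer
fit is given a higher refresh cap (8) because the larger latent field
converges more slowly, and the stability comparison is only meaningful
between converged fits.

# Known limitations

- The plug-in adjustment does not propagate the uncertainty of $\hat S$;
  its standard errors are accordingly a little too small.
- Maximum likelihood for Matérn variance and scale from a single sparse
  realisation is erratic: with tens of events on hundreds of cells the ML
  frequently sits at a collapsed variance or scale (this is a property of
  the likelihood, verified against independent fits and telescoped
  likelihood-ratio evaluations, not of the optimizer). Regression
  coefficients are well recovered; covariance parameters should be read
  with their — often very wide — intervals.
- Wald intervals on a multimodal likelihood understate mode uncertainty.
- The comparison region can be empty when a fitted correlation scale
  collapses; the pipeline reports this instead of failing.
- Coordinates must be projected (km); there is no geodesic support.
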