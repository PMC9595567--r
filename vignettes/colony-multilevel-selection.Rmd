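---
title: "Emergent colonies and multilevel selection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent colonies and multilevel selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altcolony)
```

## The model

`altcolony` simulates a population of motile, asexually reproducing
individuals on a periodic 1D or 2D habitat.  Each individual carries one
heritable quantitative trait $\phi$, its investment in altruism.  Individuals
do three things: they die at a constant rate $d$, they diffuse with motility
constant $k_D$, and they reproduce at a density- and neighbourhood-dependent
rate

$$ g_i \;=\; \max\!\Big[\, g_0\Big(1 - c\,\phi_i +
   \frac{b_{\max} A(x_i)}{b_{\max}/b_0 + A(x_i)}\Big)
   \Big(1 - \frac{D(x_i)}{K}\Big),\; 0 \Big], $$

where $D(y) = \sum_i G_{rc}(x_i - y)$ is a Gaussian kernel density estimate of
the local population density (bandwidth $\sigma_{rc}$, the *scale of
competition*) and $A(y) = \sum_i \phi_{E,i}\, G_a(x_i - y)$ is the
trait-weighted analogue (bandwidth $\sigma_a$, the *scale of altruism*),
interpretable as the concentration of a locally secreted public good.  The
benefit saturates at $b_{\max}$; competition suppresses reproduction as the
local density approaches the carrying factor $K$.  Units are reduced so that
$d = 1$ (time is measured in generations), $\sigma_a = 1$ (unit of length),
and $c = 1$ (unit of trait).  The third emergent scale is the *scale of
motility* $\sigma_m = \sqrt{2 k_D / d}$, the RMS distance moved per
generation.

Offspring appear at the parent's position and inherit $\phi$, except that
with probability $\mu$ a kick with exponentially distributed magnitude (mean
$m$) and random sign is added.  Two dialects handle negative traits:
`trait_mode = "truncate"` (the 2D convention) floors mutations at 0, which
introduces a mutational bias near $\phi = 0$; `trait_mode = "effective"` (the
1D convention) lets $\phi$ go negative but uses
$\phi_E = \max(\phi, 0)$ for all *behaviour* — both the public-good
contribution and the cost term.  Whether the cost uses $\phi$ or $\phi_E$ is
not fully determined by the model description; we use $\phi_E$ because the
cost is part of the altruistic behaviour, and a negative-trait individual
behaves exactly like a defector.

### Discretization

Space is a grid of spacing $\delta x$ with periodic boundaries; positions are
integer cell indices.  Kernels are sampled at cell centres, wrapped over
periodic images, and renormalized to unit mass ($\sum_j k_j\,\delta x^{\dim}
= 1$), which makes the discrete $D$ directly comparable to $K$ and conserves
mass exactly; both convolutions per step are computed with one forward and
one inverse FFT (the two real fields ride in the real and imaginary parts of
a single complex transform).  Time advances in steps $\delta t$ with the
sequence: (1) compute $D$, $A$, and all rates from the pre-step state;
(2) each individual reproduces with probability $g_i\,\delta t$; (3) every
individual — newborns included — dies with probability $d\,\delta t$;
(4) survivors are displaced per dimension by an exact draw from the rounded
normal with standard deviation $\sqrt{2 k_D \delta t}/\delta x$ cells.
Exposing newborns to the same step's death draw makes the conditional
expectation of the number of surviving same-step descendants of a parent
(itself included) exactly $(1 + g\,\delta t)(1 - d\,\delta t)$, which is the
quantity the selection accounting uses; the choice is switchable
(`newborn_death`).

Default parameters (selected by `dim` in `sim_params()`): $g_0 = 5$,
$\sigma_{rc} = 4$; in 1D $K = 100$, $k_D = 0.03$, $b_0 = 0.5$,
$b_{\max} = 2$, $\mu = 5\times10^{-4}$, $L = 819.2$, $\delta x = 1/80$;
in 2D $K = 40$, $k_D = 0.04$, $b_0 = 1$, $b_{\max} = 5$,
$\mu = 10^{-3}$, $L = 102.4$, $\delta x = 0.1$; both use $m = 5\times10^{-3}$
and $\delta t = 0.08$.  The initial condition places
$(1 - d/g_0)\,K\,L^{\dim}$ defectors uniformly at random — the homogeneous
steady state of a defector population.

## Evolutionary force accounting

For every step the change in the population mean trait is decomposed exactly
(`decompose_step()`, accumulated by the engine):

* **selection** $= \mathrm{Cov}_i(\phi_i, v_i)$ with
  $v_i = E[W_i]/\langle E[W]\rangle$ the *conditional* expected relative
  fitness given the current local fields.  Conditioning on $D$ and $A$ means
  that only the inherent randomness of the reproduction and death draws is
  booked as drift; the stochastic history that produced the neighbourhood is
  part of the environment and its covariance with the trait counts as
  selection.
* **drift** $= \mathrm{Cov}_i(\phi_i, w_i) - \text{selection}$, with
  $w_i = W_i/\bar W$ the realized relative fitness.  Defining drift as the
  residual absorbs the normalizer mismatch between $\bar W$ and
  $\langle E[W]\rangle$, so the three components sum to the realized
  $\Delta\bar\phi$ to machine precision at every step.
* **bias** $= E_i[w_i(\bar\phi_{\mathrm{desc},i} - \phi_i)]$, the
  fitness-weighted parent-offspring trait change; nonzero only through
  mutation, and systematically positive in truncate mode near $\phi = 0$.

In `"effective"` mode the decomposition is applied to the raw trait $\phi$
(whose transmission is unbiased), while plots and summaries report
$\bar\phi_E$; at evolved trait levels negative $\phi$ is rare and the two
means coincide.

A caution on scale: the per-step selection differential in a colony-patterned
population fluctuates strongly (order $10^{-5}$ per step at $N \sim 10^4$)
around a tiny mean, so the cumulative selection curve of a *reduced-size* run
performs a visible random walk (standard deviation $\sim10^{-2}$ over
$2.5\times10^5$ steps).  Statements about its sign are robust at the full 2D
population size ($N \approx 3.4\times10^5$) but noisy at desk scale; the test
suite treats them accordingly.

## Colony recognition and lineage tracking (1D)

Colonies are detected on the smoothed density $\rho$ (KDE with bandwidth
$\sigma_a/2$):

1. find strict local minima of $\rho$ (plateau ties produce none);
2. discard minima with $\rho \ge T_{\mathrm{high}}$ (default $0.7K$);
3. place a *tentative* border on the half-integer position next to each
   remaining minimum, on the downhill side of the central-difference
   derivative (ties: after the minimum) — borders fall between grid points so
   no individual sits on one;
4. assign each tentative colony the ancestor colony containing the plurality
   of its members' interval ancestors (ties: larger ancestral colony, then
   lower index), using individual IDs tagged at the previous interval
   boundary and inherited by descendants;
5. reject a tentative border whose two flanks share an ancestor unless the
   minimum is deeper than $T_{\mathrm{low}}$ (default $0.2K$) — the
   hysteresis that suppresses fission/fusion chatter while a division or
   collapse is in progress;
6. tabulate each ancestral colony's fitness $V$ = number of offspring
   colonies ($0$: extinct, $1$: survived, $\ge 2$: fission).

Partitions are computed at interval boundaries only (default 80 generations
= 1000 steps, the cadence of the whole interval analysis).  The first
boundary, where no ancestry exists, accepts every border below
$T_{\mathrm{high}}$.  A segment that contains no individuals is merged into a
neighbour by discarding its shallower border.  One geometric caveat: on a
ring, colony boundaries come in pairs, so detection presumes the smoothed
density is strictly positive everywhere; with double-precision Gaussians this
holds whenever gaps are shorter than $\approx 38$ kernel standard deviations,
which is always the case in simulation output (inter-colony spacing
$\approx 2\sigma_{rc}$) though not for artificially distant point clusters.

## Multilevel selection decompositions

For each interval $(t_1, t_2]$, individual fitness $W_i$ is the descendant
count from the lineage tags and $w_i = W_i/\bar W$.

**MLS 1** (`mls1_decompose()`) splits $S = \mathrm{Cov}_i(\phi_i, w_i)$ by
the law of total covariance into $S_{\mathrm{within}}$ (size-weighted mean of
within-colony covariances) and $S_{\mathrm{among}}$ (size-weighted covariance
of colony mean trait $\Phi_j$ and colony mean relative fitness); both sides
are computed independently and agree to $10^{-12}$.

**MLS 2** (`mls2_decompose()`) applies the Price equation to the population
of colonies: with colony fitness $V_j$ and $\bar V$ its mean,
$S_{\mathrm{col}} = \mathrm{Cov}_j(\Phi_j, V_j)/\bar V$ and the transmission
term $T_{\mathrm{col}} = \frac{1}{N_c \bar V}\sum_j V_j
(\bar\Phi_{\mathrm{off}(j)} - \Phi_j)$ sum to the change in the unweighted
colony-mean trait.  $\Phi_j$ uses raw $\phi$ (the distinction from $\phi_E$
is immaterial at evolved trait levels).  `split_colony_selection()` further
writes $V_j = \mathbf{1}\{V_j \ge 1\} + (V_j - \mathbf{1}\{V_j \ge 1\})$, so
colony selection splits linearly into a death (survival-indicator) and a
birth (extra-fission) component — the canonical linear split, chosen because
it is exact by the linearity of the covariance and keeps both components on
the same scale as $S_{\mathrm{col}}$.

Confidence intervals for interval means use block averaging
(`block_sem()`): block lengths double until the SEM estimate stabilizes
(relative change $< 10\%$), and the 95% CI is the mean $\pm 2$ SEM — the
standard remedy for autocorrelated series.

### Steady state versus bootstrap at reduced scale

The negative-within / positive-among (MLS 1) and positive-selection /
negative-transmission (MLS 2) sign structure is a *steady-state* property.
A quarter-size habitat ($L = 204.8$, $\approx 20$ colonies) started from
all defectors is still mid-bootstrap after 20 000 generations
($\bar\phi_E \approx 0.02$ and rising), and with so few colonies many
80-generation intervals contain no colony birth or death at all, making
$S_{\mathrm{col}}$ exactly zero there.  The test suite therefore checks the
steady-state sign structure on a run initialized at $\phi = 0.05$ (the
reference trait level of all fixed-trait analyses) with mutation enabled,
which reaches mutation–selection quasi-balance within a few thousand
generations; the all-defector bootstrap runs are kept for the
emergence-of-altruism check itself.

## Inclusive-fitness (partial regression) analysis

`neighbor_weighted_trait()` computes
$\phi_i' = \sum_{j \ne i} \phi_{E,j} G_a(x_i - x_j)$ — the public good at
$x_i$ minus the individual's own contribution.  `queller_partition()` fits
$w = \alpha + \beta_d \phi + \beta_i \phi'$ by least squares, giving
$S_{\mathrm{direct}} = \beta_d\,\mathrm{Var}(\phi)$,
$S_{\mathrm{indirect}} = \beta_i\,\mathrm{Cov}(\phi', \phi)$ (their sum is
$\mathrm{Cov}(\phi, w)$ by the normal equations), cost $c_H = -\beta_d$,
benefit $b_H = \beta_i$, and relatedness
$R = \mathrm{Cov}(\phi, \phi')/\mathrm{Var}(\phi)$, which is a regression
slope and may legitimately exceed 1.  Because realized single-step fitness is
nearly degenerate, the per-step analysis uses the conditional expected
relative fitness by default (`fitness = "expected"`, switchable to realized
interval fitness).

## Linear stability analysis

For a homogeneous population at fixed trait $\phi$ the mean-field density
dynamics admit an equilibrium $\rho_0$ (found by bracketed root finding on
$(0, K)$; the largest root is the relevant branch, and $\rho_0$ is
independent of $k_D$).  A sinusoidal perturbation of wavelength $\lambda$
grows at rate

$$ E(\lambda) = \underbrace{\frac{g_0 (b_{\max}^2/b_0)\,\phi \rho_0
   (1-\rho_0/K)}{(b_{\max}/b_0 + \phi\rho_0)^2}
   e^{-2(\pi\sigma_a/\lambda)^2}}_{\text{altruism}}
   - \underbrace{2 d (\pi\sigma_m/\lambda)^2}_{\text{motility}}
   - \underbrace{\frac{d\rho_0/K}{1-\rho_0/K}
   e^{-2(\pi\sigma_{rc}/\lambda)^2}}_{\text{competition}}. $$

Colonies are predicted where $\max_\lambda E > 0$; the maximizer
$\lambda^\*$ predicts the colony spacing (typically somewhat below
$2\sigma_{rc}$).  `dominant_wavelength()` maximizes $E$ by multi-start local
optimization on a log-spaced seed grid capped at $L/2$;
`phase_scan()` sweeps $(\sigma_{rc}, \sigma_m)$.  As an independent check,
`mean_field_growth_rate()` integrates the nonlocal mean-field PDE itself
(spectral convolutions, explicit Euler at $\delta t_{\mathrm{int}} =
5\times10^{-4}$, domain of 8 wavelengths at 128 cells each) from
$\rho_0 + 10^{-6}\rho_0 \sin(2\pi x/\lambda)$ and measures the modal growth
rate; it matches the closed form to well under 1%.

```{r lsa-example}
p <- sim_params(dim = 1)
dominant_wavelength(0.05, p)[c("rho0", "E_star", "lambda_star", "unstable")]
```

## Spatial statistics

`rdf_1d()`/`rdf_2d()` compute pair-correlation functions from the circular
autocorrelation of the occupancy grid, normalized by the uniform-random
expectation ($E(r) = n^2/X$ per offset in 1D; $F(r)\,n^2/X^2$ in 2D, where
the multiplicity $F(r)$ counts the integer representations of $r^2$ —
e.g. $F(5\delta x)/F(6\delta x) = 12/4 = 3$).  Self-pairs are excluded;
ordered pairs are used consistently in both numerator and expectation.
`density_variance()` (spatial variance of the $\sigma_a/2$ KDE) is the
colony-formation proxy, and `dominant_mode()` extracts the pattern
wavelength from the KDE's Fourier spectrum.  For the 2D hexagonal pattern,
`lattice_constant_from_count()` inverts the triangular-lattice node density
$\nu/L^2 = 2/(\sqrt{3} a^2)$; note the factor 2 (two triangles per node),
which is required for internal consistency of a count of 179 colonies in a
habitat of side 102.4 with a lattice constant near 8.2.

## What the synthetic fixtures do and do not show

`make_fixture()` builds deterministic point configurations (clusters,
engineered fissions, extinctions, shallow dips, a ten-individual scripted
lineage) on a small ring, and `make_oscillating_trace()` scripts a
border whose gap density oscillates across the hysteresis band.  These pin
down the bookkeeping — partitions, plurality ancestry, hysteresis, the
covariance identities — with hand-checkable numbers.  They do not emulate
demographic noise, mutation pressure, or pattern formation; those properties
are exercised by the simulation-based tests (colony formation at fixed
$\phi$, wavelength against the linear prediction, sign structure at
quasi-steady state, evolutionary bootstrapping across seeds).  Test problem
sizes are scaled down (quarter-length habitats, $2\times10^4$ generations,
a $5\times5$ phase grid), so stochastic outcomes are checked as qualitative
or majority properties, not as the reported headline statistics of
full-scale runs.

## Numerical choices and limitations

* Covariances use population ($1/N$) normalization throughout; the exact
  additivity identities require it.
* Kernel renormalization makes mass conservation exact; whether the original
  discrete kernels were renormalized is not stated, and the difference is
  below $10^{-10}$ at the default $\delta x$.
* Reproduction probabilities are asserted at run time
  ($g_i \delta t \le 1$); parameter validation rejects configurations where
  the *basal* rate already violates this.
* Determinism holds within this implementation (one seeded generator, fixed
  draw order: per individual reproduction then mutation, then deaths, then
  displacements), not across implementations.
* 2D colony segmentation and tracking are out of scope (the 2D pattern is
  analyzed through its radial distribution function and colony counts), as
  are off-lattice positions and non-Gaussian kernels.
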