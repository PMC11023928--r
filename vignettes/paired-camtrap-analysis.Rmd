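---
title: "Paired camera-trap analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired camera-trap analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrappair)
```

## The problem

Selective logging concessions cover a large share of the world's tropical
forests, and the main pathway by which logging depletes wildlife is not the
felling itself but the hunting that logging roads and settlements enable.
Forest-management certification (such as the Forest Stewardship Council,
FSC, scheme) requires concession holders to control hunting; whether that
requirement translates into more wildlife is an empirical question with a
difficult design: concessions differ in terrain, remoteness and history, so
a credible comparison needs certified and non-certified concessions matched
in space and surveyed simultaneously.

`camtrappair` implements the analysis for exactly that design: a set of
*concession pairs*, each pair combining one certified and one nearby
non-certified concession, surveyed with systematic camera-trap grids
deployed at the same time. The package takes photo-level annotation tables
and turns them into effort-corrected encounter rates and a formal estimate
of the certification effect, with the pair structure carried through every
inferential step. A synthetic-data generator reproduces the hierarchical
structure of such surveys so the full pipeline can be exercised and
validated without any field data.

## From photos to independent detections

Camera traps photograph whatever passes; a single animal lingering in front
of a camera produces dozens of photos that are one biological observation.
The standard remedy is a temporal independence threshold. Photos of the
same species at the same camera are chained into one *detection event*
while consecutive photos are less than `threshold_minutes` (default 10)
apart; a gap of at least the threshold starts a new event. Two conventions
matter and are both explicit options:

* **Anchor.** `build_events()` measures gaps photo-to-photo
  (`anchor = "last_photo"`), the camera-trap community norm; it makes the
  rule order-independent and equivalent to single-linkage clustering of
  the photo stream. The alternative (`"event_start"`) caps each event at
  one threshold window.
* **Boundary.** A gap of *exactly* the threshold separates events
  ("at least 10 minutes apart" means independent).

The event's *group size* is the maximum per-photo individual count among
its members — the largest number of animals seen together — not the sum,
which would double-count individuals re-triggering the camera.

The threshold itself is checked, not assumed: `sensitivity_table()`
recomputes event counts at 10, 30, 60 and 1440 minutes and tabulates their
distribution across body-mass classes, the conventional demonstration that
the choice does not redistribute detections among the groups being
compared.

## Sampling effort

Effort is active camera-days. Each camera is scheduled to take a status
photo every 12 h precisely so that a camera that dies mid-deployment can be
dated: the active window ends at the earlier of the scheduled retrieval
and the last photo plus one status interval. Reported downtime (vegetation
obstructing the lens) is subtracted afterwards. Effort is kept in
fractional days; rounding to whole camera-days happens only in display.
Cameras with a deployment record but no photos at all contribute zero
effort and are excluded from rate computations with a warning.

## Encounter rates and aggregation

The encounter rate of a species set $S$ in a sampling unit with effort $E$
camera-days is

$$ r_S = \frac{\sum_{e \in S} g_e}{E}, $$

the sum of event group sizes per camera-trap day ("observations per
camera-trap day"). Rates are additive over disjoint species sets, which the
tests exploit: the class rate equals the sum of its member species' rates.

Aggregations follow fixed conventions, all configurable but chosen to
match standard practice in the source design:

* **Body-mass classes** use half-open intervals $(\ell, u]$ with default
  edges $\{1, 10, 30, 100\}$ kg, giving five classes whose upper three are
  the conventional 10–30, 30–100 and >100 kg groupings. The two lower
  edges are not fixed by convention; 1 and 10 kg were chosen so that the
  named upper classes come out exactly and the remaining species split
  into a rodent-sized and a small-ungulate-sized class.
* **Taxonomic groups**: elephants, primates, even-toed ungulates,
  carnivores, pangolins, rodents. Shrews are carried as rodents in the
  trait table (they are not distinguishable from mice on camera and are
  functionally similar); hyraxes and aardvarks carry taxon `other` and are
  excluded from the taxon-level analysis only, for low sample size — they
  remain in the pooled, mass-class and IUCN analyses.
* **Unidentifiable records** (`"indet"`) are excluded from *all* rate
  computations, including the pooled all-mammal rate. They cannot be
  assigned a mass, category or taxon, and using them only in the pooled
  analysis would make the pooled rate incommensurable with the sum of the
  grouped ones. This is a genuine choice (`keep_indet = TRUE` reverses
  it) and is logged in the ingest disposition counts.

The *biomass index* of a concession is $\sum_s r_s m_s$ with $m_s$ the
species' mean adult body mass (kg) — kilograms observed per camera-trap
day. A verbal definition of this index that divides by effort a second
time is circulating in the literature; read literally it double-counts
effort, since the rate already contains the division. The package
implements $\sum_s r_s m_s$ (the reading consistent with "derived from
encounter rates") and offers the literal reading behind
`biomass_proxy(..., literal = TRUE)`. Either way the index is relative: it
says nothing about absolute biomass.

## The mixed model

Camera-level rates are modelled as

$$ y_{pjc} = \beta_0 + \beta_1 \,\mathrm{FSC}_{j}
   + u_p + u_{j(p)} + u_{c(j)} + \varepsilon_{pjc}, $$

with random intercepts for pair $p$, concession $j$ within pair and camera
$c$ within concession — the nesting of the survey design. For grouped
analyses the fixed part becomes `status * group`, letting the
certification effect differ among body-mass classes, IUCN categories or
taxa. Fits use REML (`lme4`); every model is also refit by maximum
likelihood because BIC comparisons of fixed-effect structures are only
valid on ML likelihoods. `BIC = -2\,\ell_{ML} + k \log n` with $n$ the
number of camera-level observations; both conventions (ML likelihood,
observation-level $n$) are stated here because neither is universal.

Implementation notes:

* A random term with fewer than two levels, or with as many levels as
  observations (one row per camera makes the camera term
  indistinguishable from the residual), is dropped with a message rather
  than being allowed to corrupt the fit.
* Singular fits — a variance component estimated at zero — are flagged,
  not fatal; at the boundary the fixed effects coincide with OLS, which
  the tests verify to $10^{-8}$.
* Aliased fixed-effect columns are a hard error naming the columns, before
  `lme4` can silently drop them.
* **Response scale.** The default is the identity (the model describes
  rates, and the headline figure of such analyses draws the fitted effect
  on the rate scale). `log1p` is available as a first-class alternative
  for heavy-tailed communities; reports name the transformation used.
* **Degrees of freedom.** Certification is a concession-level treatment
  in a paired design, so contrasts use containment degrees of freedom,
  $n_\text{pairs} - 1$. This is deliberately conservative relative to
  camera-level df and makes the pair-only degenerate model reproduce the
  classical paired t-test exactly, which the tests assert.

### Covariate selection

Geographic covariates (elevation, distances to roads, rivers, settlements,
protected areas) are z-scored and searched by BIC: exhaustively over
subsets of up to two covariates, each entering linearly or with an added
quadratic term, then forward beyond two while BIC improves, ties broken
toward fewer parameters. The selected model's contrasts are reported with
covariates held at their mean.

### Multiplicity

Group-wise certification contrasts are correlated (they share variance
components and the interaction structure), so Bonferroni is
unnecessarily blunt. `mvt_adjust()` computes each contrast's adjusted
p-value as $P(\max_j |T_j| \ge |t_i|)$ under the joint $m$-dimensional t
distribution with the contrasts' estimated correlation matrix, evaluated
by the seeded Genz–Bretz quasi-Monte-Carlo algorithm (default
$10^5$ evaluations; the Monte-Carlo standard error is attached to the
result). Two exact bounds — never below the raw p, never above the
Bonferroni envelope $\min(1, m\,p_\text{raw})$ — and monotonicity in $|t|$
are enforced on the output, so Monte-Carlo noise cannot produce a logically
inconsistent table.

## Paired nonparametric tests

Concession-level summaries (the proportion of camera locations with
hunting signs, site-covariate class proportions, the biomass index) are
compared across the 7 pairs with a two-sided Wilcoxon signed-rank test.
With so few pairs every convention is visible, so they are pinned down:

* zero differences are dropped before ranking (Wilcoxon's convention);
* ties receive midranks;
* the p-value is exact for up to 25 non-zero pairs, computed from the full
  distribution of the statistic over all $2^n$ sign assignments of the
  observed ranks (a dynamic-programming convolution, so midrank ties are
  handled exactly — the textbook null tables are not valid under ties);
* beyond 25 pairs a tie-corrected normal approximation with continuity
  correction takes over.

With 7 pairs all moving the same way the exact two-sided p is
$2/2^7 = 0.015625$ — the resolution limit of the design.

## The habituation check

If animals in hunted forests are warier of cameras, detection rates would
climb over a deployment as animals habituate, and differentially so
between arms — a confound mimicking a certification effect.
`habituation_test()` regresses $\log(\text{daily detections} + 1)$ on
deployment day, certification status, their interaction and concession
intercepts over the first 68 days of every deployment (the window keeps
all concessions represented equally; it truncates, with a warning, if a
deployment is shorter). The +1 offset is required because days without
detections exist; it is the standard remedy and is stated here because the
verbal description of such models usually omits it. The quantity of
interest is the day-by-status interaction: distinguishable from zero means
the arms' detection trends diverge.

## The synthetic-data generator

`simulate_dataset()` emulates the survey that the analysis assumes:
species $s$ at camera $c$ in concession $j$ of pair $p$ produces
independent detections as a Poisson process with rate

$$ \lambda_{spjc} = \text{base}_s \cdot \text{mult}_s^{\,[\text{certified}]}
   \cdot e^{u_p + u_j + u_c + x_c^\top \beta}, \qquad
   u \sim \mathcal{N}(0, \sigma^2) \text{ on the log scale.} $$

Random effects are log-normal and multiplicative: the simplest
positive-valued hierarchy, guaranteeing positive rates and yielding the
nested variance structure the model decomposes. Each event draws a group
size once (shifted Poisson, $1 + \text{Pois}(\bar g - 1)$); with
`emit = "photos"` it becomes a burst of three photos 1–2 s apart whose
per-photo counts never exceed the group size and attain it at least once,
so the group-size rule is genuinely exercised. Status photos appear every
12 h. Camera malfunction is a single terminal outage (the camera goes
silent some days early); the lost days are *not* written into
`downtime_days` — they are recovered downstream from the last status
photo, exercising the effort rule.

Defaults are the study conditions the package is validated under: 7
pairs, 28–36 cameras per concession, 80-day deployments, 15% outage
probability, and log-scale standard deviations of 0.3 (pair), 0.2
(concession) and 0.4 (camera) — values in the range a field ecologist
would call realistic for camera-to-camera heterogeneity in tropical
forest, chosen once and not revisited. `default_community()` provides 28
Afrotropical-forest-like species spanning all five mass classes, six taxa
and five IUCN categories with heavy-tailed rates (common duikers and
rodents around 0.1–0.25 detections/camera-day, an elephant analogue at
0.04, many rare species at 0.002–0.03, roughly 1.4 events/camera-day in
total). Certification multipliers are 1 below 10 kg and 3.5, 2.5 and 2.7
for the 10–30, 30–100 and >100 kg classes — the qualitative pattern
(effect above 10 kg, none below) the analysis is designed to detect.

What the generator does **not** emulate: spatial point patterns (the 1-km
grid is metadata only), animal movement and home ranges, diel activity,
seasonal trends, inter-species correlation beyond the shared random
effects, and detection-probability variation with vegetation or camera
model. Passing the validation suite therefore shows that the pipeline
recovers the parameters of this hierarchical Poisson world, not that any
particular field dataset satisfies its assumptions.

## Validation studies and problem sizes

The test suite validates the pipeline end to end at sizes chosen to make
the Monte-Carlo error bars meaningful while keeping a full run of the
suite within a coffee break:

* event clustering against a brute-force single-linkage oracle on 1000
  random photo streams of up to 200 photos;
* exact Wilcoxon p-values against full $2^n$ enumeration for every
  $n \le 12$;
* parameter recovery over 200 replicate surveys at the default design
  (7 × 28–36 × 80 days): mean per-class ratio estimates within 15% of the
  generator truth, and no spurious effect below 10 kg in at least 80% of
  replicates;
* type-I error of the certification contrast over 500 null-multiplier
  replicates (event-level generator path), required to stay within
  [0.03, 0.07] at nominal 0.05;
* degenerate-model equivalences (OLS, paired t-test) to $10^{-8}$.

## Known limitations

Encounter rates mix abundance and movement; a certification effect on
ranging behaviour would be indistinguishable from one on density.
The identity-scale LMM tolerates but does not model the mean–variance
relationship of rate data; the `log1p` option and, in a future extension,
count-likelihood GLMMs are the remedies. The Wilcoxon resolution floor
($p = 2/2^7$) is a property of a 7-pair design, not of the test. The
generator's downtime model is terminal-only; mid-deployment obstruction
windows are supported in ingest (via `downtime_days`) but not simulated.
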