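---
title: "Identifying blow fly puparia from spiracular-plate morphometrics"
author: "puparia package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying blow fly puparia from spiracular-plate morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puparia)
```

## The identification problem

Blow fly (Calliphoridae) puparia are among the longest-lasting insect
evidence at a death scene, but they carry far fewer diagnostic
characters than adults or larvae. The posterior spiracular plates — a
pair of sclerotized plates, each with three elongate respiratory
slits — are an exception: their geometry is stable within species and
variable between them. This package implements a complete,
quantitative identification pipeline built on that structure:

1. twelve landmarks per specimen (the start and end point of each of
   the six slits) are digitized on an image;
2. 27 candidate morphometric variables are derived from the landmarks
   and two scored qualitative characters;
3. two species are identified outright by a dichotomous pre-filter on
   qualitative characters;
4. the remaining taxa are separated by stepwise canonical discriminant
   analysis and classified by linear discriminant functions;
5. the classifier's resubstitution error rate is turned into an
   explicit probability that a single- or multi-specimen
   identification is wrong.

## Landmarks and the feature set

Points are indexed 1–12; points $2k-1$ and $2k$ are the start and end
of slit $k$. Slits 1–3 belong to the left plate, slits 4–6 to the
right. Coordinates are unitless image units; an optional scale factor
(units per pixel) multiplies all distances, and no analysis below
depends on the absolute unit.

From a configuration the package derives, per slit, the Euclidean
*length* and the *angle* between the slit segment and a user-set
horizontal reference line. Raw angles live in $[0°, 180°)$ and are
invariant to swapping a slit's endpoints. Because the two plates
mirror each other, right-plate angles are adjusted to a common
positive basis as $180° - \theta$; left-plate angles are used as
measured. With the typical digitization (slits steeper than the
horizontal on both plates) both adjusted angles fall in the same
range and are directly comparable. The configuration-level width
measures are distances between fixed point pairs: widest/narrowest
within the left plate (points 1–5 and 2–6), within the right plate
(7–11 and 8–12), and between plates (1–11 widest, 6–8 narrowest).

The candidate set screened by the stepwise analysis comprises 27
variables: the two scored characters (perispiracular papillae 0/1/2,
spiracular operculum 0/1), six lengths, six adjusted angles, the six
widths, two wide/narrow ratios (within and between plates), four
width means, and the total slit length. Feature tables additionally
carry the within- and between-plate width *totals* as auxiliary
columns (29 columns in all; see `feature_names()`). Two conventions
are worth stating because the source material leaves them open:

* The four width means are defined as the plain averages
  `meanWideWithin = (wideL + wideR)/2`,
  `meanNarrowWithin = (narrowL + narrowR)/2`,
  `meanWideAll = (wideL + wideR + wide)/3` and
  `meanNarrowAll = (narrowL + narrowR + narrow)/3`. None of these is
  among the final discriminators, so this choice cannot affect the
  headline results.
* Zero-width denominators yield `NA` ratios (an explicit undefined
  marker), never infinities; coincident slit endpoints are rejected at
  validation.

The three variables that matter downstream are `length2` (length of
the middle slit of the left plate), `angle4` (adjusted angle of the
middle slit of the right plate) and `narrow` (narrowest between-plate
distance). Variable names are positional under the uniform
$(2k-1, 2k)$ pairing; the anatomical gloss "middle slit" assumes the
digitization protocol clicks each plate's slits in the conventional
order. This is documented here rather than special-cased in the
geometry.

## The discriminant machinery

For $g$ groups on $p$ variables, let $B$, $W$ and $T = B + W$ be the
between-class, pooled within-class and total cross-product matrices
with $q = g-1$ and $N-g$ degrees of freedom. All statistics are
functions of this decomposition.

**Univariate rows.** For one variable:
total SD $=\sqrt{SST/(N-1)}$, pooled SD $=\sqrt{SSW/(N-g)}$,
$R^2 = SSB/SST$, $F = \frac{SSB/(g-1)}{SSW/(N-g)}$, and the
between-class SD uses the convention
$\sqrt{SSB\,g\,/\,(N(g-1))}$ — note the $g/N$ factor; this matches the
convention of the major statistical packages for this table and
differs from the plain $SSB/(g-1)$ mean square. Crucially,
`univariate_stats_from_summaries()` rebuilds the entire row from
per-group counts and means plus the pooled SD alone, which is exactly
what a published descriptive table provides — no raw data needed.
Each variable is analyzed on its own complete cases, so effective
sample sizes may differ across variables in the same table.

**Canonical eigenproblem.** `canonical_solve()` computes the
eigenpairs of $W^{-1}B$ through the symmetric form
$R^{-\mathsf T} B R^{-1}$ with $W = R^{\mathsf T}R$ the Cholesky
factorization — numerically stable and guaranteed real for positive
definite $W$. Raw coefficients are rescaled so each canonical variate
has pooled within-class variance one
($c^{\mathsf T}(W/(N-g))\,c = 1$), and signed so the
largest-magnitude coefficient of each variate is positive, making
coefficient tables deterministic. Canonical correlations are
$r_i = \sqrt{\lambda_i/(1+\lambda_i)}$.

**Multivariate tests.** From the eigenvalues: Wilks'
$\Lambda = \prod (1+\lambda_i)^{-1}$ with Rao's F, Pillai's trace
$V = \sum \lambda_i/(1+\lambda_i)$, the Hotelling–Lawley trace
$U = \sum\lambda_i$ with the standard two-regime F approximation, and
Roy's greatest root with its upper-bound F. The classical parameters
are $s = \min(p, q)$, $m = (|p-q|-1)/2$, $n = (N-g-p-1)/2$. When
$s = 1$ all four F approximations coincide exactly — a property the
test suite verifies, along with agreement of the eigenvalues against
an independent generalized eigensolver on randomized instances.

**Stepwise selection.** `stepwise_select()` performs forward entry
with a backward look after every entry. The entry statistic for
candidate $v$ given entered set $S$ is the partial
$R^2 = 1 - \Lambda(S\cup v)/\Lambda(S)$, with
$F = \frac{N-g-k}{g-1}\cdot\frac{R^2}{1-R^2}$ on $(g-1,\,N-g-k)$
degrees of freedom ($k = |S|$). Defaults are entry and stay levels of
0.15, the conventional stepwise-discriminant default; the separations
in this system are so strong (all entries at $p < 10^{-4}$) that the
result is insensitive to the levels. Each step records Wilks'
$\Lambda$ of the current set and the average squared canonical
correlation, ASCC $= V/(g-1)$. Adding a variable can never increase
$\Lambda$; degenerate candidates (constant or collinear, singular
total scatter) are inadmissible rather than errors.

## Identification and its probability

Two species short-circuit the measurement pipeline entirely: a folded
(partially closed) spiracular labellum is exclusive to *Cochliomyia
hominivorax*, and large perispiracular papillae (score 2) are
exclusive to *Protophormia terraenovae*. `dichotomous_prefilter()`
applies these rules first; pre-filtered specimens never enter the
discriminant analysis, mirroring their exclusion from the published
summary statistics.

For the rest, `fit_classifier()` builds pooled-covariance linear
discriminant functions with equal priors — with equal priors this is
nearest-centroid classification in the whitened canonical space, and
the hand-written implementation is cross-checked against an
independent reference LDA in the tests. Equal priors are the
defensible default for forensic casework, where collection-frequency
priors would be circular. Error is estimated by resubstitution
(reclassifying the training specimens), the estimator consistent with
reporting "$x$ of $n$ clustered with" another species; it is
optimistic relative to cross-validation, which is why the package
reports it per class and by its name.

The probability layer is deliberately simple: if a single specimen of
some class is misidentified with probability $r$ (e.g. $12/106
\approx 11.3\%$ for *Phormia regina*), then identifying $k$ specimens
independently and getting them *all* wrong has probability $r^k$
($0.016\%$ at $k = 4$). Independence across specimens is an explicit
assumption of this argument — specimens from one scene share
population, diet and rearing history, so $r^k$ is a lower bound on
the real group error in the presence of positive dependence.

## The synthetic-data generator

No raw specimen data accompany the published tables, so the package
ships the printed per-taxon summaries as generative parameters
(`builtin_population_specs()`): group sizes, per-variable means,
per-variable pooled within-class SDs, and per-group SDs recovered
from printed standard errors via $SD = SE\sqrt{N}$. The defaults are
the published study conditions: 3 subfamilies (N = 465 for
`length2`), 6 genera (N = 465), 8 measured species (N = 465; the two
pre-filter species are excluded from measured analyses, and at the
subfamily level the Chrysomyinae angle4/narrow sample is larger,
N = 207, than the length2 one, N = 178 — the per-variable counts are
kept alongside the simulation sizes).

`simulate_features()` draws each taxon from a multivariate normal
with those means and SDs. The within-class correlation defaults to
identity: no covariances are printed, the three final discriminators
are reported as uncorrelated, and all final variables are reported
normally distributed. Angles are simulated unclipped because the
printed means sit many SDs from the $[0°,180°)$ boundary. What the
generator therefore emulates is the *second-moment structure* of the
real data under normality; what it does not emulate includes
within-class correlation among the wider 27-variable set (several of
which are deterministic functions of others), measurement error of
the digitization step, and any non-normal tails — so passing
simulation tests demonstrates the statistical machinery, not the
biology.

`synthesize_landmarks()` inverts the geometry: given target lengths,
adjusted angles and (optionally) the six widths, it places 12 points
whose extracted features reproduce the targets to $10^{-9}$ relative.
Slit start points act as anchors; all width constraints reduce to
two-circle intersections solved in closed form, trying the mirror
branches in a fixed order, so the construction is deterministic and
targets harvested from any real configuration are always feasible.
Geometrically impossible targets (e.g. a between-plate narrow width
no placement can achieve) raise an infeasibility error rather than
silently approximating. Right-plate raw angles are generated as
$180° -$ target so the adjustment convention round-trips; adjusted
angles of exactly 0° or 180° are rejected (the fold-back at the
boundary makes them unrecoverable).

## Worked example

```{r example}
# published species-level conditions, landmarks synthesized per draw
specimens <- simulate_specimens("species", seed = 1,
                                include_prefilter_taxa = TRUE)
res <- run_pipeline(specimens, level = "species")

nrow(res$prefilter)        # specimens identified by qualitative characters
res$selected               # variables entered by stepwise selection
res$stepwise[c("variable", "partial_rsq", "F", "wilks", "ascc")]
res$univariate[c("variable", "r_square", "F")]
subset(res$error_rates, group == "Phormia regina")
```

With the per-class error in hand, the certainty of a multi-specimen
identification follows directly:

```{r probability}
r <- 12 / 106                        # published P. regina error rate
100 * group_misid_probability(r, 1)  # single specimen, % wrong
100 * group_misid_probability(r, 4)  # four specimens, % all wrong
```

## Numerical choices and limitations

* **Problem sizes.** Simulation-based checks use the published group
  sizes (N = 465) for distributional fidelity and $10^4$ per group
  where a law-of-large-numbers limit is being verified; both run in
  seconds.
* **Reconstruction precision.** Univariate rows rebuilt from printed
  summaries match the published subfamily row to all printed digits.
  At genus and species level the printed means are rounded to about
  six significant figures, which propagates to roughly $\pm 0.02$ on
  F statistics near 1000; the reconstructed values agree to that
  input-limited precision.
* **Ties and determinism.** Classifier ties break to the
  lexicographically smallest label; eigen signs are fixed by the
  largest-loading rule; identical seeds give identical tables.
* **What is not reproduced.** Published stepwise traces, canonical
  coefficients and multivariate test values at steps 2–3 depend on
  the unavailable raw specimen data (including their within-class
  correlations) and are implemented but not numerically reproduced;
  only quantities derivable from printed summaries are asserted
  against the publication. Cross-validated error estimation and
  quadratic discriminants are out of scope.
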