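---
title: "Methods: models, estimators and design choices in evotol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in evotol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotol)
```

evotol packages the quantitative analyses used in experimental-evolution
studies of solvent tolerance in bacteria: growth-curve fitness phenotyping,
multiplicative epistasis decomposition, mutation-catalog and
allele-trajectory analysis, resequencing variant triage, microarray
differential expression, Network Component Analysis (NCA) of transcription
factor activities, and mechanistic qPCR quantification. This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions that were genuinely open — the things a maintainer or
reviewer would want stated rather than reverse-engineered from the code.

## Growth phenotyping

### Model and estimator

Isobutanol tolerance is quantified as the maximum specific growth rate
$\mu_{\max}$ (h$^{-1}$), the slope of $\ln(\mathrm{OD}_{600})$ against time
during exponential growth, after blank subtraction. `fit_mu_max()` makes
the log-phase interval choice objective: it scans every contiguous window
of at least `min_points` usable time points, fits ordinary least squares of
$\ln(\mathrm{OD})$ on time in each, and reports the largest slope among
windows whose $R^2$ reaches `min_r2` (default 0.98). A curve with no
qualifying window is an explicit *no-growth* result
(`mu_max = 0, no_growth = TRUE`), never an error.

### Why the window is 6 h and the floor is 0.02

Two defaults deserve justification because a shorter window looks more
natural at first sight:

* **`min_points = 36`** (6 h at the 10-minute read interval). The reported
  rate is a *maximum* over many window slopes. The sampling error of a
  1-hour window slope at plate-reader read noise (SD $\approx 0.002$ OD) is
  0.005–0.05 h$^{-1}$ depending on where the window sits on the curve, and
  taking a maximum over hundreds of such windows inflates the estimate by
  2–3 standard errors — an upward bias of 10–20% of a typical
  $\mu = 0.3$ h$^{-1}$. A 6-hour window cuts the per-window slope error
  roughly tenfold (slope SE scales as $w^{-3/2}$ in the window length $w$)
  while still fitting comfortably inside the exponential phase of a 48-hour
  run; the residual selection bias is under 2% at that noise level, which
  we verify by simulation in the test suite.
* **`floor = 0.02`** OD (about ten times the read noise). Below this the
  signal is noise-dominated and $\ln(\mathrm{OD})$ is both extremely noisy
  and biased downward by the concavity of the logarithm
  ($E[\ln(a+\varepsilon)] \approx \ln a - \sigma^2/2a^2$), which drags
  window start points down and inflates slopes. Points at or below the
  floor are excluded pointwise. For noise-free data (e.g. synthetic
  curves) a small positivity guard such as `1e-4` is the right setting,
  and both values are plain arguments.

Blank handling follows plate practice: a per-well blank if the plate map
provides one, otherwise the plate-level median of designated blank wells.
Replicate wells of one strain and condition are aggregated by
`fit_plate()` into mean $\mu_{\max}$ with the sample standard error.

### Derived statistics

All on their conventional scales: relative fitness
$\mathrm{RF} = \mu_{\mathrm{mut}}/\mu_{\mathrm{ref}}$; normalized relative
fitness $\mathrm{RF}/\mathrm{RF}_{0\%}$ (equal to 1 at the 0% stressor
condition by construction); tolerance improvement and generic percent
change as $100(x - x_{\mathrm{ref}})/x_{\mathrm{ref}}$; specific
fluorescence as fluorescence per OD unit; and malate dehydrogenase
activity as $\Delta A_{340}/\mathrm{min} / (\varepsilon_{340}\, l\, c)$
with defaults $\varepsilon_{340} = 6.22$ mM$^{-1}$cm$^{-1}$, $l = 1$ cm,
$c = 0.0045$ g wet cells per reaction. Percent relative inhibition is
reported as $100(\mu_{\mathrm{mut}} - \mu_{\mathrm{wt}})/\mu_{\mathrm{mut}}$
— positive when the mutant outgrows the wild type. Published reports are not
consistent about the denominator, so it is an
explicit switch (`convention = "mut"` or `"wt"`) rather than a hidden
assumption.

## Epistasis against the multiplicative null

For a combination $S$ of mutations with observed relative fitness $w$ and
single-mutant fitnesses $w_i$, the total epistasis is
$$\varepsilon = \frac{w}{\prod_{i \in S} w_i}, \qquad
\log_{10}\varepsilon = \log_{10} w - \sum_{i\in S}\log_{10} w_i .$$
$\log\varepsilon > 0$ is synergistic (positive) epistasis. Base 10 is a
reporting choice; the sign and every significance decision are
base-invariant, which the tests assert.

Uncertainty: the default is a delta-method normal interval on
$\log_{10}\varepsilon$ with variance
$[(\mathrm{SE}_w/w)^2 + \sum_i (\mathrm{SE}_i/w_i)^2]/\ln(10)^2$,
appropriate when only mean $\pm$ SE fitness values are available. When
per-replicate fitness values exist, a seeded percentile bootstrap is
available and agrees with the delta interval on well-behaved cases to
within about 10% of the half-width. Singletons carry $\varepsilon \equiv 1$
(their own fitness is the reference); combinations referencing a missing
single mutant are flagged and skipped, never imputed. A zero-width
interval that sits within $10^{-12}$ of zero (pure floating-point residue
on noise-free input) is treated as null rather than "excluding zero".

## Mutation catalogs, trajectories and variant triage

Mutation records carry a carrier (clone or population), locus, 1-based
genomic coordinate, a class (`SNP`, `short-indel`, `SV`), and the
nucleotide/protein change strings. Packaged fixtures transcribe the
published clone and endpoint-population mutation tables; the
allele-trajectory fixture is *partially synthetic* (its file name says so):
only the two textually reported first-detection generations (180 and 266)
and the ordinal structure are anchored, all other generations being
placeholders consistent with that order.

`mutation_order()` reports each locus's first sampled generation with a
`Mut` *or* `Mixed` call — a mixed population counts as detection because
whole-population screening sees an allele long before fixation — skipping
`NT` (not-tested) generations; ties share a rank and form a mutation
cluster. `trajectory_join()` attributes the growth-rate change of each
inter-sample interval to the loci first detected in it, and is purely
descriptive: co-occurrence in an interval is correlation, not causation.

Variant triage follows the resequencing pipeline's bespoke steps, with the
external aligner/assembler stages out of scope:

* `filter_variants()` keeps SNPs with consensus quality $\ge 150$ and
  indels with supporting-read frequency $\ge 0.4$ (boundary values kept).
  The stricter quality threshold 200 historically used to pick candidates
  for Sanger verification is available as `preset = "verification"`; both
  thresholds occur in practice and the package treats them as presets
  rather than resolving the discrepancy.
* `detect_coverage_gaps()` tabulates maximal runs of depth
  $\le$ `max_depth` and length $\ge$ `min_length` as candidate large
  deletions, on 0-based half-open intervals (bedGraph convention; the
  mutation catalog is 1-based, and converters are provided).
* `homopolymer_filter()` discards reads containing any single-base run
  (N included) strictly longer than `max_run`, the artifact filter applied
  to unmapped reads before de novo assembly.

## Microarray preprocessing and differential expression

The stage mirrors a spotted-array workflow: background subtraction
(foreground minus local background, negatives retained), a
variance-stabilizing generalized-log transform, unweighted quantile
normalization, technical-spot medians, a biological-replicate acceptance
rule, one representative probe per gene, two gene filters, moderated
t-tests for three contrasts, and Benjamini–Hochberg adjustment with the
study's $p_{\mathrm{adj}} < 0.001$ cutoff.

Numerical choices:

* **glog stand-in for vsn.** The exact vsn calibration is an external
  package's algorithm; `glog_transform()` uses
  $\log_2\big((y + \sqrt{y^2 + \lambda^2})/2\big)$ with offset $x_0$ and a
  transition scale $\lambda$ calibrated, by default, as the standard
  deviation of the lowest-decile intensities (the additive-noise scale).
  It is log-like for bright spots and finite through zero and negative
  background-adjusted values. Consequently the dataset-level gene
  counts of analyses that ran the original vsn implementation are not
  reproduced exactly by construction;
  the filter cascade is instead verified against brute-force oracles on
  synthetic data.
* **Quantile normalization** replaces each column's sorted values by the
  cross-column means of sorted values; ties take the value interpolated at
  their average rank. The defining postcondition — identical sorted
  columns — holds exactly for tie-free (continuous) data and is asserted
  on every tested input.
* **Replicate rules.** Per array, a probe's value is the median of its
  technical spots; a probe survives only with acceptable signal
  (non-missing, and at least `accept_min` if set) in at least 2 of 3
  biological replicates of *every* strain-by-condition cell. What counts as an
  "acceptable" spot signal is rarely defined precisely in array
  workflows, so it is a configurable threshold, defaulting to "any non-missing
  value".
* **Probe-per-gene selection** minimizes the sum over design cells of the
  replicate standard deviation, with lexicographic probe-id tie-breaks,
  making the choice deterministic.
* **Gene filters**: value $> 100$ units in at least
  $\lceil 0.25 n \rceil$ samples, and interquartile range $> 0.5$ with
  linear-interpolation quartiles (R type 7) — the quartile definition is
  fixed and documented because it is otherwise a silent source of
  irreproducibility.
* **Moderated t.** Per gene, group means and a pooled residual variance
  over the groups entering the contrast; gene variances are shrunk toward
  a prior $s_0^2$ with prior degrees of freedom $d_0$ estimated from the
  ensemble of gene variances by matching the moments of $\log s^2$
  (digamma/trigamma identities, with a Newton inversion of the trigamma
  function). The moderated statistic uses the shrunk variance and
  $d_0 + d$ degrees of freedom. With `prior_df = 0` it reduces *exactly*
  to the ordinary pooled two-sample Student t, which is the reason the
  residual variance is pooled per contrast (two groups for the
  within-strain deltas, four for the difference-of-differences) rather
  than always over all cells. The third contrast tests
  $(\mathrm{mut}_s - \mathrm{mut}_0) - (\mathrm{wt}_s - \mathrm{wt}_0)$,
  i.e. genes whose stress response differs between strains.
* **FDR.** Step-up Benjamini–Hochberg via `stats::p.adjust`, with flags at
  the declared cutoff.

## Network Component Analysis

### Model

Expression is modeled bilinearly, $E \approx A P$, where the support of
the gene-by-TF loading matrix $A$ is fixed by a binary connectivity matrix
$Z$ (which TF may regulate which gene) and $P$ holds TF activities per
sample. The decomposition is identifiable up to a per-column scale/sign
when (i) $A$ has generically full column rank, (ii) removing any TF's
column together with all genes it regulates leaves a full-column-rank
reduced matrix, and (iii) there are at least as many conditions as TFs —
the reason analyses with few conditions must work on small TF subsets.
`check_identifiability()` evaluates all three on a random filling of the
support.

### Estimator

`decompose_nca()` minimizes $\|E - AP\|_F$ by alternating least squares:
the $P$-step is an unconstrained solve given $A$; the $A$-step solves a
small least-squares problem per support pattern (genes sharing a regulator
set are solved in one block). The objective is monotonically nonincreasing
— asserted as a property test — and iteration stops on relative
improvement below `tol`. Constrained ALS is biconvex and has genuine local
minima: random support initializations were observed to stall at nonzero
residuals on noiseless identifiable instances. The primary initialization
is therefore deterministic — the principal-subspace projection
($U_L \Sigma_L$ from the SVD of $E$) masked to the support — which reached
machine-precision residuals on every tested identifiable instance; seeded
random restarts remain as a guard (`n_restarts`). Rank-deficient normal
equations fall back to a ridge solve with jitter $10^{-8}$. The
scale/sign indeterminacy is resolved at exit: unit-norm loading columns,
dominant loading positive, $P$ rescaled inversely. All recovery claims in
the tests are stated scale/sign-invariantly (absolute correlation per TF).

### TF-subset consensus

With four conditions only four TFs are identifiable at once, so the
analysis is repeated over subsets of a larger TF panel and a TF is trusted
only if its behaviour is consistent across the subsets containing it.
Three design points here were genuinely open and are worth stating:

* **Gene restriction.** Each subset's fit uses only genes whose regulators
  all belong to the subset (`gene_rule = "exclusive"`). Genes with an
  out-of-subset regulator carry signal the subset model cannot express;
  in experiments this leak corrupted member-TF activities badly enough to
  destroy the sign consistency of genuinely changing TFs. The more
  inclusive "any member regulator" rule remains available
  (`gene_rule = "any"`).
* **Sign anchoring.** Per-fit sign conventions are not comparable across
  subsets, so each TF's activity row is re-anchored to the sign of its
  loading on a fixed reference gene — its highest-signal single-regulator
  gene, which is present in every subset containing the TF.
* **"Consistent and significant".** A TF is retained when (a) its
  activity contrast between the two sample groups keeps one sign in at
  least 80% of its subsets, and (b) its median absolute contrast is
  significant against a group-label permutation null at a level that is
  Bonferroni-corrected across the TF panel (0.05/$n_{\mathrm{TF}}$). The
  balanced label splits are enumerated exhaustively when feasible (all
  $\binom{12}{6} = 924$ splits for a 4-condition, 3-replicate design),
  making the p-values deterministic. Family-wise control matters: a
  per-TF 5% test over a 16-TF panel would flag a spurious TF in roughly
  half of all null datasets. A max-over-TFs (Westfall–Young) null was
  tried and rejected because strongly changing TFs dominate the permuted
  maximum and mask weaker true signals.

Replicate activities are summarized by `activity_ci()` as mean and
t-based 95% confidence interval; a single replicate yields a flagged,
undefined interval.

## MAK2 qPCR quantification

The two-parameter mechanistic amplification model is the recurrence
$$F_0 = D_0, \qquad F_n = F_{n-1} + k\,\ln\!\big(1 + F_{n-1}/k\big),$$
with initial target $D_0$ and characteristic constant $k$, both in
fluorescence units — a definition imported from the model's original
description, since only the parameter names are fixed by the study
context. Early cycles double the signal; as $F$ grows past $k$ the
per-cycle gain decays toward zero, reproducing the bend of a real curve
without an explicit plateau term. `fit_mak2()` fits the recurrence by
nonlinear least squares (Levenberg–Marquardt, parameters on the log scale)
to the pre-plateau region — cycles up to the first exceeding 85% of the
maximum fluorescence, a window rule that is a documented decision exposed
in configuration, as is the log-spaced multistart grid over $(D_0, k)$.
Flat curves return a *no amplification* result ($D_0 = 0$) rather than an
error. Replicate wells are fitted independently and summarized as mean
$\pm$ SE; expression is normalized as the ratio of fitted $D_0$ to a
reference gene's $D_0$, which is invariant to common fluorescence
rescaling because $cF$ is again a MAK2 trajectory with parameters
$(cD_0, ck)$.

## Synthetic-data generators

Every pipeline input can be generated with planted ground truth, under a
single integer seed split into per-generator substreams by a fixed label
hash, so that generators are pure functions of (parameters, seed) and
independent of each other. The study conditions they emulate:

* **Growth plates**: 48 h at 10-minute reads (289 points per well),
  three-phase curves — flat lag, *pure* exponential at the planted rate,
  logistic saturation — plus a constant blank offset and additive Gaussian
  read noise. The pure-exponential segment makes the planted rate an exact
  in-window log-slope, so rate recovery has an exact target. Read noise
  is instrument-specific; the default of 0.002 OD used in tests is a
  realistic plate-reader figure and a free parameter, not a claim about
  any particular instrument.
* **Fitness landscapes**: all nonempty subsets of up to 12 single mutants,
  fitness $\varepsilon_S \prod_{i \in S} w_i$ with multiplicative
  lognormal noise (positivity-preserving, matching how growth-rate ratios
  behave).
* **Expression**: loadings drawn on the exact support of a sampled
  connectivity (per-gene regulator counts in 1–5 from a truncated
  geometric calibrated to mean 1.5, optionally rejection-sampled to
  identifiability), log-scale expression $AP$ expanded to 3 biological
  replicates and 6 technical spots per probe with a constant background
  offset. Spot values are emitted on the log scale plus background — the
  generator's contract is that background subtraction and replicate
  medians alone reconstruct $AP$ exactly at zero noise; raw-intensity
  image artifacts are not modeled.
* **Allele trajectories**: deterministic WT → Mixed → Mut states around
  planted fixation generations, evaluated exactly at the sampled
  generations.
* **qPCR curves**: forward MAK2 with plateau clamp and additive noise.
* **Variant triage sets**: candidates straddling the triage thresholds,
  a uniform-depth coverage track with planted zero-depth intervals, and
  reads with planted homopolymer runs.

What passing tests on these generators does and does not show: recovery
at planted truth demonstrates the estimators are correct inverses of the
stated generative models at the stated noise; it does not validate the
generative models against real plates, arrays or sequencers (no spatial
array artifacts, no read-error model, no instrument drift). The problem
sizes used in the test suite — 100 wells for rate recovery, 1000 null
landscapes, 200-gene NCA instances, 50 consensus runs per arm, 200 null
expression datasets of 2000 genes — were chosen to make the Monte-Carlo
error of each checked proportion small relative to its acceptance margin.

## Known limitations

* The vsn stand-in is deliberately not the external vsn algorithm; exact
  numeric agreement with analyses that used it is out of scope.
* The percent-relative-inhibition denominator is a convention switch, not
  a recovered formula.
* `fit_mak2` on very-low-$D_0$ curves is weakly identified when the
  fitting window excludes the bend; the multistart grid mitigates but
  cannot remove this.
* NCA consensus assumes the connectivity is correct; it has no mechanism
  for detecting wrong edges, only for refusing unidentifiable subsets.
* The allele-trajectory fixture encodes ordinal structure with synthetic
  placeholder generations; only the first-detection generations 180 and
  266 are anchored to reported values.
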