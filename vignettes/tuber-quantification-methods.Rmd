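---
title: "Methods: quantifying and subtyping cortical tubers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and subtyping cortical tubers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuberquant)
```

## The problem

Cortical tubers are the epileptogenic cortical malformations of tuberous
sclerosis complex (TSC). Under an immunohistochemistry (IHC) panel —
vimentin for giant cells, SMI32 (non-phosphorylated neurofilament) for
dysmorphic neurons, pS6-Ser235/236 for mTORC1 activation, NeuN, GFAP,
CD3, Cr3/43, CD34, Olig2 and MBP for the supporting cellular landscape —
resected tubers are not one entity: they separate into a low-grade
pattern (type A), a giant-cell/dysmorphic-neuron-rich pattern (type B)
and a calcified pattern (type C). `tuberquant` implements the
quantification, the subtype rule, the cluster analysis that motivates it
and the accompanying statistics as one auditable pipeline, validated
end-to-end on synthetic data with exact ground truth.

## Image quantification model

**Scale.** All measurements assume a known scan resolution in µm/px
(default 0.64, a standard 100× virtual-slide resolution). A pixel count
`n` converts to area as `n × res² × 10⁻⁶` mm², exactly.

**Tissue segmentation.** Tissue is everything darker than the glass:
pixels with luminance (channel mean) below 240, after a morphological
closing (disc radius 2 px, filling small unstained holes) and removal of
speckle components under 64 px. A slide with no such pixels returns area
0 with a warning rather than an error — empty fields occur in practice
and downstream fractions are then flagged undefined (`NA`), never
silently 0.

**DAB positivity.** The original analysis used a proprietary colour
segmentation recipe; the rule here is stated in full so it can be
audited: a pixel is positive when it lies in tissue, its blue value is at
or below the marker threshold, and red exceeds blue. DAB's brown
chromogen absorbs strongly in the blue channel while hematoxylin-stained
nuclei are blue-dominant (blue ≥ red), so the two-condition rule
separates them without colour deconvolution. The rule is monotone in the
threshold: raising it never removes a positive pixel. Thresholds follow
the published per-marker values (NeuN 120; CD3, SMI32, Olig2 100;
CD34 150); "brightness threshold" is read as *at-or-below* the cutoff,
the natural direction for a dark chromogen. The area markers (pS6, GFAP,
Cr3/43, MBP) have no published threshold and default to 120, a mid-range
value between the counted-marker extremes; it is a single panel-wide
default, applied identically to every sample in a run.

**Counting.** Counted markers take the 8-connected components of their
positive mask and keep those inside the published pixel-area gate
(NeuN 120–2500; CD3 20–155; Olig2 20–155 surgical, 5–120 autopsy;
CD34 100–unbounded; SMI32 750–5000). Connectivity is not stated in the
source protocol; 8-connectivity is chosen because diagonal adjacency
within one stained cell should not split it. Densities are counts per
mm² of segmented tissue. Giant-cell (vimentin) density is different by
design: it is an eye count over 10 representative fields of 1.081 mm²
each, pooled as `sum(counts) / (10 × 1.081)`.

**Optical density and OMC.** Per-pixel OD is `-log10((L + 1)/256)` on
luminance, with the +1 offset avoiding `log 0` at full absorption and
making a blank pixel contribute exactly 0. Whether the original OD was
measured on luminance or a single channel is not documented; luminance
is used, and no blank-slide correction is modelled. Mean OD averages
over positive pixels (undefined for an empty mask), integrated OD sums.
The overall myelin content is the exact product
`OMC = MBP% × mean OD`; the identity is preserved verbatim in every
emitted result and tested as such.

**Calcification** is scored by eye on H&E (a 0/1 nominal input), not
detected from the IHC image; phantoms carry it in ground truth only.

## The subtype rule

With `gc` the giant-cell density and `dn` the dysmorphic-neuron density:

- **C** if calcification is present (its unique discriminator),
- else **B** if `gc > 10/mm²` *or* `dn > 3/mm²`,
- else **A**.

The published criteria phrase both A and B with "or", which does not
partition mixed inputs (one density high, one low); the rule above
resolves the ambiguity by treating B as the higher-grade pattern: either
exceedance suffices for B, A requires both at or below. The boundaries
are inclusive for A, so bisection along either axis lands exactly on 10
and 3. Whether the original raters additionally required visible giant
cells and dysmorphic neurons for type C is not documented; calcification
alone is sufficient here. Perituberal cortex is defined by absence:
`gc = 0`, `dn = 0`, no calcification.

## Cluster analysis

The pattern-discovery step mirrors the original workflow: the three
clustering features (pS6 %, SMI32 density, vimentin density) are
left-skewed, so each value is replaced by `log(x + ε)` with `ε = 10⁻³`
— the offset keeps the zero densities of perituberal-like samples
finite while preserving rank order. Features are then z-standardised;
the source analysis does not say whether it standardised, but mixing
percentage-scale and count-scale features in a squared Euclidean
distance without standardisation would let whichever feature has the
largest numeric range dominate the clustering, so standardisation is the
package default (and switchable). Clustering is agglomerative Ward on
squared Euclidean distances (`hclust(d², method = "ward.D")`, the
classic Ward criterion), whose merge heights are then monotone.

**Choosing the cut.** `k = 3` is the default, as a parameter rather than
an automatic choice. The automatic selector `select_k()` exists for
sensitivity analysis and uses Mojena's stopping rule: cut above the
first merge height exceeding `mean(h) + 1.25 sd(h)` (the constant from
Milligan and Cooper's comparison of stopping rules). A naive "largest
height gap" criterion was evaluated first and rejected: under Ward the
final merge height grows with cluster size even when there is no
structure, so the largest raw gap sits at the top of the tree and picks
two clusters almost regardless of the data (on simulated cohorts it
chose `k = 2` in ~90% of seeds while the 3-cluster cut recovered the
planted groups nearly perfectly). A log-scale gap removes that bias but
becomes sensitive to tiny denominators deep in the tree. Mojena's rule —
flag heights that are outliers of the whole height distribution —
selects 3 clusters in ~96% of simulated cohorts.

Per-feature one-way ANOVA across the resulting labels identifies the
discriminating markers; it is run on the log scale, the same scale on
which all downstream statistics operate for the skewed features.

## Statistics battery

- **Kruskal–Wallis** on mid-ranks with tie correction
  (`stats::kruskal.test`), with the all-ties degenerate case defined as
  `H = 0, p = 1` rather than `NaN`.
- **Pairwise post hocs** are Dunn's z tests on the joint ranking, with
  the tie-corrected variance. The original report says only "pairwise
  comparison"; Dunn's test is the standard Kruskal–Wallis follow-up, and
  both the unadjusted and Bonferroni-adjusted p are reported because the
  original correction is unstated.
- **Kendall correlation** is tau-b with tie handling, p from the normal
  approximation. Partial Kendall uses
  `(τxy − τxz·τzy)/√((1−τxz²)(1−τzy²))`; its p reuses the plain-tau
  variance `2(2n+5)/(9n(n−1))` and is approximate.
- **Chi-square** is plain Pearson without continuity correction, with
  zero marginals rejected.
- **Kappa** is Cohen's for two raters and Fleiss' for more (the source
  says only "κ coefficient"; Fleiss' is the standard multi-rater form).
  Bands are lower-inclusive per the published cutpoints: < 0.2 poor,
  0.2–<0.4 fair, 0.4–<0.6 moderate, 0.6–<0.8 good, 0.8–1.0 very good
  (so κ = 0.8 is "very good"). The degenerate design in which every
  rater gives one identical category everywhere has expected agreement
  1; κ is reported as 1 with a `degenerate` flag.
- **BCa bootstrap** (default B = 1000 at the 95% level) delegates the
  bias-correction/acceleration arithmetic to `boot::boot.ci`, with a
  guard collapsing degenerate resample distributions to a point interval
  with a warning. Seeded calls are exactly reproducible.

## What the synthetic data emulates — and what it does not

**Phantoms** emulate the geometry and colorimetry that the
quantification depends on: a tissue region whose luminance falls under
the background cutoff, brown objects with the blue channel depressed to
a configurable chromogen darkness, blue-dominant nuclei, dark basophilic
calcification blobs, and an optional diffuse brown compartment of known
mean OD. Structures are uniform in colour and placed by rejection
sampling with a one-pixel separation margin, which makes every stored
truth value *exact*: object counts equal rendered blobs, area fractions
are pixel ratios, mean ODs follow from the rendered colour in closed
form, and brute-force flood-fill counting is an exact oracle. Phantoms
are deliberately not photorealistic: no staining noise or batch effects,
no overlapping or touching cells, no out-of-focus blur, rectangular
rather than organic shapes, no pyramidal whole-slide formats. Passing
the phantom suite therefore shows the *measurement machinery* is
correct; it does not show robustness to real-slide artefacts such as
stain variability or touching nuclei, which would require instance
segmentation beyond the scope here.

**Cohorts** draw each feature per group from a (median, low, high)
triple. Skewed features (pS6, SMI32, vimentin) use a log-normal with
`meanlog = log(median)` and `sdlog = (log(high) − log(low))/(2·1.96)`,
clipped to `[low, high]` — clipping trims only tail mass on each side of
the median, so the population median is preserved exactly, and the
central ~95% band matches the configured range. Other features use a
clipped normal centred on the median. The tuber-group and control
triples for the eight published markers come from the reported cohort
summaries. SMI32 and vimentin have no published per-group summaries;
their triples are the package's own calibration, chosen to respect the
subtype definitions and the reported finding that dysmorphic-neuron and
giant-cell counts are the main cluster discriminants: type A at or
below both classifier cutoffs (vimentin 1–10/mm², median 4; SMI32
0.2–3/mm², median 1), type B clearly above at least one (12–70, median
30; 3.2–12, median 6) and type C the giant-cell-rich extreme (60–250,
median 120; 12–50, median 25). Group structure is enforced exactly: A
draws are capped at the cutoffs, B/C draws are rejection-sampled until
at least one cutoff is exceeded, C samples always carry calcification
(its prevalence outside C is definitionally 0 — the source defines C by
calcification and reports no prevalence elsewhere), and
perituberal/control samples have zero giant cells and dysmorphic
neurons. Clinical covariates (age, epilepsy duration ≤ age, AED count,
FCD-like imaging, Engel score) are plausible synthetic values for
pipeline plumbing, not re-estimates of the published cohort.

Default group sizes are 7/13/8 tubers plus 7 perituberal and 6 control
samples, a realistic surgical series of the size that motivated the
method.

```{r cohort-example}
co <- sample_cohort(cohort_spec(), seed = 1)
table(co$true_group)
```

## Numerical choices and degenerate inputs

- OD reference intensity 256 with a +1 offset; no blank correction.
- Log-transform offset `ε = 10⁻³`, small against the smallest nonzero
  configured density (0.2/mm²); double transformation is a guarded
  error.
- Zero-tissue fields: area fractions and densities are `NA` with a
  warning, never 0.
- Empty positive masks: mean OD `NA`, integrated OD 0, sample-level OMC
  0 for an unstained slide.
- Ward tie-breaks follow `hclust`'s deterministic agglomeration order;
  identical inputs give identical trees.
- Phantom placement is rejection sampling (4000 tries per structure);
  infeasible requests (total object area exceeding tissue) fail fast
  with a placement error.
- All generators consume one seed; identical (spec, seed) pairs are
  bitwise-reproducible, which the suite asserts.

## Validation problem sizes

The shipped suite exercises: exact-arithmetic phantoms up to 1024² px
(10⁶ tissue pixels); 200 random phantoms of 160–224 px against the
brute-force counting oracle across all five marker gates; 100 simulated
cohorts for cluster-count recovery and 100 planted-cluster seeds for
exact Ward recovery; 5000 null simulations for the Kruskal–Wallis
type-I error; 500 seeded replicates of BCa coverage for a normal mean
(B = 1000); and 10⁴-draw checks of generator medians and chance-level
kappa. These sizes give the relevant Monte-Carlo estimates standard
errors well inside the asserted tolerances.

## Known limitations

- The positivity rule is a two-channel heuristic, not stain
  deconvolution; heavily co-localised chromogen/counterstain would need
  the latter.
- Counting is component labelling: touching cells merge (and may then
  fall outside a size gate), which is exactly why the published protocol
  uses size gates, but instance-level separation is out of scope.
- The classifier is deterministic and hard-boundaried; samples near
  10/mm² or 3/mm² flip labels with measurement noise, and no soft
  classification is offered.
- Partial-Kendall p-values are approximate (plain-tau variance).
- Cohort draws are independent across features within a group; real
  marker correlations (e.g. pS6 with SMI32) are not modelled, so
  multivariate statistics on synthetic cohorts should be read as
  plumbing checks, not biology.
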