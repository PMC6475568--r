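---
title: "Methods: screening deletion calls with paired-end mapping evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening deletion calls with paired-end mapping evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`pemscreen` asks, for each catalogued deletion, a single question: *is
there paired-end evidence that the deleted segment is actually absent from
the sequenced genome?* The underlying model is the standard paired-end
library geometry. Fragments of length $f \sim \mathcal N(\mu, \sigma^2)$
(defaults $\mu = 500$, $\sigma = 50$) are sequenced from both ends with
reads of length $r$ (default 100). Over a real homozygous deletion of
length $D$, any fragment whose sequenced ends clear the breakpoint maps
with its mates pushed $D$ bases apart on the reference, so its outer span
($f + D$ bases) closely matches the deletion span. Over a coverage valley
caused by GC or mappability bias, fragments remain concordant (outer span
$\approx f$), and no span matches the putative deletion.

Span matching uses the base-level F-score between spans $A$ and $B$:
$$F(A,B) = \frac{2\,|A\cap B|}{|A| + |B|},$$
the harmonic mean of precision ($|A\cap B|/|B|$) and recall
($|A\cap B|/|A|$); 0 for disjoint spans or spans on different chromosomes.
$F$ is symmetric, bounded by $[0,1]$, and equals 1 only for identical
spans.

Two assumptions matter. First, *the deletion must be shorter than what the
aligner can pair across* — hence the 10 kbp size ceiling in the variant
filter. Second, *the span-match cut must out-reach the insert size*: a
pair's outer span cannot match (F > 0.7) a variant much longer than
$f/0.4$, nor discriminate a variant shorter than about $2.3\mu$ from an
ordinary concordant pair (see *Known limitations*).

## Pipeline stages and tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `bin_size` | 100 | bp | profile track bin width |
| `window_bins` | 11 | bins | smoothing window (~1.1 kb) |
| `gc_tails` | 0.05 | — | per-tail area for the GC thresholds th1/th2 |
| `map_right_area` | 0.20 | — | right-tail area above th3 (after dropping exact 0/1) |
| `min_region_length` | 500 | bp | strict minimum suspicious-segment span |
| `flag_f_threshold` | 0.9 | — | strict F cut for flagging a variant suspicious |
| `roi_pad` | 1000 | bp | ROI = variant ± (pad + L/2) |
| `pair_f_cut` | 0.7 | — | strict span-match cut for supporting pairs |
| `avg_mq_cut`, `sum_mq_cut` | 30, 90 | MAPQ | inclusive decision thresholds |
| `pair_quality_mode` | `min` | — | pair quality from the two mate MAPQs |

Thresholds th1/th2/th3 are recomputed from the input tracks' raw value
distributions (on hg18 the same recipe yields 0.26 / 0.59 / 0.92; those
reference values are used as fixed thresholds in several tests). The
decision thresholds are **inclusive** (≥ 30, ≥ 90): the rule's own minimal
worked examples — one pair at 90, two at 45, three at 30 — sit exactly on
the boundary and are accepted, which forces ≥ rather than >.

## Numerical and design choices

**Smoothing.** Degree-1 locally weighted regression with tricube weights
over a sliding window, evaluated at bin centres; missing bins are excluded
from every fit and stay missing. For symmetric, complete windows the
fitted centre value reduces to a tricube-weighted mean and is computed as
a linear filter; edges and windows touching missing values use the
explicit weighted least-squares fit. The window default is 11 bins
(~1.1 kb), not larger: the screen targets features barely longer than
500 bp, and a multi-kilobase window provably erases them (a 700 bp window
at GC 0.10 amid 0.41 background dips only ~0.05 after 51-bin smoothing —
far short of any useful threshold). Eleven bins denoise per-bin jitter by
~2× while leaving a 500–700 bp feature's contrast essentially intact.

**Segmentation.** Suspicious bins are *detected* on the smoothed track
(below th1 / above th2 for GC, below th3 for mappability); maximal runs
form candidates. Because smoothing smears shallow edges outward by several
bins, each run is then *refined to its longest contiguous subrun of
raw-violating bins*: boundary bins must violate the threshold in the raw
signal, in an unbroken chain. Trimming merely to the outermost raw
violators is not enough — when th3 is a quantile of the non-{0,1}
mappability mass, a large fraction of scattered background bins raw-violate
by construction, and isolated violators in the smeared margin would pin the
boundary bins away from the true edge. The refined segment is emitted only
if it is strictly longer than 500 bp (a 500 bp segment is excluded — "larger
than" is read literally) and its raw mean still violates the threshold.
This keeps recovered boundaries within one bin of planted window edges
(asserted in the acceptance tests) while honouring both readings of
"average value" (smoothed for detection, raw for verification).

**Quantiles.** All thresholds use the linear-interpolation empirical
quantile (R type 7), stated here for reproducibility; at genome scale any
consistent definition moves a threshold by less than one bin-value gap.

**Flagging.** A variant overlapping several suspicious regions is judged
by the *maximum single-region* F-score, not the F against the union:
max-of-singles is order-independent and conservative (the union could only
raise recall artificially by concatenating unrelated regions). The 0.9 cut
is strict, as is the 0.7 pair cut.

**Pair quality.** How the catalogue's per-pair "mapping quality" relates
to the two mate MAPQs is genuinely open — a quality of 90 exceeds the
usual 60 cap of a single mate, suggesting a sum, but nothing forces that.
The default here is `min(mapq1, mapq2)` — a pair is only as trustworthy as
its worse mate — with `mean` and `sum` available as configuration. With
simulated mates at MAPQ 60 the default makes one supporting pair
insufficient (60 < 90) and two sufficient, which is the behaviour the
decision rule's own examples imply for well-mapped pairs.

**ROI containment.** "Both ends mapped within the region of interest" is
read as full containment of both aligned mate intervals, not merely their
start positions; pairs are extracted once (via their primary alignments),
with duplicates, secondary and supplementary records excluded. Mate
orientation is recorded but not filtered on.

**Duplicate merging.** Catalogue records sharing an exact locus collapse
regardless of subtype (deletion and loss are synonyms); the smallest
accession survives, sample lists and study labels are unioned. Whether the
original procedure also required matching study labels is unstated;
locus-only merging follows the catalogue's own definition of a duplicate.

**Multi-sample variants.** Each listed sample present in the manifest is
validated independently and one supporting sample suffices to call the
variant a true positive — one sample is the minimal requirement to verify
a supporting variant. Variants whose samples all lack alignment files are
reported `unresolvable` and excluded from verdict tallies.

**Size-distribution fit.** The false-positive size histogram is
multimodal on the log scale. Rather than fitting each visually separated
modality with its own Gaussian (a manual step), `summarize_results()` fits
a seeded 3-component Gaussian mixture to $\log_{10}(\text{size})$ by EM
with k-means initialisation; the log-likelihood is non-decreasing by
construction (asserted at run time) and component means are reported in
bp. Fewer than three distinct sizes skip the fit with a warning. The
chromosome-length correlation is Pearson's $r$ with the standard
$t$-transform p-value, computed over chromosomes present in the data and
reported as not-available below three chromosomes.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` builds, from `(config, seed)` alone: a GC track
($\mathcal N(0.41, 0.05^2)$ per bin, clipped), a mappability track (70%
exact 1.0, remainder near 0.97, a configurable exact-0 mass), a
coordinate-sorted indexed BAM, a DGV-style variant table with decoy rows,
a truth table and a manifest. Implanted features are snapped to the bin
grid, non-overlapping and ≥ 20 kb apart:

* **True deletions** (600–8000 bp) are homozygously excised from the donor
  genome: no read starts inside them, straddling fragments become
  deletion-spanning pairs, and reads that would cross a breakpoint are
  dropped (in reality they would be clipped). By default their profile
  windows stay at background, testing the screen's specificity; with
  `deletions_biased = TRUE` they also get extreme profile values and
  traverse the full suspicious-then-validated-true path (the end-to-end
  acceptance test uses this mode, since unbiased deletions are never
  flagged and would leave the true-positive arm unexercised).
* **Bias artifacts** (1500–8000 bp) get extreme GC or low-mappability
  profile values and their concordant fragments thinned to 20%, producing
  a genuine coverage valley with zero discordant support. The 1500 bp
  floor is deliberate: below roughly $2.3\mu/(2/0.7 - 1) \approx 1.2$ kb an
  ordinary concordant pair *can* span-match the window with F > 0.7, so
  sub-kilobase artifacts are inherently confirmable under the decision
  rule (see limitations) and would make the truth labels themselves wrong.
* **The exact-zero mappability mass** is laid down as a few contiguous
  repeat-like blocks (recorded in the truth object), not as i.i.d.
  scattered bins. Scattered isolated zeros are unlike real repeat tracts
  and would each smear into a >500 bp suspicious dip, making a clean
  background impossible by construction.

Not simulated: sequence content and errors, soft-clipping, PCR duplicates,
GC-dependent *continuous* fragment-rate bias (the thinning is a step
function), multi-chromosome genomes, and heterozygous deletions unless
`zygosity = "het"` is set. A green end-to-end test therefore establishes
that the pipeline's logic is correct on data obeying its model — not that
the model captures every artifact of real libraries.

Snapping implants to the bin grid is part of the stated world: a profile
track can only delimit a region at bin resolution, so a 600 bp variant
offset against the grid tops out at F ≈ 0.86 against a perfectly recovered
region and could never be flagged at 0.9. Real catalogues meet this
through the sheer size of most variants relative to one bin.

## Degenerate inputs and edge behaviour

Invalid intervals (end ≤ start) are rejected everywhere with an error;
cross-chromosome comparisons score 0 rather than erroring. Degenerate
value distributions (all equal) abort threshold selection; fewer than 100
usable values abort it too. Rows with inverted or non-numeric coordinates
in a variant table are skipped, counted, and warned about. Variants with
no resolvable sample are `unresolvable`, never `false_positive`. An
unindexed alignment file produces an instruction to sort and index, not a
partial result.

## Known limitations

* **Small variants and small artifacts are confounded.** For windows
  shorter than ~2.4× the mean insert size, concordant pairs lying inside
  the window satisfy the span-match cut; under the quality rule two such
  pairs confirm the "deletion". This is a property of the published
  decision rule, not of the implementation; the generator's artifact-size
  floor keeps the synthetic truth labels meaningful.
* **Flagging is deliberately strict.** F > 0.9 against a single recovered
  region means a variant whose region is recovered one bin wide of each
  edge can drop below the cut when the variant is short; occasional
  near-misses (F 0.88–0.90) are expected and visible in the worked
  example. Loosening the cut trades precision of the suspicious set for
  recall, as the published sensitivity analysis (0.65 / 0.75 variants of
  the pair cut) illustrates.
* **Homozygosity.** The default simulation and the decision logic treat
  presence/absence cleanly; heterozygous deletions halve the spanning-pair
  yield and add concordant coverage inside the span, which weakens but
  does not break the rule (the `het` mode exists for exactly this
  experiment).
* Split-read and DOC-based *calling*, bias *correction*, CRAM input, and
  catalogue web services are out of scope.
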