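---
title: "From splinkerette reads to common insertion sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From splinkerette reads to common insertion sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbscreen)
```

## The problem

In a transposon insertional-mutagenesis screen, a mobilised DNA transposon
(here piggyBac) scatters insertions across the genomes of many independent
lesions; insertions that recur near the same locus across lesions — common
insertion sites (CIS) — implicate candidate cancer drivers. The raw data
are splinkerette-PCR junction reads; the statistical core is turning those
reads into per-lesion integration sites and asking, per genomic region,
whether the local insertion density exceeds what uniform placement would
produce. pbscreen implements that pipeline end to end, together with the
sum-of-z-scores pathway-signature scoring used to connect candidates to
patient expression cohorts, and a synthetic-screen generator that provides
ground truth for every stage.

## Read structure and trimming

A splinkerette junction read is `barcode + transposon-end tag + genomic
fragment (+ adaptor tail)`. Demultiplexing matches the barcode as a
prefix-anchored Hamming comparison (no indels) because the primers place
barcodes at a fixed offset; a read matching zero or two-plus barcodes
within `max_mismatches` (default 1) is left unassigned — ambiguity is
treated conservatively to avoid sample bleed-through. Trimming then
removes the transposon tag (again within `max_mismatches`) and everything
from the first exact occurrence of the adaptor tail onward; mismatch
tolerance is deliberately not extended to the adaptor search, which in
practice only shortens a fragment by a few bases when it fails. Reads with
no tag, or nothing between tag and adaptor, are rejected with a reason;
fragments that still match the transposon reference (near-exact substring,
either strand) are discarded as transposon-only. The restriction-site
sequence (default `GATC`, Sau3A1) is carried as metadata only: sequencing
frequently stops before the adaptor, so fragments are not required to end
at the site. No quality trimming is performed.

## From alignments to integration sites

Alignment of trimmed fragments is external (bwa in the original protocol);
pbscreen consumes SAM/BAM or BED6. The integration position is the 5'
junction coordinate of the aligned fragment — leftmost aligned base on the
+ strand, rightmost on the − strand — and the orientation is the alignment
strand. Alignments under `mapq_min` (default 10) are dropped per record.
Identical calls collapse into sites whose read count is the group size.

Within each lesion and chromosome, sites within `merge_window = 5` bp
(inclusive, `|Δpos| ≤ 5`) are transitively chained — single linkage — into
one site, negating PCR-duplicate jitter. The merged site takes the
position and orientation of its best-supported member; ties break to the
leftmost position and then to the + orientation, making the operation
deterministic, idempotent and input-order invariant (both properties are
tested, including exhaustive equivalence with a brute-force union-find
oracle on all small configurations). Merging deliberately crosses
orientations, since duplicates can be recovered from either primer; the
dominant member's orientation wins.

Two filters follow, in a fixed order: donor-chromosome exclusion (local
hopping — reintegration near the donor concatemer — inflates density
there and would skew any genome-wide null), then an optional strictly-
greater read-depth cut (`read_count > 10`). The depth cut is off for CIS
calling, which uses the full merged site set, and on for candidate gene
lists; both uses mirror practice in published screens and both are plain
flags.

## CIS calling by Gaussian kernel convolution

For sites at positions $x_i$ on one chromosome, the smoothed insertion
density at scale $h$ is the unnormalized kernel convolution

$$f_h(x) = \sum_i \exp\!\left(-\frac{(x - x_i)^2}{2h^2}\right).$$

The kernel is left unnormalized on purpose: an isolated site has peak
height 1, so heights read as effective site counts, and any normalization
cancels in a permutation test anyway. $f_h$ is evaluated on a grid of
spacing $h/10$ spanning the sites ±4h. Numerically, each site contributes
only within $8h$ of itself; the truncation error per site is below
$e^{-32} \approx 1.4\times10^{-14}$, and the tests hold grid values to
direct per-point summation within $10^{-9}$.

Significance is empirical and adjusted within chromosome: for each
chromosome and scale, `n_permutations` (default 999) draws of the same
number of sites, uniform on the chromosome, give a null distribution of
the *maximum* peak height. An observed local maximum gets the add-one
estimator

$$p = \frac{1 + \#\{\text{null maxima} \ge \text{height}\}}{B + 1},$$

which can never be exactly zero, and is called when $p < \alpha$
(default 0.05). Because every peak on a chromosome is compared against the
null of the chromosome-wide maximum, multiple peaks are controlled
family-wise within the chromosome — conservative by design. Note the
strict inequality implies a minimum usable permutation count: with 19
permutations the smallest achievable $p$ is $1/20 = 0.05$, so at
$\alpha = 0.05$ no call can be made; 199 is the practical floor and 999
the default.

A call's window is the maximal contiguous grid interval around the peak
on which the density stays at or above the null threshold — the
$\lceil (B+1)(1-\alpha) \rceil$-th order statistic of the null maxima.
A called peak's height always exceeds that threshold, so windows contain
their peaks. When several significant local maxima share one
super-threshold segment, the segment is reported once with its highest
peak. Site and lesion support (`n_sites`, `n_lesions`) are counted from
sites inside the window; at coarse scales a peak can sit *between*
flanking sites whose kernels overlap, leaving the window itself empty of
sites — the triage stage therefore looks for support within the window
extended by the call's kernel scale.

The default scale triple {10 kb, 30 kb, 100 kb} brackets the window sizes
at which screens accept compact loci (tens of kb) and question diffuse
ones (hundreds of kb). Calls whose windows overlap across scales merge
into one locus represented by the member with the smallest p-value
(smallest scale on ties), with provenance preserved. Per-site weight is 1
regardless of read count or lesion multiplicity; lesion support is
reported for triage rather than used to down-weight.

The permutation seed for each chromosome × scale is derived
deterministically from the configuration seed, so results do not depend
on iteration order, and identical seeds reproduce byte-identical calls.
Two properties anchor the implementation: translation equivariance
(shifting all sites shifts tracks and windows exactly) and additive
superposition of densities; both are tested.

## Gene annotation and triage

A site is assigned to every gene whose body — the full transcriptional
span, introns included — contains its position (`start ≤ pos ≤ end`,
1-based inclusive; BED input is converted from 0-based half-open).
Overlapping genes all receive the site; no priority scheme is imposed.
Relative orientation (`same`/`opposite`) compares transposon orientation
with gene strand, a useful signal because activating insertions tend to
share orientation with their target. CIS windows list all overlapping
genes; a gene-desert window is annotated with the gene nearest to the
*peak* (distance-to-peak, not distance-to-window — the peak is the best
point estimate of the locus) and labelled `nearest`.

Triage encodes the candidate-strength rules screens apply narratively:

* `low_read_depth` — no supporting site exceeds `min_supporting_reads`
  (default 10; one deep site clears the flag, since a single
  well-amplified junction is real evidence);
* `large_span` — window longer than `max_span` (default 100 kb, sitting
  between the spans of loci screens have accepted and doubted; raw spans
  are always reported so users can re-cut);
* `multi_gene` — more than one overlapping gene (ambiguous attribution;
  a lenient switch tolerates it);
* `blacklisted` — any associated gene on a user-extensible blacklist,
  shipped with `Nav2` only, a locus recovered above random expectation
  across independent transposon screens;
* `single_lesion` — optional, support from one lesion only.

A CIS is `strong` iff no flag applies.

## Signature scoring of expression cohorts

For a genes × samples matrix (assumed normalized/log-scale), each
signature gene is z-scored across **all** samples using the population
standard deviation (divisor $n$ — the signature is descriptive scaling,
not inference), and a sample's score is the sum of its z-scores. Scores
therefore sum to zero over the full sample set, a property the tests hold
to $10^{-9}$. Genes missing from the matrix or with zero variance are
dropped and reported as coverage. Stratification splits samples at a
gene's median expression, ties going to `low` (deterministic and
documented; the natural-language rule "higher/lower than median" leaves
ties open). Association uses Spearman's rank correlation on mid-ranks
(exact p for n ≤ 10 without ties, t-approximation otherwise) and Welch's
unpaired t-test between groups; z-scoring is by default computed on the
full matrix before any stratification, with re-standardisation within
strata left to the caller.

## The synthetic generator

`simulate_insertions()` draws, per lesion: uniform background insertions
(Poisson counts at `background_rate` per Mb per chromosome), planted CIS
clusters placed uniformly within declared windows and spread over a
stated number of lesions, and local-hopping insertions confined to a
hotspot on the donor chromosome (hotspot centre defaults to the
chromosome midpoint; it is a free parameter because the donor locus
coordinate is a property of the mouse line, not of the method). Each
emitted site spawns, with probability `duplicate_rate`, a PCR-duplicate
record jittered uniformly on ±1..5 bp — never 0, so the merge stage is
genuinely exercised. Read counts are negative-binomial (default mean 60,
dispersion 2) with a `low_depth_fraction` contaminant drawn uniformly
from 1..9 reads, so the strictly-greater >10-read filter has something to
remove. Default sizes in the analysis scripts (40 lesions, a handful of
insertions per lesion) match the scale of a prostate screen on a
sensitised background, where insertion numbers are low. Lesions are
simulated independently — the real data's animal-level coupling between
lesions has no published generative description, so none is invented.

Positions live on an abstract integer coordinate line; no sequence is
needed until reads are simulated, at which point a uniform-random genome
is generated. The generator does **not** emulate TTAA-site snapping (the
merge and CIS statistics never use base composition and no TTAA
resolution is stated for the protocol), sequence-context insertion bias,
realistic Ion Torrent error profiles, or diploidy. Passing tests
therefore demonstrate the pipeline's statistical behaviour under its own
null and planted-signal models, not robustness to those data features.

`simulate_expression()` plants one latent factor shared, with loading
$a$, by a target gene and $m$ signature genes over independent Gaussian
noise (sd $s$). The target and the signature score are then bivariate
normal with Pearson correlation
$ma^2 / \sqrt{(a^2+s^2)(m^2a^2+ms^2)}$, and the implied population
Spearman correlation $(6/\pi)\arcsin(\rho_P/2)$ is reported as truth;
`loading_for_spearman()` inverts the relation in closed form so cohorts
can be generated at a chosen effect size.

## Calibration results and problem sizes

The test suite and `scripts/acceptance.R` recompute, at sizes chosen to
keep a full run in a couple of minutes on one CPU:

* kernel-vs-direct-summation agreement on 50 random sites (≤ 1e−9);
* type-I calibration on 200 null screens × 2 chromosomes at one scale,
  $\alpha = 0.05$, 199 permutations — the false-positive rate per
  chromosome×scale test stays below $\alpha + 2\,\mathrm{SE}$ (measured
  ≈ 0.02–0.045, consistent with the analytic rate of
  $9/200 = 0.045$ implied by the strict-inequality call rule);
* power on 100 replicates of a 20-site/10 kb cluster over 50 background
  sites on 10 Mb at $h$ = 10 kb (recovered 100/100);
* exhaustive merge-oracle equivalence (385 configurations) plus 1000
  random idempotence/order-invariance checks;
* an error-free 1000-read demultiplex/trim round trip (100% / ≥99%);
* recovery of a planted Spearman correlation of 0.6 at n = 500 within
  ±0.1.

## Known limitations

The permutation null is uniform within chromosome; it corrects for
chromosome length and site count but not for fine-scale insertion-site
availability (e.g. TTAA density or chromatin accessibility), which would
require a sequence-conditioned null. The analytic significance of the
original kernel-convolution formulation is not implemented — significance
here is always empirical. Cross-scale merging keeps a single
representative call per locus rather than modelling a 2D
position–scale surface. Gene assignment is body-containment only, with no
promoter or UTR awareness. None of these affect the interfaces: every
threshold, scale and rule discussed above is an exposed parameter.
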