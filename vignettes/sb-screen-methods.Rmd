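---
title: "Models and methods behind the sbdrivers screen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the sbdrivers screen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbdrivers)
```

This vignette documents the statistical models, the tunable parameters and
the design decisions in `sbdrivers`, in the spirit of a methods section: what
each stage assumes, why the defaults are what they are, and what the
synthetic data can and cannot tell you about real screens.

## The screen and its data

A Sleeping Beauty (SB) screen mobilizes a mutagenic transposon in somatic
cells of a sensitized mouse (here: Brca1-deficient mammary epithelium, two
transposon strains crossed with two mammary Cre lines). The transposon
carries a strong internal CAG promoter plus splice/polyA elements, so an
insertion can either *activate* a downstream gene fragment — when the
promoter points with transcription ("sense") — or *disrupt* the gene
regardless of orientation. Tumours are sequenced by splinkerette PCR, which
amplifies transposon–genome junction fragments; SB integrates exclusively at
TA dinucleotides, so every junction starts at a TA.

The analysis answers four questions: which genes are hit more than chance
allows (CIS discovery), which of those look activated vs disrupted
(orientation/clustering classification), where in the gene activation starts
(exon breakpoint), and which candidates track a human tumour subtype
(expression-binned incidence correlation).

## Junction-read processing

Reads have the fixed layout IRDR end (5'), genomic flank beginning at the TA
junction, splinkerette linker (3'). Processing parameters:

| parameter | default | rationale |
|---|---|---|
| adapter mismatch tolerance | 10% of matched length | common trimmer default; the IRDR and linker are known sequences, so only sequencing error needs absorbing |
| minimum genomic segment | 20 nt | shorter segments cannot map confidently |
| seed length | 25 nt exact | unique in any genome of the sizes used here; keeps lookup index-free via `Biostrings::matchPDict` |
| mismatch budget | 3 over the full segment | matches the bounded-mismatch alignment criterion of short-read mappers in this setting |

Reads failing a step are rejected with a reason (`no_transposon`,
`no_adapter`, `too_short`, `ambiguous_map`, `too_many_mismatches`); the
reasons partition the non-accepted reads, so per-stage accounting is
conserved — a property the tests assert.

The orientation convention is a fixed 2×2 table: the transposon orientation
is `+` exactly when (IRDR end is `R`) equals (mapped strand is `+`). The
read simulator uses the same table, so the *pairing* is testable
(reads from both transposon ends of one insertion must decode to the same
orientation) even though the absolute labels are a convention. Coordinates
are 1-based inclusive throughout, with the site reported at the T of the TA.
Deduplication uses an exact-position merge window of 0 bp by default
(1-bp-apart sites remain distinct); a wider window is available but
unnecessary at the simulated duplication rates.

Real data enters as pre-mapped insertion tables (`read_insertions()`); full
short-read alignment to a reference genome is deliberately out of scope —
the exact-seed locator is designed for the package's synthetic references.

## CIS discovery

The null model is uniform insertion: the count in a window of width $w$ out
of $N$ insertions over an effective genome of length $L$ is
$X \sim \mathrm{Poisson}(\lambda = N w / L)$, and the CIS p-value is the
upper tail $P(X \ge k)$. This is a deliberate, transparent reconstruction of
concatemer-free CIS statistics on gene-centric windows; it ignores TA-site
density variation and insertion-site biases, which is why the recurrence
filter, not the p-value, carries the main specificity burden. Windows are
the gene body plus 3 kb upstream on the promoter side (strand-aware); a site
overlapping two genes' windows counts for both, mirroring annotation by
interval overlap. Retention uses raw $p < 0.05$ to mirror the screen's
stated filter; Benjamini–Hochberg q-values are reported for modern use.
$L$ defaults to the sum of the catalog's chromosome lengths; for real data a
mappable-genome length can be supplied.

The recurrence filter keeps genes recurring in at least $\theta = 5\%$ of
tumours in *both* transposon strains, with an inclusive boundary ("at
least"). The two strains' donor concatemers sit on different chromosomes,
and local hopping inflates insertion density only on the donor chromosome of
the strain carrying it, so donor artifacts fail the filter in the other
strain. Donor-chromosome insertions are therefore *retained* by default
(an `exclude_donor` flag exists). Per-strain fractions are computed within
each Cre group over that group's tumour roster, and both strains must pass.

## Driver classification

For the insertions in a gene's extended region:

* **sense fraction** $f = n_\mathrm{sense}/n$, tested against 0.5 with an
  exact two-sided binomial test (minimum-likelihood rule: sum of all outcome
  probabilities not exceeding the observed outcome's probability, with a
  $1+10^{-7}$ relative guard for floating-point ties — the same convention as
  `binom.test`, against which the implementation is cross-checked).
* **cluster score**: the largest fraction of insertions inside any sliding
  window of width 20% of the region. The maximum over all windows is
  attained at a window whose left edge sits on an insertion, so the scan
  over insertion-anchored windows is exhaustive (asserted against a
  brute-force all-starts oracle in the tests).
* **rule**: `ONCOGENE` iff $f > 0.5$, $p < 0.05$ and cluster $\ge 0.5$;
  `TSG` iff no sense bias ($p \ge 0.05$ or $f < 0.5$) with at least 5
  insertions; otherwise `AMBIGUOUS` (including the sense-biased-but-dispersed
  conflict case).

The 0.2 window fraction, 0.5 cluster threshold and 5-insertion minimum are
package choices: the screen literature describes clustering qualitatively,
so the smallest defensible test at the conventional $\alpha = 0.05$ plus
explicit, configurable geometry thresholds was preferred over an opaque
composite score. The sense-fraction denominator is all insertions in the
extended gene region; applied to a reported hotspot count pair (100 sense of
136) the same statistic gives 73.5%.

## Exon breakpoint

Normalized exon expression is $e_i = c_i/(T\,l_i)$ (counts over library size
times exon length), rescaled by $10^9$ for readability; the estimator uses
only ratios, so the scale is immaterial and the tests assert depth- and
length-invariance instead of absolute values. With mean profiles
$\bar e^{tr}, \bar e^{ct}$ and $r_i = \log\!\big((\bar e^{tr}_i +
\varepsilon)/(\bar e^{ct}_i + \varepsilon)\big)$, the breakpoint is

$$b^* = \arg\max_{2 \le b \le n}\; \overline{r}_{[b,n]} - \overline{r}_{[1,b-1]},$$

with the smallest $b$ on ties, reported only when the implied
downstream/upstream fold $\exp(\cdot)$ reaches `min_fold = 2`. The
pseudocount $\varepsilon = 10^{-8}$ guards zero-count exons and is
negligible at the default $10^9$ scale. This two-segment mean-shift scan is
a reconstruction — the exon plot it mirrors defines no estimator — and it is
verified against an independent re-implementation on random instances.

## Subtype-incidence correlation

Patients are ranked by a gene's expression (ties broken by stable patient
order) and cut into $k$ contiguous cohorts whose sizes differ by at most
one; the first $n \bmod k$ cohorts (lowest expression) absorb the remainder,
so e.g. $n = 1898$, $k = 10$ gives eight cohorts of 190 and two of 189.
$k = 10$ is used for full cohorts and $k = 6$ for BRCA1-mutant subsets
(the subset sizes reported for such cohorts are an order of magnitude
smaller). Cohort rank is correlated with the per-cohort TNBC proportion by
Spearman's $R$ — chosen because rank correlation is the convention for
monotone dose-type relationships and needs no linearity assumption; Pearson
is available behind a flag. The two-sided p-value enumerates all $k!$
orderings exactly for $k \le 8$ (feasible and exact, including ties via
average ranks) and uses the $t$ approximation otherwise. A constant
proportion vector is degenerate by decision: $R = 0$, $p = 1$, direction
`none`. Correlating against cohort index rather than median cohort
expression is equivalent in rank for monotone binning, which is the case by
construction.

Consensus across two databases requires $p < \alpha$ in both *and* matching
sign; $\alpha = 0.05$ is the package's choice of "good correlation".
Orthologue mapping keeps strict one-to-one pairs and logs unmapped,
one-to-many and many-to-one entries.

## What the synthetic data emulates — and what it does not

The generators define the package's study conditions:

* **Catalog / screen** (coordinate-only default): 5 chromosomes × 25 Mb,
  60 genes of 10–30 kb, 100 tumours per strain in one Cre group, background
  rate 50 insertions per tumour, hopping factor 3 on per-strain donor
  chromosomes, driver penetrance 0.2. The geometry keeps the per-gene null
  mean at $\lambda \approx 2$, matching the real-screen regime where a gene
  window is a vanishing fraction of the genome; the per-tumour insertion
  count is not published for such screens, so 50 is a configurable,
  realistic order of magnitude. Background insertion counts are Poisson,
  positions uniform (donor chromosome upweighted and renormalized),
  orientations fair coin flips.
* **Reads** (sequence-backed mode): 4 × 500 kb random chromosomes; reads of
  150 nt (the platform read length), flanks 40–90 nt so the linker always
  falls inside the read, substitution errors and transposon-less
  contaminants at configurable rates. Insertions sit on TA sites only when
  sequence is available; coordinate-only mode allows any position to keep
  genome-scale CIS simulations fast.
* **Exon counts**: Poisson counts with mean `depth × length × mu`, fold
  step (default 8) downstream of the planted exon in trapped samples only;
  default depth yields ≳50 reads per exon.
* **Patient cohorts**: logit-linear link
  $\operatorname{logit} P(\mathrm{TNBC}) = \operatorname{logit}(0.15) +
  s\,(\mathrm{percentile} - 0.5)$ with default slope $s = 2$; baseline 0.15
  reflects the typical TNBC share of unselected breast-cancer cohorts.
  Receptor triples are drawn consistently with the TNBC flag; a basal flag
  co-occurs with TNBC; a BRCA1-mutant flag is independent at rate 0.1.

All generators require an explicit seed and are deterministic given one, and
every simulated output carries a ground-truth sidecar for recovery scoring.

Not emulated: TA-density and chromatin-accessibility insertion biases,
concatemer-local hopping *gradients* (the model is a flat per-chromosome
multiplier), PCR duplication and depth variation in junction libraries,
indels and quality-score error models, expression dosage beyond the single
step, population structure or batch effects in the patient cohorts.
Passing tests therefore demonstrate that the *algorithms* recover planted
structure under the stated stochastic model — not that real screens are free
of the biases above; on real data the Poisson null in particular is
anti-conservative in TA-dense regions.

## Numerical choices and degenerate inputs

* Poisson tails via `ppois(k − 1, λ, lower.tail = FALSE)`; $k = 0$ returns
  exactly 1; agreement with direct mass summation is asserted to $10^{-12}$
  for $\lambda \le 50$, $k \le 200$.
* Exact binomial and permutation enumerations use a $10^{-7}$ relative (or
  $10^{-9}$ absolute) guard when comparing real-valued statistics for
  "at least as extreme", absorbing floating-point ties without changing any
  exact rational answer.
* Empty insertion tables scan to an empty result (not an error); a strain
  with zero tumours makes recurrence fractions undefined and is an error;
  missing seeds are errors everywhere by contract.
* Ties: smallest breakpoint index wins; candidate tables sort by p then
  recurrence; binning breaks expression ties by stable patient id.

## Problem sizes in the test-suite and acceptance script

The suite runs the full study conditions at sizes chosen to make the Monte
Carlo bounds meaningful while keeping a complete run on one CPU in a few
minutes: 50 replicate screens for driver recovery (sensitivity ≥ 90%, zero
false candidates), a ~10⁴-read zero-error round trip (≥ 99% exact recovery,
zero spurious sites), 100 breakpoint replicates (≥ 95% within ±1 exon),
1000 null genes for correlation calibration (rejection rate within 3 Monte
Carlo s.e. of 5%) and 200 effect-gene simulations for signed power (≥ 90%).
`scripts/acceptance.R` recomputes the same quantities (with 10 screen
replicates) from a fresh seed and writes them as JSON.

## Known limitations

The CIS statistic is a uniform-genome reconstruction, not a reimplementation
of any published CIS caller; counts such as how many genes a real screen
yields depend on the real data and mapping pipeline and are not reproduced
here. The classifier's thresholds are explicit but heuristic; genes with few
insertions are deliberately left `AMBIGUOUS`. The breakpoint detector
reports no significance beyond the fold gate. The correlation screen treats
cohorts as independent binomials and carries no covariate adjustment.
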