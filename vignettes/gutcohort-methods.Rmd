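---
title: "Methods and design of gutcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of gutcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutcohort)
```

gutcohort analyses shotgun-metagenomic gut-microbiome cohorts: who shares
sequence content with whom, which resistance and virulence genes are
carried, which taxa are core to a population, and how much a person's
community moves over space and time. This vignette records the models and
the design decisions behind each stage, including the places where a
convention had to be chosen.

## The genetic-similarity statistic

For a pair of samples the package computes a *genetic similarity* (GS) from
repeated 31-mer sketches. Each sample's sequences are reduced to the set of
canonical 31-mers (the lexicographic minimum of each window and its reverse
complement; windows containing non-ACGT characters are skipped). For
repetition $i$ of $R$ (default $R = 10$), a sketch of up to $s$ k-mers
(default $s = 10{,}000$) is drawn and the number of shared k-mers $N_i$
between the two samples' sketches is counted:

$$\mathrm{GS} = \frac{N_1 + N_2 + \dots + N_R}{N_{\mathrm{sum}}},$$

with $N_{\mathrm{sum}} = R \times s$ ($= 100{,}000$ at the defaults) when
both samples fill every sketch.

**How "random" sketches are drawn.** Each repetition keeps the $s$ k-mers
with the smallest values under a seeded hash, salted by the repetition
index (a bottom-$k$ MinHash sketch, the same construction used by the
standard sketching tools in this field). The draw is therefore a pure
function of the k-mer *set*, so two samples with identical content receive
identical sketches and score exactly GS = 1. The alternative reading —
independently resampling 10,000 k-mers per sample — would give GS far
below 1 even for identical samples (two independent draws of $10^4$ from
millions of k-mers barely overlap), which would contradict GS's use as a
similarity scale on which within-person values around 0.2 are "high" and
between-person values below 0.1 are "low". The bottom-$k$ reading is the
only one under which the statistic behaves as a containment estimate.

**Unsaturated sketches.** When a sample holds fewer than $s$ distinct
k-mers, the whole set is the sketch and the denominator becomes
$\sum_i \min(|a_i|, |b_i|)$. This keeps GS within $[0,1]$ and
$\mathrm{GS}(a,a) = 1$ for arbitrarily small inputs, and reduces to
$R \times s$ exactly in the saturated case.

For sets of equal size with true containment $c$, the sketch estimate is
very slightly biased low (the effective hash threshold is the minimum of
the two samples' $k$-th order statistics), on the order of 0.5% relative
at the default sizes — well inside the ±0.02 envelope the tests enforce
against an exact set-intersection oracle.

What to sketch is left to the caller: in the protocol this statistic comes
from, GS was computed on reads remaining after host and classified-taxon
filtering, a step upstream of this package.

## Gene screening

Virulence factors and antibiotic-resistance genes are called from
read-to-gene alignments in three steps, each with a strict inequality at
its conventional threshold:

1. **Identity filter.** Only alignments with identity strictly greater
   than 80% are kept. Identity is per *hit*, not per gene: the filter acts
   on alignments, and coverage is computed from the survivors. For SAM
   input, identity is $100 (a - m)/a$ with $a$ the number of M/=/X columns
   and $m$ the NM edit distance minus inserted/deleted bases (MD is used
   when NM is missing).
2. **Interval merge.** Surviving hits on a gene are merged as 1-based
   inclusive intervals; overlapping *and abutting* intervals merge,
   because per-base coverage is the underlying quantity. The merged total
   is the "match region".
3. **Presence call.** Coverage percent = 100 × match region / gene length;
   the gene is present only when coverage is strictly greater than 90%.
   Ninety covered bases of a 100 bp gene is an absent call.

Coverage pools all kept hits of a sample against a gene. Pooling is the
only reading under which >90% coverage is reachable from 150 bp reads, and
multi-mapped (secondary/supplementary) alignments are kept by default for
the same reason; a flag excludes them.

Bins of assembled contigs inherit a phylum label only when one phylum is
carried by strictly more than 50% of the bin's contigs, unclassified
contigs counting in the denominator.

## Community summaries

* **Core taxa**: present at ≥ 0.01% relative abundance in *every* sample.
  The floor is a per-sample abundance ("incidence" in the survey sense);
  prevalence is the cross-sample fraction above it. The coefficient of
  variation is computed over positive samples only, since volatility is
  quoted for samples that actually carry the taxon.
* **DRM screening**: a listed disease-related species is retained when its
  abundance is strictly above 0.1% in at least one sample. Whether
  per-sample positivity should use the same 0.1% or any nonzero detection
  is genuinely ambiguous in practice, so both are supported
  (`positivity =` argument); the default reuses the retention threshold.
* **Diversity**: richness S counts taxa at or above the detection floor
  (defaulting to the core floor, since no separate richness floor is
  conventional), Shannon H is computed in natural log on re-normalized
  detected taxa — the genus-level values around 1.3–1.4 reported for
  Bacteroides-dominated cohorts are only consistent with nats — and Pielou
  J = H/ln S, undefined at S ≤ 1.
* **Enterotypes**: a sample is ET_P when Prevotella exceeds Bacteroides,
  else ET_B. A dominant-marker rule was chosen over Jensen-Shannon
  clustering because it is deterministic, reproduces the described
  Bacteroides-type/Prevotella-type split including individuals whose
  enterotype flips over time, and requires no tuning. Ties go to ET_B, the
  majority state. The marker pair is configurable (e.g. phylum-level
  markers can be substituted).

## Dissimilarity, ordination and attribution

Bray-Curtis dissimilarity $d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k
(x_{ik} + x_{jk})$ underlies all community comparisons (computed via
vegan). PCoA is classical scaling of the double-centered squared
distances; Bray-Curtis is not Euclidean-embeddable, so negative
eigenvalues are dropped and their summed magnitude reported.

Group contrasts partition the strict upper triangle of the distance matrix
into within- and between-level pairs and compare the two lists with the
Wilcoxon rank-sum test. *Caveat, by design*: pairwise distances sharing a
sample are not independent, and the test is used descriptively, exactly as
is conventional for these violin-plot contrasts — no correction is
attempted. No multiple-testing adjustment is applied by default either
(raw P values are reported); `stats::p.adjust` can be applied downstream.

PERMANOVA is implemented natively from its definition:
$SS_{\mathrm{total}} = \sum_{i<j} d_{ij}^2 / n$, within-group sums
analogously per level, $R^2 = SS_{\mathrm{between}}/SS_{\mathrm{total}}$,
pseudo-F on $(a-1, n-a)$ degrees of freedom, and significance by freely
permuting sample labels with $p = (1+b)/(1+m)$, which can never report
zero. When the sample count admits no more permutations than requested
(n ≤ 7 at the default 999), the full permutation set is enumerated and p
is exact — this also serves as the bridge to the exhaustive oracle used in
the tests, where vegan's `adonis2` additionally cross-checks $R^2$ and F.
The factor sweep runs one *marginal* PERMANOVA per factor with free
permutation (no strata); a `strata` argument exists for nested designs but
is deliberately not the default, matching the way factor-attribution
lollipop summaries are usually produced.

Temporal pairs within a participant are classed *short* (consecutive
months, $|\Delta| = 1$), *long* ($|\Delta| > 6$ months) or *other*; a
six-month gap is "other", not "long".

**Stability.** A presence/absence feature is *individual-stable* for a
participant when present in every one of their samples, *cohort-stable*
when present in every sample of every participant, *time-stable* when
stable in at least one participant, otherwise *transient*. Virulence
factors get the softer conventional rule: present in strictly more than
60% of a participant's samples (3 of 5 fails, 4 of 5 passes).
Participants with a single sample carry no information about stability and
are excluded with a warning.

## The synthetic cohort generator

The generator exists so that every downstream statistic can be exercised,
with known ground truth, at desk scale. It emulates a two-arm design:
a cross-sectional survey over regions, locations nested in regions, and
participants nested in locations; and a longitudinal arm in which
participants are sampled monthly (the default pipeline configuration
follows the shape of a four-region survey with a small
participants × 12-month follow-up arm).

Log-abundances are additive:
$$\log w_{st} = \mu_t + r_{(s)t} + \ell_{(s)t} + u_{(s)t} + D_{(s)t}(m_s)
+ \varepsilon_{st},$$
softmax-normalized to percent per sample. The terms are taxon base
log-means, region, location and individual offsets, a per-participant
Gaussian random-walk drift accumulated over months, and per-sample noise.
Because effects are independent and additive on the log scale, each can be
switched off alone, and planted orderings (individual ≫ region; short
interval < long interval) are directly testable. The random walk gives
monotone expected dissimilarity growth with interval length — the
structure the short/long contrast asserts.

Default effect scales (log-SD units) were fixed once, as a caricature of a
real cohort in which the individual dominates spatial factors:
individual 1.0, region 0.3, location 0.15, noise 0.3, drift 0.15 per
month, 150 genera of which 30 are core. The first taxa are named
Bacteroides (highest base mean — the cohort is Bacteroides-dominated),
Prevotella and Bifidobacterium. A configurable fraction of participants
(default 0.15) is planted ET_P by boosting Prevotella through the
individual effect — so enterotype structure vanishes when individual
effects are switched off — with the boost (4 individual-SD) chosen so that
Prevotella actually dominates in most ET_P samples while occasional
month-to-month enterotype flips remain possible, as is observed in real
longitudinal cohorts. Yogurt consumers get a small Bifidobacterium boost
for the same reason.

Transient (non-core) taxa are detected in a sample only when their latent
log-abundance clears a taxon-specific cutoff calibrated so detection
happens with probability ≈ 0.6; with all randomness off every sample is
identical, as required of a degenerate configuration. Two enforcement
passes keep the planted truth exact: core taxa are lifted to the 0.01%
floor wherever a deep random dip would break the planted guarantee, and a
transient taxon that by chance satisfies the core rule everywhere is
knocked out of one sample (skipped in the deterministic regime, where
constant presence is the correct behaviour).

Gene truth plants each catalog gene as cohort-stable, individual-stable
(in a strict subset of participants), transient (never all samples of any
participant), or absent; present entries get coverage in [0.93, 1] and
identity in [85, 99.5], so the planted labels survive the strict screen
thresholds by construction. The hit emitter tiles reads over exactly
`round(coverage × length)` bases, with a final overlapping or clipped
read, so realized merged coverage equals the planted target to the base.
The containment simulator builds two k-mer sets sharing exactly
`round(c · n)` elements, making exact set intersection available as an
oracle for GS.

**What the generator does not emulate**: sequencing error and read-level
noise (abundance tables are generated directly, not via reads),
compositional zero-inflation beyond the threshold mechanism, taxon-taxon
correlation structure, uneven sampling schedules, or realistic phylogenetic
abundance distributions. Passing tests therefore demonstrate that the
statistics recover *planted* structure of the assumed log-normal additive
form, not that they are robust to every property of real gut data.

## Numerical conventions

* Coordinates are 1-based inclusive on the gene everywhere (BLAST-tabular
  convention; SAM positions converted on read-in).
* Kraken-style reports contribute the clade-level percent column at the
  selected rank by default; a flag recomputes percent from direct read
  counts, since either convention is seen in the wild. Low-abundance taxa
  are never dropped at the I/O layer — filtering is a downstream rule.
* All thresholds are strict inequalities (> 80, > 90, > 50%, > 60%, DRM
  > 0.1%) except the core floor, which is inclusive (≥ 0.01%).
* Ties in the enterotype rule go to ET_B; ties in hash values (probability
  ≈ $n^2/2^{53}$) would resolve by input order.
* The Wilcoxon wrapper enumerates exactly for ≤ 12 observations without
  ties and otherwise uses the normal approximation with tie and continuity
  correction; identical multisets report p = 1.
* Seeds: every generator and permutation test takes an explicit integer
  seed; a master seed derives per-stage child seeds by fixed offsets.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to make every check sharp but quick: containment
grids on $10^5$-k-mer universes at the full default sketch parameters, a
96-sample (4 regions × 2 participants × 12 months) longitudinal cohort
for effect-recovery and stability checks, 400 null datasets of 20 samples
for PERMANOVA calibration, 1,000 randomized interval fixtures, and a
200-pair coverage × identity grid for screen truth recovery. These sizes
are the package's own choice of a convincing-but-compact demonstration;
all of them scale up by changing the corresponding configuration values.

## Known limitations

* GS on real data depends on what was filtered before sketching; the
  package deliberately does not guess that step.
* The dominant-marker enterotype rule ignores every genus except the two
  markers; cohorts with a strong third driver would need a different rule.
* Group-contrast P values inherit the pairwise-distance dependence caveat
  above.
* PERMANOVA is one-factor (marginal); no sequential/partial multi-factor
  decomposition is provided.
* The Mantel test, sometimes used for the same attribution question, is
  not implemented; the PERMANOVA sweep covers that role here.
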