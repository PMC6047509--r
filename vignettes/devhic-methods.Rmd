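---
title: "devhic: methods and design notes"
author: "devhic maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{devhic: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`devhic` re-implements, as a tested R pipeline, the contact-map statistics
used to describe how three-dimensional genome organization emerges during
early vertebrate (zebrafish-like) development: insulation scores and TAD
border calling, aggregate TAD analysis (ATA), A/B compartment eigenvectors,
relative contact frequency curves, PE-SCAn pile-ups of super-enhancer hub
contacts, TAD synteny conservation from ortholog maps, spatial
co-expression statistics from sectioned RNA-seq, CTCF motif orientation at
borders, nucleosome dyad inference, Shannon-entropy expression-breadth
classification, and enhancer-promoter distance statistics. Upstream steps
(read mapping, matrix building, peak and motif calling, super-enhancer
stitching) are out of scope: peaks, motifs and super-enhancers are inputs
in their standard formats (BED/bedGraph/TSV, dense-text matrices with a
bins sidecar).

Because the original raw data are large external downloads, the package
ships a first-class synthetic data generator with *planted* ground truth.
Every downstream statistic is validated against what was planted.

# The synthetic contact model

`synthetic_spec()` fixes a toy genome and plants three structural layers.
For bins $i, j$ at separation $d$ on the same chromosome the contact
intensity is

$$\lambda_{ij} = \frac{N}{Z}\, d^{-\alpha}\,
  (1 + \tau\,[\text{same TAD}])\,
  (1 + \kappa\, E_i E_j)\,
  (1 + \eta\,[\text{both bins at hub anchors}]),$$

with Poisson counts, symmetrized; trans blocks get a uniform rate with the
same hub boost. $Z$ normalizes the expected cis total to the depth $N$.
Poisson (rather than negative binomial) noise is deliberate: the tests are
property-based and do not require overdispersion; an overdispersion knob is
a natural extension.

Defaults, and why:

* **Genome**: 2 chromosomes x 20 Mb at **20-kb bins**. 20 kb makes the
  conventional insulation parameters (window of 25 bins = 500 kb) apply
  verbatim and makes the 100-kb compartment binning an exact rebin factor
  of 5. The genome is big enough for the >5-Mb "far-cis" PE-SCAn filter,
  small enough that a full simulation takes seconds.
* **Depth** $N = 2\times10^7$ expected cis contacts. At this depth far-cis
  (>5 Mb) bin pairs carry an expected count of roughly 1-3, comparable in
  information content to the deeply pooled maps this kind of study
  analyzes; pile-up statistics over a few dozen anchor pairs are then
  measurements rather than coin flips.
* **TADs**: sizes uniform in 550 kb - 1.2 Mb, boundaries snapped to 100-kb
  multiples. Two reasons: (i) every domain is wider than the 500-kb
  insulation window, so the border caller's non-maximum suppression (which
  cannot separate minima closer than the window) is not structurally
  defeated; (ii) snapping allows compartment blocks to switch exactly at
  borders (next point). The median (~875 kb) sits between the zebrafish
  (~500 kb) and mammalian (~800 kb) medians.
* **Compartments**: $E$ is a block wave of amplitude 0.8 at 100-kb bins,
  constant over runs of consecutive TADs, flipping sign between runs with
  probability 0.4 (run lengths ~1.5-3 Mb). Compartment switches therefore
  coincide with a subset of TAD borders, as they do in real genomes. This
  matters: if compartment blocks float freely, their transitions create
  insulation dips far deeper than the TAD dips, and border recovery would
  measure compartment geography instead of domain structure.
* **Hub anchors**: 6 per chromosome, placed inside the chromosome's
  majority compartment, mirroring the fact that super-enhancers live in
  active (A) chromatin. Anchor pairs then share the sign of $E$, so the
  hub term is not confounded by the compartment term.
* **Stage series**: `stage_series()` multiplies $(\tau, \kappa, \eta)$ per
  stage; the canonical four-stage configuration
  `(1,1,1), (0,0,1), (0.3,0.3,1), (1,1,1)` emulates a developmental
  progression: structured before zygotic genome activation, structureless
  just after it, weakly re-established during gastrulation, and fully
  re-established at the latest stage. Hubs persist throughout, matching
  the observation that long-range enhancer hubs are independent of TADs
  and compartments.

`simulate_annotations()` derives every auxiliary input from the same
planted truth: GC ($0.40 + 0.05E + \mathcal{N}(0, 0.01)$) and replication
timing ($E + \mathcal{N}(0, 0.4)$) tracks; an active-mark track
($\max(0,E)$ plus noise); convergent motifs (forward within 8 kb inside
each TAD start, reverse inside each end, scores > 13) over a uniform
background; genes every ~80 kb with a TPM table containing planted
housekeeping (uniform across samples) and tissue-specific (one-hot)
expression rows; a sectioned expression matrix in which a gene adopts its
TAD's spatial archetype with probability 0.8 against a background sharing
rate of 1/10; MNase-like reads placed so that dyads reconstruct at
$\pm$150 and $\pm$300 bp around border motifs; an ortholog map to a
pseudo-species that preserves gene order and breaks synteny only at TAD
borders with configurable probability; and histone-peak/OCR/super-enhancer
interval sets. All randomness flows from the single spec seed.

## What the generator does *not* emulate

No loop extrusion or polymer physics, no overdispersed counts, no
unmappable-region structure beyond dead bins, no chromosome-territory or
Rabl geometry in trans blocks, no stage-dependent annotation changes
(peaks and motifs are stage-invariant). Passing tests therefore certify
the *statistics* — that each method recovers what was planted under
Poisson noise — not the methods' behaviour under every artefact of real
Hi-C data.

# Methods and numerical choices

**Observed/expected.** Per chromosome, the expected count at separation
$d$ is the mean over pairs in which both bins are live; zero-coverage bins
resemble strong borders and are masked throughout. O/E of an O/E matrix is
the identity on valid entries (each diagonal of an O/E matrix already has
mean 1), which the property suite asserts as idempotence.

**Insulation and borders.** `insulation_score()` uses the classic sliding
$w \times w$ inter-window square (default $w = 25$ bins; 500 kb at 20-kb
bins), normalized as $\log_2(\text{raw}/\text{chromosome mean})$. Windows
touching chromosome ends are masked; windows that lose pairs to dead bins
average over the remaining valid pairs (verified against a brute-force
double loop, exactly). Borders are local minima with dip depth — the mean
of the $w$ bins on each side minus the minimum — of at least
`min_strength` (default 0.1, the conventional threshold in log2 units);
minima within $w$ bins of a deeper minimum are suppressed, ties broken
toward the lower coordinate, so output is deterministic. The window-mean
dip depth was chosen over a two-endpoint second difference because it is
far less noise-sensitive at 20-kb resolution. Borders whose bin or either
flanking bin is uncovered are removed by `filter_borders()`.

**ATA.** Each TAD of length $L$ is extracted with $L/2$ flanks, so the
domain occupies the central 50% of the window; windows exiting the
chromosome are dropped. Windows are O/E-normalized before area-weighted
rescaling to 100x100 and averaging — averaging raw counts would let large
TADs dominate. Strength is the central 50% block mean over the mean of the
four corner blocks; it is exactly 1 on structureless matrices and
scale-invariant.

**Compartments.** Per chromosome (as HOMER does, avoiding cross-chromosome
artefacts): O/E, correlation matrix, eigendecomposition; among the first
three eigenvectors the one with the largest $|r|$ against GC content is
selected, and the sign is set so bins with positive values have the higher
mean active-mark signal. Pearson correlation is used throughout (standard
compartment practice). 100-kb bins with under half their fine bins covered
are masked during rebinning. The selected-PC search is limited to three
components because compartment signal, when present, dominates the top of
the spectrum, while an unbounded search over noise eigenvectors inflates
the best $|r|$ under the null.

**PE-SCAn.** For all same-chromosome anchor pairs separated by more than
5 Mb, the $(2r+1)^2$ O/E submatrix centred on the pair is averaged
(together with its transpose, making the pile-up exactly symmetric);
the background repeats this with both anchors shifted +1 Mb, and the
pile-up is divided by the background median. O/E is used for cis windows
because raw distance decay is visibly asymmetric across a +-200-kb window
at 5-20-Mb separations; the inter-chromosomal variant uses raw trans
counts (no decay to remove). A pair is used only if both its real and its
shifted windows fit on the chromosome, keeping the two passes
pair-for-pair comparable. Both anchors are shifted, following the
single-shift description of the procedure.

**Conservation.** Intra units are TADs, inter units strictly adjacent TAD
pairs; a gene pair is conserved when both orthologs lie within 1 Mb on one
chromosome of the comparison species (midpoint distance, species-A
midpoint distance for the strata). The ortholog map is made strictly
one-to-one on load by dropping any gene id seen twice. Per distance
stratum the larger pair class is subsampled (without replacement) to the
smaller, 100 times, and unit-level scores are averaged over draws; a unit
counts per draw only if it is represented in the drawn pairs. Note an
intrinsic property of the published stratum edges: the long stratum
(534-1212 kb) extends past the 1-Mb criterion, so even a self-comparison
is not guaranteed 100% there; the package's own self-comparison check
restricts strata to the conservable range.

**Co-expression.** Spearman correlations (average ranks) between gene
pairs separated by $d$ intervening genes, $d = 0..5$; a pair is
"correlated" above the chosen $\rho$ threshold (0.4/0.5/0.6). Per $d$ the
same-TAD correlated count is tested against the all-pairs correlated
fraction with the exact one-sided binomial tail
$P(X \ge x) = \texttt{pbinom}(x-1, n, p_0, \text{lower} = \text{FALSE})$
(one-sided, since the hypothesis is enrichment), and the per-$d$ p-values
are combined with Fisher's method, $X^2 = -2\sum\ln p_d$ on $2k$ degrees
of freedom. Distances with no same-TAD pairs are excluded and flagged.
Because the null probability is a plug-in estimate from a superset that
includes the tested pairs, the test is slightly conservative when same-TAD
pairs dominate; the calibration check therefore uses a sparse-TAD layout
(about 10% same-TAD pairs), where the rejection rate under an i.i.d. null
is close to nominal.

**Regulatory statistics.** Promoters are H3K4me3 peaks within 2 kb
(peak edge to TSS point) of a TSS; enhancers are H3K27ac peaks overlapping
H3K4me1 but not H3K4me3. The enhancer-promoter distance O/E relocates each
enhancer uniformly within a 1-Mb window around its midpoint (length
preserved, clipped to the chromosome, overlaps permitted), 100 times by
default, and reports $\log_2(\text{observed mean}/\text{expected mean})$.
Shannon entropy uses the standard definition on the normalized expression
vector, $H = -\sum p \log_2 p$ with $0\log 0 = 0$: uniform expression
maximizes $H$, so the highest-entropy genes are classified housekeeping
and the lowest tissue-specific. Published descriptions of this score
sometimes state the opposite polarity in prose; because that reading
contradicts the definition itself, the standard polarity is the default
and an `invert` flag is provided rather than guessing silently.

**Nucleosomes.** Dyads are `pos + 73` for plus-strand reads and
`pos + length - 73` for minus-strand reads (equal to the conventional
`pos - 24` at the typical 49-nt read length); mapq > 10 and motif score
> 12 filters are applied on load when requested. Phasing histograms are
site-strand aware (minus sites flip offsets).

**4C viewpoint quantification.** The flank fraction is the signal within
+-15 kb of the viewpoint (half-open symmetric interval) over the total
signal in the containing TAD; paired stage comparisons use the paired
Wilcoxon signed-rank test.

# The pipeline

`run_all()` takes a YAML/list config (validated up front: every referenced
file must exist before anything is written) and executes, per stage:
insulation -> border calling -> coverage filtering -> ATA against the
reference stage's TAD calls (the latest, most structured stage by
default), compartment eigenvector at 100 kb, relative contact frequency,
and intra-/inter-chromosomal PE-SCAn on the super-enhancer anchors; then,
once: motif orientation at the reference borders, replication-timing
stratification by compartment, conservation, co-expression and entropy
classification. All outputs are TSV/BED/bedGraph plus a `summary.json`
that is byte-identical across reruns of the same config (all randomness is
seeded from the config; no timestamps enter the summary).

Functions, not a shell binary, are the interface; `write_synthetic_dataset()`
materializes a complete four-stage dataset plus config so the whole
pipeline can be exercised purely through files.

# Problem sizes used by the test suite

Module tests run on a reduced 2 x 8 Mb genome at depth 1.2e6; the
acceptance-style checks use the default study conditions
(2 x 20 Mb, depth 2e7). The random-anchor pile-up null uses depth 5e7 with
30 anchors per chromosome so that the Monte-Carlo error of the centre
value (~2-3%) is well inside the +-10% acceptance band; the co-expression
null calibration uses 200 simulations of 1000 i.i.d. genes over 8
sections. These sizes were chosen once for statistical adequacy and are
documented here as the package's own study design.

# Known limitations

* The border caller is an insulation-minima method; it does not reproduce
  segmentation-based callers (HiCseg/CaTCH) and no manual curation step
  exists, so absolute TAD counts on real data will differ.
* Matrix balancing (ICE) is not implemented; inputs are raw or O/E.
* Compartment calls assume per-chromosome PCA on O/E correlation; very
  small chromosomes (under ~10 Mb at 100-kb bins) leave too few bins for a
  stable eigenvector and are better excluded.
* The conservation score depends on the adjacency definition (strict
  shared border); gapped "neighbouring" TADs are not counted as adjacent.
* Whether published correlation matrices were computed on O/E or raw
  counts is ambiguous in the field; O/E is used here and flagged in the
  configuration.
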