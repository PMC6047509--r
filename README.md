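# devhic

Developmental Hi-C contact-map analysis with a planted-truth simulator.

During early vertebrate development the 3D genome is rebuilt from scratch:
topologically associating domains (TADs) and A/B compartments are present
before zygotic genome activation, vanish almost completely right after it,
and are slowly re-established through gastrulation — while long-range
super-enhancer hubs persist throughout. `devhic` implements the
contact-matrix statistics used to describe this progression, for anyone
analyzing binned Hi-C maps across conditions or time points:

* **insulation scores** (sliding w×w inter-window square, `log2`
  normalized against the chromosome mean) with **TAD border calling**,
  coverage-based border filtering, and **aggregate TAD analysis** (every
  TAD plus half-length flanks rescaled to 100×100 and averaged; strength =
  center/corners);
* **A/B compartment eigenvectors** at 100 kb (per-chromosome PCA of the
  O/E correlation matrix, component selected by |Pearson r| with GC
  content, sign oriented by an active chromatin mark), and stratification
  of external tracks (e.g. replication timing) by compartment;
* **PE-SCAn** pile-ups of all pairwise super-enhancer contacts, far-cis
  (>5 Mb) and inter-chromosomal, normalized by a +1 Mb shifted background;
* **relative contact frequency** curves over exponentially spaced distance
  bins;
* **TAD synteny conservation**: fraction of TADs (and adjacent-TAD pairs)
  with an ortholog gene pair within 1 Mb in another species, stratified by
  distance and subsampled 100× to balance classes;
* **spatial co-expression**: Spearman correlation of neighbor gene pairs
  across cryosections, same-TAD enrichment tested per gene distance with
  exact binomial tails combined by Fisher's method;
* **CTCF motif orientation profiles** at borders, OCR motif enrichment
  over a shifted control, **nucleosome dyad inference** (+73 / −24 rule)
  and phasing profiles;
* **Shannon-entropy expression breadth** (housekeeping vs tissue-specific)
  and **enhancer–promoter distance O/E** via local 1-Mb shuffling;
* a **synthetic data generator** that plants TADs, compartment blocks and
  hub anchors in Poisson contact maps
  (`lambda ∝ d^-alpha (1+tau·sameTAD)(1+kappa·E_i E_j)(1+eta·hub)`), plus
  every auxiliary annotation (GC, replication timing, motifs, genes, TPM,
  sectioned expression, MNase reads, ortholog maps), so each statistic is
  testable against known truth;
* `run_all()`: a config-driven end-to-end pipeline over a stage series
  with deterministic, byte-reproducible summaries.

Coordinates are 0-based half-open everywhere (BED semantics); intervals
are plain data.frames; matrices are dense with a `chrom start end` bins
sidecar; BED/bedGraph I/O goes through rtracklayer.

## Worked example

Simulate the default study conditions (2 × 20 Mb genome, 20-kb bins,
planted TADs/compartments/hubs) and run the core analyses:

```r
library(devhic)

spec  <- synthetic_spec(seed = 1)   # planted truth fixed by the seed
m     <- simulate_hic(spec)
m
#> contact_matrix: 2000 bins, 41,728,814 total counts, 0 dead bins

ins     <- insulation_score(m, w = 25)           # 500-kb window
borders <- filter_borders(call_borders(ins, min_strength = 0.1), m)
nrow(borders); length(unlist(spec$tad_boundaries))
#> [1] 41      # called borders
#> [1] 41      # planted borders (all recovered within +-1 bin)

truth <- simulate_annotations(spec)
aggregate_tads(m, truth$tads)
#> ata_result: 39 TAD windows, strength 1.315

cp <- compartment_eigenvector(rebin(m, 1e5), truth$gc, truth$active)
abs(attr(cp, "gc_correlation_genome"))
#> [1] 0.968   # eigenvector tracks GC, as selected

pescan_intra(m, truth$super_enhancers)
#> hub_alignment: 20 anchor pairs, center enrichment 2.467
```

The insulation minima recover every planted border; ATA strength is well
above 1 (structured matrix; it is ~1.0 when the TAD term is switched
off); the compartment eigenvector correlates strongly with GC; and the
planted hub anchors show a clear PE-SCAn center enrichment over the
shifted background.

For the full stage series through files:

```r
cfg <- write_synthetic_dataset("my_run", seed = 1)  # matrices + BED/bedGraph/TSV + config.yaml
summary <- run_all(cfg)                             # writes my_run/results/
```

The `summary.json` reports, per stage, the border count, ATA strength,
compartment |r| with GC and PE-SCAn center values; on the default
four-stage series both structural metrics hit their minimum at the
structureless (post-ZGA analogue) stage.

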