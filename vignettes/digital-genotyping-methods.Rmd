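---
title: "Digital genotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital genotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digitag)
```

## The method

Digital genotyping (DG) is restriction-enzyme-targeted resequencing for
large, repeat-rich plant genomes. A methylation-sensitive enzyme with a
GC-rich recognition sequence — FseI (GGCCGGCC), or for denser assays
NgoMIV (GCCGGC) or HpaII (CCGG), a nested set sharing the CCGG core —
cuts predominantly in hypomethylated, gene-rich sequence. Each cut site
exposes two genomic flanks ("tags", one per side, default 33 bp, stored
5'→3' away from the site). Barcoded adapters are ligated to the cut
ends, samples are pooled, and short single-end reads of the form
`barcode + enzyme remnant + tag` are sequenced. Because repeat-rich,
pericentromeric DNA is heavily methylated, roughly 90% of repeat-flanked
sites are never cut, so sequencing concentrates on unique, gene-rich
tag space. The chloroplast genome carries no FseI site at all, so
plastid DNA — a large fraction of leaf DNA preps — consumes no reads
(`plastid_screen()`).

A tag observed in two inbred genotypes either matches exactly
(monomorphic), differs by substitution or small indel (a codominant
SNP/INDEL marker), or is present in only one genotype (a
presence/absence candidate, excluded from the codominant catalog).
Allele-specific read depths at each marker then give genotypes for
arbitrarily many barcoded progeny in a single lane.

## Coordinates, orientation, read layout

All coordinates are 0-based, half-open; palindromic recognition sites
are scanned on the forward strand only, each site yielding one left
("B") and one right ("F") template, the left one stored
reverse-complemented so every tag reads 5'→3' into its fragment, as
sequenced. Simulated reads carry `read_len + trim3` genomic bases after
the barcode and remnant; demultiplexing (`demultiplex()`) requires a
perfect barcode + remnant match (no mismatch tolerance), strips the
prefix, and trims `trim3` (default 1) bases from the 3' end, so
observations align exactly with `read_len`-bp digest templates and an
error-free simulation round-trips to its truth table bit-for-bit.

## Tag placement

Genome-wide tag placement uses an exact-seed bounded-mismatch matcher
(`place_tags()`, compiled): the reference is indexed by 7-mers
(mirroring a BLAST word size of 7), each tag is partitioned into
`max_mm + 1` segments so that any placement with at most `max_mm`
(default 3) mismatches must leave one segment exact, and candidates are
verified by full-length Hamming comparison on both strands. A tag is
*unique* when it has a single placement or its best placement beats the
second best by at least 2 mismatches; tests verify the matcher against
an independent exhaustive-scan oracle. Indel-containing placements are
deliberately not searched genome-wide: tags are anchored at known
restriction sites, so indels are detected only in the anchored
parent-A-versus-parent-B alignment (match +2, mismatch −3, linear gap
−5, preferring single-event explanations). Parent-B tags that fail
placement outright (an interior indel scrambles the Hamming tail) are
rescued by 7-mer sharing against the parent-A catalog and paired through
that same alignment; the default acceptance score of 15 reflects that a
3-bp indel in a fixed-length tag necessarily costs two gaps (one
interior, one compensating at the 3' end), scoring ~20–25, while
unrelated tag pairs score deeply negative.

## Genotype calling policies

`call_policy("initial")`: fewer than 4 reads → missing; allele ratio
above 4:1 → homozygous for the major allele; otherwise heterozygous.
`call_policy("refined")` tightens heterozygote calls, which draw only
half depth per allele: HET requires both alleles at least 3 times,
ratio below 15:1, and at least 15 reads total; homozygous requires a
dominating allele (minor below 3 reads or ratio at least 15:1) with at
least 4 reads; the ambiguous residue (total 4–14 with both alleles ≥ 3)
abstains to missing rather than guessing. A zero minor count is an
infinite ratio; exact ties at a homozygous decision go to allele A for
determinism. Matrix construction drops markers missing in ≥ 15% of
lines (strictly: 21/137 lines missing is dropped, 20/137 kept) and
removes markers with exactly identical segregation, keeping the
smallest physical coordinate.

The audit of calling accuracy (`audit_accuracy()`) works from
homozygous haplotypes, where only one allele should ever be sequenced.
Homozygous blocks are delineated as runs of at least 3 consecutive
concordant homozygous calls — the run length is our choice; the block
notion itself is inherent to the audit. Co-site marker-pair concordance
is reported over cells where both calls are homozygous (the regime the
audit addresses); an all-assigned-calls variant is reported alongside,
and is expectedly lower because residual heterozygous tracts produce
low-depth abstention asymmetries by design.

## The genetic map

Two-point recombination between markers uses only lines homozygous and
non-missing at both markers (H calls are ambiguous for two-point
counting in selfed RILs, so they are excluded). The observed
recombinant fraction R is corrected for selfing (r = R/(2(1−R)), the
fixation relation R = 2r/(1+2r) inverted) and converted to
centimorgans with the Kosambi function d = 25·ln((1+2r)/(1−2r)). The
physical marker order is the frame: the map is *not* re-ordered by
simulated annealing; markers lacking LOD > 3 support against both
physical neighbours are set aside, and genuine physical/genetic
discordance is surfaced by `detect_misassembly()` — a contiguous
cluster unlinked to its physical neighbourhood (r > 0.3) but tightly
linked elsewhere (r < 0.15, LOD > 3, other chromosome or > 10 Mbp away)
is flagged, with an inversion note when reversing the cluster lowers
the recombinant count against the target flanks. The r thresholds are
configurable defaults chosen to separate "unlinked" (r near 0.5 between
chromosomes) from "adjacent" (r near 0) regimes with 100+ informative
lines; LOD 3 mirrors the mapping threshold. Supercontig placement
minimizes total recombinants against framework markers and reports the
flanking interval; haplotype segmentation slides a 5-marker window at
90% identity (blocks in real material are "nearly identical", not
perfect) and reports block edges at the midpoint between the last
concordant and first discordant marker — in marker-sparse regions that
midpoint sits far from the last marker, which is the honest statement
of the resolution available.

## The synthetic-data generator

Every stage is tested against simulations with full truth tables
(`sim_config()`, `sim_parent_genomes()`, `sim_pedigree()`,
`sim_reads()`, `sim_allele_counts()`). The generator's defaults are the
study conditions:

* **Genome**: 3 chromosomes × 200 kb; the middle third of each is a
  block of ~600-bp repeat copies (1% per-copy divergence) emulating
  pericentromeric heterochromatin; FseI sites are planted every ~1.2 kb
  in the unique arms. Base composition varies in 500-bp blocks with GC
  drawn from 0.25–0.75, giving the flanking-window GC spread that the
  depth model acts on.
* **Methylation**: per-site Bernoulli — 0.90 for repeat-flanked sites,
  0.075 for unique-flanked (the documented ~90% and ~5–10%); a
  methylated site is blocked entirely (sites are cut or not cut; no
  per-cytosine model).
* **Parental divergence**: per-bp variant rate 1/289 inside tag flanks,
  15% of variants 1–3-bp indels (a typical inbred-cereal SNP:indel
  balance; the source reports combined SNP+INDEL rates only), plus 2%
  restriction-site knockouts generating presence/absence sites.
  Variants are spaced ≥ 4 bp so indel coordinate shifts stay
  independent; deletions never erode a recognition site (knockouts
  model that separately).
* **Pedigree**: single-seed descent with Poisson crossovers placed
  uniformly (no interference — interference enters only at the map
  function, applied at estimation time), default 1.2
  crossovers/chromosome/meiosis (≈ 120 cM per chromosome, the scale of
  the published sorghum map), 6 selfing generations (F7; residual
  heterozygosity (1/2)^6 ≈ 1.6%).
* **Depth**: negative binomial (dispersion 0.2) around
  `depth_mean = 41` × GC weight × per-template sequence-efficiency
  factor × per-sample pool factor (lognormal, CV 0.3, mirroring the
  documented ±31% pooling spread). The GC weight
  `exp(-gc_beta·max(0, gc − 0.45))` with `gc_beta = 8` reproduces the
  documented separation between high-depth (~45% GC) and low-depth
  (~61% GC) template groups; no functional form is documented, so an
  exponential above a pivot is our choice. The sequence-efficiency
  factor (lognormal, log-SD 0.75, fixed per template across all
  samples) models the documented observation that the same templates
  are consistently over- or under-sequenced beyond what GC explains;
  together these reproduce the > 40-fold depth spread. Heterozygous
  sites split depth binomially 1:1.
* **Protocols**: the default `"sheared"` protocol has no length bias —
  production templates are sheared to a uniform size precisely to
  remove it. `"double_digest"` (FseI × MseI) weights depth by template
  length (site-to-nearest-TTAA distance) through log-linear
  interpolation of anchors (65 bp → 0.02, 109 → 1.0, 148 → 0.55,
  286 → 0.22, 350 → 0.02), scaled so the optimal-length template sits
  at ~1.33 × `depth_mean` (the geometric centre of the 40–72× top
  tier); below 65 bp a hard 0.005 floor stands in for the size
  selection that removes small fragments almost entirely (a true zero
  would make "rarely sequenced" unfalsifiable). The 109-vs-286-bp
  anchor ratio of 4.5 encodes the documented ~4–6-fold preference for
  short templates.
* **Errors and junk**: per-base error 0.0075 in the genomic portion
  (so ~22% of 34-nt reads carry at least one error); a separate 12%
  junk fraction (corrupted barcode or remnant) models everything that
  fails the exact prefix filter, matching the ~88% usable-read rate.
  Barcode/remnant corruption and base-call error are deliberately
  separate knobs, since the pipeline filters them at different stages.
* **Determinism**: one master seed; every stage draws from a derived
  sub-stream, so a configuration reproduces byte-identical FASTQ.

What the generator does *not* emulate: real repeat-family complexity
(a single planted family), cycle-dependent quality profiles, PCR
duplicates beyond depth overdispersion, paired ends, or
reference-genome assembly error other than the misassemblies tests
plant deliberately. Passing tests therefore demonstrate the pipeline's
logic and its statistical behaviour under the documented biases, not
robustness to every artifact of a real flow cell.

## Numerical choices and degenerate inputs

Tags shorter than `(max_mm + 1) × seed_len` are searched with fewer
segments, guaranteeing completeness only up to proportionally fewer
mismatches; bases outside A/C/G/T never seed and always count as
mismatches. Truncated templates at contig ends are emitted flagged, and
excluded from read simulation. `R ≥ 0.5` clamps to r just below 0.5
(Kosambi is undefined at 0.5); marker pairs sharing fewer than 20
informative lines return status `"unknown"` rather than an estimate.
Fold-range is the 97.5th/2.5th percentile ratio of per-template mean
depth among sequenced templates; the "short templates rarely
sequenced" fraction is depth-weighted (share of sequencing drawn from
sub-65-bp templates), since a per-template count would penalize the
very rarity being measured. The double-digest tier-length analysis is
demonstrated with GC and sequence-efficiency noise disabled, isolating
the length effect the way the source experiment's per-length analysis
does; under full noise, tier membership mixes and the conditional
means flatten.

## Problem sizes used in the tests

The shipped test-suite simulations use 2–3 chromosomes of 80–200 kb
(hundreds of restriction sites, 50–100 markers), 137 RILs for
map-scale checks and 24 samples for read-level checks; these sizes
make every property measurable (binomial 3-SD bands, 3σ r-recovery,
planted-feature recovery) while keeping the whole suite around a
minute. All headline rates — the 99.7% expected-allele rate, the ~99%
F1 heterozygote rate, the > 40-fold depth spread, the GC group
separation — are recomputed from simulation at these sizes, not
asserted from constants.

## Known limitations

Genome-wide placement is mismatch-only by design; a true indel-aware
genome aligner is out of scope (tags are site-anchored). Presence/
absence candidates are catalogued but not used as markers. Depth-bias
correction during calling is future work — the bias module quantifies
it only. Multipoint maximum-likelihood ordering and QTL mapping are
deliberately absent: the physical frame plus two-point validation is
the method's stance, and QTL analysis requires external phenotypes.
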