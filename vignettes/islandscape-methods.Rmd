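---
title: "Models and methods behind islandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind islandscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandscape)
```

## The biological model

ZF-CxxC domain proteins — the H3K36 demethylase KDM2A is the motivating
example — bind DNA at nonmethylated CpG dinucleotides. Because methylation
of the cytosine blocks the interaction, and because most nonmethylated CpG
in a vertebrate genome is concentrated in CpG islands, such a protein is
expected to decorate essentially all nonmethylated CpG islands, regardless
of the transcriptional state of the associated gene, and to deplete its
substrate (H3K36me2) exactly there. islandscape implements the chain of
analyses by which this picture is established computationally:

1. **CpG-island prediction** from sequence (`detect_islands()`),
2. **ChIP tag profiling** around TSSs and across length-scaled islands
   (`tss_metaprofile()`, `scaled_island_metaprofile()`),
3. **peak calling and island occupancy** (`call_peaks()`,
   `island_occupancy()`),
4. **allele-resolved bisulfite analysis** at an imprinted island
   (`call_methylation()`, `classify_clones()`,
   `allele_enrichment_test()`),
5. **H3-normalised enrichment** and the paired promoter-versus-body test
   (`percent_input()`, `h3_normalize()`, `promoter_body_test()`),
6. **knockdown differential expression** (`volcano()`), and
7. **equilibrium/kinetic binding models** for SPR data (`fit_kinetics()`,
   `fit_steady_state()`).

A synthetic-data generator (`simulate_genome()` and friends) encodes the
same biology so that every stage can be exercised offline and checked
against known truth.

## CpG-island prediction

The classical sliding-window definition is used: windows of 200 bp that
satisfy GC fraction >= 0.50 and observed/expected CpG ratio >= 0.60 are
merged, and merged spans are trimmed (in 10-bp steps, always from the end
whose removal leaves the better margin) until the reported interval itself
passes all thresholds and is >= 200 bp. The O/E ratio is
`(#CpG x L) / (#C x #G)` with N bases excluded from all counts; windows
with more than 50% N are skipped. All four thresholds are exposed because
published island sets differ in stringency, and a stricter set is known to
miss bona fide nonmethylated islands — on the synthetic genome you can see
exactly this by raising `min_gc`/`min_oe` and watching "non-island" peaks
with island-like composition appear in the occupancy report.

The "strong versus weak" island distinction has no universal definition;
`island_strength()` offers a documented stand-in (length x O/E split at the
set median).

## The synthetic world

Sequences are drawn from a first-order Markov chain over A/C/G/T whose
C-row is scaled to hit a target CpG O/E while a fixed-point calibration of
the stationary distribution hits the target GC. Backgrounds default to GC
0.40 / O-E 0.2 (bulk vertebrate DNA, CpG-depleted by deamination of
methylated cytosines); islands default to GC 0.65 / O-E 1.0 and are
rejection-sampled to within 0.05 of target, so detectability is guaranteed
by construction rather than luck. Island lengths default to 1 kb; genes are
5 kb; a 60/20/20 split of TSS/TES/orphan islands mirrors the observation
that islands sit mostly, but not exclusively, at promoters.

The methylome gives both alleles of every background CpG methylation 1,
both alleles of a normal island 0, and an imprinted island maternal 1 /
paternal 0. An optional `mosaic_fraction` lets a fraction of background
CpGs be nonmethylated on both alleles, mimicking mosaically nonmethylated
weak sites; it defaults to 0.

ChIP tags are drawn from per-base multinomial weights:

* input and H3 (and H3K36me1) are uniform;
* KDM2A weight is `1 + fold x d(x)/d_ref` where `d(x)` is the
  nonmethylated-CpG density in a 200-bp window and `d_ref = 0.105` CpG/bp
  is the analytic density of a GC 0.65 / O-E 1.0 island — so `fold` reads
  directly as the island/background weight ratio, and a fully methylated
  island falls back to background exactly (methylation blocks binding);
* H3K36me2 is uniform times a `depletion` factor inside nonmethylated
  islands (imprinted islands get the half-way factor `(depletion+1)/2`,
  one bound allele and one not) and a further factor over expressed gene
  bodies, where it is replaced by H3K36me3;
* H3K36me3 is concentrated over expressed gene bodies.

No quantitative fold-enrichment or depletion magnitude is published for
these tracks; the defaults (fold 20, depletion 0.3, body gain 5) were
chosen once as magnitudes typical of a strong ChIP experiment and are free
parameters, not measured values. Fragment length defaults to 150 bp
(single-end tags; fragment size is rarely reported), and each tag's 5'
position is placed so the extended fragment covers the sampled midpoint.

What a green test establishes is therefore internal consistency: the
analysis stack recovers the biology that the generator encodes, at
realistic depth and noise. It does not establish anything about mappability
artefacts, copy-number variation, PCR duplicates, or antibody off-target
binding, none of which are modelled.

## Tag densities and profiles

A tag contributes coverage over its extended fragment
(`fragment_length` bp 3'-ward of its 5' end, truncated at the chromosome
start without shifting the 3' end). Densities are fragment-bp per bp; in
meta-profiles they are per anchor, averaged at each offset (TSS mode,
minus-strand windows reversed) or in scaled bins (island mode, island =
[0, 1] with flanks measured in island lengths — fixed-bp flanks can be had
by setting `flank_lengths` appropriately for a given island size, but
scaled flanks are the default because they keep short and long islands
comparable). Genes are deliberately not deduplicated when their windows
overlap: the profile is the plain average over "all promoters in a set".

`percent_input()` is a sequencing stand-in for ChIP-qPCR percent input:
library-size-normalised IP density over input density x 100. It is exactly
invariant to duplicating every tag in both tracks. H3 normalisation then
divides out nucleosome occupancy. The promoter-versus-body comparison is a
paired two-sided t-test on per-gene differences (pairing is the natural
choice since each gene contributes both amplicons; Welch's unpaired test
is available via `method = "welch"`). The degenerate all-differences-zero
case returns statistic 0, p 1 rather than NaN.

## Peak calling

A self-contained windowed Poisson caller is used (window 500 bp, step
250 bp): each window's IP fragment-midpoint count is tested against
`lambda = max(scaled input count, genome-wide background rate)`, p-values
are BH-corrected across all windows, and windows passing the FDR and a
2-fold floor are merged, with the summit at maximal IP coverage. This is
deliberately minimal — adequate for strong/weak discrimination on clean
simulations and fully testable, not a replacement for production callers
on real data. Occupancy counts an island as bound at >= 1 bp of overlap
(`min_overlap` exposed).

## Bisulfite analysis

Clones are full-length top-strand amplicon reads compared ungapped to the
reference (the generator produces exactly this; gapped alignment is out of
scope). Calls at reference CpG cytosines are C = methylated,
T = unmethylated, other = missing. Conversion efficiency is measured at
non-CpG cytosines, and clones under 0.95 are rejected — retained Cs from
failed conversion would otherwise masquerade as methylation. Clones are
classified methylated at >= 80% methylated CpGs and nonmethylated at
<= 20%; everything between is reported as partial (mosaic), never silently
dropped, and the percent-methylated figure is computed over classified
clones only. Allele-specific ChIP enrichment uses a two-sided Fisher exact
test on the 2x2 clone-count table.

## Binding model

A 1:1 Langmuir model throughout: measured affinities for one- and six-CpG
probes agree closely, so the domain engages a single CpG and no avidity
term is warranted. Association follows
`R(t) = Req (1 - e^{-(kon c + koff) t})`, `Req = Rmax c/(c + K_D)`;
dissociation decays at `koff`. `fit_kinetics()` does global nonlinear
least squares on log-scale parameters with a 5 x 5 multistart over
log-spaced `kon`/`koff` guesses (local minima are real in these fits), a
BFGS polish, and delta-method relative standard errors from the Hessian;
flat sensorgrams are refused rather than fitted. `fit_steady_state()` fits
the binding isotherm directly and flags series whose concentrations do not
bracket the half-maximal response, where `K_D` is an extrapolation. Both
report micromolar; mass-transport limitation is ignored. The published
fitting procedure behind the reference affinities is not described, which
is why both routes are provided; they agree within 2% on shared noise-free
data.

## Expression

Per-gene baselines are log-normal and independent of island association by
construction (binding tracks CpG, not transcription); replicate noise is
log-normal with SD 0.1 on the log2 scale (no published noise model; this
is a typical array replicate CV). The designated knockdown transcript is
scaled by `1 - knockdown_fraction`, default 0.6 (an ~60% mRNA decrease, as
in the motivating knockdown line). The volcano uses a pooled-variance
two-sided t-test on log2 values per transcript; the default simulation
uses 3 replicates (2 are supported but fragile at these noise levels).

## Numerical and design notes

* Coordinates are 0-based half-open everywhere in memory and on disk
  (BED); FASTA I/O goes through Biostrings, interval arithmetic through
  IRanges, all behind tibble-first interfaces.
* Determinism: every generator takes a `seed` and restores the caller's
  RNG state; identical config + seed gives byte-identical output. The
  Markov sampler consumes uniforms drawn in R so the C++ kernel inherits
  R's RNG semantics.
* The acceptance-style null calibration of the promoter-versus-body test
  runs 1000 replicates at the amplicon level (Poisson tag counts pushed
  through the same normalisation and test) rather than 1000 full genome
  simulations; the generative null is the same but the runtime is seconds
  rather than hours.
* Island placement failures (no room after 200 tries) and all degenerate
  inputs (all-N sequence, no-CpG amplicons, empty island sets, flat
  sensorgrams) raise explicit errors naming the offending piece.

## Known limitations

No paired-end tags, no sequencing-error model, no SNP-aware diploid
simulation, no repeat masking or mappability model, no HMM or
methylome-seeded island callers, no bottom-strand bisulfite chemistry, no
cooperative or mass-transport-limited binding models, and no microarray
pre-processing — expression enters as a ready-made matrix.
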