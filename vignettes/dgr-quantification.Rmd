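---
title: "Quantifying mutagenic retrohoming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutagenic retrohoming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrkit)
```

# The system being quantified

Diversity-generating retroelements (DGRs) mutagenize a target gene through an
error-prone cDNA intermediate: a dedicated reverse transcriptase copies a
template RNA and misincorporates bases specifically opposite template
adenines, and the mutagenized cDNA then replaces the homologous variable
repeat (VR) in the target. `dgrkit` implements the quantification layer for
experiments that reconstitute such a system in a tractable bacterial host:

1. **Context profiling** — estimating, for every NAN trinucleotide context
   (an adenine with its 5' and 3' neighbours), how often and into what the
   adenine is mutated.
2. **Codon fate** — the exact analytic distribution of codon outcomes under
   the adenine-mutation process, including stop-codon conversion and the set
   of accessible amino acids.
3. **Editing calling** — signature-gated quantification of DGR-mediated
   target editing from amplicon sequencing, plus repair-frequency arithmetic
   for colony-count assays.
4. **Tn-seq enrichment** — per-gene Output/Input enrichment of transposon
   insertion libraries with Mann-Whitney testing, and origin-recentered
   position/orientation maps.
5. **Synthetic data** — generators with known ground truth for every input
   the pipeline consumes, so each stage is exercisable without downloads.

# Conventions

Reads and templates live in **sense space** (the coding orientation of the
VR/reporter). The reverse transcriptase acts in **incorporated-base (cDNA)
space**: opposite a template adenine the cognate incorporation is T, and a
misincorporation is one of A, C, G. The two frames are related by Watson-Crick
complement — an incorporated C appears in a sense read as G. Context profiles
are reported in incorporated space (the frame in which misincorporation
spectra are usually quoted); `as_sense_profile()` is the pure relabelling to
sense space and is an involution.

A context triplet `XAY` is written 5'→3'; `X` is the "+1" base (immediately
5') and `Y` the "−1" base (immediately 3'), so the NAC family means "adenines
followed by a cytosine". All coordinates in the package are 0-based;
gene intervals are 0-based half-open.

# The misincorporation model

`misincorporation_model(p, spectrum, seq_error)` is both the simulation
ground truth and the estimation target:

* `p` — per-adenine misincorporation probability, either one number or a
  named vector keyed by context. The headline in-vivo value used throughout
  the examples is 0.3065.
* `spectrum` — the conditional distribution of the incorporated base given a
  misincorporation, over `{A, C, G}`; either shared or per-context. The
  in-vivo profile is dominated by C (59.3%), with G elevated specifically in
  NAC contexts (26.8%).
* `seq_error` — a uniform per-base error applied to every position (each
  wrong base equally likely). Default 0: quality modelling beyond simple
  floors is deliberately out of scope, and when FASTQ qualities are emitted
  they are constant Q37.

Independence is assumed across adenines, and non-adenine positions never
mutate except through `seq_error`. These are exactly the assumptions under
which the analytic codon-fate arithmetic below is valid.

# The 16-context synthetic template

`design_nan_template(order_seed, spacer_policy)` builds a template whose
adenines realize all 16 NAN contexts at least once. Triplets are joined with
non-A spacers (default policy `"gc"`, a 2-bp `GC` spacer, with leading and
trailing spacers so that no adenine lacks a neighbour). Adenines *inside*
AAN/NAA triplets unavoidably acquire additional contexts; with the default
policy these are CAA and AAG, both already members of the census, so the
template always shows exactly 16 distinct contexts (24 annotated adenines in
total). Every adenine occurrence is annotated and counted — contexts are
properties of positions in the sequence, not of the design intent.

Different `order_seed`s permute the triplet order while preserving the
context multiset, mirroring the use of reordered template variants to
decouple local context from broader positional effects:

```{r}
t1 <- design_nan_template(1)
t2 <- design_nan_template(2)
identical(context_census(t1), context_census(t2))
t1$sequence
```

# Codon fate: exact arithmetic, not simulation

`codon_fate()` enumerates all outcomes of a codon exactly (at most 4^3), so
the reported probabilities carry no Monte Carlo error. With the uniform
spectrum each specific substitution occurs at rate `p/3` and an adenine stays
with probability `1 − p`; at `p = 0.3065` these are 0.1022 and 0.6935, and
the classic worked example follows:

```{r}
ft <- codon_fate("AAG", p = 0.3065)
round(100 * ft$outcome_codons[["TAG"]], 2)   # AAG -> TAG
round(100 * stop_conversion("AAA", 0.3065), 2)  # AAA -> any stop
```

Internal values are exact; rounding to printed precision happens only at
presentation. Non-uniform spectra are accepted in sense space; a spectrum
measured in incorporated space is converted with `sense_spectrum()` (the
complement map), a mapping we define explicitly because the two frames are
easy to confuse.

`accessible_amino_acids()` answers the repertoire question — substituting
the adenines of AAC reaches 15 amino acids (14 beyond asparagine) and no stop
codon, whereas AAA can reach all three stops. This is why AAC-rich templates
diversify without risking truncation.

# Context profiling

`count_incorporations()` tallies, for every annotated adenine, the
incorporated base implied by each read (complement of the observed sense
base). Choices worth stating:

* The pooled misincorporation rate is **observation-weighted** (total non-T
  incorporations over total adenine observations), not an average of
  per-context rates. With a balanced template the two nearly coincide; with
  unbalanced context usage they do not, and the observation-weighted form is
  the one that matches read-level counting.
* Adenines are counted **per occurrence**: an adenine inside an overlapping
  motif contributes to every context it genuinely occupies.
* Template-edge adenines (no neighbour on one side) are excluded from context
  tallies but included in `position_ppm()` matrices.
* Indels are not handled in the counter: `anchor_and_trim()` rejects reads
  whose inter-primer segment length differs from the reference
  (`"length_mismatch"`) or that lack a primer (`"no_anchor"`), and reports
  rejection counts. Amplicons are fixed-length by construction, so this is a
  filter, not a loss.

`position_ppm()` returns per-position base probabilities (rows sum to 1,
suitable for probability-scaled logos); `aa_sampling()` translates observed
codons at expected AAN positions; `profile_concordance()` reports the
maximum per-context frequency deviation across replicate profiles, the
reproducibility check used for reordered-template designs.

# Editing calling

A read is called edited iff it carries the designed signature mutation (a
G-to-T co-transferred from the template) **and** at least one A-to-N change
at the reference's designated adenines. The two-condition gate is the point:
with a sequencing error rate `e`, a false call needs two independent errors
(one at the signature and one at an adenine), so the background is of order
`e^2` — far below the single-mutation noise floor that would contaminate an
ungated count. `editing_rate()` reports the gated fraction (also as reads
per million) and per-position mutation rates over designated adenines,
normalised by default to **total** reads (with `normalize = "edited"` as the
alternative, since both conventions appear in practice).

`design_vr_reporter()` provides a synthetic 18-adenine, AAC-rich reporter
with a signature site for simulation studies; it mimics the design logic of
an editing reporter, not any natural sequence. `repair_frequency()` is the
colony-assay arithmetic `(CFU × dilution / volume) / (OD600 × calib)` with a
configurable calibration (default 8×10^8 cells/mL/OD600, a conventional
*E. coli* value).

`pileup_rates()` applies the standard pileup quality floors (base quality ≥
30, mapping quality ≥ 20, no indel emission) to a tidy per-base alignment
frame, reproducing a filtered mpileup count without requiring binary
alignments.

# Tn-seq enrichment

The processing chain follows standard junction-sequencing practice:
`preprocess_reads()` strips terminal poly-G tails (runs of ≥ 10 G), requires
and removes the transposon junction `AAGAGACAG`, and keeps remainders ≥ 25
nt; `map_insertions()` places the 25-nt read prefix by exact, genome-wide
unique match on either strand (the analogue of demanding the aligner's
maximal mapping quality) and records the leftmost matched coordinate and
strand; `read_sam_insertions()` ingests externally mapped SAM instead,
keeping primary MAPQ-60 records. `normalize_rpm()` scales counts to reads
per million (sites sum to exactly 10^6 per library).

`gene_enrichment()` compares **site-level RPM vectors** (the union of sites
in the gene body; a site absent from one library contributes 0 there)
between Output and Input per gene:

* Fold change is the smoothed pooled ratio
  `(ΣRPM_out + 0.5) / (ΣRPM_in + 0.5)`; the 0.5-RPM smoothing keeps the
  ratio finite for genes empty in one library. No cross-gene renormalisation
  is applied, so a strongly selected gene slightly deflates every RPM in its
  own library — a few percent at realistic gene sizes, and visible in the
  worked example below.
* Significance is the two-sided Mann-Whitney U test on the site vectors,
  using the normal approximation with tie-corrected variance (ties are
  ubiquitous because absent sites are zeros). No continuity correction is
  applied, so comparing a library against itself yields p = 1 exactly. For
  small tie-free samples `mw_test()` switches to the exact null
  distribution; the implementation is verified against exhaustive rank
  enumeration for every sample-size split with n + m ≤ 12.
* Sites, not reads, are the test unit — the standard Tn-seq choice, since
  read counts per site are heavily dispersed.
* `call_hits()` applies the screen thresholds (≥ 2-fold in either direction
  and p < 0.05) to genes with at least `min_sites = 5` Input sites; a
  `"stringent"` preset applies 4-fold / p ≤ 0.01 instead.

`recenter_oric()` maps genome coordinates to signed circular offsets
`d = ((pos − oriC + L/2) mod L) − L/2`, a bijection onto `[−L/2, L/2)`, and
classifies each insert as pointing **away** from the origin iff
(strand `+` and `d > 0`) or (strand `−` and `d < 0`); sites exactly at the
origin are classed by strand (`+` → away) as a deterministic tie-break.
`orientation_preference()` bins the recentered axis and compares away vs
toward Output/Input enrichment per bin (empty classes report `NA`, never a
fabricated ratio), summarising whether the preferred strand flips across the
origin — the fingerprint of replication-linked orientation bias.

# The Tn-seq simulator

`simulate_tnseq()` places `n_sites` uniformly on both strands, draws Input
counts multinomially with uniform weights, and draws Output counts
multinomially with per-site weights

```
w = gene_weight(gene at site) × copy_gradient^(1 − |d| / (L/2)) × orientation(strand, side)
```

Both libraries total exactly `depth` reads. The copy-number term
interpolates **log-linearly** from `copy_gradient` at the origin to 1 at the
terminus; the biology only motivates a monotone decay from multi-fork
replication, so the functional form is our modelling choice (log-linear makes
the fold-excess per unit distance constant, the natural parameterisation for
a multiplicative effect). The orientation term multiplies away-pointing
inserts by `orientation_factor`, abstracting the replication-directionality
preference without simulating forks.

What the simulator deliberately does not emulate: realistic Illumina error
profiles, site-specific insertion biases, growth competition between
mutants, and read-level overdispersion beyond multinomial sampling. Passing
parameter-recovery tests therefore demonstrates that the estimators are
unbiased and correctly scaled under the stated sampling model — not that
they are robust to every pathology of real libraries.

# Problem sizes and numerical choices

The simulation studies in the tests and the acceptance script use sizes at
which binomial counting error is small but runs stay quick: 10^5 reads for
misincorporation recovery (≈ 2.4 × 10^6 adenine observations; 3σ on the
pooled rate ≈ 0.09 percentage points), 10^5 reads for editing-fraction
recovery, and a 10^6-bp toy genome with 50 tiled 10-kb genes, 2000 insertion
sites and 10^5 reads per library for the Tn-seq stage (≈ 20 sites and ≈
2 × 10^4 reads per gene). Stochastic assertions use 3-binomial-σ bands around
the analytically expected value under a fixed seed.

With a planted 10.5-fold selection advantage on one gene these settings
recover a fold change of ≈ 9.3–9.9 depending on seed: the ≈ 5–9% systematic
deficit is the RPM renormalisation effect described above (the selected gene
inflates its library's total), and is inherent to depth-normalised fold
changes rather than an estimator bug.

Other numerical choices: probabilities in `codon_fate()` are exact products
(conservation holds to 1e-12 and is asserted); PPM rows are renormalised
counts and sum to 1 within 1e-9; generator determinism is scoped (the
caller's RNG state is never disturbed, and the same seed is bit-reproducible);
the fold-change smoothing constant is 0.5 RPM in both numerator and
denominator.

# Known limitations

* The exact-prefix mapper is for fixtures and synthetic genomes; real
  genomes with repeats need an external aligner (ingest the SAM).
* Minus-strand "first mapped position" depends on read length when reads are
  longer than the 25-nt mapping prefix, exactly as in real first-position
  Tn-seq maps; the read emitter defaults to 25-nt fragments so round trips
  are exact.
* Genes are assumed non-overlapping in the annotation; a site in overlapping
  genes would be assigned to the first.
* Paired-end merging is out of scope (reads are assumed merged upstream).
* Statistical comparison of editing rates across conditions (replicate-level
  t-tests) is left to the user; the package reports the rates.

# Worked end-to-end example

```{r}
# profile a context-specific model and recover it
tr <- design_nan_template(1)
model <- misincorporation_model(0.3065, c(C = 0.593, G = 0.264, A = 0.143))
reads <- simulate_cdna_reads(tr, model, n = 20000, seed = 7)
prof <- count_incorporations(reads, tr)
round(100 * prof$pooled_rate, 2)
round(100 * misincorporation_spectrum(prof), 1)

# plant a 10.5-fold selection advantage and recover it
g <- toy_tn_genome()
sim <- simulate_tnseq(g, selection_model(gene_weight = c(gene007 = 10.5)),
                      n_sites = 2000, depth = 1e5, seed = 3)
enr <- call_hits(gene_enrichment(sim$input, sim$output, g))
subset(enr, hit, select = c(gene, fold_change, p_value))
```
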