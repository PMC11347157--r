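---
title: "Codon-resolution translation analysis with riboDwell: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-resolution translation analysis with riboDwell: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboDwell)
```

riboDwell implements the computational core of a codon-resolution
translatome analysis: when a tRNA modification enzyme is lost and specific
tRNAs (the initiator tRNA-iMet and tRNA-Gln(CUG)) are destabilised, three
measurable signatures follow. Ribosomes slow down on the codon read by the
depleted elongator tRNA (CAG), which elevates A-site footprint density
there; translational efficiency (TE) shifts for a subset of mRNAs; and
transcripts under two-uORF delayed-reinitiation control (the *Atf4*
architecture) gain main-CDS translation because scanning ribosomes
reacquire the initiator ternary complex more slowly. The package estimates
each signature from ribosome profiling, RNA-seq and tRNA-seq data, and
pairs every estimator with a generator of synthetic data with known ground
truth, so correctness is established by parameter recovery rather than by
eyeballing.

# The forward model of footprint data

## Dwell-weight elongation model

Elongation is modelled at steady state with no ribosome--ribosome
interference: the expected footprint density on a sense codon is
proportional to its dwell weight $w_c$ (dimensionless, 1 = baseline). A
footprint's A-site codon $(t, i)$ is drawn with probability

$$\Pr(t, i) \propto a_t \, w_{c(t,i)}$$

over all sense CDS codons of all transcripts, where $a_t$ is the relative
transcript abundance. This is deliberately the simplest forward model whose
parameter the occupancy estimator targets; queueing, collisions and
position-specific effects other than the optional initiation pause (below)
are outside its scope. Stop codons are excluded from sampling: a ribosome
with a stop codon in its A site is terminating, not elongating, and the
dwell table is defined over the 61 sense codons.

Footprint 5' ends are placed at the A-site first nucleotide minus a
length-specific offset. Footprint lengths default to the standard mammalian
monosome profile (28--31 nt with probabilities 0.2/0.4/0.3/0.1) with A-site
offsets of 15 nt for 28--30-mers and 16 nt for 31-mers; real protocols vary,
so both are plain arguments. Draws whose footprint would cross a transcript
boundary are resampled, which conditions the position distribution on
validity; with the default UTR lengths (60 nt) no CDS position is ever
invalid, so density remains exactly proportional to dwell weight where it
is estimated.

## Initiation pause and offset calibration

Offset calibration needs a landmark. Real ribosome profiles carry a strong
initiation peak: the first elongation cycle is slow, and for that ribosome
the A site holds codon index 1 (the codon after the initiator). The
generator therefore exposes `initiationPause`, a multiplier on the
codon-index-1 position weight. Its default is 1, keeping the steady-state
model exact for occupancy work; calibration examples and tests switch it on
(a value of 5 is typical of real start peaks). `calibrateOffsets()` then
recovers, per footprint length, the candidate offset (10--20 nt) that
maximises the number of footprints whose inferred A-site lands on codon 1.
Because simulated A-sites are codon-aligned, candidates that differ by a
non-multiple of 3 score zero and the recovery is exact, not approximate;
the per-length read floor (default 100) refuses to calibrate from noise.

## Occupancy estimation

`codonOccupancy()` uses a pooled-ratio estimator. For each transcript
passing a windowed read floor (default 64), positions within `trimCodons`
(default 5) of either CDS end are discarded to remove initiation and
termination structure, and the stop codon is never counted. For codon
identity $c$,

$$O_c = \frac{\sum_{(t,i):\, c(t,i)=c} n_{t,i}}
             {\sum_{(t,i):\, c(t,i)=c} \bar n_t},$$

with $\bar n_t$ the transcript's mean windowed count, i.e. the expected
count under uniform dwell. Summing before dividing keeps low-count
transcripts from dominating, unlike a mean of per-transcript ratios; the
profile is rescaled to mean 1 over observed codons. Multimapped footprints
are dropped by default (their codon assignment is ambiguous), with
fractional weighting available. Genotype comparison is per codon: Welch's
t-test across replicate occupancies, the null/WT ratio of means, and star
tiers at p < 0.05/0.01/0.001/0.0001. Replicate pairs with zero variance in
both groups are reported as p = 1 with a degenerate-variance flag rather
than an error.

# Translational efficiency

Counts are normalised with median-of-ratios size factors (the fallback to
total-count scaling, used only when no gene is zero-free across samples,
warns). Per gene, with $x = \log_2(\text{count}/sf + 0.5)$, the TE change is
the difference-of-differences contrast

$$\widehat{\Delta TE} = (\bar x^{fp}_{null} - \bar x^{fp}_{WT})
 - (\bar x^{rna}_{null} - \bar x^{rna}_{WT}),$$

with standard error from the four group variance-of-mean terms and
Welch--Satterthwaite degrees of freedom. The two assays may have different
replicate numbers (the motivating design was 3 footprint vs 5 RNA
replicates per genotype) and replicates are never paired across assays.

A design point worth making explicit: with three replicates per footprint
group, the plain per-gene Welch contrast has only ~68% power at a true
log2 fold change of 1 (mean 500, NB dispersion 0.05) — a closed-form
consequence of the per-gene variance estimate's 2 degrees of freedom. The
package therefore moderates the four group variances across genes by
empirical Bayes (`limma::squeezeVar`) before forming the contrast, the
standard remedy at this replicate scale; measured power rises to ~83% while
the null false-positive rate stays at the nominal 5%. `moderate = FALSE`
recovers the unmoderated contrast. Classification uses the raw p-value at
strict thresholds (p < 0.05 and |log2FC| > 0.5, so a gene exactly at 0.5 is
"unchanged"); BH q-values are emitted for the record but do not enter the
classification, matching the volcano-plot convention the thresholds come
from.

The NB count generator (`simulateTECounts()`) uses a common dispersion of
0.05 and a mean of 500 by default — typical well-expressed-gene values for
bulk libraries — and injects pure TE effects as footprint-only fold changes
in the null genotype.

# Delayed reinitiation and the Atf4 architecture

The two-uORF leader is parameterised by the uORF1 length, the spacer $d_1$
from the uORF1 stop to the uORF2 start, and the distance $d_2$ from the
uORF2 start to the main CDS start, with uORF2 overlapping the CDS out of
frame ($d_2 < \mathrm{len}(uORF2)$, $d_2 \not\equiv 0 \bmod 3$). Defaults
(uORF1 9 nt, $d_1 = 87$, uORF2 180 nt, $d_2 = 100$) give an Atf4-like
layout. Generation is constraint-checked: an impossible architecture (no
overlap, in-frame overlap, CDS shorter than the overlap) raises an error
naming the constraint.

After terminating at uORF1, a scanning 40S subunit reacquires the ternary
complex at each nucleotide independently with probability $q$ and initiates
at the next start codon it reaches, giving geometric tail masses

$$p_{uORF2} = 1-(1-q)^{d_1}, \quad
  p_{CDS} = (1-q)^{d_1}\!\left(1-(1-q)^{d_2}\right), \quad
  p_{none} = (1-q)^{d_1+d_2}.$$

uORF1 initiation is obligatory in the base model (no leaky scanning past
uORF1), which matches the mechanism's standard description; $p_{CDS}(q)$ is
unimodal on $(0,1)$ — exactly the "release under reduced ternary-complex
availability" behaviour. The per-nucleotide Bernoulli model is the minimal
one consistent with that narrative; nothing finer (e.g. distance-dependent
reacquisition) is identifiable from region counts. `fitReacquisition()`
maximises the multinomial likelihood in $q$ by bracketed 1-D optimisation
(a 2001-point grid locates the peak before refinement, because the
likelihood is sharply peaked and $-\infty$ plateaus flank it) and profiles
the likelihood for a 95% CI at the $\chi^2_1$ cutoff; all-uORF2 or all-none
counts return the boundary estimates $q = 1$ or $q = 0$ with a flag.

Region quantification attributes A-sites in the uORF2/CDS overlap to uORF2
only — a ribosome that initiated at uORF2 reads through the CDS start out
of frame — switchable to double-counting. The release statistic is the
null/WT ratio of per-genotype geometric-mean CDS/uORF1 density ratios;
uORF1 normalises out scanning flux, and the Welch test runs on per-replicate
log2 ratios. *Atf5*-like transcripts need no special casing: any second
annotated two-uORF transcript is processed identically.

# tRNA-seq quantification

Mature references are built by splicing annotated introns, appending the 3'
CCA when absent, prepending the His G-1, and collapsing identical mature
sequences into one record with a copy count. The read simulator draws an
isodecoder proportional to abundance and emits the full mature sequence,
optionally prepending one non-templated 5' nucleotide (probability
`p_extra5`, the reverse-transcriptase terminal-transferase artefact) and/or
dropping the terminal A of the CCA (probability `p_trunc3`); defaults are 0,
matching the error-free default elsewhere. `mapTrnaReads()` allows exactly
one soft 5' nucleotide by retrying unmapped reads with the first base
removed, so the artefact cannot break alignment, and end profiles tally the
5' category (-1 extra, 0 mature, +k truncated; the -1 row is always
reported) and the 3' category relative to the CCA terminus.

Multimapping is resolved explicitly: uniform 1/k splitting by default, or
expectation--maximisation over hit-set equivalence classes (fractional
assignment proportional to current abundances, iterated to a 1e-8 relative
abundance change or 100 iterations). Both conserve total mapped reads
exactly; the EM never decreases the multimap likelihood. Genotype
comparison is per isodecoder Welch on relative abundances with Sidak
family-wise adjustment $p_{adj} = 1-(1-p)^m$ — the per-species analogue of
a two-way ANOVA followed by Sidak's test, and the omnibus two-way ANOVA is
attached for reference. Isodecoders within one edit of another are
annotated, since assignment between such species (by short reads or
hybridisation probes alike) is unreliable.

# The mapper

The built-in mapper exists so the pipeline runs end to end without external
aligners: exact k-mer seeding (default k = 12) with pigeonhole-complete
multi-seeding — a read at least $k(m{+}1)$ nt long with at most $m$
substitutions always retains one exact seed — followed by full-length
mismatch verification, reporting all tied best hits with their multiplicity.
It is ungapped and sense-strand by default (stranded protocols), with
reverse-complement matching behind a flag, and is validated against an
exhaustive (reference, offset) scan. Externally aligned data enter through
a minimal SAM reader that accepts only ungapped records (pure-M CIGAR) and
the NH tag, because downstream coordinate arithmetic assumes ungapped
transcript alignments; anything else is rejected with an explicit message.
For large simulations the ground-truth origin records double as alignments
(`alignmentsFromReads()`), since simulated reads are error-free; the mapper
itself is exercised on oracle-checked inputs.

# What the synthetic data do and do not establish

The generators reproduce the features the estimators rely on: codon-level
dwell structure, footprint length/offset geometry, replicate count noise
(negative binomial), two-uORF leader architecture, isodecoder families with
targeted depletion, and non-templated tRNA end variation. They do not
emulate sequence error, ligation/PCR bias, nuclease footprint-boundary
heterogeneity, ribosome collisions, splicing isoforms, or genome-coordinate
structure. Passing recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to every artefact of
real libraries — which is the appropriate claim for a package whose real
inputs arrive as externally aligned SAM.

Problem sizes used in the shipped tests and acceptance script (chosen to
give comfortable statistical resolution at interactive runtimes): 200
transcripts and 1e6--2e6 footprints per sample for occupancy recovery, 2,100
genes for TE calibration, 1e5 ribosomes per scanning cohort, 40 isodecoders
at 2e5 reads per tRNA library.

# Numerical and edge-case policy

* Determinism: every simulator takes a seed and restores the caller's RNG
  state (`withr::with_seed`); identical configuration and seed give
  byte-identical output, including written FASTA/FASTQ/TSV.
* Degenerate variances (identical replicates) yield p = 1 plus a flag, never
  an error; all-zero count groups are flagged with finite estimates.
* Off-frame A-sites are assigned to their containing codon; A-sites outside
  the CDS are tallied (upstream/downstream) and retained for leader/uORF
  quantification, and the tallies always sum to the number of input
  alignments.
* Occupancy profiles are scale-invariant (library depth cancels) and
  normalised to mean 1 within 1e-9.
* `reinitProbabilities()` clamps $p_{CDS}$ at 0 against floating-point
  cancellation when $p_{uORF2}$ rounds to 1.
* Mann--Whitney comparisons use the exact enumeration when the smaller
  group has at most 8 members and no ties, otherwise the tie-corrected
  normal approximation with continuity correction.

# Known limitations

Single-isoform transcript models only (genes are transcripts); no E/P-site
tables, pause-site detection, or disome analysis; no GO/GSEA enrichment
(the TE gene lists are the hand-off point); TE inference is a moderated
contrast on log counts, not a full NB GLM — adequate and transparent at
this scale, but a GLM would pool information more efficiently near zero
counts; the scanning model treats reacquisition as memoryless and uORF1
initiation as obligatory by default (`uorf1Leak = 0`); the leak option
reroutes skipping ribosomes deterministically to uORF2 rather than
modelling their downstream scanning kinetics.
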