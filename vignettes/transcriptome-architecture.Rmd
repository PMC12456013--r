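---
title: "Inferring bacterial transcriptome architecture from end-enriched RNA-seq tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring bacterial transcriptome architecture from end-enriched RNA-seq tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txarch)
library(dplyr)
```

# The problem

A bacterial transcriptome is organised by three kinds of single-nucleotide
landmarks: transcription start sites (TSSs), transcript 3'-end positions
(TEPs), and the promoter and terminator sequence elements that create them.
Differential RNA-seq (dRNA-seq) locates TSSs by comparing libraries treated
with a 5'-monophosphate-dependent terminator exonuclease (TEX+), which
degrades processed 5' ends and thereby enriches genuine triphosphorylated
transcription starts, against untreated libraries (TEX-). Term-seq captures
transcript 3' ends; conventional RNA-seq coverage ties the two together into
transcription units (TUs). `txarch` implements this inference chain for a
single circular bacterial chromosome, plus a seeded generator of synthetic
genomes and tracks with a fully known planted architecture, so that every
stage can be scored against ground truth without any sequencing data.

The package is tidyverse-shaped: sites, TUs and motif hits are tibbles,
functions compose with the pipe, and results have `tidy()`/`glance()` and
`plot_*()` companions.

# End calling

A position `p` on strand `s` is a TSS peak when, in at least
`replicate_min_fraction` of TEX+/TEX- replicate pairs:

* the TEX+ 5'-end height is at least `min_height_rpm` (reads per million,
  normalised by the library's total mapped reads, not the track sum);
* the enrichment `(c+ + k)/(c- + k)` is at least `enrichment_min`, with
  pseudocount `k` applied to raw counts before normalisation;
* the height is a strict local maximum within `local_max_window` nt, ties
  resolved to the 5'-most position (3'-most for TEPs, following the reading
  direction of the respective end);
* mean RNA-seq coverage over the `downstream_support_len` nt on the
  transcript-body side of the end is at least `downstream_support_min_cov`
  RPM.

The last rule is an automated surrogate for the manual curation of candidate
peaks against coverage profiles that end-sequencing studies typically
perform; it is what removes isolated background spikes. TEP calling uses the
same machinery without the enrichment test. Defaults (1.5 RPM, 2.0-fold,
k = 1, +-2 nt, 0.5, 50 nt, 1 RPM) are typical of TEX-based callers and all
configurable through `peak_call_params()`.

Per-condition peak lists are merged across conditions with single-linkage
within +-5 nt (`merge_params()`), so a chain 100-104-108 collapses into one
site even though its extremes are 8 nt apart; the member with the greatest
height provides the representative position. Sites seen in two or more
conditions are labelled constitutive, the rest condition-specific. Merging
is idempotent and independent of input order, which the tests assert by
shuffling.

# Site classification

Categories follow the established dRNA-seq vocabulary. Each gene collects
same-strand TSSs from 300 nt upstream to 100 nt downstream of its start;
the highest-signal site is primary (P), others secondary (S). A site in two
genes' windows goes to the gene with the nearest 5' end (ties to the lower
start coordinate); equal heights resolve by proximity to the gene start and
then by 5'-most position. Unassigned sites are internal (I) on the sense
strand inside a gene body, antisense (A) within a gene body or its 100-nt
flanks on the opposite strand, and intergenic (N) otherwise, with
precedence P/S > I > A > N. TEPs mirror this on the 3' side (window 0 to
+300 nt past the gene end) and add a cis-regulatory (C) category for 3'
ends lying strictly inside a gene's 5'-UTR — the signature of
riboswitch-style premature termination. A gene without a primary TSS has no
defined 5'-UTR, so it cannot yield C calls; a primary TSS lying inside the
gene body likewise defines no UTR interval.

A transcript is leaderless when its 5'-UTR is at most 10 nt; "leadered"
UTRs (>= 10 nt) are scanned for a ribosome-binding site with an AG-rich
PWM over the 20 nt upstream of the start codon. UTR lengths for P/S sites
are clamped at zero when a site lies marginally downstream of the annotated
start, so that `utr_len` is always a length.

The classifier is verified two independent ways: against a brute-force
oracle that re-evaluates every category definition over all genes on
randomised layouts, and by mirror symmetry (reverse-complementing the
genome and flipping strands must leave categories and UTR lengths
unchanged).

# Transcription units

Every classified TSS seeds at most one TU with its nearest same-strand
downstream TEP within 15 kb (`pairing = "all"` relaxes this). The pair is
accepted when at least 80% of span positions carry >= 1 RPM RNA-seq
coverage and no sub-threshold run exceeds 50 nt. Nearest-TEP pairing was
chosen over all-pairs because, combined with internal and secondary
starts, it naturally produces several overlapping units per locus, which is
what TU-cluster statistics in end-sequencing studies reflect. Antisense and
intergenic TSSs also seed TUs (they may explain orphan transcripts) but
contribute no gene lists. TUs overlapping by at least 1 nt on the same
strand form clusters by single linkage; a strandless variant sits behind
`tu_params(stranded_clusters = FALSE)`. When calling TUs across a
multi-condition experiment, pool the coverage tracks (`pool_signals()`), as
`run_pipeline()` does — a TU active only in one condition must not fail
support for lack of coverage in another.

# Promoter models

Sigma-factor binding motifs are bipartite: an upstream (-35-side) and a
downstream (-10-side) PWM block separated by a short spacer with a prior
over its lengths. A placement's score is

```
score = logodds(up) + logodds(down) + log2 P(spacer)
```

in bits, with an extra +1 bit for SigA when the extended -10 "TG"
dinucleotide immediately precedes the -10 block (the TG element is scored
as a bonus rather than a third block because it co-occurs with, rather
than replaces, the core elements). The p-value of a hit is the probability
that a background-random word pair reaches the summed two-block score,
computed exactly by FIMO-style dynamic programming over integer-discretised
per-position scores (10^4 units per bit by default). The spacer prior
enters the score but not the null, so p-values compare like with like
across models with different spacer sets. Integerisation rounds each column
independently; the query total is shifted down by half a unit per column
before the tail lookup so p-values are never underestimated for words at
the distribution's atoms. Default thresholds are a 0-bit score floor and
p <= 1e-4; both are per-model choices surfaced in `sigma_model()`, since
no universal cutoff suits both a 12-position SigA model and an 8-position
SigH model.

Six default models ship with the package: SigA (TTGHHW / TATAAT, 17-nt
spacer, TG bonus), SigH (AGGA / GAAT, 17-18 nt), SigF/SigE/SigK
(B. subtilis-like block approximations with 14-15 nt spacers; these three
are stated approximations, fully replaceable), and the sigma-54-family SigL
(TGGCA-N6-TTGC, the -24/-12 elements with a rigid 6-nt spacer). Promoter
windows are the 50 nt upstream of the TSS, inclusive of position -1; each
model is scanned independently, so one TSS may carry several sigma
assignments. Genome-wide regulon scans (`scan_upstream_genome()`) use the
200 nt upstream of every annotated gene.

# De novo discovery

`gibbs_discover()` is a zero-or-one-occurrence-per-sequence (ZOOPS) Gibbs
site sampler: leave-one-out PWM estimation, site resampling from the exact
posterior (a no-site option weighted by `1 - zoops_prior` against site
odds summed in log space), and a +-1/+-2 phase-shift move applied when it
improves the joint likelihood, which rescues the sampler from
shifted-register optima. The best complete-data likelihood state across
restarts wins; 200 sweeps and 5 restarts recover a planted 6-mer in 50
sequences of 50 nt reliably (10/10 seeds in the test conditions) in a few
seconds. The sampler is bit-reproducible given its seed.

`discover_bipartite()` reconstructs a sigma model in two stages: the -10
block from the 20 nt nearest the TSS, then the -35 block from a spacer band
(12-22 nt by default) upstream of each -10 hit, with the spacer prior taken
from the empirical spacer histogram (stray alignments under 10% of the mass
are dropped). Stages that produce a motif under the information-content
floor (1 bit/column) raise an error naming the stage, which is also the
expected outcome on shuffled promoters.

# Terminator features

For every TEP the package reports the U-tract (T fraction of the 8 coding-
strand nt ending at the TEP) and the best stem-loop in the 60 nt upstream:
loops of 3-10 nt are enumerated at every position and stems extended
outwards while bases pair, scoring GC = 3, AU = 2, GU = 1; stems shorter
than 5 bp do not count. This is a deliberate pairing score, not a
thermodynamic folding model — it suffices to flag intrinsic-terminator
hairpins and is verified against exhaustive enumeration of all stem/loop
placements.

# The synthetic generator

`simulate_architecture()` plants a complete architecture and emits the
tracks the pipeline consumes. Design choices, in draw order (genome,
placement, architecture, heights, noise — the order is fixed so outputs
are stable):

* **Genome**: i.i.d. bases at GC 0.474, an acetogen-like composition;
  100 kb and 80 genes by default, placed without overlap on both strands
  with randomised gaps.
* **5'-UTRs**: a mixture of a modal decade (uniform 20-29 nt, weight 0.4)
  and a geometric tail (30 + Geom(p = 0.0114), weight 0.6), capped at
  250 nt. This reproduces the shape bacterial dRNA-seq studies report —
  mode 20-29 nt, median ~45 nt. A 0.6/0.4 weighting of the same components
  cannot reach a median of 45 (60% of the mass would sit below 30), which
  is why the weights are 0.4/0.6.
* **3'-UTRs**: 20 + Gamma(shape 2, scale 26), capped — mode in the 40s,
  median ~64 nt.
* **Promoters**: block sequences sampled from the assigned sigma model's
  PWMs (not fixed consensus), with the -10 block ending 7 nt upstream of
  the TSS and the spacer drawn from the model's set. Sampling from the PWM
  means a few planted promoters genuinely carry weak instances; the
  sigma-assignment accuracy on planted promoters (~0.9) measures exactly
  that.
* **RBS and codons**: AGGAGG planted 5-9 nt upstream of each start codon;
  ATG/TAA written at gene boundaries.
* **Terminators**: an 8-bp G/C stem, 4-nt loop and 8-nt U-tract ending at
  each TEP.
* **Expression**: each gene gets a lognormal expression multiplier
  (sdlog 2, floored at 0.5x) shared by its TSS, TEP and coverage signal in
  all libraries. The floor keeps every planted site above the calling
  threshold so the truth tables stay complete; the dynamic range makes
  replicate height correlations come out near 0.99, as end-sequencing
  studies report — without cross-site variance that correlation would be
  near zero and the simulated data would not resemble real tracks.
* **Signals**: TEX+ 5'-end counts are negative binomial (mean 50, size 30)
  at the jittered TSS; TEX- is depleted 5-fold; processed sites are
  planted with the opposite polarity (TEX- >= 2x TEX+) so they are
  negative cases for the enrichment test by construction. Term-seq counts
  mark TEPs; coverage is a multiplicative-noise plateau across each active
  TU; Poisson background (0.05/nt) covers every track. Positional jitter
  (sd 0.5 nt) is drawn once per site and shared across replicates and
  conditions — it models promoter-intrinsic micro-heterogeneity;
  per-replicate jitter would contradict the single-nucleotide
  reproducibility real replicates show.
* **Conditions**: two (CO2, betaine), 40% of genes active in only one;
  library size 5e6 mapped reads each, a realistic bacterial depth at which
  the 1.5 RPM threshold equals 7.5 reads.
* **Riboswitch-like TEPs**: 5% of long-UTR genes receive a premature TEP
  mid-UTR (category C in truth).

Truth TUs pair each planted TSS with its nearest planted downstream TEP,
matching the pipeline's pairing policy, so recovery scoring measures signal
recovery rather than pairing-policy disagreement.

What the generator does **not** emulate: overlapping genes and operonic
read-through (planted TUs are disjoint, so TU clusters are singletons —
cluster logic is exercised by constructed cases in the tests), sequence-
dependent coverage bias, RNA degradation gradients along transcripts,
antisense transcription, and read-level artefacts (tracks are simulated
directly; there are no reads). Passing the end-to-end tests therefore shows
the inference chain is correct under its stated signal model, not that the
thresholds are optimal for any particular real data set.

# Worked example

```{r example, eval = FALSE}
sim <- simulate_architecture(synthetic_config())
res <- run_pipeline(sim)
rec <- score_recovery(sim$truth, res, tolerance_nt = 1)
glance(rec)
```

`score_recovery()` matches called to planted sites greedily, nearest first,
one-to-one within the tolerance; with no calls at all it reports precision
1.0 alongside a `zero_calls` flag rather than an undefined value.

# Problem sizes and numerics

The shipped tests and the acceptance script run the full default
simulation (100 kb, 80 genes, 16 libraries) end to end in well under a
minute, the classification oracle on 1,000 randomised layouts, exhaustive
PWM enumerations to width 6, and ten independent Gibbs recoveries; these
sizes were chosen to exercise every rule at full fidelity while keeping a
complete run interactive. Degenerate inputs are handled explicitly: empty
peak tables merge to an empty site list, zero-variance replicate pairs are
excluded from correlation with a warning, windows truncated at genome ends
are flagged (`truncated`) and processed as-is, and p-value resolutions
below 10 bins are rejected.

# Known limitations

Single chromosome, no circular wrap-around (windows truncate at the ends);
no statistical FDR model for peak calling (thresholds are rule-based, as in
the lineage of TEX-based callers this follows); hairpin scoring is not a
free-energy model; SigF/SigE/SigK defaults are consensus approximations
meant to be replaced by `discover_bipartite()` output on real promoter
sets.
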