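# txarch

Bacterial transcriptome architecture from end-enriched RNA-seq tracks.

`txarch` is for microbiologists and bioinformaticians who have stranded
per-position sequencing tracks for a bacterial genome — differential
RNA-seq 5'-end counts (TEX+/TEX−), Term-seq 3'-end counts, and RNA-seq
coverage — and want the genome's transcriptome architecture out the other
end: transcription start sites (TSSs) and transcript 3'-end positions
(TEPs) at single-nucleotide resolution, their classification relative to
the gene annotation, transcription units and clusters, sigma-factor
promoter assignments, and intrinsic-terminator features.

## The method in brief

**TSS calling.** Position *p* is a TSS when, in enough TEX+/TEX− replicate
pairs: RPM(p) ≥ h, (c⁺+k)/(c⁻+k) ≥ e (TEX degrades processed
5'-monophosphate ends, so genuine starts are TEX+-enriched), *p* is a
local maximum within ±w nt, and downstream RNA-seq coverage supports a
transcript body. TEPs use the same rule without the enrichment test.
Per-condition calls are merged within ±5 nt (single linkage); sites seen
in ≥2 conditions are constitutive.

**Classification.** Per gene, TSSs within −300/+100 nt of the start are
primary (highest) or secondary; remaining sites are internal, antisense,
or intergenic. TEPs mirror this within +300 nt of gene ends and add a
cis-regulatory category for 3' ends inside 5'-UTRs (riboswitch-style
premature termination).

**TUs.** Each TSS pairs with its nearest downstream TEP; the pair is a TU
when ≥80% of the span has ≥1 RPM coverage with no gap >50 nt. TUs sharing
≥1 nt cluster by single linkage.

**Promoters.** Sigma-factor motifs are bipartite PWMs (−35/−10 blocks)
with spacer-length priors:
score = logodds(up) + logodds(down) + log₂P(spacer), with exact
FIMO-style p-values from integer-discretised score convolution. Six models
ship (SigA TTGHHW-17-TATAAT with extended −10 TG bonus, SigH AGGA-17/18-GAAT,
SigF/E/K, and σ⁵⁴-family SigL TGGCA-N₆-TTGC). A ZOOPS Gibbs sampler
(`gibbs_discover()`, `discover_bipartite()`) rebuilds such models de novo.

**Synthetic data.** `simulate_architecture()` plants a full architecture —
promoters, UTRs, RBS, terminators, replicate noise, background — on a
random genome and returns truth tables, so the whole chain is verifiable
offline with `score_recovery()`.

## Worked example

```r
library(txarch)

sim <- simulate_architecture(synthetic_config())
sim
#> <txa_simulation> 100,000 nt genome, 80 genes, 16 libraries, 80 TSS / 82 TEP planted

res <- run_pipeline(sim)
rec <- score_recovery(sim$truth, res, tolerance_nt = 1)
rec
#> <txa_recovery> (+-1 nt)
#>   TSS recall 1.000 precision 1.000 (labels 1.000)
#>   TEP recall 1.000 precision 1.000
#>   TU exact recovery 1.000

us <- utr_stats(res$tss, res$tep)
c(us$five$median, us$three$median)
#> [1] 36 65
```

Every planted TSS and TEP is recovered within ±1 nt at the default noise
level, all 80 transcription units are reconstructed with exactly the right
endpoints, and constitutive vs condition-specific labels agree with the
planted truth; the recovered median UTR lengths reflect the planted
distributions (5'-UTR mode 20–29 nt, 3'-UTR median ~64 nt). Classified
site tables (`res$tss`, `res$tep`) are tibbles ready for `dplyr`;
`plot_categories()`, `plot_utr_histogram()`, `plot_composition()` and
`plot_sigma_proportions()` chart the standard summaries, and
`write_sites()` / `write_tus()` emit TSV, BED6 and GFF3.

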