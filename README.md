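# codoncontext

Codon usage bias and 3′ codon-context analysis of coding sequences,
stratified by expression level, GC content and length.

## What it is for

Synonymous codons are used unevenly, and in many microbes the bias
strengthens with expression level: highly expressed genes concentrate on
a subset of preferred codons. A second layer of bias sits on *adjacent
codon pairs* — for a given 5′ codon, some 3′ neighbours are over- or
under-represented relative to independence of the two positions.
`codoncontext` is for researchers with a transcriptome-scale ORF
catalogue (FASTA of in-frame coding sequences plus per-ORF expression
values across four culture conditions) who want to quantify both layers,
compare expression strata against a ribosomal-gene reference, and render
the comparisons as ratio and differential-display tables.

Core statistics:

* **RSCU** (relative synonymous codon usage) for codon *j* of amino acid
  *i* with family size *nᵢ* and pooled group counts *xᵢⱼ*:
  RSCU*ᵢⱼ* = *xᵢⱼ nᵢ* / Σⱼ *xᵢⱼ* — 1 under no bias, *nᵢ* under exclusive
  use. Group comparisons use per-codon RSCU ratios with a 0.9–1.1
  similarity band.
* **Adjusted residuals** of the 64 × 64 adjacent codon-pair contingency
  table: *r* = (*o* − *e*) / √(*e*(1 − *p*)(1 − *q*)), approximately
  standard normal under independence; |*r*| > 3 flags preferred/avoided
  3′ context, and group differences are displayed as residual deltas with
  the same ±3 band.
* **Expression groupings**: RPKM = 10⁹·C/(N·L); ORFs are stratified by
  per-condition value (EC), highest value (HV) or average value (AV)
  into bins 1–30 / 31–70 / 71–100 / 101–999 / ≥1000 RPKM, with ribosomal
  ORFs as the separate reference group R; fold-changes are max/min across
  conditions.

A seeded synthetic generator (first-order Markov codon chains with
controllable per-family codon frequencies, codon-pair coupling, GC
targeting and four-condition expression profiles) makes the whole
pipeline testable with no external data.

## Worked example

```r
library(codoncontext)

spec <- synthetic_spec(
  n_orfs = 400, seed = 11,
  codon_frequencies = local({
    cf <- uniform_codon_frequencies()
    cf[c("GAA", "GAG")] <- c(0.7, 0.3)   # biased glutamate usage
    cf
  }),
  pair_coupling = data.frame(codon5 = "GCU", codon3 = "GAA", factor = 3)
)
orfs <- generate_orfs(spec)
em   <- generate_expression(spec, orfs)
orfs
#> orf_set: 400 ORFs (synthetic)
#>   length: 300-1566 nt; GC: 39.4-52.5%; ribosomal: 12; viral: 0

round(summary_bins(em, "highest"), 1)
#>         1-30 31-100 >100
#> highest  1.5    9.8 88.8
```

Most ORFs exceed 100 RPKM in at least one condition, the structure of a
typical transcriptome catalogue. The planted glutamate bias is recovered
through RSCU (truth: 2 × 0.7 = 1.4 for GAA):

```r
tab <- rscu_table(count_codons(orfs), group_label = "all")
subset(tab, aa == "E")
#>    amino_acid aa codon family_size count      rscu
#> 59        Glu  E   GAA           2  2368 1.4321137
#> 60        Glu  E   GAG           2   939 0.5678863
```

and the planted codon-pair coupling dominates the context map:

```r
ct <- pair_context_table(orfs, group_label = "all")
top_pairs(ct, 3, "preferred")
#>   codon5 codon3 residual
#> 1    GCU    GAA 7.296550
#> 2    AUA    UAA 3.726780
#> 3    GGG    AGU 3.654824
```

The GCU→GAA residual of 7.3 is far beyond the ±3 no-bias band; the other
two entries sit just above 3, the handful of false positives expected
among ~3900 cells under the null. One call runs every stage and writes
the TSV/JSON report bundle:

```r
res <- run_pipeline(run_config(orfs, em, out_dir = "report"))
res$group_sizes
#>       bin n_orfs
#> 1    1-30      6
#> 2   31-70     13
#> 3  71-100     26
#> 4 101-999    248
#> 5  >=1000     95
#> 6       R     12
```

The bundle contains per-group RSCU tables with preference classes,
RSCU ratio maps against the ribosomal reference, codon-pair context
tables with bias calls, top-5 preferred/avoided pair lists, differential
display maps, expression summaries and top-expressed tables, plus a
`manifest.json` recording options, package version and input digests.

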