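---
title: "Codon usage bias and 3' codon-context analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and 3' codon-context analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codoncontext)
```

## The problem

Synonymous codons are not used uniformly. In fast-growing microbes,
highly expressed genes tend to concentrate their synonymous choices on a
subset of "preferred" codons — typically those served by abundant tRNAs —
while weakly expressed genes use codons more evenly. A second, independent
layer of bias sits on *adjacent codon pairs*: for a given 5' codon, some 3'
neighbours occur more often than the two codons' individual frequencies
would predict, presumably reflecting constraints of the ribosomal A/P-site
interaction. `codoncontext` quantifies both layers for a set of open
reading frames (ORFs) stratified by expression level, GC content or
length, and provides a seeded synthetic-data generator so that every
analytical stage can be exercised and validated without any external
dataset.

The intended input is a transcriptome-scale ORF catalogue from a single
organism — the package's data model mirrors a study of the carotenogenic
yeast *Xanthophyllomyces dendrorhous* grown on glucose or succinate and
sampled at 18 h and 72 h, hence the four fixed condition labels G18, S18,
G72, S72 — but nothing in the statistics is specific to that design beyond
the number and names of conditions.

## Data model

An `orf_set` holds validated coding sequences: at least 300 nt (100
codons), length a multiple of 3, no ambiguous bases, and no in-frame stop
codon before the final codon. Sequences containing N are rejected outright
rather than having N-codons skipped, which keeps codon totals exact. A
terminal stop codon is optional — public ORF catalogues are inconsistent
about including it — but its presence is recorded per record so a mixed
convention is visible. All codon-level reporting uses the RNA alphabet
(AUG, not ATG); FASTA input is DNA.

An `expression_matrix` holds one RPKM value per ORF and condition, where

$$\mathrm{RPKM} = \frac{10^9 \, C}{N \, L}$$

with $C$ the reads mapped to the ORF, $N$ the total mapped reads of the
library and $L$ the ORF length in nt. Raw counts plus library sizes are
accepted and converted.

## Expression groupings

ORFs are stratified for codon analysis by one of three schemes: **EC**
(the RPKM under each single condition), **HV** (the highest RPKM among
the four conditions — an ORF weakly expressed in three conditions but
strongly in one is treated as highly expressed), and **AV** (the average
RPKM). Ribosomal-protein ORFs form a separate reference group **R**,
the conventional stand-in for "highly expressed genes". The binning
statistic falls into the bins 1–30, 31–70, 71–100, 101–999, and at least
1000 RPKM.

Because RPKM is continuous while the bin labels are integer ranges, the
bins are realized as half-open real intervals $[1,31)$, $[31,71)$,
$[71,101)$, $[101,1000)$, $[1000,\infty)$. A value of 30.5 therefore
stays in the lowest bin: each label owns the real interval from its lower
edge up to (not including) the next label's lower edge. ORFs whose
statistic is below 1 RPKM are left unassigned rather than forced into the
lowest bin, and `summary_bins()` reports how many were excluded so both
denominators are recoverable.

Fold-changes are the ratio between the highest and lowest RPKM of each
ORF across the four conditions, annotated `[max/min]` with ties broken by
the fixed condition order G18, S18, G72, S72. Fold-change bins 1–2,
2.1–5, 5.1–10, 10.1–50, >50 are realized upper-inclusive — $(2,5]$ and so
on — matching their decimal labels.

## RSCU

For codon $j$ of amino acid $i$ with family size $n_i$ and pooled counts
$x_{ij}$ over a group of ORFs,

$$\mathrm{RSCU}_{ij} = \frac{x_{ij}\, n_i}{\sum_j x_{ij}}.$$

RSCU is 1 under uniform synonymous usage, $n_i$ under exclusive use of
one codon, and exactly 1 for the single-codon families Met and Trp.
Three choices matter and are configurable:

* **Pooled, not averaged.** Group RSCU is computed on the concatenated
  codon counts of all member ORFs, the dataset-level convention of
  classical codon-usage tools, not as a mean of per-gene RSCU values.
* **Stop codons count.** UAA/UAG/UGA form a 3-codon TER family included
  in the table; `pair_counts(include_stop = FALSE)` and ordinary count
  subsetting allow stop-free variants.
* **Undefined is not zero.** An amino acid never observed in a group
  yields `NA` RSCU for its codons. Propagating `NA` (rather than 0)
  keeps ratio maps honest on small groups.

Preference classes reproduce the conventional three-colour display: the
family argmax (all of them, on ties) is *most common*, codons with RSCU
< 0.5 are *less frequent*, the rest *intermediate*. The 0.5 cutoff is a
display convention with no inferential content.

`ratio_map()` compares two groups codon-by-codon as
$\mathrm{RSCU}_a/\mathrm{RSCU}_b$ and flags ratios within $[0.9, 1.1]$ as
similar — the band conventionally used to call two groups' usage of a
codon equivalent. Ratios with an undefined term or a zero denominator are
undefined and never flagged similar.

## 3' codon context

Adjacent in-frame codon pairs (5' codon $p$, 3' codon $q$) are counted
within each ORF — an ORF of $k$ codons contributes $k-1$ ordered pairs,
pairs never span ORFs, and there is no wrap-around. The 64 × 64 table is
tested against independence of the two positions: expected counts are
$e_{pq} = \mathrm{row}_p \,\mathrm{col}_q / N$ and each cell gets the
adjusted residual

$$r_{pq} = \frac{o_{pq} - e_{pq}}
  {\sqrt{e_{pq}\,(1 - p_p)\,(1 - q_q)}},$$

with $p_p, q_q$ the marginal proportions. Adjusted residuals are
approximately standard normal under independence, so cells with
$r > +3$ are called *preferred* context, $r < -3$ *avoided*, and values
in $[-3, +3]$ *no bias*. No multiple-testing correction is applied by
default (the ±3 rule is the field convention for these maps); a stricter
threshold can be passed to `bias_calls()`, and a plain Pearson-residual
mode exists for sensitivity analysis. Terminal stop codons participate as
3' partners by default (switchable), so TER columns appear in the maps
while TER rows stay empty. Report output rounds residuals to integers
(half away from zero), as such tables are conventionally printed, while
full precision is kept in the objects.

`differential_map()` compares two groups cell-wise by
$\Delta = r^{(a)} - r^{(b)}$ and flags $|\Delta| \le 3$ as similar — the
same band, now on a difference of two approximately unit-variance
statistics, used as a display convention rather than a calibrated test.
`top_pairs()` ranks the most extreme cells with lexicographic
tie-breaking so output is reproducible.

## Synthetic data generator

`synthetic_spec()` + `generate_orfs()` + `generate_expression()` produce
a complete dataset with known ground truth:

* **Sequences.** Each ORF starts with AUG, ends with a stop codon drawn
  from the TER frequency vector, and contains no internal stop. Internal
  codons follow a first-order Markov chain whose emission distribution is
  `amino_acid_frequencies` × `codon_frequencies` and whose transition
  weights out of each 5' codon are multiplied by the `pair_coupling`
  factors and renormalized. With empty coupling the chain degenerates to
  i.i.d. codon sampling — the null the context module's calibration tests
  rely on. First-order generation was chosen over i.i.d. precisely so
  that pair coupling is expressible.
* **GC targeting.** A GC% target is met by tilting the within-family
  codon frequencies as $w_c \propto p_c\, e^{t\,\mathrm{gc}(c)}$, with the
  single tilt parameter $t$ solved numerically so the expected GC of an
  emitted codon matches the target. Matching is in expectation, not
  exact per sequence.
* **Expression.** RPKM(orf, condition) = base × condition multiplier ×
  log-normal noise. Defaults: base $\sim$ logN(5.54, 1.2²) — calibrated
  by simulation so that, after the default per-ORF condition multipliers
  logN(0, 0.55²) are applied, about 88% of ORFs exceed 100 RPKM on the
  highest-value basis and the median max/min fold-change is near 3,
  emulating a transcriptome dominated by moderately-to-highly expressed
  ORFs with condition-dependent variation. Measurement noise is
  logN(0, 0.1²), small enough that bin assignments are stable at default
  sizes. Ribosomal ORFs (3% of the set by default) get an 8× base boost,
  as expected of the highly expressed reference set.

What the generator does **not** emulate: real amino-acid composition
(uniform by default), genome-wide GC heterogeneity, correlated
codon-usage/expression structure (in real data highly expressed genes are
*more* biased — here codon usage and expression are independent unless
you couple them yourself), the heavy upper tail of real fold-change
distributions (a single log-normal multiplier produces almost no >50-fold
changes), and anything at the read level. Passing tests on synthetic data
therefore validate the statistical machinery — estimator definitions,
calibration of the ±3 rule under the null, power against known coupling,
determinism — not the biological conclusions one would draw from a real
catalogue.

## Validation strategy and problem sizes

The test suite checks, among others: RSCU family sums equal the family
size $n_i$ (machine tolerance); RSCU(AUG) = RSCU(UGG) = 1 on any counts;
adjusted residuals against an independent brute-force oracle on random
6 × 6 tables to $10^{-10}$; marginal conservation of $o - e$; null
calibration — with i.i.d. codons and about $10^6$ pairs, fewer than 2% of
cells exceed $|r| > 3$ (the Gaussian null would give ~0.27%; the slack
absorbs discreteness in sparse stop-codon columns); power — a single
2×-coupled pair is detected ($r > 3$) at about $10^5$ pairs; parameter
recovery — generator codon frequencies are recovered through RSCU within
0.05 at roughly $10^5$ codons per family; and byte-level determinism of
generation and of the whole report bundle under a fixed seed. These sizes
were chosen as the smallest at which the asymptotic approximations hold
comfortably; the full suite runs in well under a minute on one core.

## Known limitations

* The adjusted-residual framework treats codon pairs as draws from one
  contingency table; within-gene dependence (the same gene contributes
  many pairs) is ignored, as is standard for these maps.
* The ±3 rule makes no multiple-testing adjustment over 4096 cells; with
  large $N$ many cells clear it. Treat the calls as descriptive.
* RSCU on small groups is noisy and the 0.9–1.1 ratio band has no
  sampling-error correction; undefined entries (rather than zeros) are
  the only small-sample guard.
* GC targeting tilts synonymous choice only; it cannot reach GC values
  incompatible with the amino-acid composition and errors out rather
  than silently saturating.
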