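---
title: "Methods: codon-biased translation reprogramming statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-biased translation reprogramming statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonreprog)
```

This vignette is the package's own account of the statistical models it
implements, the assumptions behind them, the parameters that matter, and the
design choices made where the methodology was genuinely open. The biological
setting is codon-biased translational reprogramming: a cell state (for
instance a therapy-resistant tumour) in which specific mRNAs are translated
more or less efficiently according to their codon composition, driven by
changes in tRNA abundance and aminoacyl-tRNA synthetase activity, with
little or no change in global translation.

## Codon content analysis

Each gene is represented by one CDS — the longest annotated transcript, ties
broken lexicographically by transcript id so the choice is reproducible. The
content of codon $c$ in gene $g$ is

$$x_{gc} = \frac{n_{gc}}{\sum_{c' \in \text{sense}} n_{gc'}},$$

counts taken over non-overlapping frame-0 triplets. Two conventions needed
fixing because genes differ in their edge codons:

* **Stop codons are excluded** from both the feature alphabet and the
  denominator. They encode no amino acid, and excluding them keeps
  codon-level and amino-acid-level fractions on the same denominator, so
  amino-acid content is exactly the sum of its synonymous codon contents
  (and is therefore invariant to synonymous recoding, which the test suite
  checks).
* **The start codon is included.** It is a genuine methionine codon; with it
  a CDS of 100 codons ending in a stop has denominator 99.

Triplets containing ambiguity codes are skipped and counted; a record with
more than 5% skipped codons is dropped with a warning rather than silently
biased.

**Membership.** Gene $g$ is a *member* for feature $c$ when $x_{gc}$ lies in
the top 25% of that feature's distribution across the transcriptome.
Membership is rank-based, not threshold-based: exactly $\lceil 0.25 N
\rceil$ members per feature, ties broken deterministically by gene id. A
value threshold at the 75th percentile would make the member count depend on
tie structure; the rank rule makes the "top 25%" exact for every input, at
the cost of arbitrarily splitting ties — which the deterministic id
tie-break at least makes reproducible.

**Enrichment test.** For a query set $S$, each feature's $2 \times 2$ table
cross-classifies genes by $S$-membership and content-membership, with the
"outside" margin excluding $S$ (the standard contingency partition). The
Pearson chi-squared statistic (1 df) is used without Yates correction,
matching the classical form; rows with a minimum expected cell below 1 are
flagged `low_expected` instead of being suppressed. Raw p-values drive the
enriched/impoverished direction call — the convention for per-feature codon
scans — and Benjamini–Hochberg adjusted values are reported alongside for
users who want family-wise control over the 61 (or 20) features.

## tRNA aggregation and concordance

tRNA-seq quantifies isodecoders (individual tRNA genes). Analysis levels
are sums: isoacceptors add all isodecoders sharing an anticodon,
alloisoacceptors all isodecoders charging one amino acid, so totals are
conserved exactly at both levels. An optional isoacceptor-level variant sums
only isodecoders that individually pass a differential test at
$\alpha = 0.05$; it is off by default because the corresponding
alloisoacceptor rule has no such clause and the filtered sum is no longer
conservation-consistent — when no isodecoder passes, the key is emitted with
zero counts and `n_contributing = 0` rather than dropped.

Differential testing is a two-sided unpaired t-test. The pooled-variance
(Student) form is the default: with the $n = 3$ per condition typical of
tRNA-seq, Welch's correction costs most of the few degrees of freedom
available while protecting against a heteroscedasticity that cannot be
estimated at that depth anyway; Welch remains available via `var_equal =
FALSE`. Fold changes are $\log_2$ of the ratio of group means with a 0.5
pseudo-count on each mean for zero-count robustness.

Concordance pairs content calls with tRNA calls: amino acids with
alloisoacceptors, codons with isoacceptors through the **strict
Watson–Crick anticodon** (reverse complement; GTG ↔ CAC). Wobble decoding
tables are deliberately out of scope — the question asked is whether the
exact cognate tRNA moved with its codon, and wobble rules would make that
mapping many-to-many and assumption-laden.

## Ribosome-footprint statistics

**Metagene.** Each transcript's per-nucleotide 5′-end density is divided by
its own mean CDS density before averaging, so deep and shallow transcripts
contribute equally (the profile is invariant to per-transcript depth
rescaling, a tested property). The CDS is rescaled to a fixed number of
bins (default 30); UTR flanks stay at nucleotide resolution. A uniform
dataset gives a flat profile of exactly 1.

**Codon occupancy.** Site offsets are measured from the read 5′ end to the
first nucleotide of the site codon, defaults 9/12/15 nt labelled E/P/A —
the usual convention for ~30 nt footprints — and configurable because
digestion protocols shift them. A read whose offset nucleotide is out of
frame relative to the CDS is assigned to the codon containing that
nucleotide, so no read is discarded for frame jitter. Fractions are
normalised per condition and offset (they sum to 1 over sense codons); the
differential shift is $\log_2[(f_A + \varepsilon)/(f_B + \varepsilon)]$
with $\varepsilon = 10^{-6}$ guarding zero-count codons, and shifts are
standardised to z-scores across codons within each offset so a planted
pause reads directly as an outlying $|z|$.

**Stratified fold changes.** The comparison restricts a differential table
to its significant genes, ranks them by one amino acid's content, and
t-tests top-quartile against bottom-quartile $\log_2$FC. The quartiles are
recomputed *within the significant set* — the population actually analysed
— using the same rank machinery as the transcriptome background; computing
them against transcriptome-wide membership instead is possible by passing
the background content matrix with `significant_only = FALSE`, but the
within-set reading matches the stated "significantly regulated transcripts
sorted by enrichment" design. All-equal fold changes give $t = 0$, $p = 1$
by decision rather than an error.

## Signature derivation and scoring

The translation classifier uses protein threshold 0.32 and mRNA window 1.0
($\log_2$ units): `translation_down` means protein $< -0.32$ with
$|\text{mRNA}| < 1$ — protein lost without mRNA loss. The published form of
the mirrored "up" rule is typographically garbled; it is implemented as the
exact mirror (protein $> +0.32$, same mRNA window). Thresholds are strict
inequalities, so a gene exactly at $-0.32$ is unclassified. The signature
is the intersection of `translation_down` with the target amino acid's
top-content-quartile members; it is monotone in the member set (a tested
property) and an empty intersection is a valid, warned-about result.

ssGSEA follows the rank-weighted ECDF-difference form: within one sample,
genes are ranked by expression (average ranks on ties), and the score sums
the gap between the in-signature ECDF weighted by $\text{rank}^{0.25}$ and
the unweighted out-of-signature ECDF, then scores are rescaled across
samples by their range. Exponent 0.25 is the common default; the variant
that kernel-smooths the expression CDF before ranking (sometimes labelled a
Poisson kernel in other implementations) is a different estimation mode of
the same score and is not implemented here — being rank-based, the
implemented score is invariant to any monotone transform of a sample's
values, which is the property the tests pin down. Extreme groups take the
$k = \mathrm{round\text{-}half\text{-}up}(0.15 N)$ highest and lowest
scores (233 samples → 35 per group); ties break by sample id, $2k = N$
(empty middle) is allowed, $2k > N$ is an error.

Count preprocessing implements exactly the stated transform chain: genes
are removed when the fraction of samples below 10 counts exceeds 30% in
*both* groups, then $\log_2[(\text{count} + 0.5)/(\text{libsize} + 1)
\times 10^6]$.

The screen's relative nuclear fragmentation score is
$1 + 100(\text{induced} - \text{spontaneous})/(100 - \text{spontaneous})$;
the final denominator is read as $100 -$ *spontaneous* fragmentation (the
source wording leaves the term unqualified), which makes the null case
(induced = spontaneous) exactly 1 and keeps the score finite for all
spontaneous rates below 100%.

## The synthetic-data generator

The generator emulates the *statistical structure* the analyses assume, not
the biology of any real dataset:

* CDS codons are i.i.d. from a weight vector (uniform over the 61 sense
  codons by default) — the analyses only consume codon frequencies, so
  dinucleotide structure, GC gradients and codon-pair effects are
  deliberately absent. Planted bias multiplies the planted codon's
  *sampling weight*, keeping sequences valid ORFs and the bias magnitude
  interpretable.
* Fold-change tables are Gaussian in $\log_2$ around a planted stratum
  shift; footprints are uniform with importance resampling for a planted
  pause; tRNA counts are lognormal (log-sd 0.25) around lognormal
  baselines; expression counts are negative binomial with dispersion 0.1.
  None of these noise models is asserted by the source methodology; they
  are conventional choices for the respective data types.
* Every generator is a pure function of its arguments including the seed,
  with per-gene subseeds derived by index so output does not depend on
  iteration order.

Because the generator satisfies the analyses' assumptions *by
construction*, passing recovery tests demonstrates correctness of the
statistical machinery — not robustness to real-data pathologies such as
mapping bias, isodecoder cross-mapping, footprint length heterogeneity or
batch structure.

Planted effect sizes are power-driven choices, fixed once: the codon-bias
recovery uses 1,000 genes of 100–600 codons with a 50-gene GTG ×4 set; the
stratified-defect recovery plants a −0.5 log₂ shift (noise sd 0.3) on
valine top-quartile genes; the pause recovery uses a ×4 A-site enrichment
over 300 transcripts × 150 reads; the end-to-end signature run uses 800
genes with a 7.5% planted set at GTG weight ×6 and protein shift −1 (noise
sd 0.1). The ×6 bias in the signature scenario makes planted genes
unambiguous valine top-quartile members, so the recovery rate measures the
classifier and intersection logic rather than the overlap noise of a
marginal content rank; the −1/0.1 protein effect likewise keeps threshold
crossings essentially deterministic. These sizes also keep the full test
suite and the acceptance script fast (tens of seconds).

## Numerical and degenerate-input policy

* $2 \times 2$ tables with a zero margin: statistic 0, $p = 1$, flagged
  degenerate.
* t-tests with zero variance in both groups: equal means → $p = 1$;
  unequal means → $p = 0$, flagged (the difference is unambiguous under
  the observed spread).
* Constant expression vectors score 0 in ssGSEA and are flagged.
* All coordinates are 0-based half-open internally; TSV output is
  tab-delimited with a header; FASTA is wrapped at 60 columns with
  `gene|transcript` headers.

## Known limitations

* No codon-adaptation indices, GC covariate correction, or wobble-aware
  decoding models.
* No P-site offset learning from read-length distributions; offsets are
  fixed parameters.
* The ssGSEA kernelised variant is not implemented; scores from other
  toolkits may differ in scale (rank-order behaviour is the tested
  contract).
* The background universe is whichever FASTA is supplied; restricting it
  to expressed genes is the caller's choice.
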