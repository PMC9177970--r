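# calsplice

Analysis of the exonic splicing code at protein calcium-binding sites.

Exons carry, besides the protein code, short auxiliary splicing signals —
exonic splicing enhancers (ESEs) and silencers (ESSs) — that tune how
reliably the exon is included in mature mRNA. Codons for the residues that
chelate Ca²⁺, above all the Asp/Glu-rich 12-residue loop of the EF-hand
helix–loop–helix motif, are strongly biased toward enhancer-like sequence.
`calsplice` provides the machinery to quantify that bias: it scans protein
sequences for the EF-hand loop consensus, scores the encoding DNA against
ESE/ESS hexamer sets, derives codon-level splicing statistics and
codon-usage bias measures, maps intron insertion points into loop
coordinates, and tests CLIP-style peak sets for enrichment over motif-coding
intervals by randomization. A synthetic-data generator reproduces the
statistical structure of a curated EF-hand dataset so the whole pipeline is
testable without any external download. It is written for genomics
researchers working on splicing regulation and protein-domain evolution.

## The statistics at the core

* **Loop detection.** The 12-position PROSITE-style consensus
  `D-(W)-[DNS]-(ILVFYW)-[DENSTG]-[DNQGHRK]-(GP)-[LIVMC]-[DENQSTAGC]-x-x-[DE]`
  (square brackets = permitted residues, parentheses = forbidden) is matched
  window-by-window; a match at amino acid *k* maps to coding nucleotides
  3(k−1)+1 … 3(k−1)+36.
* **Positional splicing profiles.** The value at nucleotide position *i* is
  the mean, over sequences, of the score of the hexamer *starting* at *i*;
  region summaries pool the loop (EFL), the Ca²⁺-coordinating codons
  (CR = loop codons 1, 3, 5, 9, 12), the whole 108-nt motif (EFM) and the
  motif outside the loop (ROEF), against a control-exon background trimmed
  of splice-site consensus positions.
* **Codon-level ratios.** Each hexamer contributes its four in-frame and
  offset 3-mers as codon tokens; per codon c,
  ln(ESEf/ESSf) = ln[(e(c)+π)/(E+64π)] − ln[(s(c)+π)/(S+64π)] with
  pseudocount π (default 0.5), plus the count ratio ESEc/ESSc.
* **Codon-usage bias.** RSCU, the codon adaptation index
  CAI = exp(mean ln w), w(c) = RSCU(c)/max family RSCU (Sharp–Li
  exclusions), and an expected-CAI null from random synonymous re-encodings
  matched to the query's GC and amino-acid content; exact two-sided
  binomial tests for two-codon usage contrasts; a fragile/robust classifier
  (one substitution away from a stop, or not).
* **Exon splits.** An intron inserted after CDS nucleotide *i* is indexed
  by the first downstream loop nucleotide; under a random position within
  the 108-nt motif the within-loop expectation is n·36/108, tested with an
  exact binomial.
* **Interval enrichment.** Peaks are re-placed uniformly within a workspace
  (GAT-style, add-one empirical p, q-values by Benjamini–Hochberg), with a
  padding sweep around the annotation intervals.

## Worked example

```r
library(calsplice)

# Exon-count contingency for canonical vs noncanonical motifs
chi2_contingency(rbind(c(79, 178, 39), c(15, 47, 4)))
#>    chi2    df p_value
#> 1  3.69     2   0.158

# Simulate a 100-gene EF-hand cohort and run the full analysis
report <- run_pipeline(sim_config(n_genes = 100), seed = 42, n_sims = 500)
report
#> <splice_report>
#>   motifs scanned: 100
#>   region summaries: 4 rows
#>   exon splits: 100 (47.0% within loop, binomial p = 0.00551)
#>   enrichment tests: 4 (min q = 0.457)

report$split_enrichment
#>   n_splits observed_within expected_within observed_outside expected_outside
#> 1      100              47            33.3               53             66.7
```

The contingency test shows exon-count distributions of the two motif
classes are statistically indistinguishable (χ² = 3.69, p = 0.16). In the
simulated cohort, 47 of 100 intron insertion points fall inside the 36-nt
chelation loop against an expectation of 33.3 under random placement
(binomial p = 0.0055) — the generator plants the two split clusters that
the split statistics then recover. The enrichment q-values stay at ~0.5
here because the default peak model is the uniform null (programmed fold
1). `autoplot()` methods exist for profiles, codon tables and enrichment
results, and `tidy()`/`glance()` return tibble summaries.

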