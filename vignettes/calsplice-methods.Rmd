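---
title: "Methods: scoring the exonic splicing code at calcium-binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring the exonic splicing code at calcium-binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calsplice)
```

## The problem and the model

EF-hand proteins chelate Ca²⁺ through a 12-residue loop bridging two
α-helices. The loop is dominated by acidic residues — Asp is required at
position 1 and Asp/Glu at position 12 — whose GA-led codons overlap
strongly with exonic splicing enhancer (ESE) hexamers. `calsplice`
quantifies the resulting coupling between the protein code and the
splicing code at three levels: hexamer scores along the coding sequence,
per-codon enhancer/silencer ratios, and the exon–intron architecture of
the motif.

The package assumes coding sequences are in frame (CDS coordinates are
1-based, with loops codon-aligned), that a hexamer score table covering
the full 4096-mer space is available, and that interval data (peaks,
annotations, workspaces) are BED-convention 0-based half-open. U and T are
interchangeable on input; everything internal is DNA-alphabet.

## Consensus scanning

`parse_prosite_pattern()` compiles the 12-position loop consensus into
REQUIRED / FORBIDDEN / ANY constraints and `scan_protein()` tests every
window, reporting all (possibly overlapping) matches in left-to-right
order. The ambiguity letter X is treated conservatively: it never
satisfies a REQUIRED set and never violates a FORBIDDEN one, so an
X-containing window can only match through positions that do not restrict
it. S100-family pseudoloops are 14 residues long and do not fit the
12-position pattern; S100 membership is therefore caller-supplied
metadata (a gene list), never inferred. Likewise, Ca²⁺ contacts of
nonEF-hand proteins come from curated input, not structural inference.
How overlapping matches within one protein should be de-duplicated into a
curated motif set is left to the caller: the scanner reports everything.

## Positional and region scores

The profile value at nucleotide position *i* is the score of the hexamer
*starting* at *i* (not merely covering it); position 1 is the loop's
first nucleotide. This indexing makes "no silencer starts here"
statements well-defined, and `positional_profile()` reports that count
(`ess_start_count`) per position. Sequences lacking flanking context at a
boundary position are dropped from that position only, with per-position
sequence counts kept.

Region summaries pool hexamer-start scores over sequence × position
pairs. The default region sets are the 36-nt loop (EFL), the
Ca²⁺-coordinating codons (CR), the 108-nt motif (EFM) and its non-loop
remainder (ROEF); EFM is by construction the disjoint union of EFL and
ROEF, so the pooled means are exactly consistent. CR defaults to loop
codons {1, 3, 5, 9, 12} — the side-chain and water-bridged oxygen ligands
of the pentagonal-bipyramidal coordination — and excludes codon 7, whose
contact is a backbone carbonyl and therefore indifferent to codon
identity at the wobble position; the set is an argument, not a constant.

The control background trims the first nucleotide and the last three from
every control exon, because those positions are part of the 3′ and 5′
splice-site consensus rather than free exonic sequence, then pools all
hexamer starts (position-weighted; exon-weighted pooling is available).

`compare_to_background()` tests per-sequence region means against
per-exon control means. Pooled positions within one sequence are
overlapping hexamers and hence strongly autocorrelated; using sequences
and exons as the independent units keeps the type-I error of the t test
near nominal, which the test suite checks by null calibration.

## Codon-level statistics

Each hexamer contributes its four length-3 substrings (offsets 0–3) as
codon tokens, so n hexamers give exactly 4n tokens — 1182 enhancers yield
4728 and 1090 silencers 4360. The frequency ratio is reported as
ln(ESEf/ESSf) with a Haldane pseudocount π = 0.5 added per codon cell
(and 64π to each total); π is a parameter, and π = 0 is legitimate when
no zero counts exist, where the statistic reduces to the plain
log-frequency ratio. Swapping the enhancer and silencer lists negates
every log ratio exactly, a symmetry the tests assert.

Dinucleotide enrichment uses the five overlapping dinucleotides per
hexamer and the same 0.5 pseudocount.

## Codon usage bias

RSCU divides observed codon counts by the equal-usage expectation within
each synonymous family. CAI is the geometric mean of relative
adaptiveness values w(c) = RSCU(c)/max RSCU in family, excluding Met, Trp
and stops (the Sharp–Li convention); the exclusion is a flag so users can
match tools that include them. A codon absent from the reference is
floored at w = 0.01 rather than zeroing the geometric mean.

The expected-CAI null preserves the amino-acid *sequence* (not just
composition) and matches the query's GC content in expectation with a
single interpretable parameter: within each family, codon c is sampled
with weight exp(α·gc(c)), and α is tuned by bisection until the sampler's
expected GC matches the query GC to 0.1% (when attainable by synonymous
changes at all; otherwise α saturates at the nearest bound). This is a
deliberate, documented variant of GC-matched re-encoding; published
CAI utilities do not specify their samplers precisely enough to clone.

The two-codon usage bias test is the exact binomial with two-sided
p-values formed by summing point probabilities not exceeding that of the
observed count — exact at the sample sizes typical of loop-position
contrasts (a few hundred codons). Fragile codons are those one
substitution away from TAA/TAG/TGA; the classifier enumerates all nine
neighbours.

## Exon-split statistics

A split is indexed by the first loop nucleotide downstream of the intron:
an intron immediately before loop nt 1 is *within* at position 1, and one
immediately after nt 36 is *outside*. This keeps exactly 36 within-loop
positions, so the null within probability is 36/108 = 1/3 for the fixed
108-nt motif, and the expected counts for n splits are n/3 and 2n/3. The
convention at the two boundaries is stated prominently because printed
tables of within/outside totals cannot disambiguate it; the mapping
function exposes both edges explicitly through `loop_relative_position`.

The within/outside test is an exact two-sided binomial. For the pooled
112-of-262 configuration this gives p = 0.0016; the one-sided enrichment
tail is 8×10⁻⁴. The positional uniformity test is Pearson's χ² over
within-loop positions, pooling adjacent positions into equal-width bins
whenever per-position expected counts would drop below 1.

Loop-to-splice-site distances are reported only for loops wholly inside
one exon and, by default, only for exons shorter than 400 nt (longer host
exons say little about splice-site proximity); the filter boundary
excludes a 400-nt exon.

## Interval enrichment

`enrichment_test()` is a randomization test in the GAT mould: segments
are re-placed independently and uniformly over all start positions at
which they fit fully inside one workspace interval; lengths are
preserved; placements may overlap each other (the optional non-overlap
constraint of some implementations is deliberately not reproduced — the
independent-placement null is simpler and exactly enumerable on toys).
The empirical p uses add-one smoothing, p = (1 + #{sim ≥ obs})/(nSims+1),
one-sided for enrichment by default with a depletion flag. Both a
nucleotide-overlap statistic and a segment-hit count are provided, since
"peaks enriched within annotations" is ambiguous between the two.
Simulations run on a flattened axis in which workspace intervals are laid
end to end, making each null round pure vectorized arithmetic; the
per-simulation cost is O(n log m) for n segments and m annotation
intervals. Benjamini–Hochberg correction across samples and padding
values uses the standard step-up with a q < 0.01 flag, and the padding
sweep (default 0, 3, 6, 9 nt) extends annotations both ways, clips to the
workspace and re-merges.

Desk-scale defaults are nSims = 10,000 for interactive use and 5,000 in
the heavier checks; production analyses of real CLIP compendia would use
considerably more (10⁵-scale) simulations, which changes only the
resolution of the empirical p, not the estimator.

## What the generator emulates — and what it does not

`simulate_efhand_genes()` produces one canonical loop per gene inside a
108-nt motif (12 helix codons, 12 loop codons, 12 helix codons) with
30 codons of background on each side. Loop residues are drawn
position-wise from an editable frequency table digitized qualitatively
from the composition of human canonical loops (Asp ≈ a quarter of loop
residues and certain at position 1; Glu ≈ an eighth and dominant at
position 12; Gly nearly invariant at position 6; roughly half the loop
charged); each per-position distribution is validated against the
consensus at configuration time. Reverse translation applies the
documented wobble bias at loop codons 1 (GAC:GAT = 0.63:0.37) and 12
(GAG 0.62, GAA 0.30, the remainder Asp) and uniform synonymous choice
elsewhere. Exon counts follow the 79:178:39 mix of 1/2/3-exon motifs, and
split positions follow a two-cluster model — ten N-terminal-half
positions and four around codon 12 at 0.7:0.3 weight — mixed with
uniform outside-loop positions so that the within-loop fraction matches
the observed 112/262 in expectation. A `uniform` mode (within fraction
1/3 by construction) supports calibration tests, and `none` disables
splitting.

`simulate_hexamer_sets()` draws a uniform silencer set and then an
enhancer set with exponential tilting on each hexamer's GA-dinucleotide
count. Inclusion probabilities p(h) = min(1, c·e^{θ·ga(h)}) are
calibrated — c fixes the expected set size, θ (solved in log space by
root finding) fixes the expected GA frequency ratio — so the programmed
`ga_enrichment` is realized in expectation rather than merely trended
toward. Infeasible targets (beyond what the 4096-mer space can supply at
the requested set size) raise an error. Scores are shifted normals (ESE
+1, NEUTRAL 0, ESS −1, sd 0.5), giving first-order stochastic dominance
of enhancer over silencer scores.

`simulate_peaks()` places fixed-length peaks so that the expected
per-peak nucleotide overlap with the motif annotation equals
`fold_in_motifs` times the uniform-placement expectation: each peak is,
with a calibrated mixture probability, placed uniformly among starts
fully inside a motif interval, otherwise uniformly over the workspace.
The calibration targets the same overlap statistic the enrichment test
measures, so programmed and recovered fold agree in expectation without
edge-effect bias; fold 1 reduces exactly to the uniform null, and
padding the annotations of a fold-1 dataset does not manufacture signal.

What the generator does **not** emulate: real genomic coordinates and
intron sequences; linkage between paired EF-hands of one protein;
empirical eCLIP peak-length distributions (lengths are fixed per run);
the correlation structure of real hexamer score sets (scores are
conditionally independent given the label); and paralogy/phylogenetic
relatedness between genes. Tests passing on synthetic data therefore
validate the statistical machinery and its calibration, not biological
conclusions about any particular protein family.

## Numerical choices

* Internal CDS coordinates are 1-based inclusive; BED I/O is 0-based
  half-open; the converters in the interval stage are the only place the
  conventions meet.
* Root finding for the generator calibrations runs in log space with
  tolerance 1e-10, because the size-fixing constant can sit many orders
  of magnitude below 1 where an absolute-tolerance search stalls.
* Degenerate inputs are answered explicitly: constant data in the t test
  returns NA with a warning; empty segment or annotation sets yield a
  degenerate enrichment result (p = 1) with a warning; exons shorter than
  10 nt are skipped (and counted) by the control background; a zero null
  mean switches the fold to add-one smoothing with a message.
* Pipeline determinism: `run_pipeline()` derives one seed per stage from
  the master seed, and `report_json()` serializes with full precision
  (`digits = NA`) and no timestamps, so identical configuration and seed
  give byte-identical reports.

## Problem sizes in the checks

The packaged checks run the generator at the study scale of 296 canonical
loops for the end-to-end report, 5,000 randomizations for fold-recovery
checks, 200–500 replicates for p-value calibration, and exhaustive
enumeration on toy workspaces (11 placements) and toy peptides (2¹⁰
re-encodings) where brute force is the oracle. These sizes were chosen so
each statistical claim is tested at the resolution it needs.

## Known limitations

* The scanner reports all overlapping consensus matches; curating them
  into non-redundant motif records (and pairing EF-hands into lobes) is
  out of scope.
* CAI against sparse reference tables depends on the w floor for unseen
  codons; compare like with like when benchmarking against other CAI
  implementations.
* The enrichment null randomizes segments only (annotations fixed), and
  placements ignore chromosome identity beyond workspace membership —
  appropriate for transcriptome-style workspaces, not for isochore-matched
  genomic nulls.
* The χ² positional test pools adjacent loop positions at small n; with
  very few within-loop splits it is reported as NA rather than forced.
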