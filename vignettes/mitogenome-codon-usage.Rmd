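---
title: "Mitogenome composition, codon usage bias and nucleotide diversity: methods"
author: "mitocub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitogenome composition, codon usage bias and nucleotide diversity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocub)
```

# Scope and model

Animal mitochondrial genomes are small circular molecules that typically
carry 37 genes — 13 protein-coding genes (PCGs), 22 tRNAs and 2 rRNAs —
split across the heavy (H) and light (L) strands. Their codon usage is
shaped jointly by mutation pressure (the replication/repair asymmetries that
drive AT richness and strand skew) and natural selection (translational
efficiency and protein constraints). This package implements the standard
analysis chain used to dissect those forces in comparative mitogenomics:

* base composition, AT/GC content and the strand skews
  $\mathrm{ATskew} = (A - T)/(A + T)$, $\mathrm{GCskew} = (G - C)/(G + C)$;
* positional (codon-site) composition: per-position base counts, GC1, GC2,
  GC3 and $\mathrm{GC12} = (\mathrm{GC1} + \mathrm{GC2})/2$;
* relative synonymous codon usage,
  $\mathrm{RSCU}(c) = \dfrac{n_c}{\left(\sum_{c' \in \mathrm{fam}(c)} n_{c'}\right) / |\mathrm{fam}(c)|}$,
  with bias classes *overrepresented* (RSCU > 1.6), *underrepresented*
  (RSCU < 0.6) and *unbiased* otherwise, plus a start/stop codon census;
* the parity-rule-2 (PR2) plot of $y = A_3/(A_3+T_3)$ against
  $x = G_3/(G_3+C_3)$, whose neutral point is (0.5, 0.5);
* the neutrality plot: ordinary least squares of GC12 on GC3 across a
  cohort, with the Pearson correlation tested by the exact t-transform on
  $n-2$ degrees of freedom, classified as *mutation dominant* (significant,
  slope ≥ 0.5), *co-dominant* (significant, slope < 0.5) or *selection
  dominant* (non-significant);
* nucleotide diversity $\pi$ — the mean over all unordered sequence pairs of
  (differences / compared sites) — globally, per gene partition, and in
  sliding windows.

All codon-level work uses the invertebrate mitochondrial genetic code
(translation table 5): TAA/TAG are the only stops, TGA = Trp, ATA = Met and
AGA/AGG = Ser, leaving exactly 62 sense codons whose synonymous families
have sizes 2 (×12), 4 (×6), 6 (Leu) and 8 (Ser).

```{r code}
code <- genetic_code(5)
code
```

# Coordinate and sequence conventions

Internally all coordinates are **1-based inclusive**, matching both the
GenBank flat-file convention and R's own indexing; nothing is shifted at the
I/O boundary, which removes the usual off-by-one hazard entirely rather than
relocating it. Feature locations support `complement(...)` (the L strand)
and `join(...)` (origin-spanning genes on circular molecules); extraction
concatenates the intervals in transcription order and reverse-complements
L-strand features. The deposited strand is treated as the H strand, and
whole-genome composition is computed on it as-is — this is what makes the
characteristic negative AT skews of whole snail mitogenomes directly
comparable between records.

Gene labels are normalized to a canonical 37-gene vocabulary through a
synonym table (COI → COX1, ND2 → NAD2, 16S → rrnL, trnL(CUN) → trnL1, …)
because published records differ in naming; unknown labels are kept as
`other` with a warning rather than an error. Ambiguity codes other than N
are rejected at parse time; N is excluded from the numerator *and*
denominator of every statistic, so no statistic silently treats N as a
mismatch or a base.

## Stop codons and trimming

Mitochondrial PCGs often end on an incomplete stop (T or TA) completed by
post-transcriptional polyadenylation. `extract_coding_seq()` classifies the
stop from the sequence length modulo 3 — a trailing TAA/TAG is *complete*,
a trailing TA (length ≡ 2) is *incomplete_TA*, a trailing T (length ≡ 1) is
*incomplete_T* — and strips it, leaving an in-frame, stop-free `trimmed_nt`
that is the unit of all codon counting and positional composition. A
sequence of length ≡ 0 (mod 3) whose last codon is not a stop is accepted
with a warning (`stop_kind = "none"`) since real annotations occasionally
omit the stop; an internal stop in the trimmed sequence is always a hard
frame error. Start codons are counted at face value (ATN, TTG, GTG all
occupy a codon slot); stop codons are excluded from the RSCU universe and
censused separately.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| RSCU thresholds hi/lo | 1.6 / 0.6 | RSCU | conventional bias cut-offs; strict inequalities, so 1.6 itself is unbiased |
| window / step | 200 / 20 | nt | standard sliding-window setting for mitogenome π profiles; 100/20 is a common alternative and available via `run_config()` |
| neutrality alpha | 0.05 | — | significance of the GC12~GC3 Pearson test |
| slope cut | 0.5 | — | separates mutation dominance (≥ 0.5) from co-dominance below it |
| π deletion mode | pairwise | — | per-pair comparable sites; `complete` drops any column with a gap/N anywhere |
| genetic code | table 5 | — | invertebrate mitochondrial code |

The π deletion default deserves a note: published π values are usually
computed with DnaSP-style tools whose deletion mode is rarely reported, so
both modes are implemented and labelled; on gap-free alignments they agree
exactly.

# The synthetic generator and what it does (not) emulate

`simulate_mitogenome()` builds an annotated circular genome from a
`genome_spec()`: PCGs are sampled codon-by-codon from a 62-entry sense-codon
frequency vector, opened by a start drawn from {ATG .6, ATA .2, ATT .1,
TTG .1} and closed by a stop from {TAA .6, TAG .2, T .1, TA .1}; tRNAs and
rRNAs are i.i.d. sequences at the composition targets; L-strand genes are
stored reverse-complemented. The defaults — 15,000 nt total, AT 0.70,
AT skew −0.10, GC skew +0.10, 13 PCGs totalling ~10.7 kb, 22 tRNAs × 62 nt,
rRNAs of 760 + 920 nt, 9 PCGs + rrnL + 13 tRNAs on the H strand — sit inside
the ranges reported for stylommatophoran land-snail cohorts, which is the
kind of data the chain is meant for.

Two constructions make the generator's truth *analytic* rather than merely
recorded:

1. **Codon frequencies calibrated to the AT target.** Removing the AT-rich
   stop codons from a naive product measure would shift coding AT below
   target, so `codon_freqs_from_composition()` root-finds the base AT level
   at which the renormalized sense-codon distribution has per-base AT equal
   to the target exactly.
2. **Residual-count filler.** Intergenic filler is built with the exact
   base counts needed to bring the whole deposited strand to the
   content/skew targets (shuffled, so it is sequence-random but
   count-exact). If the genic sequence alone overshoots a target by more
   than 2% of the genome, the spec is declared infeasible — asking for
   AT 0.995 with GC-containing codons fails loudly instead of drifting.

Alignments come from a **star phylogeny**: one uniform ancestral row, each
taxon mutating each site independently with probability $p$ to one of the
other three bases. Two lineages then differ at a site with probability
$2p(1-p) + \tfrac{2}{3}p^2$, so expected π has a closed form — chosen
deliberately over a coalescent, because the tests need an analytic oracle,
not realism. Per-partition $p$ gives rate heterogeneity with a known π
ranking.

What the generator does **not** emulate: indels and alignment error (gap
handling is tested on hand-crafted fixtures instead), shared phylogenetic
structure beyond the star (no correlated substitutions), context-dependent
mutation, selection on codon usage within a gene, gene overlap, and
length variation of genes across the cohort. Passing tests therefore
demonstrate that the *statistics are computed correctly* and that parameter
recovery works under a known model — not that real cohorts satisfy that
model.

# Numerical choices

* GC3 (and A3/T3/G3/C3) are computed over **all sense codons**, not only
  synonymous or four-fold degenerate sites — the positional census
  convention, matching how third-position compositions are normally
  tabulated for PR2 work.
* GC12 is computed per gene over that gene's codons only; genes are never
  silently pooled before the regression.
* Cohort RSCU offers both pooling semantics — mean of per-species RSCU
  vectors and RSCU of summed counts — as distinct, labelled outputs,
  because they genuinely differ and published figures rarely say which was
  used.
* Skews with zero denominators are reported as `NA` (undefined), never 0.
* PR2 points exactly on an axis (x or y = 0.5) belong to no quadrant; the
  quadrant convention (I: x>0.5, y>0.5; counter-clockwise) is carried in
  the report output, since published plots often leave it implicit.
* OLS is delegated to `lm()` and the Pearson test to `cor.test()`; a
  constant-GC12 input is a valid fit with slope 0 and r defined as 0,
  while constant GC3 is a degenerate-fit error. The tests hold the fit to
  a hand-written normal-equations oracle at 1e-10.
* Sliding windows anchor at column 1, advance by the step, and drop
  trailing partial windows; a window longer than the alignment yields one
  truncated window with a warning.
* All statistics keep full double precision internally; rounding (4
  decimals for fractions, 3 for π) happens only in the TSV writers of the
  analysis drivers.

# Problem sizes

The default verification runs use a 12-genome synthetic cohort of 15 kb
genomes, alignments of 20 taxa × 10 kb for global π recovery and 12 taxa ×
~7 kb for the partitioned profile, and 10⁴ codons for RSCU recovery —
sizes chosen to match the cohort scale the chain targets while keeping a
full run in the order of seconds.

```{r example}
sim <- simulate_mitogenome(genome_spec(seed = 1))
dataset_composition(sim$genome)[, c("dataset", "length", "pct_AT",
                                    "at_skew", "gc_skew")]
```

# Known limitations

* The GenBank reader covers the flat-file subset that mitogenome records
  use (single record; CDS/tRNA/rRNA keys; `complement`/`join` locations;
  single-line qualifiers). It is not a general GenBank parser.
* tRNA synonym resolution needs an anticodon or an explicit 1/2 suffix to
  separate the duplicated Leu/Ser tRNAs; a bare "tRNA-Leu" is downgraded to
  `other` with a warning.
* Overlapping genes are counted once per feature in gene-set
  concatenations, so shared nucleotides contribute twice to dataset
  lengths; output metadata says so.
* No multiple-testing correction is applied across the 13 per-gene
  neutrality tests, matching standard practice for this analysis; the
  per-gene p-values are all reported, so a reader can apply one.
* ENC, CAI and other codon-usage indices, tRNA secondary structure, and
  phylogenetic reconstruction are out of scope.
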