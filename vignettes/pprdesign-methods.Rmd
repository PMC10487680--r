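---
title: "Designing and screening retargeted PPR proteins with pprdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and screening retargeted PPR proteins with pprdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprdesign)
```

## The problem

Pentatricopeptide repeat (PPR) proteins of the restorer-of-fertility
(RFL) class bind plant mitochondrial transcripts in a modular,
sequence-specific way and typically trigger cleavage near their binding
site. Each ~35-amino-acid P-class motif recognises one RNA base, and
the recognition is governed largely by the residues at motif positions
5 and 35: the canonical combinations ND, NN, SD and SN prefer U, C, G
and A respectively. Because this "PPR code" is combinatorial, a natural
16-motif RFL scaffold can be retargeted by editing a handful of
position 5/35 residues, and a whole library of such variants can be
built from a small set of synthesized DNA fragments and screened in
planta for mitochondrial gene knock-downs.

`pprdesign` implements the computational side of that workflow as
composable, individually testable steps:

1. **Scaffold model** — a PPR scaffold couples motif-level residue
   codes with the CDS that encodes them (`ppr_scaffold()`,
   `synth_scaffold()`, `apply_edits()`).
2. **Scoring and target prediction** — an additive log-odds matrix per
   scaffold (`build_pssm()`), scanned over transcript or genome
   sequences (`scan()`, `predict_library_targets()`).
3. **Library and fragment design** — combinatorial enumeration
   (`enumerate_variants()`) and synthesis-fragment tiling with an
   in-silico reassembly check (`design_fragments()`,
   `assemble_in_silico()`).
4. **Genotyping** — allele-discriminating qPCR primer design
   (`design_allele_primers()`).
5. **Phenotyping** — plate-image leaf-area quantification and 2-means
   growth classification (`measure_leaf_area()`, `classify_growth()`).
6. **Molecular read-outs** — delta-delta-Ct relative expression
   (`relative_expression()`) and strand-aware cleavage coordinate
   arithmetic (`cleavage_fragments()`, `tally_clone_ends()`).
7. **Synthetic data** — seeded generators with queryable ground truth
   for every input (`make_genome()`, `make_plate_image()`,
   `make_ct_table()`, `make_clone_ends()`, `write_scenario()`).

## The scoring model

A code table maps each (res5, res35) pair to affinity weights over
{A, C, G, U}. Published motif/base frequency tables can be loaded from
TSV (`read_code_table()`); the shipped default is deliberately simple —
weight 0.9 on the preferred base of the four canonical pairs and 0.1/3
elsewhere — because a flat, transparent prior makes the scan behaviour
easy to reason about and easy to override. Weights are regularised with
a pseudocount (default 0.01) and renormalised; pairs absent from the
table (for example the non-standard GG and SS motifs of the natural
scaffold before canonicalisation) score as uniform and are flagged
non-canonical.

For a scaffold with motifs $m_1 \dots m_L$ the score of an RNA window
$b_1 \dots b_L$ is the additive log-odds

$$ S = \sum_{i=1}^{L} \log \frac{w_{m_i}(b_i)}{\pi(b_i)} , $$

with $\pi$ a background composition (default uniform). The N-terminal
motif aligns with the 5'-most bound base. `scan()` reports, per hit,
the 1-based position of that 5'-most base *on the hit's own strand*
(for minus-strand hits this is the larger genome coordinate), which
keeps the registration convention identical on both strands. Genome
scans score both strands (`both_strands = TRUE`); transcript scans
score the given strand only. Circular records (plant mitochondrial
genomes) allow windows to wrap the origin. The option `offset5 = 1`
prepends one unscored 5' base to the reported site, for proteins whose
footprint is one base longer than their motif count, as observed for
some 16-motif proteins with 17-nt binding sites.

Ties in the ranking are broken by (transcript id, start, strand)
ascending, so results are reproducible to the byte. Windows containing
ambiguous bases are skipped rather than scored.

## Residue edits and codon choice

`apply_edits()` rewrites a motif's position 5 or 35 codon. Among the
codons of the new residue it picks the one with the fewest nucleotide
changes from the current codon, breaking ties by the lexicographically
smallest codon. This mirrors how point mutagenesis is actually done,
keeps edits minimal at the DNA level (which matters for the
allele-discriminating primers later), and is fully deterministic. An
edit carries its expected `from_res` and fails loudly when it does not
match the scaffold — stale edit lists cannot silently corrupt a design.

The package ships the two worked edit sets of the retargeting
programme: `mrpf2_edits()` (canonicalising P6 GG and P9 SS to SN) and
`atp1_retarget_edits()` (P8 position 5 S→N plus P15 position 35 N→D;
with `full = TRUE` also the two P13 edits of the directly engineered
construct).

## The synthetic scaffold

The real RFL scaffold's full CDS is not redistributed here; instead
`synth_scaffold()` generates a deterministic stand-in: 16 motifs of
exactly 105 bp (35 codons), position 5/35 codons encoding configurable
codes, all other codons random non-stop codons, and 30 bp constant
arms on both sides representing vector-homology sequence. The default
codes are random canonical pairs except where the retargeting examples
need specific values (P6 = SN, P8 = SD, P9 = SN, P13 = NT, P15
position 35 = N); `variant = "RPF2"` instead produces the
pre-canonicalisation codes P6 = GG, P9 = SS. The generator is a pure
function of its seed, so any test or scenario can be reproduced
exactly. All of this is synthetic and is labelled as such; what passing
tests show is that the *algorithms* behave correctly on sequences with
known structure, not that any particular natural scaffold sequence is
reproduced.

## Library enumeration and fragment design

The default `variable_plan()` varies motifs 2, 5, 8, 11, 14 at
position 35 and motifs 3, 6, 9, 12, 15 at position 5 — ten independent
binary choices, hence $2^{10} = 1024$ variants. The alternative residue
defaults to the canonical-code swap (S↔N at position 5, D↔N at
position 35), keeping every variant motif on a canonical recognition
pair; any other choice can be supplied per motif. Variant ids are the
zero-padded bitmask value with bit 1 on the lowest-index variable
motif, so id `0000` is the unedited scaffold and the id alone
identifies the altered motif set.

`design_fragments()` tiles the 16 motifs into windows of 4 advancing
by 3 (P1–P4, P4–P7, P7–P10, P10–P13, P13–P16), so consecutive
fragments share one fixed boundary motif. Synthesis constraints are
enforced, not assumed: each fragment must be 251–500 bp with at least
125 bp of invariant sequence at each end and at most 18 variable bases.
A single 105 bp terminal motif cannot provide a 125 bp fixed end, so
internal fragment ends are extended 20 bp into the adjacent constant
CDS and terminal fragments absorb the whole constant arm. With the
default synthetic scaffold this yields 460–470 bp fragments with
145 bp junction overlaps. `assemble_in_silico()` then verifies the
design the way the cloning step would: consecutive fragments must share
an exact suffix/prefix overlap of at least 20 bp (collapsed once), and
reassembly of any variant's fragments must reproduce that variant's CDS
byte-for-byte — a property the test-suite fuzzes over seeded variants.

## Allele-discriminating primers

Each variable motif is genotyped with two forward primers that end
(3') exactly on the most 3' base differing between the wild-type and
edited codons, plus a shared downstream reverse primer. Both forward
primers carry a deliberate mismatch at the penultimate position — the
transversion of the template base, chosen to differ from both alleles —
which destabilises extension from the wrong allele far more than from
the right one. Primer lengths (18–30 nt) are tuned toward a target
melting temperature; amplicons are kept within 80–250 bp (a qPCR
convention, configurable), and the reverse primer is kept clear of the
discriminated base so it is truly common to both assays.

Melting temperatures come from a self-contained nearest-neighbour
model: the unified duplex parameter set (Allawi & SantaLucia 1997) with
terminal initiation terms, the entropic salt correction
$0.368\,(N{-}1)\ln[\mathrm{Na^+}]$ at 50 mM monovalent salt, and total
primer concentration 250 nM with the factor-of-4 symmetry correction
for non-self-complementary duplexes. The parameter set and conditions
are fixed and named here precisely because thermal-gradient
optimisation on the bench is empirical; the model is a ranking tool,
not a replacement for it. The test suite checks the implementation
against an independently coded sum over the same published table.

Synonymous edits, or template geometry that leaves no room for a
compliant primer, raise a typed `pprdesign_undesignable` condition —
never a silent failure. A Tm window that cannot be met is reported as
a flagged best attempt with a warning.

## Leaf-area quantification

Plate photographs (100 cm², 2278 × 2278 px by default) are processed
exactly as specified for the screen: each channel is linearly
stretched to the full intensity range; every pixel's colour difference
from dark leaf green `#003300` is computed (CIEDE2000 in CIE Lab under
sRGB/D65 by default, via farver; plain RGB Euclidean as a faster
option — the colour space of the perceptual metric is a declared
choice, since "colour difference" alone does not pin one down); pixels
strictly below half the median difference are leaf pixels; and counts
are calibrated as $(10\sqrt{A_{cm^2}}/\mathrm{px})^2$ mm² per pixel —
about 0.193 mm² with the defaults, so a fully covered plate measures
exactly 10,000 mm². The half-median rule is scale-free, which is what
makes the measurement robust to lighting and resolution (the suite
checks mm² invariance when the same scene is rendered at twice the
resolution).

Two known limitations are worth stating. First, the half-median rule
assumes leaf material is a minority of the plate; if leaves cover a
large fraction, the median itself moves. Second, on a plate with *no*
leaf material, per-channel contrast stretching amplifies background
noise so that a small fraction of pixels (about 0.3% in the synthetic
scenes) lands near the dark reference and is counted; the empty-plate
measurement therefore has a small false-positive floor rather than
being exactly zero. Real screening plates always contain seedlings, so
neither regime is the operating point.

`classify_growth()` partitions per-line mean areas (week-3 values in
the screening design) by 1-D 2-means with deterministic initial
centers at the observed minimum and maximum, labels the lower-center
group "slow", and warns if supplied slow/fast control lines land in
the same group. Two lines split trivially; fewer than two distinct
values fall back to a single group with a warning.

## Expression and cleavage arithmetic

`relative_expression()` implements delta-delta-Ct with the replicate
structure used in the screen (3 biological × 3 technical): technical
replicates are averaged first; delta-Ct is taken against the mean of
the user-specified reference transcripts within each biological
replicate; the calibrator sample's mean delta-Ct is subtracted; and
the log2 fold change is the negative of the result, with the standard
deviation across biological replicates as the error estimate (the
error bars are biological, matching how such figures are drawn). The
normaliser is user-specified because screening datasets differ in
which transcripts are stable.

Coordinates are 1-based inclusive throughout, matching GenBank usage.
A cleavage site is the ordered pair of flanking positions, so a cut is
unambiguous regardless of strand. `cleavage_fragments()` assigns the
two pieces to the transcript's 5' and 3' sides by strand and reports
both size conventions explicitly: inclusive base counts (which sum
exactly to the region length — fuzz-tested) and the gel-facing
coordinate difference, which is one less. For the atp1-like region
66,938–68,982 (2045 nt, minus strand) cut between 67,227 and 67,228,
the 3' product is 290 nt inclusive and 289 nt by coordinate
difference; surfacing both avoids the perennial off-by-one between
annotation arithmetic and ladder reading.

## Synthetic data and what the tests mean

Every pipeline input has a seeded generator with queryable truth:
circular genomes with planted consensus sites on either strand
(`make_genome()`), plate scenes of dark-green discs with exact painted
pixel counts (`make_plate_image()`), Ct tables with known fold changes
(`make_ct_table()`), and clone-end samples concentrated at a known
cleavage position (`make_clone_ends()`). One scenario seed fans out to
fixed per-generator substreams, so scenarios are reproducible while
generators stay independent; `write_scenario()` materialises a full
file-based scenario (FASTA, TSV, PNG, CSV, JSON truth).

The generators emulate the *structure* of the real inputs, not their
noise processes: genome backgrounds are i.i.d. (no codon structure or
repeats), disc colours have Gaussian jitter (no shadows, specular
highlights or overlapping seedlings), and Ct noise is homoscedastic.
Passing tests therefore demonstrate correctness of the arithmetic and
the recovery behaviour under controlled conditions; they do not certify
performance on real photographs or real qPCR plates.

Problem sizes in the routine test-suite and benchmark script are kept
modest by design — 300–400 px plate scenes, 20 kb genomes, 50-variant
round-trip samples and 50-seed Ct replications — which is ample to pin
down the deterministic quantities exactly and the stochastic ones to
well inside their tolerances.

## Numerical and convention choices, collected

* Pseudocount 0.01 on code-table weights; uniform default background.
* Minimal-change codon with lexicographic tie-break for edits.
* Motif coordinates 1-based inclusive; "position 5" is codon 5 of the
  motif (CDS offset 12–14 from the motif start).
* Scan ties broken by (transcript id, start, strand); `min_score`
  default 0 (better than background); `top_k` default 5.
* Strictly-less-than at the half-median segmentation threshold.
* sRGB decoding with D65 white point for hex colours.
* Tm: Allawi & SantaLucia 1997 unified parameters, 50 mM Na+, 250 nM
  total primer, CT/4 symmetry factor.
* Between-base cleavage sites as ordered position pairs; both
  inclusive and coordinate-difference fragment sizes reported.

## A compact end-to-end example

```{r example}
scaffold <- synth_scaffold(seed = 1)
variant <- apply_edits(scaffold, atp1_retarget_edits(), name = "variant_280")
gen <- make_genome(1, length = 20000,
                   sites = data.frame(name = "atp1_site", position = 15000,
                                      strand = "-",
                                      site_seq = rna_to_dna(consensus_site(variant))))
scan(build_pssm(variant), gen$genome, top_k = 2, both_strands = TRUE)

fr <- design_fragments(variant)
identical(as.character(assemble_in_silico(fr)), variant$cds)

cleavage_fragments(transcript_region("BK010421-like", 66938, 68982, "-",
                                     cleavage_site = c(67227, 67228)))[1:3]
```
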