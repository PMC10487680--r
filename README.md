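# pprdesign

Design and screening toolkit for retargeted pentatricopeptide repeat
(PPR) proteins of the restorer-of-fertility (RFL) class.

P-class PPR proteins bind RNA one base per ~35-amino-acid motif, with
specificity set mainly by the residues at motif positions 5 and 35:
the canonical pairs ND, NN, SD and SN prefer U, C, G and A. Editing a
few of these residues retargets a natural 16-motif RFL scaffold to a
new mitochondrial transcript, where binding typically triggers
cleavage — a route to a combinatorial library of mitochondrial
"mutants". `pprdesign` implements the computational workflow around
such a library, for molecular biologists building or screening one:

* **PPR-code scoring and target prediction** — pluggable
  (res5, res35) → base affinity tables; per-scaffold log-odds matrices
  $S = \sum_i \log(w_{m_i}(b_i)/\pi(b_i))$; strand-aware scans of
  linear or circular sequences with deterministic ranking
  (`ppr_code_table`, `build_pssm`, `scan`, `predict_library_targets`).
* **Residue editing** — minimal-nucleotide-change codon edits with
  stale-edit protection (`apply_edits`, `mrpf2_edits`,
  `atp1_retarget_edits`).
* **Library and fragment design** — the 2^10 = 1024-variant default
  design space over ten variable motifs; tiling into five overlapping
  synthesis fragments (P1–P4 … P13–P16) under the 251–500 bp / 125 bp
  fixed-flank constraints; in-silico Gibson reassembly verification
  (`enumerate_variants`, `design_fragments`, `assemble_in_silico`).
* **Genotyping** — allele-discriminating qPCR primer pairs with a 3'
  terminal base on the SNP and a deliberate penultimate mismatch;
  nearest-neighbour Tm model (`design_allele_primers`, `tm_nn`).
* **Phenotyping** — plate-image leaf-area measurement (contrast
  stretch, CIEDE2000 difference from `#003300`, half-median threshold,
  mm² calibration) and 2-means slow/fast growth classification
  (`measure_leaf_area`, `classify_growth`).
* **Expression and cleavage** — delta-delta-Ct with technical
  replicates averaged first; 1-based cleavage coordinate arithmetic
  reporting both inclusive and gel-facing fragment sizes; cRT-PCR
  clone-end tallies (`relative_expression`, `cleavage_fragments`,
  `tally_clone_ends`).
* **Synthetic data** — seeded generators with queryable ground truth
  for every input: planted-site genomes, plate scenes, Ct tables,
  clone ends (`make_genome`, `make_plate_image`, `make_ct_table`,
  `make_clone_ends`, `write_scenario`).

See the methods vignette (`vignettes/pprdesign-methods.Rmd`) for the
model, conventions and design choices.

## Worked example

Retarget the synthetic 16-motif scaffold toward an atp1-like site,
recover the planted site from a circular genome, and verify the
fragment design:

```r
library(pprdesign)

scaffold <- synth_scaffold(seed = 1)
scaffold
#> PPR scaffold 'synth-mRPF2-s1': 16 motifs, CDS 1740 bp
#>   position 5/35 codes: NN NN SN NN ND SN SD SD SN SD SD SD NT SN SN ND

variant <- apply_edits(scaffold, atp1_retarget_edits(), name = "variant_280")
gen <- make_genome(1, length = 20000,
                   sites = data.frame(name = "atp1_site", position = 15000,
                                      strand = "-",
                                      site_seq = rna_to_dna(consensus_site(variant))))
scan(build_pssm(variant), gen$genome, top_k = 2, both_strands = TRUE)
#>   transcript_id start strand     score         site_seq
#> 1 synth_mito_s1 15000      - 18.791445 CCACUAGUAGGGAAGU
#> 2 synth_mito_s1 17312      +  6.613355 CCAUUAGUUGCGUAGG
```

The planted site returns as the rank-1 hit at its planted position
(15,000) and strand; the score is the summed per-motif log-odds, and
`site_seq` is the bound RNA window 5'→3' on its strand.

```r
fr <- design_fragments(variant)
fr
#> gblock_set for 'variant_280': 5 fragments
#> F1: motifs P1-P4, 470 bp, flanks 237/215 bp, 6 variable base(s)
#> F2: motifs P4-P7, 460 bp, flanks 227/215 bp, 6 variable base(s)
#> F3: motifs P7-P10, 460 bp, flanks 227/215 bp, 6 variable base(s)
#> F4: motifs P10-P13, 460 bp, flanks 227/215 bp, 6 variable base(s)
#> F5: motifs P13-P16, 470 bp, flanks 227/225 bp, 6 variable base(s)
identical(as.character(assemble_in_silico(fr)), variant$cds)
#> [1] TRUE
```

All five fragments sit inside the 251–500 bp synthesis bounds with
well over 125 bp fixed flanks, and reassembling them through their
junction overlaps reproduces the variant CDS exactly.

```r
design_allele_primers(scaffold, motif_edit(8, 5, "S", "N"))
#> allele primers for P8 pos5 (amplicon 150 bp):
#>   WT       5'-GTTCAGTGACACCCTCTGGTTACG-3'  (24 nt, Tm 59.1 degC, penultimate mismatch C)
#>   variant  5'-GTTCAGTGACACCCTCTGGTTACA-3'  (24 nt, Tm 58.1 degC, penultimate mismatch C)
#>   reverse  5'-TGGAGTCGTTTTGGGTGCCG-3'  (20 nt, Tm 59.7 degC)
```

The two forward primers differ only at the 3'-terminal base (G for the
wild-type AGC serine codon, A for the edited AAC asparagine codon) and
share the deliberate penultimate mismatch.

```r
cleavage_fragments(transcript_region("BK010421-like", 66938, 68982, "-",
                                     cleavage_site = c(67227, 67228)))[1:3]
#> $five_prime_len
#> [1] 1755
#> $three_prime_len
#> [1] 290
#> $gel_size_nt
#> [1] 289
```

The 2045 nt minus-strand region cut between 67,227 and 67,228 gives a
3' product of 290 nt by inclusive count and 289 nt by coordinate
difference — the size a gel ladder reports.

```r
relative_expression(make_ct_table(1, fold_changes = c(atp1 = 0.25, atp6 = 1.3)))
#>   sample transcript log2fc      sd n_bio
#> 1   line       atp1 -1.875 0.00758     3
#> 2   line       atp6  0.476 0.13671     3
#> 3   line        ref  0.000 0.00000     3

pl <- make_plate_image(1, discs = data.frame(x = 200, y = 200, r = 40), dim = 400)
measure_leaf_area(pl$image, plate_px = 400, n_seedlings = 12)
#> leaf area: 5025 px = 314.1 mm^2 (26.2 mm^2/seedling over 12 seedlings), threshold 38.1
```

The planted 4-fold atp1 depletion is recovered as log2 fold ≈ −2
(here −1.88 under 0.2-cycle Ct noise), and the painted 5,025-pixel
disc is measured exactly, converted with the plate calibration.

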