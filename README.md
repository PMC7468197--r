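# crucivir

Discovery and characterization of **cruciviruses** — CRESS-DNA viruses
(circular Rep-encoding single-stranded DNA viruses) whose capsid protein is
homologous to the capsids of *RNA* tombusviruses — from assembled
metagenomic contigs.

The package is written for environmental virologists mining viromes for
capsid-gene transfer across the RNA/DNA divide. It implements the full
desk pipeline such a survey needs:

* **Circular-genome resolution** — assemblers emit circular replicons as
  linear contigs whose 3' end repeats the 5' start; the longest exact
  terminal redundancy is detected and trimmed
  (`detect_terminal_redundancy()`).
* **Capsid homology screen** — six-frame translated Smith–Waterman search
  of each contig against a capsid reference library, retained at a bit
  score ≥ 50, with bit scores and E-values from the Karlin–Altschul
  transformation (bits = (λ·S − ln K)/ln 2, gapped BLOSUM62 λ = 0.267,
  K = 0.041).
* **Gene annotation** — maximal ATG-to-stop ORFs on all six frames of the
  *circle* (ORFs may wrap the origin), homology classification into
  capsid / Rep / putative ORF, with two rescue paths for broken *rep*
  frames: the ciliate genetic code (translation table 6, TAA/TAG → Gln)
  and GT..AG intron splicing with a minimal-intron rule
  (`find_orfs()`, `detect_splice_candidates()`).
* **Stem-loop origin of replication** — both strands of the circle are
  scanned for degenerate CRESS nonanucleotides (NANTANTAN, NAKWRTTAC,
  TAWWDHWAN, TRAKATTRC), a ±20 nt window around each hit is folded, and
  the cradling hairpin is scored as
  `score = |stem − 11 bp| + |loop − 11 nt|`, accepted at score ≤ 15 with
  a stem > 4 bp and loop ≥ 7 nt, plus the same-first-base and
  motif-near-stem-end exclusion rules (`find_stemloops()`).
* **Protein motif profiling** — the seven conserved Rep motifs (HUH
  endonuclease motifs I/II/III; superfamily-3 helicase Walker A/B,
  motif C, Arg finger) from an editable pattern table; motif-II trigram
  classes (HUH / HUQ / HYQ / other); capsid R/S/P domain partition with
  Gly-tract, DxDxxD Ca-binding motif and isoelectric-point profile;
  CruV vs CruCGE call (`find_rep_motifs()`, `partition_capsid()`).
* **Diversity** — SDT-style pairwise-identity matrices, mean ± SD,
  threshold clustering by connected components, one-way ANOVA across
  protein classes, and E-value-thresholded similarity networks
  (`pairwise_identity_matrix()`, `cluster_by_threshold()`,
  `build_similarity_network()`).
* **Synthetic genomes with ground truth** — `generate_genome()` /
  `generate_dataset()` plant a nonanucleotide-bearing hairpin, capsid and
  Rep CDSs (unisense or ambisense, chosen motif-II class, optional
  intron, optional ciliate code) into background sequence at a controlled
  GC, and record every coordinate, so every detector is testable without
  downloads.

Input/output: FASTA and GenBank flat files (circular topology, `join()`
across the origin), GFF3, TSV tables, GraphML networks.

## Worked example

```r
library(crucivir)

ds  <- generate_dataset(6, seed = 42)      # 6 synthetic crucivirus-like genomes
res <- run_discovery(ds$collection)        # full pipeline
res$table[, c("name","type","length","gc","orientation",
              "nonanucleotide","stemloop_score","motif2_class")]
#>      name type length    gc orientation nonanucleotide stemloop_score motif2_class
#> 1 CruV-81 CruV   2780 44.42    unisense      CAGTATTAT              4          HUQ
#> 2 CruV-82 CruV   3163 42.36   ambisense      TAATACTAT              1          HUQ
#> 3 CruV-83 CruV   3269 44.66   ambisense      TAATACTAT              3          HUQ
#> 4 CruV-84 CruV   4933 46.91    unisense      TAATACTAC              4          HUQ
#> 5 CruV-85 CruV   5244 47.67   ambisense      TATATATAT              4          HUQ
#> 6 CruV-86 CruV   6655 42.30   ambisense      TAATATTAT              1          HUQ
```

Each row is one resolved circular genome: its sequential name (numbering
continues the historical crucivirus series, smallest genome first), CruV
vs CruCGE call, length and GC, the relative orientation of capsid and
*rep*, the best accepted origin nonanucleotide with its hairpin deviation
score (0 = ideal 11 bp stem / 11 nt loop), and the Rep motif-II class
(HUQ = His-hydrophobic-Gln, the variant typical of circo- and
nanoviruses).

A single origin annotation prints as

```r
Filter(function(a) a$accepted, find_stemloops(ds$collection$records[[1]]))[[1]]
#> <StemLoop> TAGTACTAA@237(-) stem 6 loop 17 score 11 accepted
```

i.e. the 9-mer TAGTACTAA at forward-strand position 237, read on the
minus strand, cradled by a 6 bp stem around a 17 nt loop (score
|6−11| + |17−11| = 11 ≤ 15).

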