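---
title: "Crucivirus discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crucivirus discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crucivir)
```

Cruciviruses are circular Rep-encoding ssDNA (CRESS-DNA) viruses whose
capsid protein is homologous to the capsid of tombusviruses — RNA
viruses. A survey for them in assembled metagenomes needs a chain of
small, well-defined decisions: what counts as a circular genome, what
counts as a capsid hit, how an origin of replication is recognized and
scored, how a broken *rep* frame is rescued, and how diversity is
quantified. This vignette records the model behind each stage, the
parameters that matter, and the choices made where the design was
genuinely open.

## Circularity from terminal redundancy

De novo assemblers emit a circular replicon as a linear contig whose 3'
end repeats its 5' start exactly. `detect_terminal_redundancy()` searches
the longest proper suffix equal to a prefix, from half the contig length
down to `min_overlap`, and trims it. The default `min_overlap = 10`
balances false circles (a chance 10-mer repeat has probability ~10⁻⁶ per
contig end) against missed short redundancies; it is a package choice, as
assemblers differ in the overlap they leave. Only exact repeats are
considered: assemblers emit exact duplications, and resolving mismatched
overlaps is assembly polishing, out of scope here.

Internally all coordinates are 0-based, half-open, anchored on the
forward strand; a feature segment whose end does not exceed its start
wraps across the origin. Conversion to 1-based inclusive coordinates
happens only at GenBank/GFF3 serialization, where wrap-around features
become `join()` across the origin. `canonical_rotation()` (Booth's
least-rotation algorithm) gives a deterministic representative for
circular sequence comparison.

## The capsid screen

Candidate genomes are those whose six-frame translation aligns to a
capsid reference protein with a bit score of at least 50. Alignments are
affine-gap Smith–Waterman (BLOSUM62, gap open 11, extend 1); raw scores
become bit scores through the Karlin–Altschul transformation
bits = (λ·S − ln K)/ln 2 with the gapped BLOSUM62 constants λ = 0.267,
K = 0.041, recorded in `karlin_altschul_params()`. Using fixed published
constants rather than an external search engine keeps every score
reproducible from the package alone; for the ~50-bit regime the screen
operates in, the difference from a full BLAST statistics fit is well
inside the threshold's own arbitrariness.

## Stem-loop origins and their score

Rolling-circle replication initiates at a conserved nonanucleotide
presented in the loop of a DNA hairpin. Detection has three stages:

1. **Scan** both strands of the circle (wrapping the origin) for the
   degenerate 9-mers NANTANTAN, NAKWRTTAC, TAWWDHWAN and TRAKATTRC under
   IUPAC semantics.
2. **Fold** a window of the motif ± 20 nt (flank configurable in 15–20)
   on the hit's strand and extract the hairpin that cradles the motif.
3. **Score** the hairpin by its deviation from the ideal geometry,
   `|stem − 11| + |loop − 11|`, accept at score ≤ 15 with stem ≥ 5 bp and
   loop ≥ 7 nt, then apply two exclusions: among accepted hairpins
   sharing the same first nucleotide (on their own strand) only the
   best-scoring survives, and a motif lying within 4 bases of the
   hairpin's first or last nucleotide is rejected.

The folding backend deserves its own paragraph. The default,
`nussinov_dna`, is a maximum-base-pairing nested dynamic program over
Watson–Crick pairs with G·T wobble and a minimum loop of 3 — fully
deterministic and verifiable against brute-force enumeration, which the
test suite does on hundreds of random windows. But the *reported
hairpin* is deliberately not read off a traceback of that structure, for
two reasons discovered during development. First, among co-optimal
maximum-pairing structures a greedy traceback freely fragments a long
planted helix into scattered pairs, so the choice of representative
structure — not the optimum itself — would decide the annotation.
Second, maximum-pairing folding has no energy model: a single chance
pair inside a loop costs nothing and always forms, so any
self-complementary nonanucleotide (TAGTATTAC pairs its own G and C ends)
collapses its loop below the geometry filter. Thermodynamic folders
avoid this because isolated short pairs are unstable; a pairing-count
model cannot. The package therefore selects the hairpin by direct
enumeration of all maximal contiguous helices in the window, with the
motif's bases 3–9 constrained single-stranded — the nonanucleotide is
the nicking substrate and must be presented unpaired, while its first
two bases may descend into the stem, as they do in origins whose loop is
shorter than the motif. Among candidate helices, those whose enclosed
loop contains the motif midpoint are preferred, then those meeting the
geometry filter, then the lowest deviation score, then the longer stem
and the more centered loop. Every hairpin records the backend that
produced it, and a user-supplied folding function can replace the
default.

Two further conventions: the same-first-base key is strand-specific
(a hairpin is a hairpin on both strands, and a shared genomic key would
let a minus-strand reading of the same structure silently evict the
plus-strand annotation); and the de-duplication tie-breaks are score,
then loop deviation, then motif-to-apex distance, then strand, then
position — the apex distance term keeps the register that places the
nonanucleotide at the loop apex, which is where the biology puts it.

When one genome yields several accepted annotations at different loci
with similar scores, all are kept and reported; real surveys show the
same multiple-annotation behavior.

## ORFs, the ciliate code, and splice rescue

`find_orfs()` reports maximal ATG-to-stop ORFs (stop codon included) on
all six frames of the circle; an ORF may wrap the origin. The reporting
threshold of > 300 nt matches the convention for "putative ORFs", and the
300 counts the stop codon. Classification is by best local alignment to
the reference library: a product class is assigned at ≥ 25% identity
over ≥ 50% of the reference length — the homology lives in protein
space, so the nucleotide-similarity convention of interactive annotation
tools is re-expressed at protein level.

Some *rep* genes cannot be read in one frame. Two rescue paths run only
when the standard-code annotation leaves a class missing or fragmentary
(covering < 80% of its reference): first the ciliate genetic code
(translation table 6, TAA/TAG → Gln, TGA still stop), mirroring the
observation that some genomes only yield complete proteins under a
relaxed code; then intron splicing. The splice model is canonical GT..AG
donor/acceptor dinucleotides with configurable bounds (40–2000 nt as a
library function; the pipeline caps candidate introns at 300 nt, the
scale of the plant-virus introns these genomes resemble). All candidate
donor/acceptor pairs are tried in order of increasing intron length and
the first excision producing a stop-free ORF that spans the junction and
contains both an HUH-type endonuclease motif and a Walker A motif wins —
the minimal-intron rule. The rescued product must also be substantial:
at least 100 residues as a library default, and at least 80% of the
reference Rep length inside the pipeline. Without that floor, short
chance GT..AG excisions can satisfy the two motif regexes in junk
reading frames and the minimal-intron rule would prefer them to the
real intron. The exact donor/acceptor context used by any particular
study is not fixed here; the consensus is a parameter.

## Rep motifs and the CruV/CruCGE boundary

Motif patterns are data, not code: a TSV
(`inst/extdata/rep_motif_patterns.tsv`, mirrored by
`default_rep_motif_patterns()`) maps each conserved motif to a regular
expression and an expected region — endonuclease motifs I (FT[LI]NN-like),
II (H-x-[HQ]) and III (Y-x(2,3)-K) in the N-terminal 60% of the protein,
helicase Walker A (G-x(4)-G-K-[TS]), Walker B (hh-D-[DE]) and motif C
(h-x-T-S-N) in the C-terminal region, and the Arg finger within 40
residues downstream of motif C. Published logo figures do not print
regexes, so these consensus defaults are editable without touching code;
the geminivirus GRS pattern ships disabled and marked low-confidence.
Region windows exist to prevent cross-domain matches and their fractions
are configurable.

The motif-II trigram classifies as HUH (His-hydrophobic-His), HUQ
(His-hydrophobic-Gln), HYQ (exactly), or other; the hydrophobic set
{A,V,L,I,M,F,W,C} is configurable since the literature does not enumerate
membership for the "U" position. A genome is called CruCGE rather than
CruV when it has no Rep CDS at all, or when its Rep-homologous region
carries none of the seven motifs.

Capsid proteins partition into R/S/P domains by sliding a gapless
position-specific log-odds profile of reference S-domains over the
protein; the best window is the S-domain, the prefix is the R-domain and
the suffix the P-domain, so the three always tile the protein. Gapless
scoring is chosen for determinism — a gapped profile aligner would buy
little for a domain whose length is nearly constant and would make the
boundaries depend on gap parameters. The Gly-rich tract is the maximal
window of ≥ 8 residues with ≥ 50% glycine inside R (note that such a
maximal window can extend a few residues into G-poor flanks while
staying above 50%); the Ca-binding motif is every overlapping D-x-D-x-x-D
in S; the isoelectric-point profile uses bisection on the
Henderson–Hasselbalch net charge with the EMBOSS pKa table, windows
truncated at the ends.

## Diversity: identity, clusters, networks

Pairwise identity is global Needleman–Wunsch (BLOSUM62, affine gaps)
with PI = identical columns / alignment length, counting internal gap
columns and excluding terminal overhangs — the definition is recorded in
every matrix because the underlying convention is ambiguous across
tools. Summary statistics default to the sample (n−1) standard
deviation. A single deterministic alignment engine serves both capsid
and Rep; published matrices built with MAFFT or MUSCLE inside SDT will
differ by an engine-dependent offset of a couple of percentage points,
which is why reproduction of printed PI means is a tolerance question
rather than a contract.

Threshold clustering builds a graph with an edge when min_pi < PI <
max_pi (strict), collapses 100%-identical pairs to one representative
first ("nonidentical sequences"), and reports connected components of at
least `min_size` members. Single linkage is the weakest — hence most
inclusive — interpretation of clusters identified visually from an
ordered matrix; a clique mode is provided for the strict reading, and
component mode is the default. Cluster order (by size, then smallest
member id) and everything else in the module is independent of input
order.

Similarity networks convert all-vs-all local scores to E-values
E = K·m·n·e^(−λS) and keep edges below the cutoff (10⁻²⁰ for capsid-like
sets, 10⁻¹⁰ for the more divergent Reps); isolated nodes are retained so
divergent sequences remain visible. Edge sets nest monotonically in the
cutoff, and the network of a given input is byte-deterministic — these
two properties, not any particular published figure, are what the module
guarantees.

One-way ANOVA across protein classes uses the classical between/within
F statistic; the all-groups-constant, equal-means corner returns F = 0,
p = 1 by convention.

## The synthetic-genome generator

`generate_genome()` plants, into i.i.d. background sequence, a hairpin
(stem + loop + reverse-complemented stem, nonanucleotide at the loop
apex; when the loop is shorter than 9 nt the motif's 5' overhang
descends into the ascending arm), a capsid CDS and optionally a Rep CDS.
The CDSs are *mutated copies of a deterministic synthetic reference
library* — not independent random proteins — so the homology screen and
classifier face genuine divergent homology (~85% identity by default).
Each CDS is preceded by a TGA pad (a stop under both genetic codes) so
its maximal ORF starts exactly at the planted ATG; reverse translation
draws synonymous codons weighted toward the target GC, and the
background GC is compensated for the composition of the planted inserts
so the realized genome GC tracks the target within ~1 point at 3 kb.
Rep motif instantiations are planted at fixed offsets; random scaffold
positions exclude H/Y/W so no endonuclease-motif regex can arise by
chance, and point substitutions draw from an alphabet that cannot
complete a Walker pattern. An intron, when requested, is 90 nt of
G-free interior flanked by GT..AG, which makes the planted intron the
unique minimal solution with overwhelming probability.

`sample_synthetic_spec()` fixes the study conditions: lengths uniform on
2,474–7,947 nt, GC normal (mean 42.9, sd 4.9, truncated to 25–65),
stems 5–14 bp, loops 7–15 nt, a motif menu dominated by TAGTATTAC, 2%
of genomes without *rep*, ambisense:unisense 58:40, motif-II classes at
HUQ 70% / HYQ 12% / HUH 4.8% / other 13.2%, helicase motifs absent in
~3% of Reps, an intron in ~8%, a Ca-binding motif in ~15% of capsids,
and the ciliate code in ~1%. Datasets derive one RNG stream per genome
from (master seed, index), so generation is reproducible and
order-independent.

What the generator does *not* emulate: sequencing error, chimeric
contigs, uneven coverage, compositional heterogeneity along the genome,
overlapping genes, and real phylogenetic structure deeper than
"families = mutated ancestors". Passing tests therefore demonstrate
correctness of the detectors under clean, known-truth conditions — not
performance on raw environmental viromes.

"Recovery" of a planted origin is scored as: an accepted annotation on
the planted strand whose hairpin cradles the planted nonanucleotide
position. The stricter reading — identical motif register — is not
meaningful, because overlapping degenerate patterns can match the same
planted hairpin a few bases apart and the same-first-base rule then
keeps exactly one of the registers, by design. Under the study
conditions above, origin recall is ≥ 95% (measured 98.5% on 200
genomes) with 100% strand accuracy; the residual misses are small-stem,
small-loop plantings excluded by the proximity rule itself.

## Problem sizes and determinism

The shipped tests and the acceptance script run, on one CPU, at these
scales: 500 random windows for the folding oracle, 200 planted genomes
for origin recall, 200 random pairs for the alignment oracle, 50
linearized contigs through the full pipeline, 40 sequences for cluster
recovery. These sizes give binomial standard errors comfortably inside
the asserted margins while keeping a full run in minutes. Every stage of
`run_discovery()` is deterministic given its configuration — outputs are
byte-identical across reruns (the GenBank LOCUS date is a fixed
configurable string for exactly this reason).

## Known limitations

* The folding model counts pairs; it does not estimate free energy, and
  G·T wobble is weighted like any other pair. Scores are comparable
  within this package, not across folding engines.
* Bit scores and E-values use fixed gapped-BLOSUM62 constants; they are
  internally consistent but not interchangeable with BLAST output at
  high precision.
* Splice rescue considers one intron; genes needing two introns, or
  non-canonical splice sites, are reported unresolved rather than
  guessed.
* The GenBank parser covers the flat-file subset this pipeline emits and
  consumes (LOCUS/FEATURES/ORIGIN, CDS and stem_loop keys, complement
  and join locations); it is not a general-purpose GenBank reader.
* Pairwise identities depend on the alignment engine; comparisons with
  matrices from other tools carry an engine offset of a few percentage
  points.
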