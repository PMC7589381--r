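---
title: "Designing and tracking multi-paralog CRISPR knockouts in a polyploid crop"
author: "crisprpoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and tracking multi-paralog CRISPR knockouts in a polyploid crop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprpoly)
```

## The problem

Allotetraploid crops such as oilseed rape (*Brassica napus*, AACC genome)
carry most genes as small families of two to eight paralogs, typically at
89--99% nucleotide identity within a family. Recessive traits controlled by
such families -- the low-phytic-acid (*lpa*) phenotype is the motivating
example -- only become visible when several paralogs are knocked out
simultaneously. CRISPR-Cas9 makes that practical, but it changes the
computational work: a single guide RNA must hit *all* functional family
members at once while hitting nothing else in a large polyploid genome, and
the resulting plants are chimeric mosaics whose alleles must be tracked
through several selfing generations before fixed, transgene-free mutants can
be phenotyped.

`crisprpoly` implements that whole desk-side workflow: paralog discovery,
conserved guide design, allele calling, mixed-trace decomposition,
pedigree/segregation analysis, and the phenotype statistics -- together with
a seeded synthetic-data layer that simulates every input, so each component
is testable against ground truth.

## Synthetic data: what is emulated, and what is not

All generators take an explicit integer seed and wrap their randomness in
`withr::with_seed()`, so the same seed gives byte-identical output and no
global RNG state is touched.

* `simulate_gene_family()` evolves *n* copies from one random ancestor by
  point substitutions until all pairwise global-alignment identities fall in
  a target band (default 0.89--0.99, the within-family range typical of
  tetraploid rapeseed families). A `planted_site()` embeds a 20-nt
  protospacer + NGG PAM identically in every copy, optionally with a single
  SNP in one copy at a chosen protospacer position counted from the PAM --
  the configuration that makes polyploid guide design interesting.
* `simulate_nhej_alleles()` draws indel sizes from a configurable
  `indel_spectrum()` (default: +1 insertion with probability 0.3, deletions
  of 1--10 bp with geometrically decaying probability totalling 0.7 --
  plausible for error-prone end joining, and deliberately configurable since
  only observed allele lists, not a spectrum, are available for calibration)
  and places one indel per allele at the cut site. The blunt cut is fixed 3
  bp upstream of the PAM, the standard SpCas9 convention.
* `simulate_chromatogram()` renders sequences as idealised four-channel
  traces (one Gaussian peak of height 1 per base, spacing 4 grid points, sd
  = spacing/3) plus optional Gaussian noise clipped at zero. This captures
  peak overlap and mixture superposition, but none of the real-world .ab1
  pathologies: no mobility shifts, dye blobs, degrading peak heights along
  the read, or base-caller quality values. Decomposition results on real
  traces will therefore be noisier than the simulation suggests.
* `simulate_pedigree()` selfs each plant, drawing two gametes per locus
  independently from the parent's *germline* allele set. Chimeric founders
  transmit only a configured germline subset -- this is how mutations
  confined to somatic sectors ("observed in clones, never inherited") are
  modelled -- and each hemizygous T-DNA insertion segregates 1:2:1, giving
  the expected 3:1 transgenic ratio. While any transgene copy is present,
  wild-type alleles can be replaced by fresh de novo alleles at a
  per-locus rate, reproducing ongoing Cas9 activity in later generations.
  Loci are unlinked; there is no recombination model.
* `simulate_phenotypes()` draws replicate trait values from
  Normal(mean x effect, cv x mean x effect). The demo uses triple-mutant
  phytic-acid effects of 0.728 and 0.647 (27.2% and 35.3% reductions), a
  3-fold inorganic-P effect, a control PA level of 32 mg/g, CV 0.06 and five
  biological replicates -- the magnitudes and design reported for this kind
  of greenhouse experiment.

Passing tests on these simulations show the *algorithms* are correct under
their stated assumptions; they do not show that real amplicon sequencing or
HPLC phenotyping would behave as cleanly.

## Paralog discovery

`find_paralogs()` seeds with exact 11-mers, clusters seeds by diagonal, and
refines each candidate window with a banded global--local alignment
(Biostrings), reporting non-overlapping hits with identity and query
coverage above the thresholds (defaults 0.8/0.8). On small genomes the test
suite checks equivalence with an exhaustive sliding-window scan.
Identity is always matches / alignment columns with gap columns counted as
mismatches -- stated explicitly because published identity tables computed
with other denominators will differ.

`group_families()` clusters by single linkage at a within-family identity
threshold (default 0.85): appropriate because family membership in
polyploids is transitive along chains of recent duplicates.
`build_distance_tree()` is neighbour joining on 1 - identity with negative
branch lengths clamped to zero. It deliberately replaces maximum-likelihood
phylogenetics: a distance tree is sufficient to separate gene families and
assign group labels, and tests verify the 3-taxon closed form and exact
recovery of additive 4-taxon distances.

## Guide design rules

`enumerate_sites()` lists every 20-mer 5' of an NGG on either strand.
`score_conservation()` maps each candidate window into every other family
member through pairwise global alignments and records differing positions,
numbered from the PAM (1 = PAM-proximal). `filter_candidates()` keeps a
candidate iff:

* GC content is **strictly** above 40% (`gc_min = 40`);
* every member's homologous window is intact (no alignment gaps) and its
  PAM still reads NGG and is identical -- a broken PAM defeats targeting, so
  PAM mismatches are never tolerated;
* each member differs at **at most one** position, and only at protospacer
  positions 10--20 from the PAM (`seed_boundary = 10`, boundary inclusive):
  mismatches in the PAM-proximal seed abolish cleavage, while a single
  PAM-distal SNP at position 10 is tolerated by Cas9.

`off_target_scan()` is the desk-scale analogue of "no BLAST hit anywhere
else": both strands of all contigs (coding and non-coding alike) are scanned
for 23-mers with up to `max_mm = 2` protospacer mismatches and a mandatory
GG; hits overlapping the family's own loci are excluded and one remaining
hit rejects the guide. The tolerance is configurable down to 0; 2 mismatches
is a conservative stand-in for a tool-dependent "lacking hits" criterion.
Ranking of accepted guides is deterministic: fewest total cross-paralog
mismatches, then highest GC, then 5'-most position.

## Allele calling and chimerism

`call_alleles()` globally aligns a read to the wild-type reference (match 2,
mismatch -3, gap open 5, extend 2), extracts indel events and
**left-normalises** them (VCF-style leftmost placement) so that allele
identity is well defined inside homopolymers and repeats; positions are
reported relative to the cut. Substitutions are sequencing noise: more than
2 of them outside a +/-30 nt cut window, or alignment identity below 0.8,
rejects the read as a foreign amplicon. Frame consequence is the net indel
length modulo 3, computed only for coding loci.

`name_alleles()` assigns `<locus letter><number>` codes in order of first
observation and `<letter>h` for the unedited allele; the mapping is a pure
function of the ordered input, so codes are stable across generations and
re-runs. (Whether a published numbering followed first observation or
mutation type is unknowable without its supplementary tables; first
observation is the deterministic choice and is stated rather than inferred.)

`assess_chimerism()` de-duplicates clone calls by event list: more than two
distinct alleles at a locus cannot come from a fixed diploid genotype and
flags a chimera; alleles supported by a single clone set a saturation
warning since deeper cloning could reveal more.

## Trace decomposition

`decompose_trace()` regresses the mixed trace onto the control trace shifted
by -10..+10 bases, solving non-negative least squares
(`pracma::lsqnonneg`) over an analysis window of bases 10--60 downstream of
the cut and reporting normalised frequencies plus R-squared (fits below 0.9
are flagged). Two numerical choices matter:

* the window never starts closer to the cut than `max_indel`, so the
  unknown inserted bases of insertion alleles lie upstream of the fitted
  region; the one boundary base of the largest insertion is modelled as an
  uninformative flat 0.25-per-channel signal;
* shifted copies of a non-repetitive trace are close to orthogonal, which is
  what makes the NNLS identifiable; in long homopolymer or repeat regions
  adjacent shifts become collinear and frequencies can smear between
  neighbouring sizes.

Over 100 seeded mixtures of 2--4 components at trace noise 0.05 the mean
absolute per-component error is under 0.05 (measured by the test suite and
the acceptance script).

## Inheritance and selection

`expected_segregation(n)` is the closed form (4^n - 1):1 for n unlinked
hemizygous insertions; tests confirm it by exhaustive gamete enumeration for
n <= 4. `segregation_test()` is a Pearson chi-square goodness-of-fit test
with df = 1 and **no continuity correction** at alpha = 0.05; its p-value is
checked against the erfc closed form to 1e-10 and its type-I error over 500
simulated 3:1 families of n = 100 sits at the nominal 5%.
`track_alleles()` classifies each offspring allele as inherited, de novo
(novel but the offspring still carries the transgene, so Cas9 was active) or
anomalous (novel without a transgene), and reports parental mutant alleles
absent from all offspring as lost -- the germ-line-exclusion signature.
`select_candidates()` returns plants homozygous mutant at every required
locus and transgene-free, ordered by plant id.

## Phenotype statistics

`anova_tukey()` averages technical replicates to plant means when a
`tech_rep` column is present (the nesting treatment of repeated measurements
per plant is otherwise underdetermined), fits a one-way fixed-effects ANOVA
on line, computes Tukey HSD adjusted p-values from studentised-range
quantiles, and renders a compact letter display by the insert-and-absorb
algorithm (implemented here directly; the letters are deterministic for a
fixed input order). The test suite verifies F and p against a from-scratch
sums-of-squares computation to 1e-9 and checks exhaustively, for up to six
groups, that two lines share a letter iff their adjusted p is >= alpha.

## The end-to-end demo

`run_demo(seed)` chains everything: two simulated families (4 and 3
members, each with a planted target site carrying a position-10 SNP in one
copy) embedded in background contigs with decoys; paralog discovery and
family grouping; guide design; chimeric T1 loci with 3--4 distinct NHEJ
alleles each genotyped from 30 plasmid clones; a founder whose germ line
transmits one edited and one wild-type allele at loci A, B and G but only
the wild-type allele at locus E (so the E edits are lost, as in a chimera
whose edited sectors miss the germ line); three selfing generations of 50
offspring per selected parent with 3 parents kept per generation; a 3:1
transgene segregation test in T2; TIDE-style decomposition of a locus-A
mixture; selection of non-transgenic triple homozygotes in T4; and the
phenotype ANOVA. Parents are ranked by fixed homozygous loci, then by loci
carrying any mutant allele, penalising transgene-homozygous lineages because
those can never segregate the T-DNA away. With these population sizes the
probability of missing a non-transgenic triple homozygote by T4 is
negligible for any seed, which the acceptance test exercises.

Problem sizes throughout (900-nt family members, ~30 kb demo genome, 150
plants per late generation, 100-seed recovery studies) were chosen as the
smallest scales at which every statistical check is comfortably powered.

## Known limitations

* The off-target criterion is a Hamming-distance scan, not an
  energy/activity model; it has no bulge handling and no efficiency score.
* Trace simulation omits real chromatogram artefacts, and decomposition is
  frequency-level only -- it does not reconstruct allele sequences.
* Pedigree simulation assumes unlinked loci, selfing only, and a
  single-locus (or independent multi-locus) transgene.
* The ANOVA is one-way fixed effects on line; block or random effects from
  greenhouse layout are out of scope.
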