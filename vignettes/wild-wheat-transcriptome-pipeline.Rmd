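---
title: "Methods: screening, orthology, resistance-gene mining and SNP analysis for wild-wheat EST surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, orthology, resistance-gene mining and SNP analysis for wild-wheat EST surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sharest` implements the standard analysis arc of a de novo leaf-transcriptome
survey of a wild wheat relative (the motivating system is *Aegilops
sharonensis*, a diploid relative of bread wheat and a reservoir of disease
resistance): screen normalised-cDNA long reads for length and contamination,
assess assemblies, detect orthologs by best reciprocal hits, collapse pooled
assemblies to a non-redundant set, mine NB-LRR resistance-gene candidates,
call SNPs between two accessions, and estimate within-accession
heterozygosity from allelic ratios. Every stage is exercisable on synthetic
data with planted ground truth, so the statistical behaviour of each
procedure is testable end to end without external search tools or databases.

## The similarity engine

All alignment-based stages share one engine: a k-mer-seeded local aligner
(Smith–Waterman, affine gaps) over both strands, written in C++. Scoring is
match +1, mismatch −2, gap open −5 (including the first gap position), gap
extend −2. A pair is aligned only if it shares an exact k-mer (default k =
12) on some strand; the reported hit is the best-scoring local alignment,
one per (query, subject) pair, with ties resolved deterministically.

E-values use the Karlin–Altschul form $E = K\,m\,n\,e^{-\lambda S}$ with
ungapped-DNA defaults $\lambda = 1.33$, $K = 0.621$, where $m$ is the query
length and $n$ the search-space size (the total subject-set length in
database searches). This is a transparent, monotone ranking device, not a
calibrated replica of any external tool's statistics; accordingly every
threshold that gates on it (the 10⁻⁶ screens, the 10⁻¹⁰ reciprocal-best
ceiling) is a parameter, set by default to the conventional values.

Two numerical choices matter downstream. First, a local alignment
legitimately trims a mismatch sitting within 2 bp of a sequence end (the
trimmed mismatch costs more than the matches it brings), so identity
percentages on planted-substitution fixtures are exact only when
substitutions sit at least 3 bp from the ends. Second, read-to-reference
placement uses a banded variant of the same dynamic program (default band
±16 around the seed diagonal): the synthetic data are substitution-only, so
the band loses nothing, and tests verify banded and full alignment agree on
simulated reads.

## Read screening

Reads pass a cascade: length filter (keep > 45 nt), then alignment screens
against a transposon-repeat library (remove at e ≤ 10⁻⁶, ≥ 85 % of the query
aligned, ≥ 85 % identity) and against organelle and human-repeat libraries
(both at e ≤ 10⁻⁶, 90 %/90 %). Each stage sees only the survivors of the
previous one, and each stage's removal percentage is reported against the
reads *entering* that stage. This sequential-denominator convention is the
one under which published preprocessing tables of this design are
arithmetically self-consistent, and `qc_replay()` reproduces such tables
from a raw count plus per-stage removals. Adapter clipping happens upstream
at the sequencing provider, so the replay treats the clipped-read count as
an externally supplied first-stage removal. Under strict sequential
accounting one published accession column famously totals 90 reads away
from its printed final count; the replay reports the strict arithmetic and
does not chase the printed total.

## Assembly diagnostics

`n50()` is the smallest length L such that contigs of length ≥ L span at
least half the assembly (ties resolve to the largest qualifying contig
length); it is tested against a brute-force scan over all candidate
lengths. `length_vs_reads()` correlates log contig length with log
constituent-read count — in an honest overlap-layout assembly, longer
contigs are built from more reads — and is validated against a permutation
null. `self_redundancy()` aligns a contig set to itself and reports the
proportion of contigs participating in at least one significant non-self
pair. Published practice rarely defines "significant" or the denominator
here; this package fixes e ≤ 10⁻¹⁰ with at least half the query aligned
(matching the reciprocal-best significance level) and a per-sequence
denominator, both configurable.

## Orthology

A pipeline sequence q and a reference gene s are reciprocal best hits when
s is q's best reference match and q is s's best pipeline match, both at
e ≤ 10⁻¹⁰. Minimum e-value wins; ties break by bit score then lexicographic
subject id, so each query has at most one partner per reference set even
under ties. The machinery is hit-table-agnostic: synthetic runs feed it
nucleotide hits from the built-in aligner, real runs can import
protein-space tables (translated search itself is out of scope). Unions of
per-reference query sets, the 15-region four-set Venn lattice (core
orthologs = the all-four region, keyed by query id only), and genetic-map
placement (each query inherits its partner's chromosome and cM position;
`bin_index = floor(cM / bin_width)`) complete the module. Reciprocal-best
detection is verified against exhaustive enumeration over full hit
matrices, including tied e-values.

## Non-redundant clustering

Greedy identity clustering in the style of CD-HIT-EST: sequences are
visited longest-first (ties by id, so the result is independent of input
order) and each joins the first cluster whose representative it matches at
≥ 90 % identity over ≥ 80 % of the shorter sequence, else founds a new
cluster. Identity is measured on the best local alignment over both
strands; the published procedure this emulates states only "default"
settings, and whether identity was global or local is not recorded, so
local-with-coverage was chosen and the coverage floor exposed (it prevents
short fragments from being absorbed by sequences they barely overlap).
First-fit rather than best-fit assignment matches greedy incremental
clustering. Representatives (the longest member of each cluster) form the
non-redundant set; tests check the representative set is an antichain
under the similarity predicate and that cluster counts are monotone in the
threshold across the conventional sweep {70, 80, 90, 95, 98}.

## NB-LRR mining

Two independent predictors are compared. The domain cascade selects
sequences with an NB-ARC domain hit at a strict per-domain e-value (0.1),
then searches *within that set only* for an intracellular-LRR hit; NB-LRR
predictions are therefore a subset of NB-ARC predictions by construction.
The lexical route flags sequences whose annotation terms contain "nblrr" or
"nb-lrr" (case-insensitive substrings). Production runs consume externally
produced domain-hit tables; the test path uses a built-in motif scanner
over planted consensus motifs, whose e-value is the database-wide expected
chance-hit count (binomial tail × windows scanned across the whole set),
mirroring how profile-search tools scale e-values to the database so that
the 0.1 threshold bounds the false yield per database rather than per
sequence. Full profile-HMM inference is deliberately out of scope: the
scientific content here is the cascade and its thresholds, not the HMM
engine.

## SNP calling

Reads of both accessions are placed on a pseudo-reference (for synthetic
runs, the focal transcript consensus — running an assembler is out of
scope) at their best alignment; multi-mapping ties are dropped and counted,
as are reads with no passing alignment. N bases feed a separate per-column
track and never the A/C/G/T counts; sites over reference Ns are skipped.

Per column and accession, genotype likelihoods use the symmetric-error
diploid model: a homozygote XX emits X with probability $1-\varepsilon$ and
each other base with $\varepsilon/3$; a heterozygote XY emits X or Y with
$\tfrac12(1-\varepsilon)+\varepsilon/6$ and each other base with
$\varepsilon/3$. Homozygous genotypes share prior $1-\theta$, heterozygous
ones $\theta$ (defaults $\varepsilon = 0.01$, $\theta = 0.001$). The
original survey delegated calling to an external two-organism caller whose
internals are unpublished; this model reproduces its *decision rules* on a
transparent core.

A site is reported as an inter-accession SNP when the two accessions'
maximum-posterior genotypes carry **different allele sets**, the joint
posterior of that difference is ≥ 0.9, and every reported allele has ≥ 2
supporting reads in its own accession (the minimum-evidence rule applied
bilaterally, the stricter reading of "2 reads per allele"). The allele-set
formulation was chosen over "consensus alleles differ" because it is
symmetric under swapping accessions and handles heterozygous-versus-
homozygous sites — exactly the sites the heterozygosity statistic lives on,
where one accession shows a ~1:1 allele mixture and has no meaningful
majority allele. At homozygous/homozygous sites the two rules coincide.
Sites where more than two alleles have minimum read support (2 reads,
pooled) are skipped and counted; single-read error bases do not make a
site multi-allelic.

## Heterozygosity from allelic ratios

At every called SNP site, each accession's reads are tallied for the two
call alleles; the depth gate (≥ 20) counts those two alleles only, so
sequencing-error bases neither qualify nor disqualify a site (total column
depth is available as an alternative convention). A site is heterozygous in
an accession when the most/least-frequent allele ratio is ≤ 3.0 (a 1:1 to
3:1 mixture); a homozygous accession shows the ratio diverge to infinity. A
sequence is heterozygous when at least one eligible site is ("any" rule; a
"majority" alternative is provided, since published practice does not
define multi-SNP aggregation), and the per-accession rate is the percentage
of heterozygous sequences among SNP-bearing sequences with ≥ 1 eligible
site in that accession — the denominator that makes worked examples like 7
of 444 → 1.6 % arithmetically coherent. Both numerator and denominator are
exposed so either convention is auditable.

One structural limitation is worth stating plainly: the statistic only sees
heterozygosity at sites where a between-accession SNP was called. If both
accessions are heterozygous at the same site their genotype sets coincide,
no SNP is called there, and the gene silently leaves both numerator and
denominator. The recovery simulations therefore plant heterozygosity in one
accession at a time — which is also the empirical situation the method was
built for (a near-homozygous inbred versus a heterogeneous accession).

## The synthetic universe

`generate_universe()` builds: focal base transcripts (default 600–1500 nt)
with optional paralog copies (5 % of genes found a family, 10 % diverged)
and planted NB-ARC/LRR motifs (10 % of genes, half also LRR); reference
species derived by independent substitutions (5 % per site, so four
reference sets stand in for sequenced grass proteomes); two accessions
separated by substitution-only SNPs (default rate 0.002 per site — the
recovery-suite condition; substitution-only keeps planted coordinates
exact, an indel mode is out of scope); and per-gene lognormal expression
factors shared between accessions, which create the length–read-count
coupling the assembly diagnostic expects.

Heterozygosity is modelled as residual cross-lineage variation: a
heterozygous gene's second haplotype carries the *other* accession's
alleles at that gene's SNP sites, matching the outcrossing interpretation
of a heterogeneous accession and producing the ~1:1 within-accession allele
mixtures the ratio statistic detects. Default het fractions are 0.016 and
0.30 for the two accessions, the magnitudes the method was designed to
discriminate.

Reads: lengths uniform 300–800 nt (a long-read cDNA survey), plus a small
short-read tail (rate 0.02, 20–45 nt) to exercise the length filter; start
positions uniform including clipped overhangs at transcript ends, giving
near-uniform coverage (per-transcript read counts are scaled by
$(L + \bar\ell - 1)/\bar\ell$ so the `coverage` parameter is the actual
expected interior fold coverage, not a nominal one); substitution errors
(default 0.005 per base); an
ambiguous base planted in the 3′ half with probability 0.05 per read plus a
0.001 uniform background, reproducing the strong 3′ skew of ambiguous calls
in pyrosequencing-era long reads; random strand (0.5). Contaminant pools
(high-copy repeats, long organelle fragments, human-like repeats) are
spiked at binomially drawn counts (default fractions 0.008 / 0.010 /
0.0003, the order of magnitude such surveys remove). What the generator
does **not** emulate: homopolymer indel errors, quality-score structure,
chimeric reads, and assembly fragmentation — so passing recovery tests
demonstrate the statistical machinery, not robustness to every real-data
artifact.

Everything is deterministic under one integer seed; per-stream seeds are
derived arithmetically from it, and downstream recovery tests read only the
recorded truth, never re-derive it.

## Problem sizes and numerical conventions

The shipped test and acceptance suites run the recovery studies at desk
scale, chosen once as the smallest sizes at which the binomial noise of
each check is comfortably inside its tolerance: the SNP-recovery suite uses
five universes of 15 transcripts (0.8–1.2 kb) at 20× per-accession
coverage with ε = 0.005; the heterozygosity suite ten universes of 20
transcripts at 25× per fraction ∈ {0, 0.1, 0.3}, with the estimate
compared against the realized planted fraction among the sequences that
enter the per-accession denominator — coverage eligibility is independent
of heterozygosity status, so this isolates the statistic's detection error
from the binomial noise of which genes were planted heterozygous in a
small universe; the reciprocal-best
suite one hundred randomized hit universes of up to 120 genes plus one
150-gene sequence universe with paralogs. All internal coordinates are
1-based inclusive (the R/Bioconductor convention); emitted GFF3 is likewise
1-based inclusive, and the boundary behaviour is covered by an explicit
round-trip test at both sequence ends. Headline counts of the motivating
survey that depend on the real reads, external assemblers, or database
versions (total non-redundant sequences, per-assembly reciprocal-best
counts, absolute NB-LRR counts) are expressly not reproduction targets;
what is reproduced is the published tables' arithmetic and the behaviour
of each procedure under planted truth.
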