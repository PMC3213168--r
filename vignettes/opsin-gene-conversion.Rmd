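---
title: "Methods: gene conversion and purifying selection in duplicated opsin genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene conversion and purifying selection in duplicated opsin genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsinconv)
```

## The scientific problem

Catarrhine primates carry tandemly duplicated long- (L) and middle- (M)
wavelength opsin genes on the X chromosome. The two paralogs are ~96%
identical and exchange sequence by interlocus gene conversion, which tends
to homogenize them; at the same time the spectral difference between the
two pigments — determined mainly by residues 180 (exon 3), 277 and 285
(exon 5) — is maintained by purifying selection against conversion
products that erase it. The observable footprint of this antagonism, in a
sample of sequences spanning the central exons 3–5 and introns 3–4, is a
set of coupled contrasts:

1. L–M divergence is *higher* in exons (including synonymous sites) than
   in introns — the reverse of the usual coding/non-coding pattern.
2. Within-species diversity is ordinary: introns are about as variable as
   neutral references, exons less so.
3. The divergence : polymorphism ratio is lower in introns than at
   synonymous sites (a 2×2 contrast per species, Fisher's exact test).
4. Among-group trees disagree by region: exon trees place the L/M
   duplication basal to all species, intron trees cluster L with M within
   species or genera.
5. A Sawyer-style scan finds significant conversion tracts predominantly
   in introns.

`opsinconv` implements the full pipeline that measures these contrasts on
user alignments, plus a forward simulator of the generative process that
provides ground truth for calibration and power checks.

## Genotype model

The L gene is defined by Tyr277/Thr285 and the M gene by Phe277/Ala285;
any other combination at those two residues is reported as a putative
exon-5 hybrid, never silently dropped. A "spectral hybrid" is an L gene
with Ala180 or an M gene with Ser180. Peak absorbance is modeled as exactly
additive: 560 nm minus 7, 8 and 15 nm for Ala180, Phe277 and Ala285. The
eight residue combinations give seven distinct values (the −7−8 and −15
shifts coincide at 545 nm); the anchors are 560 nm (Ser/Tyr/Thr) and
530 nm (Ala/Phe/Ala). Published measurements describe the shifts as only
"nearly" additive; deviations are not modeled.

## Distances and site classes

Nucleotide diversity (π) is the unweighted mean pairwise mismatch
proportion within a group; divergence (d) the mean over between-group
pairs, with no net (within-group) subtraction. Both are computed on
complete-deletion columns: every column containing a gap or `N` in the
comparison set is removed first ('N' is treated like a gap —
conservative). π and d are reported as uncorrected proportions; the
Jukes–Cantor correction −(3/4)·ln(1−4p/3) is applied only when building
trees.

Synonymous and non-synonymous components use Nei–Gojobori pathway
counting: per-codon synonymous site fractions from the standard code
(changes creating a stop count as non-synonymous, so syn + nonsyn sites
equal exactly 3 per codon), and multi-hit codon differences averaged over
all mutational pathways excluding those through stop codons (if every
pathway passes through a stop, the average falls back to all pathways,
with a warning). Codons are reassembled across introns using the declared
exon phases; codons not fully contained in the region are excluded.

Standard errors come from a seeded bootstrap (default 1000 replicates);
the resampling unit is the site for nucleotide distances and the whole
codon for synonymous/non-synonymous statistics, preserving codon
integrity. Comparisons use the one-tailed Z test
Z = (v₁−v₂)/√(se₁²+se₂²); if both SEs are zero the statistic is undefined
and P is reported as 1 (equal values) or 0/1 by sign, with a flag.
Autosomal reference diversities are multiplied by 3/4 before comparison
with the X-linked opsins.

## Site classification for the divergence/polymorphism contrast

Using complete-deletion columns over the L and M groups of one species
(single-copy males when emulating the original design), each site is
`fixed` (both groups monomorphic, different bases), `polymorphic` (either
group segregates — a site that both differs between groups and segregates
within one is polymorphic, not fixed), or `invariant`. Coding sites are
`synonymous` if every observed base change, evaluated in the codon context
of the analyzed records' consensus at the other two positions, preserves
the amino acid; codons with several varying positions are flagged
ambiguous but classed by the same rule. The synonymous-vs-intron 2×2 table
of fixed vs polymorphic counts is tested with the two-sided Fisher's exact
test under the minimum-likelihood rule (the sum of all table probabilities
not exceeding the observed one). Three of the four published per-species
P values are reproduced exactly at two significant figures; the fourth
(the H. agilis table, printed 4.0×10⁻⁷) computes to 1.8×10⁻⁷ two-sided
(3.7×10⁻⁷ when doubling the one-sided tail) and is documented here rather
than chased.

## Trees

Among-group trees use the mean between-group p-distance on jointly
retained columns, Jukes–Cantor corrected, and neighbor joining. Negative
branch lengths are clamped to zero for output only (raw lengths are kept
as an attribute). Bootstrap supports resample columns with replacement and
report the percentage of replicates containing each internal bipartition
of the point-estimate tree; in replicates a saturated distance is clamped
just below the correction's domain boundary instead of aborting. Two
helper predicates read the topology: `has_duplication_split()` (is there a
bipartition separating all L groups from all M groups?) and
`paralog_pairs_monophyletic()` (which species' L and M form a cherry?).

## Conversion tract detection

Columns that are polymorphic and free of gaps/ambiguity form the condensed
profile; original indices are retained so tract coordinates are reported
1-based inclusive, spanning from the first to the last matching
polymorphic site (the data cannot localize a boundary between polymorphic
sites). For a pair of sequences, fragments are maximal runs of consecutive
profile columns where the pair agrees, scored by run length; an optional
BLAST-like mode (match +1, mismatch −g, Ruzzo–Tompa maximal segments) is
provided but off by default, matching the tool convention of listing
mismatch-free inner fragments.

Significance uses a column-permutation null: for each permutation the
maximum fragment score over all pairs is recorded, and a fragment's global
P is (1 + #{perm max ≥ score})/(n_perm + 1) — the max construction is the
multiplicity correction, and the +1 estimator avoids zero P values.

One scoring detail matters enormously in practice. Alignments of
population samples contain near-identical pairs (same species, same locus)
whose few differences scatter at random; under permutation such pairs
produce enormous agreement runs, and a raw run-length maximum over all
pairs is then unbeatable — the scan would have no power at all, no matter
how clear a converted tract is. A long run is strong evidence only in a
pair that disagrees often elsewhere, so each pair's run lengths enter the
global comparison multiplied by −log(1 − m), where m is that pair's
mismatch fraction over the profile. The weight is a per-pair constant,
fixed under permutation, so the exchangeable null (and hence the
family-wise error guarantee checked by the calibration test) is untouched;
an identical pair (m = 0) carries weight 0, correctly contributing no
localization evidence. Fragment tables report both the raw run-length
score and the weighted score.

Significant tracts are annotated with per-region overlap fractions from
the region map, including the fraction of tract length in introns.

## Other inferential tests

The McDonald–Kreitman contrast reuses the site classifier with two
species' orthologous groups (fixed vs polymorphic × non-synonymous vs
synonymous, Fisher two-sided). The HKA test is the classic two-locus
chi-square: method-of-moments estimates of per-locus θ and a shared
divergence time from S_j + D_j = θ_j(a_nj + τ + 1) and ΣS_j = Σθ_j a_nj
(a_n = Σ1/i, solved by bracketed root-finding in τ), variances
Var S = E S + θ²b_n (b_n = Σ1/i²) and Var D = E D + θ², one degree of
freedom; an optional per-locus factor (e.g. 3/4) scales θ for X-linked
loci. D′ is |p_AB − p_A p_B| over its frequency bound for biallelic site
pairs in phased (male single-copy) haplotypes. Fisher's exact P is
discrete, so under neutral simulation its distribution is conservative
rather than uniform; the calibration tests therefore check that rejection
rates do not exceed the nominal level, not distributional uniformity.

## The simulator

`simulate_dataset()` is the ground-truth generator: a random ancestral
sequence (with any in-frame stop codons resampled), duplication into L₀
and M₀ with divergent states forced at the masked codons, evolution along
a stem branch and a species tree, then within-species star-genealogy
sampling.

* **Mutation.** Per branch of length b (expected substitutions/site),
  Poisson(L·b) single-base changes per paralog, uniform position, uniform
  alternative base (Jukes–Cantor).
* **Conversion.** Poisson(conv_rate·L·b) events per branch: random
  direction L↔M, uniform start, geometric tract length (mean
  `tract_mean`), the donor segment overwriting the recipient. Mutations
  and conversions are interleaved in random order within a branch.
* **Selection.** An event that would change the amino acid at any masked
  codon is rejected with probability `p_purge` (default 1); an event
  creating a premature stop codon is rejected when `reject_stops` is on
  (default; disable for strictly neutral runs). Rejected events are logged
  as purged in the truth record. This event-rejection model is the minimal
  mechanism producing selective protection of the spectral difference; it
  does not model population dynamics.
* **Masked codons.** The three tuning residues plus, by default, five
  extra constrained codons spread through exons 3 and 5 (none in exon 4,
  where selection against conversion is weakest, consistent with the
  observation of conversion tracts covering exon 4). The real proteins
  differ at over a dozen constrained residues; with only the three tuning
  codons masked, conversion tracts eventually erode all other exon
  divergence by slipping between them, which no real data set shows. The
  extra codons use Ser/Ala codon pairs differing at all three positions so
  no partial tract overlap is silent.
* **Sampling.** Each species contributes `n_samples` haplotypes per locus;
  each receives Poisson(L·θ/2) private mutations, so the expected pairwise
  intron diversity equals θ exactly (star genealogy — chosen over a full
  coalescent because the pipeline's statistics depend only on the expected
  diversity, and it gives exact control of E[π]).

Default conditions: 3675-site region (exon3 169, intron3 1550, exon4 166,
intron4 1550, exon5 240), five species in three lineages
(`(Nle,(Ssy,(Hag,Hla,Hpi)))`, ultrametric depth 0.016 substitutions/site),
stem 0.014 so that L–M synonymous divergence lands near 6%, θ = 0.003
(within the 0.1–0.4% band typical of gibbon neutral references),
conv_rate = 1 per site per unit branch length, tract mean 300 bp,
p_purge = 1, 10 haplotypes per species per locus. Under these conditions
the simulated data reproduce all four observable signatures: mean
synonymous L–M divergence ≈ 6–7% against intron divergence ≈ 1%,
intron-clustered vs duplication-basal tree contrast, intron-dominated
significant tracts, and the Table-style ratio contrast.

What the simulator deliberately does not emulate: indels and the Alu
insertion that makes the real L intron 3 longer than M's (alignments are
simulated gap-free and equal-length), recombination between alleles,
demography (bottlenecks, structure), GC-biased conversion, L→M vs M→L
rate asymmetry (unknown in reality; symmetric here), heterozygous
unphased genotypes, and protein-level constraint beyond the masked
codons (non-synonymous sites outside the mask evolve neutrally, so the
simulated nonsynonymous/synonymous divergence ratio is ~1 rather than
<1 as in real data). Passing tests on simulated data therefore validate
the estimators and the direction and robustness of the signatures, not
absolute rates in real genomes.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere, including internally —
  the natural convention in this language's ecosystem — and all reports
  print 1-based inclusive coordinates.
* Heterozygote splitting is deterministic (alphabetically first base to
  copy `_a`): per-site statistics are unaffected by phasing, and
  haplotype-requiring analyses are restricted to single-copy males anyway.
* Complete deletion is applied per comparison set, not alignment-wide;
  distance matrices for trees use joint deletion across all groups.
* Ties in NJ agglomeration follow the underlying implementation's
  deterministic order; seeds are mandatory wherever randomness enters
  (bootstrap, permutation, simulation), and a fixed seed reproduces every
  output byte for byte.
* Degenerate inputs have defined behaviour rather than errors where the
  analysis can continue: empty profiles no-op downstream, zero-margin
  Fisher tables report P = 1 with a flag, undetermined genotypes are
  reported with a reason.

## Problem sizes used by the automated studies

The packaged calibration and signature studies run at reduced sizes chosen
to keep the full suite comfortably interactive while leaving Monte-Carlo
margins wide: 200 conversion-free data sets with 2 haplotypes/species/locus
and 2000 permutations for the false-positive calibration; 50 replicates
with 3 haplotypes and 1000 permutations for the signature reproduction;
100 replicates for θ recovery. The scientific conditions (tree, rates,
θ, selection) are the defaults above throughout; only sample counts and
permutation counts are scaled.

## Known limitations

* The conversion scan reports Sawyer-style *inner* fragments between
  sequences present in the alignment only; outer-sequence sources and the
  alternative Bonferroni-corrected BLAST-like P values are not
  implemented.
* The HKA implementation is the two-locus chi-square approximation; no
  coalescent-simulated null.
* No dN/dS model fitting (GY94 etc.), no sliding windows, no de-novo
  alignment — alignments are inputs.
* The scan cannot, by construction, detect conversion between sequences
  that are nearly identical genome-wide (their profile carries no
  localization information); this mirrors the underlying statistic, which
  requires differences outside the tract.
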