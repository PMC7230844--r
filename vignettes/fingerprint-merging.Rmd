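---
title: "Consensus merging and comparison of SSR fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus merging and comparison of SSR fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrdb)
library(dplyr)
```

## The data and its error structure

An SSR fingerprint is a diploid genotype profile over a fixed panel of
microsatellite markers, each locus a pair of allele sizes in base pairs.
Dinucleotide-repeat markers are preferred for variety panels because of their
polymorphism, but their 2 bp allele spacing means capillary-electrophoresis
fragment sizing — accurate to roughly 1–2 bp — can bin the same allele into
neighbouring sizes across runs. Two consequences drive the package design:

1. Genotype identity must be *offset-tolerant*. Two locus genotypes
   $[a_1, b_1]$ and $[a_2, b_2]$ are treated as the same when either the
   direct or the crossed allele pairing agrees within the base offset $n$:
   $$(|a_1{-}a_2| \le n \wedge |b_1{-}b_2| \le n) \vee
     (|a_1{-}b_2| \le n \wedge |a_2{-}b_1| \le n).$$
   The crossed condition makes heterozygote storage order immaterial. The
   comparator is symmetric and monotone in $n$ (both property-tested).
2. Every sample is genotyped repeatedly, and the replicates must be
   consolidated into one consensus fingerprint with a record of where
   agreement broke down.

A locus call is either *effective* (two alleles; homozygotes stored as an
equal pair, heterozygotes ordered low/high) or *missing*. A half call — one
allele of two — does not satisfy the diploid contract and is rejected at
construction; importers may duplicate a single call to a homozygote only
under an explicit flag (`duplicate_single`), because silently promoting half
calls would hide dropout. Allele sizes are kept as decimals at 0.1 bp
resolution rather than integers: sizing software emits fractional sizes, and
rounding is deferred to the analyses that need discrete alleles.

## Pairwise comparison

For a fingerprint pair over $p$ panel loci, each locus is classified
*missing* (fewer than two effective sides), else *same* or *different* by the
offset comparator. With counts $D$ (different), $S$ (same), $M$ (missing):
$$p = D + S + M, \qquad x = D/p.$$
The denominator of $x$ is deliberately $p$, not $p - M$: a pair with heavy
dropout should not look artificially similar. $x = 0$ (identical) and
$x = 1$ (fully different) are both admitted; they occur in practice.

Database scans score every pending fingerprint against every reference
fingerprint (reference-major order), then filter the report by three
thresholds. The defaults are the standard operating values:

| parameter | default | unit | role |
|---|---|---|---|
| `base_offset_bp` | 2 (range 0–2) | bp | allele-size tolerance absorbing CE read error |
| `min_comparison_loci` | 20 | loci | floor on mutually effective loci $p - M$ per reported pair |
| `max_diff_loci` | 20 | loci | ceiling on $D$ |
| `max_diff_fraction` | 0.05 | — | ceiling on $x$ |

`min_comparison_loci` is interpreted as a floor on $p - M$, the only quantity
that measures how much shared evidence a pair actually has. Five comparison
scopes are provided: the whole reference database, homonymy (entries whose
name or synonyms equal the pending name — exact match after whitespace
trimming; the package defines no fuzzy matching), non-homonymy (the exact
complement, so the two scopes partition the database), and externally
assigned sub-database and paired scopes.

## Hierarchical consensus merging

Replicates form a tree with four nested counts: $i$ experiments per DNA
extraction, $j$ extractions per experimenter, $k$ experimenters per sample,
$m$ samples per variety. Every experiment-layer leaf gets weight
$1/(i\,j\,k\,m)$ computed with its own branch counts, so internal nodes carry
weights $1/(j\,k\,m)$, $1/(k\,m)$, $1/m$ and the tree totals 1. The weights
are bookkeeping for error tracing — within any single peer merge the inputs
are equal-weighted by construction, and the implementation enforces that
(how support should be weighted when branch sizes differ *within* one layer
is left undefined; the situation cannot arise under the constructor).
Multiple DNA extractions by one experimenter from a single plant are
collapsed to one DNA node at SIT import: they are repeats of the same
extraction whatever their labels.

Peer merging consolidates one layer locus by locus:

- Missing inputs do not vote but stay in the support denominator, so heavy
  dropout forces an audit rather than a confident call on thin evidence.
- Effective genotypes are clustered greedily in input order: a genotype
  joins the first cluster whose founding genotype it matches at the offset.
  The heaviest cluster wins; the retained genotype is the exact modal
  genotype within the winning cluster, ties broken by smallest `allele_low`
  then `allele_high`. (Some representative must be chosen among gca-equal
  size readings; the modal reading is the least surprising one, and the
  deterministic tie-break makes merges reproducible.)
- The winning support must **strictly exceed 0.6** of the total locus weight.
  This threshold is the complement of the 40% noise boundary: with an odd
  replicate count, strictly less than 40% noise leaves the truth cluster
  above 0.6 support at every locus (e.g. 2/3 ≈ 0.67, 5/7 ≈ 0.71), while 40%
  or more drops it to at most 0.6 (3/5 = 0.6, 4/7 ≈ 0.57) and the locus is
  flagged `AUDIT_REQUIRED` and set missing pending manual reselection.
  The strict inequality is compared with a 1e-9 slack so that binary
  floating-point sums of 1/r weights cannot flip the boundary case.
- A tie between top clusters is likewise `AUDIT_REQUIRED` — the automatic
  merge cannot choose between equally supported genotypes, which is exactly
  the case the manual verification path exists for. A locus with no
  effective input at all is `DROPPED_TO_MISSING` (nothing to audit).

Cross-layer merging applies peer merging experiment → DNA → experimenter →
sample → variety. A locus flagged at any stage enters the next stage as
missing, and the audit report records every non-OK flag with the layer and
node where agreement broke down. Manual reselection must pick one of the
cluster representatives observed at the flagging layer; overriding with an
unobserved genotype requires an explicit `force` and is recorded as an
override.

## The three-tier store

Uploads land as immutable records in the experimental tier (EFD), keyed by
experiment; re-uploads are kept as repeats, never overwrites. The audit
(permitted only to the owner of the sample information table) merges each
sample's replicates; samples with open `AUDIT_REQUIRED` flags are blocked,
the rest become audited sample-tier (SFD) records. Audited fingerprints are
promoted to the local tier (LFD) that comparisons run against, where records
can be locked into immutability. Provenance is kept at every step, so an LFD
record traces back to its SFD record, the contributing EFD records, and
their plate wells and electropherogram image paths.

The store persists as a directory of plain CSV tables mirroring the
entity-relationship design (records, SIT rows, plate wells, image
references), with fingerprint payloads in one sidecar CSV per record,
referenced by path from an index table rather than stored inline — keeping
the record tables small and the payloads independently versionable.
Referential integrity is checked in code (`store_check()`), and the
save/load round trip is byte-stable.

## Genetic analysis

Allele frequencies count both alleles of every effective genotype per
marker; missing loci leave the marker's denominator. For frequency-based
distances each fingerprint is treated as a one-individual population
(frequencies 1 or 0.5/0.5 per locus) — the natural reduction when entities
are individual variety fingerprints rather than population samples. Allele
identity for frequencies and sharing uses exact equality after snapping to
the marker's repeat-unit grid (origin `size_min`), since read error would
otherwise split one allele into several.

Twelve distance measures are provided: shared-allele, Nei (1972) standard,
Nei et al. (1983) $D_A$, Rogers (1972), modified Rogers, Cavalli-Sforza &
Edwards chord (per-locus chord averaged over loci), simple matching on
offset-equal loci, Jaccard and Dice on allele-presence sets, Euclidean on
allele-frequency vectors, and the raw comparison outputs $D$ and $x$ as
distances. Pairs are scored over the loci effective on both sides. Nei's
standard distance is infinite for pairs sharing no allele at any locus;
it is reported as computed rather than capped. Trees are built by UPGMA
(average-linkage `hclust`, ultrametric by construction) or neighbour joining
(`ape::nj`, requiring at least three taxa) and serialised as Newick.

## Quality control

Three QC instruments mirror laboratory practice: reference-sample checks
(any differential locus between an in-run standard and its stored
fingerprint flags the whole run — a reference mismatch signals a systematic
error, not a sample problem; the run is flagged, not deleted), replicate
audits (per-sample consistency of the canonical three repeats), and the
noise-tolerance scan described next.

## What the synthetic generator does and does not emulate

`sim_config()` defaults describe the canonical campaign: a 20-marker
dinucleotide panel with 8 alleles per marker, 50% heterozygosity, three
repeated experiments per DNA ($i = 3$, $j = k = m = 1$), per-allele read
error of ±1 bp with probability 0.05 and ±2 bp with probability 0.01, and no
dropout. The error magnitudes follow the 1–2 bp CE sizing error; the rates
are chosen as typical for a well-run fragment-analysis lab. A *noise
replicate* re-draws every locus uniformly from the marker's allele grid
excluding the true genotype — a deliberately adversarial construction in
which a noise set agrees with truth only by chance.

The generator does not simulate electropherograms, stutter or plus-A
artifacts, allele-specific dropout, or contamination that is correlated
across loci. Passing tests therefore demonstrate the algebra and thresholds
of the pipeline on realistic error magnitudes, not robustness to every
failure mode of real traces.

The noise-tolerance scan builds, for each odd replicate count
$r \in \{3, 5, 7\}$ and each requested noise proportion, a replicate set
with `round(fraction × r)` noise members (recording the realised proportion
`n_noise/r`), merges it, and reports the largest percentage strictly below
which no configuration loses effective loci:

```{r scan}
scan <- noise_tolerance_scan(seed = 1)
glance(scan)
```

Even replicate counts are rejected: with an even count a 50/50 split has no
majority, and the boundary claim is defined for odd designs.

## Numerical and degenerate-input choices

- Offset comparisons use `<=` (closed) on absolute differences; the offset
  default is 2 bp.
- Support and cluster-weight comparisons carry 1e-9 tolerances against
  floating-point accumulation; allele sizes themselves are compared exactly.
- Merging a single fingerprint is the identity (all loci OK at support 1).
- An empty comparison queue, an empty panel, an empty merge layer, and a
  distance matrix that is asymmetric or has a non-zero diagonal are all
  rejected with informative errors rather than propagated.
- Plate design fills 96-well plates row-major (A1 … A12, B1 …) with the
  reference wells first — a fixed, printable convention chosen for
  determinism, since no layout rule is canonical.

## Problem sizes

The test suite and the reproduction script run on desk-scale inputs: panels
of 1–20 markers, up to ~35 fingerprints per comparison queue (≥ 1000 ordered
pairs), the 15-configuration noise scan on a 20-locus truth, and oracle
checks over 10,000 sampled genotype pairs. These sizes exercise every code
path while keeping a full run in well under a minute per module.

## Known limitations

- Diploid genotypes only; polyploid (> 2 alleles per locus) data are out of
  scope.
- Mixed-sample (bulk) fingerprints with three or more peaks per locus are
  not modelled.
- Ownership fields stand in for authentication; the package is a local
  library, not a multi-user server.
- Image handling is path indirection only — no trace parsing or peak-shape
  review; the audit flags point a human at the loci to re-examine.
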