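---
title: "Methods: homology-based virome characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based virome characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroscreen)
```

## The problem

Most emerging model organisms have no catalogue of the viruses that live
in and on them, yet every RNA-seq experiment run on such an animal also
sequences its virome for free. viroscreen implements the downstream,
decision-making half of a virome-mining protocol for exactly this
situation: reads have already been quality-trimmed, mapped against the
host genome and assembled by external tools (Trimmomatic, Bowtie2,
Trinity, BLAST); what remains — and what this package owns — is the chain
of filtering decisions, taxonomic annotation, quantification and set
statistics that turn raw homology-search tables into a defensible virome.
Running the external aligners and assemblers is out of scope by design:
the package consumes their tabular outputs (12/13-column alignment
tables, FASTA, count TSVs, taxonomy dump files), which makes every
decision rule testable offline against synthetic inputs.

## The pipeline model

1. **Host read subtraction** (`filter_reads_by_host_evalue`). A read with
   a host-genome hit at e-value ≤ `host_read_evalue` (default 1e-15) is
   removed. The boundary is inclusive: the step exists to strip
   host-derived reads, so a hit exactly at the cutoff counts as
   host-like. For paired data the caller supplies read-pair ids, so a
   host-like mate removes the pair.
2. **Contig triage** (`classify_contig`). Each assembled contig is judged
   from three simultaneous searches: host genome (nucleotide), viral
   proteins (cutoff 1e-5) and prokaryote proteins (cutoff 1e-10).
   Contigs shorter than 200 nt are set aside first. A contig is a
   *viral candidate* only when its best viral e-value is strictly
   smaller than both competitors' best — "unambiguous viral origin"
   operationalized as a strict three-way comparison, the only
   deterministic rule compatible with running the searches side by side.
   Ties or stronger non-viral signals are *ambiguous*.
3. **Homology trimming** (`trim_to_viral_homology`). Candidates are cut
   down to the union of their viral-hit spans (0-based half-open
   intervals; reversed protein-frame coordinates are normalized).
   Overlapping or abutting intervals merge with gap 0 and no flanks are
   added: only sequence with reported homology survives. The 200 nt gate
   is applied again to each emitted fragment, so no published fragment is
   shorter than the assembly minimum. A fragment spanning its whole
   parent keeps the parent's id — it *is* the parent — which also keeps
   downstream count tables joinable. Exact duplicates and exact
   substrings of longer retained sequences are then cleared
   (`dedupe_contigs`), as merged multi-dataset assemblies nest fragments.
4. **All-proteins screen** (`screen_against_all_proteins`). Candidates
   with a best gated hit (≤ 1e-10) to a *cellular* protein are dropped;
   candidates whose best hit is viral, or which have **no** gated hit at
   all, are kept — absence of homology is not evidence of non-viral
   origin at this stage. The judgement uses the single best hit, not a
   vote: that is the simplest rule consistent with demanding a *clear*
   non-viral origin.
5. **Eukaryotic-virus confirmation** (`confirm_eukaryotic_viral`). The
   asymmetric counterpart: a candidate is confirmed only if its best
   gated hit exists and the hit's subject taxon climbs to the virus root
   without passing a name on the prokaryote-infecting-virus exclusion
   list. No-hit candidates are dropped here — a virome built this way
   knowingly overlooks novel viruses with no detectable homology.
   "Eukaryotic virus" is a lineage-name test (virus root membership minus
   an exclusion list) rather than a host-range database lookup, which
   keeps the step deterministic and offline.
6. **Annotation** (`climb_to_family`, `annotate_contig`). Family labels
   come from climbing parent links until a family-rank node; lineages
   with no family rank (unassigned orders, unclassified clades such as
   the large invertebrate RNA-virus groups) fall through ordered,
   name-keyed fallback rules; anything else is "unclassified". Reference
   (ICTV-style) consistency is a membership check against a user-supplied
   family list — reproducing what is in practice a manual check.
   Retro-transcribing viruses get their own genome-composition group
   (`retro`) rather than being folded into dsDNA or ssRNA conventions.
7. **Quantification** (`tpm_thousand`, `depth_normalized_rpm`,
   `sds_from_mean`, `collapse_by_species`). Relative abundance is TPM
   divided by 1000 (columns sum to 1000); log2 display masks zeros as
   missing rather than pseudocounting, because a zero means "not
   detected" and a pseudocount would fabricate abundance. Viral load per
   dataset is RPM with **raw read pairs** as the depth denominator — this
   choice is fixed because it, and only it, reproduces all fourteen
   published z-scores from the printed per-dataset integers (retained
   reads do not). z-scores use the sample (n−1) standard deviation for
   the same reason. Fragments of one species are collapsed by summing raw
   counts *before* normalization. The food-derived group mean averages
   the polyA-selected **and** unknown-enrichment libraries (the embryonic
   library included) and excludes only the rRNA-depleted one — again the
   single grouping consistent with the published 14.06% mean.
8. **Core virome** (`presence_matrix`, `core_and_unique_sets`,
   `flag_food_shared`). Presence is ≥ 1 mapped read by default (any
   remapped read counts as detection; configurable because single-read
   presence is noise-sensitive). The core is the intersection over the
   included datasets — the embryonic dataset is excluded by role before
   the call, since its viral load is negligible. Venn regions are
   reported as a bitmask → count map for any plotting front end. A
   contig is food-shared only when present in *both* food-source
   replicates.
9. **Inter-population statistics** (`factor_extract`,
   `welch_t_per_factor`, `compare_populations`). Contigs are
   observations; the six replicate libraries of the two compared
   populations are the variables, RPM-normalized, then standardized;
   the correlation matrix is eigen-decomposed and factors with
   eigenvalue > 2 (at most 5) are retained; variance explained is
   100·λ/p. Because the variables are the libraries, a factor's
   per-library component loadings are the natural per-sample values, and
   the per-factor test is a Welch (unequal-variance) two-sample t-test
   between the two 3-replicate groups — the published fractional degrees
   of freedom identify the unequal-variance form.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `host_read_evalue` | 1e-15 | read removed if host hit at/below this |
| `viral_evalue` | 1e-5 | viral-protein triage cutoff |
| `prok_evalue` | 1e-10 | prokaryote-protein triage cutoff |
| `screen_evalue` | 1e-10 | all-proteins screen gate |
| `confirm_evalue` | 1e-10 | confirmation search gate |
| `min_contig_len` | 200 nt | contig and trimmed-fragment gate (inclusive) |
| `presence_min_reads` | 1 | mapped reads that count as detection |
| `eigenvalue_retain` | 2.0 | factor retention threshold |
| `tpm_divisor` | 1000 | report TPM/1000 |

The protocol's prose says contigs "longer than 200 nt" while reporting a
200 nt minimum in its results; the gate is therefore ≥ 200. The e-value
cutoff for the host-nucleotide arm of triage is not stated anywhere; the
triage rule consequently takes the host hit table as pre-thresholded by
the search that produced it and imposes no second gate.

## The synthetic world

`generate_community()` is first-class, tested code, not a fixture. Its
defaults state one fixed world: 21 viral species (a desk-scale community
the size of the published core virome), seven host datasets of which the
first is embryonic with *zero* viral expectation, two food-source
replicates, one rRNA-depleted adult library capturing viral reads at
eight times the polyA rate, species lengths 300–8000 nt (echoing the
published 200–7731 nt assembly range), `fraction_core = 0.33` and
`fraction_food = 0.29` (6 of 21 food-shared, matching the published core
composition). Non-core, non-unique species are planted in 2..(n−1) of
the included datasets so the planted core and unique sets are the
*unique* solutions of the presence analysis. Abundance weights are
log-uniform on [1, 6]: bounded away from zero so that, at the default
depth of 1e6 read pairs and 1% viral rate, every planted
species–dataset expectation is ≥ ~25 reads and exact set recovery does
not hinge on sampling luck.

`emit_hit_tables()` writes hit tables directly instead of running a
search engine, with e-values drawn log-uniformly within strata placed
relative to the cutoffs — the tests target the decision logic, not the
aligner. The emitted decoys exercise each failure path: host fragments
(triage → host), prokaryote decoys (→ prokaryotic), a no-hit contig, a
cellular look-alike that passes triage but falls to the screen, and a
phage that passes triage *and* screen but fails eukaryotic-virus
confirmation. `emit_count_tables()` draws counts multinomially from the
planted profile scaled to depth.

What a green end-to-end test establishes: the decision rules compose
correctly and recover a planted truth exactly when signal strata respect
the cutoffs. What it does not establish: behaviour on real search output
with borderline e-values, chimeric contigs, taxonomically misassigned
subjects, or assembly artefacts — real data has all of these, and the
published virome itself (94 sequences from ~1.9 billion read pairs plus
live protein databases) is not reproducible at desk scale. The package
therefore treats the printed per-dataset integers as inputs and
reproduces the published *statistics* exactly, while the *content* claims
are covered by property-based recovery tests.

## Numerical choices and degenerate inputs

* Best-hit ranking is fully deterministic: e-value, then bitscore, then
  lexicographic subject id; permutation of input rows cannot change any
  decision.
* `sds_from_mean` refuses constant vectors (a z-score is undefined);
  `tpm_thousand` refuses zero lengths and returns all-zeros for all-zero
  columns; `depth_normalized_rpm` refuses zero depth.
* Taxonomy climbing is bounded by the node count and reports cycles as
  errors naming the taxids involved.
* Eigenvalue comparisons use `>` (strictly greater than the threshold),
  matching "eigenvalue > 2".
* Variance-explained regression on the printed eigenvalues (3.161,
  2.278) is checked at the precision those three-decimal inputs can
  support — 100·0.0005/6 ≈ 0.009 per factor plus half a unit of the
  printed percentage — because 100·3.161/6 = 52.683 rounds to 52.68, not
  the published 52.69; the published value was evidently computed from
  the unrounded eigenvalue.
* IUPAC ambiguity codes outside A/C/G/T/N are mapped to N with a warning
  rather than rejected; assemblers emit them rarely and trimming
  operates on a plain alphabet.

## Known limitations

The package never runs an aligner, so its results are only as good as
the upstream searches; the screen's "clear homology" uses the e-value
gate alone (no coverage or identity criterion); host-range assignment is
by exclusion-name list, not biology; and only two-group comparisons are
supported in the factor stage, with no rotation — matching the published
design rather than generalizing it.
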