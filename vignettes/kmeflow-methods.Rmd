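---
title: "Quantifying the lysine methylome: models and methods in kmeflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the lysine methylome: models and methods in kmeflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmeflow)
```

## The problem

Lysine methylation (Kme) is a reversible post-translational modification:
the lysine epsilon-amine can carry one, two or three methyl groups (me1,
me2, me3), written by lysine methyltransferases and erased by demethylases.
Outside histones, thousands of Kme sites exist on human proteins but few
are functionally annotated. kmeflow implements the downstream quantitative
analysis for a TMT (tandem mass tag) isobaric-labelling study of the
non-histone lysine methylome across a neuronal differentiation time course:
three stages (days 0, 2 and 6), four biological replicates per stage,
twelve reporter channels per plex, and two parallel protease experiments
(trypsin/lys-C and chymotrypsin), each searched separately.

The package starts from search-engine export tables (protein and
modified-peptide quantification), not raw spectra. Everything upstream —
acquisition, spectrum matching, localization scoring, isotopic-impurity
correction — is consumed as fixture fields, never recomputed.

## The quantification model

The central quantity is **methylation stoichiometry relative to protein
abundance**. For methylated peptide $i$ of protein $p$ in sample $s$:

$$ r_{is} = \frac{x^{\text{pep}}_{is} + c}{x^{\text{prot}}_{ps} + c}, $$

where $x$ are channel-normalized abundances and $c = 0.1$ is a pseudocount.
Because a methylated peptide's abundance is (stoichiometry) × (protein
abundance), protein-level changes across differentiation cancel in $r$,
isolating changes in the fraction of protein molecules that are methylated.
The processing chain is:

1. **Protein filter** — keep proteins at high FDR confidence with ≥ 2
   unique peptides (`filter_proteins()`).
2. **Localization filter** — keep methyl-peptides with a site-localization
   score ≥ 0.9 and an unambiguous assignment (`filter_kme_peptides()`).
   Peptides with a missing score are removed and reported.
3. **Channel normalization** — "total peptide amount without scaling":
   each channel is multiplied by mean(column sums)/(its column sum)
   (`total_peptide_normalize()`). The factors are computed over the whole
   peptide export; unmodified peptides dominate those totals, which keeps
   the factors free of composition effects from the small methyl-peptide
   subset.
4. **Pseudocount** — $c = 0.1$ added to observed values only; missing
   stays missing, and a second application is a guarded error
   (`add_pseudocount()`).
5. **Protein normalization** — the per-sample ratio above
   (`normalize_kme_to_protein()`). The pseudocount is applied to both
   numerator and denominator: the Methods-level description attaches it to
   "the normalized abundances" generally, and the symmetric version keeps
   the ratio bounded; `require_pseudocount = FALSE` switches to raw
   ratios.

Statistics run on $\log_2 r$ (configurable `log2_transform`); log
transformation stabilizes the variance of reporter-ion ratios, whose noise
is multiplicative.

**Missing data.** Empty abundance cells are missing values, never zeros,
through every reader and transformation. A feature enters the statistics
only with ≥ 2 observed replicates in every day group (ANOVA degrees of
freedom); excluded features are reported, not silently dropped.

## Differential methylation

Per feature, a one-way fixed-effects ANOVA over the three day groups, with
Benjamini–Hochberg adjustment across features, then Tukey(-Kramer)
pairwise comparisons (2 vs 0, 6 vs 0, 6 vs 2) within each feature. The
pairwise p-values of ANOVA-significant features are pooled and BH-adjusted
across that pool, mirroring the two-level "adjusted p < 0.05 … adjusted
p < 0.05" decision rule; a feature is *significant* when its ANOVA
padj < α and at least one pair padj < α (α = 0.05 default). Whether the
pair level receives the extra BH step is configurable (`pair_adjust =
"bh"` or `"none"`) because the original description does not pin it down.

The F statistic and Tukey q are computed by explicit (vectorized) sums of
squares — with thousands of features, per-feature model objects are the
slow route — and p-values come from `stats::pf()` and `stats::ptukey()`.
The test suite checks both against `stats::aov()`/`stats::TukeyHSD()` and
against a numerical integration of the studentized-range distribution, to
1e-8.

Degenerate inputs are explicit: zero within-group variance with distinct
means gives p = 0 with a `degenerate` flag; a completely constant feature
is skipped with reason `"zero_variance"`.

QC mirrors standard practice: pairwise Pearson correlation of replicate
channels on log2 values (pairwise-complete, `r` missing below 3 shared
observations) and a sample PCA (complete features only, features z-scored,
samples centered, SVD, component signs fixed by the largest-magnitude
loading).

## Co-expression modules

A signed weighted network on log2 abundances:
$a_{ij} = ((1 + \mathrm{cor}_{ij})/2)^\beta$, so anti-correlated features
are disconnected rather than connected. Topological overlap
$\mathrm{TOM}_{ij} = (\sum_{u} a_{iu} a_{uj} + a_{ij}) / (\min(k_i, k_j) +
1 - a_{ij})$ measures shared neighbourhoods; features are clustered by
average linkage on $1 - \mathrm{TOM}$.

Defaults follow the two analysis levels: soft-threshold power $\beta = 30$
and minimum module size 30 at the protein level; $\beta = 18$ and minimum
size 10 for normalized Kme peptides. Two choices were genuinely open and
are package decisions:

* **Static tree cut** at height 0.99 on $1 - \mathrm{TOM}$ (configurable).
  Only "hierarchical clustering" with a size minimum is specified upstream;
  a static cut is deterministic and fully reproducible, at the cost of the
  adaptivity a dynamic cut provides.
* **No eigengene-based module merging** by default (`merge_height`
  reserved); merging is not part of the described procedure.

Clusters below the minimum size become `"grey"`; surviving modules are
labelled in decreasing size with the canonical color sequence, so the
largest module is always `"turquoise"`. Each module gets an eigengene (the
first right-singular vector of the member-z-scored matrix, sign-aligned
with the mean member profile) and a day-profile archetype: *decreasing*
(day 0 > 2 > 6), *transient_up* (day 2 highest), *increasing*
(6 > 2 > 0), else *other*. Gene-set over-representation per module is an
upper-tail hypergeometric test against a user-supplied GMT within the
quantified universe, BH-adjusted across sets — a deliberate, offline
stand-in for live GO services.

## Digestion and detectability

`digest()` performs methylation-aware in silico digestion. The
trypsin/lys-C mixture cleaves after K always (lys-C cuts K-P) and after R
unless proline follows; chymotrypsin cleaves after F/W/Y/L (configurable
to F/W/Y), never before proline. A methylated lysine is removed from the
cleavage-site set — the bulkier side chain blocks the protease — and does
**not** count toward the missed-cleavage budget (default maximum 5,
matching the search settings; blocking is configurable per methyl state
because the behaviour of me1 under lys-C is not established).

Peptide masses are monoisotopic residue sums plus water, +14.015650 Da per
methyl unit; the isobaric-label policy adds the tag mass (default TMTpro,
304.207146 Da) to the N-terminus and to every lysine that carries no
methyl (the label reaction needs the free epsilon-amine).
`detectable()` declares a peptide observable when its length is within
6–50 residues and some charge in 2–7 puts its m/z inside the 400–1600
survey window; the m/z window and charge range are instrument settings,
the length bounds are package defaults, all configurable.

`site_detectability_matrix()` combines these per site and protease. It
reproduces the characteristic asymmetry of K/R-sparse, aromatic-flanked
methylation sites: with no tryptic cut points nearby and the methylated K
itself blocked, every trypsin/lys-C peptide covering the site exceeds the
length window, while chymotrypsin releases a short aromatic-bounded
peptide that passes — so the site is observable only in the chymotrypsin
arm.

## Site-level reporting

Methylated peptides are located as exact substrings of their master
protein; each methyl becomes a site at `match start + peptide position -
1`, 1-based on the FASTA sequence *including* the initiator methionine
(lysine-number ambiguity relative to Met-cleaved numbering is a known
annotation hazard; one convention is fixed here). Peptides matching at
zero or multiple offsets are excluded and reported rather than
multi-assigned. Site identity is (accession, position, methyl state);
aggregation across the two protease experiments yields the
unique-site/shared/union overlap summary at site and protein level.

Sequence context uses the 7-mer window (±3 residues, `'-'`-padded at
termini): K/R density excluding the central K for windows, total K/R for
peptides, and positional residue frequencies over non-padding entries.
Novelty against a known-site table defaults to methyl-state-agnostic
matching (state-aware is a switch); clinical-variant joins are left joins
on (accession, position), flagging — not dropping — reference residues
other than K.

## The synthetic-data generator

`simulate_study()` generates ground-truth studies with the statistical
structure the analysis assumes; it is what the tests and the acceptance
checks run against. The defaults encode the study conditions: 250
proteins, 500 Kme sites, 3 days × 4 replicates × 2 proteases, 15% of
sites differential with a planted log2 fold change of 1.0 at day 6
(random sign), 10% lognormal replicate CV, 5% channel-loading spread, 2%
missingness, a Beta-mixture of localization scores (true sites
concentrated near 1, decoys low-scoring and mostly ambiguous), and a 10%
decoy fraction. Protein day-profiles come from four archetypes
(decreasing / transient_up / increasing / flat) with ±1 log2 amplitude,
matching the module structure the network stage expects.

Three structural choices matter:

* **Stoichiometry is multiplicative on the parent protein**, so
  protein-level changes cancel in the ratio by construction — precisely
  the property the normalization is designed to isolate, which makes the
  isolation test sharp.
* **The protein table is the roll-up (sum) of the protein's simulated
  peptides**, as consensus workflows compute it, and the peptide export
  includes an unmodified bulk complement (5 peptides per protein by
  default) that dominates the channel totals. Simulating the protein
  table as an independent measurement instead makes the peptide- and
  protein-level normalization factors drift apart and induces a spurious
  shared day shift in every null ratio.
* **Observed peptides come from the real digestion model**: each site's
  supporting peptide is chosen by methyl-aware `digest()` under the arm's
  protease (fewest missed cleavages, then shortest, among detectable
  peptides). A peptide spanning several methyl sites is emitted once and
  carries the largest planted effect among them — the peptide is the
  quantifiable unit, and adjacent methylated lysines (a real phenomenon,
  e.g. paired K-me3 sites three residues apart) cannot be separated.
  Trypsin-invisible contexts are engineered 61-residue K/R-free blocks
  with aromatics at −5/+4 around the site.

What the generator does **not** emulate: co-isolation interference and
ratio compression, isotopic impurities, retention behaviour, peptide-level
identification error beyond the decoy/ambiguity mixture, shared/razor
peptide inference, and biological correlation between sites beyond their
shared protein. Passing tests therefore demonstrate that the pipeline's
statistics and bookkeeping behave as designed under the stated noise
model, not that real data meet that model.

All randomness flows from the single `seed` field; generation is
byte-reproducible, and the packaged mini-study (50 proteins, 30 sites,
both proteases, seed 420) regenerates identically from its recorded seed.

## Problem sizes and numerical choices

The simulation-based checks use 500 sites × 10 seeds for parameter
recovery, one 500-site null study for calibration, 105 features × 5 seeds
for module recovery, and a 120-site noise-free study for the isolation
property — sizes at which every property is measured stably while a full
run of the suite stays comfortably interactive on a single core.
Tolerances follow the quantity: statistical oracles agree to 1e-8,
network oracles to 1e-12, text round-trips to 6 significant digits (the
writer's fixed float format), and the isolation property bounds
|log2FC| < 0.05.

Ties and degenerate cases are resolved deterministically everywhere:
module size ties break by first appearance, best-peptide ties by minimal
missed cleavages then length, PCA/eigengene signs by fixed conventions,
and written tables are sorted by feature id.

## Known limitations

* A site observed in both protease arms is tested separately in each; the
  union call rate is slightly anti-conservative relative to a single
  pooled test (the per-arm BH level still holds).
* The static tree cut can split one correlated block across height
  boundaries in ways a dynamic cut would not; the height is exposed.
* Protein inference is taken from the export (master accession as given);
  shared peptides and isoforms are out of scope.
* Cross-plex (cross-protease) abundances are never bridged; features merge
  only at the site-report level.
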