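---
title: "Methods: thiamine pathway genotyping and depth-profile analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thiamine pathway genotyping and depth-profile analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b1profiler)
```

## Scientific scope

Vitamin B1 (thiamine) is an obligate coenzyme of central carbon and amino
acid metabolism, yet many marine bacteria and archaea cannot synthesize it
de novo and depend on dissolved thiamine or its precursors. `b1profiler`
implements an inference chain that connects three kinds of evidence about
this economy in a stratified water column:

1. **Genomic potential** — which genomes and metagenome-assembled genomes
   (MAGs) carry the de novo thiamine biosynthesis pathway (TBP), which are
   precursor auxotrophs, and which can only salvage;
2. **Abundance and activity** — depth profiles of TBP genes and
   transcripts, normalized as RPKM, attributed to domains and taxon
   classes;
3. **Community and chemistry context** — amplicon-based community
   summaries along the depth/oxygen gradient, and replicate statistics of
   dissolved thiamine-related compounds (TRCs: B1, HMP, HET, cHET, AmMP)
   with oxygen-minimum-zone (OMZ) layer flags, fold changes and local
   maxima.

A synthetic-data module generates every input with recorded ground truth,
so the full chain is testable without downloads.

## Annotation ingest and tiered filtering

Hit tables come either as HMMER3 per-domain tabular output or plain TSV.
Each hit carries a full-sequence e-value and bit score; the gene-family
catalog (`b1_gene_catalog()`) maps family accessions to a controlled
vocabulary of gene symbols with a functional role and a filtering tier.
Two inclusive e-value cutoffs are applied: a general annotation tier
(default `1e-10`) and a stricter tier (default `1e-15`) for B1,
nitrification, and carbon-fixation families, whose annotations warrant
extra scrutiny. Sulfur-oxidation markers (`aprA`, `aprB`, `dsrA`) sit in
the general tier. Both cutoffs default to full-sequence e-values; the
choice is configurable through which column the input tables carry.

After thresholding, each protein retains at most one hit: highest bit
score, ties broken by lower e-value, then lexicographically smallest
family accession. Bit score is used because it is stable across query
lengths; the tie-break makes filtering deterministic. Filtering is
idempotent and monotone in the cutoffs (tested properties). The presence
matrix counts *distinct proteins* per genome and gene symbol, so
multi-copy genes (frequently observed for `thiG` and `thiE`) are
preserved as counts.

## Genotype model

Classification uses a three-function decomposition of the TBP:

* **PYR** — pyrimidine branch: `thiC`;
* **THZ** — thiazole branch: `thiG` or `thi4` (the `thi4`-type synthase
  occurs in both domains and is accepted for both);
* **CND** — condensation: `thiE`, or the archaeal fusion `thiDN`
  (archaea-only by default, configurable).

The eight PYR/THZ/CND combinations map onto: `PROTOTROPH` (all three),
`AUX_HMP` (missing PYR only), `AUX_HET` (missing THZ only), `AUX_DUAL`
(missing PYR and THZ), and — when CND is absent — `SALVAGE_ONLY` if any
salvage or transporter gene is present (`thiL`, `thiM`, `tenA`, `thiD`,
or any transporter symbol), else `NO_PATHWAY`. The lattice is total:
every possible gene row yields exactly one category (tested by
enumeration).

### Incompleteness-aware confidence

Any category other than `PROTOTROPH` asserts that genes are *absent*,
which for a MAG can be an assembly artifact. We model gene recovery as
independent Bernoulli events with success probability equal to the
completeness estimate `c`, so the probability that the `k` missing
synthesis *functions* are all unobserved by chance is

$$p_\mathrm{chance} = (1 - c)^k .$$

`k` counts functions (PYR/THZ/CND), not symbols: either thiazole gene
would satisfy THZ, and typical genomes encode one alternative, so
counting symbols would overstate confidence. A negative call is kept only
when `p_chance < alpha` (default 0.05); otherwise it is downgraded to
`INDETERMINATE`. The threshold comparison treats `p_chance == alpha` as
indeterminate, so a genome at 95% completeness missing one function is
never called a definite auxotroph at the default `alpha` — the boundary
case is resolved conservatively rather than left to floating-point
rounding.

Two caveats are deliberate design choices. First, contamination is not
modeled as false gene presence; it only affects the quality tier (`high`:
completeness ≥ 50% and contamination < 5%; `medium`: ≤ 10%; otherwise
`below_threshold`, with the call still computed but flagged). Second, the
independence model is *per call*, not family-wise: in a mid-completeness
band (roughly `c` between 0.75 and 0.92 for three-function prototrophs),
two genes can drop out with probability well above `alpha` while
`(1-c)^2` is already below it, so definite false negatives exceed the
nominal level there. At high completeness (≥ 0.95) and low completeness
(≤ 0.6) the rule is calibrated, which the test suite verifies on
simulated cohorts; the band in between is a known limitation of the
closed-form confidence and is the reason recovery statistics are always
reported alongside an indeterminate fraction.

For recovery statistics on degraded cohorts we score *accuracy* as "no
incorrect definite call": a call is correct if it equals the planted
category or is `INDETERMINATE`. Under per-gene dropout at 95%
completeness, exact category recovery of a three-gene prototroph is
bounded by $0.95^3 \approx 0.86$, so exact-match accuracy is not an
attainable yardstick for incomplete MAGs; what the confidence model can
and should guarantee is that wrong *definite* calls stay rare.

## RPKM and depth profiles

ORF counts are normalized as reads per kilobase per million mapped reads:
`rpkm = count / ((length/1000) * (library/1e6))`. Library sizes default
to column sums but externally supplied totals of mapped reads take
precedence, and the choice is recorded in the output attributes. The
per-sample (not per-reference-bin) library size is the default; callers
that mapped competitively per bin can pass per-bin totals explicitly.
Profiles sum RPKM over ORFs of each requested gene symbol within domains,
taxon classes, or genomes; with domain grouping the archaea:bacteria
ratio is emitted per symbol (undefined, reported as `NA`, when the
bacterial total is zero). Transcript shares within a sample always sum to
one over groups where the sample has any signal; samples with zero
thiamine-gene RPKM get `NA` shares, not zeros.

## Community ecology

Relative abundance, Shannon diversity (natural log by default,
configurable base), and Bray–Curtis dissimilarity follow their textbook
definitions and are cross-checked against vegan in the test suite.
Chloroplast-classified amplicons are removed by a case-insensitive
taxonomy substring pre-filter. Hierarchical clustering is UPGMA with the
pairwise mean of the *original* dissimilarities recomputed at each step;
ties are broken by the lexicographically smallest pair of smallest member
labels, so results are deterministic on degenerate inputs. The tree is a
valid `hclust` object and exports to Newick with ultrametric half-height
branch lengths.

Rank tests delegate to `stats::kruskal.test` and `stats::wilcox.test`
(two-sided, asymptotic, mid-rank ties); an all-constant input returns
statistic 0 and p-value 1. Indicator species analysis uses the original
single-group Dufrêne–Legendre form: specificity × fidelity, with the
maximizing group reported, and permutation p-values
`(1 + exceedances) / (1 + permutations)` under sample-label permutation
with fixed group sizes. At least 99 permutations are required for usable
p resolution; identical seeds give bit-identical output. Observed
richness, where needed, is the raw ASV count per sample.

Depth layers are epipelagic (≤ 200 m), mesopelagic (200–1000 m] and
bathypelagic (> 1000 m), with boundary depths assigned to the shallower
layer; no real sample in the motivating datasets sits exactly on a
boundary, so the convention is cosmetic but fixed.

## TRC profiles

Replicate statistics are arithmetic means and `n-1` standard deviations
of technical replicates (typically n = 3). Femtomolar inputs are
converted to pM on ingest. OMZ flags join each profile row to CTD context
at the same station/campaign within ±5 m and use inclusive
dissolved-oxygen cutoffs: OMZ at ≤ 30 µmol kg⁻¹ and OMZ core at
≤ 10 µmol kg⁻¹. Fold changes divide a target summary by the mean over a
0–100 m reference window; the default target is the mean over
OMZ-flagged mesopelagic depths, with a `max` rule available because the
underlying field observations do not pin down which summary a reported
fold refers to — both are computed and neither is privileged. Local
maxima require strict dominance over both adjacent sampled depths
(endpoints over their single neighbor) and are returned largest-first.

## Synthetic data: what it emulates and what it does not

The generator encodes seven guild archetypes with gene sets transcribed
from the genotype patterns of the motivating system: prototrophic
ammonia-oxidizing archaea (`thiC, thi4, thiDN, thiL` + `amoA`),
prototrophic *Nitrospina* (`thiCEG` + salvage cluster + `nxr`),
prototrophic sulfur-oxidizing Thioglobaceae (`thiCEG` + `apr/dsr/rbcL`),
HMP-auxotrophic SAR11 and SAR202, dual-auxotrophic Rhodobacterales
(`thiE` only among synthesis genes), and salvage-only Flavobacteriales
(`thiL` + transporter). Each archetype is self-consistent: the classifier
returns its expected category at completeness 1 (tested).

True-gene e-values are log-uniform in `[1e-40, 1e-16]`; decoys are drawn
above every threshold (`[1e-9, 1e-3]`) so filtering must remove them all.
MAG degradation drops each gene independently with probability
`1 - completeness` (block dropout by contig loss is not modeled);
contamination copies genes from random donors at a rate calibrated to the
contamination estimate.

Community simulation plants the depth-stratified composition the study
system motivates: AOA rising to 24% of amplicons and a combined
prototroph share of 31% in OMZ mesopelagic samples, against a
depth-dependent background; ASV counts are multinomial. ORF and
transcript counts are negative-binomial around RPKM-consistent
expectations (dispersion 0.2 by default; 0 recovers Poisson), with
planted archaea:bacteria RPKM ratios (thi4 3×, thiC 4×) and planted
class-level transcript shares (Gammaproteobacteria 40%, Nitrososphaeria
22%, Alphaproteobacteria 27%, Dehalococcoidia 6%, Bacteroidia 5%). Counts
are spread over 25 ORFs per gene cell so overdispersion averages out at
realistic scale; 1e5 reads per sample is the default problem size, which
keeps the full suite and the acceptance script to well under a minute
each for these stages.

TRC simulation builds a baseline profile with a multiplicative OMZ
enhancement placed so the default fold-change rule recovers the planted
fold exactly in the noiseless case and the peak depth is a strict local
maximum in the OMZ core. Replicates are log-normal (concentrations are
positive and LC-MS error is multiplicative — a testbed assumption, not a
claim about any instrument).

What the simulator does *not* emulate: sequence-level artifacts (chimeras,
mis-binning beyond uniform contamination), compositional coupling between
taxa, seasonal structure, block gene dropout, or chemistry-based TRC
production/degradation kinetics. Passing tests therefore demonstrate the
correctness and calibration of the inference chain under its own model
assumptions, not performance on real survey data.

A shipped worked example (`synthetic_station_profile()`) provides a
replicate-level TRC table and CTD context for a synthetic offshore
station constructed so that its derived statistics land on headline
values reported for the eastern North Pacific station 67–70 profiles: a
B1 local maximum of 232.52 pM in the OMZ core at 700 m, a 3.5-fold B1
increase from the upper 100 m into the OMZ mesopelagic, and companion
700-m concentrations of AmMP (25.36 pM), HMP (3.19 pM) and cHET
(29.59 pM). The package recomputes these from the replicate level; the
table is a constructed stand-in, labelled synthetic, not measured data.

## Numerical choices

* E-value cutoffs are inclusive (`<=`), matching the notation they are
  quoted in.
* `absence_confidence(c, 0)` is 1 (no absence claimed, no evidence), but
  `PROTOTROPH` calls set `p_chance = 0` since they assert no absence.
* The UPGMA symmetry check tolerates `1e-9`; Shannon input must sum to 1
  within `1e-9`.
* Permutation exceedance uses a `1e-12` slack so exactly-tied permuted
  statistics count as exceedances on every platform.
* All generators run under an isolated RNG scope: they seed their own
  stream and restore the caller's `.Random.seed`, so identical
  (arguments, seed) pairs are bit-reproducible regardless of surrounding
  code.

## Orchestration

`run_config()` + `run_pipeline()` execute annotate → genotype →
rpkm/profiles → ecology → TRC from one validated configuration (YAML
round-trip supported), write per-stage TSVs, a Newick dendrogram, a JSON
summary (genotype counts, per-layer prototroph shares and Shannon means,
domain RPKM ratios, TRC fold changes and primary maxima) and a log with
the package version, an MD5 config hash and the seed. Validation failures
(e.g. inverted e-value tiers) abort before any stage runs; stage failures
name the stage, leave partial outputs and a `FAILED` marker. The
command-line surface of this package is R itself: the exported functions
and `scripts/acceptance.R` are the entry points, and genotype summaries
take an explicit genome set rather than assuming any particular
dereplication state.
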