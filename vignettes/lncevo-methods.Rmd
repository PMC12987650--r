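---
title: "Methods: triplex-based DBS prediction and evolutionary analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triplex-based DBS prediction and evolutionary analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncevo)
```

## Scope

`lncevo` studies how human-specific (HS) long non-coding RNAs may have
reshaped transcriptional regulation, through the promoter DNA-binding
sites (DBSs) they contact via RNA:DNA triplexes. The package chains six
analysis stages — triplex-based DBD/DBS prediction, HS-gene orthology
calls, cross-genome DBS distances with age labels, population-genetic
selection scans, expression-impact statistics, and regulatory-module
discovery — and ships a seeded synthetic-data generator that produces
every input with planted ground truth, so the whole pipeline can be
exercised and validated without any external download.

## Triplex model

A triplex forms when a single-stranded RNA (the third strand) binds the
major groove of duplex DNA and hydrogen-bonds to the purine-rich strand.
`triplex_ruleset()` encodes which (third-strand base, duplex purine)
juxtapositions pair: canonical parallel (Hoogsteen) triplets U·A-T and
C·G-C; canonical antiparallel (reverse-Hoogsteen) triplets A·A-T, G·G-C,
U·A-T; and, in the `"all"` preset, a deliberately small non-canonical
extension (parallel G·G-C, antiparallel A·G-C). The published tool this
stage emulates does not enumerate its rule tables, so ours are explicit
data frames that can be swapped wholesale; results are always conditional
on the table used. We keep the extension table minimal on purpose: overly
permissive rules (e.g. a U·G wobble) make pyrimidine-rich RNA pair with
most random purine tracts, which destroys the contrast between planted
sites and background.

`align_triplex()` performs ungapped local alignment, one motif at a time
(the RNA is reversed for the antiparallel motif). Per position the score
is +1 when a rule pairs it, `tt_penalty` (default −1000) for a T·T
juxtaposition, `cc_penalty` (default 0) for C·C, and 0 otherwise. A
window qualifies when it is at least `min_nt` = 50 nt long, starts and
ends on a paired position, and its score is at least
`min_identity_percent` = 60 per 100 positions; reported identity is the
paired-position percentage. The default −1000 makes a single pyrimidine
interruption disqualifying, reproducing the qualitative effect of the
published penalty without claiming internal equivalence. Reported pairs
are, per diagonal, the maximal qualifying windows, with a second
containment filter across diagonals (a pair is suppressed when both its
RNA and DNA intervals sit inside a strictly larger pair of at least equal
identity), so a perfect uninterrupted tract yields exactly one pair.
These semantics are deliberately simple enough to be re-derived by
exhaustive enumeration of all substring pairs; the test suite checks
exact agreement on hundreds of random short sequences.

TTSs whose DNA intervals overlap or lie within `offset` = 15 bp are
chained into one DBS (`cluster_tts()`); the single bp-scale parameter is
read as the maximum inter-TTS gap, the only interpretation consistent
with "densely overlapping" sites. The DBS spans the union hull, its
identity is the unweighted mean over member TTSs (the source states no
weights), and its binding affinity is span length × identity/100.
Affinity ≥ 60 is `strong`, 36 < affinity < 60 `weak`, the rest
`subthreshold`; exactly 60 is strong and exactly 36 subthreshold, per the
printed inequalities. The same chaining on RNA intervals yields DBDs;
`select_dbd1()` ranks DBDs by genome-wide DBS count, breaking ties by
summed affinity and then 5′-position.

Promoters are the 5000 bp windows from 3500 bp upstream to 1500 bp
downstream of the TSS, read 5′→3′ on the transcript strand. Coordinates
are 0-based half-open internally; FASTA/VCF exports are 1-based.

## Orthology rule

A lncRNA gene has an ortholog in a genome when the number of its exons
with hits there *strictly exceeds* half its exon count; with 4 exons, 2
hits are not enough. A gene with no ortholog in any of the queried
genomes (classically 16 non-human mammals) is human-specific. Exon hits
are counted without synteny or ordering constraints, which the source
leaves unspecified. Missing genome columns are an error, never treated as
absence of an ortholog.

## Cross-genome distances and DBS ages

Counterpart sequences are built by substituting a sample's
highest-quality variant calls into the reference (`apply_variants()`;
SNVs only, since the distances are substitution-model based), or supplied
as FASTA. `k2p_distance()` implements the Kimura 2-parameter distance
K = −½ ln((1 − 2P − Q)√(1 − 2Q)) from transition and transversion
proportions, excluding gap/ambiguity sites pairwise and dividing by
compared sites (standard `dnadist` behaviour; the source is silent on the
denominator). Saturation (non-positive log arguments) is an explicit
flagged error, never coerced to a number; the sentinel distance 10.0 is
reserved for DBSs whose counterpart is missing entirely, as the study
prescribes for deleted regions. A Tamura–Nei implementation
(`tn93_distance()`) provides the cross-model consistency check the study
reports; the tests also compare both against an independent phylogenetics
library.

DBSs are `old` when diverged from chimpanzee (K > 0.034) yet identical to
the Altai Neanderthal (K = 0), `young` when K > 0.034 to the Altai
Neanderthal or Denisovan. Epoch flags C/A/D/V mark, within the top 20% of
human–chimp distances, genomes at distance > 0.037. Ancestor-anchored
distances (`ancestor_mode_distances()`) report the fraction of DBSs with
d(ancestor→modern) > d(ancestor→archaic); on serial synthetic lineages
this concordance approaches 1, on star topologies ½, which is why the
human-anchored distances are preferred for interpretation.

## Selection statistics

All statistics are computed from phased biallelic haplotype panels with
recorded ancestral states. `tajima_d()` uses the standard 1989 constants;
`faywu_h()` computes θ_H = Σ 2 S_i i² / (n(n−1)) over derived counts,
excluding SNPs with unknown ancestral state (they are retained for D,
which needs no polarisation). `weighted_fst()` is the Weir–Cockerham
estimator with ratio-of-sums weighting across the window's SNPs,
haplotypes paired in order into diploids. `integrated_fst()` combines the
three pairwise values for a focal population; the source cites but does
not state its combiner, so ours is pluggable with the mean over the two
focal pairs as default (max and a PBS-style combiner are selectable).

Windows are non-overlapping tiles of 1500 bp (genes) or 147 bp (DBSs, the
mean strong-DBS length); partial terminal tiles are kept at ≥ half size.
Background thresholds are empirical tail quantiles over ≥ 100 defined
windows (S = 0 windows are excluded — the source is silent; including
them would make the D background depend on invariant-window bookkeeping).
The joint call declares positive selection in a focal population when its
D falls below the population's lower-10% background threshold while D > 0
in both other populations and integrated Fst exceeds the upper-10%
threshold; the study's genome-derived defaults (−0.97/−0.96/−0.97 and
0.22) are retained as reference configuration values and regenerated from
the synthetic background in all tests.

## Expression impact

Robust expression means median TPM strictly above 0.1 in a tissue. Each
lncRNA is represented by its highest-expressed DBD-containing transcript.
Pair correlations are Spearman's rho per tissue with Benjamini–Hochberg
FDR over the *whole* family of (pair, tissue) tests — the source does not
state the family; the joint choice is the more conservative and is what
`pair_correlations()` reports. Significance requires |rho| > 0.3 and
FDR < 0.05. The random-pair background applies the identical rule to
randomly drawn lncRNA–transcript pairs and returns the significant
fraction with a binomial interval.

Tissue shift tests compare each tissue's DBS distances (for significantly
correlated pairs) against the pooled all-tissue background with a
one-sided two-sample Kolmogorov–Smirnov test; the fixed alternative is
"tissue distances stochastically larger", matching the directional claim
of increased divergence. FDR is taken across tissues × archaic genomes at
0.001, and epoch labels D/AD/ADV record which archaic genomes shifted.
eQTL records qualify at MAF ≥ 0.1 in ≥ 1 population and |ES| ≥ 0.5 in
≥ 1 tissue; `conserved` means present in all three archaic counterpart
intervals, `novel` in none. Effect sizes are consumed as supplied
(GTEx-style normalised slopes); the generator produces them by OLS of
standardised expression on genotype dosage. eQTL density in DBSs versus
promoters is compared with a one-sided Mann–Whitney test.

## Module discovery (eGRAM)

Co-regulator sets are the maximal cliques of the regulator correlation
graph at |r| ≥ 0.5 — the pairwise wording ("each lncRNA's correlated
lncRNAs") matches cliques, and a connected-components mode is available
for the looser reading. A gene is a target of a regulator when binding
affinity ≥ 60 and |r| ≥ 0.5 (correlation is unsigned by default; the
source does not say, and repression is as real as activation — a
`signed_r` switch flips this). A module is the union of a co-regulator
set's targets, kept when it has at least `module_size` = 50 genes; the
parameter is read as a minimum, not an exact size, since truncating
planted structure at an arbitrary cap would discard genes
indistinguishable from the kept ones. Modules may overlap. Enrichment is
the upper-tail hypergeometric test against the expression-matrix universe
(the space modules are built from), BH-corrected at FDR 0.01.
Cross-species comparison maps a module through an ortholog table and
reports the fraction of orthologs found in any module of the second
species plus the within-set mean correlation in both species.

## Synthetic data: what it emulates, and what it does not

The generator lays out one contig with non-overlapping promoter slots and
plants triplex tracts by mapping a pyrimidine-rich RNA through the
canonical parallel rules onto the purine strand, corrupting an evenly
spaced `1 − identity` fraction of positions to non-pairing bases. A 20 bp
unpairable spacer (wider than the chaining offset) flanks each tract so
the recovered DBS is delimited by the plant rather than by chance pairing
in random flanks — real promoters have no such insulation, so recovery
rates on real sequence would be less clean than the planted tests
suggest.

Population panels draw each SNP's derived count from the neutral site
frequency spectrum P(i) ∝ 1/i on the pooled sample of all populations and
partition carriers randomly into populations: a random subsample of a
neutral sample is itself neutral, so every population's marginal SFS is
exactly neutral (mean Tajima's D ≈ 0) while populations remain
exchangeable (Fst ≈ 0) — this is what makes the background-threshold
calibration honest. The sweep scenario skews the focal population's SFS
in the target window toward rare plus high-frequency-derived variants
(the classical sweep signature driving D and H negative) and gives the
other populations an intermediate-frequency excess there. That models
local adaptation in the focal population with the selected alleles
segregating at intermediate frequency elsewhere — exactly the
configuration the joint decision rule (focal D below threshold, D > 0
elsewhere, high integrated Fst) is designed to detect; a sweep with
simply neutral non-focal populations would fail the rule's D > 0 clause
about half the time by construction, and the rule's published form makes
sense only under this scenario. Differentiation without a sweep uses
Balding–Nichols frequency draws at a configurable Fst. The generator
performs no coalescent simulation, no recombination, no linkage and no
demography; its panels validate estimator arithmetic and decision-rule
calibration, not demographic robustness.

Expression matrices are latent-factor models (module genes = loading ×
regulator + Gaussian noise, default loading 1 and noise sd 0.3, affinely
mapped to a non-negative TPM scale whose floor essentially never binds,
preserving correlation structure). eQTLs add an additive
per-alternate-allele shift; one planted pathway is a subset of a planted
module. Real expression data are heavier-tailed, batch-structured and
compositional; passing the planted-recovery tests shows the machinery is
correct, not that real-data modules would be as crisp.

## Numerical choices and problem sizes

Ties in variant selection break to the first record; ties in DBD1
selection to summed affinity then 5′-position; ties in representative
transcripts to the lexicographically smallest id. Monomorphic columns
yield MAF 0, not errors; undefined statistics (S = 0 windows, saturated
distances, constant expression vectors) are flagged and excluded, never
coerced. All generators and the pipeline are deterministic given their
seeds; the pipeline hashes its configuration and outputs (MD5 over
version-3 serialisation) so reruns can be verified byte-for-byte.

The shipped test and acceptance workloads use desk-scale sizes chosen to
exercise every code path with stable statistics: 1500 bp windows with
θ = 0.004 and 60 haplotypes per population (≈ 30–40 SNPs per window), 60
background windows for threshold regeneration, 50 sweep replicates, 20
seeds for recovery rates, 200 DBS distances per tissue-shift test, and
modules of 55 genes over 60–180 samples. These sizes are stated here as
the package's reference configuration; all thresholds above are the
study's printed values and live in `pipeline_config()`.

## Known limitations

The triplex rule tables and penalty semantics are a documented
interpretation, not a reimplementation of the published predictor's
internals. Orthology consumes precomputed exon-hit tables; sequence
search itself is out of scope, as are external selection scanners
(XP-CLR, iSAFE, favored-mutation classifiers), liftover (a coordinate map
is an input), ancestral-sequence reconstruction, and eQTL discovery at
biobank scale. The integrated-Fst combiner is an explicit choice among
plausible readings. Distances assume substitution-only evolution;
indels in counterpart genomes are skipped, and regions deleted outright
are handled by the 10.0 sentinel convention rather than by alignment.
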