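---
title: "Methods: family-based exome variant prioritization with famfunnel"
author: "famfunnel"
output: rmarkdown::html_document
---

# Scope and model

`famfunnel` prioritizes candidate disease variants in a small kindred
segregating an apparently autosomal-dominant phenotype, from a multi-sample
annotated exome VCF.  The motivating setting is a two-generation family of
eight with four affected members (an affected parent and three affected
offspring), screened against case/control cohorts of roughly 180 individuals
each — the situation in which a single family can contribute at most a
suggestive linkage signal and every prioritization decision must be explicit
and auditable.

The pipeline has five analytic parts:

1. an ordered **filtering funnel** over the annotated variants;
2. a **k-of-3 pathogenicity consensus** over SIFT, PolyPhen-2 and REVEL;
3. an exact **two-point parametric LOD** for the surviving variants;
4. **case/control carrier screening** with a polymorphism rule;
5. a **composite candidate ranking**.

A sixth component, the **gene-dropping simulator**, generates complete
synthetic datasets with known truth labels so the whole chain can be
validated end to end.

# The filtering funnel

Six conjunctive predicate stages, each idempotent, applied in a configurable
order (default: known-variant exclusion, dominant segregation, consequence
class, population frequency, local population frequency, pathogenicity
consensus).  Because the stages are conjunctive, the final survivor set is
invariant to stage order; only the per-stage counts depend on it, and the
test suite asserts this permutation invariance explicitly.

Decisions that were genuinely open, and how they were fixed:

* **Known-variant exclusion** removes only exact (chrom, pos, ref, alt)
  matches against the curated catalogue.  A variant that merely falls in a
  panel gene is retained and flagged `panel_gene = TRUE`: gene membership is
  corroborating evidence for a novel variant, not grounds for exclusion.
* **Dominant segregation** keeps variants heterozygous in *every* affected
  member and homozygous reference in *every* unaffected member.  A missing
  call in an affected member excludes the variant — a causal dominant allele
  must be observable in each affected.  A missing call in an unaffected
  member also excludes by default, because "absent in unaffected" cannot be
  verified on a missing call; `lenient_unaffected = TRUE` relaxes this for
  datasets with patchy coverage.  Homozygous-alternate calls anywhere
  exclude: a rare fully penetrant dominant allele is not expected
  homozygous in a small kindred.
* **Consequence classes** retained by default are the union of
  protein-altering and splice classes (missense, stop gain/loss,
  inframe/frameshift indel, splice region, splice site).  Method
  descriptions in this field sometimes list only the protein-altering
  classes while results narratives add splice variants; the union is the
  default and the set is fully configurable.
* **Population frequency** keeps variants with maximum population allele
  frequency strictly below 0.01, and keeps variants with *no* recorded
  frequency: novel variants absent from the databases are the discovery
  target.  The maximum across configured frequency sources is used — the
  conservative aggregation when several databases are consulted.
* **Local frequency** drops variants at or above 0.01 in a local-population
  table, mirroring the common practice of excluding regionally common
  variants that global databases under-represent.
* **Consensus** requires at least 2 of the 3 predictors to call the variant
  damaging.  Splice-region and intronic variants carry no SIFT / PolyPhen /
  REVEL scores; such unevaluable variants bypass the stage rather than
  failing it, since a missense-oriented predictor's silence is not evidence
  of benignity.

# Pathogenicity categories

Scores are stored raw and categorized only at evaluation time, using each
tool's published convention: SIFT deleterious below 0.05; PolyPhen-2
possibly damaging from 0.446 and probably damaging from 0.908; REVEL
damaging from 0.5.  "Possibly damaging" counts toward the consensus by
default (a strict switch counts only "probably damaging").  These
thresholds reproduce the categorical letters (N/T/D/PD) printed for the
five missense candidates in the motivating study's summary table.

One documented contradiction is preserved rather than resolved: the index
candidate itself (HSPG2 p.Asp775Glu; REVEL 0.478 N, SIFT 0.171 T, PolyPhen
0.997 PD) is damaging by only one of the three predictors, yet was carried
forward in the original analysis under a stated 2-of-3 rule.  `famfunnel`
computes what the rule says: the profile *fails* strict k = 2 consensus.
The simulator's `causal_profile = "index_candidate"` option plants exactly
this discordant profile so the behaviour is testable; passing it through
the funnel requires relaxing `min_damaging` or removing the consensus
stage, and either override is recorded in the run manifest, never silent.

# The two-point LOD

For each surviving variant the package computes the classical two-point
parametric LOD,

$$\mathrm{LOD} = \log_{10} \frac{L(\theta)}{L(1/2)},$$

where $L(\theta)$ is the full pedigree likelihood of the observed marker
dosages and affection statuses under a two-locus model: a latent disease
locus with allele frequency $p_d$ and penetrances $(f_0, f_1, f_2)$, and
the observed marker with allele frequency $p_m$, in linkage equilibrium at
founder haplotype priors, recombining at fraction $\theta$.

The likelihood is evaluated by **full enumeration of phased two-locus
genotype configurations** — every member is assigned an ordered pair of
(disease, marker) haplotypes, founders weighted by Hardy–Weinberg priors,
non-founders by Mendelian transmission probabilities with recombination —
with constraint propagation from observed marker dosages and pruning of
zero-probability partial products.  No peeling or approximation: for the
pedigrees in scope (at most 12 members, enforced) the exhaustive sum is
exact, and the enumeration count `n_configs` is itself checked against an
independent naive Cartesian-product oracle in the test suite.

Defaults: $\theta = 0$, $p_d = p_m = 10^{-4}$, penetrance $(0, 1, 1)$ — a
fully penetrant dominant with no phenocopies and rare alleles.  Under this
model a single doubly heterozygous carrier founder of **unknown phase**
with $n$ fully informative non-recombinant meioses gives
$\mathrm{LOD} = (n-1)\log_{10} 2$: marginalizing the two founder phases
costs exactly one meiosis of information.  The eight-member default kindred
has six informative meioses, hence $\log_{10} 32 = 1.505$, which the
reports print as **1.50** under the truncation convention (LODs and carrier
frequencies are truncated toward zero, never rounded; full precision is
retained in the JSON outputs).

Numerical choices: when the numerator likelihood is exactly zero at the
requested $\theta$ (an obligate recombinant at $\theta = 0$), the numerator
is re-evaluated on the grid $\{0.01, 0.05, 0.1, 0.2, 0.3, 0.4\}$ and the
maximum is reported, with `theta_eval` recording the grid point.  A
genotype/phenotype pattern with zero likelihood at every $\theta$
(impossible under the penetrance model) is an error, not a silent zero.
Untyped members are marginalized; an untyped *affected* member additionally
warns, since it weakens the signal.  At $\theta = 0.5$ numerator and
denominator are computed by the same code path, so the LOD is exactly zero
— an identity the tests assert on 100 random pedigrees.

# Screening and ranking

Carrier counts in controls and cases are converted to **carrier
(heterozygote) frequencies** — fractions of individuals, not chromosomes —
and formatted by truncation to three decimals, the dialect that reproduces
cells like 6/180 → 0.033 and 8/179 → 0.044.  Population-database allele
frequencies, by contrast, are chromosome-level and rounded (8/140282 →
0.000057 at six decimals).  A variant whose raw control carrier frequency
strictly exceeds 1% is flagged a polymorphism.

The composite ranking scores each survivor as a weighted sum of six
components with power-of-two default weights (32, 16, 8, 4, 2, 1):
segregation (LOD > 0), zero cohort carriers, prior disease association of
the gene, consensus pass, kidney expression, and the externally supplied
prior gene score scaled to [0, 1].  The power-of-two weights make the
binary components lexicographic: no combination of weaker evidence can
overturn a stronger component.  Two further policies: variants flagged as
polymorphisms are demoted below every non-polymorphic candidate regardless
of score (a common variant must never emerge as the top causal candidate
while a rare segregating alternative exists), and ties break on
(chrom, pos, ref, alt), so ranking is a deterministic function of the
input *set* — permutation invariance is property-tested.  Prior gene
scores are consumed as inputs, never recomputed: they derive from external
database snapshots that are not reproducible from first principles.
An optional per-variant `validated = FALSE` override removes variants that
failed downstream wet-lab validation (sequencing false positives) before
ranking.

# The simulator

`generate_dataset()` emulates the statistical structure the funnel assumes,
not sequencing data: gene dropping on a configurable pedigree (default: the
eight-member index kindred) plants one causal variant heterozygous in
exactly the affected members, plus `n_decoys_per_class` decoys per class,
each engineered to fail exactly one designated stage and no earlier one —
non-segregating genotypes (redrawn gene drops), common population
frequency, excluded consequence class, benign consensus profile, known
panel variant, and optionally cohort polymorphisms and pass-all decoys that
survive the funnel and are separated only at screening or ranking.  Decoy
scores and frequencies are drawn uniformly on the correct side of each
threshold with a 0.005 guard band, so no test outcome ever depends on
tie-breaking at a threshold.  Cohort sizes default to 180 controls and 179
cases, matching the motivating screening design.

Every generated dataset is verified before writing: each decoy is run
through each stage in isolation and must fail exactly its own; every
genotype column must pass an independent Mendelian-consistency check.  All
randomness flows from one integer seed and floating-point values are
quantized to six decimals before writing, so a fixed seed yields
byte-identical files.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: read-level noise and genotyping error,
linkage disequilibrium between variants, realistic genome-wide variant
counts (tens of thousands of raw variants; the simulator's scale is tens),
multi-gene annotation ambiguity, and population structure in the cohorts.
The funnel's behaviour on those axes is exercised only insofar as the
filters' predicate logic covers them (missing calls, multi-allelic sites,
missing annotations).

# Problem sizes and determinism

The shipped tests run the simulator at 1 planted + 50 decoy variants per
dataset across ten seeds, gene-drop calibration at 10,000 and 100,000
drops, the LOD closed-form comparison for 2–8 informative meioses at
allele frequency $10^{-6}$, and the exhaustive 256-pattern segregation
enumeration for the eight-member kindred — sizes chosen so the full suite
completes in well under a minute while every check remains exact or has
binomial error bounds of three standard errors.  All stochastic tests fix
their seeds.

# Known limitations

* Autosomal-dominant inheritance only; recessive, compound-heterozygous and
  X-linked models are out of scope (the segregation filter and LOD model
  would both need extension).
* One family per analysis; no multipoint linkage, liability classes, or
  simulation-based empirical LOD p-values.
* The LOD enumerator is exact but exponential; it refuses pedigrees beyond
  12 members rather than approximating.
* Annotation is consumed, not computed: the package trusts the upstream
  annotation producer's transcript choice and score calibration.
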