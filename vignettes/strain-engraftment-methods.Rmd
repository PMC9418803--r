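---
title: "Methods: strain-level tracking of donor engraftment after FMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level tracking of donor engraftment after FMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After fecal microbiota transplantation (FMT), a recipient's gut community is
a mixture of persisting recipient strains, engrafted donor strains,
conspecific coexisting strains from both sources, and newly acquired
strains. Species-level profiles cannot separate these: the same species in
donor and recipient before FMT may be represented by different subspecies
lineages, and only nucleotide-level variation over species-specific marker
genes can tell whose strain survived. `fmtstrains` implements this
strain-resolved accounting — from per-sample nucleotide variant profiles to
mixed-effects models of what drives donor engraftment — together with a
fully seeded synthetic cohort generator that provides ground truth for every
claim the package makes about itself.

## SNV profiles and shared-strain calls

A profile is a 4 × L table of A/C/G/T read counts over the concatenated
clade-specific marker alignment of one species in one sample (positions
0-based), with a boolean mask of usable positions. Filtering masks
marker-boundary positions (`end_trim`, default 20 per marker end), positions
with coverage below `min_position_coverage` (default 5 reads), zeroes
alleles below `min_allele_count` (default 2 reads) or below
`min_allele_frequency` (default 10%), and re-masks positions whose retained
coverage falls under the floor. The cascade is idempotent and monotone. The
coverage, count and trim defaults are this package's own conservative
choices for marker-based strain callers; the 10% polymorphic-site threshold
is the field's convention and also defines which alleles participate in
comparisons.

Two samples are compared over their jointly usable positions. The
**maximum variant profile similarity (MVS)** is the fraction of joint
positions at which the two samples' allele sets (alleles at ≥ 10%
within-position frequency) intersect. Because a polymorphic position
contributes through set intersection, a sample carrying a 50/50 strain
mixture still matches a sample carrying either member strain — this is what
distinguishes MVS from consensus-sequence approaches and lets the caller see
sub-dominant and coexisting strains. The consensus similarity (identical
major alleles, ties broken by the fixed order A < C < G < T) is reported
alongside and can never exceed the MVS. A **shared strain** is called when
the overlap is ≥ 5,000 alignment columns and the MVS is ≥ 0.999.

Numerical choices: the per-position MVS score is binary (intersect or not),
with no partial credit for multi-allele overlaps — the simplest reading of
allele co-occurrence, kept explicit so alternates can be swapped in. Both
the ≥ 10% frequency rule and the ≥ 0.999 MVS rule are evaluated by integer
cross-multiplication (e.g. `count * 1e6 >= total * 100000`), so boundary
cases such as 3/30 reads or 4,995/5,000 positions are decided exactly, with
no floating-point tolerance. "5 kb" is counted in usable alignment columns
and enforced at comparison time, not at profile construction, so
single-sample profiles of any length are representable.

## Origin attribution

For each species detected in a post-FMT sample, with the earliest pre-FMT
recipient sample and the (pooled) donor sample as references:

* shared with the pre-FMT recipient only → **recipient**;
* shared with the donor only → **donor**;
* shared with both, while recipient and donor did not share the strain
  before FMT → **coexist**;
* shared with both *and* the pre-FMT recipient and donor already shared the
  lineage → **ambiguous**;
* shared with neither although all needed comparisons were valid → **new**;
* present before FMT (recipient or donor) but absent after → **lost**;
* any needed comparison lacking 5 kb of joint coverage → **unresolved**.

The ambiguous class is this package's design: when donor and recipient
already shared a lineage pre-FMT, post-FMT presence cannot be attributed to
either side, so such species are excluded from donor/recipient fraction
denominators and reported separately rather than silently assigned.
Unresolved species keep their species-level sharing record and contribute
their abundance to a strain-not-resolved stratum.

Donor pooling sums variant counts position-wise across donor samples
(refiltered afterwards) and averages scalar community metrics; attribution
is invariant to the order of pooled samples. Engraftment per sample is
summarised as the donor-derived strain fraction of donor- plus
recipient-derived strains; the coexist fraction uses the same denominator.
Case-level summaries default to the latest available post-FMT sample and
exclude samples collected under post-FMT antibiotics. Cases whose post-FMT
samples share no strain with the donor (no donor, coexist or ambiguous
label anywhere) are flagged as sham.

## Community metrics

All logarithms are natural. Shannon diversity is −Σ p·ln p. The centered
log-ratio (clr) transform replaces zeros by an additive pseudocount — half
the smallest nonzero abundance by default, configurable, since the choice is
not dictated by theory — recloses, and centres; the Aitchison distance is
the Euclidean distance of clr vectors over the union species universe, and
clr PCA is an isometry of that geometry (tested). The dysbiosis score is
log((Σ up + ε)/(Σ down + ε)) over disease-positive and disease-negative
taxa; the shipped taxa list is a synthetic, replaceable default assembled
from genera commonly reported in pediatric Crohn's disease work, because the
original curated lists are cited but not printed anywhere reproducible.
Lifestyle burdens sum the abundance of species annotated +1 for oral
habitat, oxygen tolerance or spore formation, excluding (and reporting)
unannotated abundance. Bray-Curtis and UniFrac are deliberately out of
scope: they do not enter the headline engraftment models.

`compare_to_controls()` fits, per metric, a mixed model with sample type as
fixed effect (controls as reference) and study and case as random
intercepts, dropping a random effect when it is degenerate (fewer than two
levels, or one observation per level) and falling back to a fixed-effects
model when none remain — reported, never silent. Continuous metrics use a
Gaussian model with Satterthwaite p-values; proportion metrics default to a
Gaussian model on the logit scale because relative-abundance burdens are
continuous proportions, not counts (a binomial family is available when
integer trials exist). Post-FMT samples earlier than 5 days after FMT are
excluded. Variance inflation factors of the fixed-effect design are computed
as diag(solve(cor(X))) and flagged above 5.

## Engraftment models

Two binomial-logit mixed models, both fitted by Laplace-approximated maximum
likelihood (lme4, bobyqa optimizer; crossed Gaussian random intercepts):

* the **case-level model** of per-sample donor-derived strain fractions
  (successes = donor strains, failures = recipient strains), with random
  intercepts for case and study;
* the **strain-level model** of individual donor-species engraftment
  (0/1 per donor-detected species), with random intercepts for case, study
  and donor.

Covariate coding is shared between the generator and the fitters and stored
with every fit: binary covariates stay 0/1 (so a coefficient is the
log-odds difference between groups), continuous covariates are centred and
scaled over the fitted rows, species relative abundances enter as log10
with a 10⁻⁵ pseudocount before scaling (whether to log abundances is not
standardised in the field; it is configurable), and the abundance
interaction is the product of the two scaled abundance columns. Lifestyle
features are coded +1/−1, missing values imputed with the feature's mean,
and the coded values averaged within each genus; the genus enters as
aggregation only, not as a random effect (offering a genus intercept was
considered and rejected as over-stratifying the feature effects — the
feature coding already operates at genus resolution). Days since FMT enters
linearly. A boundary (singular) fit — a variance component estimated at
exactly zero — is a valid maximum-likelihood estimate and is reported via a
`singular` flag; only genuine optimizer warnings mark a fit as failed, and
failure is always an explicit object. With all random-effect variances at
zero the fits reduce to plain logistic regression (tested to 10⁻⁴ on the
linear predictor).

On top of the strain model: population-level marginal effects (random
effects at zero, averaging over observed covariate rows, delta-method Wald
intervals); genus-level adjusted engraftment probabilities, optionally
substituting the minimum or maximum donor abundance observed for the genus
(the donor-supplementation simulation; observed extremes are used rather
than interval bounds); expected engrafted-strain counts for arbitrary
recipient/donor pairings (sums of predicted probabilities, with
donor-dependent covariates recomputed for the hypothetical donor); and the
full recipient × donor swap matrix with log2 fold-changes against the
actual pairing and a between-pair vs between-donor variance decomposition.

## The synthetic cohort generator

The generator is the package's measuring instrument: it produces cohorts
whose every strain event has a known label and a known generative
probability. Its defaults encode the study conditions the analysis is meant
for: antibiotic pretreatment and lavage as Bernoulli(0.5); 1/2/many FMT
rounds with probabilities 0.6/0.2/0.2; post-FMT sampling uniform on days
5–120 with 1–3 samples per case; log-normal community abundances (σ = 1)
closed to 1; per-position coverage Poisson with rate depth × abundance ×
(number of species present), so a species of average abundance sees roughly
the nominal depth; uniform sequencing error (default 0.1% per base);
conspecific lineages diverged by 0.5–2% of marker positions; 5% of shared
species carrying an identical (ambiguous) lineage in donor and recipient;
brand-new species injected at 10% of the post-FMT species count; planted
coexistence with donor fractions uniform in 30/70–70/30. One dominant
strain per species per sample (plus an optional minor strain in coexistence
events) is the default multiplicity, as real within-donor strain
multiplicity is not well characterised. Generative coefficients default to
the log-odds effects the package's own models are meant to detect (strong
positive antibiotic and lavage effects, positive donor-diversity and
negative recipient-diversity effects, near-zero time effect).

Engraftment events are drawn from an explicit logistic model:
logit p = β′x + u_study + u_case (+ u_donor when species-level terms are
present). Species present in both donor and recipient resolve donor vs
recipient as Bernoulli(p) after fixed-rate coexistence/new/loss draws;
donor-only species engraft with probability p; recipient-only species
persist with probability 1 − p (the same forces that admit donor strains
clear recipient strains). Two structural choices keep the case-level
binomial model *correctly specified* under the generator, which the
parameter-recovery validation requires: the one-sided channels are balanced
per sample (only a matched number of donor-only and recipient-only species
compete; the surplus is lost), removing a richness-driven offset from the
donor fraction, and case-level covariates are scaled over post samples —
the same row set the fitter scales over — while species-level covariates
are scaled over donor-detected events. The realized outcomes then assemble
the post-FMT community (losses absent, coexistence carrying both lineages
at the planted fraction), so truth labels and rendered samples can never
disagree.

Rendering to nucleotide profiles is **lazy**: the cohort stores genotypes
and per-sample strain assignments, and `render_cohort_sample()` regenerates
any sample's pileups deterministically from a seed derived from the cohort
seed. Unrelated-pair sets for specificity testing work the same way
(`lazy = TRUE`), so hundreds of pairs are assessed in constant memory.
Everything is bit-reproducible given config + seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: read-level artefacts (mapping bias, chimeras,
position-dependent error), marker databases with paralogues or shared
markers between species, gene-content differences between strains,
within-species abundance dynamics over time, host-derived reads, and
fungal/viral fractions. Attribution accuracy measured here is an upper
bound for real metagenomes; the specificity analysis (unrelated pairs)
correspondingly bounds the method's false-positive behaviour only under the
uniform-error model.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle or known
truth, at sizes chosen to make the checks statistically meaningful:

* MVS is compared with a brute-force per-position reimplementation on 1,000
  random profile pairs (exact equality), and the 5 kb / 99.9% boundaries
  are pinned by construction.
* Specificity uses 200 unrelated pairs of 50-species samples at 30× depth,
  0.1% error and ≥ 1% lineage divergence; the mean shared-strain count per
  pair is required to stay below 0.1.
* Attribution accuracy uses 50 rendered cases over a 100-species catalog at
  50× depth (σ = 0.8, so that most species clear the coverage floor — the
  regime "adequate depth" refers to). Accuracy is computed over
  strain-resolved, non-ambiguous species; coexist recall over planted
  mixtures whose comparisons had sufficient overlap — a species whose
  marker alignment is shorter than the 5 kb rule can never be resolved by
  any caller using that rule, which is a detection-domain limit, not a
  recall failure.
* Case-model recovery uses 20 replicate cohorts of 200 cases: 100% sign
  recovery for effects ≥ 0.5 in absolute value and ≥ 85% empirical coverage
  of 95% Wald intervals, per coefficient.
* The strain model is validated on 120-case cohorts with 80–120 species per
  community: real donors carry hundreds of profiled species per case, and
  the pairing-prediction correlation is only a meaningful statistic when
  per-case expected counts dominate their binomial noise. Required:
  predicted vs realized engrafted counts correlate at r ≥ 0.8, an
  engineered super-donor (many high-abundance, gut-adapted species) ranks
  first for ≥ 80% of recipients, and identical donors give log2
  fold-changes of exactly 0.
* Null calibration of `compare_to_controls()` uses 500 simulated null
  cohorts; the type-I error at α = 0.05 must stay within [0.025, 0.075].

## Known limitations

The crossed random intercepts are approximated under a single Laplace
integration; with very few study levels the study variance is weakly
identified (boundary fits are then common and are reported as such).
Attribution treats the pooled donor as one sample, so multi-donor cases
with time-varying donor assignment are out of scope. The strain-level
generative channels (fixed coexistence/new/loss rates, niche balancing)
attenuate the strain model's coefficients relative to their generative
values — deliberately so, since real engraftment indicators are also
contaminated by processes outside the logistic model; the strain model's
contract is therefore predictive (correlation, ranking), while exact
coefficient recovery is the case-level model's contract.
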