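# fmtstrains

Strain-level tracking of donor microbiota engraftment after fecal
microbiota transplantation (FMT).

## The problem

FMT transfers a donor's gut community into a patient, but whether the
*donor's strains* actually establish themselves — as opposed to the
recipient's own strains persisting, or new strains arriving from elsewhere —
cannot be read off species-level profiles: donor and recipient frequently
carry the same species as different subspecies lineages. `fmtstrains` is for
microbiome researchers and FMT trialists who want to

* resolve strains from marker-gene alignment data (per-species nucleotide
  count tables, as produced by clade-specific marker profilers),
* call strains shared between samples,
* attribute every post-FMT species to donor, recipient, coexisting, new or
  lost origins,
* model what drives donor engraftment with binomial-logit mixed models, and
* simulate alternative recipient/donor pairings and donor-sample
  supplementation.

A fully seeded synthetic FMT cohort generator with known ground truth
(strain genotypes, planted persistence/transfer/coexistence events, and a
generative logistic engraftment model) backs every component with
quantitative validation.

## The method in brief

**Shared strains by maximum variant profile similarity (MVS).** For one
species in two samples, over jointly usable alignment positions *J* of the
concatenated marker alignment,

```
MVS = |{ i ∈ J : A₁(i) ∩ A₂(i) ≠ ∅ }| / |J|
```

where `Aₛ(i)` is sample *s*'s allele set at position *i* — all alleles at
≥ 10% within-position frequency, so polymorphic sites arising from strain
mixtures count through set intersection. A strain is *shared* when
`|J| ≥ 5,000` columns and `MVS ≥ 0.999` (both boundaries evaluated exactly,
by integer cross-multiplication). Origins follow from which references a
post-FMT strain is shared with: pre-FMT recipient only → recipient; donor
only → donor; both (while pre-FMT recipient and donor strains were
distinct) → coexist; neither → new.

**Engraftment models.** Per post-FMT sample with `d` donor-derived and `r`
recipient-derived strains,

```
(d | d + r) ~ Binomial(d + r, p),   logit(p) = β′x + u_case + u_study
```

with centred/scaled microbiota covariates (recipient and donor Shannon
index, recipient distance to healthy controls, recipient-donor Aitchison
distance) and clinical covariates (antibiotic pretreatment, lavage, number
of FMTs, days since FMT). A second model takes individual donor species as
Bernoulli engraftment trials with abundances, genus-aggregated lifestyle
features (Gram stain, spore formation, oxygen tolerance, oral habitat,
coded ±1 with mean imputation) and a donor random intercept, and powers
marginal effects, genus-level adjusted probabilities and donor-swap
predictions.

## Worked example

Simulate a small cohort with ground truth, attribute strain origins, and
fit the case-level engraftment model:

```r
library(fmtstrains)

cfg <- cohort_config(n_cases = 12, n_species = 60, depth = 50, render = TRUE,
                     sigma_lognormal = 0.8)
cohort <- generate_fmt_cohort(cfg, seed = 42)
cohort
#> <fmt_cohort> 12 cases, 3 donors, 4 studies, 60 species catalog, renderable

origins <- do.call(rbind, lapply(cohort$cases$case_id,
                                 function(ci) attribute_case(cohort, ci)))
table(origins$label)
#>  ambiguous    coexist      donor       lost        new  recipient unresolved
#>         40         58        412        328        156        228        130

summ <- engraftment_summary(origins, which = "latest")
summary(summ$donor_fraction)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.06897 0.57000 0.76905 0.68596 0.95000 1.00000

classify_competition_outcomes(origins)
#>            new recipient_only     donor_only        coexist   species_lost
#>            102            201            391             58             89
#>     unresolved
#>            156
```

Each post-FMT species got exactly one origin label; the per-sample donor
fraction is the share of donor-derived strains among donor- plus
recipient-derived strains (here a median of 0.77 across the 12 cases'
latest samples — this synthetic cohort plants strong antibiotic and lavage
effects). The six-way table counts outcomes for species present in both the
pre-FMT recipient and the donor, i.e. the species with potential for
conspecific strain competition.

```r
fit <- fit_case_glmm(
  build_case_table(cohort,
                   summaries = engraftment_summary(origins, which = "all")),
  covariates = c("abx_pretreat", "lavage", "recipient_shannon",
                 "donor_shannon"))
fit
#> <engraftment_fit> binomial-logit, converged
#>                term estimate    se      z  p_value  lower upper
#> 1         intercept   -0.989 0.725 -1.364 1.73e-01 -2.411 0.432
#> 2      abx_pretreat    1.746 0.653  2.675 7.47e-03  0.467 3.026
#> 3            lavage    2.625 1.146  2.290 2.20e-02  0.378 4.872
#> 4 recipient_shannon   -0.250 0.258 -0.968 3.33e-01 -0.756 0.256
#> 5     donor_shannon    1.154 0.274  4.204 2.62e-05  0.616 1.692
```

Estimates are log-odds effects on donor-strain engraftment: antibiotic
pretreatment and lavage increase it, higher recipient diversity decreases
it, higher donor diversity increases it — recovering, at 12-case precision,
the coefficients the generator planted (2.09, 1.83, −0.61, +0.83).

`run_pipeline(run_config(...), out_dir)` drives the same steps end to end
and writes every stage output (abundance, metadata, truth labels, origins,
summaries, metrics, model JSON) plus a checksummed manifest; reruns with the
same config are bit-identical.

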