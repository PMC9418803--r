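# Origin attribution, engraftment summaries, competition outcomes,
# donor-species fates, specificity controls and sham flagging.

# small hand-built scenario: 4 species, explicit lineages
make_attribution_scenario <- function(seed = 50) {
  withr::with_seed(seed, {
    cat4 <- generate_catalog(4, seed = NULL,
                             marker_length_range = c(6000, 8000))
    sp <- cat4$species_id
    gD <- lapply(1:4, function(i) random_genotype(sp[i], cat4$marker_length[i],
                                                  lineage_id = "D"))
    gR <- lapply(gD, mutate_strain, divergence = 0.01, lineage_id = "R")
    render1 <- function(id, species, genos, fracs = NULL) {
      comm <- setNames(rep(1 / length(species), length(species)), species)
      sa <- setNames(lapply(seq_along(species), function(k) {
        g <- genos[[k]]
        if (is.list(g) && !inherits(g, "strain_genotype")) {
          list(genotypes = g, fractions = fracs)
        } else list(genotypes = list(g), fractions = 1)
      }), species)
      filter_profile_set(render_sample(comm, sa, cat4, sample_id = id,
                                       depth = 60, error_rate = 0.001))
    }
    list(catalog = cat4, sp = sp, gD = gD, gR = gR, render1 = render1)
  })
}

test_that("donor pooling sums counts, unions species, averages communities", {
  sc <- make_attribution_scenario()
  d1 <- sc$render1("d1", sc$sp[1:2], sc$gD[1:2])
  # single donor: identity
  pooled1 <- pool_donor_samples(list(d1))
  expect_identical(pooled1$profiles[[sc$sp[1]]]$counts, d1[[sc$sp[1]]]$counts)
  # two identical donors: counts double, Shannon of community unchanged
  pooled2 <- pool_donor_samples(list(d1, d1),
                                communities = list(
                                  setNames(c(0.5, 0.5), sc$sp[1:2]),
                                  setNames(c(0.5, 0.5), sc$sp[1:2])))
  expect_identical(pooled2$profiles[[sc$sp[1]]]$counts,
                   d1[[sc$sp[1]]]$counts * 2L)
  expect_equal(shannon_index(pooled2$community), log(2))
  # disjoint donors: pooled species set is the union
  d2 <- sc$render1("d2", sc$sp[3:4], sc$gD[3:4])
  pooled3 <- pool_donor_samples(list(d1, d2))
  expect_setequal(names(pooled3$profiles), sc$sp)
  expect_error(pool_donor_samples(list()), "empty")
})

test_that("attribution reproduces hand-built origins", {
  sc <- make_attribution_scenario()
  sp <- sc$sp
  pre <- sc$render1("pre", sp[1:3], sc$gR[1:3])
  donor <- sc$render1("don", sp[1:3], sc$gD[1:3])
  # post: sp1 donor strain, sp2 recipient strain, sp3 absent (lost),
  #       sp4 brand new
  post <- sc$render1("post", c(sp[1], sp[2], sp[4]),
                     list(sc$gD[[1]], sc$gR[[2]], sc$gD[[4]]))
  comm <- function(species) setNames(rep(1 / length(species), length(species)),
                                     species)
  ot <- attribute_origins(pre, donor, post,
                          comm(sp[1:3]), comm(sp[1:3]),
                          comm(c(sp[1], sp[2], sp[4])))
  lab <- setNames(ot$label, ot$species_id)
  expect_equal(unname(lab[sp[1]]), "donor")
  expect_equal(unname(lab[sp[2]]), "recipient")
  expect_equal(unname(lab[sp[3]]), "lost")
  expect_equal(unname(lab[sp[4]]), "new")
  # partition: every species labelled exactly once
  expect_equal(anyDuplicated(ot$species_id), 0L)

  # post identical to pre with an unrelated donor: all resolvable recipient
  ot2 <- attribute_origins(pre, donor, pre, comm(sp[1:3]),
                           setNames(1, sp[4]), comm(sp[1:3]))
  got <- ot2$label[ot2$in_post]
  expect_true(all(got %in% c("recipient", "unresolved")))
  expect_gt(sum(got == "recipient"), 0)
})

test_that("coexisting strains are recognised as shared with both sides", {
  sc <- make_attribution_scenario()
  sp <- sc$sp[1]
  pre <- sc$render1("pre", sp, sc$gR[1])
  donor <- sc$render1("don", sp, sc$gD[1])
  post <- sc$render1("post", sp, list(list(sc$gD[[1]], sc$gR[[1]])),
                     fracs = c(0.5, 0.5))
  ot <- attribute_origins(pre, donor, post, setNames(1, sp), setNames(1, sp),
                          setNames(1, sp))
  expect_equal(ot$label, "coexist")
})

test_that("engraftment summaries compute the documented fractions", {
  origins <- data.frame(
    species_id = sprintf("s%d", 1:6),
    label = c("donor", "donor", "donor", "recipient", "coexist", "new"),
    rel_abundance = c(0.3, 0.2, 0.1, 0.2, 0.1, 0.1),
    in_pre = TRUE, in_donor = TRUE, in_post = TRUE,
    shared_post_pre = NA, shared_post_donor = NA, shared_pre_donor = NA,
    sample_id = "c1_post1", case_id = "c1", day = 30, post_fmt_abx = FALSE,
    stringsAsFactors = FALSE
  )
  s <- engraftment_summary(origins, which = "all")
  expect_equal(s$donor_fraction, 0.75)
  expect_equal(s$coexist_fraction, 0.25)
  expect_equal(s$donor_abundance, 0.6)

  # no donor- or recipient-derived strains: fraction missing, no crash
  none <- origins
  none$label <- "new"
  s0 <- engraftment_summary(none, which = "all")
  expect_true(is.na(s0$donor_fraction))

  # post-FMT antibiotic-exposed samples are excluded
  ab <- origins
  ab$post_fmt_abx <- TRUE
  expect_equal(nrow(engraftment_summary(ab, which = "all")), 0)

  # latest-sample selection keeps the maximum day per case
  two <- rbind(origins,
               transform(origins, sample_id = "c1_post2", day = 60))
  slate <- engraftment_summary(two, which = "latest")
  expect_equal(slate$sample_id, "c1_post2")
})

test_that("competition outcomes partition the qualifying species", {
  origins <- data.frame(
    species_id = sprintf("s%d", 1:8),
    label = c("donor", "recipient", "coexist", "new", "lost", "unresolved",
              "ambiguous", "donor"),
    rel_abundance = 0.1,
    in_pre = c(rep(TRUE, 7), FALSE),
    in_donor = TRUE, in_post = TRUE,
    shared_post_pre = NA, shared_post_donor = NA, shared_pre_donor = NA,
    sample_id = "x", case_id = "c", day = 1, post_fmt_abx = FALSE,
    stringsAsFactors = FALSE
  )
  cc <- classify_competition_outcomes(origins)
  expect_equal(sum(cc), 7)  # species 8 is not present in both pre and donor
  expect_equal(unname(cc["donor_only"]), 1L)
  expect_equal(unname(cc["unresolved"]), 2L)  # unresolved + ambiguous

  fate <- donor_species_fate(origins)
  expect_equal(sum(fate), 1)
  expect_equal(unname(fate["engrafted_new_species"]), 1 / 8)
  expect_equal(unname(fate["engrafted_replacement"]), 1 / 8)
})

test_that("false-positive assessment summarises unrelated pairs", {
  expect_error(false_positive_assessment(list()), "at least one")
  cat5 <- generate_catalog(5, seed = 61, marker_length_range = c(6000, 8000))
  up <- generate_unrelated_pairs(3, cat5, divergence_floor = 0.01,
                                 depth = 50, error_rate = 0.001, seed = 62)
  fp <- false_positive_assessment(up$pairs)
  expect_equal(fp$mean, 0)
  expect_equal(nrow(fp$per_pair), 3)
  # positive control: a sample paired with itself shares its strains
  self <- false_positive_assessment(list(list(a = up$pairs[[1]]$a,
                                              b = up$pairs[[1]]$a)))
  expect_gt(self$mean, 0)
})

test_that("sham cases are flagged by absence of donor-shared strains", {
  expect_equal(nrow(exclude_sham_cases(data.frame(case_id = character(),
                                                  label = character()))), 0)
  cfg <- cohort_config(n_cases = 6, n_species = 40, render = TRUE,
                       depth = 50, p_sham = 0.5, ambiguous_fraction = 0,
                       post_abx_rate = 0)
  co <- generate_fmt_cohort(cfg, seed = 63)
  expect_true(any(co$cases$sham) && any(!co$cases$sham))
  origins <- do.call(rbind, lapply(co$cases$case_id,
                                   function(ci) attribute_case(co, ci)))
  flags <- exclude_sham_cases(origins)
  truth <- co$cases$sham[match(flags$case_id, co$cases$case_id)]
  expect_equal(flags$sham, truth)
})

test_that("attribution is invariant to donor-pool sample order", {
  cfg <- cohort_config(n_cases = 4, n_species = 30, render = TRUE,
                       depth = 50, pooling_rate = 1)
  co <- generate_fmt_cohort(cfg, seed = 64)
  cid <- co$cases$case_id[1]
  smp <- co$samples[co$samples$case_id == cid, ]
  donor_ids <- smp$sample_id[smp$sample_type == "donor"]
  expect_gte(length(donor_ids), 2)
  sets <- lapply(donor_ids, function(d) render_cohort_sample(co, d))
  p1 <- pool_donor_samples(sets)$profiles
  p2 <- pool_donor_samples(rev(sets))$profiles
  for (sp in names(p1)) expect_identical(p1[[sp]]$counts, p2[[sp]]$counts)
})
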