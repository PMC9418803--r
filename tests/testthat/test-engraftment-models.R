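# Model tables, GLMM fits, marginal effects, genus probabilities and the
# pairing/donor-swap simulations.

fast_cohort <- function(seed, ...) {
  args <- utils::modifyList(list(n_cases = 60, n_species = 80, n_studies = 4,
                                 render = FALSE, beta = default_case_beta()),
                            list(...))
  generate_fmt_cohort(do.call(cohort_config, args), seed = seed)
}

test_that("the case table has one row per retained post sample", {
  co <- fast_cohort(70, n_cases = 10)
  tab <- build_case_table(co)
  post <- co$samples[co$samples$sample_type == "post" &
                       !co$samples$post_fmt_abx, ]
  expect_equal(nrow(tab) + attr(tab, "n_dropped"), nrow(post))
  expect_true(all(tab$successes + tab$failures >= 1))
  # scaling applied by the design builder: mean 0, sd 1
  des <- build_engraftment_design(as.data.frame(tab),
                                  c("intercept", "recipient_shannon",
                                    "donor_shannon"))
  expect_equal(mean(des$data$recipient_shannon), 0, tolerance = 1e-9)
  expect_equal(sd(des$data$donor_shannon), 1, tolerance = 1e-9)
})

test_that("flagged cases get pre-FMT metrics imputed from the ABx+ stratum", {
  co <- fast_cohort(71, n_cases = 40, frac_missing_pre = 0.3, p_abx = 0.6)
  tab <- build_case_table(co)
  imput <- tab$impute_pre_metrics
  expect_gt(sum(imput), 0)
  ref_mean <- mean(tab$recipient_shannon[tab$abx_pretreat == 1 & !imput])
  expect_true(all(abs(tab$recipient_shannon[imput] - ref_mean) < 1e-12))
})

test_that("case GLMM recovers generative coefficients and degrades sanely", {
  co <- fast_cohort(72, n_cases = 150, n_studies = 6)
  fit <- fit_case_glmm(build_case_table(co))
  expect_true(fit$converged)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  beta <- default_case_beta()
  expect_equal(sign(est[c("abx_pretreat", "lavage", "recipient_shannon",
                          "donor_shannon")]),
               sign(beta[c("abx_pretreat", "lavage", "recipient_shannon",
                           "donor_shannon")]))
  expect_lt(abs(est["abx_pretreat"] - beta["abx_pretreat"]), 0.5)

  # single case: random-effect groups drop, fit still returned
  one <- build_case_table(co)
  one <- one[one$case_id == one$case_id[1], , drop = FALSE]
  fit1 <- suppressWarnings(fit_case_glmm(one,
                                         covariates = "days_since_fmt"))
  expect_s3_class(fit1, "engraftment_fit")
  expect_false(is.null(fit1$model))
})

test_that("zero-variance covariates are dropped with a warning", {
  co <- fast_cohort(73, n_cases = 30, p_abx = 1)
  expect_warning(fit_case_glmm(build_case_table(co),
                               covariates = c("abx_pretreat", "lavage")),
                 "zero-variance")
})

test_that("with null random effects the GLMM reduces to plain logistic", {
  covs <- c("abx_pretreat", "lavage", "recipient_shannon", "donor_shannon")
  beta0 <- c(intercept = -1, abx_pretreat = 2, lavage = 1.8,
             recipient_shannon = -0.6, donor_shannon = 0.8)
  co <- fast_cohort(74, n_cases = 120, sd_case = 0, sd_study = 0,
                    beta = beta0)
  tab <- build_case_table(co)
  fit <- fit_case_glmm(tab, covariates = covs)
  des <- build_engraftment_design(as.data.frame(tab), c("intercept", covs))
  ref <- glm(cbind(successes, failures) ~ abx_pretreat + lavage +
               recipient_shannon + donor_shannon,
             data = des$data, family = binomial())
  b_mm <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  b_glm <- coef(ref)
  names(b_glm)[1] <- "intercept"
  X <- cbind(1, as.matrix(des$data[covs]))
  eta_mm <- X %*% b_mm[c("intercept", covs)]
  eta_glm <- X %*% b_glm[c("intercept", covs)]
  expect_lt(max(abs(eta_mm - eta_glm)), 1e-4)
})

test_that("strain GLMM recovers effect signs and supports predictions", {
  co <- fast_cohort(75, n_cases = 80, beta = default_strain_beta(),
                    richness_range = c(50, 70), n_species = 120)
  tab <- build_strain_table(co)
  expect_equal(anyDuplicated(tab[c("sample_id", "species_id")]), 0L)
  fit <- fit_strain_glmm(tab)
  expect_true(fit$converged)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_gt(est["donor_abundance"], 0)
  expect_lt(est["oral_habitat"], 0)
  expect_gt(est["abx_pretreat"], 0)

  # marginal effects: monotone in a positive binary effect
  me <- marginal_effect(fit, "abx_pretreat", c(0, 1))
  expect_gt(me$probability[2], me$probability[1])
  expect_true(all(me$lower <= me$probability & me$probability <= me$upper))
  expect_error(marginal_effect(fit, "not_a_term", 0), "not a fixed effect")

  # genus probabilities: abundance substitution is monotone
  g <- tab$genus[1]
  p_obs <- genus_probability(fit, g, "observed")
  expect_lte(genus_probability(fit, g, "min"), p_obs + 1e-12)
  expect_gte(genus_probability(fit, g, "max"), p_obs - 1e-12)
  expect_error(genus_probability(fit, "no_such_genus"), "absent")

  # pairing predictions: empty donor and linearity of expectation
  pt <- build_pair_table(co, co$cases$case_id[1], co$cases$donor_id[1])
  expect_equal(predict_pairing(fit, pt[0, ]), 0)
  expect_equal(predict_pairing(fit, rbind(pt, pt)),
               2 * predict_pairing(fit, pt))
})

test_that("donor swap matrix is consistent and spots identical donors", {
  co <- fast_cohort(76, n_cases = 25, beta = default_strain_beta(),
                    n_donors = 6)
  fit <- fit_strain_glmm(build_strain_table(co))
  sw <- donor_swap_matrix(fit, co)
  expect_equal(dim(sw$predicted), c(25, 6))
  # diagonal consistency with predict_pairing and zero self fold-change
  ci <- co$cases$case_id[1]
  di <- co$cases$donor_id[1]
  expect_equal(sw$predicted[ci, di],
               predict_pairing(fit, build_pair_table(co, ci, di)))
  expect_equal(unname(sw$log2_fold_change[cbind(co$cases$case_id,
                                                co$cases$donor_id)]),
               rep(0, 25))
  # an injected duplicate donor gives an identical column
  co$donor_communities[["dup"]] <- co$donor_communities[[di]]
  sw2 <- donor_swap_matrix(fit, co)
  expect_equal(unname(sw2$predicted[, di]), unname(sw2$predicted[, "dup"]))
})

test_that("variance inflation flags engineered collinearity", {
  set.seed(77)
  x <- rnorm(100)
  X <- cbind(a = x, b = x + rnorm(100, sd = 0.05), c = rnorm(100))
  v <- variance_inflation(X)
  expect_gt(v[["a"]], 5)
  expect_lt(v[["c"]], 2)
})
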