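# Binomial-logit mixed models of donor strain engraftment: a case-level
# model of donor-derived strain fractions and a strain-level model of
# individual engraftment events, with marginal-effect, abundance-
# substitution and donor-swap simulations on top.

#' Build the case-level model table
#'
#' One row per retained post-FMT sample with the response counts (successes =
#' donor-derived strains, failures = recipient-derived strains) and the raw
#' case covariates. Counts come from the cohort's truth labels, or from
#' attribution summaries when supplied. For cases flagged for pre-FMT metric
#' imputation, recipient microbiota metrics are replaced by the mean values
#' observed in antibiotically pretreated cases.
#'
#' @param cohort an `fmt_cohort`.
#' @param summaries optional [engraftment_summary()] output (with
#'   `which = "all"`) supplying observed counts per sample.
#' @param exclude_post_abx drop post samples with post-FMT antibiotic
#'   exposure.
#' @return data.frame (class `case_model_table`); rows with zero resolved
#'   donor+recipient strains are dropped and counted in
#'   `attr(, "n_dropped")`.
#' @export
build_case_table <- function(cohort, summaries = NULL,
                             exclude_post_abx = TRUE) {
  smp <- cohort$samples
  post <- smp[smp$sample_type == "post", , drop = FALSE]
  if (exclude_post_abx) post <- post[!post$post_fmt_abx, , drop = FALSE]
  if (is.null(summaries)) {
    ev <- cohort$events
    agg <- do.call(rbind, lapply(split(ev, ev$sample_id), function(d) {
      data.frame(sample_id = d$sample_id[1],
                 successes = sum(d$outcome == "donor"),
                 failures = sum(d$outcome == "recipient"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    agg <- data.frame(sample_id = summaries$sample_id,
                      successes = summaries$n_donor,
                      failures = summaries$n_recipient,
                      stringsAsFactors = FALSE)
  }
  tab <- merge(post[c("sample_id", "case_id", "day")], agg, by = "sample_id")
  tab <- merge(tab, cohort$cases[c("case_id", "study_id", "donor_id",
                                   "abx_pretreat", "lavage", "n_fmts",
                                   "pooled_donor", "impute_pre_metrics")],
               by = "case_id")
  tab <- merge(tab, cohort$case_metrics, by = "case_id")
  tab$days_since_fmt <- tab$day
  pre_metrics <- c("recipient_shannon", "recipient_dist_controls",
                   "recipient_donor_dist")
  if (any(tab$impute_pre_metrics)) {
    ref <- tab$abx_pretreat == 1 & !tab$impute_pre_metrics
    for (m in pre_metrics) {
      tab[[m]][tab$impute_pre_metrics] <- mean(tab[[m]][ref])
    }
  }
  drop <- tab$successes + tab$failures == 0
  out <- tab[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  class(out) <- c("case_model_table", "data.frame")
  out
}

#' Build the strain-level model table
#'
#' One row per donor-detected species per case (latest post-FMT sample by
#' default): the engraftment indicator, donor and recipient relative
#' abundances, genus-aggregated mean-imputed lifestyle features, and the
#' case-level clinical and microbiota covariates.
#'
#' @param cohort an `fmt_cohort`.
#' @param origins optional attributed origin rows; when supplied, engraftment
#'   is taken from the attribution labels (donor or coexisting strain
#'   detected) instead of the truth labels.
#' @param latest_only use only the latest post sample per case.
#' @param exclude_post_abx drop post samples with post-FMT antibiotic
#'   exposure.
#' @return data.frame of class `strain_model_table`.
#' @export
build_strain_table <- function(cohort, origins = NULL, latest_only = TRUE,
                               exclude_post_abx = TRUE) {
  ev <- cohort$events
  ev <- ev[ev$kind %in% c("both", "donor_only"), , drop = FALSE]
  smp <- cohort$samples
  if (exclude_post_abx) {
    ok <- smp$sample_id[!smp$post_fmt_abx]
    ev <- ev[ev$sample_id %in% ok, , drop = FALSE]
  }
  if (latest_only) {
    post <- smp[smp$sample_type == "post" & smp$sample_id %in% ev$sample_id, ]
    keep <- unlist(lapply(split(post, post$case_id), function(d) {
      d$sample_id[which.max(d$day)]
    }))
    ev <- ev[ev$sample_id %in% keep, , drop = FALSE]
  }
  if (!is.null(origins)) {
    key_ev <- paste(ev$sample_id, ev$species_id)
    key_or <- paste(origins$sample_id, origins$species_id)
    lab <- origins$label[match(key_ev, key_or)]
    ev$engrafted <- as.integer(lab %in% c("donor", "coexist"))
  }
  ev$genus <- cohort$catalog$genus[match(ev$species_id,
                                         cohort$catalog$species_id)]
  rownames(ev) <- NULL
  class(ev) <- c("strain_model_table", "data.frame")
  ev
}

make_fit <- function(model, coefs, scaling, covariates, data, raw, family,
                     converged, message = NULL, response = NULL) {
  structure(list(model = model, coefficients = coefs,
                 ranef_variance = if (!is.null(model) &&
                                      inherits(model, "merMod")) {
                   vc <- lme4::VarCorr(model)
                   stats::setNames(vapply(vc, function(v) v[1, 1], numeric(1)),
                                   names(vc))
                 } else NULL,
                 scaling = scaling, covariates = covariates,
                 data = data, raw_data = raw,
                 family = family, converged = converged,
                 message = message, response = response),
            class = "engraftment_fit")
}

#' @exportS3Method base::print
print.engraftment_fit <- function(x, ...) {
  cat(sprintf("<engraftment_fit> %s, %s\n", x$family,
              if (x$converged) "converged" else
                paste("NOT converged:", x$message)))
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 3)
  if (!is.null(x$ranef_variance)) {
    cat("Random-intercept variances:\n")
    print(round(x$ranef_variance, 4))
  }
  invisible(x)
}

coef_table <- function(model) {
  ct <- stats::coef(summary(model))
  data.frame(term = sub("\\(Intercept\\)", "intercept", rownames(ct)),
             estimate = ct[, "Estimate"], se = ct[, "Std. Error"],
             z = ct[, "z value"], p_value = ct[, "Pr(>|z|)"],
             lower = ct[, "Estimate"] - 1.96 * ct[, "Std. Error"],
             upper = ct[, "Estimate"] + 1.96 * ct[, "Std. Error"],
             row.names = NULL, stringsAsFactors = FALSE)
}

fit_engraftment_glmm <- function(table, covariates, random, response_formula,
                                 extra_cols, abundance_pseudocount) {
  des <- build_engraftment_design(as.data.frame(table),
                                  c("intercept", covariates),
                                  abundance_pseudocount = abundance_pseudocount)
  dat <- des$data
  sds <- vapply(covariates, function(cc) stats::sd(dat[[cc]]), numeric(1))
  if (any(sds == 0 | is.na(sds))) {
    dead <- covariates[sds == 0 | is.na(sds)]
    warning("dropping zero-variance covariates: ",
            paste(dead, collapse = ", "))
    covariates <- setdiff(covariates, dead)
  }
  random <- random[vapply(random, function(r) {
    length(unique(dat[[r]])) >= 2L
  }, logical(1))]
  re_terms <- if (length(random)) {
    paste(sprintf("(1 | %s)", random), collapse = " + ")
  } else NULL
  rhs <- paste(c(covariates, re_terms), collapse = " + ")
  if (rhs == "") rhs <- "1"
  fml <- stats::as.formula(paste(response_formula, "~", rhs))
  model <- tryCatch({
    if (length(random)) {
      lme4::glmer(fml, data = dat, family = stats::binomial(),
                  control = lme4::glmerControl(optimizer = "bobyqa"))
    } else {
      stats::glm(fml, data = dat, family = stats::binomial())
    }
  }, error = function(e) e)
  if (inherits(model, "error")) {
    return(make_fit(NULL, NULL, des$scaling, covariates, dat, table,
                    "binomial-logit", FALSE, conditionMessage(model)))
  }
  # boundary (singular) fits are valid maximum-likelihood estimates with a
  # variance component at 0; only genuine optimizer warnings fail the fit
  singular <- inherits(model, "merMod") && lme4::isSingular(model)
  converged <- if (inherits(model, "merMod")) {
    msgs <- model@optinfo$conv$lme4$messages %||% character(0)
    all(grepl("boundary \\(singular\\)", msgs))
  } else model$converged
  ct <- coef_table(model)
  fit <- make_fit(model, ct, des$scaling, covariates, dat, table,
                  "binomial-logit", converged,
                  if (!converged) "optimizer reported convergence warnings",
                  response = response_formula)
  fit$singular <- singular
  fit
}

#' Fit the case-level engraftment GLMM
#'
#' Binomial-logit mixed model of donor-derived strain fractions
#' (successes = donor strains, failures = recipient strains) with random
#' intercepts for case and study, estimated by Laplace-approximated maximum
#' likelihood. Random-effect groups with fewer than two levels are dropped
#' (logged in the fit); non-convergence yields an explicit failure object,
#' never a silent result.
#'
#' @param table a [build_case_table()] result.
#' @param covariates fixed-effect names (see [cohort_config()] for the
#'   supported set); continuous covariates are centred/scaled internally and
#'   the scaling stored for back-transformation.
#' @param random random-intercept grouping columns.
#' @param abundance_pseudocount pseudocount for log-abundance covariates.
#' @return an `engraftment_fit`.
#' @export
fit_case_glmm <- function(table,
                          covariates = setdiff(names(default_case_beta()),
                                               "intercept"),
                          random = c("case_id", "study_id"),
                          abundance_pseudocount = 1e-5) {
  fit_engraftment_glmm(table, covariates, random,
                       "cbind(successes, failures)",
                       c("successes", "failures"), abundance_pseudocount)
}

#' Fit the strain-level engraftment GLMM
#'
#' Binomial-logit mixed model of individual donor-strain engraftment
#' (`engrafted` in 0/1) with donor and recipient abundances, their
#' interaction, genus-aggregated lifestyle features and clinical covariates
#' as fixed effects, and crossed random intercepts for case, study and donor.
#'
#' @param table a [build_strain_table()] result.
#' @inheritParams fit_case_glmm
#' @return an `engraftment_fit`.
#' @export
fit_strain_glmm <- function(table,
                            covariates = setdiff(names(default_strain_beta()),
                                                 "intercept"),
                            random = c("case_id", "study_id", "donor_id"),
                            abundance_pseudocount = 1e-5) {
  fit_engraftment_glmm(table, covariates, random, "engrafted",
                       "engrafted", abundance_pseudocount)
}

fixed_effect_vector <- function(fit) {
  co <- fit$coefficients
  b <- stats::setNames(co$estimate, co$term)
  b
}

design_from_scaled <- function(fit, dat) {
  cbind(intercept = rep(1, nrow(dat)),
        as.matrix(dat[fit$covariates]))
}

# transform a raw covariate value onto the model's scaled scale
scale_value <- function(fit, variable, value,
                        abundance_pseudocount = 1e-5) {
  if (variable %in% c("donor_abundance", "recipient_abundance")) {
    value <- log10(value + abundance_pseudocount)
  }
  sc <- fit$scaling[[variable]]
  if (is.null(sc)) return(value)
  (value - sc$center) / sc$scale
}

#' Population-level marginal effect of one covariate
#'
#' Predicted engraftment probability at chosen covariate values, averaging
#' over the observed values of all other covariates with random effects at
#' zero (population level); Wald confidence intervals by the delta method.
#'
#' @param fit an `engraftment_fit`.
#' @param variable a fixed-effect covariate of the fit.
#' @param values values on the raw covariate scale (e.g. days, Shannon
#'   index, 0/1 for binary covariates); abundances on the relative-abundance
#'   scale.
#' @param scaled set `TRUE` when `values` are already on the model's
#'   centred/scaled scale.
#' @return data.frame `value`, `probability`, `lower`, `upper`.
#' @export
marginal_effect <- function(fit, variable, values, scaled = FALSE) {
  if (!fit$converged || is.null(fit$model)) {
    stop("cannot compute marginal effects from a failed fit", call. = FALSE)
  }
  if (!variable %in% fit$covariates) {
    stop("variable '", variable, "' is not a fixed effect of this model",
         call. = FALSE)
  }
  b <- fixed_effect_vector(fit)
  V <- as.matrix(stats::vcov(fit$model))
  out <- lapply(values, function(v) {
    dat <- fit$data
    dat[[variable]] <- if (scaled) v else scale_value(fit, variable, v)
    if ("abundance_interaction" %in% fit$covariates &&
        variable %in% c("donor_abundance", "recipient_abundance")) {
      dat$abundance_interaction <- dat$donor_abundance * dat$recipient_abundance
    }
    X <- design_from_scaled(fit, dat)
    eta <- as.vector(X %*% b[colnames(X)])
    p <- invlogit(eta)
    g <- colMeans(p * (1 - p) * X)
    se <- sqrt(as.vector(t(g) %*% V %*% g))
    data.frame(value = v, probability = mean(p),
               lower = mean(p) - 1.96 * se, upper = mean(p) + 1.96 * se)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Adjusted engraftment probability of a genus
#'
#' Median model-predicted engraftment probability (random effects at zero)
#' across the rows of one genus, optionally substituting the minimum or
#' maximum donor relative abundance observed for that genus anywhere in the
#' cohort — the abundance-substitution simulation for donor-sample
#' supplementation.
#'
#' @param fit a strain-level `engraftment_fit` (data must carry `genus`).
#' @param genus genus label.
#' @param abundance_mode `"observed"`, `"min"` or `"max"`.
#' @return median predicted probability.
#' @export
genus_probability <- function(fit, genus,
                              abundance_mode = c("observed", "min", "max")) {
  abundance_mode <- match.arg(abundance_mode)
  dat <- fit$data
  if (!"genus" %in% names(dat)) stop("fit table lacks a genus column", call. = FALSE)
  rows <- dat$genus == genus
  if (!any(rows)) stop("genus '", genus, "' absent from the model table",
                       call. = FALSE)
  dat <- dat[rows, , drop = FALSE]
  if (abundance_mode != "observed") {
    extreme <- if (abundance_mode == "min") min(dat$donor_abundance) else
      max(dat$donor_abundance)
    dat$donor_abundance <- extreme
    if ("abundance_interaction" %in% fit$covariates) {
      dat$abundance_interaction <- dat$donor_abundance * dat$recipient_abundance
    }
  }
  b <- fixed_effect_vector(fit)
  X <- design_from_scaled(fit, dat)
  stats::median(invlogit(as.vector(X %*% b[colnames(X)])))
}

#' Covariate rows for a hypothetical recipient/donor pairing
#'
#' Builds the strain-level covariate table for pairing a given recipient
#' (pre-FMT state and clinical covariates) with a given donor: one row per
#' donor species, with donor-dependent microbiota covariates (donor Shannon
#' index, recipient-donor Aitchison distance) recomputed for the hypothetical
#' donor.
#'
#' @param cohort an `fmt_cohort`.
#' @param case_id recipient case.
#' @param donor_id donor (any donor of the cohort).
#' @return data.frame of raw covariate rows.
#' @export
build_pair_table <- function(cohort, case_id, donor_id) {
  i <- match(case_id, cohort$cases$case_id)
  if (is.na(i)) stop("unknown case ", case_id, call. = FALSE)
  dcomm <- cohort$donor_communities[[donor_id]]
  if (is.null(dcomm)) stop("unknown donor ", donor_id, call. = FALSE)
  pre <- cohort$communities[[paste0(case_id, "_pre")]]
  sp <- names(dcomm)
  feats <- species_feature_codes(cohort$catalog)
  cm <- cohort$case_metrics[i, ]
  post <- cohort$samples[cohort$samples$case_id == case_id &
                           cohort$samples$sample_type == "post", ]
  df <- data.frame(
    case_id = case_id, donor_id = donor_id,
    study_id = cohort$cases$study_id[i],
    species_id = sp,
    genus = cohort$catalog$genus[match(sp, cohort$catalog$species_id)],
    donor_abundance = unname(dcomm[sp]),
    recipient_abundance = ifelse(sp %in% names(pre), pre[sp], 0),
    abx_pretreat = cohort$cases$abx_pretreat[i],
    lavage = cohort$cases$lavage[i],
    n_fmts = cohort$cases$n_fmts[i],
    pooled_donor = cohort$cases$pooled_donor[i],
    days_since_fmt = max(post$day),
    recipient_shannon = cm$recipient_shannon,
    donor_shannon = shannon_index(dcomm),
    recipient_dist_controls = cm$recipient_dist_controls,
    recipient_donor_dist = aitchison_distance(pre, dcomm),
    stringsAsFactors = FALSE
  )
  merge(df, feats, by = "species_id", sort = FALSE)
}

#' Expected engrafted donor-strain count for a pairing
#'
#' Sums the model-predicted engraftment probabilities over the donor's
#' species (random effects at zero): the expected number of donor-derived
#' strains the pairing would produce.
#'
#' @param fit a strain-level `engraftment_fit`.
#' @param pair_table raw covariate rows from [build_pair_table()].
#' @return expected count (non-negative scalar).
#' @export
predict_pairing <- function(fit, pair_table) {
  if (nrow(pair_table) == 0) return(0)
  des <- build_engraftment_design(pair_table,
                                  c("intercept", fit$covariates),
                                  scaling = fit$scaling)
  b <- fixed_effect_vector(fit)
  sum(invlogit(as.vector(des$X %*% b[colnames(des$X)])))
}

#' Donor-swap simulation across all recipient/donor pairs
#'
#' Predicts the expected engrafted strain count for every recipient x donor
#' combination, the log2 fold-change of each pairing relative to the
#' recipient's actual donor, the best and worst donor per recipient, and a
#' variance decomposition (between-pair vs. between-donor).
#'
#' @param fit a strain-level `engraftment_fit`.
#' @param cohort the `fmt_cohort` the fit came from.
#' @return list: `predicted` (recipient x donor matrix), `log2_fold_change`
#'   (vs. the actual pairing), `actual` (named vector), `best_donor`,
#'   `worst_donor`, `variance_between_pair`, `variance_between_donor`.
#' @export
donor_swap_matrix <- function(fit, cohort) {
  cases <- cohort$cases$case_id
  donors <- names(cohort$donor_communities)
  pred <- matrix(NA_real_, length(cases), length(donors),
                 dimnames = list(cases, donors))
  for (ci in cases) {
    for (di in donors) {
      pred[ci, di] <- predict_pairing(fit, build_pair_table(cohort, ci, di))
    }
  }
  actual <- stats::setNames(
    pred[cbind(cases, cohort$cases$donor_id)], cases)
  lfc <- log2(sweep(pred, 1L, actual, "/"))
  c_means <- colMeans(pred)
  c_vars <- apply(pred, 2L, stats::var)
  list(predicted = pred,
       log2_fold_change = lfc,
       actual = actual,
       best_donor = donors[apply(pred, 1L, which.max)],
       worst_donor = donors[apply(pred, 1L, which.min)],
       variance_between_pair = mean(c_vars),
       variance_between_donor = stats::var(c_means))
}
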