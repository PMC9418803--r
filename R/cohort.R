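# Synthetic FMT cohort generator with full ground truth. Communities,
# clinical covariates and strain-level engraftment events are generated from
# an explicit logistic model (known coefficients); nucleotide-level rendering
# of SNV profiles is optional and lazy, so model-calibration studies stay
# cheap while attribution studies get realistic pileups.

#' Configuration for a synthetic FMT cohort
#'
#' The defaults encode the study conditions the generator emulates: clinical
#' covariates mirror meta-cohort ranges (antibiotic pretreatment and lavage as
#' Bernoulli(0.5), 1/2/many FMT rounds, sampling 5-120 days after FMT),
#' communities are heavy-tailed log-normal compositions, and the generative
#' engraftment coefficients default to the log-odds effects reported for the
#' case-level engraftment model (positive antibiotic and lavage effects,
#' negative recipient-diversity effect, near-zero time effect).
#'
#' @param n_cases number of FMT cases.
#' @param n_donors number of donors.
#' @param n_studies number of studies cases are spread over.
#' @param n_species catalog size (ignored when `catalog` is supplied).
#' @param n_controls healthy-control communities used for
#'   distance-to-controls covariates.
#' @param catalog optional pre-built [generate_catalog()] result.
#' @param feature_missing_rate catalog annotation missingness.
#' @param beta named generative log-odds coefficient vector. Supported names:
#'   `intercept`, `abx_pretreat`, `lavage`, `n_fmts`, `pooled_donor`,
#'   `days_since_fmt`, `recipient_shannon`, `donor_shannon`,
#'   `recipient_dist_controls`, `recipient_donor_dist` (case level);
#'   `donor_abundance`, `recipient_abundance`, `abundance_interaction`,
#'   `oral_habitat`, `spore_forming`, `oxygen_tolerant`, `gram_positive`
#'   (species level). Binary covariates are coded 0/1; continuous covariates
#'   are centred and scaled cohort-wide before the coefficients apply, so a
#'   coefficient of 2 on `abx_pretreat` is exactly the generative log-odds
#'   difference between pretreated and untreated cases.
#' @param sd_case,sd_study,sd_donor random-intercept standard deviations of
#'   the generative model (the donor intercept only enters when `beta`
#'   contains species-level terms).
#' @param richness_range species per community (uniform draw).
#' @param sigma_lognormal log-normal sigma of community abundances.
#' @param donor_species_weight sampling weight favouring the case donor's
#'   species when drawing the recipient pre-FMT community (controls
#'   recipient/donor species overlap).
#' @param p_coexist,p_new,p_lost outcome-class rates for species present in
#'   both recipient and donor (coexistence, replacement by a new strain, and
#'   species loss); the remaining mass resolves donor-vs-recipient through
#'   the logistic model.
#' @param new_species_rate expected injected brand-new species per post
#'   sample, as a fraction of its species count.
#' @param ambiguous_fraction probability that the recipient's pre-FMT lineage
#'   of a shared species is identical to the donor lineage.
#' @param divergence_range per-position divergence range between conspecific
#'   lineages.
#' @param coexist_fraction_range within-species donor-strain fraction for
#'   planted coexistence events.
#' @param p_abx,p_lavage,p_nfmts,pooling_rate clinical covariate
#'   distributions.
#' @param day_range,n_post_range,post_abx_rate post-FMT sampling design.
#' @param frac_missing_pre fraction of cases whose pre-FMT microbiota metrics
#'   must be imputed (the pre-FMT profile itself remains available).
#' @param p_sham fraction of sham (no-transfer) cases.
#' @param depth,error_rate rendering parameters (see [render_sample()]).
#' @param abundance_pseudocount pseudocount for log10 abundance covariates.
#' @param render logical: prepare genotypes and per-sample render
#'   specifications (profiles themselves are rendered lazily by
#'   [render_cohort_sample()]).
#' @param add_super_donor engineer one extra donor carrying many
#'   high-abundance, gut-adapted (non-oral, non-sporulating, oxygen-
#'   intolerant) species.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 50,
                          n_donors = max(2L, ceiling(n_cases / 4)),
                          n_studies = 4,
                          n_species = 100,
                          n_controls = 20,
                          catalog = NULL,
                          feature_missing_rate = 0.2,
                          beta = default_case_beta(),
                          sd_case = 0.3, sd_study = 0.2, sd_donor = 0.2,
                          richness_range = c(30, 60),
                          sigma_lognormal = 1,
                          donor_species_weight = 3,
                          p_coexist = 0.05, p_new = 0.10, p_lost = 0.10,
                          new_species_rate = 0.10,
                          ambiguous_fraction = 0.05,
                          divergence_range = c(0.005, 0.02),
                          coexist_fraction_range = c(0.3, 0.7),
                          p_abx = 0.5, p_lavage = 0.5,
                          p_nfmts = c(0.6, 0.2, 0.2),
                          pooling_rate = 0.15,
                          day_range = c(5, 120),
                          n_post_range = c(1, 3),
                          post_abx_rate = 0.05,
                          frac_missing_pre = 0,
                          p_sham = 0,
                          depth = 30, error_rate = 0.001,
                          abundance_pseudocount = 1e-5,
                          render = FALSE,
                          add_super_donor = FALSE) {
  cfg <- as.list(environment())
  bad <- setdiff(names(cfg$beta),
                 c("intercept", case_covariate_names(), species_covariate_names()))
  if (length(bad)) {
    stop("unsupported covariates in `beta`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Default generative coefficients of the case-level engraftment model
#'
#' Log-odds effects of clinical and microbiota covariates on donor-strain
#' engraftment: strong positive antibiotic-pretreatment and lavage effects,
#' a positive donor-diversity and negative recipient-diversity effect,
#' positive recipient dysbiosis (distance to controls), and a negligible
#' time effect.
#' @export
default_case_beta <- function() {
  c(intercept = -1,
    abx_pretreat = 2.09, lavage = 1.83, n_fmts = 0.71,
    recipient_shannon = -0.61, donor_shannon = 0.83,
    recipient_dist_controls = 0.46, recipient_donor_dist = 0.13,
    days_since_fmt = -0.01)
}

#' Default generative coefficients of the strain-level engraftment model
#'
#' Extends the case-level effects with species relative abundances (positive
#' in the donor, weakly negative in the recipient, negative interaction) and
#' lifestyle features (oral, spore-forming, oxygen-tolerant and gram-positive
#' species engraft less).
#' @export
default_strain_beta <- function() {
  c(intercept = -2,
    donor_abundance = 1.51, recipient_abundance = -0.06,
    abundance_interaction = -0.07,
    oral_habitat = -0.81, spore_forming = -0.12, oxygen_tolerant = -0.11,
    gram_positive = -0.2,
    abx_pretreat = 2.09, lavage = 1.83, n_fmts = 0.71)
}

case_covariate_names <- function() {
  c("abx_pretreat", "lavage", "n_fmts", "pooled_donor", "days_since_fmt",
    "recipient_shannon", "donor_shannon", "recipient_dist_controls",
    "recipient_donor_dist")
}

species_covariate_names <- function() {
  c("donor_abundance", "recipient_abundance", "abundance_interaction",
    "oral_habitat", "spore_forming", "oxygen_tolerant", "gram_positive")
}

binary_covariates <- function() c("abx_pretreat", "lavage", "pooled_donor")

#' Genus-aggregated, mean-imputed lifestyle feature codes
#'
#' Features are coded +1/-1 at the species level, missing values are replaced
#' by each feature's mean frequency across species, and the coded values are
#' then aggregated (averaged) at the genus level.
#'
#' @param catalog a `species_catalog`.
#' @return data.frame `species_id` plus the four aggregated feature columns.
#' @export
species_feature_codes <- function(catalog) {
  out <- data.frame(species_id = catalog$species_id, stringsAsFactors = FALSE)
  for (f in catalog_features()) {
    v <- as.numeric(catalog[[f]])
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    out[[f]] <- stats::ave(v, catalog$genus, FUN = mean)
  }
  out
}

scale_continuous <- function(df, cols, scaling = NULL) {
  cols <- intersect(cols, names(df))
  if (is.null(scaling)) {
    scaling <- lapply(df[cols], function(v) {
      s <- stats::sd(v)
      list(center = mean(v), scale = if (is.na(s) || s == 0) 1 else s)
    })
  }
  for (cc in intersect(cols, names(scaling))) {
    df[[cc]] <- (df[[cc]] - scaling[[cc]]$center) / scaling[[cc]]$scale
  }
  list(data = df, scaling = scaling)
}

continuous_covariates <- function() {
  c("n_fmts", "days_since_fmt", "recipient_shannon", "donor_shannon",
    "recipient_dist_controls", "recipient_donor_dist",
    "donor_abundance", "recipient_abundance")
}

#' Build the (scaled) engraftment design matrix
#'
#' Shared by the generator and the model fitters so that generative
#' coefficients and fitted coefficients refer to identical covariate codings:
#' abundances enter as log10 with a pseudocount, continuous covariates are
#' centred/scaled (scaling reusable for prediction), binary covariates stay
#' 0/1, and the abundance interaction is the product of the two scaled
#' abundance columns.
#'
#' @param df data.frame with raw covariate columns.
#' @param terms covariate names (order of the returned columns); `intercept`
#'   allowed.
#' @param scaling previously stored scaling list (for prediction on new
#'   data), or `NULL` to estimate from `df`.
#' @param abundance_pseudocount pseudocount for the log10 transform.
#' @return list with `X` (matrix incl. intercept), `data` (scaled df) and
#'   `scaling`.
#' @export
build_engraftment_design <- function(df, terms, scaling = NULL,
                                     abundance_pseudocount = 1e-5) {
  for (ab in c("donor_abundance", "recipient_abundance")) {
    if (ab %in% terms && ab %in% names(df) &&
        is.null(attr(df, "abundance_logged"))) {
      df[[ab]] <- log10(df[[ab]] + abundance_pseudocount)
    }
  }
  attr(df, "abundance_logged") <- TRUE
  sc <- scale_continuous(df, continuous_covariates(), scaling)
  df <- sc$data
  if ("abundance_interaction" %in% terms) {
    df$abundance_interaction <- df$donor_abundance * df$recipient_abundance
  }
  cols <- setdiff(terms, "intercept")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing covariates: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- cbind(intercept = rep(1, nrow(df)),
             as.matrix(df[cols]))
  list(X = X[, intersect(c("intercept", cols), colnames(X)), drop = FALSE],
       data = df, scaling = sc$scaling)
}

lognormal_community <- function(species, sigma) {
  close_composition(stats::setNames(rlnorm(length(species), 0, sigma), species))
}

#' Generate a synthetic FMT cohort with ground truth
#'
#' Draws donors, healthy controls and FMT cases with clinical covariates and
#' log-normal communities; for every post-FMT sample, resolves the fate of
#' each species through an explicit logistic engraftment model
#' (`invlogit(beta' x + u_study + u_case [+ u_donor])`) plus fixed rates of
#' coexistence, strain turnover and species loss; assembles the post-FMT
#' communities accordingly and records everything as truth labels. With
#' `render = TRUE`, conspecific lineages (donor, recipient, new) are
#' materialised as genotypes diverged within `divergence_range` so that
#' samples can be rendered to SNV profiles via [render_cohort_sample()].
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the cohort is bit-identical given config + seed.
#' @return an `fmt_cohort` list: `catalog`, `cases`, `samples`, `communities`,
#'   `case_metrics`, `events` (truth labels incl. generative probabilities),
#'   `truth` (beta, scaling, random intercepts), `controls`, and - when
#'   rendered - `genotypes` and `render_spec`.
#' @export
generate_fmt_cohort <- function(config = cohort_config(), seed = 1L) {
  cfg <- config
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed_or_stream(seed, {
    catalog <- cfg$catalog %||%
      generate_catalog(cfg$n_species, cfg$feature_missing_rate)
    feats <- species_feature_codes(catalog)
    n_cases <- cfg$n_cases
    if (n_cases == 0) {
      return(empty_cohort(catalog, cfg, seed))
    }
    has_species_beta <- any(names(cfg$beta) %in% species_covariate_names())

    study_ids <- sprintf("study%02d", seq_len(cfg$n_studies))
    u_study <- stats::setNames(rnorm(cfg$n_studies, 0, cfg$sd_study), study_ids)

    n_donors <- cfg$n_donors + as.integer(cfg$add_super_donor)
    donor_ids <- sprintf("donor%03d", seq_len(n_donors))
    u_donor <- stats::setNames(rnorm(n_donors, 0, cfg$sd_donor), donor_ids)
    donor_comm <- lapply(seq_len(n_donors), function(d) {
      r <- min(nrow(catalog), sample(cfg$richness_range[1]:cfg$richness_range[2], 1))
      lognormal_community(sample(catalog$species_id, r), cfg$sigma_lognormal)
    })
    names(donor_comm) <- donor_ids
    if (cfg$add_super_donor) {
      # gut-adapted species: most negative summed lifestyle codes
      score <- rowSums(as.matrix(feats[catalog_features()]))
      r <- cfg$richness_range[2]
      sp <- catalog$species_id[order(score)][seq_len(r)]
      donor_comm[[n_donors]] <- lognormal_community(sp, 0.3)
    }

    controls <- lapply(seq_len(cfg$n_controls), function(i) {
      r <- min(nrow(catalog), sample(cfg$richness_range[1]:cfg$richness_range[2], 1))
      lognormal_community(sample(catalog$species_id, r), cfg$sigma_lognormal)
    })
    names(controls) <- sprintf("control%03d", seq_len(cfg$n_controls))

    case_ids <- sprintf("case%03d", seq_len(n_cases))
    u_case <- stats::setNames(rnorm(n_cases, 0, cfg$sd_case), case_ids)
    cases <- data.frame(
      case_id = case_ids,
      study_id = sample(study_ids, n_cases, replace = TRUE),
      donor_id = sample(donor_ids[seq_len(cfg$n_donors)], n_cases,
                        replace = TRUE),
      abx_pretreat = rbinom(n_cases, 1, cfg$p_abx),
      lavage = rbinom(n_cases, 1, cfg$p_lavage),
      n_fmts = sample(1:3, n_cases, replace = TRUE, prob = cfg$p_nfmts),
      route = sample(c("colon", "nasogastric", "enema", "capsule"),
                     n_cases, replace = TRUE),
      pooled_donor = rbinom(n_cases, 1, cfg$pooling_rate),
      impute_pre_metrics = runif(n_cases) < cfg$frac_missing_pre,
      sham = runif(n_cases) < cfg$p_sham,
      stringsAsFactors = FALSE
    )

    # recipient pre-FMT communities, overlapping the assigned donor's species
    pre_comm <- vector("list", n_cases)
    for (i in seq_len(n_cases)) {
      r <- min(nrow(catalog), sample(cfg$richness_range[1]:cfg$richness_range[2], 1))
      w <- rep(1, nrow(catalog))
      w[catalog$species_id %in% names(donor_comm[[cases$donor_id[i]]])] <-
        cfg$donor_species_weight
      sp <- sample(catalog$species_id, r, prob = w)
      pre_comm[[i]] <- lognormal_community(sp, cfg$sigma_lognormal)
    }
    names(pre_comm) <- case_ids

    # sample sheet: one pre, one or two donor samples, 1..k post samples
    samples <- list()
    for (i in seq_len(n_cases)) {
      cid <- case_ids[i]
      n_post <- sample(cfg$n_post_range[1]:cfg$n_post_range[2], 1)
      days <- sort(round(runif(n_post, cfg$day_range[1], cfg$day_range[2])))
      n_dsmp <- 1L + cases$pooled_donor[i]
      samples[[i]] <- data.frame(
        sample_id = c(paste0(cid, "_pre"),
                      paste0(cid, "_donor", seq_len(n_dsmp)),
                      paste0(cid, "_post", seq_len(n_post))),
        case_id = cid,
        sample_type = c("pre", rep("donor", n_dsmp), rep("post", n_post)),
        day = c(NA, rep(NA, n_dsmp), days),
        post_fmt_abx = c(FALSE, rep(FALSE, n_dsmp),
                         runif(n_post) < cfg$post_abx_rate),
        stringsAsFactors = FALSE
      )
    }
    samples <- do.call(rbind, samples)
    rownames(samples) <- NULL

    # per-case microbiota metrics (pooled donors: mean of scalar metrics)
    case_metrics <- data.frame(case_id = case_ids, stringsAsFactors = FALSE)
    case_metrics$recipient_shannon <-
      vapply(pre_comm, shannon_index, numeric(1))
    case_metrics$donor_shannon <-
      vapply(cases$donor_id, function(d) shannon_index(donor_comm[[d]]),
             numeric(1))
    case_metrics$recipient_dist_controls <-
      vapply(pre_comm, distance_to_reference, numeric(1), reference = controls)
    case_metrics$recipient_donor_dist <- vapply(seq_len(n_cases), function(i) {
      aitchison_distance(pre_comm[[i]], donor_comm[[cases$donor_id[i]]])
    }, numeric(1))

    # candidate engraftment events for every post sample
    post_samples <- samples[samples$sample_type == "post", , drop = FALSE]
    ev <- list()
    for (j in seq_len(nrow(post_samples))) {
      cid <- post_samples$case_id[j]
      i <- match(cid, case_ids)
      D <- names(donor_comm[[cases$donor_id[i]]])
      R <- names(pre_comm[[cid]])
      sp_all <- union(D, R)
      kind <- ifelse(sp_all %in% D & sp_all %in% R, "both",
                     ifelse(sp_all %in% D, "donor_only", "recipient_only"))
      ev[[j]] <- data.frame(
        sample_id = post_samples$sample_id[j],
        case_id = cid, study_id = cases$study_id[i],
        donor_id = cases$donor_id[i],
        day = post_samples$day[j],
        species_id = sp_all, kind = kind,
        donor_abundance = ifelse(sp_all %in% D,
                                 donor_comm[[cases$donor_id[i]]][sp_all], 0),
        recipient_abundance = ifelse(sp_all %in% R, pre_comm[[cid]][sp_all], 0),
        stringsAsFactors = FALSE
      )
    }
    events <- do.call(rbind, ev)
    rownames(events) <- NULL
    events <- merge(events, feats, by = "species_id", sort = FALSE)
    events <- merge(events, cases[c("case_id", "abx_pretreat", "lavage",
                                    "n_fmts", "pooled_donor")],
                    by = "case_id", sort = FALSE)
    events$days_since_fmt <- events$day
    events <- merge(events, case_metrics, by = "case_id", sort = FALSE)
    events <- events[order(events$sample_id, events$species_id), ]
    rownames(events) <- NULL

    # Linear predictor. Case-level covariates are scaled over post samples
    # (one row each) and species-level covariates over donor-detected events,
    # matching the row sets the respective model fitters scale over.
    beta <- cfg$beta
    eta <- rep(if ("intercept" %in% names(beta)) unname(beta[["intercept"]])
               else 0, nrow(events))
    truth_scaling <- list()
    case_terms <- intersect(names(beta), case_covariate_names())
    if (length(case_terms)) {
      smp_cov <- events[!duplicated(events$sample_id), , drop = FALSE]
      dc <- build_engraftment_design(smp_cov, case_terms,
                                     abundance_pseudocount =
                                       cfg$abundance_pseudocount)
      truth_scaling$case <- dc$scaling
      eta_s <- as.vector(dc$X[, case_terms, drop = FALSE] %*% beta[case_terms])
      eta <- eta + eta_s[match(events$sample_id, smp_cov$sample_id)]
    }
    sp_terms <- intersect(names(beta), species_covariate_names())
    if (length(sp_terms)) {
      sub <- events$kind %in% c("both", "donor_only")
      ds0 <- build_engraftment_design(events[sub, , drop = FALSE], sp_terms,
                                      abundance_pseudocount =
                                        cfg$abundance_pseudocount)
      truth_scaling$species <- ds0$scaling
      dsA <- build_engraftment_design(events, sp_terms, scaling = ds0$scaling,
                                      abundance_pseudocount =
                                        cfg$abundance_pseudocount)
      eta <- eta + as.vector(dsA$X[, sp_terms, drop = FALSE] %*% beta[sp_terms])
    }
    eta <- eta + u_study[events$study_id] + u_case[events$case_id]
    if (has_species_beta) eta <- eta + u_donor[events$donor_id]
    events$p_true <- invlogit(eta)

    # resolve outcomes
    n <- nrow(events)
    cls <- runif(n)
    outcome <- character(n)
    sham_event <- cases$sham[match(events$case_id, case_ids)]
    both <- events$kind == "both"
    donly <- events$kind == "donor_only"
    ronly <- events$kind == "recipient_only"
    q1 <- cfg$p_coexist; q2 <- q1 + cfg$p_new; q3 <- q2 + cfg$p_lost
    draw <- runif(n)
    outcome[both & cls < q1] <- "coexist"
    outcome[both & cls >= q1 & cls < q2] <- "new"
    outcome[both & cls >= q2 & cls < q3] <- "lost"
    rest <- both & cls >= q3
    outcome[rest] <- ifelse(draw[rest] < events$p_true[rest],
                            "donor", "recipient")
    outcome[donly] <- ifelse(draw[donly] < events$p_true[donly],
                             "donor", "lost")
    outcome[ronly] <- ifelse(draw[ronly] < 1 - events$p_true[ronly],
                             "recipient", "lost")
    # Balance the one-sided channels per sample: only a matched number of
    # donor-only and recipient-only species compete for open niches, the
    # surplus is lost. This keeps the donor-derived strain fraction
    # logit-linear in the covariates (no richness-driven offset), the
    # property the case-level binomial model assumes.
    for (sid in unique(events$sample_id)) {
      sel <- events$sample_id == sid
      ido <- which(sel & donly)
      iro <- which(sel & ronly)
      m <- min(length(ido), length(iro))
      if (length(ido) > m) {
        outcome[ido[sample.int(length(ido), length(ido) - m)]] <- "lost"
      }
      if (length(iro) > m) {
        outcome[iro[sample.int(length(iro), length(iro) - m)]] <- "lost"
      }
    }
    # sham cases: no donor material was transferred
    outcome[sham_event & outcome %in% c("donor", "coexist") & both] <- "recipient"
    outcome[sham_event & donly & outcome == "donor"] <- "lost"
    events$outcome <- outcome
    events$engrafted <- as.integer(outcome %in% c("donor", "coexist"))
    events$coexist_fraction <- ifelse(
      outcome == "coexist",
      runif(n, cfg$coexist_fraction_range[1], cfg$coexist_fraction_range[2]),
      NA_real_)
    events$lineage_ambiguous <- FALSE

    # ambiguous lineages: recipient pre-FMT lineage identical to donor's
    amb <- stats::setNames(vector("list", n_cases), case_ids)
    for (i in seq_len(n_cases)) {
      shared <- intersect(names(pre_comm[[case_ids[i]]]),
                          names(donor_comm[[cases$donor_id[i]]]))
      amb[[i]] <- shared[runif(length(shared)) < cfg$ambiguous_fraction]
    }
    for (i in seq_len(n_cases)) {
      sel <- events$case_id == case_ids[i] & events$species_id %in% amb[[i]]
      events$lineage_ambiguous[sel] <- TRUE
    }

    # injected brand-new species per post sample
    inj <- list()
    for (j in seq_len(nrow(post_samples))) {
      sid <- post_samples$sample_id[j]
      cid <- post_samples$case_id[j]
      i <- match(cid, case_ids)
      used <- union(names(donor_comm[[cases$donor_id[i]]]),
                    names(pre_comm[[cid]]))
      pool <- setdiff(catalog$species_id, used)
      n_new <- min(length(pool),
                   rpois(1, cfg$new_species_rate *
                           sum(events$sample_id == sid &
                                 events$outcome %in%
                                 c("donor", "recipient", "coexist", "new"))))
      if (n_new > 0) {
        sp <- sample(pool, n_new)
        inj[[length(inj) + 1L]] <- data.frame(
          sample_id = sid, case_id = cid,
          study_id = cases$study_id[i], donor_id = cases$donor_id[i],
          day = post_samples$day[j], species_id = sp, kind = "injected",
          donor_abundance = 0, recipient_abundance = 0,
          p_true = NA_real_, outcome = "new", engrafted = 0L,
          coexist_fraction = NA_real_, lineage_ambiguous = FALSE,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(inj)) {
      inj <- do.call(rbind, inj)
      inj <- merge(inj, feats, by = "species_id", sort = FALSE)
      inj <- merge(inj, cases[c("case_id", "abx_pretreat", "lavage",
                                "n_fmts", "pooled_donor")],
                   by = "case_id", sort = FALSE)
      inj$days_since_fmt <- inj$day
      inj <- merge(inj, case_metrics, by = "case_id", sort = FALSE)
      events <- rbind(events[names(events)], inj[names(events)])
    }
    events <- events[order(events$sample_id, events$species_id), ]
    rownames(events) <- NULL

    # post-FMT communities from outcomes
    communities <- c(controls, stats::setNames(pre_comm, paste0(case_ids, "_pre")))
    for (i in seq_len(n_cases)) {
      n_dsmp <- 1L + cases$pooled_donor[i]
      for (d in seq_len(n_dsmp)) {
        communities[[paste0(case_ids[i], "_donor", d)]] <-
          donor_comm[[cases$donor_id[i]]]
      }
    }
    for (j in seq_len(nrow(post_samples))) {
      sid <- post_samples$sample_id[j]
      e <- events[events$sample_id == sid, ]
      present <- e$outcome %in% c("donor", "recipient", "coexist", "new")
      e <- e[present, , drop = FALSE]
      if (nrow(e) == 0) next
      ab <- numeric(nrow(e))
      donor_src <- e$outcome == "donor" & e$donor_abundance > 0
      ab[donor_src] <- e$donor_abundance[donor_src]
      rec_src <- e$outcome == "recipient"
      ab[rec_src] <- e$recipient_abundance[rec_src]
      co <- e$outcome == "coexist"
      ab[co] <- e$donor_abundance[co] + e$recipient_abundance[co]
      nw <- e$outcome == "new"
      ab[nw] <- pmax(e$donor_abundance[nw], e$recipient_abundance[nw],
                     rlnorm(sum(nw), log(0.01), 0.5) / 10)
      communities[[sid]] <- close_composition(
        stats::setNames(ab, e$species_id))
    }

    cohort <- structure(list(
      catalog = catalog, cases = cases, samples = samples,
      communities = communities, case_metrics = case_metrics,
      donor_communities = donor_comm, controls = controls,
      events = events,
      truth = list(beta = cfg$beta, scaling = truth_scaling,
                   u_study = u_study, u_case = u_case, u_donor = u_donor,
                   has_species_beta = has_species_beta),
      config = cfg, seed = seed
    ), class = "fmt_cohort")

    if (cfg$render) cohort <- prepare_rendering(cohort)
    cohort
  })
}

empty_cohort <- function(catalog, cfg, seed) {
  cases <- data.frame(case_id = character(), study_id = character(),
                      donor_id = character(), abx_pretreat = integer(),
                      lavage = integer(), n_fmts = integer(),
                      route = character(), pooled_donor = integer(),
                      impute_pre_metrics = logical(), sham = logical(),
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = character(), case_id = character(),
                        sample_type = character(), day = double(),
                        post_fmt_abx = logical(), stringsAsFactors = FALSE)
  events <- data.frame(sample_id = character(), case_id = character(),
                       study_id = character(), donor_id = character(),
                       day = double(), species_id = character(),
                       kind = character(), donor_abundance = double(),
                       recipient_abundance = double(), p_true = double(),
                       outcome = character(), engrafted = integer(),
                       coexist_fraction = double(),
                       lineage_ambiguous = logical(), stringsAsFactors = FALSE)
  structure(list(
    catalog = catalog,
    cases = cases, samples = samples, communities = list(),
    case_metrics = data.frame(case_id = character(),
                              recipient_shannon = double(),
                              donor_shannon = double(),
                              recipient_dist_controls = double(),
                              recipient_donor_dist = double(),
                              stringsAsFactors = FALSE),
    donor_communities = list(), controls = list(),
    events = events,
    truth = list(beta = cfg$beta), config = cfg, seed = seed
  ), class = "fmt_cohort")
}

#' @exportS3Method base::print
print.fmt_cohort <- function(x, ...) {
  cat(sprintf(
    "<fmt_cohort> %d cases, %d donors, %d studies, %d species catalog%s\n",
    nrow(x$cases), length(x$donor_communities),
    length(unique(x$cases$study_id)), nrow(x$catalog),
    if (!is.null(x$genotypes)) ", renderable" else ""))
  invisible(x)
}

# Materialise lineage genotypes and per-sample strain assignments so that
# render_cohort_sample() can produce SNV profiles on demand (lazy: genotypes
# are stored once; profiles are rendered per sample from a derived seed).
prepare_rendering <- function(cohort) {
  cfg <- cohort$config
  catalog <- cohort$catalog
  drange <- cfg$divergence_range
  used_species <- unique(unlist(lapply(cohort$communities, names)))
  ancestors <- stats::setNames(vector("list", length(used_species)), used_species)
  for (sp in used_species) {
    L <- catalog$marker_length[match(sp, catalog$species_id)]
    ancestors[[sp]] <- random_genotype(sp, L, lineage_id = paste0("anc:", sp))
  }
  genotypes <- list()
  new_lineage <- function(base, id) {
    g <- mutate_strain(base, runif(1, drange[1], drange[2]), lineage_id = id)
    genotypes[[g$species_id]][[id]] <<- g
    id
  }
  # donor lineages
  for (d in names(cohort$donor_communities)) {
    for (sp in names(cohort$donor_communities[[d]])) {
      new_lineage(ancestors[[sp]], sprintf("D:%s:%s", d, sp))
    }
  }
  # recipient lineages (identical to donor lineage for ambiguous species)
  amb_events <- unique(cohort$events[cohort$events$lineage_ambiguous,
                                     c("case_id", "species_id")])
  for (i in seq_len(nrow(cohort$cases))) {
    cid <- cohort$cases$case_id[i]
    did <- cohort$cases$donor_id[i]
    for (sp in names(cohort$communities[[paste0(cid, "_pre")]])) {
      rid <- sprintf("R:%s:%s", cid, sp)
      donor_lid <- sprintf("D:%s:%s", did, sp)
      ambiguous <- nrow(amb_events) > 0 &&
        any(amb_events$case_id == cid & amb_events$species_id == sp)
      if (ambiguous && !is.null(genotypes[[sp]][[donor_lid]])) {
        genotypes[[sp]][[rid]] <- genotypes[[sp]][[donor_lid]]
      } else if (!is.null(genotypes[[sp]][[donor_lid]])) {
        new_lineage(genotypes[[sp]][[donor_lid]], rid)
      } else {
        new_lineage(ancestors[[sp]], rid)
      }
    }
  }
  # new lineages for "new" outcomes
  nw <- cohort$events[cohort$events$outcome == "new", , drop = FALSE]
  for (k in seq_len(nrow(nw))) {
    sp <- nw$species_id[k]
    nid <- sprintf("N:%s:%s", nw$sample_id[k], sp)
    base_d <- genotypes[[sp]][[sprintf("D:%s:%s", nw$donor_id[k], sp)]]
    base_r <- genotypes[[sp]][[sprintf("R:%s:%s", nw$case_id[k], sp)]]
    new_lineage(base_d %||% base_r %||% ancestors[[sp]], nid)
  }
  cohort$genotypes <- genotypes
  cohort
}

sample_strain_assignment <- function(cohort, sample_id) {
  smp <- cohort$samples[cohort$samples$sample_id == sample_id, ]
  if (nrow(smp) != 1L) stop("unknown sample ", sample_id, call. = FALSE)
  cid <- smp$case_id
  did <- cohort$cases$donor_id[match(cid, cohort$cases$case_id)]
  comm <- cohort$communities[[sample_id]]
  sa <- stats::setNames(vector("list", length(comm)), names(comm))
  one <- function(lid, sp) list(genotypes = list(cohort$genotypes[[sp]][[lid]]),
                                fractions = 1)
  if (smp$sample_type == "pre") {
    for (sp in names(comm)) sa[[sp]] <- one(sprintf("R:%s:%s", cid, sp), sp)
  } else if (smp$sample_type == "donor") {
    for (sp in names(comm)) sa[[sp]] <- one(sprintf("D:%s:%s", did, sp), sp)
  } else {
    e <- cohort$events[cohort$events$sample_id == sample_id, ]
    for (sp in names(comm)) {
      row <- e[e$species_id == sp, ][1, ]
      sa[[sp]] <- switch(row$outcome,
        donor = one(sprintf("D:%s:%s", did, sp), sp),
        recipient = one(sprintf("R:%s:%s", cid, sp), sp),
        new = one(sprintf("N:%s:%s", sample_id, sp), sp),
        coexist = list(
          genotypes = list(cohort$genotypes[[sp]][[sprintf("D:%s:%s", did, sp)]],
                           cohort$genotypes[[sp]][[sprintf("R:%s:%s", cid, sp)]]),
          fractions = c(row$coexist_fraction, 1 - row$coexist_fraction)),
        stop("unexpected outcome for present species")
      )
    }
  }
  sa
}

#' Render the observed SNV profiles of one cohort sample
#'
#' Deterministic given the cohort (the per-sample seed is derived from the
#' cohort seed), so repeated calls reproduce identical profiles without the
#' cohort having to hold every pileup in memory.
#'
#' @param cohort a rendered-mode `fmt_cohort` (`render = TRUE`).
#' @param sample_id sample to render.
#' @param depth,error_rate override the cohort configuration if given.
#' @return named list of `snv_profile` objects.
#' @export
render_cohort_sample <- function(cohort, sample_id, depth = NULL,
                                 error_rate = NULL) {
  if (is.null(cohort$genotypes)) {
    stop("cohort was generated with render = FALSE", call. = FALSE)
  }
  idx <- match(sample_id, cohort$samples$sample_id)
  if (is.na(idx)) stop("unknown sample ", sample_id, call. = FALSE)
  sa <- sample_strain_assignment(cohort, sample_id)
  seed <- (abs(cohort$seed) * 1009 + idx * 7919) %% 2147483647
  render_sample(cohort$communities[[sample_id]], sa, cohort$catalog,
                sample_id = sample_id,
                depth = depth %||% cohort$config$depth,
                error_rate = error_rate %||% cohort$config$error_rate,
                seed = as.integer(seed))
}
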