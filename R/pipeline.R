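# End-to-end orchestration: simulate -> render -> compare -> attribute ->
# metrics -> fit, written to a run directory with a manifest, fully
# reproducible under a single seed.

#' Assemble a pipeline run configuration
#'
#' All thresholds of the analysis (5 kb minimum overlap, 99.9% MVS, 10%
#' allele frequency, 5-day post-FMT filter) are surfaced here with their
#' defaults; the resolved configuration is written next to the outputs of
#' every run.
#'
#' @param seed integer seed governing every stochastic stage.
#' @param cohort a [cohort_config()] (rendering is forced on).
#' @param filter a [filter_params()].
#' @param call a [call_params()].
#' @param min_post_day post-FMT samples earlier than this many days are
#'   excluded from metric comparisons.
#' @param fit_case_model fit the case-level GLMM on the attributed counts.
#' @param case_covariates fixed effects for the case-level model; the default
#'   subset keeps demo-sized runs identifiable (use the full
#'   [default_case_beta()] set for cohorts of >= 50 cases).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_config(n_cases = 10, n_species = 40,
                                              render = TRUE),
                       filter = filter_params(),
                       call = call_params(),
                       min_post_day = 5,
                       fit_case_model = TRUE,
                       case_covariates = c("abx_pretreat", "lavage",
                                           "recipient_shannon",
                                           "donor_shannon")) {
  cohort$render <- TRUE
  structure(list(seed = seed, cohort = cohort, filter = filter, call = call,
                 min_post_day = min_post_day, fit_case_model = fit_case_model,
                 case_covariates = case_covariates),
            class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full strain-tracking pipeline
#'
#' Simulates a cohort, attributes origins for every case, summarises
#' engraftment, computes community metrics, optionally fits the case-level
#' GLMM, and writes every stage output (TSV/JSON) plus a manifest with
#' checksums to `out_dir`. Reruns with the same configuration reproduce the
#' manifest bit-identically; a failing stage halts with the stage named,
#' retaining partial outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add <- function(p) files[[length(files) + 1L]] <<- p

  add(stage("config", {
    p <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), p)
    p
  }))

  cohort <- stage("simulate", generate_fmt_cohort(config$cohort, config$seed))
  add(stage("simulate", {
    ab <- abundance_table(cohort)
    write_tsv(ab, file.path(out_dir, "relative_abundance.tsv"))
  }))
  add(stage("simulate", {
    meta <- merge(cohort$samples,
                  cohort$cases[c("case_id", "study_id", "donor_id",
                                 "abx_pretreat", "lavage", "n_fmts", "route")],
                  by = "case_id")
    write_tsv(meta, file.path(out_dir, "metadata.tsv"))
  }))
  add(stage("simulate", {
    write_tsv(cohort$events, file.path(out_dir, "truth_labels.tsv"))
  }))

  origins <- stage("attribute", {
    res <- do.call(rbind, lapply(cohort$cases$case_id, function(cid) {
      attribute_case(cohort, cid, config$call, config$filter)
    }))
    res %||% data.frame(species_id = character(), label = character(),
                        rel_abundance = double(), in_pre = logical(),
                        in_donor = logical(), in_post = logical(),
                        shared_post_pre = character(),
                        shared_post_donor = character(),
                        shared_pre_donor = character(),
                        sample_id = character(), case_id = character(),
                        day = double(), post_fmt_abx = logical())
  })
  add(write_tsv(origins, file.path(out_dir, "origins.tsv")))

  summaries <- stage("summarise",
                     engraftment_summary(origins, which = "all"))
  add(write_tsv(summaries, file.path(out_dir, "engraftment_summary.tsv")))

  metrics <- stage("metrics", sample_metric_table(cohort))
  add(write_tsv(metrics, file.path(out_dir, "sample_metrics.tsv")))

  if (config$fit_case_model && nrow(cohort$cases) > 0 &&
      nrow(summaries) > 0) {
    fit <- stage("fit", {
      tab <- build_case_table(cohort, summaries = summaries)
      fit_case_glmm(tab, covariates = config$case_covariates)
    })
    add(stage("fit", {
      p <- file.path(out_dir, "case_model.json")
      jsonlite::write_json(list(converged = fit$converged,
                                coefficients = fit$coefficients,
                                ranef_variance = as.list(fit$ranef_variance),
                                scaling = fit$scaling),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      p
    }))
  }

  manifest <- data.frame(
    file = basename(unlist(files)),
    md5 = unname(tools::md5sum(unlist(files))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

abundance_table <- function(cohort) {
  sp <- cohort$catalog$species_id
  if (length(cohort$communities) == 0L) {
    return(data.frame(species_id = sp, stringsAsFactors = FALSE))
  }
  m <- vapply(cohort$communities, function(cm) {
    v <- stats::setNames(numeric(length(sp)), sp)
    v[names(cm)] <- cm
    v
  }, numeric(length(sp)))
  cbind(data.frame(species_id = sp, stringsAsFactors = FALSE),
        as.data.frame(m, check.names = FALSE))
}

sample_metric_table <- function(cohort) {
  cfgd <- read_dysbiosis_config()
  genus_of <- stats::setNames(cohort$catalog$genus, cohort$catalog$species_id)
  rows <- lapply(names(cohort$communities), function(sid) {
    cm <- cohort$communities[[sid]]
    lb <- lifestyle_burden(cm, cohort$catalog)
    i <- match(sid, cohort$samples$sample_id)
    data.frame(
      sample_id = sid,
      sample_type = if (is.na(i)) "control" else cohort$samples$sample_type[i],
      case_id = if (is.na(i)) sid else cohort$samples$case_id[i],
      study_id = if (is.na(i)) "controls" else
        cohort$cases$study_id[match(cohort$samples$case_id[i],
                                    cohort$cases$case_id)],
      day = if (is.na(i)) NA_real_ else cohort$samples$day[i],
      shannon = shannon_index(cm),
      dysbiosis = dysbiosis_score(cm, cfgd$up_taxa, cfgd$down_taxa,
                                  genus_of = genus_of),
      oral_abundance = lb[["oral_abundance"]],
      oxygen_tolerant_abundance = lb[["oxygen_tolerant_abundance"]],
      spore_abundance = lb[["spore_abundance"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), sample_type = character(),
                      case_id = character(), study_id = character(),
                      day = double(), shannon = double(),
                      dysbiosis = double(), oral_abundance = double(),
                      oxygen_tolerant_abundance = double(),
                      spore_abundance = double(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summaries of a completed pipeline run
#'
#' Reads a run directory back into machine-readable tables: per-case origin
#' fractions (strain and abundance), competition-outcome counts, the
#' case-model coefficient table, and the truth-vs-estimate comparison when
#' truth labels exist.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list of data.frames.
#' @export
report_run <- function(run_dir) {
  need <- file.path(run_dir, c("origins.tsv", "engraftment_summary.tsv"))
  if (!all(file.exists(need))) {
    stop("incomplete run directory: ", run_dir, call. = FALSE)
  }
  origins <- read.delim(file.path(run_dir, "origins.tsv"),
                        stringsAsFactors = FALSE)
  summaries <- read.delim(file.path(run_dir, "engraftment_summary.tsv"),
                          stringsAsFactors = FALSE)
  out <- list(
    origins = origins,
    engraftment_summary = summaries,
    competition_outcomes = as.data.frame(
      t(classify_competition_outcomes(origins))),
    sham_flags = exclude_sham_cases(origins)
  )
  cm <- file.path(run_dir, "case_model.json")
  if (file.exists(cm)) {
    out$case_model <- jsonlite::fromJSON(cm)$coefficients
  }
  tl <- file.path(run_dir, "truth_labels.tsv")
  if (file.exists(tl)) {
    truth <- read.delim(tl, stringsAsFactors = FALSE)
    key_t <- paste(truth$sample_id, truth$species_id)
    key_o <- paste(origins$sample_id, origins$species_id)
    m <- match(key_o, key_t)
    out$truth_comparison <- data.frame(
      sample_id = origins$sample_id, species_id = origins$species_id,
      label = origins$label, truth = truth$outcome[m],
      stringsAsFactors = FALSE
    )
  }
  out
}
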