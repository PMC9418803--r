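# Origin attribution: classify every species observed in a post-FMT sample
# as donor-derived, recipient-derived, coexisting, new, lost, ambiguous or
# unresolved, by combining shared-strain calls between the post-FMT sample
# and the pre-FMT recipient and (pooled) donor samples.

#' Pool donor samples
#'
#' Variant profiles are pooled by summing nucleotide counts per position
#' (refilter the result before comparison); per-species masks are unioned.
#' Scalar microbiota metrics of pooled donors should be averaged — a helper
#' for that is returned alongside; pooled communities are the renormalised
#' mean of the input communities.
#'
#' @param profile_sets list of named profile lists (one per donor sample).
#' @param communities optional list of named abundance vectors to average.
#' @return list with `profiles` (pooled, unfiltered), `community` (mean,
#'   closed; `NULL` if not supplied).
#' @export
pool_donor_samples <- function(profile_sets, communities = NULL) {
  if (length(profile_sets) == 0L) stop("empty donor set", call. = FALSE)
  all_sp <- unique(unlist(lapply(profile_sets, names)))
  pooled <- stats::setNames(vector("list", length(all_sp)), all_sp)
  for (sp in all_sp) {
    ps <- Filter(Negate(is.null), lapply(profile_sets, `[[`, sp))
    counts <- ps[[1]]$counts
    mask <- ps[[1]]$mask
    if (length(ps) > 1L) {
      for (p in ps[-1]) {
        stopifnot(p$L == ncol(counts))
        counts <- counts + p$counts
        mask <- mask | p$mask
      }
    }
    pooled[[sp]] <- new_snv_profile(counts, mask, "pooled_donor", sp,
                                    marker_lengths = ps[[1]]$marker_lengths)
  }
  community <- NULL
  if (!is.null(communities)) {
    sp_u <- unique(unlist(lapply(communities, names)))
    m <- sapply(communities, function(cm) {
      v <- stats::setNames(numeric(length(sp_u)), sp_u)
      v[names(cm)] <- cm
      v
    })
    community <- close_composition(rowMeans(as.matrix(m)))
  }
  list(profiles = pooled, community = community)
}

shared_status <- function(pa, pb, sp, params) {
  if (is.null(pa[[sp]]) || is.null(pb[[sp]])) return("insufficient_overlap")
  compare_profiles(pa[[sp]], pb[[sp]], params)$shared_call
}

#' Attribute the origin of every species in a post-FMT sample
#'
#' Per species: a strain shared exclusively with the pre-FMT recipient is
#' recipient-derived; shared exclusively with the donor, donor-derived;
#' shared with both while recipient and donor strains are distinct,
#' coexisting; shared with both while the pre-FMT recipient and donor already
#' shared the strain, ambiguous; shared with neither (all needed comparisons
#' valid), new; present before FMT (in recipient or donor) but absent after,
#' lost; and unresolved when any needed comparison lacks overlap (the table
#' records whether the species itself is shared so species-level fallback
#' summaries remain possible).
#'
#' @param pre_profiles,donor_profiles,post_profiles named, filtered profile
#'   lists (donor pooled via [pool_donor_samples()] and refiltered).
#' @param pre_community,donor_community,post_community named closed
#'   relative-abundance vectors.
#' @param params a [call_params()] object.
#' @return `data.frame` of class `origin_table`: `species_id`, `label`,
#'   `rel_abundance` (in the post sample; 0 for lost), `in_pre`, `in_donor`,
#'   `in_post`, and the three pairwise shared-strain statuses.
#' @export
attribute_origins <- function(pre_profiles, donor_profiles, post_profiles,
                              pre_community, donor_community, post_community,
                              params = call_params()) {
  if (is.null(post_profiles)) stop("missing post-FMT profile set", call. = FALSE)
  sp_post <- names(post_community)[post_community > 0]
  sp_pre <- names(pre_community)[pre_community > 0]
  sp_donor <- names(donor_community)[donor_community > 0]
  universe <- sort(union(union(sp_post, sp_pre), sp_donor))
  n <- length(universe)
  label <- character(n)
  s_pre <- s_donor <- s_pre_donor <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    sp <- universe[k]
    in_post <- sp %in% sp_post
    in_pre <- sp %in% sp_pre
    in_donor <- sp %in% sp_donor
    if (!in_post) {
      label[k] <- "lost"
      next
    }
    if (!in_pre && !in_donor) {
      label[k] <- "new"
      next
    }
    if (in_pre) s_pre[k] <- shared_status(post_profiles, pre_profiles, sp, params)
    if (in_donor) s_donor[k] <- shared_status(post_profiles, donor_profiles, sp,
                                              params)
    if ((in_pre && s_pre[k] == "insufficient_overlap") ||
        (in_donor && s_donor[k] == "insufficient_overlap")) {
      label[k] <- "unresolved"
      next
    }
    shared_pre <- in_pre && s_pre[k] == "shared"
    shared_donor <- in_donor && s_donor[k] == "shared"
    if (shared_pre && shared_donor) {
      s_pre_donor[k] <- shared_status(pre_profiles, donor_profiles, sp, params)
      label[k] <- switch(s_pre_donor[k],
                         shared = "ambiguous",
                         not_shared = "coexist",
                         insufficient_overlap = "unresolved")
    } else if (shared_pre) {
      label[k] <- "recipient"
    } else if (shared_donor) {
      label[k] <- "donor"
    } else {
      label[k] <- "new"
    }
  }
  out <- data.frame(
    species_id = universe, label = label,
    rel_abundance = ifelse(universe %in% sp_post,
                           post_community[universe], 0),
    in_pre = universe %in% sp_pre,
    in_donor = universe %in% sp_donor,
    in_post = universe %in% sp_post,
    shared_post_pre = s_pre, shared_post_donor = s_donor,
    shared_pre_donor = s_pre_donor,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("origin_table", "data.frame")
  out
}

#' Attribute all post-FMT samples of one synthetic cohort case
#'
#' Renders (lazily) and filters the pre-FMT, donor and post-FMT profiles of a
#' case, pools donor samples, and runs [attribute_origins()] per post sample.
#'
#' @param cohort a rendered-mode `fmt_cohort`.
#' @param case_id case to attribute.
#' @param params,fparams calling and filtering parameters.
#' @return `data.frame` of origin rows with `sample_id`, `day` and
#'   `post_fmt_abx` columns added.
#' @export
attribute_case <- function(cohort, case_id, params = call_params(),
                           fparams = filter_params()) {
  smp <- cohort$samples[cohort$samples$case_id == case_id, ]
  if (nrow(smp) == 0) stop("unknown case ", case_id, call. = FALSE)
  pre_id <- smp$sample_id[smp$sample_type == "pre"][1]
  donor_ids <- smp$sample_id[smp$sample_type == "donor"]
  post <- smp[smp$sample_type == "post", , drop = FALSE]
  pre_prof <- filter_profile_set(render_cohort_sample(cohort, pre_id), fparams)
  donor_sets <- lapply(donor_ids, function(d) render_cohort_sample(cohort, d))
  pooled <- pool_donor_samples(donor_sets,
                               cohort$communities[donor_ids])
  donor_prof <- filter_profile_set(pooled$profiles, fparams)
  out <- list()
  for (j in seq_len(nrow(post))) {
    sid <- post$sample_id[j]
    post_prof <- filter_profile_set(render_cohort_sample(cohort, sid), fparams)
    ot <- attribute_origins(pre_prof, donor_prof, post_prof,
                            cohort$communities[[pre_id]],
                            pooled$community,
                            cohort$communities[[sid]], params)
    ot$sample_id <- sid
    ot$case_id <- case_id
    ot$day <- post$day[j]
    ot$post_fmt_abx <- post$post_fmt_abx[j]
    out[[j]] <- ot
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample engraftment summary of an attributed case
#'
#' The donor fraction is the number of donor-derived strains over the total
#' of donor- and recipient-derived strains per post-FMT sample; the coexist
#' fraction is reported relative to the same denominator. Abundance-weighted
#' analogs sum relative abundances. Ambiguous strains are excluded from the
#' denominators and reported separately.
#'
#' @param origins output of [attribute_case()] (or an `origin_table` with
#'   `sample_id`, `day`, `post_fmt_abx` columns).
#' @param which `"latest"` (maximum day per case) or `"all"`.
#' @param exclude_post_abx drop samples collected under post-FMT antibiotic
#'   exposure.
#' @param max_day optional upper day limit (e.g. 120 for response analyses
#'   restricted to four months).
#' @return data.frame, one row per retained post sample: strain counts per
#'   label, `donor_fraction`, `coexist_fraction` (both `NA` when no donor- or
#'   recipient-derived strains were detected), and abundance-weighted
#'   fractions.
#' @export
engraftment_summary <- function(origins, which = c("latest", "all"),
                                exclude_post_abx = TRUE, max_day = NULL) {
  which <- match.arg(which)
  if (exclude_post_abx) origins <- origins[!origins$post_fmt_abx, , drop = FALSE]
  if (!is.null(max_day)) origins <- origins[origins$day <= max_day, , drop = FALSE]
  if (nrow(origins) == 0) {
    return(data.frame(case_id = character(), sample_id = character(),
                      day = double(), n_donor = integer(),
                      n_recipient = integer(), n_coexist = integer(),
                      n_new = integer(), n_ambiguous = integer(),
                      n_unresolved = integer(), n_lost = integer(),
                      donor_fraction = double(), coexist_fraction = double(),
                      donor_abundance = double(),
                      recipient_abundance = double(),
                      coexist_abundance = double(), new_abundance = double(),
                      unresolved_abundance = double(),
                      stringsAsFactors = FALSE))
  }
  if (which == "latest") {
    keep <- unlist(lapply(split(origins, origins$case_id), function(d) {
      d$sample_id[d$day == max(d$day)]
    }))
    origins <- origins[origins$sample_id %in% keep, , drop = FALSE]
  }
  res <- lapply(split(origins, origins$sample_id), function(d) {
    n_lab <- function(l) sum(d$label == l)
    ab_lab <- function(l) sum(d$rel_abundance[d$label == l])
    denom <- n_lab("donor") + n_lab("recipient")
    data.frame(
      case_id = d$case_id[1], sample_id = d$sample_id[1], day = d$day[1],
      n_donor = n_lab("donor"), n_recipient = n_lab("recipient"),
      n_coexist = n_lab("coexist"), n_new = n_lab("new"),
      n_ambiguous = n_lab("ambiguous"), n_unresolved = n_lab("unresolved"),
      n_lost = n_lab("lost"),
      donor_fraction = if (denom > 0) n_lab("donor") / denom else NA_real_,
      coexist_fraction = if (denom > 0) n_lab("coexist") / denom else NA_real_,
      donor_abundance = ab_lab("donor"), recipient_abundance = ab_lab("recipient"),
      coexist_abundance = ab_lab("coexist"), new_abundance = ab_lab("new"),
      unresolved_abundance = ab_lab("unresolved") + ab_lab("ambiguous"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Six-way competition outcomes for species present in recipient and donor
#'
#' For species detected in both the pre-FMT recipient and the donor — the
#' set with potential for conspecific strain competition — counts the
#' mutually exclusive outcomes: a new strain, only the recipient strain, only
#' the donor strain, coexistence, loss of the species, or an unresolved
#' strain. Ambiguous shared lineages fall into the unresolved class.
#'
#' @param origins attributed origin rows (any number of cases/samples).
#' @return named integer vector over
#'   `c("new", "recipient_only", "donor_only", "coexist", "species_lost",
#'   "unresolved")`; counts sum to the number of qualifying species rows.
#' @export
classify_competition_outcomes <- function(origins) {
  q <- origins[origins$in_pre & origins$in_donor, , drop = FALSE]
  map <- c(new = "new", recipient = "recipient_only", donor = "donor_only",
           coexist = "coexist", lost = "species_lost",
           unresolved = "unresolved", ambiguous = "unresolved")
  cls <- factor(unname(map[q$label]),
                levels = c("new", "recipient_only", "donor_only", "coexist",
                           "species_lost", "unresolved"))
  counts <- table(cls)
  out <- stats::setNames(as.integer(counts), names(counts))
  stopifnot(sum(out) == nrow(q))
  out
}

#' Fate of donor species after FMT
#'
#' Over all species detected in the donor: the fractions that did not
#' engraft, engrafted into an empty species niche (species absent from the
#' pre-FMT recipient), or engrafted by replacing a conspecific recipient
#' strain; the remainder (unresolved strains, ambiguous lineages,
#' coexistence) is reported so the four fractions sum to 1.
#'
#' @param origins attributed origin rows.
#' @return named numeric vector `not_engrafted`, `engrafted_new_species`,
#'   `engrafted_replacement`, `unresolved_or_other` (sums to 1).
#' @export
donor_species_fate <- function(origins) {
  d <- origins[origins$in_donor, , drop = FALSE]
  n <- nrow(d)
  if (n == 0) {
    return(c(not_engrafted = NA_real_, engrafted_new_species = NA_real_,
             engrafted_replacement = NA_real_, unresolved_or_other = NA_real_))
  }
  new_niche <- sum(d$label == "donor" & !d$in_pre)
  replacement <- sum(d$label == "donor" & d$in_pre)
  not_eng <- sum(d$label %in% c("recipient", "lost", "new"))
  other <- n - new_niche - replacement - not_eng
  c(not_engrafted = not_eng / n,
    engrafted_new_species = new_niche / n,
    engrafted_replacement = replacement / n,
    unresolved_or_other = other / n)
}

#' False-positive shared-strain assessment on unrelated sample pairs
#'
#' Runs the shared-strain caller on sample pairs from unrelated individuals
#' (no true shared lineages) and summarises the per-pair counts — the
#' specificity control for engraftment inference.
#'
#' @param pairs either a list of pairs, each a list with elements `a` and `b`
#'   (named profile lists), e.g. `generate_unrelated_pairs()$pairs`, or a lazy
#'   `unrelated_pair_set` (`generate_unrelated_pairs(lazy = TRUE)`), which is
#'   streamed pair by pair in constant memory.
#' @param params a [call_params()] object.
#' @param fparams a [filter_params()] object applied to each sample.
#' @return list: `mean`, `sd`, and `per_pair` (data.frame of counts).
#' @export
false_positive_assessment <- function(pairs, params = call_params(),
                                      fparams = filter_params()) {
  one <- function(pair) {
    a <- filter_profile_set(pair$a, fparams)
    b <- filter_profile_set(pair$b, fparams)
    n_shared_strains(pairwise_shared_strains(a, b, params))
  }
  if (inherits(pairs, "unrelated_pair_set")) {
    counts <- vapply(seq_len(pairs$n_pairs),
                     function(i) one(pairs$pair(i)), numeric(1))
  } else {
    if (length(pairs) == 0L) stop("need at least one pair", call. = FALSE)
    counts <- vapply(pairs, one, numeric(1))
  }
  list(mean = mean(counts), sd = stats::sd(counts),
       per_pair = data.frame(pair = seq_along(counts), n_shared = counts))
}

#' Flag sham FMT cases
#'
#' A case is flagged sham when none of its post-FMT samples carries any
#' donor-shared strain (donor-derived, coexisting or ambiguous) — the rule
#' used to exclude placebo-arm cases when donor assignment is unknown.
#'
#' @param origins attributed origin rows covering one or more cases (must
#'   contain a `case_id` column).
#' @return data.frame `case_id`, `sham` (logical).
#' @export
exclude_sham_cases <- function(origins) {
  if (nrow(origins) == 0) {
    return(data.frame(case_id = character(), sham = logical()))
  }
  res <- lapply(split(origins, origins$case_id), function(d) {
    data.frame(case_id = d$case_id[1],
               sham = !any(d$label %in% c("donor", "coexist", "ambiguous")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
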