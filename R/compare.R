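# Pairwise strain comparison by maximum variant profile similarity (MVS):
# the fraction of jointly usable alignment positions at which the two
# samples' allele sets (alleles at >= 10% within-position frequency)
# intersect. Shared strains are called at >= 5 kb overlap and MVS >= 99.9%.

#' Shared-strain calling parameters
#'
#' @param min_overlap_bp minimum jointly usable alignment positions
#'   (default 5,000 — "5 kb" counted as alignment columns).
#' @param min_mvs minimum MVS for a shared-strain call (default 0.999). The
#'   comparison is exact: the integer position counts are compared by
#'   cross-multiplication against the decimal threshold, with no floating
#'   tolerance.
#' @export
call_params <- function(min_overlap_bp = 5000L, min_mvs = 0.999) {
  if (min_overlap_bp <= 0) stop("`min_overlap_bp` must be positive", call. = FALSE)
  if (min_mvs <= 0 || min_mvs > 1) stop("`min_mvs` must be in (0, 1]", call. = FALSE)
  structure(list(min_overlap_bp = as.integer(min_overlap_bp),
                 min_mvs = min_mvs),
            class = "call_params")
}

allele_presence <- function(p, min_allele_frequency = NULL) {
  maf <- min_allele_frequency %||%
    (if (!is.null(p$params)) p$params$min_allele_frequency else 0.10)
  tot <- colSums(p$counts)
  # exact rational comparison counts/tot >= maf via integer cross-
  # multiplication (boundary cases like 3/30 = 10% must pass);
  # rep(each = 4) matches the column-major 4 x L layout
  (p$counts > 0L) & (p$counts * 1e6 >= rep(tot * round(maf * 1e6), each = 4L))
}

#' Allele set of a profile at one position
#'
#' Alleles surviving the minimum-frequency filter at a usable position.
#'
#' @param p an `snv_profile`.
#' @param pos 0-based position; must be usable (unmasked), else an error.
#' @param min_allele_frequency frequency threshold (defaults to the profile's
#'   filter provenance, or 0.10).
#' @return character subset of `c("A","C","G","T")` (non-empty).
#' @export
allele_set <- function(p, pos, min_allele_frequency = NULL) {
  stopifnot(inherits(p, "snv_profile"))
  if (pos < 0 || pos >= p$L) stop("position out of range", call. = FALSE)
  if (!p$mask[pos + 1L]) stop("position ", pos, " is masked", call. = FALSE)
  pres <- allele_presence(p, min_allele_frequency)[, pos + 1L]
  ALLELES[pres]
}

#' Compare two SNV profiles of one species
#'
#' Over the jointly usable positions, computes the MVS (fraction of positions
#' whose allele sets intersect), the consensus similarity (fraction with
#' identical major alleles, ties broken A < C < G < T), and the shared-strain
#' call. Polymorphic positions contribute through set intersection, so a
#' strain mixture matches a pure sample of either member strain.
#'
#' @param a,b `snv_profile` objects for the same species and alignment length.
#' @param params a [call_params()] object.
#' @return one-row `data.frame` (class `comparison_result`): `species_id`,
#'   `sample_a`, `sample_b`, `overlap_bp`, `mvs`, `consensus_similarity`,
#'   `shared` (logical, `NA` when overlap is insufficient) and `shared_call`
#'   in `{"shared", "not_shared", "insufficient_overlap"}`.
#' @export
compare_profiles <- function(a, b, params = call_params()) {
  stopifnot(inherits(a, "snv_profile"), inherits(b, "snv_profile"))
  if (!identical(a$species_id, b$species_id)) {
    stop("profiles are from different species", call. = FALSE)
  }
  if (a$L != b$L) stop("profiles have mismatched alignment lengths", call. = FALSE)
  joint <- a$mask & b$mask
  overlap <- sum(joint)
  if (overlap == 0L) {
    res <- data.frame(species_id = a$species_id, sample_a = a$sample_id,
                      sample_b = b$sample_id, overlap_bp = 0L,
                      mvs = NA_real_, consensus_similarity = NA_real_,
                      shared = NA, shared_call = "insufficient_overlap",
                      stringsAsFactors = FALSE)
    class(res) <- c("comparison_result", "data.frame")
    return(res)
  }
  pa <- allele_presence(a)[, joint, drop = FALSE]
  pb <- allele_presence(b)[, joint, drop = FALSE]
  n_int <- sum(colSums(pa & pb) > 0L)
  mvs <- n_int / overlap
  maj_a <- major_allele_index(a$counts[, joint, drop = FALSE])
  maj_b <- major_allele_index(b$counts[, joint, drop = FALSE])
  consensus <- mean(maj_a == maj_b)
  enough <- overlap >= params$min_overlap_bp
  # exact rational comparison: n_int/overlap >= min_mvs via integer products
  passes <- n_int * 1e6 >= overlap * round(params$min_mvs * 1e6)
  res <- data.frame(species_id = a$species_id, sample_a = a$sample_id,
                    sample_b = b$sample_id, overlap_bp = overlap,
                    mvs = mvs, consensus_similarity = consensus,
                    shared = if (enough) passes else NA,
                    shared_call = if (!enough) "insufficient_overlap"
                                  else if (passes) "shared" else "not_shared",
                    stringsAsFactors = FALSE)
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Per-species strain comparison between two samples
#'
#' Compares every species with a profile in both samples and counts the
#' shared-strain calls.
#'
#' @param profiles_a,profiles_b named lists of `snv_profile` objects (names =
#'   species ids), e.g. from [render_sample()] followed by
#'   [filter_profile()].
#' @param params a [call_params()] object.
#' @return `data.frame` with one [compare_profiles()] row per common species;
#'   the number of shared strains is in `attr(, "n_shared")`.
#' @export
pairwise_shared_strains <- function(profiles_a, profiles_b,
                                    params = call_params()) {
  common <- intersect(names(profiles_a), names(profiles_b))
  if (length(common) == 0L) {
    out <- data.frame(species_id = character(), sample_a = character(),
                      sample_b = character(), overlap_bp = integer(),
                      mvs = double(), consensus_similarity = double(),
                      shared = logical(), shared_call = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_shared") <- 0L
    return(out)
  }
  rows <- lapply(common, function(sp) {
    compare_profiles(profiles_a[[sp]], profiles_b[[sp]], params)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_shared") <- sum(out$shared_call == "shared")
  out
}

#' @rdname pairwise_shared_strains
#' @param comparison a result of `pairwise_shared_strains()`.
#' @return `n_shared_strains`: integer count of shared-strain calls.
#' @export
n_shared_strains <- function(comparison) {
  sum(comparison$shared_call == "shared")
}

#' Filter every profile of a sample set
#' @param profiles named list of `snv_profile` objects.
#' @param params a [filter_params()] object.
#' @return named list of filtered profiles.
#' @export
filter_profile_set <- function(profiles, params = filter_params()) {
  lapply(profiles, filter_profile, params = params)
}
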