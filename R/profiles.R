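# SNV profiles: per-sample, per-species nucleotide variant profiles over the
# concatenated clade-specific marker alignment. Positions are 0-based and
# contiguous; a logical mask marks the usable positions.

new_snv_profile <- function(counts, mask, sample_id, species_id,
                            marker_lengths = NULL, filtered = FALSE,
                            params = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L, length(mask) == ncol(counts))
  rownames(counts) <- ALLELES
  structure(
    list(sample_id = sample_id,
         species_id = species_id,
         L = ncol(counts),
         counts = counts,
         mask = as.logical(mask),
         marker_lengths = marker_lengths %||% ncol(counts),
         filtered = filtered,
         params = params),
    class = "snv_profile"
  )
}

#' Number of usable (covered, unmasked) positions of a profile
#' @param p an `snv_profile`.
#' @export
covered_length <- function(p) {
  stopifnot(inherits(p, "snv_profile"))
  sum(p$mask)
}

#' @exportS3Method base::print
print.snv_profile <- function(x, ...) {
  cat(sprintf("<snv_profile> %s / %s: L = %d, usable = %d%s\n",
              x$sample_id, x$species_id, x$L, covered_length(x),
              if (x$filtered) ", filtered" else ""))
  invisible(x)
}

#' Build a nucleotide variant profile from a position-allele count table
#'
#' @param count_table data.frame with columns `position` (0-based, within
#'   `[0, L)`), `count_A`, `count_C`, `count_G`, `count_T`. Positions absent
#'   from the table get zero counts and are masked.
#' @param species_id,sample_id identifiers stored in the profile.
#' @param L total alignment length (positions).
#' @param marker_lengths optional integer vector of per-marker lengths summing
#'   to `L`, used for marker-end trimming during filtering.
#' @return an `snv_profile`.
#' @export
build_profile <- function(count_table, species_id, sample_id, L,
                          marker_lengths = NULL) {
  stopifnot_scalar_count(L, "L")
  needed <- c("position", paste0("count_", ALLELES))
  if (nrow(count_table) == 0 && !all(needed %in% names(count_table))) {
    count_table <- as.data.frame(setNames(rep(list(integer()), 5), needed))
  }
  if (!all(needed %in% names(count_table))) {
    stop("count_table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  pos <- count_table$position
  if (anyDuplicated(pos)) stop("duplicate positions in count table", call. = FALSE)
  if (length(pos) && (any(pos < 0) || any(pos >= L))) {
    stop("positions must lie within [0, L)", call. = FALSE)
  }
  cm <- t(as.matrix(count_table[paste0("count_", ALLELES)]))
  if (any(cm < 0)) stop("negative counts", call. = FALSE)
  counts <- matrix(0L, nrow = 4L, ncol = L)
  if (length(pos)) counts[, pos + 1L] <- as.integer(cm)
  mask <- colSums(counts) > 0
  new_snv_profile(counts, mask, sample_id, species_id,
                  marker_lengths = marker_lengths)
}

#' Filtering parameters for SNV profiles
#'
#' Defaults implement a conservative denoising cascade for marker-based
#' strain profiles: positions need >= 5 reads, alleles need >= 2 reads and
#' >= 10% within-position frequency (the polymorphic-site threshold used for
#' shared-strain calling), and 20 positions at each marker boundary are
#' trimmed.
#'
#' @param min_position_coverage minimum reads per position.
#' @param min_allele_count minimum reads per retained allele.
#' @param min_allele_frequency minimum within-position allele frequency in
#'   (0, 0.5).
#' @param end_trim positions masked at each end of every marker.
#' @export
filter_params <- function(min_position_coverage = 5L,
                          min_allele_count = 2L,
                          min_allele_frequency = 0.10,
                          end_trim = 20L) {
  if (min_allele_frequency <= 0 || min_allele_frequency >= 0.5) {
    stop("`min_allele_frequency` must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(min_position_coverage = min_position_coverage,
                 min_allele_count = min_allele_count,
                 min_allele_frequency = min_allele_frequency,
                 end_trim = end_trim),
            class = "filter_params")
}

marker_end_mask <- function(marker_lengths, end_trim) {
  # TRUE where a position survives the per-marker end trim
  unlist(lapply(marker_lengths, function(ml) {
    keep <- rep(TRUE, ml)
    t <- min(end_trim, ml)
    if (t > 0) {
      keep[seq_len(t)] <- FALSE
      keep[ml - seq_len(t) + 1L] <- FALSE
    }
    keep
  }), use.names = FALSE)
}

#' Filter an SNV profile
#'
#' Masks marker-boundary positions and positions below the coverage floor,
#' zeroes alleles below the frequency or count thresholds, and re-masks
#' positions whose remaining coverage falls below the floor. The operation is
#' idempotent.
#'
#' @param p an `snv_profile`.
#' @param params a [filter_params()] object.
#' @return the filtered `snv_profile` (with `filtered = TRUE`).
#' @export
filter_profile <- function(p, params = filter_params()) {
  stopifnot(inherits(p, "snv_profile"), inherits(params, "filter_params"))
  counts <- p$counts
  mask <- p$mask & marker_end_mask(p$marker_lengths, params$end_trim)
  tot <- colSums(counts)
  mask <- mask & tot >= params$min_position_coverage
  # exact rational frequency comparison (see allele_presence)
  drop <- (counts * 1e6 <
             rep(tot * round(params$min_allele_frequency * 1e6), each = 4L)) |
    (counts < params$min_allele_count)
  counts[drop] <- 0L
  mask <- mask & colSums(counts) >= params$min_position_coverage
  counts[, !mask] <- p$counts[, !mask]  # masked positions keep raw counts
  new_snv_profile(counts, mask, p$sample_id, p$species_id,
                  marker_lengths = p$marker_lengths, filtered = TRUE,
                  params = params)
}

#' Merge per-sample profiles of one species into an aligned stack
#'
#' @param profiles list of `snv_profile` objects with identical `species_id`
#'   and alignment length.
#' @return an `snv_profile_stack`: a 4 x L x n counts array, an L x n mask
#'   matrix, and the sample ids; joint-coverage lookups are O(1) column
#'   operations.
#' @export
merge_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  lapply(profiles, function(p) stopifnot(inherits(p, "snv_profile")))
  sp <- unique(vapply(profiles, `[[`, "", "species_id"))
  if (length(sp) != 1L) stop("profiles mix species: ", paste(sp, collapse = ", "),
                             call. = FALSE)
  Ls <- unique(vapply(profiles, `[[`, 0L, "L"))
  if (length(Ls) != 1L) stop("profiles have mismatched alignment lengths",
                             call. = FALSE)
  n <- length(profiles)
  counts <- array(0L, dim = c(4L, Ls, n),
                  dimnames = list(ALLELES, NULL, NULL))
  mask <- matrix(FALSE, nrow = Ls, ncol = n)
  for (i in seq_len(n)) {
    counts[, , i] <- profiles[[i]]$counts
    mask[, i] <- profiles[[i]]$mask
  }
  structure(list(species_id = sp, L = Ls,
                 sample_ids = vapply(profiles, `[[`, "", "sample_id"),
                 counts = counts, mask = mask),
            class = "snv_profile_stack")
}

major_allele_index <- function(counts) {
  # ties broken by fixed allele order A < C < G < T
  max.col(t(counts), ties.method = "first")
}

#' Consensus sequence of a profile
#'
#' The major allele at every usable position; masked positions yield `N`.
#' Ties are broken by the fixed allele order A < C < G < T.
#'
#' @param p an `snv_profile`.
#' @return a single string over `{A, C, G, T, N}` of length `L`.
#' @export
consensus_sequence <- function(p) {
  stopifnot(inherits(p, "snv_profile"))
  out <- rep("N", p$L)
  if (any(p$mask)) {
    out[p$mask] <- ALLELES[major_allele_index(p$counts[, p$mask, drop = FALSE])]
  }
  paste(out, collapse = "")
}

#' Write / read an SNV profile as TSV
#'
#' The header records sample, species, alignment length, marker structure and
#' filter provenance; only covered positions are written, with a `usable`
#' column preserving the mask, so the round trip is lossless. Gzipped paths
#' (`.gz`) are handled transparently.
#'
#' @param p an `snv_profile`.
#' @param path output file path.
#' @export
write_profile_tsv <- function(p, path) {
  stopifnot(inherits(p, "snv_profile"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_id=%s", p$sample_id),
    sprintf("# species_id=%s", p$species_id),
    sprintf("# L=%d", p$L),
    sprintf("# marker_lengths=%s", paste(p$marker_lengths, collapse = ",")),
    sprintf("# filtered=%s", p$filtered)
  ), con)
  keep <- colSums(p$counts) > 0 | p$mask
  df <- data.frame(position = which(keep) - 1L,
                   count_A = p$counts[1L, keep],
                   count_C = p$counts[2L, keep],
                   count_G = p$counts[3L, keep],
                   count_T = p$counts[4L, keep],
                   usable = as.integer(p$mask[keep]))
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param path input file path (plain or gzipped TSV).
#' @return `read_profile_tsv`: the reconstructed `snv_profile`.
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s=", key), "",
                           grep(sprintf("^# %s=", key), hdr, value = TRUE)[1])
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(
    read.table(text = body, header = TRUE, sep = "\t",
               colClasses = "integer"),
    error = function(e) stop(sprintf("malformed profile TSV '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  L <- as.integer(get("L"))
  counts <- matrix(0L, 4L, L)
  mask <- rep(FALSE, L)
  if (nrow(df)) {
    counts[, df$position + 1L] <- t(as.matrix(df[paste0("count_", ALLELES)]))
    mask[df$position + 1L] <- df$usable == 1L
  }
  new_snv_profile(counts, mask,
                  sample_id = get("sample_id"), species_id = get("species_id"),
                  marker_lengths = as.integer(strsplit(get("marker_lengths"),
                                                       ",")[[1]]),
                  filtered = identical(get("filtered"), "TRUE"))
}
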