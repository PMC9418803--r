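# Shared fixtures and independent oracles, all built in code.

# profile from an explicit 4 x L count matrix (rows A, C, G, T)
profile_from_counts <- function(counts, sample_id = "s", species_id = "sp",
                                mask = NULL) {
  counts <- as.matrix(counts)
  pos <- which(colSums(counts) > 0) - 1L
  df <- data.frame(position = pos,
                   count_A = counts[1, pos + 1L],
                   count_C = counts[2, pos + 1L],
                   count_G = counts[3, pos + 1L],
                   count_T = counts[4, pos + 1L])
  p <- build_profile(df, species_id, sample_id, L = ncol(counts))
  if (!is.null(mask)) p$mask <- mask
  p
}

# uniform-coverage single-allele profile over L positions
flat_profile <- function(alleles, coverage = 10L, sample_id = "s",
                         species_id = "sp") {
  L <- length(alleles)
  counts <- matrix(0L, 4L, L)
  counts[cbind(alleles, seq_len(L))] <- coverage
  profile_from_counts(counts, sample_id, species_id)
}

# independent brute-force MVS oracle: explicit per-position loop, allele sets
# from the exact >= 10% frequency rule written as count * 10 >= total reads
brute_force_mvs <- function(a, b) {
  joint <- which(a$mask & b$mask)
  if (length(joint) == 0L) return(list(overlap = 0L, mvs = NA_real_))
  hits <- 0L
  for (i in joint) {
    ca <- a$counts[, i]
    cb <- b$counts[, i]
    sa <- which(ca > 0 & ca * 10 >= sum(ca))
    sb <- which(cb > 0 & cb * 10 >= sum(cb))
    if (length(intersect(sa, sb)) > 0L) hits <- hits + 1L
  }
  list(overlap = length(joint), mvs = hits / length(joint))
}

# random profile with Dirichlet-ish allele mixtures and random coverage gaps
random_test_profile <- function(L, sample_id = "s", species_id = "sp") {
  counts <- matrix(0L, 4L, L)
  for (i in seq_len(L)) {
    if (runif(1) < 0.15) next  # uncovered
    k <- sample(1:3, 1, prob = c(0.7, 0.25, 0.05))
    alleles <- sample(1:4, k)
    counts[alleles, i] <- rpois(k, lambda = c(20, 4, 2)[seq_len(k)]) + 1L
  }
  profile_from_counts(counts, sample_id, species_id)
}

# truth-vs-label comparison for a rendered cohort
label_truth_table <- function(cohort, origins) {
  ev <- cohort$events
  key_t <- paste(ev$sample_id, ev$species_id)
  key_o <- paste(origins$sample_id, origins$species_id)
  m <- match(key_o, key_t)
  data.frame(sample_id = origins$sample_id,
             species_id = origins$species_id,
             label = origins$label,
             truth = ev$outcome[m],
             ambiguous_lineage = ev$lineage_ambiguous[m],
             coexist_fraction = ev$coexist_fraction[m],
             stringsAsFactors = FALSE)
}
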