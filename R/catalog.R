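#' Generate a synthetic species catalog
#'
#' Creates a catalog of marker-gene-profiled bacterial species with genus and
#' phylum labels, concatenated marker-alignment lengths, and four lifestyle
#' features (Gram stain, spore formation, oxygen tolerance, oral habitat)
#' coded `+1` / `-1` with configurable missingness, mirroring the annotation
#' tables that strain-tracking analyses aggregate from culture databases.
#'
#' Genus sizes follow a skewed (Zipf-like) distribution so that a few genera
#' hold many species, as in real gut communities.
#'
#' @param n_species number of species (>= 1).
#' @param feature_missing_rate probability that a feature annotation is
#'   missing (`NA`) for a species.
#' @param seed optional integer seed; the catalog is deterministic given it.
#' @param n_genera number of genera to distribute species over.
#' @param marker_length_range integer range (min, max) of the concatenated
#'   marker alignment length per species; lengths are drawn uniformly, so with
#'   the default 2,000-20,000 bp range >80% of species exceed the 5 kb
#'   comparison overlap threshold.
#' @param genus_skew exponent of the Zipf weight `1/rank^genus_skew` used for
#'   genus assignment.
#' @param feature_prevalence named list of probabilities that each feature is
#'   `+1` (before missingness).
#' @return a `data.frame` of class `species_catalog` with columns
#'   `species_id`, `genus`, `phylum`, `marker_length`, `n_markers`,
#'   `gram_positive`, `spore_forming`, `oxygen_tolerant`, `oral_habitat`.
#'   The realised missingness rate is recorded in
#'   `attr(, "feature_missing_rate")`.
#' @export
generate_catalog <- function(n_species,
                             feature_missing_rate = 0.2,
                             seed = NULL,
                             n_genera = max(1L, ceiling(n_species / 4)),
                             marker_length_range = c(2000L, 20000L),
                             genus_skew = 1,
                             feature_prevalence = list(gram_positive = 0.5,
                                                       spore_forming = 0.3,
                                                       oxygen_tolerant = 0.3,
                                                       oral_habitat = 0.2)) {
  if (length(n_species) != 1L || is.na(n_species) || n_species < 1) {
    stop("`n_species` must be a positive integer", call. = FALSE)
  }
  if (feature_missing_rate < 0 || feature_missing_rate > 1) {
    stop("`feature_missing_rate` must be in [0, 1]", call. = FALSE)
  }
  with_seed_or_stream(seed, {
    genus_ids <- sprintf("g%03d", seq_len(n_genera))
    w <- (1 / seq_len(n_genera))^genus_skew
    genus <- sample(genus_ids, n_species, replace = TRUE, prob = w)
    phyla <- c("Bacteroidetes", "Firmicutes", "Proteobacteria", "Actinobacteria")
    genus_phylum <- sample(phyla, n_genera, replace = TRUE,
                           prob = c(0.25, 0.45, 0.15, 0.15))
    names(genus_phylum) <- genus_ids
    marker_length <- as.integer(round(runif(n_species,
                                            marker_length_range[1],
                                            marker_length_range[2])))
    feats <- lapply(feature_prevalence, function(prev) {
      x <- ifelse(runif(n_species) < prev, 1L, -1L)
      x[runif(n_species) < feature_missing_rate] <- NA_integer_
      x
    })
    cat_df <- data.frame(
      species_id = sprintf("s%04d", seq_len(n_species)),
      genus = genus,
      phylum = unname(genus_phylum[genus]),
      marker_length = marker_length,
      n_markers = pmax(1L, as.integer(round(marker_length / 1000))),
      stringsAsFactors = FALSE
    )
    for (f in names(feats)) cat_df[[f]] <- feats[[f]]
    feat_mat <- as.matrix(cat_df[names(feats)])
    attr(cat_df, "feature_missing_rate") <- mean(is.na(feat_mat))
    class(cat_df) <- c("species_catalog", "data.frame")
    cat_df
  })
}

catalog_features <- function() {
  c("gram_positive", "spore_forming", "oxygen_tolerant", "oral_habitat")
}

#' Draw a random strain genotype over a species' marker alignment
#'
#' @param species_id species identifier.
#' @param L alignment length in positions.
#' @param lineage_id label for the subspecies lineage this genotype represents.
#' @param seed optional seed.
#' @return object of class `strain_genotype`: integer allele vector (1..4 for
#'   A, C, G, T) of length `L`.
#' @export
random_genotype <- function(species_id, L, lineage_id = "lin1", seed = NULL) {
  with_seed_or_stream(seed, {
    structure(
      list(species_id = species_id,
           alleles = sample.int(4L, L, replace = TRUE),
           lineage_id = lineage_id,
           L = as.integer(L)),
      class = "strain_genotype"
    )
  })
}

#' Mutate a strain genotype to a given expected divergence
#'
#' Each position differs from the parent independently with probability
#' `divergence`; substituted alleles are drawn uniformly from the three
#' alternatives, so the realised number of differing positions is
#' Binomial(L, divergence).
#'
#' @param parent a `strain_genotype`.
#' @param divergence per-position substitution probability in \[0, 1\].
#' @param lineage_id lineage label for the child genotype.
#' @param seed optional seed.
#' @return a new `strain_genotype` of the same length.
#' @export
mutate_strain <- function(parent, divergence, lineage_id = NULL, seed = NULL) {
  stopifnot(inherits(parent, "strain_genotype"))
  if (length(divergence) != 1L || is.na(divergence) ||
      divergence < 0 || divergence > 1) {
    stop("`divergence` must be a single value in [0, 1]", call. = FALSE)
  }
  with_seed_or_stream(seed, {
    alleles <- parent$alleles
    flip <- which(runif(parent$L) < divergence)
    if (length(flip)) {
      shift <- sample.int(3L, length(flip), replace = TRUE)
      alleles[flip] <- ((alleles[flip] - 1L + shift) %% 4L) + 1L
    }
    structure(
      list(species_id = parent$species_id,
           alleles = alleles,
           lineage_id = lineage_id %||% paste0(parent$lineage_id, ".m"),
           L = parent$L),
      class = "strain_genotype"
    )
  })
}

#' Hamming divergence between two genotypes of one species
#' @param a,b `strain_genotype` objects with equal length.
#' @return proportion of differing positions.
#' @export
genotype_divergence <- function(a, b) {
  stopifnot(inherits(a, "strain_genotype"), inherits(b, "strain_genotype"),
            a$L == b$L)
  mean(a$alleles != b$alleles)
}
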