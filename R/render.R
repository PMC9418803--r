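# Rendering: turn a community plus strain genotypes into observed per-species
# SNV profiles, emulating marker-mapped read pileups.

#' Render observed SNV profiles for one sample
#'
#' Per-position coverage is Poisson with rate
#' `depth * abundance * coverage_scale`; by default `coverage_scale` is the
#' number of species present, so a species at the average relative abundance
#' receives approximately `depth` coverage. Allele counts at each position are
#' multinomial over the strain mixture convolved with a uniform sequencing
#' error; zero-coverage positions are masked.
#'
#' @param community named relative-abundance vector (sums to 1); species with
#'   zero abundance yield no profile.
#' @param strain_assignment named list: species -> list with `genotypes`
#'   (list of [random_genotype()] objects) and `fractions` (within-species
#'   mixture fractions summing to 1).
#' @param catalog a `species_catalog` (supplies marker structure).
#' @param sample_id identifier stored in the profiles.
#' @param depth nominal mean per-species coverage.
#' @param error_rate per-base sequencing error probability.
#' @param coverage_scale multiplier linking relative abundance to coverage;
#'   default `sum(community > 0)`.
#' @param seed optional seed.
#' @return named list of `snv_profile` objects (one per present species).
#' @export
render_sample <- function(community, strain_assignment, catalog,
                          sample_id = "sample", depth = 30,
                          error_rate = 0.001, coverage_scale = NULL,
                          seed = NULL) {
  if (depth < 0) stop("`depth` must be non-negative", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.75) {
    stop("`error_rate` must be in [0, 0.75]", call. = FALSE)
  }
  check_closed(community, name = "community")
  present <- names(community)[community > 0]
  coverage_scale <- coverage_scale %||% length(present)
  idx <- match(present, catalog$species_id)
  if (anyNA(idx)) stop("community species missing from catalog", call. = FALSE)
  with_seed_or_stream(seed, {
    profiles <- vector("list", length(present))
    names(profiles) <- present
    for (k in seq_along(present)) {
      sp <- present[k]
      sa <- strain_assignment[[sp]]
      if (is.null(sa)) stop("no strain assignment for species ", sp, call. = FALSE)
      fr <- sa$fractions
      if (abs(sum(fr) - 1) > 1e-8) {
        stop("within-species fractions must sum to 1 for ", sp, call. = FALSE)
      }
      L <- catalog$marker_length[idx[k]]
      nm <- catalog$n_markers[idx[k]]
      lam <- depth * community[[sp]] * coverage_scale
      cov <- rpois(L, lam)
      if (length(sa$genotypes) == 1L) {
        # single-strain fast path: errors are rare, draw them sparsely
        g <- sa$genotypes[[1]]
        stopifnot(g$L == L)
        counts <- matrix(0L, nrow = 4L, ncol = L)
        nerr <- rbinom(L, cov, error_rate)
        counts[cbind(g$alleles, seq_len(L))] <- cov - nerr
        ie <- which(nerr > 0L)
        if (length(ie)) {
          ones <- ie[nerr[ie] == 1L]
          if (length(ones)) {
            shift <- sample.int(3L, length(ones), replace = TRUE)
            rows <- ((g$alleles[ones] - 1L + shift) %% 4L) + 1L
            ii <- cbind(rows, ones)
            counts[ii] <- counts[ii] + 1L
          }
          for (j in ie[nerr[ie] > 1L]) {
            alt <- setdiff(1:4, g$alleles[j])
            counts[alt, j] <- counts[alt, j] +
              drop(stats::rmultinom(1L, nerr[j], rep(1 / 3, 3)))
          }
        }
      } else {
        prob <- matrix(error_rate / 3, nrow = 4L, ncol = L)
        for (j in seq_along(sa$genotypes)) {
          g <- sa$genotypes[[j]]
          stopifnot(g$L == L)
          ii <- cbind(g$alleles, seq_len(L))
          prob[ii] <- prob[ii] + fr[j] * (1 - 4 * error_rate / 3)
        }
        counts <- rmultinom_positions(cov, prob)
      }
      ml <- rep(L %/% nm, nm)
      ml[nm] <- ml[nm] + L - sum(ml)
      profiles[[k]] <- new_snv_profile(counts, cov > 0, sample_id, sp,
                                       marker_lengths = ml)
    }
    profiles
  })
}

#' Generate unrelated sample pairs with disjoint strain lineages
#'
#' Builds pairs of samples whose conspecific genotypes all diverge by at least
#' `divergence_floor`, so no truly shared strains exist — the negative-control
#' design used to measure the false-positive shared-strain rate. Communities
#' of the two samples cover the same species (compositions overlap at the
#' species level; only the strains differ).
#'
#' @param n_pairs number of pairs (>= 1).
#' @param catalog a `species_catalog`.
#' @param n_species_per_sample species drawn per pair (defaults to all).
#' @param divergence_floor minimum pairwise genotype divergence; values below
#'   the 0.001 resolving power of the default 99.9% MVS threshold trigger a
#'   warning.
#' @param divergence_max upper end of the divergence draw.
#' @param depth,error_rate,sigma_lognormal rendering and composition
#'   parameters (see [render_sample()]).
#' @param seed integer seed (required when `lazy = TRUE`).
#' @param lazy when `TRUE`, pairs are not materialised: the result carries a
#'   `pair(i)` closure that renders pair `i` deterministically from a derived
#'   seed, so arbitrarily many pairs can be assessed in constant memory.
#' @return with `lazy = FALSE`, a list with `pairs` (each a list of two named
#'   profile lists `a`, `b`) and `truth_shared` (integer 0 per pair, by
#'   construction); with `lazy = TRUE`, an `unrelated_pair_set` with elements
#'   `n_pairs` and `pair`.
#' @export
generate_unrelated_pairs <- function(n_pairs, catalog,
                                     n_species_per_sample = nrow(catalog),
                                     divergence_floor = 0.003,
                                     divergence_max = max(0.02, divergence_floor),
                                     depth = 30, error_rate = 0.001,
                                     sigma_lognormal = 1, seed = NULL,
                                     lazy = FALSE) {
  if (n_pairs < 1) stop("`n_pairs` must be >= 1", call. = FALSE)
  if (divergence_floor < 0.001) {
    warning("divergence floor below the resolving power (0.1%) of the default ",
            "99.9% MVS threshold; called shared strains may not be false positives")
  }
  make_pair <- function(i) {
    sp <- sample(catalog$species_id, n_species_per_sample)
    comm <- close_composition(stats::setNames(
      rlnorm(length(sp), 0, sigma_lognormal), sp))
    idx <- match(sp, catalog$species_id)
    sa_a <- sa_b <- vector("list", length(sp))
    names(sa_a) <- names(sa_b) <- sp
    for (k in seq_along(sp)) {
      g0 <- random_genotype(sp[k], catalog$marker_length[idx[k]],
                            lineage_id = sprintf("p%d.%s.a", i, sp[k]))
      d <- runif(1, divergence_floor, divergence_max)
      g1 <- mutate_strain(g0, d, lineage_id = sprintf("p%d.%s.b", i, sp[k]))
      sa_a[[k]] <- list(genotypes = list(g0), fractions = 1)
      sa_b[[k]] <- list(genotypes = list(g1), fractions = 1)
    }
    list(a = render_sample(comm, sa_a, catalog,
                           sample_id = sprintf("pair%d_a", i),
                           depth = depth, error_rate = error_rate),
         b = render_sample(comm, sa_b, catalog,
                           sample_id = sprintf("pair%d_b", i),
                           depth = depth, error_rate = error_rate))
  }
  if (lazy) {
    if (is.null(seed)) stop("`lazy = TRUE` requires a seed", call. = FALSE)
    return(structure(list(
      n_pairs = n_pairs,
      pair = function(i) {
        withr::with_seed(as.integer((seed * 131 + i * 7919) %% 2147483647),
                         make_pair(i))
      }
    ), class = "unrelated_pair_set"))
  }
  with_seed_or_stream(seed, {
    pairs <- lapply(seq_len(n_pairs), make_pair)
    list(pairs = pairs, truth_shared = rep(0L, n_pairs))
  })
}
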