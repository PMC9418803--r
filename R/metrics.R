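# Compositional and ecological community metrics used as model covariates
# and dysbiosis readouts. Natural-log base throughout (Shannon, clr,
# dysbiosis score).

#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * ln(p_i))` over positive abundances.
#'
#' @param p closed relative-abundance vector (sums to 1).
#' @return diversity in nats.
#' @export
shannon_index <- function(p) {
  check_closed(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

default_pseudocount <- function(x) {
  nz <- x[x > 0]
  if (length(nz) == 0L) stop("all-zero composition", call. = FALSE)
  min(nz) / 2
}

#' Centered log-ratio (clr) transform
#'
#' Zeros are replaced by an additive pseudocount (default: half the smallest
#' nonzero abundance) before re-closure; the output is centred to sum to 0.
#'
#' @param p closed relative-abundance vector.
#' @param pseudocount zero-replacement value; `NULL` for the default.
#' @return real vector of clr coordinates (sums to 0).
#' @export
clr_transform <- function(p, pseudocount = NULL) {
  check_closed(p)
  eps <- pseudocount %||% default_pseudocount(p)
  x <- p
  x[x == 0] <- eps
  x <- x / sum(x)
  lx <- log(x)
  lx - mean(lx)
}

align_compositions <- function(a, b) {
  universe <- union(names(a), names(b))
  if (is.null(universe)) {
    stopifnot(length(a) == length(b))
    return(list(a = a, b = b))
  }
  fill <- function(x) {
    y <- stats::setNames(numeric(length(universe)), universe)
    y[names(x)] <- x
    y
  }
  list(a = fill(a), b = fill(b))
}

#' Aitchison distance between two community profiles
#'
#' Euclidean distance between clr vectors over the union species universe
#' (with zero replacement); satisfies the metric axioms.
#'
#' @param a,b named closed relative-abundance vectors.
#' @param pseudocount zero replacement shared by both compositions (default:
#'   half the smallest nonzero abundance across the pair).
#' @return non-negative distance.
#' @export
aitchison_distance <- function(a, b, pseudocount = NULL) {
  al <- align_compositions(a, b)
  eps <- pseudocount %||% default_pseudocount(c(al$a, al$b))
  sqrt(sum((clr_transform(al$a, eps) - clr_transform(al$b, eps))^2))
}

#' Mean Aitchison distance of a sample to a reference set
#'
#' @param sample named closed relative-abundance vector.
#' @param reference list of reference community vectors (e.g. healthy
#'   controls).
#' @inheritParams aitchison_distance
#' @return mean distance to the reference communities.
#' @export
distance_to_reference <- function(sample, reference, pseudocount = NULL) {
  if (length(reference) == 0L) stop("empty reference set", call. = FALSE)
  mean(vapply(reference, function(r) {
    aitchison_distance(sample, r, pseudocount)
  }, numeric(1)))
}

#' PCA of clr-transformed community profiles
#'
#' @param abundance_matrix samples x species relative-abundance matrix (rows
#'   closed to 1).
#' @param pseudocount zero replacement applied matrix-wide (default: half the
#'   smallest nonzero entry).
#' @return list with `scores`, `loadings` and `explained_variance` (per
#'   component, fractions summing to 1).
#' @export
pca_clr <- function(abundance_matrix, pseudocount = NULL) {
  stopifnot(is.matrix(abundance_matrix))
  if (nrow(abundance_matrix) < 2L) {
    stop("PCA needs at least 2 samples", call. = FALSE)
  }
  eps <- pseudocount %||% default_pseudocount(as.vector(abundance_matrix))
  clr_mat <- t(apply(abundance_matrix, 1L, clr_transform, pseudocount = eps))
  pc <- stats::prcomp(clr_mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = ev / sum(ev))
}

#' Microbial dysbiosis score
#'
#' Log-ratio (natural log) of the cumulative relative abundance of taxa
#' positively vs. negatively associated with disease:
#' `log((sum(up) + eps) / (sum(down) + eps))`.
#'
#' @param p named closed relative-abundance vector; names may be species ids
#'   or genus labels (see `genus_of`).
#' @param up_taxa,down_taxa disjoint character vectors of taxa.
#' @param eps pseudocount (> 0).
#' @param genus_of optional named map species -> genus, applied to `names(p)`
#'   before matching the taxa lists.
#' @return dysbiosis score (0 when the two cumulative abundances are equal).
#' @export
dysbiosis_score <- function(p, up_taxa, down_taxa, eps = 1e-6,
                            genus_of = NULL) {
  if (length(up_taxa) == 0L || length(down_taxa) == 0L) {
    stop("taxa lists must be non-empty", call. = FALSE)
  }
  if (length(intersect(up_taxa, down_taxa)) > 0L) {
    stop("up and down taxa lists overlap", call. = FALSE)
  }
  if (eps <= 0) stop("`eps` must be positive", call. = FALSE)
  labels <- if (is.null(genus_of)) names(p) else unname(genus_of[names(p)])
  up <- sum(p[labels %in% up_taxa])
  down <- sum(p[labels %in% down_taxa])
  log((up + eps) / (down + eps))
}

#' Read the bundled default dysbiosis taxa configuration
#'
#' A replaceable, editable TSV listing genera treated as disease-positive
#' ("up") or disease-negative ("down"). The shipped list is a synthetic
#' default assembled from genera commonly reported in pediatric Crohn's
#' disease dysbiosis work; users analysing real data should substitute their
#' own curated lists.
#'
#' @param path TSV with columns `taxon` and `direction` (`up`/`down`);
#'   default: the file shipped with the package.
#' @return list with `up_taxa` and `down_taxa`.
#' @export
read_dysbiosis_config <- function(path = system.file("extdata",
                                                     "dysbiosis_taxa.tsv",
                                                     package = "fmtstrains")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  list(up_taxa = df$taxon[df$direction == "up"],
       down_taxa = df$taxon[df$direction == "down"])
}

#' Cumulative abundance of lifestyle-annotated taxa
#'
#' Sums the relative abundance of species annotated `+1` for oral habitat,
#' oxygen tolerance, and spore formation. Species with missing annotations
#' are excluded from the numerator; their total abundance is reported so the
#' exclusion is visible.
#'
#' @param p named closed relative-abundance vector (species ids).
#' @param annotations a `species_catalog` (or data.frame with `species_id`
#'   and feature columns coded +1/-1/NA).
#' @return named vector: `oral_abundance`, `oxygen_tolerant_abundance`,
#'   `spore_abundance`, `unannotated_abundance`.
#' @export
lifestyle_burden <- function(p, annotations) {
  idx <- match(names(p), annotations$species_id)
  burden <- function(col) {
    v <- annotations[[col]][idx]
    sum(p[!is.na(v) & v == 1L])
  }
  miss <- rowSums(is.na(as.matrix(
    annotations[idx, catalog_features(), drop = FALSE]))) > 0
  c(oral_abundance = burden("oral_habitat"),
    oxygen_tolerant_abundance = burden("oxygen_tolerant"),
    spore_abundance = burden("spore_forming"),
    unannotated_abundance = sum(p[miss]))
}

#' Variance inflation factors of a design matrix
#' @param X numeric design matrix (no intercept column).
#' @return named VIF vector; values above 5 flag collinearity.
#' @export
variance_inflation <- function(X) {
  X <- as.matrix(X)
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2L) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  R <- stats::cor(X)
  v <- diag(solve(R))
  stats::setNames(v, colnames(X))
}

#' Mixed-model comparison of microbiota metrics to controls
#'
#' For each metric, fits a mixed-effects model with sample type as fixed
#' effect (controls as reference) and study and case as random intercepts,
#' as is standard for meta-cohorts with repeated sampling. Continuous metrics
#' use a Gaussian model (Satterthwaite p-values via lmerTest); proportion
#' metrics can be analysed on the logit scale (`family = "gaussian_logit"`)
#' or, when integer trials are available, with a binomial GLMM. Post-FMT
#' samples collected fewer than `min_post_day` days after FMT are excluded.
#'
#' @param metrics data.frame with columns `sample_id`, `sample_type`,
#'   `study_id`, `case_id`, `day` (may be `NA` for non-post samples) and one
#'   column per metric.
#' @param metric_cols names of the metric columns to model.
#' @param family one of `"gaussian"`, `"gaussian_logit"`, `"binomial"`;
#'   recycled over metrics.
#' @param reference sample type used as reference level (must be present).
#' @param min_post_day minimum days-after-FMT for post-FMT samples.
#' @param trials column with binomial trial counts (required for
#'   `family = "binomial"`).
#' @return data.frame of fixed-effect rows (metric, term, estimate, se,
#'   p_value, singular); variance inflation factors of the sample-type design
#'   are attached as `attr(, "vif")`; singular fits are reported, not
#'   dropped.
#' @export
compare_to_controls <- function(metrics, metric_cols,
                                family = "gaussian",
                                reference = "control",
                                min_post_day = 5,
                                trials = NULL) {
  stopifnot(all(c("sample_type", "study_id", "case_id") %in% names(metrics)))
  if (!reference %in% metrics$sample_type) {
    stop("reference sample type '", reference, "' absent from data", call. = FALSE)
  }
  keep <- !(metrics$sample_type == "post" &
              !is.na(metrics$day) & metrics$day < min_post_day)
  metrics <- metrics[keep, , drop = FALSE]
  if (length(unique(metrics$sample_type)) < 2L) {
    stop("need at least two sample types including the reference", call. = FALSE)
  }
  metrics$sample_type <- stats::relevel(factor(metrics$sample_type),
                                        ref = reference)
  family <- rep_len(family, length(metric_cols))
  out <- list()
  for (i in seq_along(metric_cols)) {
    m <- metric_cols[i]
    df <- metrics
    df$.y <- df[[m]]
    fam <- family[i]
    if (fam == "gaussian_logit") {
      eps <- 1e-6
      df$.y <- stats::qlogis(pmin(pmax(df$.y, eps), 1 - eps))
    }
    # drop degenerate random effects (fewer than 2 levels, or one
    # observation per level, which leaves the variance unidentifiable)
    usable_re <- vapply(c("study_id", "case_id"), function(g) {
      nl <- length(unique(df[[g]]))
      nl >= 2L && nl < nrow(df)
    }, logical(1))
    re <- paste(sprintf("(1 | %s)", names(usable_re)[usable_re]),
                collapse = " + ")
    fit <- tryCatch({
      if (fam == "binomial") {
        if (is.null(trials)) stop("binomial family needs a `trials` column")
        df$.n <- df[[trials]]
        lhs <- "cbind(round(.y * .n), .n - round(.y * .n))"
        if (any(usable_re)) {
          lme4::glmer(stats::as.formula(paste(lhs, "~ sample_type +", re)),
                      data = df, family = stats::binomial())
        } else {
          stats::glm(stats::as.formula(paste(lhs, "~ sample_type")),
                     data = df, family = stats::binomial())
        }
      } else {
        if (any(usable_re)) {
          lmerTest::lmer(stats::as.formula(paste(".y ~ sample_type +", re)),
                         data = df)
        } else {
          stats::lm(.y ~ sample_type, data = df)
        }
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      out[[m]] <- data.frame(metric = m, term = NA_character_,
                             estimate = NA_real_, se = NA_real_,
                             p_value = NA_real_, singular = NA,
                             error = conditionMessage(fit),
                             stringsAsFactors = FALSE)
      next
    }
    ct <- stats::coef(summary(fit))
    pcol <- grep("^Pr\\(", colnames(ct), value = TRUE)[1]
    rows <- grepl("^sample_type", rownames(ct))
    out[[m]] <- data.frame(metric = m,
                           term = sub("^sample_type", "", rownames(ct)[rows]),
                           estimate = ct[rows, "Estimate"],
                           se = ct[rows, "Std. Error"],
                           p_value = ct[rows, pcol],
                           singular = if (inherits(fit, "merMod"))
                             lme4::isSingular(fit) else FALSE,
                           error = NA_character_,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  X <- stats::model.matrix(~sample_type, metrics)[, -1, drop = FALSE]
  vif <- variance_inflation(X)
  if (any(vif > 5, na.rm = TRUE)) {
    warning("variance inflation factor above 5 for: ",
            paste(names(vif)[vif > 5], collapse = ", "))
  }
  attr(res, "vif") <- vif
  res
}
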