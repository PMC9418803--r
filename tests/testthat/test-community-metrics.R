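# Compositional metrics: Shannon, clr, Aitchison, PCA, dysbiosis score,
# lifestyle burdens, and the mixed-model comparison against controls.

test_that("Shannon index matches closed-form values", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4))
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_error(shannon_index(c(0.5, 0.2)), "closed")
  # agreement with the vegan implementation on random profiles
  skip_if_not_installed("vegan")
  set.seed(3)
  for (i in 1:5) {
    p <- close_composition(rlnorm(30))
    expect_equal(shannon_index(p), unname(vegan::diversity(p)))
  }
})

test_that("clr transform centres and reproduces the two-part identity", {
  expect_equal(clr_transform(rep(0.2, 5)), rep(0, 5))
  expect_equal(clr_transform(c(0.9, 0.1)),
               c(log(9) / 2, -log(9) / 2))
  set.seed(4)
  for (i in 1:10) {
    p <- close_composition(c(rlnorm(20), rep(0, 5)))
    expect_equal(sum(clr_transform(p)), 0, tolerance = 1e-12)
  }
  expect_error(clr_transform(c(a = 0, b = 0) + 0), "closed|all-zero")
})

test_that("Aitchison distance is a metric", {
  set.seed(5)
  mk <- function() close_composition(setNames(rlnorm(12), paste0("s", 1:12)))
  a <- mk()
  expect_equal(aitchison_distance(a, a), 0)
  for (i in 1:10) {
    x <- mk(); y <- mk(); z <- mk()
    expect_equal(aitchison_distance(x, y), aitchison_distance(y, x))
    expect_lte(aitchison_distance(x, z),
               aitchison_distance(x, y) + aitchison_distance(y, z) + 1e-9)
  }
  expect_error(distance_to_reference(a, list()), "empty")
  expect_equal(distance_to_reference(a, list(a, a)), 0)
})

test_that("clr PCA is an isometry of the Aitchison geometry", {
  set.seed(6)
  m <- t(replicate(8, close_composition(rlnorm(15))))
  colnames(m) <- paste0("s", 1:15)
  expect_error(pca_clr(m[1, , drop = FALSE]), "at least 2")
  pc <- pca_clr(m)
  expect_equal(sum(pc$explained_variance), 1)
  # two identical samples: their score distance is 0
  m2 <- rbind(m, m[1, ])
  pc2 <- pca_clr(m2)
  expect_equal(unname(pc2$scores[1, ]), unname(pc2$scores[9, ]),
               tolerance = 1e-9)
  # full-rank scores reproduce pairwise Aitchison distances
  eps <- min(m[m > 0]) / 2
  d_scores <- as.matrix(dist(pc$scores))
  for (i in 1:4) for (j in 5:8) {
    expect_equal(d_scores[i, j],
                 aitchison_distance(m[i, ], m[j, ], pseudocount = eps),
                 tolerance = 1e-8)
  }
})

test_that("dysbiosis score behaves as a signed log-ratio", {
  p <- c(Escherichia = 0.25, Faecalibacterium = 0.25, Other = 0.5)
  expect_equal(dysbiosis_score(p, "Escherichia", "Faecalibacterium"), 0)
  p2 <- c(Faecalibacterium = 0.5, Other = 0.5)
  expect_equal(dysbiosis_score(p2, "Escherichia", "Faecalibacterium",
                               eps = 1e-6),
               log(1e-6 / (0.5 + 1e-6)))
  # monotone in the disease-positive burden; antisymmetric under swap
  p3 <- c(Escherichia = 0.4, Faecalibacterium = 0.25, Other = 0.35)
  expect_gt(dysbiosis_score(p3, "Escherichia", "Faecalibacterium"),
            dysbiosis_score(p, "Escherichia", "Faecalibacterium"))
  expect_equal(dysbiosis_score(p3, "Escherichia", "Faecalibacterium"),
               -dysbiosis_score(p3, "Faecalibacterium", "Escherichia"))
  expect_error(dysbiosis_score(p, "Escherichia", "Escherichia"), "overlap")
  cfgd <- read_dysbiosis_config()
  expect_gt(length(cfgd$up_taxa), 0)
  expect_length(intersect(cfgd$up_taxa, cfgd$down_taxa), 0)
})

test_that("lifestyle burdens sum annotated abundance", {
  cat4 <- data.frame(species_id = paste0("s", 1:4),
                     genus = "g", phylum = "p",
                     marker_length = 5000L, n_markers = 5L,
                     gram_positive = c(1L, -1L, 1L, NA),
                     spore_forming = c(-1L, -1L, 1L, 1L),
                     oxygen_tolerant = c(1L, 1L, -1L, -1L),
                     oral_habitat = c(1L, -1L, -1L, NA))
  p <- setNames(c(0.5, 0.2, 0.2, 0.1), cat4$species_id)
  lb <- lifestyle_burden(p, cat4)
  expect_equal(unname(lb["oral_abundance"]), 0.5)
  expect_equal(unname(lb["oxygen_tolerant_abundance"]), 0.7)
  expect_equal(unname(lb["spore_abundance"]), 0.3)
  expect_equal(unname(lb["unannotated_abundance"]), 0.1)
  expect_equal(unname(lifestyle_burden(p[2], cat4)["oral_abundance"]), 0)
})

test_that("metrics are invariant to species ordering", {
  set.seed(8)
  p <- close_composition(setNames(rlnorm(10), paste0("s", 1:10)))
  perm <- sample(10)
  expect_equal(shannon_index(p), shannon_index(p[perm]))
  expect_equal(aitchison_distance(p, p[perm]), 0)
})

test_that("compare_to_controls flags planted shifts but needs controls", {
  # two studies, each holding controls and post-FMT samples, so the
  # sample-type contrast is estimated within studies
  sim <- function(shift, seed) {
    withr::with_seed(seed, {
      rows <- list()
      for (s in 1:2) for (i in 1:15) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("c%d_%d", s, i), sample_type = "control",
          study_id = paste0("st", s), case_id = sprintf("cc%d_%d", s, i),
          day = NA, y = rnorm(1))
      }
      for (s in 1:2) for (i in 1:15) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("f%d_%d", s, i), sample_type = "post",
          study_id = paste0("st", s), case_id = sprintf("fc%d_%d", s, i),
          day = 30, y = rnorm(1) + shift)
      }
      do.call(rbind, rows)
    })
  }
  d <- sim(1, 90)
  expect_error(compare_to_controls(d[d$sample_type == "control", ], "y"),
               "two sample types")
  # power > 0.8 for a +1 SD shift at n = 30 per group
  hits <- vapply(1:25, function(s) {
    res <- suppressMessages(compare_to_controls(sim(1, 200 + s), "y"))
    res$p_value[res$term == "post"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
  # early post-FMT samples are excluded by the 5-day rule
  d$day[d$sample_type == "post"] <- 2
  expect_error(suppressMessages(compare_to_controls(d, "y")),
               "two sample types")
})
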