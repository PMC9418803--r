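# Profile construction, filtering, merging, consensus and TSV round trips.

test_that("build_profile handles empty, minimal and invalid tables", {
  p0 <- build_profile(data.frame(), "sp", "s", L = 50)
  expect_equal(covered_length(p0), 0)
  expect_equal(p0$L, 50)

  p1 <- build_profile(data.frame(position = 3, count_A = 10, count_C = 0,
                                 count_G = 0, count_T = 0), "sp", "s", L = 10)
  expect_equal(covered_length(p1), 1)
  expect_equal(substr(consensus_sequence(p1), 4, 4), "A")

  dup <- data.frame(position = c(1, 1), count_A = c(1, 2), count_C = 0,
                    count_G = 0, count_T = 0)
  expect_error(build_profile(dup, "sp", "s", L = 10), "duplicate")
  neg <- data.frame(position = 1, count_A = -1, count_C = 0,
                    count_G = 0, count_T = 0)
  expect_error(build_profile(neg, "sp", "s", L = 10), "negative")
  oob <- data.frame(position = 10, count_A = 1, count_C = 0,
                    count_G = 0, count_T = 0)
  expect_error(build_profile(oob, "sp", "s", L = 10), "within")
})

test_that("filtering masks thin positions and zeroes weak alleles", {
  fp <- filter_params(end_trim = 0L)
  # coverage 3 < 5: masked
  low <- profile_from_counts(matrix(c(3, 0, 0, 0), 4, 1))
  expect_equal(covered_length(filter_profile(low, fp)), 0)
  # 90/10: both alleles retained (boundary of the 10% rule)
  poly <- profile_from_counts(matrix(c(90, 10, 0, 0), 4, 1))
  f <- filter_profile(poly, fp)
  expect_equal(allele_set(f, 0), c("A", "C"))
  # 95/5: minor allele zeroed, position monomorphic
  mono <- filter_profile(profile_from_counts(matrix(c(95, 5, 0, 0), 4, 1)), fp)
  expect_equal(allele_set(mono, 0), "A")
  expect_equal(unname(mono$counts[2, 1]), 0L)
})

test_that("filtering is idempotent and monotone", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_test_profile(200)
    fp <- filter_params(end_trim = sample(0:5, 1))
    f1 <- filter_profile(p, fp)
    f2 <- filter_profile(f1, fp)
    expect_identical(f1$counts, f2$counts)
    expect_identical(f1$mask, f2$mask)
    expect_lte(covered_length(f1), covered_length(p))
    expect_true(all(f1$counts[, f1$mask] <= p$counts[, f1$mask]))
  }
})

test_that("marker-end trimming masks the boundary positions", {
  counts <- matrix(10L, 4L, 60)
  p <- profile_from_counts(counts)
  p$marker_lengths <- c(30L, 30L)
  f <- filter_profile(p, filter_params(end_trim = 5L))
  expect_false(any(f$mask[c(1:5, 26:35, 56:60)]))
  expect_true(all(f$mask[6:25]))
})

test_that("merging aligns profiles and rejects mismatches", {
  a <- flat_profile(c(1, 2, 3), sample_id = "a")
  b <- flat_profile(c(1, 2, 4), sample_id = "b")
  st <- merge_profiles(list(a))
  expect_equal(st$counts[, , 1], a$counts, ignore_attr = TRUE)
  expect_error(merge_profiles(list(a, flat_profile(c(1, 2), sample_id = "c"))),
               "mismatched")
  bad <- flat_profile(c(1, 2, 3))
  bad$species_id <- "other"
  expect_error(merge_profiles(list(a, bad)), "mix species")
  # disjoint coverage: joint covered length 0
  c1 <- profile_from_counts(matrix(c(5, 0, 0, 0, 0, 0, 0, 0), 4, 2))
  c2 <- profile_from_counts(matrix(c(0, 0, 0, 0, 5, 0, 0, 0), 4, 2))
  st2 <- merge_profiles(list(c1, c2))
  expect_equal(sum(st2$mask[, 1] & st2$mask[, 2]), 0)
})

test_that("consensus uses the fixed tie-break and N for masked positions", {
  p <- profile_from_counts(matrix(c(10, 0, 0, 0,
                                    0, 0, 0, 0,
                                    5, 5, 0, 0), 4, 3))
  expect_equal(consensus_sequence(p), "ANA")
})

test_that("profile TSV round trip is lossless, including gzip", {
  set.seed(7)
  p <- filter_profile(random_test_profile(120), filter_params(end_trim = 2))
  for (ext in c(".tsv", ".tsv.gz")) {
    path <- tempfile(fileext = ext)
    write_profile_tsv(p, path)
    q <- read_profile_tsv(path)
    expect_identical(q$counts, p$counts)
    expect_identical(q$mask, p$mask)
    expect_identical(q$sample_id, p$sample_id)
    expect_identical(q$marker_lengths, as.integer(p$marker_lengths))
    unlink(path)
  }
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("# sample_id=s", "# species_id=sp", "# L=10",
               "# marker_lengths=10", "# filtered=FALSE",
               "position\tcount_A", "oops"), bad)
  expect_error(read_profile_tsv(bad), "malformed")
  unlink(bad)
})

test_that("error-free single-strain rendering reproduces the genotype", {
  cat1 <- generate_catalog(3, seed = 2, marker_length_range = c(2000, 3000))
  g <- random_genotype(cat1$species_id[1], cat1$marker_length[1], seed = 3)
  comm <- setNames(c(1, 0, 0), cat1$species_id)
  sa <- setNames(list(list(genotypes = list(g), fractions = 1)),
                 cat1$species_id[1])
  prof <- render_sample(comm, sa, cat1, depth = 60, error_rate = 0, seed = 4)
  # zero-abundance species yield no profile
  expect_named(prof, cat1$species_id[1])
  p <- prof[[1]]
  cons <- strsplit(consensus_sequence(p), "")[[1]]
  covered <- p$mask
  expect_equal(cons[covered], c("A", "C", "G", "T")[g$alleles[covered]])
})

test_that("a 50/50 strain mixture shows both alleles at divergent sites", {
  L <- 10000
  g1 <- random_genotype("sp", L, seed = 11)
  g2 <- mutate_strain(g1, 0.01, seed = 12)
  cat1 <- data.frame(species_id = "sp", genus = "g", phylum = "p",
                     marker_length = L, n_markers = 1L,
                     gram_positive = 1L, spore_forming = 1L,
                     oxygen_tolerant = 1L, oral_habitat = 1L)
  comm <- c(sp = 1)
  sa <- list(sp = list(genotypes = list(g1, g2), fractions = c(0.5, 0.5)))
  prof <- render_sample(comm, sa, cat1, depth = 50, error_rate = 0.001,
                        seed = 13)
  p <- prof$sp
  div <- which(g1$alleles != g2$alleles & p$mask)
  both_seen <- vapply(div, function(i) {
    cc <- p$counts[, i]
    tot <- sum(cc)
    cc[g1$alleles[i]] * 10 >= tot && cc[g2$alleles[i]] * 10 >= tot
  }, logical(1))
  expect_gte(mean(both_seen), 0.95)
})
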