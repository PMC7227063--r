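test_that("configuration is validated and the seed is mandatory", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(k_alleles = 0, seed = 1), "k_alleles")
  expect_error(sim_config(n_chroms = 0, seed = 1), "at least one")
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
})

test_that("an identity allele with no noise gives a concordant graph", {
  cfg <- sim_config(k_alleles = 1, ops_per_allele = 0, n_noise_edges = 0,
                    edges_per_allele = 4, seed = 4)
  sim <- simulate_instance(cfg)
  expect_true(all(gsgtools:::is_reference_concordant(sim$gsg)))
  expect_equal(nrow(sim$truth$tsv_edges), 0)
  expect_equal(heterogeneity_fraction(sim$gsg)$fraction, 0)
})

test_that("generation is reproducible given the seed", {
  cfg <- sim_config(k_alleles = 2, ops_per_allele = 2, n_noise_edges = 3,
                    seed = 99)
  s1 <- simulate_instance(cfg)
  s2 <- simulate_instance(cfg)
  expect_identical(s1$gsg, s2$gsg)
  expect_identical(s1$truth$tsv_edges, s2$truth$tsv_edges)
})

test_that("every planted edge is concordant in its source allele", {
  withr::with_seed(1, seeds <- sample.int(1e6, 10))
  for (sd in seeds) {
    sim <- simulate_instance(sim_config(k_alleles = 2, ops_per_allele = 2,
                                        edges_per_allele = 5, seed = sd))
    pl <- sim$truth$planted
    for (r in seq_len(nrow(pl)))
      expect_true(is_concordant(pl[r, ],
                                sim$truth$arrangements[[pl$source_allele[r]]]))
  }
})

test_that("overlapping rearrangements can plant detectable conflicts", {
  # two alleles inverting overlapping runs of the same locus produce
  # conflicting edge pairs that the classifier flags
  found <- FALSE
  for (sd in 1:12) {
    sim <- simulate_instance(sim_config(segments_per_chrom = 4,
                                        k_alleles = 2, ops_per_allele = 1,
                                        edges_per_allele = 4,
                                        n_noise_edges = 0, seed = sd))
    hf <- heterogeneity_fraction(sim$gsg)
    if (hf$counts[["IN_CONFLICT"]] > 0) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("conflicted fraction rises with forced allele overlap", {
  # same locus rearranged in both alleles (overlap forced by a tiny
  # segment pool) versus alleles rearranging disjoint chromosomes
  frac_overlap <- frac_disjoint <- numeric(0)
  for (sd in 1:10) {
    ov <- simulate_instance(sim_config(n_chroms = 1, segments_per_chrom = 3,
                                       k_alleles = 2, ops_per_allele = 2,
                                       edges_per_allele = 4, seed = sd))
    frac_overlap <- c(frac_overlap,
                      heterogeneity_fraction(ov$gsg)$fraction)
    dj <- simulate_instance(sim_config(n_chroms = 1, segments_per_chrom = 3,
                                       k_alleles = 1, ops_per_allele = 2,
                                       edges_per_allele = 8, seed = sd))
    frac_disjoint <- c(frac_disjoint,
                       heterogeneity_fraction(dj$gsg)$fraction)
  }
  expect_gte(mean(frac_overlap), mean(frac_disjoint) - 0.05)
})

test_that("call evaluation applies the documented conventions", {
  sim <- simulate_instance(sim_config(k_alleles = 2, ops_per_allele = 1,
                                      edges_per_allele = 4, seed = 12))
  truth <- sim$truth
  # perfect calls
  calls <- call_tsvs(sim$gsg, truth$arrangements)
  pr <- evaluate_calls(truth, calls)
  expect_equal(pr$recall, 1.0)
  # empty calls: precision 1 by convention, recall 0 (when truth nonempty)
  empty <- calls[0, ]
  pr0 <- evaluate_calls(truth, empty)
  expect_equal(pr0$precision, 1.0)
  if (nrow(truth$tsv_edges) > 0) expect_equal(pr0$recall, 0.0)
  # extra bogus call (an adjacency never planted) lowers precision only
  truth_keys <- edge_keys(gsgtools:::canonicalise_edges(
    truth$planted[, c("id1", "end1", "id2", "end2", "weight")]))
  ids <- sim$gsg$segments$id
  cand <- expand.grid(id1 = ids, id2 = ids, stringsAsFactors = FALSE)
  cand <- cand[cand$id1 < cand$id2, ]
  cand$end1 <- "H"; cand$end2 <- "H"; cand$weight <- 1
  cand_keys <- paste0(cand$id1, ":H--", cand$id2, ":H")  # already canonical
  pick <- cand[which(!cand_keys %in% truth_keys)[1], ]
  bogus <- calls[1, ]
  bogus[, c("id1", "end1", "id2", "end2")] <-
    pick[, c("id1", "end1", "id2", "end2")]
  pr2 <- evaluate_calls(truth, rbind(calls, bogus))
  expect_equal(pr2$recall, 1.0)
  expect_lt(pr2$precision, 1.0)
})
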