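fig1 <- parse_gsg(fig1_text)

test_that("reference arrangement orders segments genomically", {
  ref <- reference_arrangement(fig1)
  expect_equal(ref$rank, c(u = 0L, v = 1L))
  expect_equal(ref$orient, c(u = 1L, v = 1L))

  seg <- data.frame(id = c("b1", "a1", "a2"), chrom = c("chr2", "chr1", "chr1"),
                    start = c(0, 100, 0), end = c(50, 200, 100))
  g <- gsg(seg, chrom_order = c("chr2", "chr1"))
  ref2 <- reference_arrangement(g)
  expect_equal(names(sort(ref2$rank)), c("b1", "a2", "a1"))

  empty <- gsg(data.frame(id = character(), chrom = character(),
                          start = numeric(), end = numeric()))
  expect_length(reference_arrangement(empty)$rank, 0)
})

test_that("concordance follows the tail-then-head rule and figure flips", {
  ref <- reference_arrangement(fig1)
  tt <- fig1$edges[fig1$edges$end1 == "T", ]
  hh <- fig1$edges[fig1$edges$end1 == "H", ]
  # both conflicting edges are discordant in the reference
  expect_false(is_concordant(tt, ref))
  expect_false(is_concordant(hh, ref))
  # flipping v makes the tail-tail edge concordant
  arr_b <- arrangement(rank = c(u = 0L, v = 1L), orient = c(u = 1L, v = 0L))
  expect_true(is_concordant(tt, arr_b))
  expect_false(is_concordant(hh, arr_b))
  # flipping u makes the head-head edge concordant
  arr_c <- arrangement(rank = c(u = 0L, v = 1L), orient = c(u = 0L, v = 1L))
  expect_true(is_concordant(hh, arr_c))
  expect_false(is_concordant(tt, arr_c))
  # a reference-like tail-head edge is concordant as-is, and the test is
  # symmetric in the stored endpoint order
  th <- data.frame(id1 = "u", end1 = "T", id2 = "v", end2 = "H")
  expect_true(is_concordant(th, ref))
  th_sw <- data.frame(id1 = "v", end1 = "H", id2 = "u", end2 = "T")
  expect_true(is_concordant(th_sw, ref))
  expect_error(is_concordant(data.frame(id1 = "q", end1 = "T",
                                        id2 = "v", end2 = "H"), ref),
               "missing")
})

test_that("objective value counts each edge once across arrangements", {
  ref <- reference_arrangement(fig1)
  arr_b <- arrangement(rank = c(u = 0L, v = 1L), orient = c(u = 1L, v = 0L))
  arr_c <- arrangement(rank = c(u = 0L, v = 1L), orient = c(u = 0L, v = 1L))
  expect_equal(objective_value(fig1, ref)$weight, 0)
  ob <- objective_value(fig1, arr_b)
  expect_equal(ob$weight, 3)
  expect_equal(ob$edges, "u:T--v:T")
  both <- objective_value(fig1, list(arr_b, arr_c))
  expect_equal(both$weight, 5)
  expect_setequal(both$edges, edge_keys(fig1$edges))
  # monotone under appending an arrangement
  expect_gte(both$weight, ob$weight)
})

test_that("reversal is an involution that preserves concordance", {
  ref <- reference_arrangement(fig1)
  rev <- reverse_arrangement(ref)
  expect_equal(rev$rank, c(u = 1L, v = 0L))
  expect_equal(rev$orient, c(u = 0L, v = 0L))
  expect_equal(reverse_arrangement(rev), ref)

  # exhaustive: all arrangements of up to 4 segments, reversal symmetry
  withr::with_seed(3, {
    g <- random_gsg(4, 6)
    perms <- gsgtools:::all_permutations(4)
    ors <- gsgtools:::orientation_grid(4)
    ids <- g$segments$id
    for (p in seq_len(nrow(perms))) {
      for (o in seq_len(nrow(ors))) {
        rank <- integer(4); rank[perms[p, ]] <- 0:3
        arr <- arrangement(stats::setNames(rank, ids),
                           stats::setNames(ors[o, ], ids))
        expect_equal(gsgtools:::concordant_mask(g, arr),
                     gsgtools:::concordant_mask(g, reverse_arrangement(arr)))
      }
    }
  })
})

test_that("concordant and discordant edges partition the edge set", {
  withr::with_seed(9, {
    for (i in 1:20) {
      g <- random_gsg(sample(3:5, 1), sample(3:8, 1))
      arr <- oracle_greedy_ends(g)
      m <- gsgtools:::concordant_mask(g, arr)
      expect_equal(sum(g$edges$weight[m]) + sum(g$edges$weight[!m]),
                   total_weight(g))
    }
  })
})

test_that("exactly one of the four placements satisfies a fixed edge", {
  seg <- three_segments()[1:2, ]
  ends <- expand.grid(a = c("H", "T"), b = c("H", "T"),
                      f_placed = 0:1, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(ends))) {
    ed <- data.frame(id1 = "u", end1 = ends$a[r],
                     id2 = "v", end2 = ends$b[r], weight = 1)
    hits <- 0
    for (pos in c("before", "after")) for (f in 0:1) {
      rank <- if (pos == "before") c(v = 0L, u = 1L) else c(u = 0L, v = 1L)
      arr <- arrangement(rank,
                         orient = c(u = as.integer(ends$f_placed[r]),
                                    v = as.integer(f)))
      hits <- hits + is_concordant(ed, arr)
    }
    expect_equal(hits, 1)
  }
})

test_that("TSV calling distinguishes rearranged, distant and spliced edges", {
  arr_b <- arrangement(rank = c(u = 0L, v = 1L), orient = c(u = 1L, v = 0L))
  arr_c <- arrangement(rank = c(u = 0L, v = 1L), orient = c(u = 0L, v = 1L))
  calls <- call_tsvs(fig1, list(arr_b, arr_c))
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$category, "REARRANGED")
  expect_setequal(calls$alleles, c("1", "2"))
  # breakpoints: H -> start, T -> end
  tt <- calls[calls$type == "TT", ]
  expect_equal(c(tt$pos1, tt$pos2), c(100, 200))
  hh <- calls[calls$type == "HH", ]
  expect_equal(c(hh$pos1, hh$pos2), c(0, 100))

  # reference-concordant cross-chromosome edge: DISTANT
  seg <- data.frame(id = c("a", "b"), chrom = c("chr1", "chr2"),
                    start = 0, end = 100)
  g2 <- gsg(seg, data.frame(id1 = "a", end1 = "T", id2 = "b", end2 = "H",
                            weight = 4))
  calls2 <- call_tsvs(g2, reference_arrangement(g2))
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$category, "DISTANT")

  # nearby same-chromosome reference edge: explained by splicing, no call
  seg3 <- data.frame(id = c("a", "b"), chrom = "chr1",
                     start = c(0, 1100), end = c(100, 1200))
  g3 <- gsg(seg3, data.frame(id1 = "a", end1 = "T", id2 = "b", end2 = "H",
                             weight = 4))
  expect_equal(nrow(call_tsvs(g3, reference_arrangement(g3),
                              max_distance = 200000)), 0)
  # but the same edge beyond the distance threshold is DISTANT
  far <- call_tsvs(g3, reference_arrangement(g3), max_distance = 500)
  expect_equal(far$category, "DISTANT")
})

test_that("BEDPE and arrangement writers emit deterministic text", {
  arr_b <- arrangement(rank = c(u = 0L, v = 1L), orient = c(u = 1L, v = 0L))
  calls <- call_tsvs(fig1, list(arr_b))
  out <- capture.output(write_bedpe(calls))
  expect_match(out, "^chr1\t100\t101\tchr1\t200\t201\tu:T--v:T\t3\tTT\tREARRANGED\t1$")
  lines <- capture.output(write_arrangements(list(arr_b)))
  expect_equal(lines, "1\tu\t-v")
})
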