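# Fixtures are generated in code; callers control the RNG (withr::with_seed).

fig1_text <- paste(
  "# two segments, two conflicting edges",
  "S\tu\tchr1\t0\t100",
  "S\tv\tchr1\t100\t200",
  "E\tu\tT\tv\tT\t3",
  "E\tu\tH\tv\tH\t2",
  sep = "\n")

three_segments <- function() {
  data.frame(id = c("u", "v", "w"), chrom = "chr1",
             start = c(0, 100, 200), end = c(100, 200, 300),
             stringsAsFactors = FALSE)
}

# Random GSG: n segments (1-kb tiling, one chromosome by default), edges
# drawn uniformly over distinct-segment endpoint pairs; duplicates merge.
random_gsg <- function(n_segments, n_edges, weight_max = 10,
                       n_chroms = 1) {
  per <- ceiling(n_segments / n_chroms)
  chrom <- rep(paste0("chr", seq_len(n_chroms)), each = per)[seq_len(n_segments)]
  idx <- stats::ave(seq_len(n_segments), chrom, FUN = seq_along)
  segments <- data.frame(
    id = paste0("s", seq_len(n_segments)), chrom = chrom,
    start = (idx - 1) * 1000, end = idx * 1000,
    stringsAsFactors = FALSE)
  pair <- replicate(n_edges, sample(segments$id, 2))
  edges <- data.frame(
    id1 = pair[1, ], end1 = sample(c("H", "T"), n_edges, replace = TRUE),
    id2 = pair[2, ], end2 = sample(c("H", "T"), n_edges, replace = TRUE),
    weight = sample.int(weight_max, n_edges, replace = TRUE),
    stringsAsFactors = FALSE)
  gsg(segments, edges)
}

# Random simple cycle in the segment-edge-augmented graph, over at most
# `max_segments` segments. Each chosen segment participates as one of:
#   "ehat"   - both endpoints joined by its segment edge,
#   "single" - one endpoint with two adjacency edges (adjacency degree 2),
#   "both"   - both endpoints as two separate adjacency-degree-2 vertices.
# Returns list(cycle = list(vertices, kinds), gsg = graph of the cycle's
# adjacency edges with unit weights). `max_pass_through` caps the number of
# vertices carrying two adjacency edges (the compatibility
# characterization's proof covers cycles with at most two such vertices).
random_simple_cycle <- function(max_segments = 5, max_pass_through = Inf) {
  repeat {
    m <- sample(2:max_segments, 1)
    ids <- paste0("s", seq_len(m))
    units <- list()
    for (i in seq_len(m)) {
      mode <- sample(c("ehat", "single", "both"), 1,
                     prob = c(0.45, 0.4, 0.15))
      if (mode == "ehat") {
        units[[length(units) + 1L]] <- list(seg = ids[i], type = "ehat")
      } else if (mode == "single") {
        units[[length(units) + 1L]] <-
          list(seg = ids[i], type = "single", end = sample(c("H", "T"), 1))
      } else {
        units[[length(units) + 1L]] <-
          list(seg = ids[i], type = "single", end = "H")
        units[[length(units) + 1L]] <-
          list(seg = ids[i], type = "single", end = "T")
      }
    }
    if (length(units) < 2) next
    units <- sample(units)
    segs <- vapply(units, `[[`, character(1), "seg")
    if (any(segs == c(segs[-1], segs[1]))) next  # within-segment E edge
    vertices <- character(0); kinds <- character(0)
    for (u in units) {
      if (u$type == "ehat") {
        ends <- sample(c("H", "T"))
        vertices <- c(vertices, paste0(u$seg, ":", ends))
        kinds <- c(kinds, "S", "E")
      } else {
        vertices <- c(vertices, paste0(u$seg, ":", u$end))
        kinds <- c(kinds, "E")
      }
    }
    # adjacency edges: between each vertex with kind "E" and the next
    nv <- length(vertices)
    epos <- which(kinds == "E")
    e_from <- vertices[epos]
    e_to <- vertices[ifelse(epos == nv, 1L, epos + 1L)]
    edges <- data.frame(
      id1 = sub(":[HT]$", "", e_from), end1 = sub("^.*:", "", e_from),
      id2 = sub(":[HT]$", "", e_to), end2 = sub("^.*:", "", e_to),
      weight = 1, stringsAsFactors = FALSE)
    kk <- apply(edges, 1, function(r) {
      a <- paste0(r[["id1"]], ":", r[["end1"]])
      b <- paste0(r[["id2"]], ":", r[["end2"]])
      paste(sort(c(a, b)), collapse = "--")
    })
    if (anyDuplicated(kk)) next  # parallel edges would merge in a GSG
    nv <- length(vertices)
    prev <- c(nv, seq_len(nv - 1))
    if (sum((kinds[prev] == "E") + (kinds == "E") == 2) > max_pass_through)
      next
    seg_df <- data.frame(id = ids, chrom = "chr1",
                         start = (seq_len(m) - 1) * 1000,
                         end = seq_len(m) * 1000, stringsAsFactors = FALSE)
    return(list(cycle = list(vertices = vertices, kinds = kinds),
                gsg = gsg(seg_df, edges)))
  }
}

# Random acyclic conflict-graph subgraph: a segment tree in which every
# segment enters with both endpoints (joined by its segment edge) and each
# new segment attaches through exactly one adjacency edge to a random
# endpoint already present. Returns a GSG of the adjacency edges.
random_segment_tree <- function(max_segments = 3) {
  m <- sample(2:max_segments, 1)
  ids <- paste0("s", seq_len(m))
  edges <- NULL
  for (i in 2:m) {
    target <- sample(ids[seq_len(i - 1)], 1)
    edges <- rbind(edges, data.frame(
      id1 = ids[i], end1 = sample(c("H", "T"), 1),
      id2 = target, end2 = sample(c("H", "T"), 1),
      weight = 1, stringsAsFactors = FALSE))
  }
  seg_df <- data.frame(id = ids, chrom = "chr1",
                       start = (seq_len(m) - 1) * 1000,
                       end = seq_len(m) * 1000, stringsAsFactors = FALSE)
  gsg(seg_df, edges)
}
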