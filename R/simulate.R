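#' Configuration for the synthetic GSG generator
#'
#' The generator emulates the graph a heterogeneous RNA-seq sample would
#' induce: a reference segmentation, k rearranged alleles derived from it
#' by inversions, moves and swaps of segment runs, read-support edges drawn
#' so as to be concordant in their source allele, and uniform noise edges.
#'
#' Defaults model a small diploid locus: one chromosome cut into five
#' 1-kb segments, two alleles each carrying one rearrangement operation,
#' four supporting adjacencies per allele with mean read support 10, and
#' no noise. Noise weights default to strictly less than the planted mean
#' so planted signal dominates; both are overridable.
#'
#' @param n_chroms number of chromosomes.
#' @param segments_per_chrom segments per chromosome (1-kb each).
#' @param k_alleles number of alleles (>= 1).
#' @param ops_per_allele rearrangement operations applied per allele.
#' @param edges_per_allele supporting edges drawn per allele.
#' @param weight_mean mean read support of planted edges (integer law,
#'   support >= 1).
#' @param n_noise_edges uniform random endpoint-pair edges added.
#' @param noise_weight_max maximum noise-edge weight.
#' @param seed mandatory integer seed; the generator is reproducible.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_chroms = 1, segments_per_chrom = 5,
                       k_alleles = 2, ops_per_allele = 1,
                       edges_per_allele = 4, weight_mean = 10,
                       n_noise_edges = 0, noise_weight_max = 3,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_chroms = n_chroms,
              segments_per_chrom = segments_per_chrom,
              k_alleles = k_alleles, ops_per_allele = ops_per_allele,
              edges_per_allele = edges_per_allele,
              weight_mean = weight_mean,
              n_noise_edges = n_noise_edges,
              noise_weight_max = noise_weight_max,
              seed = as.integer(seed))
  if (cfg$k_alleles < 1) stop("k_alleles must be >= 1")
  if (any(unlist(cfg[c("n_chroms", "segments_per_chrom",
                       "ops_per_allele", "edges_per_allele",
                       "n_noise_edges")]) < 0))
    stop("counts must be nonnegative")
  if (cfg$n_chroms < 1 || cfg$segments_per_chrom < 1)
    stop("need at least one chromosome with one segment")
  structure(cfg, class = "sim_config")
}

# --- rearrangement operations on an arrangement ------------------------

# An allele is carried as (ids in rank order, orient named vector).
op_invert <- function(ord, orient) {
  n <- length(ord$ids)
  if (n < 1) return(ord)
  i <- sample.int(n, 1); j <- min(n, i + sample.int(max(1, n - i + 1), 1) - 1L)
  run <- i:j
  ord$ids[run] <- rev(ord$ids[run])
  orient[ord$ids[run]] <- 1L - orient[ord$ids[run]]
  ord$orient <- orient
  ord
}

op_move <- function(ord, orient) {
  n <- length(ord$ids)
  if (n < 2) { ord$orient <- orient; return(ord) }
  i <- sample.int(n, 1); j <- min(n, i + sample.int(max(1, n - i + 1), 1) - 1L)
  run <- ord$ids[i:j]
  rest <- ord$ids[-(i:j)]
  pos <- sample.int(length(rest) + 1L, 1) - 1L
  ord$ids <- append(rest, run, after = pos)
  ord$orient <- orient
  ord
}

op_swap <- function(ord, orient) {
  n <- length(ord$ids)
  if (n < 2) { ord$orient <- orient; return(ord) }
  picks <- sort(sample.int(n, 2))
  ord$ids[picks] <- ord$ids[rev(picks)]
  ord$orient <- orient
  ord
}

apply_random_ops <- function(ids, n_ops) {
  ord <- list(ids = ids,
              orient = stats::setNames(rep(1L, length(ids)), ids))
  for (i in seq_len(n_ops)) {
    op <- sample(c("invert", "move", "swap"), 1)
    ord <- switch(op,
                  invert = op_invert(ord, ord$orient),
                  move = op_move(ord, ord$orient),
                  swap = op_swap(ord, ord$orient))
  }
  arrangement(rank = stats::setNames(seq_along(ord$ids) - 1L, ord$ids),
              orient = ord$orient)
}

# Draw one edge concordant in `arr`: pick an ordered segment pair
# (adjacent in the arrangement with probability p_adjacent, else any
# ordered pair, modelling splicing across intervening segments) and take
# the facing ends dictated by the orientations.
sample_concordant_edge <- function(arr, p_adjacent = 0.7) {
  ids <- names(sort(arr$rank))
  n <- length(ids)
  if (n < 2) stop("need at least two segments to draw an edge")
  if (n == 2 || stats::runif(1) < p_adjacent) {
    i <- sample.int(n - 1L, 1); j <- i + 1L
  } else {
    pick <- sort(sample.int(n, 2)); i <- pick[1]; j <- pick[2]
  }
  u <- ids[i]; v <- ids[j]
  data.frame(id1 = u,
             end1 = if (arr$orient[[u]] == 1L) "T" else "H",
             id2 = v,
             end2 = if (arr$orient[[v]] == 1L) "H" else "T",
             weight = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate a GSG instance with planted alleles and known truth
#'
#' Builds the reference segmentation, derives each allele from the
#' reference arrangement by seeded random rearrangement operations, draws
#' per-allele edges guaranteed concordant in their source allele (asserted
#' at generation time), adds uniform noise edges, and returns the merged
#' graph together with the ground truth: the planted arrangements, the
#' planted edges that are reference-discordant (the true TSVs), and each
#' planted edge's source allele.
#'
#' @param config a [sim_config()].
#' @return list with `gsg` and `truth` (list: `arrangements`,
#'   `tsv_edges` data.frame with `source_allele`, `planted` all planted
#'   edges).
#' @export
simulate_instance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_seg_total <- config$n_chroms * config$segments_per_chrom
  if (config$edges_per_allele > 0 && n_seg_total < 2)
    stop("cannot draw edges on a graph with fewer than two segments")
  withr::with_seed(config$seed, {
    seg_len <- 1000
    segments <- do.call(rbind, lapply(seq_len(config$n_chroms), function(c) {
      k <- config$segments_per_chrom
      data.frame(id = sprintf("s%d_%d", c, seq_len(k)),
                 chrom = sprintf("chr%d", c),
                 start = (seq_len(k) - 1) * seg_len,
                 end = seq_len(k) * seg_len,
                 stringsAsFactors = FALSE)
    }))
    base <- gsg(segments)
    ref_ids <- default_order(base)

    arrs <- lapply(seq_len(config$k_alleles), function(i)
      apply_random_ops(ref_ids, config$ops_per_allele))

    planted <- list()
    for (i in seq_len(config$k_alleles)) {
      for (r in seq_len(config$edges_per_allele)) {
        ed <- sample_concordant_edge(arrs[[i]])
        ed$weight <- max(1, stats::rpois(1, config$weight_mean))
        ed$source_allele <- i
        planted[[length(planted) + 1L]] <- ed
      }
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(id1 = character(), end1 = character(),
                 id2 = character(), end2 = character(),
                 weight = numeric(), source_allele = integer())

    noise <- list()
    for (r in seq_len(config$n_noise_edges)) {
      pick <- sample(segments$id, 2)
      noise[[r]] <- data.frame(
        id1 = pick[1], end1 = sample(c("H", "T"), 1),
        id2 = pick[2], end2 = sample(c("H", "T"), 1),
        weight = sample.int(config$noise_weight_max, 1),
        stringsAsFactors = FALSE)
    }
    noise <- if (length(noise)) do.call(rbind, noise) else NULL

    all_edges <- rbind(planted[, c("id1", "end1", "id2", "end2", "weight")],
                       noise)
    g <- gsg(segments, all_edges)

    # construction soundness: every planted edge concordant in its allele
    for (r in seq_len(nrow(planted))) {
      if (!is_concordant(planted[r, ], arrs[[planted$source_allele[r]]]))
        stop("internal error: planted edge discordant in source allele")
    }

    ref_conc <- if (nrow(planted)) {
      # map planted rows to canonical keys, then to reference concordance
      pk <- row_edge_keys(planted)
      rc <- is_reference_concordant(g)
      unname(stats::setNames(rc, edge_keys(g$edges))[pk])
    } else logical(0)
    tsv_edges <- planted[!ref_conc, , drop = FALSE]
    rownames(tsv_edges) <- NULL

    list(gsg = g,
         truth = list(arrangements = arrs, tsv_edges = tsv_edges,
                      planted = planted))
  })
}

#' Precision and recall of TSV calls against simulated truth
#'
#' Calls are matched to planted true TSV edges by exact breakpoint-pair
#' identity (unordered pair of segment-id/end endpoints); allele phasing is
#' ignored since equivalent phasings abound. With no calls, precision is
#' reported as 1 by convention; with no true TSVs, recall is 1.
#'
#' @param truth the `truth` element of [simulate_instance()] output.
#' @param calls data.frame from [call_tsvs()].
#' @return list with `precision` and `recall` in `[0, 1]`.
#' @export
evaluate_calls <- function(truth, calls) {
  truth_keys <- unique(if (nrow(truth$tsv_edges))
    row_edge_keys(truth$tsv_edges) else character(0))
  call_keys <- unique(if (NROW(calls))
    row_edge_keys(calls) else character(0))
  precision <- if (length(call_keys) == 0) 1 else
    mean(call_keys %in% truth_keys)
  recall <- if (length(truth_keys) == 0) 1 else
    mean(truth_keys %in% call_keys)
  list(precision = precision, recall = recall)
}
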