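#' Arrangements of genome segments
#'
#' An arrangement models one allele's rearranged genome: a permutation of all
#' segments (`rank`, 0-based) plus a per-segment orientation bit (`orient`,
#' 1 = original orientation, 0 = inverted). An arrangement set is an ordered
#' list of k arrangements over the same segments.
#'
#' @param rank named integer vector; a bijection onto `0:(n-1)`.
#' @param orient named integer vector over the same names, values in `{0,1}`.
#' @return object of class `"arrangement"`.
#' @export
arrangement <- function(rank, orient) {
  rank <- stats::setNames(as.integer(rank), names(rank))
  orient <- stats::setNames(as.integer(orient), names(orient))
  n <- length(rank)
  if (!setequal(names(rank), names(orient)) || length(orient) != n)
    stop("rank and orient must cover the same segment ids")
  if (n > 0 && !setequal(rank, 0:(n - 1)))
    stop("rank must be a bijection onto 0..n-1")
  if (any(!orient %in% c(0L, 1L)))
    stop("orient values must be 0 or 1")
  structure(list(rank = rank, orient = orient[names(rank)]),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  ids <- names(sort(x$rank))
  signs <- ifelse(x$orient[ids] == 1L, "", "-")
  cat("Arrangement:", paste0(signs, ids, collapse = " "), "\n")
  invisible(x)
}

#' Format an arrangement as signed segment ids in rank order
#'
#' A minus sign marks an inverted segment (`orient == 0`).
#' @param arr an [arrangement()].
#' @return character vector of signed segment ids.
#' @export
arrangement_signed_ids <- function(arr) {
  ids <- names(sort(arr$rank))
  paste0(ifelse(arr$orient[ids] == 1L, "", "-"), ids)
}

#' The reference arrangement of a GSG
#'
#' Segments in genomic order (chromosome order, then start coordinate), all
#' in original orientation. This encodes the unrearranged genome baseline
#' against which TSVs are defined.
#'
#' @param x a [gsg()] object.
#' @return an [arrangement()].
#' @export
reference_arrangement <- function(x) {
  stopifnot(inherits(x, "gsg"))
  s <- x$segments
  ord <- order(match(s$chrom, x$chrom_order), s$start)
  ids <- s$id[ord]
  arrangement(rank = stats::setNames(seq_along(ids) - 1L, ids),
              orient = stats::setNames(rep(1L, length(ids)), ids))
}

#' Reverse an arrangement
#'
#' Reverses the segment order and flips every orientation. The reverse of an
#' arrangement describes the same double-stranded molecule read from the
#' other end, so it leaves every edge's concordance unchanged; reversal is
#' an involution.
#'
#' @param arr an [arrangement()].
#' @return an [arrangement()].
#' @export
reverse_arrangement <- function(arr) {
  n <- length(arr$rank)
  arrangement(rank = n - 1L - arr$rank, orient = 1L - arr$orient)
}

#' Edge concordance under an arrangement
#'
#' An edge joining segment `u` on end `a` and segment `v` on end `b`
#' (with `rank(u) < rank(v)`) is concordant iff `orient(u) = [a = T]` and
#' `orient(v) = [b = H]`: reading the arranged genome 5' to 3' must leave
#' `u`'s connecting end as a tail and `v`'s as a head. The test is symmetric
#' in the edge's endpoint order.
#'
#' @param edge a one-row edge data.frame (columns `id1,end1,id2,end2`) or a
#'   list with those fields.
#' @param arr an [arrangement()] covering both segments.
#' @return logical scalar.
#' @export
is_concordant <- function(edge, arr) {
  u <- edge$id1; a <- edge$end1; v <- edge$id2; b <- edge$end2
  ru <- arr$rank[u]; rv <- arr$rank[v]
  if (is.na(ru) || is.na(rv))
    stop("edge endpoint segment missing from arrangement")
  if (ru > rv) { tmp <- u; u <- v; v <- tmp; tmp <- a; a <- b; b <- tmp }
  (arr$orient[[u]] == as.integer(a == "T")) &&
    (arr$orient[[v]] == as.integer(b == "H"))
}

# Vectorised concordance of all edges of a gsg under one arrangement.
concordant_mask <- function(x, arr) {
  e <- x$edges
  if (nrow(e) == 0) return(logical(0))
  ru <- arr$rank[e$id1]; rv <- arr$rank[e$id2]
  if (anyNA(ru) || anyNA(rv))
    stop("arrangement does not cover all edge endpoints")
  swap <- ru > rv
  u <- ifelse(swap, e$id2, e$id1)
  v <- ifelse(swap, e$id1, e$id2)
  a <- ifelse(swap, e$end2, e$end1)
  b <- ifelse(swap, e$end1, e$end2)
  unname((arr$orient[u] == as.integer(a == "T")) &
           (arr$orient[v] == as.integer(b == "H")))
}

#' The MCAP objective value of an arrangement set
#'
#' Sums the weight of edges concordant in *at least one* of the k
#' arrangements; each edge counts once however many arrangements satisfy it.
#'
#' @param x a [gsg()] object.
#' @param arrs a single [arrangement()] or a list of arrangements over the
#'   graph's segments.
#' @return list with `weight` (numeric) and `edges` (character vector of
#'   satisfied edge keys).
#' @export
objective_value <- function(x, arrs) {
  stopifnot(inherits(x, "gsg"))
  if (inherits(arrs, "arrangement")) arrs <- list(arrs)
  sat <- rep(FALSE, nrow(x$edges))
  for (arr in arrs) sat <- sat | concordant_mask(x, arr)
  list(weight = sum(x$edges$weight[sat]), edges = edge_keys(x$edges)[sat])
}

# Reference concordance used for TSV categories and conflict labelling:
# an edge "agrees with the reference genome" only if both endpoints are on
# the same chromosome *and* the edge is concordant under the reference
# arrangement. Cross-chromosome adjacencies always surface as TSVs.
is_reference_concordant <- function(x, ref = reference_arrangement(x)) {
  e <- x$edges
  ch <- x$segments$chrom[match(e$id1, x$segments$id)] ==
    x$segments$chrom[match(e$id2, x$segments$id)]
  ch & concordant_mask(x, ref)
}

# Genomic gap between two segments on the same chromosome: start of the
# later minus end of the earlier; Inf across chromosomes.
segment_gap <- function(x, id1, id2) {
  s <- x$segments
  i <- match(id1, s$id); j <- match(id2, s$id)
  ifelse(s$chrom[i] != s$chrom[j], Inf,
         pmax(s$start[i], s$start[j]) - pmin(s$end[i], s$end[j]))
}

#' Call transcriptomic structural variants from a solved arrangement set
#'
#' A TSV is a novel transcript adjacency not explainable by alternative
#' splicing. Qualifying edges must be concordant in at least one solution
#' arrangement and fall in one of two categories: `REARRANGED` — discordant
#' under the reference arrangement (the adjacency exists only in a
#' rearranged allele); `DISTANT` — concordant under the reference order as
#' well, but joining segments on different chromosomes or separated by a
#' genomic gap larger than `max_distance` (too far to be a splicing event).
#' Edges concordant in the reference and nearby are not called.
#'
#' Breakpoint coordinates: an `H` endpoint maps to the segment's start, a
#' `T` endpoint to the segment's end. All arrangement indices satisfying an
#' edge are reported in `alleles` (phasings are generally non-unique).
#'
#' @param x a [gsg()] object.
#' @param arrs a list of solution [arrangement()]s (or one arrangement).
#' @param max_distance genomic gap (bp) beyond which a reference-concordant
#'   adjacency is called `DISTANT`; default 200000.
#' @return data.frame with one row per call: breakpoints, connection type,
#'   weight, category and supporting allele indices (comma-separated), plus
#'   the underlying edge identity columns.
#' @export
call_tsvs <- function(x, arrs, max_distance = 200000) {
  stopifnot(inherits(x, "gsg"), max_distance > 0)
  if (inherits(arrs, "arrangement")) arrs <- list(arrs)
  e <- x$edges
  empty <- data.frame(
    chrom1 = character(), pos1 = numeric(), bpend1 = character(),
    chrom2 = character(), pos2 = numeric(), bpend2 = character(),
    name = character(), weight = numeric(), type = character(),
    category = character(), alleles = character(),
    id1 = character(), end1 = character(), id2 = character(),
    end2 = character(), stringsAsFactors = FALSE)
  if (nrow(e) == 0) return(empty)
  masks <- vapply(arrs, function(a) concordant_mask(x, a),
                  logical(nrow(e)))
  masks <- matrix(masks, nrow = nrow(e))
  sat_any <- rowSums(masks) > 0
  ref <- reference_arrangement(x)
  ref_def3 <- concordant_mask(x, ref)
  gap <- segment_gap(x, e$id1, e$id2)
  same_chr <- is.finite(gap)
  rearranged <- sat_any & !ref_def3
  distant <- sat_any & ref_def3 & (!same_chr | gap > max_distance)
  keep <- which(rearranged | distant)
  if (!length(keep)) return(empty)
  s <- x$segments
  bp_pos <- function(id, end) {
    i <- match(id, s$id)
    ifelse(end == "H", s$start[i], s$end[i])
  }
  out <- data.frame(
    chrom1 = s$chrom[match(e$id1[keep], s$id)],
    pos1 = bp_pos(e$id1[keep], e$end1[keep]),
    bpend1 = e$end1[keep],
    chrom2 = s$chrom[match(e$id2[keep], s$id)],
    pos2 = bp_pos(e$id2[keep], e$end2[keep]),
    bpend2 = e$end2[keep],
    name = edge_keys(e)[keep],
    weight = e$weight[keep],
    type = paste0(e$end1[keep], e$end2[keep]),
    category = ifelse(rearranged[keep], "REARRANGED", "DISTANT"),
    alleles = vapply(keep, function(i)
      paste(which(masks[i, ]), collapse = ","), character(1)),
    id1 = e$id1[keep], end1 = e$end1[keep],
    id2 = e$id2[keep], end2 = e$end2[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write TSV calls as BEDPE
#'
#' Each breakpoint becomes a 1-bp half-open interval. Columns: chrom1,
#' start1, end1, chrom2, start2, end2, name, score (read support), end-type
#' pair, category, allele list.
#'
#' @param calls output of [call_tsvs()].
#' @param con file path or connection.
#' @export
write_bedpe <- function(calls, con = stdout()) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%g\t%s\t%s\t%s",
                   calls$chrom1, as.integer(calls$pos1),
                   as.integer(calls$pos1) + 1L,
                   calls$chrom2, as.integer(calls$pos2),
                   as.integer(calls$pos2) + 1L,
                   calls$name, calls$weight, calls$type,
                   calls$category, calls$alleles)
  writeLines(lines, con)
  invisible(calls)
}

#' Write arrangements, one per line
#'
#' Line format: allele index, then signed segment ids in rank order
#' (`-` marks inverted orientation).
#'
#' @param arrs list of [arrangement()]s.
#' @param con file path or connection.
#' @export
write_arrangements <- function(arrs, con = stdout()) {
  if (inherits(arrs, "arrangement")) arrs <- list(arrs)
  lines <- vapply(seq_along(arrs), function(i)
    paste(c(i, arrangement_signed_ids(arrs[[i]])), collapse = "\t"),
    character(1))
  writeLines(lines, con)
  invisible(arrs)
}
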