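#' Construct a genome segment graph
#'
#' A genome segment graph (GSG) is a weighted undirected graph whose vertices
#' are the head (5'-proximal) and tail (3'-proximal) endpoints of genomic
#' segments, and whose edges record read-supported adjacencies between
#' endpoints of two *different* segments. Edge weight is the number of
#' supporting reads. Segments partition each chromosome into disjoint
#' intervals (0-based, half-open coordinates).
#'
#' Duplicate edges (same unordered endpoint pair) are merged by summing their
#' weights, so the graph holds at most one edge per endpoint pair.
#'
#' @param segments data.frame with columns `id` (character, unique), `chrom`
#'   (character), `start`, `end` (numeric, 0-based half-open, `start < end`).
#' @param edges data.frame with columns `id1`, `end1`, `id2`, `end2`,
#'   `weight`; `end1`/`end2` are `"H"` or `"T"`. May have zero rows.
#' @param chrom_order character vector of chromosome names; defaults to
#'   first-appearance order in `segments`.
#' @return An object of class `"gsg"`: a list with elements `segments`,
#'   `edges` (canonicalised, merged) and `chrom_order`.
#' @examples
#' g <- gsg(
#'   segments = data.frame(id = c("u", "v"), chrom = "chr1",
#'                         start = c(0, 100), end = c(100, 200)),
#'   edges = data.frame(id1 = c("u", "u"), end1 = c("T", "H"),
#'                      id2 = c("v", "v"), end2 = c("T", "H"),
#'                      weight = c(3, 2))
#' )
#' total_weight(g)
#' @export
gsg <- function(segments, edges = NULL, chrom_order = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end")
  if (!all(need %in% names(segments)))
    stop("segments must have columns id, chrom, start, end")
  segments$id <- as.character(segments$id)
  segments$chrom <- as.character(segments$chrom)
  segments$start <- as.numeric(segments$start)
  segments$end <- as.numeric(segments$end)
  if (anyDuplicated(segments$id))
    stop("segment ids must be unique within a GSG")
  if (any(!(segments$start < segments$end)))
    stop("every segment must satisfy start < end")
  # disjointness per chromosome
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments on chromosome ", ch)
  }
  if (is.null(chrom_order)) chrom_order <- unique(segments$chrom)
  if (!setequal(chrom_order, unique(segments$chrom)) && nrow(segments) > 0)
    stop("chrom_order must name exactly the chromosomes present")

  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(id1 = character(), end1 = character(),
                        id2 = character(), end2 = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    neede <- c("id1", "end1", "id2", "end2", "weight")
    if (!all(neede %in% names(edges)))
      stop("edges must have columns id1, end1, id2, end2, weight")
    edges$id1 <- as.character(edges$id1)
    edges$id2 <- as.character(edges$id2)
    edges$end1 <- toupper(as.character(edges$end1))
    edges$end2 <- toupper(as.character(edges$end2))
    edges$weight <- as.numeric(edges$weight)
    if (!all(edges$end1 %in% c("H", "T")) || !all(edges$end2 %in% c("H", "T")))
      stop("edge ends must be 'H' or 'T'")
    bad <- setdiff(c(edges$id1, edges$id2), segments$id)
    if (length(bad))
      stop("edge endpoint references unknown segment(s): ",
           paste(bad, collapse = ", "))
    if (any(edges$id1 == edges$id2))
      stop("within-segment edges are not allowed")
    if (any(edges$weight < 0)) stop("edge weights must be nonnegative")
    edges <- canonicalise_edges(edges)
  }
  structure(list(segments = segments, edges = edges,
                 chrom_order = chrom_order),
            class = "gsg")
}

# Orders each edge's endpoints canonically (lexicographic on "id:end" keys)
# and merges duplicate unordered endpoint pairs by summing weights.
canonicalise_edges <- function(edges) {
  k1 <- paste0(edges$id1, ":", edges$end1)
  k2 <- paste0(edges$id2, ":", edges$end2)
  swap <- k2 < k1
  if (any(swap)) {
    tmp <- edges[swap, c("id1", "end1")]
    edges[swap, c("id1", "end1")] <- edges[swap, c("id2", "end2")]
    edges[swap, c("id2", "end2")] <- tmp
  }
  key <- edge_keys(edges)
  if (anyDuplicated(key)) {
    w <- tapply(edges$weight, key, sum)
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$weight <- as.numeric(w[edge_keys(edges)])
  }
  edges <- edges[order(edge_keys(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Canonical string keys for GSG edges
#'
#' @param edges an edge data.frame (as stored in a [gsg()] object).
#' @return character vector, one key per edge (`"id1:end1--id2:end2"`).
#' @export
edge_keys <- function(edges) {
  paste0(edges$id1, ":", edges$end1, "--", edges$id2, ":", edges$end2)
}

# Row-wise canonical keys for possibly non-canonical edge rows; preserves
# row order (unlike canonicalise_edges, which sorts and merges).
row_edge_keys <- function(edges) {
  k1 <- paste0(edges$id1, ":", edges$end1)
  k2 <- paste0(edges$id2, ":", edges$end2)
  ifelse(k1 <= k2, paste0(k1, "--", k2), paste0(k2, "--", k1))
}

#' @export
print.gsg <- function(x, ...) {
  cat(sprintf("Genome segment graph: %d segments on %d chromosome(s), %d edges (total weight %g)\n",
              nrow(x$segments), length(x$chrom_order), nrow(x$edges),
              total_weight(x)))
  invisible(x)
}

#' Read a genome segment graph from its plain-text format
#'
#' The format is line-based and whitespace separated; `#` starts a comment.
#' Segment records are `S <id> <chrom> <start> <end>` and edge records are
#' `E <id1> <H|T> <id2> <H|T> <weight>`. Chromosome order is taken from
#' first appearance. Duplicate edge lines are merged by summing weights.
#'
#' @param con a file path or connection.
#' @return A [gsg()] object.
#' @export
read_gsg <- function(con) {
  lines <- readLines(con)
  lines_raw <- sub("#.*$", "", lines)
  seg <- list(); edg <- list()
  for (i in seq_along(lines_raw)) {
    ln <- trimws(lines_raw[[i]])
    if (!nzchar(ln)) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[[1]] == "S") {
      if (length(f) != 5)
        stop("malformed segment record at line ", i)
      st <- suppressWarnings(as.numeric(f[[4]]))
      en <- suppressWarnings(as.numeric(f[[5]]))
      if (is.na(st) || is.na(en))
        stop("malformed segment coordinates at line ", i)
      seg[[length(seg) + 1L]] <- data.frame(
        id = f[[2]], chrom = f[[3]], start = st, end = en,
        stringsAsFactors = FALSE)
    } else if (f[[1]] == "E") {
      if (length(f) != 6)
        stop("malformed edge record at line ", i)
      w <- suppressWarnings(as.numeric(f[[6]]))
      if (is.na(w)) stop("malformed edge weight at line ", i)
      edg[[length(edg) + 1L]] <- data.frame(
        id1 = f[[2]], end1 = f[[3]], id2 = f[[4]], end2 = f[[5]],
        weight = w, stringsAsFactors = FALSE)
    } else {
      stop("unknown record type '", f[[1]], "' at line ", i)
    }
  }
  segments <- if (length(seg)) do.call(rbind, seg) else
    data.frame(id = character(), chrom = character(),
               start = numeric(), end = numeric())
  edges <- if (length(edg)) do.call(rbind, edg) else NULL
  gsg(segments, edges)
}

#' @rdname read_gsg
#' @param text a character scalar holding the whole file content.
#' @export
parse_gsg <- function(text) read_gsg(textConnection(text))

#' Write a genome segment graph in the plain-text format
#'
#' Segments are emitted sorted by (chromosome order, start); edges follow in
#' canonical lexicographic endpoint-key order, so output is deterministic.
#'
#' @param x a [gsg()] object.
#' @param con a file path or connection; defaults to stdout.
#' @export
write_gsg <- function(x, con = stdout()) {
  stopifnot(inherits(x, "gsg"))
  s <- x$segments
  s <- s[order(match(s$chrom, x$chrom_order), s$start), , drop = FALSE]
  out <- c(
    sprintf("S\t%s\t%s\t%s\t%s", s$id, s$chrom,
            format(s$start, scientific = FALSE, trim = TRUE),
            format(s$end, scientific = FALSE, trim = TRUE)),
    sprintf("E\t%s\t%s\t%s\t%s\t%g", x$edges$id1, x$edges$end1,
            x$edges$id2, x$edges$end2, x$edges$weight)
  )
  writeLines(out, con)
  invisible(x)
}

#' Total weight of a GSG edge subset
#'
#' The weight of an edge set is the sum of its per-edge read supports;
#' it is additive over disjoint subsets.
#'
#' @param x a [gsg()] object.
#' @param subset optional: edge data.frame, or character vector of edge keys
#'   (see [edge_keys()]), or logical/integer index into `x$edges`. Default:
#'   all edges.
#' @return nonnegative numeric scalar.
#' @export
total_weight <- function(x, subset = NULL) {
  stopifnot(inherits(x, "gsg"))
  if (is.null(subset)) return(sum(x$edges$weight))
  keys <- edge_keys(x$edges)
  if (is.data.frame(subset)) subset <- edge_keys(canonicalise_edges(subset))
  if (is.character(subset)) {
    if (!all(subset %in% keys))
      stop("subset contains edges not present in the graph")
    idx <- match(subset, keys)
  } else idx <- subset
  sum(x$edges$weight[idx])
}

#' Split a GSG into connected components
#'
#' Components are computed over the segment-level adjacency induced by the
#' edges (two segments are adjacent if any edge joins their endpoints).
#' Segments with no incident edge each form a singleton component.
#' Components are returned ordered by genomic position of their first
#' segment, and their union reconstructs the input graph.
#'
#' @param x a [gsg()] object.
#' @return list of `gsg` objects.
#' @export
gsg_components <- function(x) {
  stopifnot(inherits(x, "gsg"))
  n <- nrow(x$segments)
  if (n == 0) return(list())
  gr <- igraph::graph_from_data_frame(
    d = data.frame(from = x$edges$id1, to = x$edges$id2),
    directed = FALSE,
    vertices = data.frame(name = x$segments$id))
  memb <- igraph::components(gr)$membership[x$segments$id]
  # order components genomically by their first segment
  s <- x$segments
  ord <- order(match(s$chrom, x$chrom_order), s$start)
  comp_order <- unique(memb[ord])
  lapply(comp_order, function(cid) {
    ids <- s$id[memb == cid]
    seg <- s[s$id %in% ids, , drop = FALSE]
    edg <- x$edges[x$edges$id1 %in% ids & x$edges$id2 %in% ids, , drop = FALSE]
    gsg(seg, edg, chrom_order = intersect(x$chrom_order, unique(seg$chrom)))
  })
}

# The two-segment, two-conflicting-edge example graph used throughout the
# documentation and tests: segments u=[0,100) and v=[100,200) on chr1 with a
# tail-tail edge of weight 3 and a head-head edge of weight 2. Neither edge
# is concordant with the reference order, and no single arrangement can
# satisfy both.
#' Small worked-example graph with two conflicting edges
#'
#' @return a [gsg()] with 2 segments and 2 mutually conflicting edges
#'   (tail-tail weight 3, head-head weight 2).
#' @export
example_conflict_gsg <- function() {
  gsg(
    segments = data.frame(id = c("u", "v"), chrom = "chr1",
                          start = c(0, 100), end = c(100, 200),
                          stringsAsFactors = FALSE),
    edges = data.frame(id1 = c("u", "u"), end1 = c("T", "H"),
                       id2 = c("v", "v"), end2 = c("T", "H"),
                       weight = c(3, 2), stringsAsFactors = FALSE))
}
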