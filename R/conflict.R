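#' Conflict graph: GSG plus segment edges
#'
#' For conflict analysis the graph is augmented with one *segment edge* per
#' segment joining its own head and tail endpoints; these form a perfect
#' matching on the endpoint vertices. Adjacency edges keep their identity
#' (`kind = "E"`), segment edges are `kind = "S"`. Edge weights are ignored
#' here: conflict structure is a purely topological notion.
#'
#' @param x a [gsg()] object.
#' @return object of class `"conflict_graph"`: the base graph plus an
#'   adjacency index over endpoint vertices (`"id:H"` / `"id:T"`).
#' @export
conflict_graph <- function(x) {
  stopifnot(inherits(x, "gsg"))
  ids <- x$segments$id
  verts <- c(paste0(ids, ":H"), paste0(ids, ":T"))
  adj <- stats::setNames(
    lapply(verts, function(v)
      data.frame(to = character(), kind = character(), eidx = integer(),
                 stringsAsFactors = FALSE)),
    verts)
  push <- function(a, b, kind, eidx) {
    adj[[a]] <<- rbind(adj[[a]],
                       data.frame(to = b, kind = kind, eidx = eidx,
                                  stringsAsFactors = FALSE))
  }
  e <- x$edges
  for (j in seq_len(nrow(e))) {
    a <- paste0(e$id1[j], ":", e$end1[j])
    b <- paste0(e$id2[j], ":", e$end2[j])
    push(a, b, "E", j)
    push(b, a, "E", j)
  }
  for (id in ids) {
    push(paste0(id, ":H"), paste0(id, ":T"), "S", NA_integer_)
    push(paste0(id, ":T"), paste0(id, ":H"), "S", NA_integer_)
  }
  # canonical neighbour order for deterministic first-attempt DFS
  adj <- lapply(adj, function(d) d[order(d$to, d$kind), , drop = FALSE])
  structure(list(gsg = x, adj = adj), class = "conflict_graph")
}

vertex_segment <- function(v) sub(":[HT]$", "", v)

#' Cycle compatibility test
#'
#' A simple cycle (alternating arbitrarily between adjacency edges and
#' segment edges) can have all of its adjacency edges made concordant by a
#' single arrangement if and only if exactly two of its vertices have
#' adjacency-edge degree 2 within the cycle and those two vertices lie on
#' different segments. Intuitively: a satisfying arrangement reads the
#' cycle as a 5'-to-3' walk, which must enter and leave the cycle's
#' extremes through adjacency edges at two distinct segments; any other
#' degree pattern forces some adjacency to point the wrong way.
#'
#' @param cycle list with `vertices` (character vector of endpoint vertices
#'   `"id:H"`/`"id:T"`, each exactly once; the cycle closes from the last
#'   back to the first) and `kinds` (character vector, same length;
#'   `kinds[i]` is `"E"` or `"S"` for the edge from `vertices[i]` to the
#'   next vertex).
#' @return logical: `TRUE` if compatible.
#' @export
is_cycle_compatible <- function(cycle) {
  v <- cycle$vertices
  kinds <- cycle$kinds
  m <- length(v)
  if (m < 2 || length(kinds) != m)
    stop("cycle must give one edge kind per vertex")
  if (anyDuplicated(v)) stop("cycle is not simple")
  # vertex i touches cycle edges i-1 (cyclic) and i
  prev <- c(m, seq_len(m - 1))
  degE <- (kinds[prev] == "E") + (kinds == "E")
  hot <- which(degE == 2)
  length(hot) == 2 &&
    vertex_segment(v[hot[1]]) != vertex_segment(v[hot[2]])
}

# One bounded DFS enumeration of simple paths from `from` to `to` avoiding
# adjacency edge `skip_eidx`. Closes each found path with that edge and
# tests cycle compatibility. Returns:
#   list(outcome = "IN_CONFLICT", witness = cycle)  on first bad cycle
#   list(outcome = "NOT_IN_CONFLICT")               if enumeration finishes
#   list(outcome = "TIMEOUT")                       if wall clock exceeded
dfs_attempt <- function(adj, from, to, skip_eidx, timeout,
                        shuffle_seed = NULL) {
  if (timeout <= 0) return(list(outcome = "TIMEOUT"))
  if (!is.null(shuffle_seed)) {
    adj <- withr::with_seed(shuffle_seed,
      lapply(adj, function(d) d[sample(nrow(d)), , drop = FALSE]))
  }
  t0 <- proc.time()[["elapsed"]]
  result <- NULL
  path <- character(0)
  kinds <- character(0)
  visited <- new.env(parent = emptyenv())
  recurse <- function(v) {
    if (!is.null(result)) return()
    if (proc.time()[["elapsed"]] - t0 > timeout) {
      result <<- list(outcome = "TIMEOUT")
      return()
    }
    path[length(path) + 1L] <<- v
    assign(v, TRUE, envir = visited)
    if (v == to && length(path) > 1) {
      cyc <- list(vertices = path, kinds = c(kinds, "E"))
      if (!is_cycle_compatible(cyc))
        result <<- list(outcome = "IN_CONFLICT", witness = cyc)
    } else {
      nb <- adj[[v]]
      for (r in seq_len(nrow(nb))) {
        w <- nb$to[r]
        if (!is.na(nb$eidx[r]) && nb$eidx[r] == skip_eidx) next
        if (!is.null(visited[[w]])) next
        kinds[length(kinds) + 1L] <<- nb$kind[r]
        recurse(w)
        kinds <<- kinds[-length(kinds)]
        if (!is.null(result)) break
      }
    }
    path <<- path[-length(path)]
    rm(list = v, envir = visited)
  }
  recurse(from)
  if (is.null(result)) list(outcome = "NOT_IN_CONFLICT") else result
}

#' Classify a discordant edge as conflict-involved or not
#'
#' Enumerates simple paths between the edge's two endpoint vertices in the
#' conflict graph with the edge itself removed; each path closed with the
#' edge forms a simple cycle. The first cycle failing the compatibility
#' test ([is_cycle_compatible()]) proves the edge sits in a conflict
#' structure (the cycle is returned as a witness). If enumeration completes
#' with only compatible cycles (or none — an acyclic neighbourhood is
#' always satisfiable), the edge is labelled `NOT_IN_CONFLICT`. An
#' enumeration attempt that exceeds `timeout` seconds is retried with a
#' seeded shuffle of the DFS neighbour order; after `max_reruns` retries
#' the label is `UNDECIDED`.
#'
#' @param cg a [conflict_graph()].
#' @param edge index into `cg$gsg$edges` or an edge key
#'   (see [edge_keys()]). Must be discordant against the reference
#'   arrangement (cross-chromosome edges count as discordant).
#' @param timeout per-attempt wall-clock budget in seconds (default 0.5).
#' @param max_reruns shuffled retries allowed after the first attempt
#'   (default 1000).
#' @param seed integer; rerun r shuffles with seed `seed + r`.
#' @return list with `label` (`IN_CONFLICT`, `NOT_IN_CONFLICT` or
#'   `UNDECIDED`), `witness` (cycle or `NULL`) and `attempts`.
#' @export
classify_discordant_edge <- function(cg, edge, timeout = 0.5,
                                     max_reruns = 1000, seed = 1) {
  stopifnot(inherits(cg, "conflict_graph"))
  x <- cg$gsg
  keys <- edge_keys(x$edges)
  j <- if (is.character(edge)) match(edge, keys) else as.integer(edge)
  if (is.na(j) || j < 1 || j > nrow(x$edges))
    stop("edge not found in graph")
  if (is_reference_concordant(x)[j])
    stop("edge is concordant with the reference arrangement; ",
         "only discordant edges are classified")
  from <- paste0(x$edges$id1[j], ":", x$edges$end1[j])
  to <- paste0(x$edges$id2[j], ":", x$edges$end2[j])
  for (attempt in seq_len(1L + max_reruns)) {
    res <- dfs_attempt(cg$adj, from, to, skip_eidx = j, timeout = timeout,
                       shuffle_seed = if (attempt > 1) seed + attempt - 1L)
    if (res$outcome == "IN_CONFLICT")
      return(list(label = "IN_CONFLICT", witness = res$witness,
                  attempts = attempt))
    if (res$outcome == "NOT_IN_CONFLICT")
      return(list(label = "NOT_IN_CONFLICT", witness = NULL,
                  attempts = attempt))
  }
  list(label = "UNDECIDED", witness = NULL, attempts = 1L + max_reruns)
}

#' Fraction of discordant edges involved in conflict structures
#'
#' Classifies every reference-discordant edge of the graph and returns the
#' proportion labelled `IN_CONFLICT` among all discordant edges. This
#' fraction quantifies sample heterogeneity: conflict-involved edges
#' require more than one allele to explain.
#'
#' @param x a [gsg()] or [conflict_graph()].
#' @inheritParams classify_discordant_edge
#' @return list with `fraction` (0 when there are no discordant edges),
#'   `counts` (named tally over the three labels), and `labels` (per-edge
#'   data.frame: edge key, label, witness as a semicolon-joined vertex
#'   list).
#' @export
heterogeneity_fraction <- function(x, timeout = 0.5, max_reruns = 1000,
                                   seed = 1) {
  cg <- if (inherits(x, "conflict_graph")) x else conflict_graph(x)
  g <- cg$gsg
  disc <- which(!is_reference_concordant(g))
  counts <- c(IN_CONFLICT = 0L, NOT_IN_CONFLICT = 0L, UNDECIDED = 0L)
  labels <- data.frame(edge = character(), label = character(),
                       witness = character(), stringsAsFactors = FALSE)
  for (j in disc) {
    cl <- classify_discordant_edge(cg, j, timeout = timeout,
                                   max_reruns = max_reruns, seed = seed)
    counts[cl$label] <- counts[cl$label] + 1L
    labels <- rbind(labels, data.frame(
      edge = edge_keys(g$edges)[j], label = cl$label,
      witness = if (is.null(cl$witness)) "" else
        paste(cl$witness$vertices, collapse = ";"),
      stringsAsFactors = FALSE))
  }
  frac <- if (length(disc) == 0) 0 else
    unname(counts["IN_CONFLICT"] / length(disc))
  list(fraction = frac, counts = counts, labels = labels)
}
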