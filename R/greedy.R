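#' Greedy approximation solvers for the single-arrangement problem
#'
#' Both solvers place segments one at a time in a given processing order and
#' keep, at each step, the placement making the largest weight of edges to
#' already-placed segments concordant. The end-placement variant considers
#' four options per segment (append or prepend, each in both orientations);
#' because those four options make disjoint edge subsets concordant whose
#' union is every edge to placed segments, the best option always captures
#' at least a quarter of that weight, giving a `w(E)/4` floor overall. The
#' insertion variant additionally tries every internal position (its
#' candidate set contains the four end options, so the same floor holds);
#' inserting never disturbs the relative order or orientation of placed
#' segments, so previously concordant edges stay concordant.
#'
#' Tie-breaking is fixed for reproducibility: append/orient-1, then
#' append/orient-0, then prepend/orient-1, then prepend/orient-0; for the
#' insertion variant, lowest insertion index first and orient 1 before 0.
#'
#' @param x a [gsg()] object.
#' @param order character vector: a permutation of the segment ids giving
#'   the processing order; default genomic order.
#' @return list with `arrangement`, `weight` (total concordant weight) and
#'   `trace` (per-iteration candidate gains and choice).
#' @name greedy_scap
NULL

default_order <- function(x) {
  s <- x$segments
  s$id[order(match(s$chrom, x$chrom_order), s$start)]
}

check_order <- function(x, order) {
  if (!setequal(order, x$segments$id) ||
      length(order) != nrow(x$segments) || anyDuplicated(order))
    stop("order must be a permutation of the graph's segment ids")
}

# Edges joining segment `sid` to any segment in `placed`.
incident_to_placed <- function(x, sid, placed) {
  e <- x$edges
  e[(e$id1 == sid & e$id2 %in% placed) |
      (e$id2 == sid & e$id1 %in% placed), , drop = FALSE]
}

arrangement_from_order <- function(ids, orient) {
  arrangement(rank = stats::setNames(seq_along(ids) - 1L, ids),
              orient = orient[ids])
}

# Gain of placing `sid` given tentative full order `ids` and orientations:
# weight of edges between sid and placed segments concordant in the
# tentative arrangement (direct evaluation of the concordance rule).
placement_gain <- function(x, sid, ids, orient, einc) {
  if (nrow(einc) == 0) return(0)
  arr <- arrangement_from_order(ids, orient)
  sum(einc$weight[vapply(seq_len(nrow(einc)), function(i)
    is_concordant(einc[i, ], arr), logical(1))])
}

#' @rdname greedy_scap
#' @export
scap_greedy_ends <- function(x, order = default_order(x)) {
  stopifnot(inherits(x, "gsg"))
  check_order(x, order)
  n <- length(order)
  trace <- list()
  if (n == 0)
    return(list(arrangement = arrangement(integer(0), integer(0)),
                weight = 0, trace = trace))
  ids <- order[1]
  orient <- stats::setNames(rep(1L, n), order)
  total <- 0
  opts <- c("append_1", "append_0", "prepend_1", "prepend_0")
  for (i in seq_len(n)[-1]) {
    sid <- order[i]
    einc <- incident_to_placed(x, sid, ids)
    gains <- stats::setNames(numeric(4), opts)
    for (o in opts) {
      ornt <- orient
      ornt[sid] <- as.integer(sub(".*_", "", o))
      cand <- if (startsWith(o, "append")) c(ids, sid) else c(sid, ids)
      gains[o] <- placement_gain(x, sid, cand, ornt, einc)
    }
    pick <- opts[which.max(gains)]  # first max: fixed priority order
    orient[sid] <- as.integer(sub(".*_", "", pick))
    ids <- if (startsWith(pick, "append")) c(ids, sid) else c(sid, ids)
    total <- total + gains[[pick]]
    trace[[length(trace) + 1L]] <-
      list(segment = sid, gains = gains, chosen = pick)
  }
  list(arrangement = arrangement_from_order(ids, orient),
       weight = total, trace = trace)
}

#' @rdname greedy_scap
#' @export
scap_greedy_insert <- function(x, order = default_order(x)) {
  stopifnot(inherits(x, "gsg"))
  check_order(x, order)
  n <- length(order)
  trace <- list()
  if (n == 0)
    return(list(arrangement = arrangement(integer(0), integer(0)),
                weight = 0, trace = trace))
  ids <- order[1]
  orient <- stats::setNames(rep(1L, n), order)
  total <- 0
  for (i in seq_len(n)[-1]) {
    sid <- order[i]
    einc <- incident_to_placed(x, sid, ids)
    m <- length(ids)
    gains <- matrix(NA_real_, nrow = m + 1L, ncol = 2,
                    dimnames = list(NULL, c("orient_1", "orient_0")))
    best <- list(gain = -Inf, pos = NA, orient = NA)
    for (pos in 0:m) {
      for (f in c(1L, 0L)) {
        ornt <- orient
        ornt[sid] <- f
        cand <- append(ids, sid, after = pos)
        g <- placement_gain(x, sid, cand, ornt, einc)
        gains[pos + 1L, 2L - f] <- g
        if (g > best$gain) best <- list(gain = g, pos = pos, orient = f)
      }
    }
    orient[sid] <- best$orient
    ids <- append(ids, sid, after = best$pos)
    total <- total + best$gain
    trace[[length(trace) + 1L]] <-
      list(segment = sid, gains = gains,
           chosen = sprintf("pos%d_orient%d", best$pos, best$orient))
  }
  list(arrangement = arrangement_from_order(ids, orient),
       weight = total, trace = trace)
}

#' Iterative multi-arrangement solver
#'
#' Approximates the k-arrangement objective by solving a series of
#' single-arrangement instances: each round runs `oracle` on the residual
#' graph in which edges already made concordant by earlier rounds have
#' weight zero (topology is kept, only weights change). With an exact
#' single-arrangement oracle and k = 2 the total satisfied weight is at
#' least 3/4 of the 2-arrangement optimum; with the end-placement greedy as
#' oracle it is at least 3/16.
#'
#' @param x a [gsg()] object.
#' @param k positive integer number of arrangements.
#' @param oracle function `gsg -> arrangement`; defaults to
#'   [scap_greedy_ends()] in genomic order. [oracle_exact()] and
#'   [oracle_greedy_ends()] are provided.
#' @return list with `arrangements` (length-k list), `weight` (objective of
#'   the set) and `round_gains` (weight newly satisfied per round).
#' @export
mcap_iterative <- function(x, k, oracle = oracle_greedy_ends) {
  stopifnot(inherits(x, "gsg"))
  if (k < 1) stop("k must be a positive integer")
  resid <- x
  arrs <- vector("list", k)
  round_gains <- numeric(k)
  for (i in seq_len(k)) {
    arrs[[i]] <- oracle(resid)
    sat <- concordant_mask(resid, arrs[[i]])
    round_gains[i] <- sum(resid$edges$weight[sat])
    resid$edges$weight[sat] <- 0
  }
  list(arrangements = arrs,
       weight = objective_value(x, arrs)$weight,
       round_gains = round_gains)
}

#' Single-arrangement oracles for [mcap_iterative()]
#' @param x a [gsg()] object.
#' @return an [arrangement()].
#' @export
oracle_exact <- function(x) scap_exact(x)$arrangement

#' @rdname oracle_exact
#' @export
oracle_greedy_ends <- function(x) scap_greedy_ends(x)$arrangement

#' @rdname oracle_exact
#' @export
oracle_greedy_insert <- function(x) scap_greedy_insert(x)$arrangement
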