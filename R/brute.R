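#' Brute-force exact solvers for small genome segment graphs
#'
#' These enumerate all `n! * 2^n` arrangements of `n` segments and serve as
#' the ground-truth oracle for the approximation solvers and the ILP. They
#' are only intended for toy instances and refuse to run above a size cap.
#'
#' @name brute_force
NULL

# All permutations of 1..n, one per row, in lexicographic order.
all_permutations <- function(n) {
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }
  do.call(rbind, out)
}

# 0/1 orientation grid, 2^n rows; first segment varies slowest.
orientation_grid <- function(n) {
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  g <- as.matrix(expand.grid(rep(list(c(1L, 0L)), n))[, n:1, drop = FALSE])
  dimnames(g) <- NULL
  g[, seq_len(n), drop = FALSE]
}

# Concordance masks of every edge under a block of arrangements.
# ranks: m x n matrix of 0-based ranks; orients: m x n of 0/1.
# Returns m x nE logical matrix.
block_masks <- function(x, ranks, orients) {
  e <- x$edges
  ids <- x$segments$id
  nE <- nrow(e)
  m <- nrow(ranks)
  out <- matrix(FALSE, m, nE)
  if (nE == 0) return(out)
  ui <- match(e$id1, ids); vi <- match(e$id2, ids)
  at <- as.integer(e$end1 == "T"); ah <- 1L - at
  bh <- as.integer(e$end2 == "H"); bt <- 1L - bh
  for (j in seq_len(nE)) {
    swap <- ranks[, ui[j]] > ranks[, vi[j]]
    c_fwd <- (orients[, ui[j]] == at[j]) & (orients[, vi[j]] == bh[j])
    c_rev <- (orients[, vi[j]] == bt[j]) & (orients[, ui[j]] == ah[j])
    out[, j] <- (!swap & c_fwd) | (swap & c_rev)
  }
  out
}

# Enumerate arrangements chunkwise, calling visit(ranks, orients, masks)
# on each block. Chunks keep memory bounded for n up to the cap.
enumerate_arrangements <- function(x, visit, perm_chunk = 720L) {
  n <- nrow(x$segments)
  P <- all_permutations(n)
  O <- orientation_grid(n)
  no <- nrow(O)
  nperm <- nrow(P)
  starts <- seq(1L, nperm, by = perm_chunk)
  for (s in starts) {
    idx <- s:min(s + perm_chunk - 1L, nperm)
    p <- length(idx)
    # ranks from permutation rows: row r places segment P[r,pos] at rank pos-1
    Rk <- matrix(0L, p, n)
    if (n > 0)
      Rk[cbind(rep(seq_len(p), n), as.vector(P[idx, , drop = FALSE]))] <-
        rep(0:(n - 1L), each = p)
    ranks <- Rk[rep(seq_len(p), each = no), , drop = FALSE]
    orients <- O[rep(seq_len(no), p), , drop = FALSE]
    visit(ranks, orients, block_masks(x, ranks, orients))
  }
  invisible(NULL)
}

row_to_arrangement <- function(x, rank_row, orient_row) {
  ids <- x$segments$id
  arrangement(rank = stats::setNames(as.integer(rank_row), ids),
              orient = stats::setNames(as.integer(orient_row), ids))
}

#' Exact single-arrangement optimum by exhaustive enumeration
#'
#' Maximises the total weight of concordant edges over all arrangements
#' (the k = 1 problem). Ties are broken by enumeration order, so the result
#' is deterministic.
#'
#' @param x a [gsg()] object.
#' @param cap refuse instances with more segments than this (default 8).
#' @return list with `arrangement` and `weight`.
#' @export
scap_exact <- function(x, cap = 8L) {
  stopifnot(inherits(x, "gsg"))
  n <- nrow(x$segments)
  if (n > cap)
    stop("instance has ", n, " segments; brute force capped at ", cap)
  w <- x$edges$weight
  best <- list(weight = -1, rank = NULL, orient = NULL)
  enumerate_arrangements(x, function(ranks, orients, masks) {
    wt <- if (ncol(masks)) as.numeric(masks %*% w) else
      numeric(nrow(ranks))
    i <- which.max(wt)
    if (wt[i] > best$weight) {
      best <<- list(weight = wt[i], rank = ranks[i, ], orient = orients[i, ])
    }
  })
  list(arrangement = row_to_arrangement(x, best$rank, best$orient),
       weight = best$weight)
}

mask_pack <- function(masks) {
  # pack logical rows into integers (requires <= 30 edges)
  nE <- ncol(masks)
  if (nE == 0) return(rep(0L, nrow(masks)))
  as.integer(masks %*% (2^(seq_len(nE) - 1)))
}

mask_weights <- function(packed, w) {
  nE <- length(w)
  out <- numeric(length(packed))
  for (j in seq_len(nE))
    out <- out + w[j] * (bitwAnd(packed, as.integer(2^(j - 1))) != 0)
  out
}

#' Exact k-arrangement optimum by mask enumeration
#'
#' Computes the maximum total weight of edges concordant in at least one of
#' k arrangements. All distinct concordant-edge masks are enumerated first
#' (an arrangement and its reverse share a mask, and many arrangements
#' collapse onto few masks), then the best k-subset union is searched over
#' distinct masks only.
#'
#' @param x a [gsg()] object with at most 30 edges.
#' @param k positive integer number of arrangements.
#' @param cap refuse instances with more segments than this (default 5).
#' @return list with `arrangements` (list of k [arrangement()]s) and
#'   `weight`.
#' @export
mcap_exact <- function(x, k, cap = 5L) {
  stopifnot(inherits(x, "gsg"), k >= 1)
  n <- nrow(x$segments)
  if (n > cap)
    stop("instance has ", n, " segments; brute force capped at ", cap)
  if (nrow(x$edges) > 30)
    stop("mask enumeration supports at most 30 edges")
  w <- x$edges$weight
  seen <- new.env(parent = emptyenv())
  reps <- list()  # representative (rank, orient) per distinct mask
  packed <- integer(0)
  enumerate_arrangements(x, function(ranks, orients, masks) {
    pk <- mask_pack(masks)
    for (i in seq_along(pk)) {
      key <- as.character(pk[i])
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        packed[length(packed) + 1L] <<- pk[i]
        reps[[length(reps) + 1L]] <<- list(rank = ranks[i, ],
                                           orient = orients[i, ])
      }
    }
  })
  m <- length(packed)
  kk <- min(k, m)
  if (kk == 1L || m == 1L) {
    wt <- mask_weights(packed, w)
    best_i <- which.max(wt)
    sel <- rep(best_i, 1)
    best_w <- wt[best_i]
  } else if (kk == 2L) {
    grid_i <- rep(seq_len(m), each = m)
    grid_j <- rep(seq_len(m), m)
    keep <- grid_i <= grid_j
    grid_i <- grid_i[keep]; grid_j <- grid_j[keep]
    uw <- mask_weights(bitwOr(packed[grid_i], packed[grid_j]), w)
    b <- which.max(uw)
    sel <- c(grid_i[b], grid_j[b])
    best_w <- uw[b]
  } else {
    best_w <- -1; sel <- NULL
    total <- sum(w)
    rec <- function(start, chosen, union_mask) {
      uw <- mask_weights(union_mask, w)
      if (length(chosen) > 0 && uw >= total - 1e-12) {
        # saturated: padding with repeats completes an optimal set
        pad <- c(chosen, rep(chosen[length(chosen)], kk - length(chosen)))
        if (uw > best_w) { best_w <<- uw; sel <<- pad }
        return()
      }
      if (length(chosen) == kk) {
        if (uw > best_w) { best_w <<- uw; sel <<- chosen }
        return()
      }
      need <- kk - length(chosen)
      if (m - start + 1L < need) return()
      for (i in start:m)
        rec(i + 1L, c(chosen, i), bitwOr(union_mask, packed[i]))
    }
    rec(1L, integer(0), 0L)
    if (is.null(sel)) { sel <- rep(1L, kk); best_w <- mask_weights(packed[1L], w) }
  }
  sel <- c(sel, rep(sel[length(sel)], k - length(sel)))
  arrs <- lapply(sel, function(i)
    row_to_arrangement(x, reps[[i]]$rank, reps[[i]]$orient))
  list(arrangements = arrs, weight = best_w)
}
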