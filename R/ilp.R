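#' Build the integer linear program for the k-arrangement problem
#'
#' Encodes the search for k arrangements maximising the weight of edges
#' concordant in at least one arrangement as a 0/1 program. Per arrangement
#' i there are orientation variables `y[u,i]` (1 = original), one ordering
#' variable per unordered segment pair (`z[{u,v},i]` = 1 iff u precedes v;
#' the reverse direction is represented structurally as `1 - z`, which
#' satisfies the antisymmetry identity exactly), and edge indicators
#' `x[e,i]`. A cover variable `q[e]` marks edges satisfied by any
#' arrangement; the objective is `sum_e w(e) * q[e]`.
#'
#' Each edge contributes four cap constraints per arrangement tying `x` to
#' the concordance condition of its connection type (with u the edge's
#' first segment, v its second): tail-head requires `z = y_u = y_v`;
#' tail-tail `z = y_u = 1 - y_v`; head-tail `z = 1 - y_u = 1 - y_v`;
#' head-head `z = 1 - y_u = y_v`. The caps are one-sided (`x` bounded
#' above); maximisation supplies the converse. Ordering consistency is
#' enforced by a transitivity band over every segment triple. With k = 1
#' the program is the single-arrangement (homogeneous) formulation.
#'
#' @param x a [gsg()] object.
#' @param k positive integer number of arrangements.
#' @return object of class `"ilp_model"`; see [solve_ilp()].
#' @export
build_ilp <- function(x, k) {
  stopifnot(inherits(x, "gsg"))
  if (k < 1) stop("k must be a positive integer")
  ids <- x$segments$id
  n <- length(ids)
  e <- x$edges
  nE <- nrow(e)

  vars <- character(0)
  add_vars <- function(v) vars <<- c(vars, v)
  for (i in seq_len(k)) {
    if (n >= 2) {
      pr <- utils::combn(n, 2)
      add_vars(sprintf("z|%s|%s|%d", ids[pr[1, ]], ids[pr[2, ]], i))
    }
    add_vars(sprintf("y|%s|%d", ids, i))
  }
  for (i in seq_len(k))
    if (nE > 0) add_vars(sprintf("x|%d|%d", seq_len(nE), i))
  if (nE > 0) add_vars(sprintf("q|%d", seq_len(nE)))
  vidx <- stats::setNames(seq_along(vars), vars)
  nvar <- length(vars)

  obj <- numeric(nvar)
  if (nE > 0) obj[vidx[sprintf("q|%d", seq_len(nE))]] <- e$weight

  rows <- list()  # each: list(cols, coefs, lb, ub)
  add_row <- function(cols, coefs, lb, ub)
    rows[[length(rows) + 1L]] <<- list(cols = cols, coefs = coefs,
                                       lb = lb, ub = ub)

  # literal: list(var = index or NA, sign, const); value = sign*v + const
  lit <- function(name, negate = FALSE) {
    if (negate) list(var = vidx[[name]], sign = -1, const = 1)
    else list(var = vidx[[name]], sign = 1, const = 0)
  }
  zlit <- function(u, v, i) {
    iu <- match(u, ids); iv <- match(v, ids)
    if (iu < iv) lit(sprintf("z|%s|%s|%d", u, v, i))
    else lit(sprintf("z|%s|%s|%d", v, u, i), negate = TRUE)
  }
  # x <= p - q + 1 and x <= q - p + 1 for literals p, q
  add_eq_cap <- function(xv, p, q) {
    add_row(c(xv, p$var, q$var), c(1, -p$sign, q$sign),
            -Inf, 1 + p$const - q$const)
    add_row(c(xv, p$var, q$var), c(1, p$sign, -q$sign),
            -Inf, 1 - p$const + q$const)
  }

  for (i in seq_len(k)) {
    for (j in seq_len(nE)) {
      u <- e$id1[j]; v <- e$id2[j]
      a <- e$end1[j]; b <- e$end2[j]
      xv <- vidx[[sprintf("x|%d|%d", j, i)]]
      yu <- function(neg = FALSE) lit(sprintf("y|%s|%d", u, i), neg)
      yv <- function(neg = FALSE) lit(sprintf("y|%s|%d", v, i), neg)
      zz <- zlit(u, v, i)
      if (a == "T" && b == "H") {        # z = y_u = y_v
        add_eq_cap(xv, yu(), yv())
        add_eq_cap(xv, zz, yu())
      } else if (a == "T" && b == "T") { # z = y_u = 1 - y_v
        add_eq_cap(xv, yu(), yv(TRUE))
        add_eq_cap(xv, zz, yu())
      } else if (a == "H" && b == "T") { # z = 1 - y_u = 1 - y_v
        add_eq_cap(xv, yu(TRUE), yv(TRUE))
        add_eq_cap(xv, zz, yu(TRUE))
      } else {                           # HH: z = 1 - y_u = y_v
        add_eq_cap(xv, yu(TRUE), yv())
        add_eq_cap(xv, zz, yu(TRUE))
      }
    }
    # transitivity over triples: 0 <= z12 + z23 - z13 <= 1
    if (n >= 3) {
      tri <- utils::combn(n, 3)
      for (t in seq_len(ncol(tri))) {
        s1 <- ids[tri[1, t]]; s2 <- ids[tri[2, t]]; s3 <- ids[tri[3, t]]
        add_row(c(vidx[[sprintf("z|%s|%s|%d", s1, s2, i)]],
                  vidx[[sprintf("z|%s|%s|%d", s2, s3, i)]],
                  vidx[[sprintf("z|%s|%s|%d", s1, s3, i)]]),
                c(1, 1, -1), 0, 1)
      }
    }
  }
  # q linking: q_e <= sum_i x_e^i ; q_e <= 1
  for (j in seq_len(nE)) {
    qv <- vidx[[sprintf("q|%d", j)]]
    xv <- vidx[sprintf("x|%d|%d", j, seq_len(k))]
    add_row(c(qv, xv), c(1, rep(-1, k)), -Inf, 0)
    add_row(qv, 1, -Inf, 1)
  }

  # branching: per edge (heaviest first) its x across arrangements, then
  # orientation and ordering variables arrangement by arrangement.
  border <- integer(0)
  if (nE > 0) {
    eord <- order(-e$weight)
    for (j in eord)
      border <- c(border, vidx[sprintf("x|%d|%d", j, seq_len(k))])
  }
  for (i in seq_len(k)) {
    if (n >= 2) {
      pr <- utils::combn(n, 2)
      border <- c(border,
                  vidx[sprintf("z|%s|%s|%d", ids[pr[1, ]], ids[pr[2, ]], i)])
    }
    border <- c(border, vidx[sprintf("y|%s|%d", ids, i)])
  }

  structure(list(gsg = x, k = k, nvar = nvar, vars = vars, vidx = vidx,
                 obj = obj, rows = rows, branch_order = unname(border)),
            class = "ilp_model")
}

#' @export
print.ilp_model <- function(x, ...) {
  cat(sprintf("0/1 program: %d variables, %d constraints (k = %d, %d segments, %d edges)\n",
              x$nvar, length(x$rows), x$k, nrow(x$gsg$segments),
              nrow(x$gsg$edges)))
  invisible(x)
}

#' Solve a built ILP model exactly
#'
#' Runs the package's deterministic branch-and-bound backend. When a time
#' limit is given and reached after an incumbent exists, the incumbent is
#' decoded and the status is `FEASIBLE_TIME_LIMIT`. The backend is fully
#' deterministic, so `seed` is accepted for interface stability but has no
#' effect.
#'
#' Each arrangement is decoded from the ordering variables (which form a
#' total order by antisymmetry and transitivity) and the orientation
#' variables. The decoded set's true objective can only be larger than or
#' equal to the solver objective, because an `x` variable may be 0 on an
#' edge the decoded arrangement happens to satisfy.
#'
#' @param model an [build_ilp()] model.
#' @param time_limit seconds, or `NULL` for no limit.
#' @param seed ignored (deterministic backend).
#' @return list with `arrangements` (length-k list of [arrangement()]s) and
#'   `status` (list: `state` in `OPTIMAL`, `FEASIBLE_TIME_LIMIT`,
#'   `INFEASIBLE_ERROR`; `objective`; `seconds`; `nodes`).
#' @export
solve_ilp <- function(model, time_limit = NULL, seed = NULL) {
  stopifnot(inherits(model, "ilp_model"))
  rows <- model$rows
  lens <- vapply(rows, function(r) length(r$cols), integer(1))
  res <- .bnb_solve(
    nvar = model$nvar,
    obj = model$obj,
    rowptr_col = c(0L, cumsum(lens))[seq_along(rows)],
    rowptr_len = lens,
    cols = as.integer(unlist(lapply(rows, `[[`, "cols"))) - 1L,
    coefs = as.numeric(unlist(lapply(rows, `[[`, "coefs"))),
    rlb = vapply(rows, `[[`, numeric(1), "lb"),
    rub = vapply(rows, `[[`, numeric(1), "ub"),
    branch_order = as.integer(model$branch_order) - 1L,
    time_limit = if (is.null(time_limit)) -1 else as.numeric(time_limit))
  state <- c("OPTIMAL", "FEASIBLE_TIME_LIMIT", "INFEASIBLE_ERROR")[res$status + 1L]
  status <- list(state = state, objective = res$objective,
                 seconds = res$seconds, nodes = res$nodes)
  if (state == "INFEASIBLE_ERROR")
    return(list(arrangements = NULL, status = status))
  sol <- stats::setNames(res$solution, model$vars)
  x <- model$gsg
  ids <- x$segments$id
  n <- length(ids)
  arrs <- lapply(seq_len(model$k), function(i) {
    prec <- matrix(FALSE, n, n)  # prec[a,b]: a precedes b
    if (n >= 2) {
      pr <- utils::combn(n, 2)
      zv <- sol[sprintf("z|%s|%s|%d", ids[pr[1, ]], ids[pr[2, ]], i)]
      for (t in seq_len(ncol(pr))) {
        prec[pr[1, t], pr[2, t]] <- zv[t] == 1L
        prec[pr[2, t], pr[1, t]] <- zv[t] == 0L
      }
    }
    rank <- colSums(prec)  # number of segments preceding each
    orient <- sol[sprintf("y|%s|%d", ids, i)]
    arrangement(rank = stats::setNames(as.integer(rank), ids),
                orient = stats::setNames(as.integer(orient), ids))
  })
  list(arrangements = arrs, status = status, solution = sol)
}

#' Detect transcriptomic structural variants by per-component exact solving
#'
#' The production pipeline for heterogeneous samples: splits the graph into
#' connected components, solves the k-arrangement ILP exactly on each
#' (k = 2 models a diploid sample), composes the per-component arrangements
#' into genome-wide arrangements in genomic order, and calls TSVs from the
#' composed solution. A component whose solve fails falls back to its
#' reference arrangement with a warning; a component that hits the time
#' limit contributes its incumbent.
#'
#' @param x a [gsg()] object.
#' @param k number of arrangements per component (default 2, diploid).
#' @param max_distance see [call_tsvs()].
#' @param time_limit per-component time limit in seconds (default 3600).
#' @param method `"ilp"` (exact, default), `"brute"` (enumeration, tiny
#'   components only), `"greedy-ends"`, `"greedy-insert"` or `"iterative"`
#'   (greedy rounds via [mcap_iterative()]).
#' @return list with `arrangements` (k genome-wide arrangements), `calls`
#'   (TSV data.frame from [call_tsvs()]), `statuses` (per component) and
#'   `objective` (total satisfied weight).
#' @export
detect_tsvs <- function(x, k = 2, max_distance = 200000,
                        time_limit = 3600,
                        method = c("ilp", "brute", "greedy-ends",
                                   "greedy-insert", "iterative")) {
  stopifnot(inherits(x, "gsg"))
  method <- match.arg(method)
  comps <- gsg_components(x)
  statuses <- vector("list", length(comps))
  comp_arrs <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    if (nrow(comp$edges) == 0) {
      comp_arrs[[ci]] <- rep(list(reference_arrangement(comp)), k)
      statuses[[ci]] <- list(state = "OPTIMAL", objective = 0,
                             seconds = 0, nodes = 0)
      next
    }
    res <- tryCatch({
      switch(method,
        ilp = {
          sr <- solve_ilp(build_ilp(comp, k), time_limit = time_limit)
          if (is.null(sr$arrangements)) stop("no incumbent")
          list(arrs = sr$arrangements, status = sr$status)
        },
        brute = {
          br <- mcap_exact(comp, k)
          list(arrs = br$arrangements,
               status = list(state = "OPTIMAL", objective = br$weight,
                             seconds = NA_real_, nodes = NA_real_))
        },
        {
          oracle <- switch(method,
            "greedy-ends" = oracle_greedy_ends,
            "greedy-insert" = oracle_greedy_insert,
            "iterative" = oracle_greedy_ends)
          it <- mcap_iterative(comp, k, oracle)
          list(arrs = it$arrangements,
               status = list(state = "OPTIMAL", objective = it$weight,
                             seconds = NA_real_, nodes = NA_real_))
        })
    }, error = function(err) {
      warning("component ", ci, " failed (", conditionMessage(err),
              "); using reference arrangement", call. = FALSE)
      list(arrs = rep(list(reference_arrangement(comp)), k),
           status = list(state = "INFEASIBLE_ERROR", objective = NA_real_,
                         seconds = NA_real_, nodes = NA_real_))
    })
    comp_arrs[[ci]] <- res$arrs
    statuses[[ci]] <- res$status
  }
  arrs <- compose_arrangements(comp_arrs, k)
  calls <- call_tsvs(x, arrs, max_distance = max_distance)
  list(arrangements = arrs, calls = calls, statuses = statuses,
       objective = objective_value(x, arrs)$weight)
}

# Concatenate per-component arrangements (components already in genomic
# order) into genome-wide arrangements by offsetting ranks.
compose_arrangements <- function(comp_arrs, k) {
  lapply(seq_len(k), function(i) {
    rank <- integer(0); orient <- integer(0); offset <- 0L
    for (ca in comp_arrs) {
      a <- ca[[i]]
      rank <- c(rank, a$rank + offset)
      orient <- c(orient, a$orient)
      offset <- offset + length(a$rank)
    }
    arrangement(rank = rank, orient = orient)
  })
}
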