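#' Build the interval graph of a set of same-chromosome intervals
#'
#' Vertices are the input intervals (one vertex per row, duplicates kept
#' distinct); an undirected edge joins two vertices iff their intervals
#' overlap under the half-open predicate.  Intended for inspection and
#' testing; the clique sweep does not materialize the graph.
#'
#' @param intervals A data.frame with `chrom`, `start`, `end` columns, all
#'   rows on one chromosome.
#' @return A list of class `interval_graph` with elements `vertices` (the
#'   input data.frame) and `adj` (symmetric logical adjacency matrix, no
#'   self-edges).
#' @export
build_interval_graph <- function(intervals) {
  if (length(unique(intervals$chrom)) > 1)
    stop("intervals span multiple chromosomes; build one graph per chromosome",
         call. = FALSE)
  n <- nrow(intervals)
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    adj <- outer(seq_len(n), seq_len(n), function(i, j)
      intervals_overlap(intervals$start[i], intervals$end[i],
                        intervals$start[j], intervals$end[j]))
    diag(adj) <- FALSE
  }
  structure(list(vertices = intervals, adj = adj), class = "interval_graph")
}

#' Enumerate maximal cliques of an interval set by endpoint sweep
#'
#' The maximal cliques of an interval graph are exactly the maximal sets of
#' pairwise-overlapping intervals, and each corresponds to a point of
#' maximal overlap.  The sweep sorts the 2n endpoints by coordinate
#' (processing end events before start events at equal coordinates, so
#' touching intervals are not adjacent), maintains the set of active
#' intervals, and emits the active set as a maximal clique at each end
#' event that follows at least one start event since the last emission.
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` on one
#'   chromosome; may contain duplicate coordinates (distinct vertices).
#' @return A list of integer vectors, each the sorted row indices of one
#'   maximal clique.  Empty input gives an empty list; a lone interval is a
#'   singleton clique (downstream filters remove singletons).
#' @seealso [brute_force_maximal_cliques()] for the testing oracle,
#'   [clique_mcr()] and [clique_outer()] for the derived regions.
#' @export
sweep_maximal_cliques <- function(intervals) {
  n <- nrow(intervals)
  if (n == 0) return(list())
  if (length(unique(intervals$chrom)) > 1)
    stop("intervals span multiple chromosomes", call. = FALSE)
  # event type 0 = end, 1 = start; ends sort first at equal coordinates
  ev_pos <- c(intervals$start, intervals$end)
  ev_type <- rep(c(1L, 0L), each = n)
  ev_idx <- rep(seq_len(n), 2L)
  o <- order(ev_pos, ev_type)
  active <- logical(n)
  added_since_emit <- FALSE
  cliques <- vector("list", n)
  k <- 0L
  for (e in o) {
    v <- ev_idx[e]
    if (ev_type[e] == 1L) {
      active[v] <- TRUE
      added_since_emit <- TRUE
    } else {
      if (added_since_emit) {
        k <- k + 1L
        cliques[[k]] <- which(active)
        added_since_emit <- FALSE
      }
      active[v] <- FALSE
    }
  }
  cliques[seq_len(k)]
}

#' Brute-force maximal clique enumeration (testing oracle)
#'
#' Bron-Kerbosch with pivoting over the explicit adjacency matrix.
#' Exponential in the worst case; refuses more than `max_n` intervals.
#' Kept independent of the sweep so the two can check each other.
#'
#' @inheritParams sweep_maximal_cliques
#' @param max_n Hard cap on the number of intervals (default 20).
#' @return A list of sorted integer vectors (canonical form, ordered
#'   lexicographically) — comparable by `setequal`-style identity with the
#'   canonicalized sweep output.
#' @export
brute_force_maximal_cliques <- function(intervals, max_n = 20) {
  n <- nrow(intervals)
  if (n > max_n)
    stop("brute-force oracle capped at ", max_n, " intervals", call. = FALSE)
  if (n == 0) return(list())
  adj <- build_interval_graph(intervals)$adj
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- sort(R)
      return(invisible(NULL))
    }
    pivot_pool <- c(P, X)
    u <- pivot_pool[which.max(vapply(pivot_pool,
                                     function(w) sum(adj[w, P]), 0))]
    for (v in setdiff(P, which(adj[u, ]))) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  canonicalize_cliques(out)
}

#' Canonical ordering of a clique list
#'
#' Sorts members within each clique and orders cliques lexicographically,
#' so two enumerations can be compared with `identical()`.
#'
#' @param cliques List of integer vectors.
#' @return List of sorted integer vectors in lexicographic order.
#' @export
canonicalize_cliques <- function(cliques) {
  cliques <- lapply(cliques, sort)
  keys <- vapply(cliques, function(x) paste(x, collapse = ","), "")
  cliques[order(keys)]
}

#' Minimal common region (MCR) of a clique
#'
#' The intersection of all member intervals: `[max(starts), min(ends))`.
#' Pairwise-intersecting intervals on a line always share a common point
#' (the 1-D Helly property), so the MCR of a true clique is nonempty.
#'
#' @param intervals Data.frame of intervals (`chrom`, `start`, `end`).
#' @param members Integer row indices of the clique members.
#' @return A one-row [genomic_interval()].
#' @export
clique_mcr <- function(intervals, members) {
  if (!length(members)) stop("empty clique", call. = FALSE)
  genomic_interval(intervals$chrom[members[1]],
                   max(intervals$start[members]),
                   min(intervals$end[members]))
}

#' Outer span of a clique
#'
#' The union extent of all member intervals: `[min(starts), max(ends))`.
#'
#' @inheritParams clique_mcr
#' @return A one-row [genomic_interval()].
#' @export
clique_outer <- function(intervals, members) {
  if (!length(members)) stop("empty clique", call. = FALSE)
  genomic_interval(intervals$chrom[members[1]],
                   min(intervals$start[members]),
                   max(intervals$end[members]))
}
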