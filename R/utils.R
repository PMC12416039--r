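# Shared numeric helpers.

#' Round half away from zero to a fixed number of decimals
#'
#' Published frequency tables in pharmacoepidemiology conventionally use
#' half-up rounding, whereas [base::round()] rounds half to even. A small
#' epsilon absorbs binary floating-point representation error (e.g. values
#' stored as 12.4149999...).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.125, 2.5), 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Largest-remainder apportionment
#'
#' Distributes `n` units over categories in proportion to `weights` so the
#' realized counts sum exactly to `n`: each category first receives the floor
#' of its quota, then the leftover units go to the categories with the
#' largest fractional remainders (ties broken by name order).
#'
#' Weights must be nonnegative and sum to 1; sums within `tol` of 1 (such as
#' percentages read off a printed table that rounds to 100.1) are normalized,
#' anything further off is an error.
#'
#' @param weights named nonnegative numeric vector summing to 1 (within `tol`).
#' @param n total count to apportion.
#' @param tol allowed deviation of `sum(weights)` from 1 before erroring.
#' @return named integer vector of counts summing to `n`.
#' @export
#' @examples
#' largest_remainder(c(a = 0.5, b = 0.5), 5)
largest_remainder <- function(weights, n, tol = 0.005) {
  stopifnot(is.numeric(weights), length(weights) >= 1, n >= 0)
  if (is.null(names(weights)) || anyDuplicated(names(weights))) {
    stop("weights must have unique names")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (abs(s - 1) > tol) {
    stop(sprintf("weights sum to %.6f, not 1 (tolerance %g)", s, tol))
  }
  quota <- weights / s * n
  counts <- floor(quota)
  leftover <- n - sum(counts)
  if (leftover > 0) {
    frac <- quota - counts
    take <- order(-frac, names(weights))[seq_len(leftover)]
    counts[take] <- counts[take] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Shannon entropy of a count or probability vector, in bits
#'
#' @param counts nonnegative weights; zeros are ignored.
#' @return entropy in bits (log base 2).
#' @export
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Union length of half-open intervals [start, end), after merging overlaps.
# `bridge` merges intervals separated by a gap <= bridge before measuring.
merge_intervals <- function(starts, ends, bridge = 0) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + bridge) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# Kahn topological sort over an edge list; returns node order or NULL on cycle.
topo_order <- function(nodes, from, to) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(from)) {
    indeg[[to[i]]] <- indeg[[to[i]]] + 1L
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
  }
  queue <- sort(names(indeg)[indeg == 0L])
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
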