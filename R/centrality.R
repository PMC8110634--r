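#' Single-source shortest-path census
#'
#' Breadth-first shortest paths along directed connections, ignoring
#' polarity. Distances are hop counts; `path_count[u]` is the number of
#' distinct shortest paths from `source` to `u` (sigma in the usual
#' betweenness notation), accumulated breadth-first. In a causal loop
#' diagram a shortest path is the causal pathway with the fewest mediating
#' variables.
#'
#' @param diagram a `cld` object.
#' @param source a declared variable name.
#' @return List with named components `source`, `distance` (named integer
#'   vector) and `path_count` (named numeric vector). Unreachable variables
#'   are absent from both vectors; `distance[source] = 0`,
#'   `path_count[source] = 1`.
#' @examples
#' d <- chain_cld(c("A", "B", "C"))
#' single_source_shortest_paths(d, "A")$distance  # A=0, B=1, C=2
#' @export
single_source_shortest_paths <- function(diagram, source) {
  stopifnot_cld(diagram)
  idx <- cld_index(diagram)
  s <- match(normalize_name(source), idx$names)
  if (is.na(s)) stop("unknown source variable: ", source)
  cen <- bfs_census(idx$adj, idx$n, s)
  reach <- which(cen$dist >= 0L)
  list(source = idx$names[s],
       distance = stats::setNames(cen$dist[reach], idx$names[reach]),
       path_count = stats::setNames(cen$sigma[reach], idx$names[reach]))
}

# BFS from s over adjacency lists: returns dist (-1 = unreachable), sigma
# (shortest-path counts), predecessor lists, and vertices in visit order.
bfs_census <- function(adj, n, s) {
  dist <- rep(-1L, n)
  sigma <- numeric(n)
  preds <- vector("list", n)
  order_v <- integer(n)
  nord <- 0L
  dist[s] <- 0L
  sigma[s] <- 1
  queue <- integer(n)
  queue[1L] <- s
  qh <- 1L
  qt <- 1L
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    nord <- nord + 1L
    order_v[nord] <- v
    dv <- dist[v]
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dv + 1L
        qt <- qt + 1L
        queue[qt] <- w
      }
      if (dist[w] == dv + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds,
       order = order_v[seq_len(nord)])
}

# Betweenness (Brandes accumulation) and outward closeness in one pass over
# sources. Returns raw (unnormalized) betweenness, per-source reachable
# counts and distance sums.
centrality_engine <- function(adj, n) {
  bc <- numeric(n)
  reach <- integer(n)
  dsum <- numeric(n)
  for (s in seq_len(n)) {
    cen <- bfs_census(adj, n, s)
    reach[s] <- length(cen$order) - 1L
    dsum[s] <- sum(cen$dist[cen$dist > 0L])
    delta <- numeric(n)
    ord <- cen$order
    for (i in rev(seq_along(ord))) {
      w <- ord[i]
      coeff <- (1 + delta[w]) / cen$sigma[w]
      for (v in cen$preds[[w]]) delta[v] <- delta[v] + cen$sigma[v] * coeff
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  list(bc_raw = bc, reach = reach, dsum = dsum)
}

#' Normalized betweenness centrality
#'
#' For each variable v, the fraction of shortest paths between ordered pairs
#' of other variables that pass through v:
#' \deqn{BC_v = \frac{1}{(N-1)(N-2)} \sum_{s \ne v \ne t}
#'       \frac{\sigma(s,t\,|\,v)}{\sigma(s,t)}}
#' where N is the number of variables, \eqn{\sigma(s,t)} the number of
#' shortest s-to-t paths and \eqn{\sigma(s,t|v)} the number of those passing
#' through v. Endpoints are excluded (s and t range over variables other
#' than v), so a variable with no incoming connections always scores 0.
#' Ordered pairs with no connecting path contribute 0. Values lie in [0, 1].
#'
#' @param diagram a `cld` object with at least 3 variables (the
#'   normalization is undefined below that).
#' @return Named numeric vector over all variables, in name order.
#' @examples
#' d <- chain_cld(c("A", "B", "C"))
#' betweenness_centrality(d)  # B = 1/2 (one pair A->C, normalization 1/2)
#' @export
betweenness_centrality <- function(diagram) {
  stopifnot_cld(diagram)
  idx <- cld_index(diagram)
  if (idx$n < 3) stop("betweenness normalization requires at least 3 variables")
  eng <- centrality_engine(idx$adj, idx$n)
  stats::setNames(eng$bc_raw / ((idx$n - 1) * (idx$n - 2)), idx$names)
}

#' Outward closeness centrality
#'
#' For each variable v with at least one reachable variable,
#' \deqn{CC_v = \frac{n-1}{\sum_u d(v,u)}}
#' where the sum runs over the n-1 variables reachable from v by directed
#' paths and d(v,u) is the shortest-path hop distance. A variable reaching
#' nothing scores 0 by convention. Closeness is outward (paths *from* v),
#' which is why exogenous variables can score high closeness while having
#' zero betweenness.
#'
#' The `"as_printed"` variant is the formula above, computed on the reachable
#' set only. The `"wf_scaled"` variant applies the Wasserman-Faust correction
#' for disconnected graphs, multiplying by the reachable fraction
#' (n-1)/(N-1); the two coincide on strongly connected diagrams.
#'
#' @param diagram a `cld` object.
#' @param variant `"as_printed"` or `"wf_scaled"`.
#' @return Named numeric vector over all variables, in name order.
#' @examples
#' d <- chain_cld(c("A", "B", "C"))
#' closeness_centrality(d)  # A = 2/3, B = 1, C = 0
#' @export
closeness_centrality <- function(diagram,
                                 variant = c("as_printed", "wf_scaled")) {
  stopifnot_cld(diagram)
  variant <- match.arg(variant)
  idx <- cld_index(diagram)
  eng <- centrality_engine(idx$adj, idx$n)
  closeness_from_engine(eng, idx$n, variant, idx$names)
}

closeness_from_engine <- function(eng, n, variant, names = NULL) {
  cc <- ifelse(eng$reach > 0, eng$reach / eng$dsum, 0)
  if (variant == "wf_scaled" && n > 1) cc <- cc * eng$reach / (n - 1)
  if (!is.null(names)) names(cc) <- names
  cc
}

#' Both centrality measures in one table
#'
#' @param diagram a `cld` object.
#' @param variant closeness variant, see [closeness_centrality()].
#' @return Object of class `cld_centrality`: data frame with columns
#'   `variable`, `betweenness`, `closeness`, plus attributes
#'   `closeness_variant` and `n_variables`.
#' @export
centrality_table <- function(diagram,
                             variant = c("as_printed", "wf_scaled")) {
  stopifnot_cld(diagram)
  variant <- match.arg(variant)
  idx <- cld_index(diagram)
  if (idx$n < 3) stop("betweenness normalization requires at least 3 variables")
  eng <- centrality_engine(idx$adj, idx$n)
  out <- data.frame(
    variable = idx$names,
    betweenness = eng$bc_raw / ((idx$n - 1) * (idx$n - 2)),
    closeness = closeness_from_engine(eng, idx$n, variant),
    stringsAsFactors = FALSE
  )
  attr(out, "closeness_variant") <- variant
  attr(out, "n_variables") <- idx$n
  class(out) <- c("cld_centrality", "data.frame")
  out
}

#' Spearman rank correlation between two centrality maps
#'
#' Pearson correlation of average-ranked values (ties receive mean ranks),
#' via [stats::cor()]. The two maps must be keyed by the same variables.
#'
#' @param a,b named numeric vectors over identical key sets (any order).
#' @return Correlation in [-1, 1].
#' @export
spearman_rank_correlation <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b)) ||
      length(a) != length(b)) {
    stop("inputs must be named vectors over identical key sets")
  }
  if (length(a) < 3) stop("need at least 3 keys")
  stats::cor(a, b[names(a)], method = "spearman")
}
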