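# Brute-force oracles and tiny builders used across the suite. All oracles
# work by exhaustive enumeration and stay independent of the package's
# BFS/Brandes/DFS code paths.

make_cld <- function(edges, vars = NULL, polarity = NULL) {
  # edges: 2-column character matrix / data frame of (source, target)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("source", "target")
  edges$polarity <- if (is.null(polarity)) 1L else polarity
  if (is.null(vars)) {
    vars <- data.frame(name = sort(unique(c(edges$source, edges$target))),
                       category = "physical", stringsAsFactors = FALSE)
  }
  parse_edge_tables(edges, vars)
}

# Random digraph on n named nodes: each ordered pair present independently
# with probability p, random polarity. Isolated nodes allowed.
random_cld <- function(n, p = 0.3, neg = 0.4) {
  nm <- LETTERS[seq_len(n)]
  pairs <- expand.grid(source = nm, target = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  vars <- data.frame(name = nm, category = "physical",
                     stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    return(parse_edge_tables(
      data.frame(source = character(), target = character(),
                 polarity = integer()), vars))
  }
  pol <- ifelse(stats::runif(nrow(edges)) < neg, -1L, 1L)
  make_cld(edges, vars, pol)
}

# All simple paths s -> t as lists of vertex names, by exhaustive DFS.
all_simple_paths_bf <- function(diagram, s, t) {
  adj <- split(diagram$connections$target, diagram$connections$source)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t && length(path) > 1) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (w in adj[[v]]) {
      if (!w %in% path) walk(c(path, w))
    }
  }
  if (s == t) return(list(s))
  walk(s)
  out
}

# sigma(s,t) and d(s,t) for every target, by enumerating all simple paths.
path_census_bf <- function(diagram, s) {
  nm <- diagram$variables$name
  dist <- c(stats::setNames(0L, s))
  cnt <- c(stats::setNames(1, s))
  for (t in setdiff(nm, s)) {
    paths <- all_simple_paths_bf(diagram, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1)) - 1L
    dist[t] <- min(lens)
    cnt[t] <- sum(lens == min(lens))
  }
  list(distance = dist, path_count = cnt)
}

# Normalized betweenness by enumerating every shortest path of every
# ordered pair and tallying interior vertices.
betweenness_bf <- function(diagram) {
  nm <- diagram$variables$name
  n <- length(nm)
  bc <- stats::setNames(numeric(n), nm)
  for (s in nm) for (t in setdiff(nm, s)) {
    paths <- all_simple_paths_bf(diagram, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1)) - 1L
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (p in shortest) {
      interior <- setdiff(p, c(s, t))
      bc[interior] <- bc[interior] + 1 / sigma
    }
  }
  bc / ((n - 1) * (n - 2))
}

# Outward closeness from igraph's distance matrix (independent of the
# package's BFS).
closeness_ig <- function(diagram, variant = "as_printed") {
  g <- as_igraph(diagram)
  dm <- igraph::distances(g, mode = "out")
  nm <- diagram$variables$name
  dm <- dm[nm, nm, drop = FALSE]
  n <- length(nm)
  cc <- vapply(nm, function(v) {
    d <- dm[v, setdiff(nm, v)]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    val <- length(d) / sum(d)
    if (variant == "wf_scaled") val <- val * length(d) / (n - 1)
    val
  }, numeric(1))
  cc
}

# Every simple directed cycle of length 2..max_len as a canonical member
# tuple, by checking all vertex subsets and all rotations-fixed orders.
cycles_bf <- function(diagram, max_len) {
  nm <- sort(diagram$variables$name)
  has <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  has[cbind(diagram$connections$source, diagram$connections$target)] <- TRUE
  found <- character(0)
  for (k in 2:max_len) {
    if (k > length(nm)) break
    subs <- utils::combn(nm, k, simplify = FALSE)
    for (sub in subs) {
      first <- sub[1]                     # lexicographically least
      rest <- sub[-1]
      perms <- all_perms(rest)
      for (pm in perms) {
        cyc <- c(first, pm)
        nxt <- c(cyc[-1], cyc[1])
        if (all(has[cbind(cyc, nxt)])) {
          found <- c(found, paste(cyc, collapse = "\x01"))
        }
      }
    }
  }
  sort(found)
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}

loop_keys <- function(loops) {
  sort(vapply(loops, function(l) paste(l$members, collapse = "\x01"),
              character(1)))
}

# Canonical rotation of a cycle given as an ordered member vector.
canon <- function(members) {
  i <- which(members == min(members))[1]
  if (i > 1) members <- c(members[i:length(members)], members[seq_len(i - 1)])
  paste(members, collapse = "\x01")
}
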