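#' Generate a random causal loop diagram
#'
#' Random diagrams with the gross structure typical of group-model-building
#' diagrams: a few dozen variables in three health categories, a density of
#' roughly four connections per variable, a handful of exogenous
#' (in-degree-zero) variables, a fraction of negative connections, and a
#' fraction of connections sitting in reciprocal pairs (2-cycles, the direct
#' feedback loops). Defaults mirror the published diagram's shape: 38
#' variables, 150 connections, 3 exogenous variables, about a third of
#' connections negative, and about 19% of connections in reciprocal pairs.
#'
#' Construction guarantees: exactly `n_connections` distinct ordered pairs,
#' no self-loops, the designated exogenous variables receive no incoming
#' connections, and every other variable receives at least one (so
#' [exogenous_variables()] returns exactly `n_exogenous` names). The
#' reciprocal-pair fraction is approximate (random fill can close extra
#' pairs). The result is deterministic given `seed`.
#'
#' @param n_variables,n_connections diagram size.
#' @param negative_fraction probability a connection is negative.
#' @param n_exogenous number of in-degree-zero variables.
#' @param reciprocal_fraction target fraction of connections in 2-cycles.
#' @param category_weights length-3 weights for (brain, physical,
#'   psychosocial) category assignment.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return A `cld` object.
#' @examples
#' d <- generate_random_cld(n_variables = 10, n_connections = 30,
#'                          n_exogenous = 2, seed = 1)
#' length(exogenous_variables(d))  # 2
#' @export
generate_random_cld <- function(n_variables = 38, n_connections = 150,
                                negative_fraction = 1 / 3, n_exogenous = 3,
                                reciprocal_fraction = 0.19,
                                category_weights = c(16, 14, 8) / 38,
                                seed = 1) {
  n <- as.integer(n_variables)
  m <- as.integer(n_connections)
  if (n < 2) stop("need at least 2 variables")
  if (n_exogenous >= n) stop("n_exogenous must be smaller than n_variables")
  if (negative_fraction < 0 || negative_fraction > 1 ||
      reciprocal_fraction < 0 || reciprocal_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  k <- n - n_exogenous                       # endogenous (allowed targets)
  if (m > (n - 1L) * k) {
    stop("infeasible: at most ", (n - 1L) * k,
         " connections can avoid incoming edges on ", n_exogenous,
         " exogenous variables")
  }
  if (m < k) {
    stop("infeasible: need at least ", k, " connections so that every ",
         "non-exogenous variable is influenced")
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  nm <- sprintf("V%0*d", nchar(n), seq_len(n))
  exo <- sort(sample(nm, n_exogenous))
  endo <- setdiff(nm, exo)
  cats <- sample(CATEGORIES, n, replace = TRUE, prob = category_weights)

  has <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  add_edge <- function(s, t) has[s, t] <<- TRUE

  # every endogenous variable gets one incoming edge; exogenous variables
  # are used as sources first so none is left isolated
  first_targets <- sample(endo)
  for (i in seq_along(first_targets)) {
    t <- first_targets[i]
    s <- if (i <= length(exo)) exo[i] else {
      cand <- setdiff(nm, t)
      cand[sample.int(length(cand), 1L)]
    }
    add_edge(s, t)
  }

  # reciprocal pairs among endogenous variables
  want_pairs <- round(reciprocal_fraction * m / 2)
  if (length(endo) >= 2 && want_pairs > 0) {
    pairs_done <- 0L
    attempts <- 0L
    while (pairs_done < want_pairs && attempts < 50L * want_pairs) {
      attempts <- attempts + 1L
      ab <- sample(endo, 2L)
      new_edges <- sum(!has[ab[1], ab[2]], !has[ab[2], ab[1]])
      if (new_edges > 0 && sum(has) + new_edges <= m) {
        add_edge(ab[1], ab[2])
        add_edge(ab[2], ab[1])
        if (new_edges > 0) pairs_done <- pairs_done + 1L
      }
    }
  }

  # fill with random absent pairs targeting endogenous variables
  allowed <- !has
  diag(allowed) <- FALSE
  allowed[, exo] <- FALSE
  need <- m - sum(has)
  if (need > 0) {
    absent <- which(allowed)
    pick <- absent[sample.int(length(absent), need)]
    has[pick] <- TRUE
  }

  ij <- which(has, arr.ind = TRUE)
  pol <- ifelse(stats::runif(nrow(ij)) < negative_fraction, -1L, 1L)
  con <- data.frame(source = nm[ij[, 1]], target = nm[ij[, 2]],
                    polarity = pol, stringsAsFactors = FALSE)
  vars <- data.frame(name = nm, category = cats, stringsAsFactors = FALSE)
  parse_edge_tables(con, vars)
}

#' Build a diagram from a feedback-loop table
#'
#' Reads each row of a loop table as a directed cycle
#' `first -> second (-> third) -> first`, takes the union of the implied
#' connections (duplicates merged), and assigns every connection polarity
#' +1 — the canonical assignment under which every listed loop is
#' reinforcing (only the polarity *product* of a loop is constrained by a
#' reinforcing-loop table, so the all-positive choice is a representative,
#' not a claim about individual connections).
#'
#' Note that the union of a set of printed loops can contain short cycles
#' beyond the printed ones: loops sharing variables compose. Enumeration on
#' the result is therefore guaranteed to *contain* each listed loop, not to
#' equal the list.
#'
#' @param rows data frame whose rows name 2 or 3 variables. Uses columns
#'   `first_variable`, `second_variable`, `third_variable` when present
#'   (the layout of [ad_loop_rows()]), otherwise the first 2-3 character
#'   columns after an optional `loop` id column. Empty strings and `NA`
#'   mark absent third members.
#' @param categories optional named character vector mapping variable names
#'   to categories. Unmapped variables default to `"physical"`; by default
#'   the packaged Alzheimer's-diagram categories are used for names that
#'   match.
#' @return A `cld` object.
#' @examples
#' fix <- fixture_from_loop_table(ad_loop_rows())
#' fix
#' @export
fixture_from_loop_table <- function(rows, categories = NULL) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  want <- c("first_variable", "second_variable", "third_variable")
  if (all(want[1:2] %in% names(rows))) {
    cols <- intersect(want, names(rows))
  } else {
    cols <- setdiff(names(rows)[vapply(rows, is.character, logical(1))],
                    "loop")[1:3]
    cols <- cols[!is.na(cols)]
  }
  if (length(cols) < 2) stop("loop rows need at least 2 variable columns")

  src <- character(0)
  tgt <- character(0)
  for (i in seq_len(nrow(rows))) {
    mem <- normalize_name(unlist(rows[i, cols], use.names = FALSE))
    mem <- mem[!is.na(mem) & mem != ""]
    if (length(mem) < 2) stop("row ", i, " names fewer than 2 variables")
    nxt <- c(mem[-1], mem[1])
    src <- c(src, mem)
    tgt <- c(tgt, nxt)
  }
  keep <- !duplicated(paste(src, tgt, sep = "\r"))
  con <- data.frame(source = src[keep], target = tgt[keep], polarity = 1L,
                    stringsAsFactors = FALSE)

  nm <- sort(unique(c(src, tgt)))
  if (is.null(categories)) categories <- ad_categories()
  cat <- ifelse(nm %in% names(categories), unname(categories[nm]), "physical")
  vars <- data.frame(name = nm, category = cat, stringsAsFactors = FALSE)
  parse_edge_tables(con, vars)
}

ad_categories <- function() {
  path <- system.file("extdata", "synthetic_ad_cld_variables.csv",
                      package = "cldtools")
  if (path == "") return(character(0))
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(v$category, v$name)
}

#' Diagram with a planted, known loop census
#'
#' Builds vertex-disjoint cycles so that the true loop census is exactly
#' the requested counts: `n_direct` reinforcing 2-cycles, `n_indirect`
#' reinforcing 3-cycles, and `n_balancing` balancing 3-cycles (one negative
#' edge each, placed at a seeded random position). Disjointness means
#' enumeration must recover exactly these loops and nothing else — the
#' generator is its own oracle.
#'
#' Direct cycles are labelled category brain, balancing cycles physical,
#' and each reinforcing 3-cycle spans all three categories (so it is
#' cross-scale under category labels).
#'
#' @param n_direct,n_indirect,n_balancing non-negative loop counts.
#' @param seed seed for the negative-edge placement.
#' @return A `cld` object.
#' @export
planted_cycle_cld <- function(n_direct, n_indirect, n_balancing, seed = 1) {
  stopifnot(n_direct >= 0, n_indirect >= 0, n_balancing >= 0)
  if (n_direct + n_indirect + n_balancing == 0) {
    stop("plant at least one cycle")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  vars <- list()
  con <- list()
  emit <- function(members, cats, pols) {
    vars[[length(vars) + 1L]] <<- data.frame(name = members, category = cats,
                                             stringsAsFactors = FALSE)
    nxt <- c(members[-1], members[1])
    con[[length(con) + 1L]] <<- data.frame(source = members, target = nxt,
                                           polarity = pols,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_direct)) {
    emit(sprintf("direct%02d_%s", i, c("a", "b")), rep("brain", 2), c(1L, 1L))
  }
  for (i in seq_len(n_indirect)) {
    emit(sprintf("indirect%02d_%s", i, c("a", "b", "c")),
         c("brain", "physical", "psychosocial"), rep(1L, 3))
  }
  for (i in seq_len(n_balancing)) {
    pols <- rep(1L, 3)
    pols[sample.int(3L, 1L)] <- -1L
    emit(sprintf("balancing%02d_%s", i, c("a", "b", "c")),
         rep("physical", 3), pols)
  }
  parse_edge_tables(do.call(rbind, con), do.call(rbind, vars))
}

#' A simple directed chain diagram
#'
#' Convenience constructor for examples and tests: the path
#' `names[1] -> names[2] -> ...` with all-positive connections.
#'
#' @param names variable names, in chain order (>= 2).
#' @param category category given to every variable.
#' @return A `cld` object.
#' @export
chain_cld <- function(names, category = "physical") {
  stopifnot(length(names) >= 2)
  vars <- data.frame(name = names, category = category,
                     stringsAsFactors = FALSE)
  con <- data.frame(source = names[-length(names)], target = names[-1],
                    polarity = 1L, stringsAsFactors = FALSE)
  parse_edge_tables(con, vars)
}
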