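# Internal mutation engine on the integer edge representation.
# edges: 2-column integer matrix (source, target); pol: +-1 vector;
# n: number of variables; pos_frac: probability that an added connection is
# positive (taken from the original diagram's sign composition).
# Draws from the current RNG stream.
mutate_edges <- function(edges, pol, n, n_mutations,
                         pos_frac, kind_probs = c(1, 1, 1) / 3) {
  kinds <- c("rewire", "add", "delete")
  events <- vector("list", n_mutations)
  for (k in seq_len(n_mutations)) {
    m <- nrow(edges)
    # feasibility of each kind on the current state
    outdeg <- tabulate(edges[, 1], nbins = n)
    rewirable <- which(outdeg[edges[, 1]] < n - 1L)
    feasible <- c(rewire = length(rewirable) > 0,
                  add = m < n * (n - 1L),
                  delete = m > 0L)
    if (!any(feasible & kind_probs > 0)) {
      stop("diagram admits no mutation of any requested kind")
    }
    repeat {
      kind <- kinds[sample.int(3L, 1L, prob = kind_probs)]
      if (feasible[[kind]]) break
    }
    if (kind == "rewire") {
      e <- rewirable[sample.int(length(rewirable), 1L)]
      s <- edges[e, 1]
      cand <- setdiff(seq_len(n), c(s, edges[edges[, 1] == s, 2]))
      tnew <- cand[sample.int(length(cand), 1L)]
      ev <- list(kind = "rewire",
                 before = c(s, edges[e, 2], pol[e]),
                 after = c(s, tnew, pol[e]))
      edges[e, 2] <- tnew
    } else if (kind == "add") {
      present <- matrix(FALSE, n, n)
      present[edges] <- TRUE
      diag(present) <- TRUE
      absent <- which(!present)               # column-major cell index
      cell <- absent[sample.int(length(absent), 1L)]
      s <- ((cell - 1L) %% n) + 1L
      t <- ((cell - 1L) %/% n) + 1L
      p <- if (stats::runif(1) < pos_frac) 1L else -1L
      ev <- list(kind = "add", before = NULL, after = c(s, t, p))
      edges <- rbind(edges, c(s, t))
      pol <- c(pol, p)
    } else {
      e <- sample.int(m, 1L)
      ev <- list(kind = "delete", before = c(edges[e, 1], edges[e, 2], pol[e]),
                 after = NULL)
      edges <- edges[-e, , drop = FALSE]
      pol <- pol[-e]
    }
    events[[k]] <- ev
  }
  list(edges = edges, pol = pol, events = events)
}

event_df <- function(events, names) {
  dfrow <- function(ev) {
    b <- ev$before
    a <- ev$after
    data.frame(
      kind = ev$kind,
      before_source = if (is.null(b)) NA_character_ else names[b[1]],
      before_target = if (is.null(b)) NA_character_ else names[b[2]],
      before_polarity = if (is.null(b)) NA_integer_ else b[3],
      after_source = if (is.null(a)) NA_character_ else names[a[1]],
      after_target = if (is.null(a)) NA_character_ else names[a[2]],
      after_polarity = if (is.null(a)) NA_integer_ else a[3],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, lapply(events, dfrow))
}

#' Randomly mutate a diagram's connection structure
#'
#' Applies `n_mutations` structural mutations sequentially to a copy of the
#' diagram. Each mutation kind is drawn with probabilities `kind_probs`
#' (default equiprobable): a *rewire* keeps a connection's source and
#' polarity but resamples its target uniformly among variables that are
#' neither the source nor already one of its targets; an *add* inserts a
#' uniformly random absent ordered pair (no self-loop), positive with
#' probability equal to the original diagram's positive-connection fraction;
#' a *delete* removes a uniformly random connection. A drawn kind that is
#' infeasible in the current state (e.g. an add on a complete digraph) is
#' redrawn, so exactly `n_mutations` mutations are applied. Mutations never
#' touch the variable set.
#'
#' Randomness comes from the current R random number generator; call
#' `set.seed()` first for reproducibility.
#'
#' @param diagram a `cld` object with at least one connection.
#' @param n_mutations number of mutations (>= 1).
#' @param kind_probs length-3 numeric weights for (rewire, add, delete).
#' @return List with `diagram` (the mutated `cld`) and `events` (a data
#'   frame logging each mutation's kind and before/after connection).
#' @examples
#' set.seed(1)
#' mut <- mutate_cld(synthetic_ad_cld(), n_mutations = 5)
#' mut$events$kind
#' @export
mutate_cld <- function(diagram, n_mutations, kind_probs = c(1, 1, 1) / 3) {
  stopifnot_cld(diagram)
  if (n_mutations < 1) stop("n_mutations must be >= 1")
  if (nrow(diagram$connections) < 1) stop("diagram has no connections")
  stopifnot(length(kind_probs) == 3, all(kind_probs >= 0), sum(kind_probs) > 0)
  idx <- cld_index(diagram)
  pos_frac <- mean(idx$polarity > 0)
  res <- mutate_edges(idx$edges, idx$polarity, idx$n, n_mutations,
                      pos_frac, kind_probs)
  con <- data.frame(source = idx$names[res$edges[, 1]],
                    target = idx$names[res$edges[, 2]],
                    polarity = as.integer(res$pol),
                    stringsAsFactors = FALSE)
  out <- parse_edge_tables(con, diagram$variables)
  list(diagram = out, events = event_df(res$events, idx$names))
}

#' Centrality robustness under a structural-mutation ensemble
#'
#' Quantifies how stable the centrality values are to small errors in the
#' diagram's wiring: generates `n_replicates` mutated copies (each
#' `n_mutations` mutations away from the original, see [mutate_cld()]),
#' computes betweenness and closeness on every copy, and summarizes each
#' variable's distribution by quartiles. The interquartile range is the
#' usual robustness error bar.
#'
#' Replicate r runs under its own RNG substream derived deterministically
#' from `seed`: child seeds are drawn once by
#' `sample.int(.Machine$integer.max, n_replicates)` under `set.seed(seed)`,
#' and replicate r is generated under `set.seed(child[r])`. Summaries are
#' therefore bit-reproducible for fixed inputs and invariant to replicate
#' execution order. Quartiles use linear interpolation
#' ([stats::quantile()] type 7).
#'
#' @param diagram a `cld` object (>= 3 variables).
#' @param n_replicates ensemble size (published protocol: 1000).
#' @param n_mutations mutations per replicate (published protocol: 5);
#'   0 gives the degenerate ensemble in which every replicate is the
#'   original diagram.
#' @param seed integer seed for the ensemble.
#' @param variant closeness variant, see [closeness_centrality()].
#' @param kind_probs mutation-kind weights, see [mutate_cld()].
#' @return Object of class `cld_robustness`: list with
#'   `per_variable` (data frame: `variable`, `measure`, `q1`, `median`,
#'   `q3`), `n_replicates`, `n_mutations`, `seed`, `closeness_variant`,
#'   `kind_probs`, and `quartile_type` (7, linear interpolation).
#' @export
centrality_ensemble <- function(diagram, n_replicates = 1000,
                                n_mutations = 5, seed,
                                variant = c("as_printed", "wf_scaled"),
                                kind_probs = c(1, 1, 1) / 3) {
  stopifnot_cld(diagram)
  variant <- match.arg(variant)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (n_mutations < 0) stop("n_mutations must be >= 0")
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  idx <- cld_index(diagram)
  n <- idx$n
  if (n < 3) stop("betweenness normalization requires at least 3 variables")
  pos_frac <- mean(idx$polarity > 0)
  norm <- (n - 1) * (n - 2)

  child_seeds <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max, n_replicates)
  })

  bc_mat <- matrix(NA_real_, n_replicates, n)
  cc_mat <- matrix(NA_real_, n_replicates, n)
  for (r in seq_len(n_replicates)) {
    edges <- idx$edges
    pol <- idx$polarity
    if (n_mutations > 0) {
      old <- get_rng_state()
      set.seed(child_seeds[r])
      res <- mutate_edges(edges, pol, n, n_mutations, pos_frac, kind_probs)
      restore_rng_state(old)
      edges <- res$edges
    }
    adj <- adj_from_edges(edges, n)
    eng <- centrality_engine(adj, n)
    bc_mat[r, ] <- eng$bc_raw / norm
    cc_mat[r, ] <- closeness_from_engine(eng, n, variant)
  }

  qs <- function(mat) apply(mat, 2, stats::quantile,
                            probs = c(0.25, 0.5, 0.75), type = 7)
  qb <- qs(bc_mat)
  qc <- qs(cc_mat)
  per_variable <- rbind(
    data.frame(variable = idx$names, measure = "betweenness",
               q1 = qb[1, ], median = qb[2, ], q3 = qb[3, ],
               stringsAsFactors = FALSE),
    data.frame(variable = idx$names, measure = "closeness",
               q1 = qc[1, ], median = qc[2, ], q3 = qc[3, ],
               stringsAsFactors = FALSE)
  )
  rownames(per_variable) <- NULL
  structure(list(per_variable = per_variable,
                 n_replicates = n_replicates, n_mutations = n_mutations,
                 seed = as.integer(seed), closeness_variant = variant,
                 kind_probs = kind_probs, quartile_type = 7L),
            class = "cld_robustness")
}

#' @export
print.cld_robustness <- function(x, ...) {
  cat(sprintf(paste0("Centrality robustness ensemble: %d replicates x %d ",
                     "mutations (seed %d, closeness '%s')\n"),
              x$n_replicates, x$n_mutations, x$seed, x$closeness_variant))
  bc <- x$per_variable[x$per_variable$measure == "betweenness", ]
  bc <- bc[order(-bc$median), ]
  top <- utils::head(bc, 5)
  cat("top betweenness medians (IQR):\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-42s %.4f (%.4f-%.4f)\n", top$variable[i],
                top$median[i], top$q1[i], top$q3[i]))
  }
  invisible(x)
}

adj_from_edges <- function(edges, n) {
  if (!nrow(edges)) return(rep(list(integer(0)), n))
  o <- order(edges[, 1], edges[, 2])
  unname(split(edges[o, 2], factor(edges[o, 1], levels = seq_len(n))))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Error-bar plot of centrality robustness
#'
#' Draws each variable's median centrality with its interquartile band from
#' a [centrality_ensemble()] summary, ordered by decreasing median.
#'
#' @param x a `cld_robustness` object.
#' @param measure `"betweenness"` or `"closeness"`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plotted subset of `x$per_variable`.
#' @export
plot_centrality_robustness <- function(x, measure = c("betweenness",
                                                      "closeness"), ...) {
  measure <- match.arg(measure)
  df <- x$per_variable[x$per_variable$measure == measure, ]
  df <- df[order(df$median, decreasing = TRUE), ]
  k <- nrow(df)
  op <- graphics::par(mar = c(10, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_len(k), df$median, ylim = range(c(df$q1, df$q3)),
                 xaxt = "n", xlab = "", ylab = measure, pch = 19, ...)
  graphics::arrows(seq_len(k), df$q1, seq_len(k), df$q3, angle = 90,
                   code = 3, length = 0.03)
  graphics::axis(1, at = seq_len(k), labels = df$variable, las = 2,
                 cex.axis = 0.6)
  invisible(df)
}
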