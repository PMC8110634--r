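#' Enumerate feedback loops
#'
#' Finds every simple directed cycle of length 2 to `max_length` and
#' classifies it. Each cycle is reported once, in its canonical rotation
#' (starting at its lexicographically least member); directed cycles are
#' identified up to rotation only, so the two traversal directions of the
#' same variable set are distinct loops. Output order is deterministic:
#' by length, then by member tuple.
#'
#' Classification: a loop is *reinforcing* when the product of its edge
#' polarities is +1 (a self-strengthening cycle) and *balancing* when the
#' product is -1 (self-limiting, homeostatic); *direct* with exactly two
#' members, *indirect* with three or more; *within-scale* when all members
#' share one spatial-scale label, *cross-scale* when they span several (see
#' [classify_loop_scale()]).
#'
#' The search is a bounded-depth DFS with a root-is-minimum pruning rule,
#' suitable for small bounds (the intended regime, e.g. `max_length <= 6`
#' on diagrams of some tens of variables); it makes no attempt at a full
#' unbounded cycle census, whose size grows combinatorially.
#'
#' @param diagram a `cld` object.
#' @param max_length maximal number of variables in a loop (>= 2).
#' @param label_field which variable label defines a loop's scale:
#'   `"scale"`, `"category"`, or `"auto"` (the default: `scale` when every
#'   variable carries one, otherwise the health category as a proxy,
#'   recorded in the result's `scale_label_field` attribute).
#' @return Object of class `cld_loops`: a list of loops, each a list with
#'   `members` (cycle order), `polarities` (edge signs, closing edge last),
#'   `polarity_product`, `loop_class` (`reinforcing`/`balancing`),
#'   `length_class` (`direct`/`indirect`) and `scale_class`
#'   (`within_scale`/`cross_scale`/`unlabeled`).
#' @examples
#' d <- planted_cycle_cld(n_direct = 1, n_indirect = 2, n_balancing = 0)
#' length(enumerate_loops(d, max_length = 3))  # 3
#' @export
enumerate_loops <- function(diagram, max_length = 3,
                            label_field = c("auto", "scale", "category")) {
  stopifnot_cld(diagram)
  label_field <- match.arg(label_field)
  if (max_length < 2) stop("max_length must be >= 2")
  idx <- cld_index(diagram)
  n <- idx$n
  pol <- matrix(0L, n, n)
  if (nrow(idx$edges)) pol[idx$edges] <- idx$polarity

  loops <- list()
  path <- integer(max_length)
  on_path <- logical(n)
  dfs <- function(root, v, depth) {
    for (w in idx$adj[[v]]) {
      if (w == root && depth >= 2L) {
        loops[[length(loops) + 1L]] <<- path[seq_len(depth)]
      } else if (w > root && !on_path[w] && depth < max_length) {
        path[depth + 1L] <<- w
        on_path[w] <<- TRUE
        dfs(root, w, depth + 1L)
        on_path[w] <<- FALSE
      }
    }
  }
  for (root in seq_len(n)) {
    path[1L] <- root
    on_path[root] <- TRUE
    dfs(root, root, 1L)
    on_path[root] <- FALSE
  }

  if (label_field == "auto") {
    label_field <- if (!anyNA(diagram$variables$scale)) "scale" else "category"
  }
  labels <- stats::setNames(diagram$variables[[label_field]],
                            diagram$variables$name)

  build <- function(verts) {
    members <- idx$names[verts]
    k <- length(verts)
    pols <- vapply(seq_len(k), function(i) {
      pol[verts[i], verts[if (i == k) 1L else i + 1L]]
    }, integer(1))
    prod_pol <- prod(pols)
    lab <- labels[members]
    scale_class <- if (anyNA(lab)) "unlabeled"
      else if (length(unique(lab)) == 1L) "within_scale" else "cross_scale"
    list(members = members, polarities = pols,
         polarity_product = prod_pol,
         loop_class = if (prod_pol > 0) "reinforcing" else "balancing",
         length_class = if (k == 2L) "direct" else "indirect",
         scale_class = scale_class)
  }
  out <- lapply(loops, build)
  if (length(out)) {
    key_len <- vapply(out, function(l) length(l$members), integer(1))
    key_tup <- vapply(out, function(l) paste(l$members, collapse = "\x01"),
                      character(1))
    out <- out[order(key_len, key_tup)]
  }
  structure(out, class = "cld_loops", scale_label_field = label_field,
            max_length = max_length)
}

#' @export
print.cld_loops <- function(x, ...) {
  k <- length(x)
  cat(sprintf("%d feedback loop(s) up to length %d (scale label: %s)\n",
              k, attr(x, "max_length"), attr(x, "scale_label_field")))
  if (k) print(loop_table(x), row.names = FALSE)
  invisible(x)
}

#' Scale classification of a loop
#'
#' A loop is *within-scale* when all its members carry the same label
#' (e.g. all cellular), *cross-scale* when at least two distinct labels
#' occur, and *unlabeled* when any member lacks the chosen label.
#'
#' @param members character vector of loop member names (or a loop element
#'   of a [enumerate_loops()] result).
#' @param diagram the `cld` the loop lives in.
#' @param label_field `"scale"` or `"category"`.
#' @return `"within_scale"`, `"cross_scale"` or `"unlabeled"`.
#' @export
classify_loop_scale <- function(members, diagram,
                                label_field = c("scale", "category")) {
  stopifnot_cld(diagram)
  label_field <- match.arg(label_field)
  if (is.list(members)) members <- members$members
  i <- match(members, diagram$variables$name)
  if (anyNA(i)) stop("loop member(s) not declared: ",
                     paste(members[is.na(i)], collapse = ", "))
  lab <- diagram$variables[[label_field]][i]
  if (anyNA(lab)) return("unlabeled")
  if (length(unique(lab)) == 1L) "within_scale" else "cross_scale"
}

#' Feedback loops through a given variable
#'
#' The subset of [enumerate_loops()] output whose members include
#' `variable`.
#'
#' @param diagram a `cld` object.
#' @param variable a declared variable name.
#' @inheritParams enumerate_loops
#' @return A `cld_loops` object.
#' @export
loops_containing <- function(diagram, variable, max_length = 3,
                             label_field = c("auto", "scale", "category")) {
  stopifnot_cld(diagram)
  variable <- normalize_name(variable)
  if (!variable %in% diagram$variables$name) {
    stop("unknown variable: ", variable)
  }
  all_loops <- enumerate_loops(diagram, max_length, label_field)
  keep <- vapply(all_loops, function(l) variable %in% l$members, logical(1))
  structure(all_loops[keep], class = "cld_loops",
            scale_label_field = attr(all_loops, "scale_label_field"),
            max_length = max_length)
}

#' Tabulate feedback loops
#'
#' One row per loop with identifiers assigned in deterministic order:
#' `RD1..` for direct loops (two members) and `RI1..` for indirect loops,
#' following the enumeration order (length, then member tuple).
#'
#' @param loops a `cld_loops` object (or plain list of loops).
#' @return Data frame with columns `loop`, `first_variable`,
#'   `second_variable`, `third_variable` (and further `..._variable`
#'   columns if longer loops are present), `loop_class`, `scale_class`.
#'   Header-only when `loops` is empty.
#' @export
loop_table <- function(loops) {
  ord <- c("first", "second", "third", "fourth", "fifth", "sixth",
           "seventh", "eighth", "ninth", "tenth")
  kmax <- max(3L, if (length(loops))
    max(vapply(loops, function(l) length(l$members), integer(1))) else 0L)
  if (kmax > length(ord)) stop("loops longer than ", length(ord),
                               " members are not tabulated")
  cols <- paste0(ord[seq_len(kmax)], "_variable")
  if (!length(loops)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(character(0)), kmax),
        list(character(0)), list(character(0))),
      c("loop", cols, "loop_class", "scale_class")))
    return(out)
  }
  is_direct <- vapply(loops, function(l) l$length_class == "direct",
                      logical(1))
  id <- character(length(loops))
  id[is_direct] <- paste0("RD", seq_len(sum(is_direct)))
  id[!is_direct] <- paste0("RI", seq_len(sum(!is_direct)))
  mem <- t(vapply(loops, function(l) {
    m <- l$members
    c(m, rep(NA_character_, kmax - length(m)))
  }, character(kmax)))
  out <- data.frame(loop = id, mem, stringsAsFactors = FALSE)
  names(out) <- c("loop", cols)
  out$loop_class <- vapply(loops, `[[`, character(1), "loop_class")
  out$scale_class <- vapply(loops, `[[`, character(1), "scale_class")
  rownames(out) <- NULL
  out
}
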