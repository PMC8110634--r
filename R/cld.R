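#' @keywords internal
"_PACKAGE"

CATEGORIES <- c("brain", "physical", "psychosocial")

# Trim leading/trailing whitespace and collapse internal runs to one space.
# Variable names are matched case-sensitively after this normalization.
normalize_name <- function(x) {
  x <- gsub("[[:space:]]+", " ", as.character(x))
  trimws(x)
}

# Map the accepted polarity encodings onto the integers +1 / -1.
# Accepted tokens: "+", "-", "+1", "-1", 1, -1 and the typographic minus.
normalize_polarity <- function(x) {
  tok <- trimws(as.character(x))
  tok <- gsub("−", "-", tok)  # typographic minus
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("+", "+1", "1")] <- 1L
  out[tok %in% c("-", "-1")] <- -1L
  out
}

#' Construct a causal loop diagram
#'
#' A causal loop diagram (CLD) is a directed graph whose nodes are system
#' variables and whose signed edges encode hypothesized causal influences.
#' A positive connection means the target moves in the same direction as the
#' source; a negative connection means it moves in the opposite direction.
#'
#' @param variables data frame with columns `name` and `category`
#'   (one of `"brain"`, `"physical"`, `"psychosocial"`), and optionally
#'   `scale` (a free-text characteristic spatial-scale label such as
#'   `"cellular"`) and `definition`.
#' @param connections data frame with columns `source`, `target`,
#'   `polarity` (any of `+`, `-`, `+1`, `-1`, `1`, `-1`) and optionally
#'   `evidence` (free-text citations).
#' @param permissive if `TRUE`, edge endpoints that are not declared in
#'   `variables` are auto-declared with category `"physical"` (with a
#'   warning) instead of raising an error, and self-loop rows are dropped
#'   with a warning instead of raising.
#'
#' @return An object of class `cld`: a list with validated, name-normalized
#'   `variables` and `connections` data frames. Connections are stored with
#'   integer polarity in `{-1, 1}`, sorted by source then target; variables
#'   are sorted by name.
#'
#' @details Invariants enforced here: unique variable names; categories from
#'   the closed three-value set; no self-loops; at most one connection per
#'   ordered pair (an effect with several mechanisms must be pre-aggregated);
#'   every endpoint declared. Reciprocal pairs (A to B and B to A) are
#'   permitted: they are the diagram's direct feedback loops.
#'
#' @examples
#' d <- cld(
#'   variables = data.frame(name = c("A", "B"),
#'                          category = c("brain", "physical")),
#'   connections = data.frame(source = c("A", "B"), target = c("B", "A"),
#'                            polarity = c("+", "-"))
#' )
#' d
#' @export
cld <- function(variables, connections, permissive = FALSE) {
  parse_edge_tables(connections, variables, permissive = permissive)
}

#' Build a diagram from tabular edge and variable rows
#'
#' Lower-level constructor used by [cld()] and the file readers: takes raw
#' rows, normalizes names and polarity tokens, and raises on any structural
#' error (duplicate ordered pair, self-loop, unknown polarity token,
#' undeclared endpoint).
#'
#' @param edge_rows data frame with columns `source`, `target`, `polarity`
#'   and optionally `evidence`.
#' @param variable_rows data frame with columns `name`, `category` and
#'   optionally `scale`, `definition`. May be `NULL` with
#'   `permissive = TRUE`, in which case all endpoints are auto-declared.
#' @inheritParams cld
#' @return A validated `cld` object.
#' @export
parse_edge_tables <- function(edge_rows, variable_rows, permissive = FALSE) {
  edge_rows <- as.data.frame(edge_rows, stringsAsFactors = FALSE)
  req <- c("source", "target", "polarity")
  if (!all(req %in% names(edge_rows))) {
    stop("edge rows must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(variable_rows)) {
    variable_rows <- data.frame(name = character(), category = character(),
                                stringsAsFactors = FALSE)
    if (!permissive) stop("variable rows are required unless permissive = TRUE")
  }
  variable_rows <- as.data.frame(variable_rows, stringsAsFactors = FALSE)
  if (!all(c("name", "category") %in% names(variable_rows))) {
    stop("variable rows must have columns: name, category")
  }

  vars <- data.frame(
    name = normalize_name(variable_rows$name),
    category = normalize_name(variable_rows$category),
    scale = if ("scale" %in% names(variable_rows))
      as.character(variable_rows$scale) else
        rep(NA_character_, nrow(variable_rows)),
    definition = if ("definition" %in% names(variable_rows))
      as.character(variable_rows$definition) else
        rep(NA_character_, nrow(variable_rows)),
    stringsAsFactors = FALSE
  )
  vars$scale[!is.na(vars$scale) & vars$scale == ""] <- NA_character_
  if (any(vars$name == "")) stop("variable names must be non-empty")
  if (anyDuplicated(vars$name)) {
    stop("duplicate variable names: ",
         paste(unique(vars$name[duplicated(vars$name)]), collapse = ", "))
  }
  bad_cat <- setdiff(unique(vars$category), CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "),
         " (must be one of ", paste(CATEGORIES, collapse = ", "), ")")
  }

  con <- data.frame(
    source = normalize_name(edge_rows$source),
    target = normalize_name(edge_rows$target),
    polarity = normalize_polarity(edge_rows$polarity),
    evidence = if ("evidence" %in% names(edge_rows))
      as.character(edge_rows$evidence) else
        rep(NA_character_, nrow(edge_rows)),
    stringsAsFactors = FALSE
  )
  if (anyNA(con$polarity)) {
    bad <- unique(trimws(as.character(edge_rows$polarity)))[
      is.na(normalize_polarity(unique(as.character(edge_rows$polarity))))]
    stop("unknown polarity token: ", paste(bad, collapse = ", "))
  }
  self <- con$source == con$target
  if (any(self)) {
    if (permissive) {
      warning(sum(self), " self-loop row(s) dropped")
      con <- con[!self, , drop = FALSE]
    } else {
      stop("self-loops are not allowed (offending variable: ",
           paste(unique(con$source[self]), collapse = ", "), ")")
    }
  }
  key <- paste(con$source, con$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- con[duplicated(key), , drop = FALSE]
    stop("duplicate ordered pair(s): ",
         paste(unique(paste(dup$source, "->", dup$target)), collapse = "; "))
  }
  undeclared <- setdiff(unique(c(con$source, con$target)), vars$name)
  if (length(undeclared)) {
    if (permissive) {
      warning("auto-declaring undeclared variable(s) with category 'physical': ",
              paste(undeclared, collapse = ", "))
      vars <- rbind(vars, data.frame(name = undeclared, category = "physical",
                                     scale = NA_character_,
                                     definition = NA_character_,
                                     stringsAsFactors = FALSE))
    } else {
      stop("connection endpoint(s) not declared as variables: ",
           paste(undeclared, collapse = ", "))
    }
  }

  vars <- vars[order(vars$name), , drop = FALSE]
  con <- con[order(con$source, con$target), , drop = FALSE]
  rownames(vars) <- NULL
  rownames(con) <- NULL
  structure(list(variables = vars, connections = con), class = "cld")
}

#' @export
print.cld <- function(x, ...) {
  n_neg <- sum(x$connections$polarity < 0)
  cat(sprintf("Causal loop diagram: %d variables, %d connections (%d negative)\n",
              nrow(x$variables), nrow(x$connections), n_neg))
  tab <- table(factor(x$variables$category, levels = CATEGORIES))
  cat("  categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  exo <- exogenous_variables(x)
  if (length(exo)) cat("  exogenous:", paste(exo, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.cld <- function(x, ...) {
  sprintf("<cld: %d variables, %d connections>",
          nrow(x$variables), nrow(x$connections))
}

is_cld <- function(x) inherits(x, "cld")

stopifnot_cld <- function(x) {
  if (!is_cld(x)) stop("expected a 'cld' object; see cld() or read_cld()")
  invisible(x)
}

# Integer-indexed view used by all graph algorithms: variable i is
# vars$name[i] (lexicographic order), adjacency as out-neighbor lists.
cld_index <- function(diagram) {
  nm <- diagram$variables$name
  n <- length(nm)
  si <- match(diagram$connections$source, nm)
  ti <- match(diagram$connections$target, nm)
  adj <- vector("list", n)
  radj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (length(si)) {
    o <- order(si, ti)
    adj <- unname(split(ti[o], factor(si[o], levels = seq_len(n))))
    o2 <- order(ti, si)
    radj <- unname(split(si[o2], factor(ti[o2], levels = seq_len(n))))
  } else {
    radj <- adj
  }
  list(n = n, names = nm, adj = adj, radj = radj,
       edges = cbind(si, ti), polarity = diagram$connections$polarity)
}

#' Validate a causal loop diagram representation
#'
#' Total validation: never raises, reports every violation found. An empty
#' `errors` table means the diagram is loadable by all analysis functions.
#'
#' @param diagram a `cld` object, or a list with `variables`/`connections`
#'   data frames that has not been through [cld()].
#' @return An object of class `cld_validation`: list with data frames
#'   `errors` and `warnings`, each with columns `code` and `message`.
#'   Error codes: `BAD_STRUCTURE`, `DUPLICATE_NAME`, `BAD_CATEGORY`,
#'   `SELF_LOOP`, `DUPLICATE_PAIR`, `BAD_POLARITY`, `UNDECLARED_VARIABLE`.
#'   Warning codes: `ISOLATED_VARIABLE`, `MISSING_SCALE`.
#' @export
validate_cld <- function(diagram) {
  err <- list()
  wrn <- list()
  add_err <- function(code, msg) err[[length(err) + 1L]] <<- c(code, msg)
  add_wrn <- function(code, msg) wrn[[length(wrn) + 1L]] <<- c(code, msg)

  ok <- is.list(diagram) && !is.null(diagram$variables) &&
    !is.null(diagram$connections)
  if (!ok) {
    add_err("BAD_STRUCTURE", "expected a list with $variables and $connections")
  } else {
    vars <- as.data.frame(diagram$variables, stringsAsFactors = FALSE)
    con <- as.data.frame(diagram$connections, stringsAsFactors = FALSE)
    if (!all(c("name", "category") %in% names(vars))) {
      add_err("BAD_STRUCTURE", "variables need columns name, category")
      vars <- data.frame(name = character(), category = character())
    }
    if (!all(c("source", "target", "polarity") %in% names(con))) {
      add_err("BAD_STRUCTURE", "connections need columns source, target, polarity")
      con <- data.frame(source = character(), target = character(),
                        polarity = integer())
    }
    nm <- normalize_name(vars$name)
    dup <- unique(nm[duplicated(nm)])
    for (d in dup) add_err("DUPLICATE_NAME", paste0("duplicate variable: ", d))
    bad <- unique(vars$category[!vars$category %in% CATEGORIES])
    for (b in bad) add_err("BAD_CATEGORY", paste0("unknown category: ", b))

    src <- normalize_name(con$source)
    tgt <- normalize_name(con$target)
    pol <- normalize_polarity(con$polarity)
    for (i in which(src == tgt)) {
      add_err("SELF_LOOP", paste0("self-loop on: ", src[i]))
    }
    key <- paste(src, tgt, sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
      add_err("DUPLICATE_PAIR", paste0("duplicate pair: ", pr[1], " -> ", pr[2]))
    }
    for (i in which(is.na(pol))) {
      add_err("BAD_POLARITY",
              paste0("unknown polarity token in row ", i, ": ", con$polarity[i]))
    }
    for (u in setdiff(unique(c(src, tgt)), nm)) {
      add_err("UNDECLARED_VARIABLE", paste0("endpoint not declared: ", u))
    }
    deg <- table(factor(c(src, tgt), levels = unique(nm)))
    for (v in names(deg)[deg == 0]) {
      add_wrn("ISOLATED_VARIABLE", paste0("variable has no connections: ", v))
    }
    if ("scale" %in% names(vars)) {
      miss <- nm[is.na(vars$scale) | vars$scale == ""]
    } else {
      miss <- nm
    }
    for (v in miss) add_wrn("MISSING_SCALE", paste0("no spatial-scale label: ", v))
  }

  as_df <- function(x) {
    if (!length(x)) return(data.frame(code = character(), message = character(),
                                      stringsAsFactors = FALSE))
    m <- do.call(rbind, x)
    data.frame(code = m[, 1], message = m[, 2], stringsAsFactors = FALSE)
  }
  structure(list(errors = as_df(err), warnings = as_df(wrn)),
            class = "cld_validation")
}

#' @export
print.cld_validation <- function(x, ...) {
  cat(sprintf("CLD validation: %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) {
    cat("errors:\n")
    for (i in seq_len(nrow(x$errors)))
      cat(sprintf("  [%s] %s\n", x$errors$code[i], x$errors$message[i]))
  }
  if (nrow(x$warnings)) {
    cat("warnings:\n")
    for (i in seq_len(nrow(x$warnings)))
      cat(sprintf("  [%s] %s\n", x$warnings$code[i], x$warnings$message[i]))
  }
  invisible(x)
}

#' Exogenous variables of a diagram
#'
#' Exogenous variables influence the system without being influenced by it:
#' they are exactly the variables with in-degree zero. They can be read as
#' the context or history of the system (and they always have betweenness
#' centrality zero, since no path can pass through them).
#'
#' @param diagram a `cld` object.
#' @return Character vector of variable names, sorted.
#' @examples
#' d <- chain_cld(c("A", "B", "C"))  # A -> B -> C
#' exogenous_variables(d)            # "A"
#' @export
exogenous_variables <- function(diagram) {
  stopifnot_cld(diagram)
  indeg <- table(factor(diagram$connections$target,
                        levels = diagram$variables$name))
  sort(names(indeg)[indeg == 0])
}

#' Convert a diagram to an igraph graph
#'
#' Vertex attributes `category` and `scale` and the edge attribute
#' `polarity` are carried over.
#'
#' @param diagram a `cld` object.
#' @return An [igraph::graph] object (directed).
#' @export
as_igraph <- function(diagram) {
  stopifnot_cld(diagram)
  g <- igraph::graph_from_data_frame(
    diagram$connections[, c("source", "target", "polarity")],
    directed = TRUE,
    vertices = diagram$variables[, c("name", "category", "scale")]
  )
  g
}
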