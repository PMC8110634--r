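#' Read a causal loop diagram from delimited files or a workbook
#'
#' Two delimited files (variables and connections) or one XLSX workbook whose
#' first sheet lists variables and second sheet lists connections. Headers are
#' required. Column names can be remapped with `col_map` when a source file
#' uses a different layout (e.g. `col_map = list(source = "From",
#' target = "To", polarity = "Sign")`).
#'
#' @param connections path to the connections file (CSV/TSV by extension), or
#'   a single `.xlsx` path holding both sheets.
#' @param variables path to the variables file; ignored for XLSX input.
#' @param col_map optional named list remapping the expected column names
#'   (`name`, `category`, `scale`, `definition`, `source`, `target`,
#'   `polarity`, `evidence`) to the columns present in the files.
#' @param permissive passed to [parse_edge_tables()].
#' @return A `cld` object.
#' @export
read_cld <- function(connections, variables = NULL, col_map = NULL,
                     permissive = FALSE) {
  if (grepl("\\.xlsx$", connections, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the 'readxl' package")
    }
    var_rows <- as.data.frame(readxl::read_excel(connections, sheet = 1))
    edge_rows <- as.data.frame(readxl::read_excel(connections, sheet = 2))
  } else {
    if (is.null(variables)) stop("a variables file is required for delimited input")
    edge_rows <- read_delim_auto(connections)
    var_rows <- read_delim_auto(variables)
  }
  if (!is.null(col_map)) {
    var_rows <- apply_col_map(var_rows, col_map,
                              c("name", "category", "scale", "definition"))
    edge_rows <- apply_col_map(edge_rows, col_map,
                               c("source", "target", "polarity", "evidence"))
  }
  parse_edge_tables(edge_rows, var_rows, permissive = permissive)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    encoding = "UTF-8", check.names = FALSE)
}

apply_col_map <- function(df, col_map, fields) {
  for (f in intersect(names(col_map), fields)) {
    from <- col_map[[f]]
    if (from %in% names(df)) names(df)[names(df) == from] <- f
  }
  df
}

#' The packaged synthetic Alzheimer's disease diagram
#'
#' Loads the synthetic reconstruction of the published 38-variable,
#' 150-connection Alzheimer's disease causal loop diagram shipped with the
#' package. The reconstruction embeds the 30 printed reinforcing feedback
#' loops (see [ad_loop_rows()]), the three printed exogenous variables
#' (education level, head trauma, ApoE-4 carriership), the three health
#' categories, and narrative-derived connections among risk factors,
#' vascular and neurodegenerative pathology, and functional outcomes. It is
#' a stand-in with the published diagram's printed structure, not a copy of
#' the deposited diagram; connection-level detail beyond the printed loop
#' table is synthetic.
#'
#' @return A `cld` object with 38 variables and 150 connections.
#' @examples
#' d <- synthetic_ad_cld()
#' d
#' @export
synthetic_ad_cld <- function() {
  read_cld(
    system.file("extdata", "synthetic_ad_cld_connections.csv",
                package = "cldtools", mustWork = TRUE),
    system.file("extdata", "synthetic_ad_cld_variables.csv",
                package = "cldtools", mustWork = TRUE)
  )
}

#' The printed feedback-loop table
#'
#' The transcription of the published table of 30 reinforcing feedback loops
#' (14 direct, RD1-RD14; 16 indirect, RI1-RI16) in the Alzheimer's disease
#' diagram. Use [fixture_from_loop_table()] to turn it into a diagram.
#'
#' @return Data frame with columns `loop`, `first_variable`,
#'   `second_variable`, `third_variable` (empty for direct loops).
#' @export
ad_loop_rows <- function() {
  utils::read.csv(
    system.file("extdata", "reinforcing_loops_table.csv",
                package = "cldtools", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Serialize a diagram
#'
#' Deterministic text serialization (variables sorted by name, connections by
#' source then target — the storage order of a `cld`). GraphML and DOT carry
#' `polarity` as an edge attribute and `category`/`scale` as node attributes;
#' negative connections are drawn dashed in DOT, mirroring the usual
#' dotted-line convention for negative polarity. JSON uses a `nodes` list of
#' `{id, category, scale, definition}` and an `edges` list of
#' `{from, to, polarity}`; `parse_cld_json()` inverts it exactly.
#'
#' @param diagram a `cld` object.
#' @param format one of `"graphml"`, `"dot"`, `"json"`.
#' @return A single character string with the serialized diagram.
#' @examples
#' d <- chain_cld(c("A", "B"))
#' identical(parse_cld_json(export_cld(d, "json")), d)
#' @export
export_cld <- function(diagram, format = c("json", "graphml", "dot")) {
  stopifnot_cld(diagram)
  format <- match.arg(format)
  switch(format,
    json = export_json(diagram),
    graphml = export_graphml(diagram),
    dot = export_dot(diagram)
  )
}

export_json <- function(diagram) {
  v <- diagram$variables
  e <- diagram$connections
  obj <- list(
    nodes = data.frame(id = v$name, category = v$category, scale = v$scale,
                       definition = v$definition, stringsAsFactors = FALSE),
    edges = data.frame(from = e$source, to = e$target, polarity = e$polarity,
                       evidence = e$evidence, stringsAsFactors = FALSE)
  )
  as.character(jsonlite::toJSON(obj, dataframe = "rows", na = "null",
                                auto_unbox = TRUE, pretty = TRUE))
}

#' Parse a JSON-serialized diagram
#'
#' Inverse of `export_cld(diagram, "json")`: round-trips variables,
#' connections, polarities and categories exactly.
#'
#' @param text JSON string produced by [export_cld()].
#' @return A `cld` object.
#' @export
parse_cld_json <- function(text) {
  obj <- jsonlite::fromJSON(text)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  names(nodes)[names(nodes) == "id"] <- "name"
  names(edges)[names(edges) == "from"] <- "source"
  names(edges)[names(edges) == "to"] <- "target"
  parse_edge_tables(edges, nodes)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

export_graphml <- function(diagram) {
  v <- diagram$variables
  e <- diagram$connections
  head <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"category\" for=\"node\" attr.name=\"category\" attr.type=\"string\"/>",
    "  <key id=\"scale\" for=\"node\" attr.name=\"scale\" attr.type=\"string\"/>",
    "  <key id=\"polarity\" for=\"edge\" attr.name=\"polarity\" attr.type=\"int\"/>",
    "  <graph id=\"cld\" edgedefault=\"directed\">"
  )
  nodes <- vapply(seq_len(nrow(v)), function(i) {
    sc <- if (is.na(v$scale[i])) "" else sprintf(
      "<data key=\"scale\">%s</data>", xml_escape(v$scale[i]))
    sprintf("    <node id=\"%s\"><data key=\"category\">%s</data>%s</node>",
            xml_escape(v$name[i]), xml_escape(v$category[i]), sc)
  }, character(1))
  edges <- vapply(seq_len(nrow(e)), function(i) {
    sprintf(paste0("    <edge source=\"%s\" target=\"%s\">",
                   "<data key=\"polarity\">%+d</data></edge>"),
            xml_escape(e$source[i]), xml_escape(e$target[i]), e$polarity[i])
  }, character(1))
  paste(c(head, nodes, edges, "  </graph>", "</graphml>", ""), collapse = "\n")
}

export_dot <- function(diagram) {
  v <- diagram$variables
  e <- diagram$connections
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  nodes <- sprintf("  %s [category=%s, scale=%s];", q(v$name), q(v$category),
                   q(ifelse(is.na(v$scale), "", v$scale)))
  style <- ifelse(e$polarity < 0, ", style=dashed", "")
  edges <- sprintf("  %s -> %s [polarity=%s%s];", q(e$source), q(e$target),
                   sprintf("\"%+d\"", e$polarity), style)
  paste(c("digraph cld {", nodes, edges, "}", ""), collapse = "\n")
}

#' Parse a GraphML-serialized diagram
#'
#' Inverse of `export_cld(diagram, "graphml")` for the subset of GraphML this
#' package writes (via the igraph reader): variables, categories, scales,
#' connections and polarities round-trip exactly. Definitions and evidence do
#' not travel through GraphML.
#'
#' @param text GraphML string.
#' @return A `cld` object.
#' @export
parse_cld_graphml <- function(text) {
  tf <- tempfile(fileext = ".graphml")
  on.exit(unlink(tf))
  writeLines(text, tf)
  g <- igraph::read_graph(tf, format = "graphml")
  vat <- igraph::vertex_attr(g)
  id_col <- if (!is.null(vat$name)) vat$name else vat$id
  vars <- data.frame(name = id_col,
                     category = vat$category,
                     scale = if (is.null(vat$scale)) NA_character_ else
                       ifelse(vat$scale == "", NA_character_, vat$scale),
                     stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(source = id_col[el[, 1]], target = id_col[el[, 2]],
                      polarity = igraph::edge_attr(g, "polarity"),
                      stringsAsFactors = FALSE)
  parse_edge_tables(edges, vars)
}
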