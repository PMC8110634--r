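#' Run the full diagram-analysis pipeline
#'
#' Ties the stages together: parse and validate the diagram, compute both
#' centralities and their Spearman correlation (under both closeness
#' variants), run the structural-robustness ensemble, enumerate and
#' tabulate feedback loops, list exogenous variables, and write everything
#' to `out_dir` as TSV/JSON (plus optional diagram exports). Every output
#' carries the run configuration: TSVs get `#`-prefixed metadata header
#' lines, and `summary.json` records the full configuration.
#'
#' @param connections a `cld` object, or path to a connections file
#'   (CSV/TSV/XLSX), see [read_cld()].
#' @param variables path to the variables file for delimited input.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for the robustness ensemble (required).
#' @param closeness_variant see [closeness_centrality()].
#' @param n_replicates,n_mutations,kind_probs see [centrality_ensemble()].
#' @param max_loop_length see [enumerate_loops()].
#' @param export_formats subset of `c("graphml", "dot", "json")`; each
#'   writes `diagram.<format>` to `out_dir`.
#' @param col_map see [read_cld()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`diagram`,
#'   `validation`, `centrality` under the requested variant, `spearman`
#'   for both variants, `robustness`, `loops`, `loop_table`, `exogenous`,
#'   `paths` of written files).
#' @export
run_cld_pipeline <- function(connections, variables = NULL, out_dir,
                             seed,
                             closeness_variant = c("as_printed", "wf_scaled"),
                             n_replicates = 1000, n_mutations = 5,
                             kind_probs = c(1, 1, 1) / 3,
                             max_loop_length = 3,
                             export_formats = character(),
                             col_map = NULL, quiet = FALSE) {
  closeness_variant <- match.arg(closeness_variant)
  if (missing(seed)) stop("an integer seed is required")
  say <- function(...) if (!quiet) message(...)

  diagram <- if (is_cld(connections)) connections else
    read_cld(connections, variables, col_map = col_map)
  report <- validate_cld(diagram)
  if (nrow(report$errors)) {
    stop("diagram failed validation:\n",
         paste(sprintf("  [%s] %s", report$errors$code,
                       report$errors$message), collapse = "\n"))
  }
  say(sprintf("diagram: %d variables, %d connections",
              nrow(diagram$variables), nrow(diagram$connections)))
  say(sprintf("config: seed=%d replicates=%d mutations=%d closeness=%s",
              as.integer(seed), n_replicates, n_mutations, closeness_variant))

  cent <- centrality_table(diagram, closeness_variant)
  bc <- stats::setNames(cent$betweenness, cent$variable)
  rho <- vapply(c("as_printed", "wf_scaled"), function(v) {
    cc <- closeness_centrality(diagram, v)
    spearman_rank_correlation(bc, cc)
  }, numeric(1))
  exo <- exogenous_variables(diagram)
  rob <- centrality_ensemble(diagram, n_replicates = n_replicates,
                             n_mutations = n_mutations, seed = seed,
                             variant = closeness_variant,
                             kind_probs = kind_probs)
  loops <- enumerate_loops(diagram, max_length = max_loop_length)
  ltab <- loop_table(loops)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(
    sprintf("# cldtools %s", as.character(utils::packageVersion("cldtools"))),
    sprintf("# seed=%d n_replicates=%d n_mutations=%d", as.integer(seed),
            n_replicates, n_mutations),
    sprintf("# closeness_variant=%s max_loop_length=%d kind_probs=%s",
            closeness_variant, max_loop_length,
            paste(signif(kind_probs, 6), collapse = ",")),
    sprintf("# n_variables=%d n_connections=%d", nrow(diagram$variables),
            nrow(diagram$connections))
  )
  write_tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(meta, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  paths <- list(
    centrality = write_tsv(cent, "centrality.tsv"),
    robustness = write_tsv(rob$per_variable, "robustness.tsv"),
    loops = write_tsv(ltab, "loops.tsv")
  )
  summary <- list(
    config = list(seed = as.integer(seed), n_replicates = n_replicates,
                  n_mutations = n_mutations, kind_probs = kind_probs,
                  closeness_variant = closeness_variant,
                  max_loop_length = max_loop_length),
    n_variables = nrow(diagram$variables),
    n_connections = nrow(diagram$connections),
    spearman_bc_cc = as.list(rho),
    exogenous = exo,
    n_loops = length(loops),
    n_direct = sum(ltab$loop_class != "" &
                     startsWith(ltab$loop, "RD")),
    n_indirect = sum(startsWith(ltab$loop, "RI")),
    n_balancing = sum(ltab$loop_class == "balancing"),
    warnings = report$warnings
  )
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (fmt in export_formats) {
    f <- file.path(out_dir, paste0("diagram.", fmt))
    writeLines(export_cld(diagram, fmt), f)
    paths[[paste0("export_", fmt)]] <- f
  }
  say(sprintf("wrote %d file(s) to %s", length(paths), out_dir))
  say(sprintf("spearman rho (BC vs CC): as_printed=%.3f wf_scaled=%.3f",
              rho[["as_printed"]], rho[["wf_scaled"]]))

  invisible(list(diagram = diagram, validation = report, centrality = cent,
                 spearman = rho, robustness = rob, loops = loops,
                 loop_table = ltab, exogenous = exo, paths = paths))
}
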