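#' Load a pipeline run configuration from YAML
#'
#' See [validate_run_config()] for the recognised fields.
#'
#' @param path YAML file path.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  cfg
}

#' Validate a pipeline run configuration
#'
#' Checks every field and returns all violations at once as a character
#' vector of messages naming the offending field (empty when valid); it
#' never raises. Recognised fields: `seed_gene` (default "AHR"), `alpha`
#' (default 0.05, in (0,1)), `k` (default 3, >= 1), `split_quantile`
#' (default 0.5), `sources` (named list source -> edge-table path),
#' `alias_map` (optional TSV path), `filters` (optional per-source overrides
#' with fields of [source_filter()]), `tcdd_datasets` / `ccrcc_datasets`
#' (lists of `{id, expr, labels}` path triples), `cohort` (cohort TSV path),
#' `annotation` (optional cluster TSV path).
#'
#' @param config configuration list (e.g. from [load_run_config()]).
#' @return character vector of error messages (length 0 when valid).
#' @export
validate_run_config <- function(config) {
  errs <- character(0)
  add <- function(...) errs <<- c(errs, sprintf(...))
  alpha <- config$alpha %||% 0.05
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    add("alpha: must be a number in (0, 1), got %s", paste(alpha, collapse = ","))
  k <- config$k %||% 3L
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    add("k: must be an integer >= 1, got %s", paste(k, collapse = ","))
  sq <- config$split_quantile %||% 0.5
  if (!is.numeric(sq) || sq <= 0 || sq >= 1)
    add("split_quantile: must lie in (0, 1)")
  seed_gene <- config$seed_gene %||% "AHR"
  if (!is.character(seed_gene) || !nzchar(trimws(seed_gene)))
    add("seed_gene: must be a non-empty symbol")
  if (!is.null(config$sources)) {
    if (is.null(names(config$sources)))
      add("sources: must be a named list (source -> path)")
    else for (s in names(config$sources)) {
      if (!toupper(s) %in% PPI_SOURCES)
        add("sources.%s: unknown source (expected one of %s)", s,
            paste(PPI_SOURCES, collapse = ", "))
      if (!file.exists(config$sources[[s]]))
        add("sources.%s: file not found: %s", s, config$sources[[s]])
    }
  }
  for (cond in c("tcdd_datasets", "ccrcc_datasets")) {
    for (i in seq_along(config[[cond]])) {
      ds <- config[[cond]][[i]]
      for (f in c("id", "expr", "labels"))
        if (is.null(ds[[f]])) add("%s[%d].%s: missing", cond, i, f)
      for (f in c("expr", "labels"))
        if (!is.null(ds[[f]]) && !file.exists(ds[[f]]))
          add("%s[%d].%s: file not found: %s", cond, i, f, ds[[f]])
    }
  }
  for (f in c("alias_map", "cohort", "annotation"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      add("%s: file not found: %s", f, config[[f]])
  errs
}

consensus_for <- function(datasets, k) {
  calls <- do.call(rbind, lapply(datasets, function(ds) {
    mat <- read_expression_tsv(ds$expr)
    labels <- read_labels_tsv(ds$labels)
    groups <- unname(labels[colnames(mat)])
    call_direction(compute_logfc(mat, groups), ds$id)
  }))
  consensus_vote(calls, k = k)
}

#' Run the full pipeline from one configuration
#'
#' Executes, in order, whichever stages the configuration describes:
#' network assembly (per-source read, filter, ego extraction, merge),
#' DEG direction consensus for the TCDD and ccRCC conditions, the per-gene
#' survival screen over the DEG-table genes, and the significance +
#' concordance selection. All tabular outputs, the merged network (GraphML
#' and SIF), the selection counts (JSON) and a run manifest (tool version,
#' config hash, input checksums, per-stage row counts) are written under
#' `out_dir`. Outputs are deterministic given identical inputs and
#' configuration; on a stage failure, outputs of completed stages are kept
#' and the manifest records the failure point.
#'
#' @param config configuration list (see [validate_run_config()]).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage results
#'   (`network`, `summary`, `deg_table`, `screen`, `selection`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  errs <- validate_run_config(config)
  if (length(errs))
    stop_usage("invalid configuration:\n  %s", paste(errs, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha %||% 0.05
  k <- as.integer(config$k %||% 3L)
  seed_gene <- toupper(config$seed_gene %||% "AHR")
  input_paths <- c(unlist(config$sources),
                   unlist(lapply(c(config$tcdd_datasets, config$ccrcc_datasets),
                                 function(d) c(d$expr, d$labels))),
                   config$alias_map, config$cohort, config$annotation)
  manifest <- list(tool = "ahrnet",
                   version = as.character(utils::packageVersion("ahrnet")),
                   config_hash = object_md5(config[setdiff(names(config), "config_path")]),
                   inputs = as.list(tools::md5sum(input_paths)),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), status = "running")
  res <- list()
  finish <- function(status, failed = NULL) {
    manifest$status <<- status
    if (!is.null(failed)) manifest$failed_stage <<- failed
    manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      finish("failed", failed = name)
      stop_usage("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if (!is.null(config$sources)) stage("network", function() {
    filters <- default_source_filters()
    for (s in names(config$filters %||% list())) {
      ov <- config$filters[[s]]
      filters[[toupper(s)]] <- do.call(source_filter, c(list(source = s), ov))
    }
    nets <- list()
    for (s in names(config$sources)) {
      src <- toupper(s)
      rec <- read_source_table(config$sources[[s]], src, strict = FALSE)
      if (!is.null(config$alias_map)) rec <- apply_alias_map(rec, config$alias_map)
      rec <- apply_source_filter(rec, filters[[src]])
      nets[[src]] <- suppressWarnings(extract_ego_network(rec, seed_gene))
    }
    merged <- merge_networks(nets)
    res$network <<- merged
    res$summary <<- summarize_network(nets, merged)
    write_network_graphml(merged, file.path(out_dir, "merged_network.graphml"))
    write_network_sif(merged, file.path(out_dir, "merged_network.sif"))
    write_tsv(res$summary, file.path(out_dir, "network_summary.tsv"))
    manifest$stages$network <<- list(n_sources = length(nets),
                                     n_nodes = length(network_nodes(merged)),
                                     n_edges = nrow(merged$edges))
  })

  if (!is.null(config$tcdd_datasets) && !is.null(config$ccrcc_datasets))
    stage("degs", function() {
      tcdd <- consensus_for(config$tcdd_datasets, k)
      ccrcc <- consensus_for(config$ccrcc_datasets, k)
      write_tsv(tcdd, file.path(out_dir, "consensus_tcdd.tsv"))
      write_tsv(ccrcc, file.path(out_dir, "consensus_ccrcc.tsv"))
      res$deg_table <<- build_deg_table(tcdd, ccrcc)
      write_tsv(res$deg_table, file.path(out_dir, "deg_table.tsv"))
      manifest$stages$degs <<- list(n_defined_tcdd = nrow(res$deg_table))
    })

  if (!is.null(config$cohort) && !is.null(res$deg_table))
    stage("survival", function() {
      cohort <- read_cohort_tsv(config$cohort)
      genes <- intersect(res$deg_table$gene, colnames(cohort$expression))
      res$screen <<- screen_panel(cohort, genes, alpha = alpha,
                                  split_quantile = config$split_quantile %||% 0.5)
      write_tsv(res$screen, file.path(out_dir, "survival_screen.tsv"))
      manifest$stages$survival <<-
        list(n_screened = nrow(res$screen),
             n_skipped = nrow(attr(res$screen, "skipped")))
    })

  if (!is.null(res$screen))
    stage("concordance", function() {
      joined <- merge(res$deg_table,
                      res$screen[c("gene", "fdr_p", "worse_survival_level")],
                      by = "gene")
      joined <- significance_filter(joined, alpha = alpha)
      joined <- concordance_classify(joined)
      joined <- assign_cluster(joined, config$annotation)
      res$selection <<- build_selection_tables(joined)
      write_tsv(res$selection$table2, file.path(out_dir, "table2.tsv"))
      write_tsv(res$selection$table3, file.path(out_dir, "table3.tsv"))
      jsonlite::write_json(res$selection$counts,
                           file.path(out_dir, "counts.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      manifest$stages$concordance <<- res$selection$counts
    })

  finish("ok")
  res$manifest <- manifest
  invisible(res)
}
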