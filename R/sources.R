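#' Interaction databases recognised by the network-assembly stage
#'
#' Canonical ordering used for provenance strings, score columns and
#' summary-table columns.
#' @export
PPI_SOURCES <- c("BIOGRID", "HIPPIE", "STRING", "INTACT", "KEGG")

# Fixed per-source TSV layouts (first two columns are always the node pair).
source_dialects <- list(
  BIOGRID = list(cols = c("node_a", "node_b", "biogrid_score"),
                 score = "biogrid_score", type = NULL, evidence = NULL),
  HIPPIE  = list(cols = c("node_a", "node_b", "score"),
                 score = "score", type = NULL, evidence = NULL),
  STRING  = list(cols = c("node_a", "node_b", "experimental_score", "evidence"),
                 score = "experimental_score", type = NULL, evidence = "evidence"),
  INTACT  = list(cols = c("node_a", "node_b", "interaction_type"),
                 score = NULL, type = "interaction_type", evidence = NULL),
  KEGG    = list(cols = c("node_a", "node_b", "pathway"),
                 score = NULL, type = NULL, evidence = "pathway")
)

check_source <- function(source) {
  source <- toupper(source)
  if (length(source) != 1L || !source %in% PPI_SOURCES)
    stop_usage("unknown interaction source '%s' (expected one of %s)",
               paste(source, collapse = ","), paste(PPI_SOURCES, collapse = ", "))
  source
}

clean_symbol <- function(x) toupper(trimws(as.character(x)))

#' Read a per-database interaction export
#'
#' Each database export is a fixed-layout TSV whose first two columns name the
#' interacting gene pair; remaining columns carry the database's native score,
#' interaction-type or evidence annotation. Gene symbols are uppercased and
#' whitespace-stripped. Rows lacking either node symbol are malformed: with
#' `strict = TRUE` (default) the first such row raises a parse error naming
#' its line number; with `strict = FALSE` malformed rows are dropped with one
#' warning each.
#'
#' @param path path to the TSV export.
#' @param dialect one of "BIOGRID", "HIPPIE", "STRING", "INTACT", "KEGG".
#' @param strict raise on malformed rows (default) or drop them with warnings.
#' @return data frame of interaction records with columns `node_a`, `node_b`,
#'   `source`, `score`, `interaction_type`, `evidence` (NA where the dialect
#'   carries no such field).
#' @export
read_source_table <- function(path, dialect, strict = TRUE) {
  dialect <- check_source(dialect)
  if (!file.exists(path)) stop_usage("interaction table not found: %s", path)
  d <- source_dialects[[dialect]]
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop_usage("%s: dialect %s needs at least two node columns, found %d",
               path, dialect, ncol(tab))
  missing_cols <- setdiff(d$cols[1:2], names(tab))
  if (length(missing_cols))
    stop_usage("%s: missing required column(s) %s for dialect %s",
               path, paste(missing_cols, collapse = ", "), dialect)

  node_a <- clean_symbol(tab$node_a)
  node_b <- clean_symbol(tab$node_b)
  bad <- which(is.na(node_a) | node_a == "" | is.na(node_b) | node_b == "" |
                 node_a == "NA" | node_b == "NA")
  if (length(bad)) {
    if (strict)
      stop_usage("%s: malformed interaction row at line %d (missing node symbol)",
                 path, bad[1L] + 1L)  # +1 for the header line
    for (i in bad)
      warning(sprintf("%s: dropping malformed row at line %d", path, i + 1L),
              call. = FALSE)
  }

  get_num <- function(col) {
    if (is.null(col) || !col %in% names(tab)) return(rep(NA_real_, nrow(tab)))
    suppressWarnings(as.numeric(tab[[col]]))
  }
  get_chr <- function(col) {
    if (is.null(col) || !col %in% names(tab)) return(rep(NA_character_, nrow(tab)))
    v <- trimws(tab[[col]])
    v[v == ""] <- NA_character_
    v
  }
  rec <- data.frame(node_a = node_a, node_b = node_b,
                    source = rep(dialect, nrow(tab)),
                    score = get_num(d$score),
                    interaction_type = get_chr(d$type),
                    evidence = get_chr(d$evidence),
                    stringsAsFactors = FALSE)
  if (length(bad)) rec <- rec[-bad, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Map gene symbols through an alias table
#'
#' Applies a two-column symbol alias map (columns `alias`, `symbol`) to both
#' node columns of an interaction-record frame, so that the same protein
#' reported under different identifiers by different databases merges to one
#' node. Symbols absent from the map pass through unchanged.
#'
#' @param records interaction records from [read_source_table()].
#' @param alias_map data frame with columns `alias` and `symbol`, or a path to
#'   a two-column TSV.
#' @export
apply_alias_map <- function(records, alias_map) {
  if (is.character(alias_map)) alias_map <- read_tsv(alias_map)
  if (!all(c("alias", "symbol") %in% names(alias_map)))
    stop_usage("alias map needs columns 'alias' and 'symbol'")
  map <- stats::setNames(clean_symbol(alias_map$symbol), clean_symbol(alias_map$alias))
  remap <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
  records$node_a <- remap(records$node_a)
  records$node_b <- remap(records$node_b)
  records
}

#' Construct a per-source interaction filter
#'
#' Encodes one database's inclusion rule: a minimum confidence score
#' (strictly greater-than by default), a whitelist of interaction types
#' and/or a blacklist of evidence channels. Records with an absent score are
#' excluded whenever a score criterion is set.
#'
#' @param source one of `PPI_SOURCES`.
#' @param min_score minimum score, or NULL for no score criterion.
#' @param strict use strict `>` comparison (default) rather than `>=`.
#' @param allowed_types character vector of admissible interaction-type
#'   labels, or NULL.
#' @param exclude_evidence character vector of evidence labels to drop, or NULL.
#' @export
source_filter <- function(source, min_score = NULL, strict = TRUE,
                          allowed_types = NULL, exclude_evidence = NULL) {
  structure(list(source = check_source(source), min_score = min_score,
                 strict = strict, allowed_types = allowed_types,
                 exclude_evidence = exclude_evidence),
            class = "source_filter")
}

#' Default per-database filters
#'
#' The five inclusion rules applied before network assembly:
#' * STRING: experimental score strictly > 0 and no text-mining evidence;
#' * BIOGRID: database score strictly > 0;
#' * HIPPIE: confidence score strictly > 0.5;
#' * IntAct: interaction type "association" or "physical association";
#' * KEGG: pass-through (manually curated pathway edges carry no score).
#'
#' @return named list of [source_filter()] objects.
#' @export
default_source_filters <- function() {
  list(
    BIOGRID = source_filter("BIOGRID", min_score = 0),
    HIPPIE  = source_filter("HIPPIE", min_score = 0.5),
    STRING  = source_filter("STRING", min_score = 0,
                            exclude_evidence = "textmining"),
    INTACT  = source_filter("INTACT",
                            allowed_types = c("association", "physical association")),
    KEGG    = source_filter("KEGG")
  )
}

#' Apply a per-source filter to interaction records
#'
#' Returns exactly the records satisfying every criterion set in `spec`,
#' preserving input order. All records must carry `spec$source`.
#'
#' @param records interaction-record data frame.
#' @param spec a [source_filter()].
#' @export
apply_source_filter <- function(records, spec) {
  stopifnot(inherits(spec, "source_filter"))
  if (nrow(records) == 0L) return(records)
  if (!all(records$source == spec$source))
    stop_usage("filter for %s applied to records from %s", spec$source,
               paste(unique(setdiff(records$source, spec$source)), collapse = ","))
  keep <- rep(TRUE, nrow(records))
  if (!is.null(spec$min_score)) {
    ok <- if (spec$strict) records$score > spec$min_score else records$score >= spec$min_score
    keep <- keep & !is.na(records$score) & ok
  }
  if (!is.null(spec$allowed_types))
    keep <- keep & !is.na(records$interaction_type) &
      records$interaction_type %in% spec$allowed_types
  if (!is.null(spec$exclude_evidence))
    keep <- keep & !(records$evidence %in% spec$exclude_evidence &
                       !is.na(records$evidence))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
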