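#' Functional cluster vocabulary
#'
#' The six functional groupings of AHR interactors used to annotate the
#' final tables: the cytosolic chaperone complex, regulatory partners,
#' transcription partners, TCDD-responsive transcripts, degradation
#' machinery acting in the absence of ligand, and a default bucket for
#' interactors with no curated functional relationship.
#' @export
CLUSTER_NAMES <- c("Cytosolic complex", "Regulatory functions",
                   "Transcription partners", "TCDD transcript",
                   "Degradation (no TCDD)", "No function")

#' Flag significant survival associations
#'
#' Marks each joined DEG/survival record significant when its FDR-adjusted
#' log-rank p-value is strictly below `alpha`. Records without an `fdr_p`
#' value are unevaluable and dropped (reported via the `unevaluable`
#' attribute).
#'
#' @param records data frame with at least columns `gene` and `fdr_p`.
#' @param alpha FDR level (default 0.05); strict `<` comparison.
#' @export
significance_filter <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records), "fdr_p" %in% names(records))
  if (alpha <= 0 || alpha >= 1) stop_usage("alpha must lie in (0, 1)")
  bad <- is.na(records$fdr_p)
  out <- records[!bad, , drop = FALSE]
  out$significant <- out$fdr_p < alpha
  attr(out, "unevaluable") <- records$gene[bad]
  rownames(out) <- NULL
  out
}

#' Flag expression--survival concordance and final selection
#'
#' A record is concordant when its ccRCC consensus expression level equals
#' the expression level its survival analysis associates with worse outcome;
#' records with an undefined ccRCC level can never be concordant. The final
#' selection requires significance AND concordance.
#'
#' @param records data frame with columns `ccrcc_level`,
#'   `worse_survival_level` and `significant` (see [significance_filter()]).
#' @export
concordance_classify <- function(records) {
  need <- c("ccrcc_level", "worse_survival_level", "significant")
  stopifnot(all(need %in% names(records)))
  records$concordant <- !is.na(records$ccrcc_level) &
    records$ccrcc_level == records$worse_survival_level
  records$selected <- records$significant & records$concordant
  records
}

#' Attach functional clusters to records
#'
#' Joins a gene-to-cluster annotation; genes without an annotation fall into
#' "No function". Annotation values must come from [CLUSTER_NAMES]
#' (case-sensitively).
#'
#' @param records data frame with a `gene` column.
#' @param annotation data frame with columns `gene` and `cluster`, a path to
#'   such a TSV, or NULL (everything defaults to "No function").
#' @export
assign_cluster <- function(records, annotation = NULL) {
  if (is.character(annotation)) annotation <- read_tsv(annotation)
  if (is.null(annotation))
    annotation <- data.frame(gene = character(0), cluster = character(0))
  if (!all(c("gene", "cluster") %in% names(annotation)))
    stop_usage("annotation needs columns 'gene' and 'cluster'")
  unknown <- setdiff(unique(annotation$cluster), CLUSTER_NAMES)
  if (length(unknown))
    stop_usage("unknown cluster name(s): %s", paste(unknown, collapse = ", "))
  map <- stats::setNames(annotation$cluster, clean_symbol(annotation$gene))
  cl <- unname(map[clean_symbol(records$gene)])
  cl[is.na(cl)] <- "No function"
  records$cluster <- cl
  records
}

#' Build the final selection tables and counts
#'
#' From fully classified records (after [significance_filter()] and
#' [concordance_classify()]) produces:
#' * `table2`: one row per tested gene in the layout of the full DEG/survival
#'   summary, with an `x_mark` ("X" iff concordant, regardless of
#'   significance) and the `selected` flag;
#' * `table3`: only selected genes (significant AND concordant), with their
#'   TCDD direction;
#' * `counts`: tested/significant/selected tallies split by TCDD direction.
#'
#' @param records classified record frame with columns `gene`, `tcdd_level`,
#'   `ccrcc_level`, `fdr_p`, `worse_survival_level`, `significant`,
#'   `concordant`, `selected`.
#' @return list with elements `table2`, `table3`, `counts`.
#' @export
build_selection_tables <- function(records) {
  need <- c("gene", "tcdd_level", "ccrcc_level", "fdr_p",
            "worse_survival_level", "significant", "concordant", "selected")
  stopifnot(all(need %in% names(records)))
  r <- records[order(records$gene), , drop = FALSE]
  table2 <- data.frame(gene = r$gene, tcdd_level = r$tcdd_level,
                       ccrcc_level = r$ccrcc_level, fdr_p = r$fdr_p,
                       worse_survival_level = r$worse_survival_level,
                       x_mark = ifelse(r$concordant, "X", ""),
                       significant = r$significant, selected = r$selected,
                       stringsAsFactors = FALSE)
  if ("cluster" %in% names(r)) table2$cluster <- r$cluster
  sel <- r[r$selected, , drop = FALSE]
  table3 <- data.frame(gene = sel$gene, tcdd_level = sel$tcdd_level,
                       ccrcc_level = sel$ccrcc_level, fdr_p = sel$fdr_p,
                       worse_survival_level = sel$worse_survival_level,
                       stringsAsFactors = FALSE)
  if ("cluster" %in% names(sel)) table3$cluster <- sel$cluster
  rownames(table2) <- rownames(table3) <- NULL
  up <- r$tcdd_level == "HIGH"
  counts <- list(
    n_tested = nrow(r),
    n_tcdd_up = sum(up), n_tcdd_down = sum(!up),
    n_sig_up = sum(r$significant & up), n_sig_down = sum(r$significant & !up),
    n_sig_total = sum(r$significant),
    n_sel_up = sum(r$selected & up), n_sel_down = sum(r$selected & !up),
    n_sel_total = sum(r$selected))
  list(table2 = table2, table3 = table3, counts = counts)
}
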