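TABLE2_MD5 <- "551924a66e11f9c2dac4deb6184a5a98"
TABLE2_NROW <- 52L

#' Load the packaged DEG/survival summary fixture
#'
#' The package ships, as a plain TSV under `inst/extdata/`, the published
#' 52-gene summary of AHR interactors with a defined TCDD-exposure
#' consensus: per gene the TCDD and ccRCC expression levels
#' (HIGH/LOW), the FDR-adjusted overall-survival log-rank p-value from the
#' ccRCC Kaplan-Meier screen, the expression level associated with worse
#' survival, and the published concordance mark (`x_mark`). The raw
#' (unadjusted) p-values behind the FDR column were never published, so this
#' table is an input to the concordance stage, not a recomputation target.
#'
#' The file is checksum- and structure-verified on load: 52 rows, closed
#' HIGH/LOW vocabulary, p-values in (0, 1].
#'
#' @param path override the packaged file (mainly for tests).
#' @return data frame with columns `gene`, `tcdd_level`, `ccrcc_level`,
#'   `os_fdr_p`, `low_surv_level`, `x_mark`.
#' @export
load_table2_fixture <- function(path = NULL) {
  packaged <- is.null(path)
  path <- path %||% system.file("extdata", "table2_degs.tsv",
                                package = "ahrnet", mustWork = TRUE)
  if (packaged && unname(tools::md5sum(path)) != TABLE2_MD5)
    stop_usage("fixture integrity error: %s does not match its frozen checksum",
               path)
  tab <- read_tsv(path, colClasses = "character")
  tab$os_fdr_p <- as.numeric(tab$os_fdr_p)
  tab$x_mark[is.na(tab$x_mark)] <- ""
  if (nrow(tab) != TABLE2_NROW)
    stop_usage("fixture integrity error: expected %d rows, found %d",
               TABLE2_NROW, nrow(tab))
  if (!all(tab$tcdd_level %in% c("HIGH", "LOW")) ||
      !all(tab$ccrcc_level %in% c("HIGH", "LOW")) ||
      !all(tab$low_surv_level %in% c("HIGH", "LOW")))
    stop_usage("fixture integrity error: expression levels outside {HIGH, LOW}")
  if (any(is.na(tab$os_fdr_p)) || any(tab$os_fdr_p <= 0) || any(tab$os_fdr_p > 1))
    stop_usage("fixture integrity error: os_fdr_p outside (0, 1]")
  if (!all(tab$x_mark %in% c("", "X")))
    stop_usage("fixture integrity error: x_mark must be '' or 'X'")
  tab
}

#' Run the significance + concordance selection on a published-style table
#'
#' Convenience wrapper chaining [significance_filter()],
#' [concordance_classify()], [assign_cluster()] and
#' [build_selection_tables()] on a table shaped like
#' [load_table2_fixture()] output (or the pipeline's own joined table).
#'
#' @param tab data frame with columns `gene`, `tcdd_level`, `ccrcc_level`,
#'   `os_fdr_p` (or `fdr_p`) and `low_surv_level` (or
#'   `worse_survival_level`).
#' @param alpha FDR significance level.
#' @param annotation optional gene-to-cluster annotation (see
#'   [assign_cluster()]).
#' @return list with `table2`, `table3`, `counts` (see
#'   [build_selection_tables()]).
#' @export
select_concordant_genes <- function(tab, alpha = 0.05, annotation = NULL) {
  if (!"fdr_p" %in% names(tab) && "os_fdr_p" %in% names(tab))
    tab$fdr_p <- tab$os_fdr_p
  if (!"worse_survival_level" %in% names(tab) && "low_surv_level" %in% names(tab))
    tab$worse_survival_level <- tab$low_surv_level
  tab <- significance_filter(tab, alpha = alpha)
  tab <- concordance_classify(tab)
  if (!is.null(annotation)) tab <- assign_cluster(tab, annotation)
  build_selection_tables(tab)
}
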