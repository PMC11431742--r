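#' Two-group log2 fold change per gene
#'
#' The direction statistic behind the consensus vote: mean log2 expression of
#' the treated group minus mean log2 expression of the control group. If the
#' matrix is not already on log scale, `log2(x + pseudocount)` is applied
#' first (all values must then be positive).
#'
#' @param mat numeric gene-by-sample matrix with unique rownames.
#' @param groups per-sample labels, `"treated"` or `"control"`.
#' @param already_log is `mat` already on log2 scale (default TRUE)?
#' @param pseudocount added before the internal log2 transform.
#' @return named numeric vector of logFC values, one per gene.
#' @export
compute_logfc <- function(mat, groups, already_log = TRUE, pseudocount = 1) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop_usage("expression matrix needs unique gene rownames")
  if (length(groups) != ncol(mat))
    stop_usage("length(groups) (%d) != number of samples (%d)",
               length(groups), ncol(mat))
  if (!all(groups %in% c("treated", "control")))
    stop_usage("groups must be 'treated' or 'control'")
  if (!any(groups == "treated") || !any(groups == "control"))
    stop_usage("both groups must be non-empty")
  if (!already_log) {
    if (any(mat <= 0)) {
      g <- rownames(mat)[which(rowSums(mat <= 0) > 0)[1L]]
      stop_usage("non-positive expression value for gene %s; cannot log-transform", g)
    }
    mat <- log2(mat + pseudocount)
  }
  rowMeans(mat[, groups == "treated", drop = FALSE]) -
    rowMeans(mat[, groups == "control", drop = FALSE])
}

#' Call per-gene regulation direction from the logFC sign
#'
#' Strict sign rule, no magnitude threshold: logFC > 0 is UP, logFC < 0 is
#' DOWN, exactly 0 is NONE.
#'
#' @param logfc named numeric vector from [compute_logfc()].
#' @param dataset_id dataset identifier carried into the output.
#' @return data frame with columns `gene`, `dataset_id`, `logfc`, `call`.
#' @export
call_direction <- function(logfc, dataset_id) {
  stopifnot(is.numeric(logfc), !is.null(names(logfc)))
  call <- ifelse(logfc > 0, "UP", ifelse(logfc < 0, "DOWN", "NONE"))
  data.frame(gene = names(logfc), dataset_id = dataset_id,
             logfc = unname(logfc), call = unname(call),
             stringsAsFactors = FALSE)
}

#' k-of-n consensus over per-dataset direction calls
#'
#' A gene is UP (resp. DOWN) when at least `k` of the `n` datasets call it UP
#' (resp. DOWN) and that direction holds the strict majority of the two vote
#' counts; otherwise its consensus is UNDEFINED. For `k > n/2` (the default
#' k = 3 over 5 datasets) the majority condition is implied by the
#' threshold; for smaller `k` it breaks the tie that would otherwise let
#' both directions qualify, and keeps the defined-gene set monotone
#' (shrinking) in `k`. A gene absent from a dataset contributes a NONE call
#' for it, so `n` is fixed across genes.
#'
#' @param calls row-bound direction-call frames from [call_direction()],
#'   at most one call per (gene, dataset).
#' @param k vote threshold (default 3).
#' @param datasets dataset identifiers defining `n`; defaults to the distinct
#'   `dataset_id`s present in `calls`.
#' @return data frame with columns `gene`, `n_datasets`, `n_up`, `n_down`,
#'   `n_none`, `k`, `consensus`.
#' @export
consensus_vote <- function(calls, k = 3L, datasets = NULL) {
  stopifnot(k >= 1L)
  datasets <- datasets %||% unique(calls$dataset_id)
  n <- length(datasets)
  calls <- calls[calls$dataset_id %in% datasets, , drop = FALSE]
  if (anyDuplicated(calls[c("gene", "dataset_id")])) {
    d <- calls[duplicated(calls[c("gene", "dataset_id")]), , drop = FALSE][1L, ]
    stop_usage("duplicate direction call for gene %s in dataset %s",
               d$gene, d$dataset_id)
  }
  genes <- sort(unique(calls$gene))
  n_up <- vapply(genes, function(g)
    sum(calls$call[calls$gene == g] == "UP"), integer(1))
  n_down <- vapply(genes, function(g)
    sum(calls$call[calls$gene == g] == "DOWN"), integer(1))
  n_none <- n - n_up - n_down
  consensus <- rep("UNDEFINED", length(genes))
  consensus[n_up >= k & n_up > n_down] <- "UP"
  consensus[n_down >= k & n_down > n_up] <- "DOWN"
  data.frame(gene = genes, n_datasets = n, n_up = unname(n_up),
             n_down = unname(n_down), n_none = unname(n_none), k = k,
             consensus = consensus, stringsAsFactors = FALSE)
}

#' Join treatment and disease consensus calls into a DEG table
#'
#' One row per gene with the TCDD-exposure and ccRCC consensus expressed as
#' HIGH (UP) / LOW (DOWN) levels; UNDEFINED maps to NA. By default only genes
#' with a defined TCDD consensus are retained, since undefined genes are
#' dropped from all downstream analyses.
#'
#' @param tcdd_consensus,ccrcc_consensus consensus frames from
#'   [consensus_vote()].
#' @param keep_undefined retain genes whose TCDD consensus is UNDEFINED.
#' @return data frame with columns `gene`, `tcdd_level`, `ccrcc_level`.
#' @export
build_deg_table <- function(tcdd_consensus, ccrcc_consensus,
                            keep_undefined = FALSE) {
  as_level <- function(x) c(UP = "HIGH", DOWN = "LOW", UNDEFINED = NA)[x]
  tc <- tcdd_consensus
  if (!keep_undefined) tc <- tc[tc$consensus != "UNDEFINED", , drop = FALSE]
  if (nrow(tc) == 0L)
    return(data.frame(gene = character(0), tcdd_level = character(0),
                      ccrcc_level = character(0), stringsAsFactors = FALSE))
  cc <- stats::setNames(as_level(ccrcc_consensus$consensus), ccrcc_consensus$gene)
  out <- data.frame(gene = tc$gene,
                    tcdd_level = unname(as_level(tc$consensus)),
                    ccrcc_level = unname(cc[tc$gene]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an expression matrix / sample-label pair from TSV
#'
#' The matrix TSV has genes in the first column and one column per sample;
#' the label TSV has columns `sample` and `group` (`treated`/`control`).
#'
#' @param path expression TSV path.
#' @return numeric matrix, genes in rows.
#' @export
read_expression_tsv <- function(path) {
  tab <- read_tsv(path)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- tab[[1]]
  mat
}

#' @rdname read_expression_tsv
#' @param mat gene-by-sample matrix to write.
#' @export
write_expression_tsv <- function(mat, path) {
  write_tsv(data.frame(gene = rownames(mat), mat, check.names = FALSE), path)
}

#' @rdname read_expression_tsv
#' @export
read_labels_tsv <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("sample", "group") %in% names(tab)))
    stop_usage("label table needs columns 'sample' and 'group': %s", path)
  stats::setNames(tab$group, tab$sample)
}
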