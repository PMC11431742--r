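#' Simulation configuration for synthetic pipeline inputs
#'
#' One config object drives all three generators; the seed fully determines
#' every output. Defaults mirror the study conditions the pipeline is
#' calibrated for: five two-group expression comparisons with three samples
#' per arm, a planted log2 shift of 1.0 against Gaussian noise of sd 0.5,
#' and a 2000-subject survival cohort with exponential event times, planted
#' hazard ratios tied to a median-recoverable HIGH/LOW expression split, and
#' ~20% uniform censoring.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes in the expression universe.
#' @param n_datasets number of two-group comparisons generated.
#' @param samples_per_group samples per arm in each comparison.
#' @param planted_up,planted_down disjoint gene-name vectors receiving a
#'   positive / negative treated-mean shift; defaults plant the first and
#'   second 20% of the gene universe.
#' @param effect_size planted shift in log2 units (default 1.0).
#' @param noise_sd per-observation Gaussian noise sd in log2 units
#'   (default 0.5).
#' @param cohort_n survival-cohort size (default 2000).
#' @param true_hr_by_gene named vector of generative hazard ratios
#'   (HIGH vs LOW) per cohort gene; genes at 1 are null. Defaults to one
#'   harmful (HR 2), one protective (HR 0.5) and three null genes.
#' @param censor_fraction target fraction of censored subjects in \[0, 1).
#' @param baseline_hazard exponential baseline hazard per month (default
#'   0.02, i.e. median survival around 35 months for the reference group).
#' @param edge_counts_per_source named vector: filter-passing seed-incident
#'   edges to plant per interaction database.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, n_datasets = 5L,
                       samples_per_group = 3L,
                       planted_up = NULL, planted_down = NULL,
                       effect_size = 1.0, noise_sd = 0.5,
                       cohort_n = 2000L, true_hr_by_gene = NULL,
                       censor_fraction = 0.2, baseline_hazard = 0.02,
                       edge_counts_per_source = c(BIOGRID = 60, HIPPIE = 50,
                                                  STRING = 25, INTACT = 10,
                                                  KEGG = 20)) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  planted_up <- planted_up %||% genes[seq_len(max(1L, n_genes %/% 5L))]
  planted_down <- planted_down %||%
    genes[max(1L, n_genes %/% 5L) + seq_len(max(1L, n_genes %/% 5L))]
  true_hr_by_gene <- true_hr_by_gene %||%
    stats::setNames(c(2, 0.5, 1, 1, 1), genes[seq_len(5L)])
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              genes = genes, n_datasets = as.integer(n_datasets),
              samples_per_group = as.integer(samples_per_group),
              planted_up = planted_up, planted_down = planted_down,
              effect_size = effect_size, noise_sd = noise_sd,
              cohort_n = as.integer(cohort_n),
              true_hr_by_gene = true_hr_by_gene,
              censor_fraction = censor_fraction,
              baseline_hazard = baseline_hazard,
              edge_counts_per_source = edge_counts_per_source)
  if (length(intersect(planted_up, planted_down)))
    stop_usage("planted_up and planted_down must be disjoint")
  if (!all(c(planted_up, planted_down) %in% genes))
    stop_usage("planted genes must belong to the %d-gene universe", n_genes)
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop_usage("censor_fraction must lie in [0, 1)")
  if (baseline_hazard <= 0) stop_usage("baseline_hazard must be positive")
  if (noise_sd < 0) stop_usage("noise_sd must be non-negative")
  if (any(true_hr_by_gene <= 0)) stop_usage("hazard ratios must be positive")
  structure(cfg, class = "sim_config")
}

#' Generate five interaction-database exports with known ground truth
#'
#' Writes one TSV per database in that database's dialect, planting
#' `edge_counts_per_source` filter-passing seed-incident edges per source
#' (overlapping partner sets across sources), plus decoy rows that the
#' assembly stage must remove: sub-threshold scores, text-mining evidence,
#' disallowed interaction types, interactor-interactor edges and duplicate
#' rows with lower scores. The merged post-filter ego network implied by the
#' planted edges is emitted alongside as `ground_truth_network.tsv`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed_gene seed node symbol (default "AHR").
#' @return list with `paths` (named per source), `truth_path` and `truth`
#'   (data frame `partner`, `sources`, `support_count`).
#' @export
gen_ppi_sources <- function(config, out_dir, seed_gene = "AHR") {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 101L)
  pool <- sprintf("INT%03d", seq_len(150L))
  counts <- config$edge_counts_per_source
  truth_sets <- list()
  paths <- character(0)

  for (src in PPI_SOURCES) {
    k <- as.integer(counts[[src]] %||% 0L)
    partners <- if (k > 0) sample(pool, min(k, length(pool))) else character(0)
    truth_sets[[src]] <- partners
    sg <- rep(seed_gene, length(partners))
    rows <- switch(src,
      BIOGRID = data.frame(node_a = sg, node_b = partners,
                           biogrid_score = round(stats::runif(length(partners), 0.1, 5), 3)),
      HIPPIE  = data.frame(node_a = sg, node_b = partners,
                           score = round(stats::runif(length(partners), 0.51, 0.99), 3)),
      STRING  = data.frame(node_a = sg, node_b = partners,
                           experimental_score = round(stats::runif(length(partners), 0.1, 1), 3),
                           evidence = rep("experiments", length(partners))),
      INTACT  = data.frame(node_a = sg, node_b = partners,
                           interaction_type = sample(c("association", "physical association"),
                                                     length(partners), replace = TRUE)),
      KEGG    = data.frame(node_a = sg, node_b = partners,
                           pathway = sample(c("hsa04066", "hsa05211", "hsa05200"),
                                            length(partners), replace = TRUE)))
    if (length(partners)) {
      decoy_partner <- sample(pool, 4L)
      decoys <- switch(src,
        BIOGRID = rbind(
          data.frame(node_a = seed_gene, node_b = decoy_partner[1:2], biogrid_score = 0),
          data.frame(node_a = partners[1L], node_b = decoy_partner[3L],
                     biogrid_score = 2)),                       # interactor-interactor
        HIPPIE = rbind(
          data.frame(node_a = seed_gene, node_b = decoy_partner[1:2],
                     score = round(stats::runif(2, 0, 0.5), 3)), # sub-threshold
          data.frame(node_a = seed_gene, node_b = partners[1L],
                     score = 0.2)),                              # duplicate, lower score
        STRING = rbind(
          data.frame(node_a = seed_gene, node_b = decoy_partner[1L],
                     experimental_score = 0, evidence = "experiments"),
          data.frame(node_a = seed_gene, node_b = decoy_partner[2L],
                     experimental_score = 0.8, evidence = "textmining")),
        INTACT = data.frame(node_a = seed_gene, node_b = decoy_partner[1:2],
                            interaction_type = "colocalization"),
        KEGG = data.frame(node_a = partners[1L], node_b = decoy_partner[1L],
                          pathway = "hsa05207"))
      rows <- rbind(rows, decoys)
      rows <- rows[sample(nrow(rows)), , drop = FALSE]
    }
    p <- file.path(out_dir, paste0(tolower(src), ".tsv"))
    write_tsv(rows, p)
    paths[src] <- p
  }

  all_partners <- sort(unique(unlist(truth_sets)))
  src_of <- vapply(all_partners, function(p)
    paste(PPI_SOURCES[vapply(PPI_SOURCES, function(s) p %in% truth_sets[[s]], TRUE)],
          collapse = ","), "")
  truth <- data.frame(partner = all_partners, sources = unname(src_of),
                      support_count = lengths(strsplit(unname(src_of), ",")),
                      stringsAsFactors = FALSE)
  truth_path <- file.path(out_dir, "ground_truth_network.tsv")
  write_tsv(truth, truth_path)
  list(paths = paths, truth_path = truth_path, truth = truth)
}

#' Generate two-group expression comparisons with planted directions
#'
#' Each of `n_datasets` comparisons draws a per-gene baseline (log2 scale,
#' N(7, 1)), shifts the treated-arm mean by +/- `effect_size` for planted
#' genes, and adds N(0, `noise_sd`) observation noise. The generative truth
#' (each gene's planted direction) is returned, and written as
#' `expression_truth.tsv` when `out_dir` is given.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, each comparison is written
#'   as `expr_<id>.tsv` + `labels_<id>.tsv`.
#' @param id_prefix dataset-id prefix (default "SIM").
#' @return list with `datasets` (each: `dataset_id`, `matrix`, `groups`) and
#'   `truth` (data frame `gene`, `direction`).
#' @export
gen_expression_datasets <- function(config, out_dir = NULL, id_prefix = "SIM") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 202L)
  genes <- config$genes
  shift <- stats::setNames(rep(0, length(genes)), genes)
  shift[config$planted_up] <- config$effect_size
  shift[config$planted_down] <- -config$effect_size
  spg <- config$samples_per_group
  groups <- rep(c("treated", "control"), each = spg)
  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    baseline <- stats::rnorm(length(genes), mean = 7, sd = 1)
    mu <- cbind(matrix(baseline + shift, length(genes), spg),
                matrix(baseline, length(genes), spg))
    mat <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                       nrow(mu), ncol(mu))
    dimnames(mat) <- list(genes, paste0("S", seq_len(2L * spg)))
    datasets[[d]] <- list(dataset_id = sprintf("%s%02d", id_prefix, d),
                          matrix = mat, groups = groups)
  }
  truth <- data.frame(gene = genes,
                      direction = ifelse(shift > 0, "UP",
                                         ifelse(shift < 0, "DOWN", "NONE")),
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ds in datasets) {
      write_expression_tsv(ds$matrix,
                           file.path(out_dir, paste0("expr_", ds$dataset_id, ".tsv")))
      write_tsv(data.frame(sample = colnames(ds$matrix), group = ds$groups),
                file.path(out_dir, paste0("labels_", ds$dataset_id, ".tsv")))
    }
    write_tsv(truth, file.path(out_dir, "expression_truth.tsv"))
  }
  list(datasets = datasets, truth = truth)
}

# Uniform-censoring upper bound u such that the expected censored fraction
# over the cohort's exponential event rates equals the target.
censor_upper_bound <- function(rates, target) {
  f <- function(u) mean((1 - exp(-rates * u)) / (rates * u)) - target
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Generate a survival cohort with planted per-gene hazard ratios
#'
#' Each gene in `true_hr_by_gene` splits the cohort into equal HIGH/LOW
#' halves; its expression values are drawn well-separated around the split
#' so that a median dichotomization recovers the generative grouping
#' exactly. Event times are exponential with hazard
#' `baseline_hazard * prod(HR_g ^ I(subject HIGH for g))` (genes at HR 1
#' contribute nothing, so configs with a single non-unit gene have an exact
#' marginal hazard ratio). Censoring is independent Uniform(0, u), with u
#' solved so the expected censored fraction matches `censor_fraction`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; writes `cohort.tsv` and
#'   `survival_truth.tsv` when given.
#' @return list with `cohort` (a [survival_cohort()]) and `truth` (data
#'   frame `gene`, `true_hr`).
#' @export
gen_survival_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303L)
  n <- config$cohort_n
  hrs <- config$true_hr_by_gene
  genes <- names(hrs)
  high <- matrix(FALSE, n, length(genes), dimnames = list(NULL, genes))
  expr <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
  for (j in seq_along(genes)) {
    hi <- sample(n, n %/% 2L)
    high[hi, j] <- TRUE
    expr[, j] <- ifelse(high[, j], 1, 0) + stats::runif(n, -0.3, 0.3)
  }
  log_rate <- log(config$baseline_hazard) +
    high %*% matrix(log(hrs), ncol = 1L)
  rate <- exp(drop(log_rate))
  t_event <- stats::rexp(n, rate)
  if (config$censor_fraction > 0) {
    u <- censor_upper_bound(rate, config$censor_fraction)
    c_time <- stats::runif(n, 0, u)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  cohort <- survival_cohort(time, event, expr)
  truth <- data.frame(gene = genes, true_hr = unname(hrs),
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    write_tsv(truth, file.path(out_dir, "survival_truth.tsv"))
  }
  list(cohort = cohort, truth = truth)
}
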