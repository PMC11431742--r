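#' Build a survival cohort object
#'
#' Follow-up time (months), an event indicator (1 = death observed, 0 =
#' censored) and a subjects-by-genes expression matrix used for per-gene
#' dichotomization.
#'
#' @param time positive follow-up times in months.
#' @param event 0/1 (or logical) event indicator.
#' @param expression numeric matrix, one row per subject, one column per gene.
#' @param subject_id optional subject identifiers.
#' @export
survival_cohort <- function(time, event, expression, subject_id = NULL) {
  event <- as.integer(event)
  expression <- as.matrix(expression)
  if (any(!is.finite(time)) || any(time <= 0))
    stop_usage("all follow-up times must be positive and finite")
  if (!all(event %in% c(0L, 1L))) stop_usage("event must be 0/1")
  if (length(time) != length(event) || nrow(expression) != length(time))
    stop_usage("time, event and expression rows must have equal length")
  if (is.null(colnames(expression)))
    stop_usage("expression matrix needs gene column names")
  structure(list(subject_id = subject_id %||% paste0("S", seq_along(time)),
                 time = as.numeric(time), event = event,
                 expression = expression),
            class = "survival_cohort")
}

#' Median split of an expression vector into HIGH/LOW groups
#'
#' Labels a subject HIGH when its value is strictly above the chosen
#' quantile (median by default); values tied with the cutpoint go to LOW.
#' At least 4 subjects are required, and a split leaving either group empty
#' (all values identical, or the maximum equal to the cutpoint) is a
#' degenerate-split error — callers screening many genes skip such genes.
#'
#' @param values numeric expression values, one per subject.
#' @param quantile cut quantile in (0,1); default 0.5 (the median).
#' @return character vector of "HIGH"/"LOW" labels.
#' @export
dichotomize_by_median <- function(values, quantile = 0.5) {
  if (length(values) < 4L) stop_usage("need at least 4 subjects to dichotomize")
  if (any(!is.finite(values))) stop_usage("expression values must be finite")
  cut <- stats::quantile(values, quantile, names = FALSE)
  lab <- ifelse(values > cut, "HIGH", "LOW")
  if (!any(lab == "HIGH") || !any(lab == "LOW"))
    stop(structure(class = c("degenerate_split", "error", "condition"),
                   list(message = "degenerate split: a group is empty",
                        call = NULL)))
  lab
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the curve as a data
#' frame. A subject censored at an event time is counted at risk for that
#' time.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @return `km_curve` data frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop_usage("empty cohort")
  if (length(time) != length(event)) stop_usage("time/event length mismatch")
  if (any(time <= 0)) stop_usage("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Direct evaluation of the standard one-degree-of-freedom log-rank
#' chi-square: observed minus expected events in the first group, summed
#' over distinct event times with the usual hypergeometric variance. The
#' direct form keeps per-call overhead low enough to screen hundreds of
#' thousands of gene/cohort combinations; it agrees with
#' [survival::survdiff()] to numerical precision.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @param group two-level group labels, both levels present.
#' @param timefix normalize near-tied floating-point times with
#'   [survival::aeqSurv()] (the survdiff/coxph convention). Callers testing
#'   many genes against one fixed cohort may normalize once and pass FALSE.
#' @return list with `statistic` (chi-square), `p_value`, `df` (always 1).
#' @export
logrank_test <- function(time, event, group, timefix = TRUE) {
  n <- length(time)
  if (length(event) != n || length(group) != n)
    stop_usage("time, event and group must have equal length")
  if (timefix) {
    s <- survival::aeqSurv(survival::Surv(time, event))
    time <- s[, 1L]
    event <- s[, 2L]
  }
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L)
    stop_usage("log-rank test needs exactly two non-empty groups (got %d)",
               length(lev))
  g1 <- as.character(group) == lev[1L]
  ot <- order(time)
  t <- time[ot]; e <- event[ot] == 1L; in1 <- g1[ot]
  t1 <- t[in1]                      # sorted subset
  ut <- unique(t[e])                # distinct event times, ascending
  if (length(ut) == 0L) return(list(statistic = 0, p_value = 1, df = 1L))
  n_at  <- n - findInterval(ut, t, left.open = TRUE)
  n1_at <- length(t1) - findInterval(ut, t1, left.open = TRUE)
  d  <- tabulate(findInterval(t[e], ut), length(ut))
  d1 <- tabulate(findInterval(t[e & in1], ut), length(ut))
  expct <- d * n1_at / n_at
  ok <- n_at > 1L
  v <- sum(d[ok] * (n1_at[ok] / n_at[ok]) * (1 - n1_at[ok] / n_at[ok]) *
             (n_at[ok] - d[ok]) / (n_at[ok] - 1L))
  if (v <= 0) return(list(statistic = 0, p_value = 1, df = 1L))
  stat <- (sum(d1) - sum(expct))^2 / v
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Hazard ratio for a binary expression group
#'
#' Proportional-hazards fit of a single HIGH-vs-LOW indicator via
#' [survival::coxph()] (Newton-Raphson on the partial likelihood; Breslow
#' tie handling by default so the score test coincides with the log-rank
#' statistic). The 95% CI is `exp(beta +/- z * se)` from the observed
#' information. A monotone partial likelihood (all events on one side,
#' complete separation) is flagged as `diverged` with an unbounded CI.
#'
#' @inheritParams logrank_test
#' @param group labels; level "HIGH" (if present, otherwise the second
#'   sorted level) is the numerator of the hazard ratio.
#' @param ties tie handling, "breslow" (default) or "efron".
#' @param conf_level CI coverage, default 0.95.
#' @return list with `hr`, `ci_low`, `ci_high`, `beta`, `se`, `diverged`.
#' @export
cox_hr_binary <- function(time, event, group, ties = c("breslow", "efron"),
                          conf_level = 0.95) {
  ties <- match.arg(ties)
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L) stop_usage("need exactly two non-empty groups")
  if (sum(event) == 0L) stop_usage("no events observed; hazard ratio undefined")
  high <- if ("HIGH" %in% lev) "HIGH" else lev[2L]
  x <- as.integer(as.character(group) == high)
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (diverged)
    list(hr = exp(beta), ci_low = 0, ci_high = Inf, beta = beta, se = se,
         diverged = TRUE)
  else
    list(hr = exp(beta), ci_low = exp(beta - z * se),
         ci_high = exp(beta + z * se), beta = beta, se = se, diverged = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment over the screened family, returned in input order
#' (delegates to [stats::p.adjust()]). All p-values must lie in (0, 1].
#'
#' @param p raw p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop_usage("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene survival screen with FDR control
#'
#' For every gene: dichotomize the cohort at the expression median, compare
#' the HIGH and LOW groups by the log-rank test, estimate the HIGH-vs-LOW
#' hazard ratio with its 95% CI, and record which expression level
#' associates with worse survival (HIGH iff HR > 1). Benjamini-Hochberg
#' adjustment is applied across exactly the genes actually tested in this
#' run; genes with a degenerate median split are skipped, excluded from the
#' FDR family, and listed in the `skipped` attribute.
#'
#' @param cohort a [survival_cohort()].
#' @param genes genes to screen; defaults to all columns of the cohort's
#'   expression matrix.
#' @param alpha FDR significance level; significance uses the strict
#'   inequality `fdr_p < alpha`.
#' @param split_quantile dichotomization quantile (0.5 = median).
#' @param ties tie handling for the Cox fit.
#' @return data frame with one row per tested gene: `gene`,
#'   `logrank_statistic`, `p_value`, `fdr_p`, `hr`, `hr_ci_low`,
#'   `hr_ci_high`, `worse_survival_level`, `significant`, `diverged`.
#' @export
screen_panel <- function(cohort, genes = NULL, alpha = 0.05,
                         split_quantile = 0.5, ties = "breslow") {
  stopifnot(inherits(cohort, "survival_cohort"))
  genes <- genes %||% colnames(cohort$expression)
  missing <- setdiff(genes, colnames(cohort$expression))
  if (length(missing))
    stop_usage("gene(s) absent from cohort expression: %s",
               paste(utils::head(missing, 5), collapse = ", "))
  rows <- vector("list", length(genes))
  skipped <- list()
  tfix <- survival::aeqSurv(survival::Surv(cohort$time, cohort$event))
  for (i in seq_along(genes)) {
    g <- genes[i]
    lab <- tryCatch(dichotomize_by_median(cohort$expression[, g], split_quantile),
                    degenerate_split = function(e) NULL)
    if (is.null(lab)) {
      warning(sprintf("gene %s skipped: degenerate expression split", g),
              call. = FALSE)
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene = g, reason = "degenerate split",
                   stringsAsFactors = FALSE)
      next
    }
    lr <- logrank_test(tfix[, 1L], tfix[, 2L], lab, timefix = FALSE)
    cx <- cox_hr_binary(cohort$time, cohort$event, lab, ties = ties)
    rows[[i]] <- data.frame(
      gene = g, logrank_statistic = lr$statistic, p_value = lr$p_value,
      hr = cx$hr, hr_ci_low = cx$ci_low, hr_ci_high = cx$ci_high,
      worse_survival_level = if (cx$hr > 1) "HIGH" else "LOW",
      diverged = cx$diverged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene = character(0), logrank_statistic = numeric(0),
                      p_value = numeric(0), hr = numeric(0),
                      hr_ci_low = numeric(0), hr_ci_high = numeric(0),
                      worse_survival_level = character(0),
                      diverged = logical(0), stringsAsFactors = FALSE)
  out$fdr_p <- if (nrow(out)) bh_adjust(out$p_value) else numeric(0)
  out$significant <- out$fdr_p < alpha
  out <- out[c("gene", "logrank_statistic", "p_value", "fdr_p", "hr",
               "hr_ci_low", "hr_ci_high", "worse_survival_level",
               "significant", "diverged")]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(0), reason = character(0))
  out
}

#' Read / write a survival cohort TSV
#'
#' Layout: columns `subject`, `time_months`, `event`, then one column per
#' gene.
#'
#' @param path TSV path.
#' @export
read_cohort_tsv <- function(path) {
  tab <- read_tsv(path)
  need <- c("subject", "time_months", "event")
  if (!all(need %in% names(tab)))
    stop_usage("cohort table needs columns %s: %s",
               paste(need, collapse = ", "), path)
  expr <- as.matrix(tab[, setdiff(names(tab), need), drop = FALSE])
  mode(expr) <- "numeric"
  survival_cohort(tab$time_months, tab$event, expr, subject_id = tab$subject)
}

#' @rdname read_cohort_tsv
#' @param cohort a [survival_cohort()].
#' @export
write_cohort_tsv <- function(cohort, path) {
  write_tsv(data.frame(subject = cohort$subject_id,
                       time_months = cohort$time, event = cohort$event,
                       cohort$expression, check.names = FALSE), path)
}
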