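# Small in-code fixture builders shared across test files.

make_records <- function(node_a, node_b, source = "HIPPIE", score = NA_real_,
                         interaction_type = NA_character_,
                         evidence = NA_character_) {
  n <- max(length(node_a), length(node_b))
  data.frame(node_a = rep_len(node_a, n), node_b = rep_len(node_b, n),
             source = rep_len(source, n), score = rep_len(score, n),
             interaction_type = rep_len(interaction_type, n),
             evidence = rep_len(evidence, n), stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# Independent recount of a merged ego network: per-source partner sets from
# a list of record frames, filtered by a hand-coded restatement of the five
# database rules, unioned over sources.
brute_force_merge <- function(records_by_source, seed = "AHR") {
  sets <- lapply(names(records_by_source), function(src) {
    r <- records_by_source[[src]]
    keep <- switch(src,
      BIOGRID = !is.na(r$score) & r$score > 0,
      HIPPIE  = !is.na(r$score) & r$score > 0.5,
      STRING  = !is.na(r$score) & r$score > 0 &
        !(r$evidence %in% "textmining" & !is.na(r$evidence)),
      INTACT  = r$interaction_type %in% c("association", "physical association"),
      KEGG    = rep(TRUE, nrow(r)))
    r <- r[keep & (r$node_a == seed | r$node_b == seed), , drop = FALSE]
    partners <- ifelse(r$node_a == seed, r$node_b, r$node_a)
    unique(partners[partners != seed])
  })
  names(sets) <- names(records_by_source)
  sets
}

# Naive step-by-step risk-set recount of the product-limit estimator,
# evaluated at the distinct observed times.
naive_km <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(event == 1 & time == ut[i])
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Direct evaluation of the BH step-up formula, independent of p.adjust.
manual_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
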