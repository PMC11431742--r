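test_that("ego extraction keeps only seed-incident edges", {
  rec <- make_records(c("AHR", "X", "AHR"), c("X", "Y", "Y"), "KEGG")
  net <- extract_ego_network(rec, "AHR")
  expect_equal(net$edges$partner, c("X", "Y"))
  expect_equal(attr(net, "n_dropped_nonincident"), 1L)

  # self-loop dropped by default, kept on request
  loop <- make_records("AHR", "AHR", "KEGG")
  expect_warning(none <- extract_ego_network(loop, "AHR"), "no AHR-incident")
  expect_equal(nrow(none$edges), 0L)
  withloop <- extract_ego_network(loop, "AHR", keep_self_loops = TRUE)
  expect_equal(withloop$edges$partner, "AHR")

  expect_error(extract_ego_network(rec, ""), "non-empty")
})

test_that("duplicate edges within a source collapse to the best score", {
  rec <- make_records(rep("AHR", 3), c("X", "X", "Y"), "HIPPIE",
                      score = c(0.6, 0.9, 0.7))
  net <- extract_ego_network(rec, "AHR")
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$score_HIPPIE[net$edges$partner == "X"], 0.9)

  # 10-row mixed fixture: 6 seed-incident (one duplicated) -> 5 edges
  rec10 <- make_records(
    c("AHR", "AHR", "AHR", "AHR", "AHR", "AHR", "X", "Y", "Z", "W"),
    c("A", "B", "C", "D", "E", "A", "Y", "Z", "W", "X"),
    "BIOGRID", score = seq(0.1, 1, length.out = 10))
  net10 <- extract_ego_network(rec10, "AHR")
  expect_equal(nrow(net10$edges), 5L)
  expect_equal(attr(net10, "n_dropped_nonincident"), 4L)
})

test_that("merge unions provenance and is idempotent and commutative", {
  n1 <- extract_ego_network(make_records("AHR", "X", "BIOGRID", 2), "AHR")
  n2 <- extract_ego_network(make_records("X", "AHR", "HIPPIE", 0.8), "AHR")
  m <- merge_networks(list(n1, n2))
  expect_equal(m$edges$sources, "BIOGRID,HIPPIE")
  expect_equal(m$edges$support_count, 2L)
  expect_equal(m$edges$score_BIOGRID, 2)
  expect_equal(m$edges$score_HIPPIE, 0.8)

  # idempotence
  twice <- merge_networks(list(m, m))
  expect_equal(twice$edges, m$edges)

  # commutativity / associativity in resulting sets
  n3 <- extract_ego_network(make_records("AHR", c("Y", "X"), "KEGG"), "AHR")
  perms <- list(list(n1, n2, n3), list(n3, n1, n2), list(n2, n3, n1))
  merged <- lapply(perms, merge_networks)
  for (m2 in merged[-1]) expect_equal(m2$edges, merged[[1]]$edges)

  bad <- extract_ego_network(make_records("TP53", "X", "KEGG"), "TP53")
  expect_error(merge_networks(list(n1, bad)), "different seeds")
})

test_that("generated sources assemble into the generator's ground truth and
           match a brute-force set union", {
  cfg <- sim_config(seed = 42)
  td <- withr::local_tempdir()
  ppi <- gen_ppi_sources(cfg, td)
  filters <- default_source_filters()
  recs <- nets <- list()
  for (s in names(ppi$paths)) {
    recs[[s]] <- read_source_table(ppi$paths[[s]], s)
    nets[[s]] <- extract_ego_network(apply_source_filter(recs[[s]], filters[[s]]),
                                     "AHR")
  }
  merged <- merge_networks(nets)

  # generator's own truth record
  expect_equal(merged$edges$partner, ppi$truth$partner)
  expect_equal(merged$edges$sources, ppi$truth$sources)
  expect_equal(merged$edges$support_count, ppi$truth$support_count)

  # independent brute-force union over hand-filtered per-source partner sets
  sets <- brute_force_merge(recs)
  expect_setequal(merged$edges$partner, unique(unlist(sets)))
  for (s in names(sets))
    expect_setequal(nets[[s]]$edges$partner, sets[[s]])

  # sum of support counts equals the sum of per-source edge counts
  expect_equal(sum(merged$edges$support_count),
               sum(vapply(nets, function(n) nrow(n$edges), 0L)))

  # all merged edges remain seed-incident with non-empty provenance
  expect_true(all(merged$edges$support_count >= 1L))
  expect_true(all(nchar(merged$edges$sources) > 0L))
})

test_that("network summary uses the canonical column order and recounts", {
  cfg <- sim_config(seed = 5)
  td <- withr::local_tempdir()
  ppi <- gen_ppi_sources(cfg, td)
  filters <- default_source_filters()
  nets <- lapply(stats::setNames(nm = PPI_SOURCES), function(s)
    extract_ego_network(apply_source_filter(read_source_table(ppi$paths[[s]], s),
                                            filters[[s]]), "AHR"))
  merged <- merge_networks(nets)
  summ <- summarize_network(nets, merged)
  expect_equal(names(summ), c("metric", "BIOGRID", "HIPPIE", "STRING",
                              "IntAct", "KEGG", "Merged"))
  for (s in PPI_SOURCES) {
    col <- c(BIOGRID = "BIOGRID", HIPPIE = "HIPPIE", STRING = "STRING",
             INTACT = "IntAct", KEGG = "KEGG")[[s]]
    expect_equal(summ[[col]], c(nrow(nets[[s]]$edges) + 1L, nrow(nets[[s]]$edges)))
  }
  expect_equal(summ$Merged[2], nrow(merged$edges))
  expect_equal(summ$Merged[1], summ$Merged[2] + 1L)  # star network: nodes = edges + 1

  # all-zero summary on empty inputs
  empty <- suppressWarnings(extract_ego_network(make_records(character(0),
                                                             character(0), "KEGG"),
                                                "AHR"))
  zsum <- summarize_network(stats::setNames(rep(list(empty), 5), PPI_SOURCES), empty)
  expect_true(all(as.matrix(zsum[, -1]) == 0))
})

test_that("GraphML round-trip preserves nodes, edges, provenance and scores", {
  cfg <- sim_config(seed = 9)
  td <- withr::local_tempdir()
  ppi <- gen_ppi_sources(cfg, td)
  nets <- lapply(stats::setNames(nm = PPI_SOURCES), function(s)
    extract_ego_network(apply_source_filter(read_source_table(ppi$paths[[s]], s),
                                            default_source_filters()[[s]]), "AHR"))
  merged <- merge_networks(nets)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(merged, path)
  back <- read_network_graphml(path)
  expect_setequal(network_nodes(back), network_nodes(merged))
  expect_equal(back$edges, merged$edges)

  sif <- withr::local_tempfile(fileext = ".sif")
  write_network_sif(merged, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(merged$edges))
  expect_true(all(grepl("^AHR pp ", lines)))
})
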