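score_cols <- paste0("score_",
                     c("BIOGRID", "HIPPIE", "STRING", "INTACT", "KEGG"))

empty_edges <- function() {
  out <- data.frame(partner = character(0), sources = character(0),
                    support_count = integer(0), stringsAsFactors = FALSE)
  for (sc in score_cols) out[[sc]] <- numeric(0)
  out
}

new_ego_network <- function(seed, edges, n_dropped_nonincident = 0L) {
  edges <- edges[order(edges$partner), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(seed = seed, edges = edges),
            n_dropped_nonincident = n_dropped_nonincident,
            class = "ego_network")
}

#' @export
print.ego_network <- function(x, ...) {
  cat(sprintf("<ego_network> seed %s: %d partner(s), %d edge(s)\n",
              x$seed, nrow(x$edges), nrow(x$edges)))
  invisible(x)
}

#' Nodes of an ego network
#'
#' The seed plus its retained direct interactors.
#' @param net an `ego_network`.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "ego_network"))
  unique(c(net$seed, net$edges$partner))
}

#' Extract the seed-centred ego network from interaction records
#'
#' Keeps only edges incident to `seed`; interactions between the seed's
#' interactors are dropped (and counted in the `n_dropped_nonincident`
#' attribute), so the result is a star network around the seed. Duplicate
#' seed--partner rows within a source collapse to one edge retaining that
#' source's maximum score. Self-loops on the seed are discarded unless
#' `keep_self_loops = TRUE`.
#'
#' @param records interaction-record data frame (any mix of sources).
#' @param seed seed gene symbol.
#' @param keep_self_loops retain a (seed, seed) edge if present.
#' @return an `ego_network`: list with `seed` and an `edges` data frame
#'   (`partner`, `sources` provenance string, `support_count`, one
#'   `score_<SOURCE>` column per database).
#' @export
extract_ego_network <- function(records, seed, keep_self_loops = FALSE) {
  seed <- clean_symbol(seed)
  if (is.na(seed) || seed == "") stop_usage("seed symbol must be non-empty")
  inc <- records$node_a == seed | records$node_b == seed
  n_drop <- sum(!inc)
  rec <- records[inc, , drop = FALSE]
  if (!keep_self_loops)
    rec <- rec[!(rec$node_a == seed & rec$node_b == seed), , drop = FALSE]
  if (nrow(rec) == 0L) {
    warning(sprintf("no %s-incident interactions found", seed), call. = FALSE)
    return(new_ego_network(seed, empty_edges(), n_drop))
  }
  partner <- ifelse(rec$node_a == seed, rec$node_b, rec$node_a)
  partner[rec$node_a == seed & rec$node_b == seed] <- seed
  # per (partner, source): keep the maximum score (NA if none present)
  key <- paste(partner, rec$source, sep = "\r")
  best <- vapply(split(rec$score, key), function(s)
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE), numeric(1))
  ks <- strsplit(names(best), "\r", fixed = TRUE)
  ps <- vapply(ks, `[`, "", 1L)
  ss <- vapply(ks, `[`, "", 2L)

  edges <- empty_edges()
  for (p in sort(unique(ps))) {
    src <- PPI_SOURCES[PPI_SOURCES %in% ss[ps == p]]
    row <- data.frame(partner = p, sources = paste(src, collapse = ","),
                      support_count = length(src), stringsAsFactors = FALSE)
    for (s in PPI_SOURCES)
      row[[paste0("score_", s)]] <-
        if (s %in% src) unname(best[paste(p, s, sep = "\r")]) else NA_real_
    edges <- rbind(edges, row)
  }
  new_ego_network(seed, edges, n_drop)
}

#' Merge per-source ego networks into one provenance-annotated network
#'
#' Edge identity is the unordered seed--partner pair; provenance is the union
#' of contributing databases, each keeping its own best score. All inputs
#' must share the same seed. The merge is commutative, associative and
#' idempotent in the resulting node and edge sets.
#'
#' @param networks list of `ego_network` objects.
#' @return merged `ego_network`.
#' @export
merge_networks <- function(networks) {
  stopifnot(length(networks) >= 1L,
            all(vapply(networks, inherits, TRUE, "ego_network")))
  seeds <- unique(vapply(networks, function(n) n$seed, ""))
  if (length(seeds) != 1L)
    stop_usage("cannot merge networks with different seeds: %s",
               paste(seeds, collapse = ", "))
  all_edges <- do.call(rbind, lapply(networks, function(n) n$edges))
  if (nrow(all_edges) == 0L) return(new_ego_network(seeds, empty_edges()))
  merged <- empty_edges()
  for (p in sort(unique(all_edges$partner))) {
    sub <- all_edges[all_edges$partner == p, , drop = FALSE]
    row <- data.frame(partner = p, sources = "", support_count = 0L,
                      stringsAsFactors = FALSE)
    src <- character(0)
    for (s in PPI_SOURCES) {
      sc <- sub[[paste0("score_", s)]]
      here <- vapply(strsplit(sub$sources, ",", fixed = TRUE),
                     function(v) s %in% v, TRUE)
      if (any(here)) {
        src <- c(src, s)
        row[[paste0("score_", s)]] <-
          if (all(is.na(sc[here]))) NA_real_ else max(sc[here], na.rm = TRUE)
      } else row[[paste0("score_", s)]] <- NA_real_
    }
    row$sources <- paste(src, collapse = ",")
    row$support_count <- length(src)
    merged <- rbind(merged, row)
  }
  new_ego_network(seeds, merged)
}

#' Tabulate per-source and merged network sizes
#'
#' One column per database plus the merged network, rows `Nodes` and `Edges`
#' (the layout of the usual network-derivation summary table).
#'
#' @param networks named list of per-source `ego_network`s (names from
#'   `PPI_SOURCES`).
#' @param merged merged `ego_network`.
#' @export
summarize_network <- function(networks, merged) {
  cols <- c(BIOGRID = "BIOGRID", HIPPIE = "HIPPIE", STRING = "STRING",
            IntAct = "INTACT", KEGG = "KEGG")
  out <- data.frame(metric = c("Nodes", "Edges"), stringsAsFactors = FALSE)
  for (label in names(cols)) {
    net <- networks[[cols[[label]]]]
    out[[label]] <- if (is.null(net)) c(0L, 0L) else
      c(length(network_nodes(net)) * (nrow(net$edges) > 0L), nrow(net$edges))
  }
  out$Merged <- c(length(network_nodes(merged)) * (nrow(merged$edges) > 0L),
                  nrow(merged$edges))
  out
}

ego_igraph <- function(net) {
  nodes <- network_nodes(net)
  if (nrow(net$edges) == 0L)
    return(igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$seed, to = net$edges$partner,
               sources = net$edges$sources,
               support_count = net$edges$support_count,
               net$edges[score_cols], stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  igraph::graph_attr(g, "seed") <- net$seed
  g
}

#' Write / read an ego network as GraphML
#'
#' Provenance (`sources`, `support_count`) and per-source best scores travel
#' as edge attributes; the seed as a graph attribute. `read_network_graphml()`
#' inverts `write_network_graphml()` up to node set, edge set, provenance and
#' scores.
#'
#' @param net an `ego_network`.
#' @param path GraphML file path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(ego_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  seed <- igraph::graph_attr(g, "seed")
  ed <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ed) == 0L) return(new_ego_network(seed, empty_edges()))
  partner <- ifelse(ed$from == seed, ed$to, ed$from)
  edges <- data.frame(partner = partner, sources = ed$sources,
                      support_count = as.integer(ed$support_count),
                      stringsAsFactors = FALSE)
  for (sc in score_cols) {
    v <- as.numeric(ed[[sc]])
    v[is.nan(v)] <- NA_real_  # igraph serialises NA as NaN
    edges[[sc]] <- v
  }
  new_ego_network(seed, edges)
}

#' Write an ego network in SIF format
#'
#' One line per edge: `SEED pp PARTNER`.
#' @param net an `ego_network`.
#' @param path output path.
#' @export
write_network_sif <- function(net, path) {
  lines <- if (nrow(net$edges)) paste(net$seed, "pp", net$edges$partner) else character(0)
  writeLines(lines, path)
  invisible(path)
}
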