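## The piRNA-mRNA regulatory network: a bipartite graph whose edges are the
## free-energy-filtered target pairs, with degree tables, a hub report, and
## pathway-restricted subnetworks. Emitted as GraphML / SIF / TSV for
## downstream viewers (Cytoscape-compatible); no layout or rendering here.

#' Build the bipartite piRNA-mRNA regulatory network
#'
#' Edges are the deduplicated (piRNA, mRNA) pairs of the input site or pair
#' table, optionally filtered on the empirical edge p-value when an
#' `empirical_p` column is present.
#'
#' @param pairs a `target_sites` table (already free-energy filtered) or the
#'   output of [target_pairs()].
#' @param edge_p_cutoff drop edges with `empirical_p >= edge_p_cutoff` when
#'   that column exists (default 0.05); ignored otherwise.
#' @return object of class `regulatory_network`: list with `graph` (a
#'   bipartite `igraph`; vertex attribute `type` is `"piRNA"`/`"mRNA"`),
#'   `edges` (`data.frame` with `pirna_id`, `mrna_id`, `delta_g`,
#'   `penalty_score`, optional `empirical_p`), `degree` (named integer over
#'   all nodes) and `hubs` (piRNAs ranked by target count).
#' @export
build_network <- function(pairs, edge_p_cutoff = 0.05) {
  if (inherits(pairs, "target_sites") || "site_start" %in% names(pairs)) {
    pairs <- if ("empirical_p" %in% names(pairs)) {
      p <- target_pairs(pairs)
      best <- paste(pairs$pirna_id, pairs$mrna_id) # carry min empirical p per pair
      ep <- tapply(pairs$empirical_p, best, min)
      p$empirical_p <- as.numeric(ep[paste(p$pirna_id, p$mrna_id)])
      p
    } else {
      target_pairs(pairs)
    }
  }
  if ("empirical_p" %in% names(pairs)) {
    pairs <- pairs[pairs$empirical_p < edge_p_cutoff, , drop = FALSE]
  }
  edges <- unique(pairs[, intersect(c("pirna_id", "mrna_id", "delta_g",
                                      "penalty_score", "empirical_p"),
                                    names(pairs)), drop = FALSE])
  rownames(edges) <- NULL
  pirna_nodes <- unique(edges$pirna_id)
  mrna_nodes <- unique(edges$mrna_id)
  if (length(intersect(pirna_nodes, mrna_nodes)) > 0) {
    stop("piRNA and mRNA ids overlap; network would not be bipartite", call. = FALSE)
  }
  verts <- data.frame(name = c(pirna_nodes, mrna_nodes),
                      type = rep(c("piRNA", "mRNA"),
                                 c(length(pirna_nodes), length(mrna_nodes))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  deg <- igraph::degree(g)
  hub_tab <- sort(deg[pirna_nodes], decreasing = TRUE)
  structure(list(graph = g, edges = edges, degree = deg,
                 hubs = data.frame(pirna_id = names(hub_tab),
                                   n_targets = as.integer(hub_tab),
                                   stringsAsFactors = FALSE, row.names = NULL)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  np <- sum(igraph::V(x$graph)$type == "piRNA")
  nm <- sum(igraph::V(x$graph)$type == "mRNA")
  cat("piRNA-mRNA regulatory network:", np, "piRNAs,", nm, "mRNAs,",
      nrow(x$edges), "edges\n")
  if (nrow(x$hubs) > 0) {
    cat("  top hub:", x$hubs$pirna_id[1], "with", x$hubs$n_targets[1], "targets\n")
  }
  invisible(x)
}

#' Pathway-restricted subnetwork
#'
#' Induced subgraph on the mRNAs belonging to a gene set (e.g. the genes of
#' the Wnt, TGF-beta or Hippo signalling pathways) plus their piRNA
#' neighbours.
#'
#' @param net a `regulatory_network`.
#' @param pathway_genes non-empty character vector of mRNA/gene ids.
#' @return a `regulatory_network` restricted to those mRNAs; empty (with a
#'   warning) when the gene set misses the network entirely.
#' @export
pathway_subnetwork <- function(net, pathway_genes) {
  stopifnot(inherits(net, "regulatory_network"), length(pathway_genes) > 0)
  keep <- net$edges$mrna_id %in% pathway_genes
  if (!any(keep)) warning("pathway gene set does not intersect the network")
  build_network(net$edges[keep, , drop = FALSE])
}

#' Write a regulatory network to standard graph formats
#'
#' @param net a `regulatory_network`.
#' @param prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>.sif` and `<prefix>_edges.tsv`.
#' @return the written paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(net$graph, gml, format = "graphml")
  sif <- paste0(prefix, ".sif")
  writeLines(sprintf("%s\ttargets\t%s", net$edges$pirna_id, net$edges$mrna_id), sif)
  tsv <- paste0(prefix, "_edges.tsv")
  write.table(net$edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gml, sif, tsv))
}
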