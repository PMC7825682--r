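# Weighted patient risk-compatibility network: nodes are patients, an edge
# joins two patients sharing at least `threshold` of the six parameter
# classes, with the shared-class count (0..6) as edge weight.

#' Risk-compatibility score between two class profiles
#'
#' Counts how many of the six parameter classes (gender, age group,
#' hypertension, obesity, thick neck, sleepiness) two patients share. All
#' six parameters carry equal weight; the score equals 6 minus the Hamming
#' distance over the class slots.
#'
#' @param p,q Single-row profile data frames (see [discretize_patients()]).
#' @return Integer in 0..6, symmetric in its arguments.
#' @examples
#' prof <- archetype_profiles()
#' compatibility_score(prof[1, ], prof[2, ])
#' @export
compatibility_score <- function(p, q) {
  mp <- profile_matrix(p); mq <- profile_matrix(q)
  stopifnot(nrow(mp) == 1, nrow(mq) == 1)
  as.integer(sum(mp[1, ] == mq[1, ]))
}

# All pairwise compatibility scores as an integer matrix (ids on dimnames).
compatibility_score_matrix <- function(profiles) {
  m <- profile_matrix(profiles)
  n <- nrow(m)
  s <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(ncol(m))) {
    eq <- outer(m[, j], m[, j], "==")
    s <- s + eq
  }
  diag(s) <- 6L
  s
}

#' Build the patient risk-compatibility network
#'
#' Connects every pair of patients whose compatibility score reaches the
#' threshold; the score is kept as the edge weight. Patients without any
#' compatible partner remain as isolated nodes.
#'
#' @param profiles Class-profile data frame with unique `id`s.
#' @param threshold Minimum shared-class count for an edge, in 1..6
#'   (default 4, the "at least 4 out of 6" rule).
#' @return An object of class `compat_network`: list with `nodes` (ids),
#'   `edges` (data frame `from`, `to`, `weight`), `threshold` and the
#'   `profiles` used.
#' @examples
#' prof <- generate_clustered_cohort(seed = 1)
#' net <- build_network(prof)
#' net
#' @export
build_network <- function(profiles, threshold = 4L) {
  stopifnot(threshold >= 1, threshold <= 6)
  if (anyDuplicated(profiles$id)) stop("duplicate patient ids")
  s <- compatibility_score_matrix(profiles)
  ids <- rownames(s)
  keep <- which(upper.tri(s) & s >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      weight = as.integer(s[keep]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges,
                 threshold = as.integer(threshold),
                 profiles = profiles),
            class = "compat_network")
}

#' @export
print.compat_network <- function(x, ...) {
  cat("Risk-compatibility network:", length(x$nodes), "patients,",
      nrow(x$edges), "edges (threshold", paste0(x$threshold, "/6)"), "\n")
  invisible(x)
}

# Internal constructor for tests/oracles: a network from an explicit edge
# list, bypassing profiles.
network_from_edges <- function(nodes, edges, threshold = NA_integer_) {
  edges$weight <- if (nrow(edges)) as.numeric(edges$weight) else numeric()
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes),
            !any(edges$from == edges$to))
  structure(list(nodes = as.character(nodes), edges = edges,
                 threshold = threshold, profiles = NULL),
            class = "compat_network")
}

#' Convert a compatibility network to an igraph object
#'
#' @param net A `compat_network`.
#' @return An undirected weighted [igraph::igraph] graph carrying the class
#'   profiles as node attributes when available.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "compat_network"))
  vertices <- data.frame(name = net$nodes, stringsAsFactors = FALSE)
  if (!is.null(net$profiles))
    vertices <- cbind(vertices,
                      net$profiles[match(net$nodes, net$profiles$id),
                                   setdiff(names(net$profiles), "id"),
                                   drop = FALSE])
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = vertices)
}

#' Summarize network connectivity
#'
#' @param net A `compat_network`.
#' @return One-row data frame: node count, edge count, density, number of
#'   connected components and giant-component size.
#' @export
network_summary <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  n <- length(net$nodes)
  data.frame(n_nodes = n, n_edges = nrow(net$edges),
             density = if (n > 1) nrow(net$edges) / choose(n, 2) else 0,
             n_components = comp$no,
             giant_component = if (comp$no > 0) max(comp$csize) else 0L)
}

#' Sweep the compatibility threshold
#'
#' Rebuilds the network at each threshold and reports connectivity summaries
#' plus the community structure found by modularity maximization. Used to
#' justify the working threshold: low thresholds give one dense giant
#' community, high thresholds shatter the graph into small components.
#'
#' @param profiles Class-profile data frame.
#' @param thresholds Integer thresholds to evaluate (default 1:6).
#' @param weighted Passed to [detect_communities()].
#' @param seed Seed for community detection.
#' @return Data frame with one row per threshold: the [network_summary()]
#'   columns plus `n_communities` and `modularity`.
#' @export
threshold_sweep <- function(profiles, thresholds = 1:6, weighted = TRUE,
                            seed = 1L) {
  rows <- lapply(thresholds, function(t) {
    net <- build_network(profiles, threshold = t)
    s <- network_summary(net)
    s$threshold <- t
    if (nrow(net$edges) > 0) {
      part <- detect_communities(net, seed = seed, weighted = weighted)
      s$n_communities <- part$m
      s$modularity <- part$modularity
    } else {
      s$n_communities <- length(net$nodes)
      s$modularity <- 0
    }
    s
  })
  out <- do.call(rbind, rows)
  out[, c("threshold", "n_nodes", "n_edges", "density", "n_components",
          "giant_component", "n_communities", "modularity")]
}

#' Export the network edge list as CSV
#'
#' @param net A `compat_network`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_edge_csv <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the network as GraphML
#'
#' Node attributes (class profile, community, coordinates) travel with the
#' graph so it can be opened in standard network tools.
#'
#' @param net A `compat_network`.
#' @param path Output file.
#' @param partition Optional `community_partition` to embed.
#' @param layout Optional `force_layout` result to embed.
#' @return The path, invisibly.
#' @export
write_graphml <- function(net, path, partition = NULL, layout = NULL) {
  g <- decorate_graph(net, partition, layout)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

decorate_graph <- function(net, partition = NULL, layout = NULL) {
  g <- as_igraph(net)
  if (!is.null(partition))
    g <- igraph::set_vertex_attr(g, "community",
                                 value = unname(partition$membership[net$nodes]))
  if (!is.null(layout)) {
    co <- layout$coordinates
    idx <- match(net$nodes, co$id)
    g <- igraph::set_vertex_attr(g, "x", value = co$x[idx])
    g <- igraph::set_vertex_attr(g, "y", value = co$y[idx])
  }
  g
}

#' Export the network as GEXF
#'
#' Minimal GEXF 1.2 writer embedding the six class attributes, the community
#' id and layout coordinates.
#'
#' @inheritParams write_graphml
#' @return The path, invisibly.
#' @export
write_gexf <- function(net, path, partition = NULL, layout = NULL) {
  stopifnot(inherits(net, "compat_network"))
  prof <- net$profiles
  attrs <- character(0)
  if (!is.null(prof)) attrs <- profile_columns
  has_comm <- !is.null(partition)
  xml_escape <- function(x)
    gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", as.character(x))))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph defaultedgetype="undirected">')
  all_attrs <- c(attrs, if (has_comm) "community")
  if (length(all_attrs)) {
    w('    <attributes class="node">')
    for (i in seq_along(all_attrs))
      w('      <attribute id="%d" title="%s" type="string"/>', i - 1L,
        all_attrs[i])
    w('    </attributes>')
  }
  w('    <nodes>')
  co <- if (!is.null(layout)) layout$coordinates else NULL
  for (v in net$nodes) {
    vals <- character(0)
    if (!is.null(prof)) {
      row <- prof[prof$id == v, , drop = FALSE]
      vals <- vapply(attrs, function(a) as.character(row[[a]]), "")
    }
    if (has_comm) vals <- c(vals, as.character(partition$membership[[v]]))
    w('      <node id="%s" label="%s">', xml_escape(v), xml_escape(v))
    if (length(vals)) {
      w('        <attvalues>')
      for (i in seq_along(vals))
        w('          <attvalue for="%d" value="%s"/>', i - 1L,
          xml_escape(vals[i]))
      w('        </attvalues>')
    }
    if (!is.null(co)) {
      idx <- match(v, co$id)
      w('        <viz:position xmlns:viz="http://www.gexf.net/1.2draft/viz" x="%.6f" y="%.6f" z="0"/>',
        co$x[idx], co$y[idx])
    }
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  if (nrow(net$edges))
    for (i in seq_len(nrow(net$edges)))
      w('      <edge id="%d" source="%s" target="%s" weight="%s"/>', i - 1L,
        xml_escape(net$edges$from[i]), xml_escape(net$edges$to[i]),
        format(net$edges$weight[i]))
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}
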