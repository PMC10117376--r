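# Interaction network construction and MCODE dense-cluster detection.
# igraph is used as the graph container; the MCODE algorithm itself
# (vertex weighting, seeded expansion, haircut/fluff post-processing) is
# implemented here.

split_channels <- function(x) {
  lapply(strsplit(as.character(x), "[;,|]"), function(ch) trimws(ch[nzchar(trimws(ch))]))
}

#' Read a confidence-scored edge table
#'
#' Expects tab-separated columns `protein_a`, `protein_b`,
#' `combined_score`, `channels` (channels separated by `;`).
#'
#' @param path File path.
#' @return Data frame of edges.
#' @export
read_edge_table <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("protein_a", "protein_b", "combined_score", "channels")
  if (!all(need %in% names(df))) {
    stopf("edge table must have columns %s", paste(need, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score))
  if (length(bad) > 0L) {
    stopf("malformed combined_score at line %d of %s", bad[1] + 1L, path)
  }
  df$combined_score <- score
  df
}

#' Build the interaction graph
#'
#' Keeps edges with `combined_score >= min_score` whose evidence channels
#' intersect `allowed_channels` (the high-confidence, experimental/curated
#' regime used for published interactome networks). Self-loops and
#' duplicate edges are dropped with logged counts; edges touching proteins
#' outside `node_list` are dropped with a warning count. Every listed node
#' is retained even if isolated.
#'
#' @param node_list Character vector of proteins (the filtered interactome).
#' @param edges Edge data frame (`protein_a`, `protein_b`,
#'   `combined_score`, `channels`).
#' @param min_score Minimum combined confidence score, default 0.700.
#' @param allowed_channels Evidence channels accepted, default
#'   experimental + curated database.
#' @return An undirected simple `igraph` object with attribute counters
#'   `dropped_unknown`, `dropped_self`, `dropped_duplicate`.
#' @export
build_graph <- function(node_list, edges,
                        min_score = 0.700,
                        allowed_channels = c("experimental", "database")) {
  nodes <- sort(unique(canonical_symbol(node_list)))
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    igraph::graph_attr(g, "dropped_unknown") <- 0L
    igraph::graph_attr(g, "dropped_self") <- 0L
    igraph::graph_attr(g, "dropped_duplicate") <- 0L
    return(g)
  }
  if (!is.numeric(edges$combined_score) ||
      any(edges$combined_score < 0 | edges$combined_score > 1)) {
    stopf("combined_score must be numeric in [0, 1]")
  }
  a <- canonical_symbol(edges$protein_a)
  b <- canonical_symbol(edges$protein_b)
  chan <- split_channels(edges$channels)
  keep_chan <- vapply(chan, function(ch) length(intersect(ch, allowed_channels)) > 0, logical(1))
  keep <- edges$combined_score >= min_score & keep_chan

  known <- a %in% nodes & b %in% nodes
  dropped_unknown <- sum(keep & !known)
  if (dropped_unknown > 0L) {
    warnf("%d edge(s) referenced proteins outside the node list and were dropped",
          dropped_unknown)
  }
  keep <- keep & known

  self <- a == b
  dropped_self <- sum(keep & self)
  keep <- keep & !self

  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  dropped_duplicate <- sum(keep & dup)
  keep <- keep & !dup

  el <- cbind(lo[keep], hi[keep])
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2],
               combined_score = edges$combined_score[keep],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::graph_attr(g, "dropped_unknown") <- dropped_unknown
  igraph::graph_attr(g, "dropped_self") <- dropped_self
  igraph::graph_attr(g, "dropped_duplicate") <- dropped_duplicate
  g
}

graph_density_simple <- function(n, m) {
  if (n < 2) return(0)
  2 * m / (n * (n - 1))
}

#' Summarize network components, degree, and hubs
#'
#' @param graph An `igraph` object.
#' @param top_k Number of hubs to report (default 3, degree descending,
#'   ties broken lexicographically).
#' @return List with `n_nodes`, `n_edges`, `mean_degree`,
#'   `component_sizes` (descending, ties by lexicographically smallest
#'   member), `components` (member lists in the same order), `n_isolated`,
#'   and `hubs` (data frame `protein`, `degree`).
#' @export
component_summary <- function(graph, top_k = 3L) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  comp <- igraph::components(graph)
  members <- unname(split(igraph::V(graph)$name, comp$membership))
  members <- lapply(members, sort)
  sizes <- vapply(members, length, integer(1))
  first <- vapply(members, function(x) x[1], character(1))
  ord <- order(-sizes, first)
  members <- members[ord]
  sizes <- sizes[ord]

  deg <- igraph::degree(graph)
  hub_ord <- order(-deg, igraph::V(graph)$name)
  k <- min(top_k, n)
  hubs <- data.frame(protein = igraph::V(graph)$name[hub_ord][seq_len(k)],
                     degree = as.integer(deg[hub_ord][seq_len(k)]),
                     stringsAsFactors = FALSE)
  list(n_nodes = n,
       n_edges = m,
       mean_degree = if (n > 0) 2 * m / n else 0,
       component_sizes = as.integer(sizes),
       components = members,
       n_isolated = sum(sizes == 1L),
       hubs = hubs)
}

#' Extract the largest connected component
#'
#' @param graph An `igraph` object.
#' @return Induced subgraph of the largest component (ties broken by
#'   lexicographically smallest member).
#' @export
largest_component <- function(graph) {
  cs <- component_summary(graph, top_k = 0L)
  if (length(cs$components) == 0L) return(graph)
  igraph::induced_subgraph(graph, cs$components[[1]])
}

#' MCODE parameter set
#'
#' Defaults follow the published algorithm/plugin defaults: degree cutoff
#' 2, node score (vertex weight percentage) cutoff 0.2, k-core filter 2,
#' maximum expansion depth 100, haircut on, fluff off.
#'
#' @param degree_cutoff Minimum degree for a vertex to receive weight.
#' @param vwp Vertex weight percentage in `[0, 1)`: a neighbor joins a
#'   complex when its weight is at least `(1 - vwp)` of the seed weight.
#' @param k_core Complexes must contain a k-core of at least this order.
#' @param max_depth Maximum expansion distance from the seed.
#' @param haircut Iteratively remove singly-connected complex members
#'   (2-core the complex).
#' @param fluff Add boundary neighbors whose closed-neighborhood density
#'   exceeds `fluff_density`.
#' @param fluff_density Density threshold used when `fluff = TRUE`.
#' @return List of parameters (class `mcode_params`).
#' @export
mcode_params <- function(degree_cutoff = 2L, vwp = 0.2, k_core = 2L,
                         max_depth = 100L, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.1) {
  if (vwp < 0 || vwp >= 1) stopf("'vwp' must lie in [0, 1)")
  if (degree_cutoff < 0 || k_core < 0 || max_depth < 0) {
    stopf("MCODE cutoffs must be non-negative")
  }
  structure(list(degree_cutoff = as.integer(degree_cutoff), vwp = vwp,
                 k_core = as.integer(k_core), max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density),
            class = "mcode_params")
}

# Highest k-core of an igraph (vertex names), with its order k.
highest_kcore <- function(g) {
  if (igraph::vcount(g) == 0L) return(list(k = 0L, members = character()))
  core <- igraph::coreness(g)
  k <- max(core)
  list(k = k, members = igraph::V(g)$name[core == k])
}

#' MCODE vertex weight
#'
#' The weight of a vertex is the order of the highest k-core of its closed
#' neighborhood multiplied by the density of that k-core. Vertices of
#' degree below `degree_cutoff` (including isolated vertices) weigh 0.
#'
#' @param graph An `igraph` object.
#' @param node Vertex name.
#' @param degree_cutoff Minimum degree (default 2).
#' @return Non-negative numeric weight.
#' @export
mcode_vertex_weight <- function(graph, node, degree_cutoff = 2L) {
  if (!node %in% igraph::V(graph)$name) stopf("unknown node '%s'", node)
  deg <- igraph::degree(graph, node)
  if (deg < degree_cutoff) return(0)
  nbh <- c(node, igraph::neighbors(graph, node)$name)
  sub <- igraph::induced_subgraph(graph, unique(nbh))
  hk <- highest_kcore(sub)
  if (hk$k == 0L) return(0)
  core_sub <- igraph::induced_subgraph(sub, hk$members)
  hk$k * graph_density_simple(igraph::vcount(core_sub), igraph::ecount(core_sub))
}

two_core_members <- function(graph, members) {
  repeat {
    sub <- igraph::induced_subgraph(graph, members)
    deg <- igraph::degree(sub)
    drop <- igraph::V(sub)$name[deg < 2]
    if (length(drop) == 0L || length(members) == 0L) break
    members <- setdiff(members, drop)
    if (length(members) == 0L) break
  }
  members
}

#' Detect dense clusters with the MCODE algorithm
#'
#' Seeds complexes from the unvisited vertex of highest weight and expands
#' breadth-first, admitting a neighbor when its weight is at least
#' `(1 - vwp)` times the seed weight, up to `max_depth` steps from the
#' seed. Complexes are post-processed with the optional fluff step, then
#' haircut (2-coring), then discarded unless they contain a k-core of
#' order `k_core`. Each vertex belongs to at most one complex. Clusters
#' are scored `density * size` and reported in descending score order; all
#' orderings use (weight descending, name ascending) so results are
#' independent of input vertex order.
#'
#' @param graph An `igraph` object.
#' @param params An [mcode_params()] list.
#' @return List of clusters, each a list with `members`, `size`,
#'   `density`, `score`, `seed`.
#' @export
mcode_complexes <- function(graph, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  nodes <- sort(igraph::V(graph)$name)
  if (length(nodes) == 0L) return(list())
  w <- vapply(nodes, function(v) mcode_vertex_weight(graph, v, params$degree_cutoff),
              numeric(1))
  seed_order <- nodes[order(-w, nodes)]
  in_complex <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  clusters <- list()

  for (seed in seed_order) {
    if (in_complex[[seed]] || w[[seed]] <= 0) next
    threshold <- (1 - params$vwp) * w[[seed]]
    members <- seed
    examined <- stats::setNames(rep(FALSE, length(nodes)), nodes)
    examined[[seed]] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- character()
      for (u in frontier) {
        for (v in sort(igraph::neighbors(graph, u)$name)) {
          if (examined[[v]] || in_complex[[v]]) next
          examined[[v]] <- TRUE
          if (w[[v]] >= threshold) {
            members <- c(members, v)
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }

    if (params$fluff) {
      boundary <- setdiff(
        unique(unlist(lapply(members, function(u) igraph::neighbors(graph, u)$name))),
        members)
      boundary <- sort(boundary[!in_complex[boundary]])
      add <- boundary[vapply(boundary, function(v) {
        nbh <- unique(c(v, igraph::neighbors(graph, v)$name))
        sub <- igraph::induced_subgraph(graph, nbh)
        graph_density_simple(igraph::vcount(sub), igraph::ecount(sub)) >
          params$fluff_density
      }, logical(1))]
      members <- c(members, add)
    }

    if (params$haircut) members <- two_core_members(graph, members)
    if (length(members) < 2L) next

    sub <- igraph::induced_subgraph(graph, members)
    if (params$k_core > 0L && max(igraph::coreness(sub)) < params$k_core) next

    dens <- graph_density_simple(igraph::vcount(sub), igraph::ecount(sub))
    clusters[[length(clusters) + 1L]] <- list(
      members = sort(members),
      size = length(members),
      density = dens,
      score = dens * length(members),
      seed = seed)
    in_complex[members] <- TRUE
  }

  if (length(clusters) == 0L) return(clusters)
  first <- vapply(clusters, function(cl) cl$members[1], character(1))
  ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
               -vapply(clusters, `[[`, integer(1), "size"),
               first)
  clusters[ord]
}

#' Cluster membership as a data frame
#'
#' @param clusters Output of [mcode_complexes()].
#' @return Data frame `cluster_id`, `protein_id`, `cluster_score`.
#' @export
cluster_membership <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(cluster_id = integer(), protein_id = character(),
                      cluster_score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    data.frame(cluster_id = i, protein_id = clusters[[i]]$members,
               cluster_score = clusters[[i]]$score, stringsAsFactors = FALSE)
  }))
}
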