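# Independent oracles written against plain base R data structures, so
# they share no code path with the implementations they check.
# Graphs are represented as a list(nodes = character, edges = 2-column
# character matrix).

oracle_graph <- function(nodes, edges) {
  edges <- if (length(edges) == 0) matrix(character(), ncol = 2) else
    matrix(as.character(edges), ncol = 2, byrow = TRUE)
  list(nodes = nodes, edges = edges)
}

oracle_neighbors <- function(og, v) {
  e <- og$edges
  sort(unique(c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])))
}

oracle_degree <- function(og, members = og$nodes) {
  vapply(members, function(v) sum(oracle_neighbors(og, v) %in% members),
         integer(1))
}

# connected components by hand-rolled BFS
oracle_components <- function(og) {
  unseen <- og$nodes
  comps <- list()
  while (length(unseen) > 0) {
    frontier <- unseen[1]
    comp <- character()
    while (length(frontier) > 0) {
      comp <- union(comp, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, oracle_neighbors, og = og))), comp)
    }
    comps[[length(comps) + 1]] <- sort(comp)
    unseen <- setdiff(unseen, comp)
  }
  comps[order(-vapply(comps, length, integer(1)),
              vapply(comps, `[`, character(1), 1))]
}

oracle_subgraph_edges <- function(og, members) {
  e <- og$edges
  e[e[, 1] %in% members & e[, 2] %in% members, , drop = FALSE]
}

oracle_density <- function(og, members) {
  n <- length(members)
  if (n < 2) return(0)
  m <- nrow(oracle_subgraph_edges(og, members))
  2 * m / (n * (n - 1))
}

# k-core by iterative removal of vertices with degree < k
oracle_kcore <- function(og, k, members = og$nodes) {
  repeat {
    if (length(members) == 0) return(character())
    deg <- vapply(members, function(v) {
      sum(oracle_neighbors(og, v) %in% members)
    }, integer(1))
    drop <- members[deg < k]
    if (length(drop) == 0) return(sort(members))
    members <- setdiff(members, drop)
  }
}

# highest k such that the k-core of `members` is non-empty, with that core
oracle_highest_kcore <- function(og, members = og$nodes) {
  k <- 0
  core <- sort(members)
  repeat {
    nxt <- oracle_kcore(og, k + 1, members)
    if (length(nxt) == 0) return(list(k = k, members = core))
    k <- k + 1
    core <- nxt
  }
}

# MCODE vertex weight recomputed from first principles
oracle_vertex_weight <- function(og, v, degree_cutoff = 2) {
  nbrs <- oracle_neighbors(og, v)
  if (length(nbrs) < degree_cutoff) return(0)
  closed <- c(v, nbrs)
  hk <- oracle_highest_kcore(og, closed)
  if (hk$k == 0) return(0)
  hk$k * oracle_density(og, hk$members)
}

# densest subgraph of a component by exhaustive subset enumeration
# (ties: larger subset, then lexicographically smallest membership)
oracle_densest_subgraph <- function(og, component) {
  best <- NULL
  n <- length(component)
  for (size in 2:n) {
    subsets <- utils::combn(component, size, simplify = FALSE)
    for (s in subsets) {
      d <- oracle_density(og, s)
      if (is.null(best) || d > best$density + 1e-12 ||
          (abs(d - best$density) < 1e-12 && size > length(best$members))) {
        best <- list(members = sort(s), density = d)
      }
    }
  }
  best
}

# convert an igraph-ready edge data frame to an oracle graph
edges_to_oracle <- function(nodes, edge_df) {
  oracle_graph(nodes, t(as.matrix(edge_df[, c("protein_a", "protein_b")])))
}

# family-wise permutation oracle for Tukey-adjusted p-values: permutes
# group labels, recomputes the max studentized-range statistic, and
# reports the fraction of permutations reaching the observed pairwise q.
oracle_perm_tukey <- function(groups, group_a, group_b, B = 4000) {
  sizes <- vapply(groups, length, integer(1))
  pool <- unlist(groups)
  k <- length(groups)
  n <- sum(sizes)
  qstat <- function(values) {
    idx <- rep(seq_len(k), sizes)
    means <- tapply(values, idx, mean)
    mse <- sum((values - means[idx])^2) / (n - k)
    qmax <- 0
    qab <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / sizes[i] + 1 / sizes[j]))
      q <- if (se > 0) abs(means[j] - means[i]) / se else Inf
      qmax <- max(qmax, q)
      if ((names(groups)[i] == group_a && names(groups)[j] == group_b) ||
          (names(groups)[i] == group_b && names(groups)[j] == group_a)) {
        qab <- q
      }
    }
    c(qmax = unname(qmax), qab = unname(qab))
  }
  obs <- qstat(pool)
  hits <- 0
  for (b in seq_len(B)) {
    hits <- hits + (qstat(sample(pool))[["qmax"]] >= obs[["qab"]])
  }
  hits / B
}
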