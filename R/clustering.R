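#' Single-linkage connected components of an ANI graph
#'
#' Iterative depth-first search over the adjacency structure. Isolated
#' nodes form singleton components. Components are ordered by their
#' lexicographically smallest member and members are sorted within each
#' component, so the partition is deterministic.
#'
#' @param graph An `ani_graph`.
#' @return List of character vectors (the components); a partition of
#'   the node set.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "ani_graph"))
  adj <- graph_adjacency(graph)
  visited <- setNames(rep(FALSE, length(graph$nodes)), graph$nodes)
  comps <- list()
  for (start in graph$nodes) {
    if (visited[[start]]) next
    stack <- start
    members <- character(0)
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (visited[[v]]) next
      visited[[v]] <- TRUE
      members <- c(members, v)
      nb <- adj[[v]]
      stack <- c(stack, nb[!visited[nb]])
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

#' Maximal cliques of a component subgraph
#'
#' Exact enumeration by Bron-Kerbosch with pivoting. Every maximal clique
#' of size >= 2 is reported; a node may appear in several cliques
#' (genuinely intermediate bins belong to more than one genome cluster).
#' Singletons are not emitted here — they are created during orphan
#' assignment. Output is deterministic: cliques sorted by size
#' (descending), then lexicographically by members.
#'
#' Worst-case clique enumeration is exponential, so components larger
#' than `max_exact` nodes fall back to a greedy heuristic (repeatedly
#' grow a clique from the lexicographically first uncovered node) with a
#' warning; at realistic MAG-cluster sizes the exact path is always
#' taken.
#'
#' @param nodes Character vector: the component's nodes.
#' @param edges Edge data frame restricted to (or a superset of) the
#'   component.
#' @param max_exact Safety bound on exact enumeration; default 5000.
#' @return List of character vectors (sorted members of each clique).
#' @export
maximal_cliques <- function(nodes, edges, max_exact = 5000) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (id in nodes) adj[[id]] <- character(0)
  if (nrow(edges) > 0L) {
    inside <- edges$bin_a %in% nodes & edges$bin_b %in% nodes
    for (i in which(inside)) {
      a <- edges$bin_a[i]; b <- edges$bin_b[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  cliques <- if (length(nodes) > max_exact) {
    warning("component with ", length(nodes), " nodes exceeds the exact ",
            "clique bound (", max_exact, "); using greedy heuristic",
            call. = FALSE)
    greedy_cliques(nodes, adj)
  } else {
    bron_kerbosch(adj)
  }
  cliques <- Filter(function(cl) length(cl) >= 2L, cliques)
  cliques <- lapply(cliques, sort)
  ord <- order(-lengths(cliques),
               vapply(cliques, paste, character(1), collapse = "\r"))
  cliques[ord]
}

# Bron-Kerbosch with pivot (choose the pivot with most neighbours in
# P union X). Returns all maximal cliques including singletons.
bron_kerbosch <- function(adj) {
  out <- list()
  recurse <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      out[[length(out) + 1L]] <<- R
      return(invisible())
    }
    px <- c(P, X)
    deg <- vapply(px, function(u) sum(adj[[u]] %in% P), integer(1))
    pivot <- px[[which.max(deg)]]
    for (v in setdiff(P, adj[[pivot]])) {
      nb <- adj[[v]]
      recurse(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible()
  }
  recurse(character(0), sort(names(adj)), character(0))
  out
}

# Greedy fallback for oversized components: each node seeds a clique
# grown by adding, in lexicographic order, nodes adjacent to all current
# members; duplicates removed.
greedy_cliques <- function(nodes, adj) {
  seen <- character(0)
  out <- list()
  for (seed in sort(nodes)) {
    clique <- seed
    for (cand in adj[[seed]]) {
      if (all(clique %in% adj[[cand]])) clique <- c(clique, cand)
    }
    key <- paste(sort(clique), collapse = "\r")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- sort(clique)
    }
  }
  out
}

# Constructor for a genome cluster.
bin_cluster <- function(cluster_id, members, component_id,
                        attached_members = character(0)) {
  structure(list(cluster_id = cluster_id,
                 members = sort(unique(members)),
                 component_id = component_id,
                 attached_members = sort(attached_members)),
            class = "bin_cluster")
}

#' @export
print.bin_cluster <- function(x, ...) {
  cat(sprintf("<bin_cluster> %s (component %s): {%s}%s\n",
              x$cluster_id, x$component_id,
              paste(x$members, collapse = ", "),
              if (length(x$attached_members) > 0L)
                paste0(" [attached: ",
                       paste(x$attached_members, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Attach orphan bins to cliques and emit the final cluster list
#'
#' A node covered by no clique of size >= 2 is attached to every clique
#' containing one of its graph neighbours (so every above-cutoff pair
#' ends up co-clustered); a node with no neighbours becomes a singleton
#' cluster. Under exact clique enumeration every non-isolated node is
#' already in some clique, so attachment only acts on singleton
#' components and after the greedy fallback.
#'
#' @param cliques List of cliques (from [maximal_cliques()]).
#' @param graph The `ani_graph`.
#' @param eligible_nodes Nodes to consider (default: all graph nodes).
#' @param component_id Label used in cluster IDs.
#' @return List of `bin_cluster` objects.
#' @export
assign_orphans <- function(cliques, graph, eligible_nodes = graph$nodes,
                           component_id = "001") {
  adj <- graph_adjacency(graph)
  covered <- unique(unlist(cliques))
  orphans <- setdiff(eligible_nodes, covered)
  attached <- setNames(vector("list", length(cliques)),
                       seq_along(cliques))
  singletons <- character(0)
  for (v in sort(orphans)) {
    nb <- intersect(adj[[v]], eligible_nodes)
    hit <- FALSE
    for (i in seq_along(cliques)) {
      if (length(intersect(nb, cliques[[i]])) > 0L) {
        attached[[i]] <- c(attached[[i]], v)
        hit <- TRUE
      }
    }
    if (!hit) singletons <- c(singletons, v)
  }
  clusters <- list()
  for (i in seq_along(cliques)) {
    att <- attached[[i]]
    clusters[[length(clusters) + 1L]] <- bin_cluster(
      sprintf("%s.%03d", component_id, i),
      c(cliques[[i]], att), component_id,
      attached_members = if (is.null(att)) character(0) else att)
  }
  for (v in singletons) {
    clusters[[length(clusters) + 1L]] <- bin_cluster(
      sprintf("%s.%03d", component_id, length(clusters) + 1L),
      v, component_id)
  }
  clusters
}

#' Cluster the ANI graph into genome clusters
#'
#' Full clustering stage: single-linkage components, maximal-clique
#' enumeration inside each component, orphan attachment, and singleton
#' creation. Guarantees that both endpoints of every graph edge share at
#' least one cluster and that every node belongs to at least one cluster.
#'
#' @param graph An `ani_graph`.
#' @param max_exact Passed to [maximal_cliques()].
#' @return List of `bin_cluster` objects, ordered by cluster ID.
#' @export
cluster_bins <- function(graph, max_exact = 5000) {
  comps <- connected_components(graph)
  clusters <- list()
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    comp_id <- sprintf("%03d", ci)
    cliques <- maximal_cliques(comp, graph$edges, max_exact = max_exact)
    sub <- structure(list(nodes = comp,
                          edges = graph$edges[
                            graph$edges$bin_a %in% comp &
                              graph$edges$bin_b %in% comp, , drop = FALSE],
                          cutoff = graph$cutoff),
                     class = "ani_graph")
    clusters <- c(clusters,
                  assign_orphans(cliques, sub, eligible_nodes = comp,
                                 component_id = comp_id))
  }
  clusters[order(vapply(clusters, `[[`, character(1), "cluster_id"))]
}

#' Dump clusters as a TSV (debugging aid)
#' @param clusters List of `bin_cluster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id,
               component_id = cl$component_id,
               member = cl$members,
               attached = cl$members %in% cl$attached_members,
               stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(cluster_id = character(0), component_id = character(0),
                       member = character(0), attached = logical(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
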