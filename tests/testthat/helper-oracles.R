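# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately brute-force / closed-form and never
# calls the code paths it is used to check.

# --- graph fixtures ---------------------------------------------------

# Random undirected simple graph on nodes n01..nNN with edge prob p;
# returned as a magderep-style edge data frame (ani fixed above cutoff).
random_edge_list <- function(n, p, seed, ani = 99.5) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  rows <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < p)
        rows[[length(rows) + 1L]] <- data.frame(
          bin_a = nodes[i], bin_b = nodes[j], ani = ani,
          aligned_fraction = 1, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(bin_a = character(0), bin_b = character(0),
                      ani = numeric(0), aligned_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

graph_from_edges <- function(nodes, edges, cutoff = 99) {
  structure(list(nodes = sort(nodes), edges = edges, cutoff = cutoff),
            class = "ani_graph")
}

# --- component oracle: boolean transitive closure ---------------------

oracle_components <- function(nodes, edges) {
  n <- length(nodes)
  adj <- diag(TRUE, n)
  rownames(adj) <- colnames(adj) <- nodes
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      adj[edges$bin_a[r], edges$bin_b[r]] <- TRUE
      adj[edges$bin_b[r], edges$bin_a[r]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(lapply(seq_len(n), function(i) sort(nodes[adj[i, ]])))
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

# --- clique oracle: exhaustive subset enumeration (n <= 12) -----------

oracle_max_cliques <- function(nodes, edges) {
  n <- length(nodes)
  stopifnot(n <= 16)
  adj <- integer(n) # bitmask adjacency
  idx <- setNames(seq_len(n), nodes)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      i <- idx[[edges$bin_a[r]]]; j <- idx[[edges$bin_b[r]]]
      adj[i] <- bitwOr(adj[i], bitwShiftL(1L, j - 1L))
      adj[j] <- bitwOr(adj[j], bitwShiftL(1L, i - 1L))
    }
  }
  masks <- seq_len(bitwShiftL(1L, n) - 1L)
  is_clique <- vapply(masks, function(m) {
    for (i in seq_len(n)) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(m, bit) != 0L) {
        rest <- bitwAnd(m, bitwNot(bit))
        if (bitwAnd(adj[i], rest) != rest) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  cliques <- masks[is_clique]
  maximal <- vapply(cliques, function(m) {
    for (i in seq_len(n)) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(m, bit) == 0L && bitwAnd(adj[i], m) == m) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- lapply(cliques[maximal], function(m)
    sort(nodes[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]))
  out[lengths(out) >= 2L]
}

# canonical string form of a clique list, order-independent
clique_key <- function(cliques) {
  sort(vapply(cliques, paste, character(1), collapse = ","))
}

# --- k-mer oracle: string-based canonical k-mer set -------------------

oracle_canonical_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (length(km) == 0L) next
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km)))
    out <- c(out, pmin(km, rc))
  }
  unique(out)
}

# --- small sequence fixtures ------------------------------------------

tiny_bin <- function(id, seqs, sample = "s1") {
  sequence_bin(id, sample, seqs)
}

# write a quality table in the CheckM2 dialect
write_checkm2 <- function(df, path) {
  write.table(data.frame(Name = df$bin_id, Completeness = df$completeness,
                         Contamination = df$contamination),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
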