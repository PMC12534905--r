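#' FracMinHash sketch of a bin
#'
#' Builds a fraction-scaled MinHash sketch of the bin's canonical k-mer
#' set: each distinct canonical k-mer (minimum of forward and
#' reverse-complement 2-bit encodings) is hashed with a fixed 64-bit
#' mixer, the hash truncated to its top 53 bits (so values are exactly
#' representable as R doubles), and retained iff it falls below
#' `2^53 / scaled`. k-mers containing N are skipped. The sketch is
#' deterministic across runs and platforms.
#'
#' Containment between such sketches estimates ANI robustly even when the
#' two bins differ widely in completeness, which is exactly the regime of
#' sample-wise MAGs (a Jaccard-based estimate would be biased downward
#' for incomplete bins).
#'
#' @param bin A `sequence_bin`.
#' @param k k-mer size, default 21.
#' @param scaled Sampling factor, default 200 (on average one k-mer in
#'   200 is retained).
#' @return An object of class `kmer_sketch` with fields `bin_id`, `k`,
#'   `scaled`, `hashes` (sorted numeric), `genome_kmer_count`.
#' @export
sketch_bin <- function(bin, k = 21, scaled = 200) {
  stopifnot(inherits(bin, "sequence_bin"))
  res <- .sketch_sequences(bin$contigs, as.integer(k), as.numeric(scaled))
  if (res$genome_kmer_count == 0)
    stop("bin '", bin$bin_id, "' yields an empty sketch (all contigs ",
         "shorter than k = ", k, " or all-N)", call. = FALSE)
  structure(
    list(bin_id = bin$bin_id, k = as.integer(k), scaled = as.numeric(scaled),
         hashes = res$hashes, genome_kmer_count = res$genome_kmer_count),
    class = "kmer_sketch"
  )
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("<kmer_sketch> %s: k=%d scaled=%g, %d hashes (of %g k-mers)\n",
              x$bin_id, x$k, x$scaled, length(x$hashes),
              x$genome_kmer_count))
  invisible(x)
}

#' Estimate ANI between two sketches
#'
#' Containment `C = |A intersect B| / min(|A|, |B|)` over the retained
#' hash sets; `ANI = 100 * C^(1/k)` when `C > 0`, else 0. Using the
#' smaller sketch as denominator makes the estimate insensitive to
#' completeness differences between the bins. The containment itself is
#' reported as the aligned fraction. Symmetric in its arguments.
#'
#' @param a,b `kmer_sketch` objects with identical `k` and `scaled`.
#' @return One-row data frame with columns `bin_a`, `bin_b`, `ani`,
#'   `aligned_fraction` (pair in canonical lexicographic order).
#' @export
estimate_ani <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (a$k != b$k || a$scaled != b$scaled)
    stop("sketches have mismatched k or scaled (", a$k, "/", a$scaled,
         " vs ", b$k, "/", b$scaled, ")", call. = FALSE)
  if (length(a$hashes) == 0L || length(b$hashes) == 0L)
    stop("cannot estimate ANI from an empty sketch", call. = FALSE)
  inter <- .hash_intersection_size(a$hashes, b$hashes)
  containment <- inter / min(length(a$hashes), length(b$hashes))
  ani <- if (containment > 0) 100 * containment^(1 / a$k) else 0
  data.frame(bin_a = min(a$bin_id, b$bin_id),
             bin_b = max(a$bin_id, b$bin_id),
             ani = ani, aligned_fraction = containment,
             stringsAsFactors = FALSE)
}

# All-vs-all ANI edges for a list of sketches (unfiltered).
all_pairs_ani <- function(sketches) {
  n <- length(sketches)
  if (n < 2L) return(empty_edges())
  rows <- vector("list", n * (n - 1L) / 2L)
  idx <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      rows[[idx]] <- estimate_ani(sketches[[i]], sketches[[j]])
      idx <- idx + 1L
    }
  }
  canonicalize_edges(do.call(rbind, rows))
}

#' Build the thresholded ANI graph
#'
#' Computes (internal sketch engine) or accepts (pre-computed edge list)
#' all pairwise ANI estimates, and retains an edge iff
#' `ani >= cutoff` and `aligned_fraction >= min_aligned_fraction`.
#' Every bin appears as a node even when isolated; bins whose sketch is
#' empty (all contigs shorter than k) are dropped with a warning.
#'
#' @param bins Named list of `sequence_bin`.
#' @param edges Optional pre-computed edge data frame (from
#'   [read_ani_edges()] or [estimate_ani()]); when `NULL` the internal
#'   estimator is used.
#' @param cutoff ANI cutoff in percent, default 99 (strain level).
#' @param min_aligned_fraction Aligned-fraction gate in `[0, 1]`;
#'   default 0 (off).
#' @param k,scaled Sketch parameters for the internal engine.
#' @return An object of class `ani_graph` with fields `nodes`, `edges`,
#'   `cutoff`.
#' @export
build_ani_graph <- function(bins, edges = NULL, cutoff = 99,
                            min_aligned_fraction = 0,
                            k = 21, scaled = 200) {
  stopifnot(length(bins) >= 1L, cutoff > 0, cutoff <= 100)
  nodes <- sort(names(bins))
  if (is.null(edges)) {
    sketches <- list()
    for (id in nodes) {
      sk <- tryCatch(sketch_bin(bins[[id]], k = k, scaled = scaled),
                     error = function(e) {
                       warning("excluding bin '", id, "': ",
                               conditionMessage(e), call. = FALSE)
                       NULL
                     })
      if (!is.null(sk)) sketches[[id]] <- sk
    }
    nodes <- sort(names(sketches))
    edges <- all_pairs_ani(sketches)
  } else {
    edges <- canonicalize_edges(edges)
    unknown <- setdiff(unique(c(edges$bin_a, edges$bin_b)), nodes)
    if (length(unknown) > 0L)
      stop("edge list names unknown bin(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  keep <- edges$ani >= cutoff & edges$aligned_fraction >= min_aligned_fraction
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "ani_graph")
}

#' @export
print.ani_graph <- function(x, ...) {
  cat(sprintf("<ani_graph> %d nodes, %d edges at ANI >= %g\n",
              length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

# Adjacency list (named list of sorted character vectors) of an ani_graph.
graph_adjacency <- function(graph) {
  adj <- setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (id in graph$nodes) adj[[id]] <- character(0)
  if (nrow(graph$edges) > 0L) {
    for (i in seq_len(nrow(graph$edges))) {
      a <- graph$edges$bin_a[i]; b <- graph$edges$bin_b[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}
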