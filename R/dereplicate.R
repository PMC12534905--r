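#' Pipeline configuration
#'
#' Assembles and validates the knobs of the dereplication pipeline.
#'
#' @param ani_cutoff ANI cutoff in percent (default 99, strain level).
#' @param purity_threshold Purity gate in percent (default 95; the `-p`
#'   flag). Bins with purity <= threshold are discarded before clustering.
#' @param min_completeness Completeness floor for the final output set in
#'   percent (default 50; the `-c` flag).
#' @param min_length Minimum bin length in bp (default 200 kb).
#' @param min_aligned_fraction Aligned-fraction gate on ANI edges in
#'   `[0, 1]` (default 0, off).
#' @param k,scaled Sketch parameters of the internal ANI engine.
#' @param no_reassembly When `TRUE`, clusters always emit their
#'   best-scoring member (even if none passes the high-quality gate) and
#'   no merging is attempted — useful when dereplicating against
#'   reference genomes.
#' @param reassembly_backend `"containment_merge"` (built-in, default) or
#'   `"external_assembler"`.
#' @param assembler_cmd Command template for an external assembler, with
#'   `{input}` and `{output}` placeholders for FASTA paths; `NULL` to
#'   disable.
#' @param quality_cmd Command template for an external quality estimator
#'   producing a CheckM2-dialect TSV, with `{input}` (FASTA) and
#'   `{output}` (TSV) placeholders; `NULL` to disable.
#' @param quality_provider Optional function `(sequence_bin) ->
#'   list(completeness, contamination)` used to score merged bins when no
#'   external quality tool is configured (e.g.
#'   [truth_quality_provider()] in synthetic runs).
#' @param containment_threshold Contig-dedup containment threshold of the
#'   built-in merge backend (default 0.95).
#' @param min_contig_length Minimum contig length kept from an external
#'   assembler's output (default 500 bp).
#' @param threads Worker count; accepted for interface compatibility.
#'   All computations are deterministic and thread-count-invariant (the
#'   current implementation is serial, so this holds trivially).
#' @param seed Master seed recorded in the run summary.
#' @param verbose Log per-stage counts via `message()`.
#' @return A list of class `derep_config`.
#' @export
derep_config <- function(ani_cutoff = 99, purity_threshold = 95,
                         min_completeness = 50, min_length = 200000,
                         min_aligned_fraction = 0, k = 21, scaled = 200,
                         no_reassembly = FALSE,
                         reassembly_backend = c("containment_merge",
                                                "external_assembler"),
                         assembler_cmd = NULL, quality_cmd = NULL,
                         quality_provider = NULL,
                         containment_threshold = 0.95,
                         min_contig_length = 500,
                         threads = 1, seed = 1, verbose = FALSE) {
  reassembly_backend <- match.arg(reassembly_backend)
  if (ani_cutoff <= 0 || ani_cutoff > 100)
    stop("ani_cutoff must be in (0, 100]", call. = FALSE)
  if (purity_threshold < 0 || purity_threshold > 100)
    stop("purity_threshold must be in [0, 100]", call. = FALSE)
  if (min_completeness < 0 || min_completeness > 100)
    stop("min_completeness must be in [0, 100]", call. = FALSE)
  if (min_length < 0) stop("min_length must be >= 0", call. = FALSE)
  if (min_aligned_fraction < 0 || min_aligned_fraction > 1)
    stop("min_aligned_fraction must be in [0, 1]", call. = FALSE)
  if (threads < 1) stop("threads must be >= 1", call. = FALSE)
  structure(list(
    ani_cutoff = ani_cutoff, purity_threshold = purity_threshold,
    min_completeness = min_completeness, min_length = min_length,
    min_aligned_fraction = min_aligned_fraction, k = k, scaled = scaled,
    no_reassembly = isTRUE(no_reassembly),
    reassembly_backend = reassembly_backend,
    assembler_cmd = assembler_cmd, quality_cmd = quality_cmd,
    quality_provider = quality_provider,
    containment_threshold = containment_threshold,
    min_contig_length = min_contig_length,
    threads = as.integer(threads), seed = as.integer(seed),
    verbose = isTRUE(verbose)
  ), class = "derep_config")
}

log_stage <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Select a cluster's high-quality representative
#'
#' Among cluster members passing the high-quality gate
#' (completeness > 90, contamination < 5), returns the one with the
#' highest quality score; ties broken lexicographically by bin ID.
#'
#' @param cluster A `bin_cluster`.
#' @param qualities Quality table covering all members.
#' @return A bin ID, or `NULL` when no member qualifies.
#' @export
select_representative <- function(cluster, qualities) {
  members <- cluster$members
  recs <- do.call(rbind, lapply(members, quality_for,
                                qualities = qualities))
  ok <- is_high_quality(recs)
  if (!any(ok)) return(NULL)
  cand <- recs[ok, , drop = FALSE]
  cand <- cand[order(-cand$quality_score, cand$bin_id), , drop = FALSE]
  cand$bin_id[1L]
}

# Best-scoring member regardless of the high-quality gate (no-reassembly
# fallback; without it, clusters with no qualifying member would emit
# nothing).
best_member <- function(cluster, qualities) {
  recs <- do.call(rbind, lapply(cluster$members, quality_for,
                                qualities = qualities))
  recs <- recs[order(-recs$quality_score, recs$bin_id), , drop = FALSE]
  recs$bin_id[1L]
}

#' Merge the bins of a cluster into one contig set
#'
#' The union of all member contigs; contig IDs are prefixed with the
#' source bin ID so they stay unique. Deterministic order: by source bin
#' ID, then original contig order. A singleton cluster merges to its only
#' member's contigs (identity up to the ID prefix).
#'
#' @param cluster A `bin_cluster`.
#' @param bins Named list of `sequence_bin` covering the members.
#' @return A `sequence_bin` with `bin_id = "merged_<cluster_id>"`.
#' @export
merge_bins <- function(cluster, bins) {
  members <- sort(cluster$members)
  missing <- setdiff(members, names(bins))
  if (length(missing) > 0L)
    stop("cluster ", cluster$cluster_id, " references unknown bin(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  contigs <- character(0)
  for (m in members) {
    cc <- bins[[m]]$contigs
    names(cc) <- paste(m, names(cc), sep = ":")
    contigs <- c(contigs, cc)
  }
  sequence_bin(paste0("merged_", cluster$cluster_id), "merged", contigs)
}

#' Reassemble a merged contig set
#'
#' Two backends. `containment_merge` (built-in, default): greedy
#' deduplication — contigs are processed longest-first and a contig is
#' dropped when at least `containment_threshold` of its canonical k-mers
#' are contained in a single longer retained contig; this removes the
#' redundancy between overlapping bins while keeping every unique
#' region, standing in for a real assembler in offline runs.
#' `external_assembler`: the merged contigs are written to FASTA and a
#' user-configured assembler command template is run; output contigs of
#' at least `min_contig_length` bp form the new bin. On assembler failure
#' (non-zero exit or empty output) `NULL` is returned and the caller
#' falls back to the best original bin.
#'
#' @param merged A `sequence_bin` from [merge_bins()].
#' @param backend `"containment_merge"` or `"external_assembler"`.
#' @param assembler_cmd Command template with `{input}`/`{output}`
#'   placeholders (external backend only).
#' @param k k-mer size for containment testing.
#' @param containment_threshold Drop threshold in `[0, 1]`, default 0.95.
#' @param min_contig_length Minimum output contig length for the
#'   external backend.
#' @return A `sequence_bin`, or `NULL` on external-assembler failure.
#' @export
reassemble <- function(merged,
                       backend = c("containment_merge",
                                   "external_assembler"),
                       assembler_cmd = NULL, k = 21,
                       containment_threshold = 0.95,
                       min_contig_length = 500) {
  backend <- match.arg(backend)
  stopifnot(inherits(merged, "sequence_bin"))
  if (backend == "external_assembler") {
    return(reassemble_external(merged, assembler_cmd, min_contig_length))
  }
  contigs <- merged$contigs
  ord <- order(-nchar(contigs), names(contigs))
  contigs <- contigs[ord]
  kept_sets <- list()
  kept <- character(0)
  for (i in seq_along(contigs)) {
    km <- .sketch_sequences(contigs[[i]], as.integer(k), 1)$hashes
    drop <- FALSE
    if (length(km) > 0L) {
      for (s in kept_sets) {
        if (.hash_intersection_size(km, s) / length(km) >=
            containment_threshold) { drop <- TRUE; break }
      }
    }
    if (!drop) {
      kept <- c(kept, names(contigs)[i])
      kept_sets[[length(kept_sets) + 1L]] <- km
    }
  }
  kept <- sort(kept)
  sequence_bin(merged$bin_id, merged$sample_id, merged$contigs[kept])
}

# Run an external assembler command template; NULL on failure.
reassemble_external <- function(merged, assembler_cmd, min_contig_length) {
  if (is.null(assembler_cmd))
    stop("external_assembler backend requires assembler_cmd", call. = FALSE)
  tmp_in <- tempfile(fileext = ".fa")
  tmp_out <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  write_bin_fasta(merged, tmp_in)
  cmd <- gsub("{input}", tmp_in, assembler_cmd, fixed = TRUE)
  cmd <- gsub("{output}", tmp_out, cmd, fixed = TRUE)
  status <- tryCatch(system(cmd), error = function(e) 1L)
  if (!identical(as.integer(status), 0L) || !file.exists(tmp_out)) {
    warning("assembler command failed for ", merged$bin_id, call. = FALSE)
    return(NULL)
  }
  set <- tryCatch(Biostrings::readBStringSet(tmp_out),
                  error = function(e) NULL)
  if (is.null(set) || length(set) == 0L) {
    warning("assembler produced no contigs for ", merged$bin_id,
            call. = FALSE)
    return(NULL)
  }
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs <- seqs[nchar(seqs) >= min_contig_length]
  if (length(seqs) == 0L) {
    warning("assembler output all below min_contig_length for ",
            merged$bin_id, call. = FALSE)
    return(NULL)
  }
  sequence_bin(merged$bin_id, merged$sample_id, seqs)
}

#' Score a merged bin
#'
#' When an external quality tool is configured its CheckM2-dialect
#' report is parsed; otherwise a pluggable provider function is used
#' (ground truth in synthetic runs). With neither available, a
#' conservative surrogate is returned — the member maxima of
#' completeness and contamination — under which a merged candidate can
#' never beat the best input (merging without a quality estimate cannot
#' be validated, so it is never preferred).
#'
#' @param merged A `sequence_bin`.
#' @param member_qualities Quality rows of the cluster's members.
#' @param quality_provider Function `(bin) -> list(completeness,
#'   contamination)`, or `NULL`.
#' @param quality_cmd External command template (`{input}`/`{output}`
#'   placeholders), or `NULL`.
#' @return A quality-record row with an extra `provider` column, or
#'   `NULL` on external-tool failure.
#' @export
score_merged <- function(merged, member_qualities,
                         quality_provider = NULL, quality_cmd = NULL) {
  if (!is.null(quality_cmd)) {
    tmp_in <- tempfile(fileext = ".fa")
    tmp_out <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
    write_bin_fasta(merged, tmp_in)
    cmd <- gsub("{input}", tmp_in, quality_cmd, fixed = TRUE)
    cmd <- gsub("{output}", tmp_out, cmd, fixed = TRUE)
    status <- tryCatch(system(cmd), error = function(e) 1L)
    rec <- NULL
    if (identical(as.integer(status), 0L) && file.exists(tmp_out))
      rec <- tryCatch(read_quality_table(tmp_out), error = function(e) NULL)
    if (is.null(rec) || nrow(rec) == 0L) {
      warning("external quality tool failed for ", merged$bin_id,
              call. = FALSE)
      return(NULL)
    }
    out <- quality_record(merged$bin_id, rec$completeness[1L],
                          rec$contamination[1L])
    out$provider <- "external"
    return(out)
  }
  if (!is.null(quality_provider)) {
    est <- quality_provider(merged)
    out <- quality_record(merged$bin_id, est$completeness,
                          est$contamination)
    out$provider <- "provider"
    return(out)
  }
  out <- quality_record(merged$bin_id,
                        max(member_qualities$completeness),
                        max(member_qualities$contamination))
  out$provider <- "surrogate"
  out
}

#' Choose the best candidate for a cluster
#'
#' Argmax of quality score over the cluster's members plus (optionally)
#' the merged candidate. Ties are broken lexicographically by bin ID,
#' except that the merged candidate loses exact ties to any original bin
#' (prefer original data over a construct).
#'
#' @param cluster A `bin_cluster`.
#' @param member_qualities Quality rows of the members.
#' @param merged_quality Quality row of the merged candidate (with its
#'   `bin_id`), or `NULL` when no merge was attempted/succeeded.
#' @return A list of class `cluster_decision` with fields `cluster_id`,
#'   `mode` (`representative`, `merged_reassembled` or
#'   `merged_rejected`), `chosen_bin`, `candidate_scores`.
#' @export
choose_best <- function(cluster, member_qualities, merged_quality = NULL) {
  cand <- member_qualities[, c("bin_id", "quality_score"), drop = FALSE]
  cand$is_merged <- FALSE
  merged_attempted <- !is.null(merged_quality)
  if (merged_attempted) {
    cand <- rbind(cand, data.frame(
      bin_id = merged_quality$bin_id,
      quality_score = merged_quality$quality_score,
      is_merged = TRUE, stringsAsFactors = FALSE))
  }
  # merged loses exact ties: sort is_merged after score, before bin_id
  cand <- cand[order(-cand$quality_score, cand$is_merged, cand$bin_id), ,
               drop = FALSE]
  chosen <- cand[1L, ]
  mode <- if (!merged_attempted) "representative"
          else if (chosen$is_merged) "merged_reassembled"
          else "merged_rejected"
  structure(list(
    cluster_id = cluster$cluster_id, mode = mode,
    chosen_bin = chosen$bin_id,
    candidate_scores = setNames(cand$quality_score, cand$bin_id)
  ), class = "cluster_decision")
}

#' Remove residual redundancy among chosen bins
#'
#' Recomputes all pairwise ANI among the chosen bins from sequence
#' (merged bins included) and, while any pair is at or above the cutoff,
#' drops the lower-quality member of the currently worst offending pair
#' (highest ANI first; quality ties keep the lexicographically smaller
#' bin ID). Greedy and deterministic; terminates with no pair at or
#' above the cutoff.
#'
#' @param chosen List of entries `list(bin, quality, cluster_id, source,
#'   member_bins)`; duplicates by bin ID are collapsed first (a bin
#'   chosen by several cliques is the same genome).
#' @param cutoff ANI cutoff in percent.
#' @param k,scaled Sketch parameters.
#' @param decisions Cluster decisions to carry into the result.
#' @return An object of class `dereplication_result` with fields
#'   `retained`, `decisions`, `dropped_redundant`.
#' @export
remove_redundancy <- function(chosen, cutoff, k = 21, scaled = 200,
                              decisions = list()) {
  ids <- vapply(chosen, function(x) x$bin$bin_id, character(1))
  chosen <- chosen[!duplicated(ids)]
  chosen <- chosen[order(vapply(chosen, function(x) x$bin$bin_id,
                                character(1)))]
  dropped <- data.frame(bin_id = character(0), kept_rival = character(0),
                        ani = numeric(0), stringsAsFactors = FALSE)
  if (length(chosen) >= 2L) {
    sketches <- lapply(chosen, function(x)
      sketch_bin(x$bin, k = k, scaled = scaled))
    names(sketches) <- vapply(chosen, function(x) x$bin$bin_id,
                              character(1))
    edges <- all_pairs_ani(sketches)
    qual_of <- setNames(vapply(chosen, function(x) x$quality$quality_score,
                               numeric(1)),
                        names(sketches))
    alive <- names(sketches)
    repeat {
      live <- edges[edges$bin_a %in% alive & edges$bin_b %in% alive &
                      edges$ani >= cutoff, , drop = FALSE]
      if (nrow(live) == 0L) break
      live <- live[order(-live$ani, live$bin_a, live$bin_b), , drop = FALSE]
      a <- live$bin_a[1L]; b <- live$bin_b[1L]
      loser <- if (qual_of[[a]] < qual_of[[b]]) a
               else if (qual_of[[b]] < qual_of[[a]]) b
               else max(a, b)  # quality tie: keep lexicographically smaller
      winner <- setdiff(c(a, b), loser)
      dropped <- rbind(dropped, data.frame(
        bin_id = loser, kept_rival = winner, ani = live$ani[1L],
        stringsAsFactors = FALSE))
      alive <- setdiff(alive, loser)
    }
    chosen <- chosen[vapply(chosen, function(x) x$bin$bin_id %in% alive,
                            logical(1))]
  }
  structure(list(retained = chosen, decisions = decisions,
                 dropped_redundant = dropped),
            class = "dereplication_result")
}

#' @export
print.dereplication_result <- function(x, ...) {
  cat(sprintf("<dereplication_result> %d retained bin(s), %d dropped as redundant\n",
              length(x$retained), nrow(x$dropped_redundant)))
  invisible(x)
}

#' Run the full dereplication pipeline
#'
#' Stages, in order: length filter, purity filter, ANI graph,
#' single-linkage components, maximal cliques, orphan assignment,
#' per-cluster representative selection or merge-and-reassemble, final
#' redundancy removal, completeness filter. Per-stage counts are logged
#' when `config$verbose` is set and always recorded in the returned
#' `stage_counts`.
#'
#' @param bins Named list of `sequence_bin`.
#' @param qualities Quality table covering every bin.
#' @param config A `derep_config`.
#' @param edges Optional pre-computed ANI edge list (skips the internal
#'   estimator).
#' @return A `dereplication_result`; additional fields `clusters`,
#'   `stage_counts`, `graph`.
#' @export
run_pipeline <- function(bins, qualities, config = derep_config(),
                         edges = NULL) {
  stopifnot(inherits(config, "derep_config"))
  counts <- c(input = length(bins))
  log_stage(config, "input bins: %d", length(bins))

  bins <- filter_by_length(bins, config$min_length)
  counts["after_length_filter"] <- length(bins)
  log_stage(config, "after length filter (>= %d bp): %d",
            config$min_length, length(bins))

  if (length(bins) > 0L) {
    pf <- filter_by_purity(bins, qualities, config$purity_threshold)
    bins <- pf$retained
  }
  counts["after_purity_filter"] <- length(bins)
  log_stage(config, "after purity filter (> %g%%): %d",
            config$purity_threshold, length(bins))

  if (length(bins) == 0L) {
    warning("no bins survive the input filters; returning empty result",
            call. = FALSE)
    res <- structure(list(retained = list(), decisions = list(),
                          dropped_redundant = data.frame(
                            bin_id = character(0),
                            kept_rival = character(0), ani = numeric(0),
                            stringsAsFactors = FALSE)),
                     class = "dereplication_result")
    res$clusters <- list()
    res$stage_counts <- counts
    return(res)
  }

  if (!is.null(edges)) {
    # pre-computed edges may name bins removed by the input filters
    edges <- edges[edges$bin_a %in% names(bins) &
                     edges$bin_b %in% names(bins), , drop = FALSE]
  }
  graph <- build_ani_graph(bins, edges = edges, cutoff = config$ani_cutoff,
                           min_aligned_fraction = config$min_aligned_fraction,
                           k = config$k, scaled = config$scaled)
  counts["graph_nodes"] <- length(graph$nodes)
  counts["graph_edges"] <- nrow(graph$edges)
  log_stage(config, "ANI graph: %d nodes, %d edges at >= %g%%",
            length(graph$nodes), nrow(graph$edges), config$ani_cutoff)

  clusters <- cluster_bins(graph)
  counts["clusters"] <- length(clusters)
  log_stage(config, "clusters: %d", length(clusters))

  decisions <- list()
  chosen <- list()
  n_merged <- 0L
  for (cl in clusters) {
    mq <- do.call(rbind, lapply(cl$members, quality_for,
                                qualities = qualities))
    rep_id <- select_representative(cl, qualities)
    if (!is.null(rep_id)) {
      dec <- choose_best_representative(cl, mq, rep_id)
      entry_bin <- bins[[rep_id]]
      entry_q <- quality_for(qualities, rep_id)
      src <- "input"
    } else if (config$no_reassembly) {
      best <- best_member(cl, qualities)
      dec <- choose_best_representative(cl, mq, best)
      entry_bin <- bins[[best]]
      entry_q <- quality_for(qualities, best)
      src <- "input"
    } else {
      merged <- merge_bins(cl, bins)
      reassembled <- reassemble(
        merged, backend = config$reassembly_backend,
        assembler_cmd = config$assembler_cmd, k = config$k,
        containment_threshold = config$containment_threshold,
        min_contig_length = config$min_contig_length)
      merged_q <- if (is.null(reassembled)) NULL else
        score_merged(reassembled, mq,
                     quality_provider = config$quality_provider,
                     quality_cmd = config$quality_cmd)
      dec <- choose_best(cl, mq, merged_q)
      if (dec$mode == "merged_reassembled") {
        n_merged <- n_merged + 1L
        entry_bin <- reassembled
        entry_q <- merged_q[, colnames(qualities), drop = FALSE]
        src <- "merged"
      } else {
        entry_bin <- bins[[dec$chosen_bin]]
        entry_q <- quality_for(qualities, dec$chosen_bin)
        src <- "input"
      }
    }
    decisions[[length(decisions) + 1L]] <- dec
    chosen[[length(chosen) + 1L]] <- list(
      bin = entry_bin, quality = entry_q, cluster_id = cl$cluster_id,
      source = src, member_bins = cl$members)
  }
  counts["merged_reassembled"] <- n_merged
  log_stage(config, "per-cluster decisions: %d (of which merged: %d)",
            length(decisions), n_merged)

  result <- remove_redundancy(chosen, cutoff = config$ani_cutoff,
                              k = config$k, scaled = config$scaled,
                              decisions = decisions)
  counts["after_redundancy_removal"] <- length(result$retained)
  log_stage(config, "after redundancy removal: %d",
            length(result$retained))

  keep <- vapply(result$retained, function(r)
    r$quality$completeness >= config$min_completeness, logical(1))
  result$retained <- result$retained[keep]
  counts["after_completeness_filter"] <- length(result$retained)
  log_stage(config, "after completeness filter (>= %g%%): %d",
            config$min_completeness, length(result$retained))

  result$clusters <- clusters
  result$graph <- graph
  result$stage_counts <- counts
  result
}

# Decision record for the no-merge paths (a representative was found, or
# no_reassembly forced the best member).
choose_best_representative <- function(cluster, member_qualities, chosen) {
  structure(list(
    cluster_id = cluster$cluster_id, mode = "representative",
    chosen_bin = chosen,
    candidate_scores = setNames(member_qualities$quality_score,
                                member_qualities$bin_id)
  ), class = "cluster_decision")
}

#' Write a flat key-value run summary
#' @param result A `dereplication_result` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(result, path) {
  lines <- c(
    sprintf("%s: %s", names(result$stage_counts), result$stage_counts),
    sprintf("decision_%s: %s=%s",
            vapply(result$decisions, `[[`, character(1), "cluster_id"),
            vapply(result$decisions, `[[`, character(1), "mode"),
            vapply(result$decisions, `[[`, character(1), "chosen_bin")),
    sprintf("dropped_redundant: %s (kept %s, ani %.4f)",
            result$dropped_redundant$bin_id,
            result$dropped_redundant$kept_rival,
            result$dropped_redundant$ani)
  )
  writeLines(lines, path)
  invisible(path)
}
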