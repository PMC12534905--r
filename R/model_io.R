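#' Construct a sequence bin
#'
#' A bin is a named set of contigs putatively originating from one genome
#' in one sample; it is the unit being dereplicated. Contigs are stored as
#' a named character vector (names = contig IDs, values = DNA sequences
#' over A/C/G/T/N).
#'
#' @param bin_id Bin identifier, unique across a run.
#' @param sample_id Sample the bin was assembled from.
#' @param contigs Named character vector of DNA sequences. Sequences are
#'   uppercased and non-ACGTN characters are mapped to N.
#' @return An object of class `sequence_bin`.
#' @export
sequence_bin <- function(bin_id, sample_id, contigs) {
  stopifnot(is.character(bin_id), length(bin_id) == 1L, nzchar(bin_id))
  stopifnot(is.character(contigs), length(contigs) >= 1L)
  ids <- names(contigs)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("all contigs must be named", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate contig id in bin '", bin_id, "': ",
         ids[duplicated(ids)][1L], call. = FALSE)
  seqs <- normalize_dna(contigs)
  if (any(nchar(seqs) < 1L))
    stop("bin '", bin_id, "' contains an empty contig", call. = FALSE)
  structure(
    list(bin_id = bin_id, sample_id = sample_id, contigs = seqs),
    class = "sequence_bin"
  )
}

#' @export
print.sequence_bin <- function(x, ...) {
  cat(sprintf("<sequence_bin> %s (sample %s): %d contigs, %s bp\n",
              x$bin_id, x$sample_id, length(x$contigs),
              format(bin_length(x), big.mark = ",")))
  invisible(x)
}

#' Total length of a bin in base pairs
#' @param bin A `sequence_bin`.
#' @return Integer total contig length.
#' @export
bin_length <- function(bin) sum(nchar(bin$contigs))

# Uppercase and map everything outside {A,C,G,T,N} (IUPAC ambiguity codes
# and stray characters) to N. Real assemblies contain such codes; rejecting
# them would be hostile.
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# Strip directory and one .fa/.fasta/.fna extension (optionally .gz).
bin_stem <- function(path) {
  sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
}

#' Read a directory of FASTA bins
#'
#' One `sequence_bin` per FASTA file (`.fa`, `.fasta`, `.fna`, optionally
#' gzipped). The bin ID is the file stem; the sample ID is the part of the
#' stem before the first occurrence of `sample_delim` (the whole stem when
#' the delimiter is absent). How sample provenance is encoded in file names
#' varies between binning tools, hence the configurable delimiter.
#'
#' @param directory_path Directory containing the FASTA files.
#' @param sample_delim Delimiter separating sample ID from the rest of the
#'   file stem. Default `"__"`.
#' @return Named list of `sequence_bin` objects (names = bin IDs),
#'   in lexicographic bin-ID order.
#' @export
read_bins <- function(directory_path, sample_delim = "__") {
  if (!dir.exists(directory_path))
    stop("bin directory does not exist: ", directory_path, call. = FALSE)
  files <- list.files(directory_path,
                      pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop("no FASTA files (*.fa, *.fasta, *.fna) found in ",
         directory_path, call. = FALSE)
  files <- files[order(bin_stem(files))]
  stems <- bin_stem(files)
  if (anyDuplicated(stems))
    stop("duplicate bin id across files: ", stems[duplicated(stems)][1L],
         call. = FALSE)
  bins <- lapply(seq_along(files), function(i) {
    set <- tryCatch(Biostrings::readBStringSet(files[i]),
                    error = function(e)
                      stop("cannot parse FASTA file ", files[i], ": ",
                           conditionMessage(e), call. = FALSE))
    if (length(set) == 0L)
      stop("cannot parse FASTA file ", files[i], ": no records",
           call. = FALSE)
    seqs <- as.character(set)
    # contig id = first whitespace-delimited word of the header
    names(seqs) <- sub("\\s.*$", "", names(set))
    sid <- strsplit(stems[i], sample_delim, fixed = TRUE)[[1L]][1L]
    sequence_bin(stems[i], sid, seqs)
  })
  names(bins) <- stems
  bins
}

#' Write a bin to a FASTA file
#' @param bin A `sequence_bin`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_fasta <- function(bin, path) {
  set <- Biostrings::DNAStringSet(bin$contigs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a quality record
#'
#' Carries the completeness/contamination estimate for one bin together
#' with the derived purity (100 - contamination, floored at 0) and the
#' quality score (completeness - 5 x contamination).
#'
#' @param bin_id Bin identifier.
#' @param completeness Percent in `[0, 100]`.
#' @param contamination Percent, `>= 0` (may exceed 100 for badly
#'   contaminated bins).
#' @return A one-row data frame with columns `bin_id`, `completeness`,
#'   `contamination`, `purity`, `quality_score`.
#' @export
quality_record <- function(bin_id, completeness, contamination) {
  if (!is.numeric(completeness) || is.na(completeness) ||
      completeness < 0 || completeness > 100)
    stop("completeness must be in [0, 100], got ", completeness,
         call. = FALSE)
  if (!is.numeric(contamination) || is.na(contamination) || contamination < 0)
    stop("contamination must be >= 0, got ", contamination, call. = FALSE)
  data.frame(
    bin_id        = as.character(bin_id),
    completeness  = as.numeric(completeness),
    contamination = as.numeric(contamination),
    purity        = 100 - pmin(as.numeric(contamination), 100),
    quality_score = quality_score(completeness, contamination),
    stringsAsFactors = FALSE
  )
}

#' Read a CheckM2-style quality table
#'
#' Expects a TSV whose header contains columns `Name`, `Completeness` and
#' `Contamination` (the `quality_report.tsv` dialect); extra columns are
#' ignored.
#'
#' @param path Path to the TSV file.
#' @return Data frame with one row per bin and columns `bin_id`,
#'   `completeness`, `contamination`, `purity`, `quality_score`.
#' @export
read_quality_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE,
                    colClasses = "character")
  required <- c("Name", "Completeness", "Contamination")
  missing <- setdiff(required, colnames(tab))
  if (length(missing) > 0L)
    stop("quality table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$Name))
    stop("duplicate bin name in quality table: ",
         tab$Name[duplicated(tab$Name)][1L], call. = FALSE)
  comp <- suppressWarnings(as.numeric(tab$Completeness))
  cont <- suppressWarnings(as.numeric(tab$Contamination))
  bad <- which(is.na(comp) | is.na(cont))
  if (length(bad) > 0L)
    stop("non-numeric completeness/contamination in quality table row(s): ",
         paste(tab$Name[bad], collapse = ", "), call. = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    quality_record(tab$Name[i], comp[i], cont[i])))
  rownames(recs) <- recs$bin_id
  recs
}

# Look up one bin's quality record; error if absent.
quality_for <- function(qualities, bin_id) {
  idx <- match(bin_id, qualities$bin_id)
  if (is.na(idx))
    stop("no quality record for bin '", bin_id, "'", call. = FALSE)
  qualities[idx, , drop = FALSE]
}

#' Read a skani-style ANI edge list
#'
#' Expects the `skani dist` TSV dialect with columns `Ref_file`,
#' `Query_file`, `ANI`, `Align_fraction_ref`, `Align_fraction_query`.
#' Genome paths are mapped to bin IDs by file stem. Edges are
#' canonicalized to unordered pairs with `bin_a < bin_b`; when both
#' orientations of a pair are present the higher ANI is kept
#' (conservative toward clustering). The aligned fraction is the minimum
#' of the two reported fractions.
#'
#' @param path Path to the TSV file.
#' @param bin_ids Character vector of known bin IDs. Rows naming unknown
#'   genomes are skipped with a warning; an error is raised if every row
#'   is skipped.
#' @return Data frame of edges with columns `bin_a`, `bin_b`, `ani`,
#'   `aligned_fraction`.
#' @export
read_ani_edges <- function(path, bin_ids) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  required <- c("Ref_file", "Query_file", "ANI",
                "Align_fraction_ref", "Align_fraction_query")
  missing <- setdiff(required, colnames(tab))
  if (length(missing) > 0L)
    stop("ANI edge list ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) return(empty_edges())
  a <- bin_stem(tab$Ref_file)
  b <- bin_stem(tab$Query_file)
  known <- a %in% bin_ids & b %in% bin_ids
  if (any(!known)) {
    skipped <- unique(c(a[!known & !(a %in% bin_ids)],
                        b[!known & !(b %in% bin_ids)]))
    warning("skipping ", sum(!known), " ANI row(s) naming unknown bin(s): ",
            paste(utils::head(skipped, 5L), collapse = ", "), call. = FALSE)
    if (!any(known))
      stop("all rows of ", path, " name unknown bins", call. = FALSE)
  }
  edges <- data.frame(
    bin_a = pmin(a[known], b[known]),
    bin_b = pmax(a[known], b[known]),
    ani = as.numeric(tab$ANI[known]),
    aligned_fraction = pmin(as.numeric(tab$Align_fraction_ref[known]),
                            as.numeric(tab$Align_fraction_query[known])),
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$bin_a != edges$bin_b, , drop = FALSE]
  canonicalize_edges(edges)
}

# Deduplicate unordered pairs keeping the record with the higher ANI;
# deterministic lexicographic ordering of the result.
canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0L) return(empty_edges())
  swap <- edges$bin_a > edges$bin_b
  if (any(swap)) {
    tmp <- edges$bin_a[swap]
    edges$bin_a[swap] <- edges$bin_b[swap]
    edges$bin_b[swap] <- tmp
  }
  edges <- edges[edges$bin_a != edges$bin_b, , drop = FALSE]
  if (nrow(edges) == 0L) return(empty_edges())
  edges <- edges[order(edges$bin_a, edges$bin_b, -edges$ani), , drop = FALSE]
  key <- paste(edges$bin_a, edges$bin_b, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

empty_edges <- function() {
  data.frame(bin_a = character(0), bin_b = character(0),
             ani = numeric(0), aligned_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write the dereplication output
#'
#' Writes one FASTA file per retained bin plus a TSV report
#' (`dereplication_report.tsv`) with columns `bin_id`, `source`
#' (`input` or `merged`), `cluster_id`, `completeness`, `contamination`,
#' `quality_score`, `member_bins`. Files are written in lexicographic
#' bin-ID order so output is deterministic.
#'
#' @param result A `dereplication_result` from [run_pipeline()].
#' @param directory_path Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_output <- function(result, directory_path) {
  stopifnot(inherits(result, "dereplication_result"))
  if (!dir.exists(directory_path) &&
      !dir.create(directory_path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", directory_path, call. = FALSE)
  retained <- result$retained
  ord <- order(vapply(retained, function(r) r$bin$bin_id, character(1)))
  retained <- retained[ord]
  paths <- character(0)
  rows <- lapply(retained, function(r) {
    q <- r$quality
    data.frame(bin_id = r$bin$bin_id,
               source = r$source,
               cluster_id = r$cluster_id,
               completeness = q$completeness,
               contamination = q$contamination,
               quality_score = q$quality_score,
               member_bins = paste(r$member_bins, collapse = ","),
               stringsAsFactors = FALSE)
  })
  report <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(bin_id = character(0), source = character(0),
               cluster_id = character(0), completeness = numeric(0),
               contamination = numeric(0), quality_score = numeric(0),
               member_bins = character(0), stringsAsFactors = FALSE)
  for (r in retained) {
    p <- file.path(directory_path, paste0(r$bin$bin_id, ".fa"))
    write_bin_fasta(r$bin, p)
    paths <- c(paths, p)
  }
  report_path <- file.path(directory_path, "dereplication_report.tsv")
  write.table(report, report_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, report_path))
}
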