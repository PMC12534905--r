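#' @name synthetic
#' @title Labelled synthetic metagenome bins
#'
#' @description
#' The generator builds a fully labelled world in which every pipeline
#' stage can be verified against ground truth: species genomes at a
#' controlled between-species identity, strains at a controlled
#' within-species identity, and per-sample bins that are random contig
#' subsets of a strain (controlled completeness) with admixed foreign
#' contigs (controlled contamination). Mutations are substitutions only,
#' so true ANI between any two genomes is exactly their position-wise
#' identity — a closed-form oracle. All randomness flows from one master
#' seed via a documented per-stage derivation.
NULL

# Derived seed for stage `n` of master seed `seed`; kept below 2^31.
derive_seed <- function(seed, n) {
  as.integer((as.numeric(seed) * 1000003 + n) %% 2147483629)
}

#' Simulate a random genome
#'
#' i.i.d. bases at the stated GC content (A and T each at
#' `(1 - gc) / 2`, C and G each at `gc / 2`).
#'
#' @param length Genome length in bp (>= 10000).
#' @param gc_content GC fraction in (0, 1).
#' @param seed Integer seed; the sequence is deterministic per seed.
#' @return A DNA string.
#' @export
simulate_genome <- function(length, gc_content = 0.5, seed = 1) {
  stopifnot(length >= 10000, gc_content > 0, gc_content < 1)
  set.seed(seed)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Mutate a genome to a target identity
#'
#' Point substitutions at per-base rate `(100 - target_ani) / 100`,
#' uniform over positions, each substituting a uniformly random
#' different base. No indels, so the realized per-base identity is the
#' exact true ANI of the pair.
#'
#' @param genome DNA string.
#' @param target_ani Target identity in percent, in `[80, 100]`.
#' @param seed Integer seed.
#' @return List with `sequence` (the mutant) and `realized_identity`
#'   (percent, exact).
#' @export
mutate_to_ani <- function(genome, target_ani, seed = 1) {
  stopifnot(target_ani >= 80, target_ani <= 100)
  rate <- (100 - target_ani) / 100
  chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (rate > 0) {
    set.seed(seed)
    hit <- which(runif(n) < rate)
    if (length(hit) > 0L) {
      bases <- c("A", "C", "G", "T")
      # uniformly random *different* base at each hit position
      repl <- vapply(hit, function(i)
        sample(setdiff(bases, chars[i]), 1L), character(1))
      chars[hit] <- repl
    }
    realized <- 100 * (1 - length(hit) / n)
  } else {
    realized <- 100
  }
  list(sequence = paste(chars, collapse = ""),
       realized_identity = realized)
}

#' Exact position-wise identity of two equal-length sequences
#' @param a,b DNA strings of equal length.
#' @return Percent identity.
#' @export
seq_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  100 * mean(charToRaw(a) == charToRaw(b))
}

#' Build a bin from a strain genome
#'
#' The strain is tiled into non-overlapping contigs with lengths drawn
#' uniformly from `contig_length_range`; a uniformly ordered subset of
#' the tiles is taken until it totals at least `completeness`% of the
#' genome. Contamination is added as contigs cut from the contaminant
#' genome totaling `contamination`% of the bin's native length. The
#' truth entry records the exact realized values.
#'
#' @param strain DNA string (the source genome).
#' @param completeness Target completeness percent in `(0, 100]`.
#' @param contamination Target contamination percent (of native length),
#'   `>= 0`.
#' @param contaminant_genome DNA string the foreign contigs are cut
#'   from; required when `contamination > 0`.
#' @param contig_length_range Contig length bounds in bp, default
#'   5-50 kb.
#' @param seed Integer seed.
#' @param bin_id,sample_id Identifiers for the resulting bin.
#' @return List with `bin` (a `sequence_bin`) and `truth` (realized
#'   completeness/contamination, native intervals, lengths).
#' @export
make_bin <- function(strain, completeness, contamination = 0,
                     contaminant_genome = NULL,
                     contig_length_range = c(5000, 50000), seed = 1,
                     bin_id = "bin", sample_id = "s1") {
  stopifnot(completeness > 0, completeness <= 100, contamination >= 0)
  if (contamination > 0 && is.null(contaminant_genome))
    stop("contamination > 0 requires a contaminant genome", call. = FALSE)
  glen <- nchar(strain)
  set.seed(seed)
  # tile the genome
  starts <- integer(0); ends <- integer(0); pos <- 1L
  while (pos <= glen) {
    len <- sample(contig_length_range[1L]:contig_length_range[2L], 1L)
    starts <- c(starts, pos)
    ends <- c(ends, min(pos + len - 1L, glen))
    pos <- pos + len
  }
  target <- completeness / 100 * glen
  ord <- sample(seq_along(starts))
  cum <- cumsum((ends - starts + 1L)[ord])
  take <- ord[seq_len(which(cum >= min(target, sum(ends - starts + 1L)))[1L])]
  take <- sort(take)
  native <- vapply(take, function(i) substr(strain, starts[i], ends[i]),
                   character(1))
  names(native) <- sprintf("native_%04d", take)
  native_len <- sum(ends[take] - starts[take] + 1L)

  contam <- character(0)
  contam_len <- 0L
  if (contamination > 0) {
    target_c <- contamination / 100 * native_len
    i <- 0L
    clen_g <- nchar(contaminant_genome)
    while (contam_len < target_c) {
      i <- i + 1L
      len <- sample(contig_length_range[1L]:contig_length_range[2L], 1L)
      # cap at the remaining contamination budget (>= 100 bp so the
      # fragment still carries k-mers), so realized ~ target
      len <- min(len, clen_g, max(ceiling(target_c - contam_len), 100L))
      st <- sample.int(clen_g - len + 1L, 1L)
      contam[sprintf("foreign_%04d", i)] <-
        substr(contaminant_genome, st, st + len - 1L)
      contam_len <- contam_len + len
    }
  }
  bin <- sequence_bin(bin_id, sample_id, c(native, contam))
  list(
    bin = bin,
    truth = list(
      native_intervals = data.frame(start = starts[take], end = ends[take]),
      native_length = native_len, contam_length = contam_len,
      completeness = 100 * native_len / glen,
      contamination = if (native_len > 0) 100 * contam_len / native_len
                      else 0
    )
  )
}

#' Simulate a fully labelled multi-sample dataset
#'
#' `n_species` species genomes are derived from one root genome at a
#' pairwise identity of about `between_ani_max`; within each species,
#' `strains_per_species` strains are derived at a pairwise identity of
#' about `within_ani` (a single strain is the species genome itself).
#' Each sample contributes one bin per species, drawn from the sample's
#' strain with completeness and contamination drawn uniformly from the
#' stated ranges; the contaminant is the next species' genome. The truth
#' object records realized completeness/contamination per bin and exact
#' pairwise identity between all strain genomes.
#'
#' @param n_species Number of species (genome clusters), default 3.
#' @param strains_per_species Strains per species, default 1.
#' @param samples Number of samples, default 4.
#' @param within_ani Within-species pairwise identity in percent,
#'   default 99.5 (must exceed `between_ani_max`).
#' @param between_ani_max Between-species pairwise identity ceiling in
#'   percent, default 90.
#' @param completeness_range,contamination_range Uniform sampling ranges
#'   for bin quality, defaults `c(92, 100)` and `c(0, 2)`.
#' @param genome_length Genome length in bp, default 300 kb (large
#'   enough that >90%-complete bins clear the 200 kb length filter).
#' @param gc_content GC fraction, default 0.5.
#' @param contig_length_range Contig length bounds, default 5-50 kb.
#' @param seed Master seed.
#' @return List with `bins` (named list of `sequence_bin`), `qualities`
#'   (quality table from realized truth), and `truth` (list:
#'   `bin_table`, `ani` pairwise identity table, `strain_genomes`,
#'   `species_of_strain`).
#' @export
simulate_dataset <- function(n_species = 3, strains_per_species = 1,
                             samples = 4, within_ani = 99.5,
                             between_ani_max = 90,
                             completeness_range = c(92, 100),
                             contamination_range = c(0, 2),
                             genome_length = 300000, gc_content = 0.5,
                             contig_length_range = c(5000, 50000),
                             seed = 1) {
  if (within_ani <= between_ani_max)
    stop("within_ani must exceed between_ani_max (got ", within_ani,
         " <= ", between_ani_max, ")", call. = FALSE)
  root <- simulate_genome(genome_length, gc_content, derive_seed(seed, 0))
  # each species diverges from the root at rate 1 - sqrt(between/100),
  # so two species sit at ~between_ani_max pairwise identity
  sp_target <- 100 * sqrt(between_ani_max / 100)
  species_genomes <- lapply(seq_len(n_species), function(s)
    mutate_to_ani(root, sp_target, derive_seed(seed, s))$sequence)
  st_target <- 100 * sqrt(within_ani / 100)
  strain_genomes <- list()
  species_of_strain <- character(0)
  for (s in seq_len(n_species)) {
    for (t in seq_len(strains_per_species)) {
      id <- sprintf("sp%02d_st%02d", s, t)
      strain_genomes[[id]] <- if (strains_per_species == 1)
        species_genomes[[s]]
      else
        mutate_to_ani(species_genomes[[s]], st_target,
                      derive_seed(seed, 100 + s * 10 + t))$sequence
      species_of_strain[id] <- sprintf("sp%02d", s)
    }
  }
  # exact pairwise identity between strain genomes
  sids <- names(strain_genomes)
  ani_rows <- list()
  if (length(sids) >= 2L) {
    for (i in seq_len(length(sids) - 1L)) {
      for (j in seq((i + 1L), length(sids))) {
        ani_rows[[length(ani_rows) + 1L]] <- data.frame(
          strain_a = sids[i], strain_b = sids[j],
          ani = seq_identity(strain_genomes[[sids[i]]],
                             strain_genomes[[sids[j]]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  ani <- if (length(ani_rows) > 0L) do.call(rbind, ani_rows) else
    data.frame(strain_a = character(0), strain_b = character(0),
               ani = numeric(0), stringsAsFactors = FALSE)

  bins <- list()
  rows <- list()
  counter <- 1000L
  set.seed(derive_seed(seed, 999))
  comp_draw <- matrix(runif(samples * n_species, completeness_range[1L],
                            completeness_range[2L]), nrow = samples)
  cont_draw <- matrix(runif(samples * n_species, contamination_range[1L],
                            contamination_range[2L]), nrow = samples)
  for (smp in seq_len(samples)) {
    for (s in seq_len(n_species)) {
      t <- ((smp - 1L) %% strains_per_species) + 1L
      strain_id <- sprintf("sp%02d_st%02d", s, t)
      bin_id <- sprintf("s%02d__sp%02d_st%02d", smp, s, t)
      counter <- counter + 1L
      contaminant_sp <- (s %% n_species) + 1L
      mb <- make_bin(
        strain_genomes[[strain_id]],
        completeness = comp_draw[smp, s],
        contamination = cont_draw[smp, s],
        contaminant_genome = if (cont_draw[smp, s] > 0 && n_species > 1)
          species_genomes[[contaminant_sp]] else NULL,
        contig_length_range = contig_length_range,
        seed = derive_seed(seed, counter),
        bin_id = bin_id, sample_id = sprintf("s%02d", smp))
      bins[[bin_id]] <- mb$bin
      rows[[length(rows) + 1L]] <- data.frame(
        bin_id = bin_id, sample = sprintf("s%02d", smp),
        species = sprintf("sp%02d", s), strain = strain_id,
        completeness = mb$truth$completeness,
        contamination = mb$truth$contamination,
        contaminant = if (cont_draw[smp, s] > 0 && n_species > 1)
          sprintf("sp%02d", contaminant_sp) else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  bin_table <- do.call(rbind, rows)
  qualities <- do.call(rbind, lapply(seq_len(nrow(bin_table)), function(i)
    quality_record(bin_table$bin_id[i], bin_table$completeness[i],
                   bin_table$contamination[i])))
  rownames(qualities) <- qualities$bin_id
  list(bins = bins[order(names(bins))], qualities = qualities,
       truth = list(bin_table = bin_table, ani = ani,
                    strain_genomes = strain_genomes,
                    species_of_strain = species_of_strain))
}

#' Ground-truth quality provider for merged bins
#'
#' Returns a function suitable as `quality_provider` in [derep_config()].
#' For a (possibly merged) bin it computes the full canonical k-mer set
#' of the bin and of every reference genome; the source genome is the
#' one with the highest containment of the bin. Completeness proxy =
#' fraction of the source genome's k-mers present in the bin;
#' contamination proxy = k-mers foreign to the source, relative to the
#' bin's native content. Exact for substitution-only synthetic data
#' (every bin contig is a substring of some reference genome).
#'
#' @param genomes Named list or character vector of reference genome
#'   sequences (e.g. `truth$strain_genomes` from [simulate_dataset()]).
#' @param k k-mer size, default 21.
#' @return Function `(sequence_bin) -> list(completeness,
#'   contamination, source_genome)`.
#' @export
truth_quality_provider <- function(genomes, k = 21) {
  genomes <- as.list(genomes)
  stopifnot(length(genomes) >= 1L, !is.null(names(genomes)))
  ref_sets <- lapply(genomes, function(g)
    .sketch_sequences(g, as.integer(k), 1)$hashes)
  function(bin) {
    stopifnot(inherits(bin, "sequence_bin"))
    bk <- .sketch_sequences(bin$contigs, as.integer(k), 1)$hashes
    inter <- vapply(ref_sets, function(s)
      .hash_intersection_size(bk, s), numeric(1))
    src <- names(which.max(inter))
    native <- inter[[src]]
    completeness <- 100 * native / length(ref_sets[[src]])
    contamination <- if (native > 0)
      100 * (length(bk) - native) / native else 0
    list(completeness = min(completeness, 100),
         contamination = contamination, source_genome = src)
  }
}

#' Write a simulated dataset to disk
#'
#' Writes one FASTA per bin under `<dir>/bins/`, a CheckM2-dialect
#' `quality_report.tsv` built from the realized truth, and the truth
#' tables (`truth_bins.tsv`, `truth_ani.tsv`).
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  bin_dir <- file.path(dir, "bins")
  dir.create(bin_dir, recursive = TRUE, showWarnings = FALSE)
  for (b in dataset$bins)
    write_bin_fasta(b, file.path(bin_dir, paste0(b$bin_id, ".fa")))
  qpath <- file.path(dir, "quality_report.tsv")
  qtab <- data.frame(Name = dataset$qualities$bin_id,
                     Completeness = dataset$qualities$completeness,
                     Contamination = dataset$qualities$contamination)
  write.table(qtab, qpath, sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- file.path(dir, "truth_bins.tsv")
  write.table(dataset$truth$bin_table, tb, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ta <- file.path(dir, "truth_ani.tsv")
  write.table(dataset$truth$ani, ta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(bin_dir = bin_dir, quality = qpath, truth_bins = tb,
                 truth_ani = ta))
}
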