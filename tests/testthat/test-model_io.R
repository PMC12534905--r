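test_that("read_bins parses a directory of FASTA bins", {
  dir <- withr::local_tempdir()
  writeLines(c(">c1 some description", "ACGTACGT", ">c2", "acgt"),
             file.path(dir, "s1__binA.fa"))
  writeLines(c(">c1", "ACRTACGT"), file.path(dir, "s2__binB.fasta"))
  bins <- read_bins(dir)

  expect_length(bins, 2L)
  expect_named(bins, c("s1__binA", "s2__binB"))
  expect_equal(vapply(bins, `[[`, character(1), "sample_id"),
               c(s1__binA = "s1", s2__binB = "s2"))
  expect_equal(sum(lengths(lapply(bins, `[[`, "contigs"))), 3L)
  # case normalization and header word splitting
  expect_equal(unname(bins$s1__binA$contigs[["c2"]]), "ACGT")
  # non-ACGTN characters map to N
  expect_equal(unname(bins$s2__binB$contigs[["c1"]]), "ACNTACGT")
  expect_equal(bin_length(bins$s1__binA), 12L)
})

test_that("read_bins error policy", {
  dir <- withr::local_tempdir()
  expect_error(read_bins(dir), "no FASTA files")
  writeLines("not fasta at all", file.path(dir, "bad.fa"))
  expect_error(read_bins(dir), "bad.fa")
})

test_that("sample delimiter is configurable", {
  dir <- withr::local_tempdir()
  writeLines(c(">c1", "ACGT"), file.path(dir, "sampleX-binZ.fa"))
  bins <- read_bins(dir, sample_delim = "-")
  expect_equal(bins[[1]]$sample_id, "sampleX")
  bins2 <- read_bins(dir, sample_delim = "__")
  expect_equal(bins2[[1]]$sample_id, "sampleX-binZ") # whole stem
})

test_that("sequence_bin rejects malformed input", {
  expect_error(sequence_bin("b", "s", c("ACGT")), "named")
  expect_error(sequence_bin("b", "s", c(c1 = "ACGT", c1 = "TTTT")),
               "duplicate contig")
})

test_that("quality table parses the CheckM2 dialect and derives scores", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Name\tCompleteness\tContamination\tExtra",
               "binA\t100\t0\tx",
               "binB\t90\t5\ty",
               "binC\t50\t10\tz"), path)
  q <- read_quality_table(path)
  expect_equal(q$quality_score, c(100, 65, 0))
  expect_equal(q$purity, c(100, 95, 90))
})

test_that("quality table error policy", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Name\tCompleteness", "binA\t90"), path)
  expect_error(read_quality_table(path), "Contamination")
  writeLines(c("Name\tCompleteness\tContamination",
               "binA\t90\t1", "binA\t80\t1"), path)
  expect_error(read_quality_table(path), "duplicate")
  writeLines(c("Name\tCompleteness\tContamination", "binA\tlots\t1"), path)
  expect_error(read_quality_table(path), "non-numeric")
})

test_that("read_ani_edges canonicalizes skani-style rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  header <- "Ref_file\tQuery_file\tANI\tAlign_fraction_ref\tAlign_fraction_query"
  writeLines(c(header,
               "bins/A.fa\tbins/B.fa\t99.5\t0.9\t0.8",
               "bins/B.fa\tbins/A.fa\t99.4\t0.85\t0.95"), path)
  e <- read_ani_edges(path, c("A", "B"))
  expect_equal(nrow(e), 1L)
  expect_equal(e$bin_a, "A")
  expect_equal(e$ani, 99.5)          # higher of the two orientations
  expect_equal(e$aligned_fraction, 0.8) # min of the pair's fractions

  # empty file with valid header -> empty edge set
  writeLines(header, path)
  expect_equal(nrow(read_ani_edges(path, c("A", "B"))), 0L)

  # unknown genome: row skipped with warning, others kept
  writeLines(c(header,
               "A.fa\tB.fa\t99.5\t0.9\t0.9",
               "A.fa\tX.fa\t99.9\t0.9\t0.9"), path)
  expect_warning(e <- read_ani_edges(path, c("A", "B")), "unknown")
  expect_equal(nrow(e), 1L)
  # all rows unknown -> error
  writeLines(c(header, "X.fa\tY.fa\t99.9\t0.9\t0.9"), path)
  expect_error(suppressWarnings(read_ani_edges(path, c("A", "B"))),
               "unknown bins")
})

test_that("FASTA round trip preserves sequences exactly", {
  dir <- withr::local_tempdir()
  set.seed(42)
  for (i in 1:3) {
    seqs <- vapply(1:4, function(j)
      paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- paste0("ctg", 1:4)
    write_bin_fasta(tiny_bin(sprintf("s%d__b%d", i, i), seqs),
                    file.path(dir, sprintf("s%d__b%d.fa", i, i)))
  }
  bins <- read_bins(dir)
  bins2_dir <- withr::local_tempdir()
  for (b in bins)
    write_bin_fasta(b, file.path(bins2_dir, paste0(b$bin_id, ".fa")))
  bins2 <- read_bins(bins2_dir)
  expect_equal(lapply(bins2, `[[`, "contigs"),
               lapply(bins, `[[`, "contigs"))
})

test_that("write_output emits FASTA set + report and round-trips scores", {
  out <- withr::local_tempdir()
  mk <- function(id, comp, cont, src = "input", members = id) {
    list(bin = tiny_bin(id, c(c1 = "ACGTACGTACGT")),
         quality = quality_record(id, comp, cont),
         cluster_id = "001.001", source = src, member_bins = members)
  }
  result <- structure(list(
    retained = list(mk("b1", 95, 1), mk("b2", 80, 2),
                    mk("merged_001", 99, 0, "merged", c("b3", "b4"))),
    decisions = list(),
    dropped_redundant = data.frame()), class = "dereplication_result")
  paths <- write_output(result, out)
  expect_length(list.files(out, pattern = "\\.fa$"), 3L)
  rep <- read.delim(file.path(out, "dereplication_report.tsv"))
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$member_bins[rep$bin_id == "merged_001"], "b3,b4")
  expect_equal(rep$source[rep$bin_id == "merged_001"], "merged")
  # report quality scores re-derive from completeness/contamination
  expect_equal(rep$quality_score,
               rep$completeness - 5 * rep$contamination)

  # empty result: header-only report, no error
  empty <- structure(list(retained = list(), decisions = list(),
                          dropped_redundant = data.frame()),
                     class = "dereplication_result")
  out2 <- withr::local_tempdir()
  expect_no_error(write_output(empty, out2))
  expect_equal(nrow(read.delim(file.path(out2, "dereplication_report.tsv"))),
               0L)
})

test_that("canonical edge sets have no duplicates or self-edges", {
  set.seed(9)
  for (trial in 1:20) {
    n <- sample(2:8, 1)
    ids <- sprintf("b%d", sample(n))
    raw <- data.frame(
      bin_a = sample(ids, 30, replace = TRUE),
      bin_b = sample(ids, 30, replace = TRUE),
      ani = runif(30, 90, 100), aligned_fraction = runif(30),
      stringsAsFactors = FALSE)
    ce <- magderep:::canonicalize_edges(raw)
    expect_true(all(ce$bin_a < ce$bin_b))
    expect_false(any(duplicated(paste(ce$bin_a, ce$bin_b))))
  }
})
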