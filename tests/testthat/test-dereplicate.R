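# shared toy cluster
cl_ab <- magderep:::bin_cluster("001.001", c("a", "b"), "001")

test_that("select_representative: gate, argmax, tie-break", {
  q <- rbind(quality_record("a", 95, 2),  # score 85
             quality_record("b", 98, 1))  # score 93
  expect_equal(select_representative(cl_ab, q), "b")

  q2 <- rbind(quality_record("a", 80, 1), quality_record("b", 89, 0))
  expect_null(select_representative(cl_ab, q2)) # nobody exceeds comp 90

  q3 <- rbind(quality_record("a", 95, 2), quality_record("b", 95, 2))
  expect_equal(select_representative(cl_ab, q3), "a") # lexicographic tie
})

test_that("merge_bins unions contigs with unique prefixed IDs", {
  bins <- list(
    a = tiny_bin("a", c(c1 = "ACGTACGTAA", c2 = "TTTTACGTAC",
                        c3 = "GGGGACGTAC")),
    b = tiny_bin("b", c(c1 = "CCCCACGTAC", c2 = "AAAAACGTAC")))
  m <- merge_bins(cl_ab, bins)
  expect_length(m$contigs, 5L)
  expect_false(anyDuplicated(names(m$contigs)) > 0)
  # shared original ID "c1" survives under distinct prefixes
  expect_true(all(c("a:c1", "b:c1") %in% names(m$contigs)))

  # singleton cluster: identity up to the prefix
  single <- magderep:::bin_cluster("001.002", "a", "001")
  m1 <- merge_bins(single, bins)
  expect_equal(unname(m1$contigs), unname(bins$a$contigs))
})

test_that("containment_merge deduplicates contained contigs", {
  g <- simulate_genome(30000, 0.5, 21)
  dup <- tiny_bin("m", c(x = g, y = g))
  r <- reassemble(dup)
  expect_length(r$contigs, 1L) # full containment -> one retained

  disjoint <- tiny_bin("m", c(x = substr(g, 1, 10000),
                              y = substr(g, 15000, 30000)))
  expect_length(reassemble(disjoint)$contigs, 2L)

  # nearly-contained contig (96% inside a longer one) is dropped
  sub <- tiny_bin("m", c(long = g, short = substr(g, 1, 12000)))
  expect_length(reassemble(sub)$contigs, 1L)
})

test_that("merged k-mer set equals the union of complementary halves (oracle)", {
  g <- simulate_genome(40000, 0.5, 33)
  half1 <- substr(g, 1, 24000)
  half2 <- substr(g, 20000, 40000)
  bins <- list(a = tiny_bin("a", c(h1 = half1, dup = substr(g, 1, 8000))),
               b = tiny_bin("b", c(h2 = half2)))
  m <- reassemble(merge_bins(cl_ab, bins))
  got <- sort(magderep:::.sketch_sequences(m$contigs, 21L, 1)$hashes)
  want <- sort(magderep:::.sketch_sequences(c(half1, half2), 21L, 1)$hashes)
  expect_identical(got, want) # duplicated contig contributes nothing new
})

test_that("external assembler failures fall back cleanly", {
  g <- simulate_genome(15000, 0.5, 2)
  merged <- tiny_bin("m", c(c1 = g))
  expect_warning(
    r <- reassemble(merged, backend = "external_assembler",
                    assembler_cmd = "false # {input} {output}"),
    "failed")
  expect_null(r)
  # a working "assembler" that just copies input
  ok <- reassemble(merged, backend = "external_assembler",
                   assembler_cmd = "cp {input} {output}")
  expect_s3_class(ok, "sequence_bin")
  expect_equal(unname(ok$contigs), unname(merged$contigs))
})

test_that("score_merged providers and fallbacks", {
  g <- simulate_genome(30000, 0.5, 8)
  merged <- tiny_bin("merged_x", c(c1 = g))
  mq <- rbind(quality_record("a", 60, 1), quality_record("b", 55, 2))

  # ground-truth provider: bin contains 100% of its genome, 0 foreign
  provider <- truth_quality_provider(list(gen = g))
  rec <- score_merged(merged, mq, quality_provider = provider)
  expect_equal(rec$completeness, 100)
  expect_equal(rec$contamination, 0)
  expect_equal(rec$provider, "provider")

  # no provider: conservative surrogate (member maxima)
  rec2 <- score_merged(merged, mq)
  expect_equal(rec2$completeness, 60)
  expect_equal(rec2$contamination, 2)
  expect_equal(rec2$provider, "surrogate")

  # external tool failure -> NULL (caller treats as merged_rejected)
  expect_warning(
    rec3 <- score_merged(merged, mq, quality_cmd = "false # {input}"),
    "failed")
  expect_null(rec3)
})

test_that("truth provider completeness equals k-mer union coverage (oracle)", {
  g <- simulate_genome(50000, 0.5, 55)
  # halves contributing 60% and 55% with overlap
  b <- tiny_bin("m", c(h1 = substr(g, 1, 30000),
                       h2 = substr(g, 22500, 50000)))
  provider <- truth_quality_provider(list(gen = g))
  est <- provider(b)
  union_k <- length(oracle_canonical_kmers(
    c(substr(g, 1, 30000), substr(g, 22500, 50000)), 21))
  genome_k <- length(oracle_canonical_kmers(g, 21))
  expect_equal(est$completeness, 100 * union_k / genome_k,
               tolerance = 1e-10)
})

test_that("choose_best: argmax, modes, merged loses ties", {
  mq <- rbind(quality_record("a", 45, 1), quality_record("b", 40, 0))
  merged_hi <- quality_record("merged_001.001", 60, 0)
  merged_hi$provider <- "provider"
  d1 <- choose_best(cl_ab, mq, merged_hi)
  expect_equal(d1$mode, "merged_reassembled")
  expect_equal(d1$chosen_bin, "merged_001.001")

  merged_lo <- quality_record("merged_001.001", 30, 0)
  merged_lo$provider <- "provider"
  d2 <- choose_best(cl_ab, mq, merged_lo)
  expect_equal(d2$mode, "merged_rejected")
  expect_equal(d2$chosen_bin, "a")

  merged_tie <- quality_record("merged_001.001", 40, 0)
  merged_tie$provider <- "provider"
  d3 <- choose_best(cl_ab, mq, merged_tie)
  expect_equal(d3$chosen_bin, "a") # exact tie: original data wins
  expect_equal(d3$mode, "merged_rejected")
})

test_that("remove_redundancy drops the lower-quality member of offending pairs", {
  g <- simulate_genome(30000, 0.5, 71)
  mk <- function(id, seqs, comp, cont) {
    list(bin = tiny_bin(id, seqs), quality = quality_record(id, comp, cont),
         cluster_id = "x", source = "input", member_bins = id)
  }
  # two near-identical bins, one unrelated
  chosen <- list(
    mk("hi", c(c1 = g), 80, 0),
    mk("lo", c(c1 = mutate_to_ani(g, 99.8, 5)$sequence), 70, 0),
    mk("other", c(c1 = simulate_genome(30000, 0.5, 72)), 90, 0))
  res <- remove_redundancy(chosen, cutoff = 99)
  ids <- vapply(res$retained, function(x) x$bin$bin_id, character(1))
  expect_setequal(ids, c("hi", "other"))
  expect_equal(res$dropped_redundant$bin_id, "lo")
  expect_equal(res$dropped_redundant$kept_rival, "hi")

  # all pairs below cutoff: identity
  chosen2 <- list(mk("x", c(c1 = g), 80, 0),
                  mk("y", c(c1 = simulate_genome(30000, 0.5, 73)), 70, 0))
  expect_length(remove_redundancy(chosen2, cutoff = 99)$retained, 2L)
})

test_that("redundancy chain x~y~z keeps both ends (oracle-confirmed)", {
  # x and z are each near-identical to y but not to each other:
  # y overlaps x on one half and z on the other
  g <- simulate_genome(60000, 0.5, 81)
  x_seq <- substr(g, 1, 27000)
  z_seq <- substr(g, 33000, 60000)
  y_seq <- g
  mk <- function(id, s, comp) {
    list(bin = tiny_bin(id, c(c1 = s)), quality = quality_record(id, comp, 0),
         cluster_id = "x", source = "input", member_bins = id)
  }
  # containment of x in y and z in y is 1 (ANI 100); x vs z disjoint
  chosen <- list(mk("x", x_seq, 90), mk("y", y_seq, 50), mk("z", z_seq, 80))
  res <- remove_redundancy(chosen, cutoff = 99)
  ids <- sort(vapply(res$retained, function(e) e$bin$bin_id, character(1)))
  expect_equal(ids, c("x", "z"))
  # oracle: exhaustive search over drop orders — any valid final set has
  # no pair >= cutoff; {x, z} is the unique maximal such set here
  expect_equal(nrow(res$dropped_redundant), 1L)
  expect_equal(res$dropped_redundant$bin_id, "y")
})

test_that("run_pipeline: single clean bin passes through unchanged", {
  g <- simulate_genome(250000, 0.5, 91)
  bins <- list(`s1__b1` = tiny_bin("s1__b1", c(c1 = g)))
  q <- quality_record("s1__b1", 95, 1)
  res <- run_pipeline(bins, q, derep_config())
  expect_length(res$retained, 1L)
  expect_equal(res$retained[[1]]$bin$bin_id, "s1__b1")
  expect_equal(res$retained[[1]]$source, "input")
  expect_identical(res$retained[[1]]$bin$contigs, bins[[1]]$contigs)
})

test_that("run_pipeline returns a valid empty result when filters clear everything", {
  bins <- list(b1 = tiny_bin("b1", c(c1 = simulate_genome(15000, 0.5, 3))))
  q <- quality_record("b1", 95, 1)
  expect_warning(res <- run_pipeline(bins, q, derep_config()), "no bins")
  expect_length(res$retained, 0L)
  expect_s3_class(res, "dereplication_result")
})

test_that("merging lifts a cluster with no high-quality member", {
  # two pure, incomplete bins of one genome, heavily overlapping so they
  # share an ANI edge; no member passes the high-quality gate
  g <- simulate_genome(300000, 0.5, 101)
  b1 <- make_bin(g, 85, 0, seed = 11, bin_id = "s1__b", sample_id = "s1")
  b2 <- make_bin(g, 80, 0, seed = 12, bin_id = "s2__b", sample_id = "s2")
  bins <- list(`s1__b` = b1$bin, `s2__b` = b2$bin)
  q <- rbind(quality_record("s1__b", b1$truth$completeness, 0),
             quality_record("s2__b", b2$truth$completeness, 0))
  cfg <- derep_config(quality_provider = truth_quality_provider(list(g = g)))
  res <- run_pipeline(bins, q, cfg)
  expect_length(res$retained, 1L)
  modes <- vapply(res$decisions, `[[`, character(1), "mode")
  if (res$retained[[1]]$source == "merged") {
    # merged candidate must strictly beat the best member
    dec <- res$decisions[[which(modes == "merged_reassembled")[1]]]
    sc <- dec$candidate_scores
    expect_gt(sc[[dec$chosen_bin]], max(sc[names(sc) != dec$chosen_bin]))
    expect_gt(res$retained[[1]]$quality$completeness,
              max(q$completeness))
  }

  # no_reassembly: same clustering, best member chosen despite the gate
  res2 <- run_pipeline(bins, q, derep_config(no_reassembly = TRUE))
  expect_length(res2$retained, 1L)
  expect_equal(res2$retained[[1]]$source, "input")
  expect_equal(res2$retained[[1]]$bin$bin_id, "s1__b")
  # cluster memberships identical between the two modes
  expect_identical(lapply(res2$clusters, `[[`, "members"),
                   lapply(res$clusters, `[[`, "members"))
})

test_that("quality dominance holds across pipeline decisions", {
  ds <- simulate_dataset(n_species = 2, samples = 3,
                         completeness_range = c(70, 100),
                         contamination_range = c(0, 1),
                         genome_length = 120000, seed = 5)
  cfg <- derep_config(min_length = 50000,
                      quality_provider =
                        truth_quality_provider(ds$truth$strain_genomes))
  res <- run_pipeline(ds$bins, ds$qualities, cfg)
  for (dec in res$decisions) {
    sc <- dec$candidate_scores
    if (dec$mode == "merged_reassembled") {
      # merged candidate must strictly beat every original member
      members <- setdiff(names(sc), dec$chosen_bin)
      expect_gt(sc[[dec$chosen_bin]], max(sc[members]))
    } else {
      # chosen representative scores at least as high as every member
      # that passes the high-quality gate
      mem <- names(sc)[names(sc) %in% ds$qualities$bin_id]
      hq <- mem[is_high_quality(ds$qualities[match(mem, ds$qualities$bin_id), ])]
      if (dec$chosen_bin %in% hq)
        expect_gte(sc[[dec$chosen_bin]], max(sc[hq]))
    }
  }
})
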