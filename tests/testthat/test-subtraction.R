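test_that("k-mer index enumerates canonical k-mers exactly", {
  idx <- suppressMessages(build_kmer_index(c(s = "ACGTACGT"), k = 4))
  expect_setequal(idx$kmers, c("ACGT", "CGTA", "GTAC"))

  # brute-force check on a random sequence: canonical set of all windows
  set.seed(3)
  s <- random_dna(200, 0.5)
  idx <- build_kmer_index(c(s = s), k = 25)
  wins <- substring(s, 1:(200 - 24), 25:200)
  expect_setequal(idx$kmers, unique(pmin(wins, revcomp(wins))))

  expect_length(build_kmer_index(character(0), k = 25)$kmers, 0)
  expect_length(build_kmer_index(c(s = strrep("A", 24)), k = 25)$kmers, 0)
  # k-mers containing non-ACGT are skipped
  expect_length(suppressMessages(build_kmer_index(c(s = "ACGTNACGT"), k = 5))$kmers, 0)
})

test_that("subtract_reads applies the shared-k-mer removal rule", {
  set.seed(9)
  female <- c(f1 = random_dna(300, 0.5))
  idx <- build_kmer_index(female, k = 25)

  verbatim <- substr(female[[1]], 50, 149)          # substring of a transcript
  rc_read <- revcomp(substr(female[[1]], 120, 219)) # other strand
  one_kmer <- paste0(random_dna(40, 0.5), substr(female[[1]], 10, 34),
                     random_dna(35, 0.5))           # shares exactly one window
  clean <- random_dna(100, 0.5)
  reads <- tibble::tibble(
    id = c("verbatim", "rc", "one_kmer", "clean", "short"),
    seq = c(verbatim, rc_read, one_kmer, clean, "ACGT"))
  kept <- suppressMessages(subtract_reads(reads, idx))
  expect_identical(kept$id, "clean")
  expect_equal(attr(kept, "n_short"), 1)
  expect_equal(attr(kept, "n_removed"), 3)
})

test_that("subtract_reads agrees with the brute-force window scanner", {
  set.seed(14)
  female <- setNames(replicate(4, random_dna(400, 0.5)), paste0("f", 1:4))
  idx <- build_kmer_index(female, k = 25)
  # mixture: female fragments (some reverse complemented), chimeras, noise
  frags <- vapply(1:30, function(i) {
    src <- sample(female, 1)
    a <- sample(300, 1)
    s <- substr(src, a, a + 99)
    if (runif(1) < 0.5) revcomp(s) else s
  }, character(1))
  noise <- vapply(1:30, function(i) random_dna(100, 0.5), character(1))
  chim <- vapply(1:20, function(i) {
    src <- sample(female, 1)
    paste0(random_dna(60, 0.5), substr(src, 100, 139))
  }, character(1))
  reads <- tibble::tibble(id = sprintf("r%02d", 1:80),
                          seq = c(frags, noise, chim))
  kept <- subtract_reads(reads, idx)
  expect_identical(kept$id, reads$id[oracle_subtract(reads$seq, female, 25)])
  # order preserved
  expect_identical(kept$id, sort(kept$id)[rank(match(kept$id, reads$id))])
})

test_that("enlarging the female transcriptome never grows the retained set", {
  set.seed(21)
  female_small <- setNames(replicate(2, random_dna(400, 0.5)), c("f1", "f2"))
  female_big <- c(female_small,
                  setNames(replicate(3, random_dna(400, 0.5)), paste0("g", 1:3)))
  reads <- tibble::tibble(
    id = sprintf("r%02d", 1:60),
    seq = c(vapply(1:30, function(i) random_dna(100, 0.5), character(1)),
            vapply(1:30, function(i) {
              src <- sample(female_big, 1)
              a <- sample(300, 1)
              substr(src, a, a + 99)
            }, character(1))))
  k_small <- subtract_reads(reads, build_kmer_index(female_small, 25))
  k_big <- subtract_reads(reads, build_kmer_index(female_big, 25))
  expect_true(all(k_big$id %in% k_small$id))
})

test_that("unitig assembly reconstructs transcripts from tiled reads", {
  set.seed(30)
  tx <- random_dna(1000, 0.5)
  ctg <- assemble_candidates(tiled_reads(tx), k = 25)
  expect_equal(nrow(ctg), 1)
  expect_identical(canon_seq(ctg$seq), canon_seq(tx))

  # two k-mer-disjoint transcripts -> two contigs
  tx2 <- random_dna(600, 0.5)
  reads <- dplyr::bind_rows(tiled_reads(tx, id_prefix = "a"),
                            tiled_reads(tx2, id_prefix = "b"))
  ctg2 <- assemble_candidates(reads, k = 25)
  expect_equal(nrow(ctg2), 2)
  expect_setequal_canon(ctg2$seq, c(tx, tx2))

  # invariance under read shuffling
  for (i in 1:3) {
    sh <- reads[sample.int(nrow(reads)), ]
    expect_identical(assemble_candidates(sh, k = 25), ctg2)
  }

  # empty input -> empty FASTA, not an error
  expect_equal(nrow(assemble_candidates(tibble::tibble(id = character(0),
                                                       seq = character(0)))), 0)
  # short unitigs are dropped
  expect_equal(nrow(assemble_candidates(tiled_reads(random_dna(150, 0.5),
                                                    read_len = 60, step = 10),
                                        k = 25, min_len = 200)), 0)
})

test_that("genomic-coverage classification applies the depth window and female zero rule", {
  set.seed(33)
  contigs <- tibble::tibble(id = c("in_window", "low", "high", "female_cov"),
                            seq = replicate(4, random_dna(500, 0.5)))
  male <- dplyr::bind_rows(
    exact_depth_reads(contigs$seq[1], 8, id_prefix = "m1"),
    exact_depth_reads(contigs$seq[2], 2, id_prefix = "m2"),
    exact_depth_reads(contigs$seq[3], 16, id_prefix = "m3"),
    exact_depth_reads(contigs$seq[4], 8, id_prefix = "m4"))
  female <- exact_depth_reads(contigs$seq[4], 6, id_prefix = "f1")
  cls <- classify_by_genomic_coverage(contigs, male, female)
  expect_identical(cls$verdict, c("retained", "rejected_low_male",
                                  "rejected_high_male", "rejected_female_cov"))
  expect_equal(cls$male_depth[1], 8, tolerance = 0.05)
  expect_equal(cls$female_depth[1:3], rep(0, 3))

  # identity threshold: 1 mismatch in 100 bp passes at 0.99, 2 do not
  base <- contigs$seq[1]
  mk <- function(pos) { x <- substr(base, 101, 200)
    for (p in pos) substr(x, p, p) <- setdiff(c("A","C","G","T"),
                                              substr(x, p, p))[1]
    x }
  d <- msyscan:::match_read_depth(tibble::tibble(id = "c", seq = base),
                                  tibble::tibble(id = "x", seq = mk(50)))
  expect_gt(d$depth, 0)
  d2 <- msyscan:::match_read_depth(tibble::tibble(id = "c", seq = base),
                                   tibble::tibble(id = "x", seq = mk(c(40, 60))))
  expect_equal(d2$depth, 0)
})
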