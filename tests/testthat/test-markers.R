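test_that("marker mapping classifies unique, multi, and unmapped correctly", {
  set.seed(71)
  chrA <- random_dna(5e4, 0.45)
  chrB <- random_dna(3e4, 0.45)
  m_unique <- substr(chrA, 10001, 10040)
  dup <- substr(chrA, 20001, 20030)
  substr(chrB, 5001, 5030) <- dup             # planted second copy
  m_rc <- revcomp(substr(chrB, 1001, 1025))   # minus-strand hit
  m_absent <- "TTTTTTTTTTTTTTTTTTTTCCCCCCCCCCCCCCCCCCCC"
  genome <- c(chrA = chrA, chrB = chrB)
  # exhaustive-scan guard on the unmapped truth
  expect_false(grepl(m_absent, chrA, fixed = TRUE) ||
                 grepl(m_absent, chrB, fixed = TRUE) ||
                 grepl(revcomp(m_absent), chrA, fixed = TRUE) ||
                 grepl(revcomp(m_absent), chrB, fixed = TRUE))

  hits <- map_markers(tibble::tibble(
    id = c("u", "d", "rc", "none"),
    seq = c(m_unique, dup, m_rc, m_absent)), genome, max_mismatch_rate = 0)
  expect_identical(hits$status, c("unique", "multi", "unique", "unmapped"))
  expect_equal(hits$chrom[1], "chrA")
  expect_equal(hits$start[1], 10000)
  expect_equal(hits$end[1], 10040)
  expect_equal(hits$strand[3], "-")
  expect_equal(hits$n_hits[2], 2)
})

test_that("Fisher exact p matches enumeration and the stats oracle", {
  expect_identical(fisher_exact_2x2(matrix(1, 2, 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252)

  set.seed(72)
  pick <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1)
  for (i in 1:40) {
    r1 <- sample(0:30, 1); r2 <- sample(0:30, 1)
    if (r1 + r2 == 0) next
    c1 <- pick(max(0, r1 + r2 - 30), min(30, r1 + r2))
    k <- pick(max(0, c1 - r2), min(r1, c1))
    tab <- matrix(c(k, c1 - k, r1 - k, r2 - c1 + k), 2)
    p_pkg <- fisher_exact_2x2(tab)
    p_ref <- stats::fisher.test(tab)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
    # transposition invariance
    expect_equal(fisher_exact_2x2(t(tab)), p_pkg, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "zero")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("MSY enrichment contrasts hits against bin-count background", {
  lens <- c(chr5 = 1e6, chr1 = 1e6)
  msy <- tibble::tibble(chrom = "chr5", start = 3e5, end = 6e5)
  mk_hits <- function(starts, chroms) tibble::tibble(
    id = sprintf("m%d", seq_along(starts)), length = 40, status = "unique",
    n_hits = 1L, chrom = chroms, start = starts, end = starts + 40,
    strand = "+")
  # all four unique hits inside a 3-bin MSY out of 20 bins
  enr <- msy_enrichment(mk_hits(c(3.1e5, 4e5, 4.5e5, 5.9e5), rep("chr5", 4)),
                        msy, lens)
  expect_equal(enr$bins_in, 3)
  expect_equal(enr$bins_out, 17)
  expect_equal(enr$p_value,
               fisher_exact_2x2(matrix(c(4, 0, 3, 17), 2, byrow = TRUE)))
  expect_lt(enr$p_value, 0.01)

  # hits spread proportionally to length are unremarkable
  null_hits <- mk_hits(c(3.5e5, seq(1e5, 9e5, length.out = 6)),
                       c("chr5", rep("chr1", 6)))
  enr0 <- msy_enrichment(null_hits, msy, lens)
  expect_gt(enr0$p_value, 0.5)
  expect_equal(enr0$p_value, stats::fisher.test(
    matrix(c(enr0$hits_in, enr0$hits_out, enr0$bins_in, enr0$bins_out),
           2, byrow = TRUE))$p.value, tolerance = 1e-10)

  # zero unique hits is a precondition failure
  no_uq <- tibble::tibble(id = "m", length = 40, status = "unmapped",
                          n_hits = 0L, chrom = NA, start = NA, end = NA,
                          strand = NA)
  expect_error(msy_enrichment(no_uq, msy, lens), "unique")
})

test_that("simulated markers land where their truth label says", {
  g <- small_genome(seed = 73)
  mk <- simulate_markers(g, n_msy = 3, n_autosomal = 2, n_unmapped = 2,
                         seed = 74)
  expect_equal(nrow(mk), 7)
  hits <- map_markers(mk, g)
  joined <- dplyr::left_join(mk, hits, by = "id")
  msy_hits <- joined[joined$truth == "msy", ]
  expect_true(all(msy_hits$status == "unique"))
  expect_true(all(msy_hits$chrom == g$msy$chrom &
                    msy_hits$start >= g$msy$start &
                    msy_hits$end <= g$msy$end))
  expect_true(all(joined$status[joined$truth == "unmapped"] == "unmapped"))
  expect_true(all(joined$chrom[joined$truth == "autosomal"] != g$msy$chrom))
})
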