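test_that("genome spec rejects invalid MSY intervals", {
  expect_error(genome_spec(msy_interval = c(2e5, 2e5)), "non-empty")
  expect_error(genome_spec(msy_interval = c(9e5, 1.2e6)), "outside")
  expect_error(genome_spec(msy_interval = c(3e5, 3.5e5), min_msy_len = 1e5),
               "min_msy_len")
  expect_error(genome_spec(n_gametolog_genes = 0), "n_gametolog_genes")
})

test_that("genome simulation is deterministic and truth-consistent", {
  g1 <- small_genome(seed = 5)
  g2 <- small_genome(seed = 5)
  expect_identical(g1$x, g2$x)
  expect_identical(g1$y, g2$y)
  expect_identical(g1$genes, g2$genes)

  # byte-identical FASTA output
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome(g1, d1); write_genome(g2, d2)
  for (f in c("genome_X.fasta", "genome_Y.fasta"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # planted gene records re-scan to the emitted sequences
  for (i in seq_len(nrow(g1$genes))) {
    gn <- g1$genes[i, ]
    expect_identical(substr(g1$x[[gn$chrom]], gn$start + 1, gn$end), gn$x_seq)
    if (gn$type == "gametolog")
      expect_identical(substr(g1$y[[gn$chrom]], gn$start + 1, gn$end), gn$y_seq)
  }

  # Y equals X outside the MSY, differs inside
  msy <- g1$msy
  x5 <- g1$x[["chr5"]]; y5 <- g1$y[["chr5"]]
  expect_identical(substr(x5, 1, msy$start), substr(y5, 1, msy$start))
  expect_identical(substr(x5, msy$end + 1, nchar(x5)),
                   substr(y5, msy$end + 1, nchar(y5)))
  expect_identical(g1$x[["chr1"]], g1$y[["chr1"]])
  expect_false(substr(x5, msy$start + 1, msy$end) ==
                 substr(y5, msy$start + 1, msy$end))
})

test_that("a 14-gene spec yields 14 XY pairs inside the MSY", {
  g <- small_genome(seed = 8, n_gam = 14, chr5 = 6e5, msy = c(1e5, 5e5))
  gam <- g$genes[g$genes$type == "gametolog", ]
  expect_equal(nrow(gam), 14)
  expect_true(all(gam$start >= 1e5 & gam$end <= 5e5))
  expect_true(all(nchar(gam$x_seq) == nchar(gam$y_seq)))
  # every X/Y copy pair is k-mer-distinguishable at k = 25
  for (i in seq_len(nrow(gam))) {
    kx <- build_kmer_index(gam$x_seq[i], 25)
    ky <- build_kmer_index(gam$y_seq[i], 25)
    expect_length(intersect(kx$kmers, ky$kmers), 0)
  }
})

test_that("read simulation conserves coverage and respects haplotype truth", {
  g <- small_genome(seed = 2, chr5 = 2e5, chr1 = 1e5, msy = c(5e4, 1.6e5))
  rl <- 125
  m <- simulate_reads(g, "male", "DNA", depth = 20, read_length = rl, seed = 1)
  f <- simulate_reads(g, "female", "DNA", depth = 20, read_length = rl, seed = 2)
  L <- sum(nchar(g$x))
  expect_equal(nrow(m) * rl, 20 * L, tolerance = 1e-3)
  expect_equal(nrow(f) * rl, 20 * L, tolerance = 1e-3)

  # females carry no Y-derived sequence: every read re-scans to X
  fs <- f[sample.int(nrow(f), 200), ]
  expect_true(all(substring(g$x[fs$src], fs$src_start + 1, fs$src_end) == fs$seq))

  # male depth over the MSY is about half the female depth
  msy <- g$msy
  in_iv <- function(r) !is.na(r$chrom) & r$chrom == msy$chrom &
    r$start >= msy$start & r$end <= msy$end
  ratio <- sum(in_iv(m)) / sum(in_iv(f))
  expect_equal(ratio, 0.5, tolerance = 0.08)

  # same seed is byte-identical
  m2 <- simulate_reads(g, "male", "DNA", depth = 20, read_length = rl, seed = 1)
  expect_identical(m, m2)
})

test_that("mean autosomal male depth sits within 3 sampling SDs of target", {
  g <- small_genome(seed = 6, chr5 = 2e5, chr1 = 2e5, msy = c(5e4, 1.5e5))
  m <- simulate_reads(g, "male", "DNA", depth = 20, read_length = 125,
                      seed = 3, with_seq = FALSE)
  bins <- bin_depth(m, c(chr1 = 2e5), bin_size = 1e5)
  # per-bin depth is a sum of ~depth*bs/rl Poisson-ish read counts times rl/bs
  sd_bin <- sqrt(20 * 125 / 1e5)
  expect_true(all(abs(bins$depth - 20) < 3 * sd_bin))
})

test_that("gametolog clock simulation recovers its expected divergence", {
  # true_age 0 -> identical copies
  s0 <- simulate_gametolog_pair(clock_sim_spec(true_age = 0, seed = 1), 100)
  expect_identical(s0$sequences$seq[1], s0$sequences$seq[2])

  # expected dS = 2 * age * rate; NG86 estimate within 3 binomial SEs
  cl <- clock_sim_spec(true_age = 100, rate = 0.002, seed = 21)
  sim <- simulate_gametolog_pair(cl, 2000)
  expect_equal(sim$truth$expected_ds_xy, 0.4)
  d <- ng86_ds(sim$sequences$seq[1], sim$sequences$seq[2])
  ps_exp <- 0.75 * (1 - exp(-4 * 0.4 / 3))
  se_ps <- sqrt(ps_exp * (1 - ps_exp) / d$S)
  se_ds <- se_ps / (1 - 4 * ps_exp / 3)
  expect_lt(abs(d$dS - 0.4), 3 * se_ds)

  # determinism
  sim2 <- simulate_gametolog_pair(cl, 2000)
  expect_identical(sim$sequences, sim2$sequences)

  # near-saturation warning
  expect_warning(
    simulate_gametolog_pair(clock_sim_spec(true_age = 500, rate = 0.003,
                                           calibration = c(O = 600),
                                           seed = 1), 60),
    "satur")
})

test_that("climate simulation plants its documented cohort and focal truth", {
  spec <- climate_sim_spec(seed = 12)
  sim <- simulate_climate(spec)
  expect_equal(sum(sim$species$system %in% c("TSD", "GSD")), 200)
  expect_equal(sum(sim$species$system == "TSD"), 101)
  expect_equal(sum(sim$species$system == "GSD"), 99)

  # focal truth is exactly 3 sample SDs below the realized TSD mean
  tsd <- sim$species$true_temp_c[sim$species$system == "TSD"]
  focal <- sim$species$true_temp_c[sim$species$system == "focal"]
  expect_equal(focal, mean(tsd) - 3 * sd(tsd))

  # determinism, through the CSV writers
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_climate(sim, d1)
  write_climate(simulate_climate(spec), d2)
  for (f in c("climate_grid.csv", "species.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
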