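test_that("NG86 site counts and worked example match hand enumeration", {
  # TTT: only the third-position change to TTC is synonymous -> 1/3 site
  tab <- msyscan:::ng86_tables()
  expect_equal(tab$sites[["TTT"]], 1 / 3)
  expect_equal(tab$sites[["TTT"]], oracle_syn_sites("TTT"))

  d <- ng86_ds("GGGGGGGGGTTT", "GGAGGGGGGTTT")
  expect_equal(d$Sd, 1)
  expect_equal(d$S, 10 / 3)
  expect_equal(d$ps, 0.3)
  expect_equal(d$dS, -0.75 * log(0.6))
  expect_equal(d$S + d$N, 3 * 4)
})

test_that("ng86_ds is symmetric, non-negative, zero iff identical", {
  set.seed(11)
  for (i in 1:10) {
    a <- random_sense_cds(20)
    b <- paste(msyscan:::evolve_third_positions(
      msyscan:::split_codons(a), 0.2), collapse = "")
    dab <- ng86_ds(a, b)
    dba <- ng86_ds(b, a)
    expect_equal(dab$dS, dba$dS)
    expect_gte(dab$dS, 0)
    expect_equal(dab$S + dab$N, 3 * dab$n_codons_used)
  }
  expect_equal(ng86_ds("ATGAAA", "ATGAAA")$dS, 0)
})

test_that("ng86_ds matches the brute-force oracle on random pairs", {
  set.seed(42)
  for (i in 1:25) {
    a <- random_sense_cds(sample(5:25, 1))
    b <- paste(msyscan:::evolve_third_positions(
      msyscan:::split_codons(a), runif(1, 0, 0.5)), collapse = "")
    o <- oracle_ng86(a, b)
    d <- ng86_ds(a, b)
    expect_equal(d$S, o$S, tolerance = 1e-12)
    expect_equal(d$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(d$dS, o$dS, tolerance = 1e-12)
  }
})

test_that("ng86_ds errors at synonymous saturation", {
  # force ps >= 0.75: a run of 4-fold codons with all third positions changed
  a <- strrep("GGG", 30)
  b <- strrep("GGA", 30)
  expect_error(ng86_ds(a, b), "satur")
})

test_that("codon alignment handles identity, single indel, and toy oracle", {
  aln <- align_codons(c(a = "ATGAAA", b = "ATGAAA"))
  expect_equal(aln$seq, c("ATGAAA", "ATGAAA"))

  # one inserted codon -> one 3-column gap
  aln <- align_codons(c(a = "ATGAAATTTGGG", b = "ATGTTTGGG"))
  expect_equal(nchar(aln$seq[1]), 12)
  expect_equal(lengths(regmatches(aln$seq[2], gregexpr("---", aln$seq[2]))), 1)
  expect_equal(gsub("-", "", aln$seq[2]), "ATGTTTGGG")

  set.seed(5)
  for (i in 1:8) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- random_sense_cds(na); b <- random_sense_cds(nb)
    aln <- align_codons(c(x = a, y = b))
    expect_equal(attr(aln, "score"),
                 oracle_codon_align_score(msyscan:::split_codons(a),
                                          msyscan:::split_codons(b)))
    # alignment is deterministic
    expect_identical(aln$seq, align_codons(c(x = a, y = b))$seq)
  }
})

test_that("two-taxon dS tree splits the pairwise distance", {
  set.seed(7)
  a <- random_sense_cds(60)
  b <- paste(msyscan:::evolve_third_positions(
    msyscan:::split_codons(a), 0.2), collapse = "")
  dt <- concatenate_and_tree(c(X = a, Y = b))
  expect_equal(sum(dt$tree$edge.length), dt$ds["X", "Y"])
})

test_that("additive distance matrices are recovered exactly; negatives clamp to zero", {
  tree <- ape::read.tree(text = "((A:0.10,B:0.20):0.05,(C:0.15,D:0.25):0.05);")
  dm <- stats::cophenetic(tree)
  fit <- phangorn::nnls.tree(stats::as.dist(dm), ape::unroot(tree),
                             method = "unrooted")
  expect_equal(stats::cophenetic(fit)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-8)

  # distances violating the triangle structure force a negative LS branch;
  # the non-negative fit clamps it at zero
  bad <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.2, 0.5, 0.2, 0),
                3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  topo <- ape::read.tree(text = "(A,B,C);")
  fit2 <- phangorn::nnls.tree(stats::as.dist(bad), topo, method = "unrooted")
  expect_true(all(fit2$edge.length >= 0))
  expect_true(any(abs(fit2$edge.length) < 1e-10))
})

test_that("calibration arithmetic: rate from dated node, age from dS(X,Y)", {
  # per-lineage path X -> calibration node is 0.4 (pairwise X-OUT = 0.8)
  # over 200 Myr: rate 0.002; pairwise dS(X,Y) = 0.4 -> age 0.2/0.002 = 100
  ds <- matrix(c(0, 0.4, 0.8,
                 0.4, 0, 0.8,
                 0.8, 0.8, 0), 3,
               dimnames = list(c("X", "Y", "OUT"), c("X", "Y", "OUT")))
  age <- calibrate_and_date(ds, c(OUT = 200))
  expect_equal(age$rate, 0.002)
  expect_equal(age$age, 100)

  ds0 <- ds; ds0["X", "Y"] <- ds0["Y", "X"] <- 0
  expect_equal(calibrate_and_date(ds0, c(OUT = 200))$age, 0)

  # invariance under rescaling all dS by a constant
  expect_equal(calibrate_and_date(ds * 3.7, c(OUT = 200))$age, 100)
})

test_that("bootstrap CI collapses to [0, 0] for identical X and Y", {
  sim <- simulate_gametolog_pair(clock_sim_spec(true_age = 0, seed = 2), 100)
  dt <- concatenate_and_tree(sim$sequences, sim$topology)
  ba <- bootstrap_age(dt, clock_sim_spec(true_age = 0, seed = 2)$calibration,
                      n = 50, seed = 9)
  expect_equal(ba$age, 0)
  expect_equal(ba$lower, 0)
  expect_equal(ba$upper, 0)
})

test_that("bootstrap CI narrows with concatenation length", {
  width_at <- function(n_codons, seed) {
    cl <- clock_sim_spec(true_age = 100, rate = 0.0015, seed = seed)
    sim <- simulate_gametolog_pair(cl, n_codons)
    dt <- concatenate_and_tree(sim$sequences, sim$topology)
    ba <- bootstrap_age(dt, cl$calibration, n = 100, seed = seed)
    ba$upper - ba$lower
  }
  w_short <- mean(vapply(1:3, function(s) width_at(100, s), numeric(1)))
  w_long <- mean(vapply(1:3, function(s) width_at(1000, s), numeric(1)))
  expect_lt(w_long, w_short)
})

test_that("bootstrap is reproducible under a fixed seed", {
  cl <- clock_sim_spec(true_age = 80, seed = 4)
  sim <- simulate_gametolog_pair(cl, 300)
  dt <- concatenate_and_tree(sim$sequences, sim$topology)
  b1 <- bootstrap_age(dt, cl$calibration, n = 40, seed = 17)
  b2 <- bootstrap_age(dt, cl$calibration, n = 40, seed = 17)
  expect_identical(b1$replicates, b2$replicates)
})
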