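test_that("gametolog pairing accepts diverged pairs and rejects alleles/strangers", {
  # planted pair at dS ~ 0.3 (the 95-97%-identity regime generalized)
  cl <- clock_sim_spec(true_age = 100, rate = 0.0015, seed = 61)
  sim <- simulate_gametolog_pair(cl, 300)
  x <- sim$sequences$seq[sim$sequences$id == "X"]
  y <- sim$sequences$seq[sim$sequences$id == "Y"]
  females <- tibble::tibble(id = c("gamX", "other1", "other2"),
                            seq = c(x, random_sense_cds(300), random_sense_cds(280)))
  hit <- find_x_gametolog(c(Y = y), females)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$x_id, "gamX")
  expect_gte(hit$identity, 0.90)
  expect_lt(hit$identity, 0.99)

  # reverse-complemented candidate still pairs
  hit_rc <- find_x_gametolog(c(Y = revcomp(y)), females)
  expect_equal(hit_rc$x_id, "gamX")

  # identical sequence (an allele, not a gametolog) is excluded
  allele <- find_x_gametolog(c(Y = x), females)
  expect_equal(nrow(allele), 0)
  expect_true(isTRUE(attr(allele, "allelic")))

  # best hit far below the window -> no pair
  stranger <- find_x_gametolog(c(Y = random_sense_cds(300)), females)
  expect_equal(nrow(stranger), 0)
})

test_that("pairing is symmetric between the X and Y directions", {
  set.seed(62)
  cl <- clock_sim_spec(true_age = 116, seed = 63)
  pairs <- lapply(1:4, function(i) {
    s <- simulate_gametolog_pair(clock_sim_spec(true_age = 116, seed = 63 + i), 200)
    list(x = s$sequences$seq[1], y = s$sequences$seq[2])
  })
  xs <- tibble::tibble(id = sprintf("X%d", 1:4),
                       seq = vapply(pairs, `[[`, character(1), "x"))
  ys <- tibble::tibble(id = sprintf("Y%d", 1:4),
                       seq = vapply(pairs, `[[`, character(1), "y"))
  fwd <- pair_gametologs(ys, xs)
  rev <- pair_gametologs(xs, ys)
  expect_equal(nrow(fwd), 4)
  expect_identical(sub("X", "", fwd$x_id)[order(fwd$y_id)],
                   sub("Y", "", fwd$y_id)[order(fwd$y_id)])
  expect_identical(sub("Y", "", rev$x_id)[order(rev$y_id)],
                   sub("X", "", rev$y_id)[order(rev$y_id)])
})

test_that("copy-number check separates XY pairs from autosomal paralogs", {
  g <- small_genome(seed = 44, chr5 = 2e5, chr1 = 1.5e5, msy = c(4e4, 1.5e5),
                    n_gam = 2, n_auto = 2)
  m <- simulate_reads(g, "male", "DNA", depth = 20, read_length = 125, seed = 5)
  f <- simulate_reads(g, "female", "DNA", depth = 20, read_length = 125, seed = 6)
  gam <- g$genes[g$genes$type == "gametolog", ][1, ]
  cc <- check_copy_number(gam$x_seq, gam$y_seq, m, f)
  expect_equal(cc$verdict, "consistent")
  expect_equal(cc$female_x_depth / cc$male_x_depth, 2, tolerance = 0.35)
  expect_equal(cc$female_y_depth, 0)

  # an autosomal gene behaves 1:1 in both sexes on both "copies"
  auto <- g$genes[g$genes$type == "autosomal", ][1, ]
  cc2 <- check_copy_number(auto$x_seq, auto$x_seq, m, f)
  expect_equal(cc2$verdict, "inconsistent")

  # zero-depth input is indeterminate, not an error
  none <- tibble::tibble(id = character(0), seq = character(0))
  cc3 <- check_copy_number(gam$x_seq, gam$y_seq, none, none)
  expect_equal(cc3$verdict, "indeterminate")
})

test_that("synteny report summarises modal chromosome and MSY containment", {
  ann <- tibble::tibble(id = sprintf("g%d_X", 1:6),
                        chrom = c(rep("chr5", 5), "chr3"),
                        start = c(seq(1e5, 5e5, 1e5), 2e5),
                        end = c(seq(1e5, 5e5, 1e5), 2e5) + 900)
  pairs <- tibble::tibble(y_id = sprintf("c%d", 1:6),
                          x_id = sprintf("g%d_X", 1:6))
  msy <- tibble::tibble(chrom = "chr5", start = 0, end = 6e5)
  rep1 <- synteny_check(pairs, ann, msy)
  expect_equal(rep1$modal_chrom, "chr5")
  expect_equal(rep1$modal_fraction, 5 / 6)
  expect_equal(rep1$n_inside_msy, 5)
  expect_false(rep1$all_inside_msy)

  rep2 <- synteny_check(pairs[1:5, ], ann, msy)
  expect_equal(rep2$modal_fraction, 1)
  expect_true(rep2$all_inside_msy)

  expect_equal(nrow(synteny_check(pairs[0, ], ann)), 0)
})
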