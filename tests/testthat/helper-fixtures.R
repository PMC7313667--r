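# Shared fixture builders. Everything is generated in code at test time.

small_genome <- function(seed = 3, n_gam = 5, n_auto = 4,
                         chr5 = 4e5, chr1 = 2e5,
                         msy = c(1e5, 2.5e5), true_age = 116) {
  genome_spec(
    chrom_lengths = c(chr5 = chr5, chr1 = chr1),
    msy_chrom = "chr5", msy_interval = msy,
    n_gametolog_genes = n_gam, n_autosomal_genes = n_auto,
    clock = clock_sim_spec(true_age = true_age, seed = seed + 100),
    seed = seed) |>
    simulate_genome()
}

# deterministic error-free reads tiling a sequence end to end
tiled_reads <- function(seq, read_len = 100, step = 20, id_prefix = "t") {
  L <- nchar(seq)
  starts <- unique(c(seq(1, L - read_len + 1, by = step), L - read_len + 1))
  tibble::tibble(id = sprintf("%s_%03d", id_prefix, seq_along(starts)),
                 seq = substring(seq, starts, starts + read_len - 1))
}

# reads placed on a sequence set at an exact mean depth (full tiling of
# depth * len / read_len reads, evenly spaced, fully contained)
exact_depth_reads <- function(seq, depth, read_len = 100, id_prefix = "d") {
  L <- nchar(seq)
  n <- round(depth * L / read_len)
  starts <- floor(seq(0, L - read_len, length.out = n)) + 1
  tibble::tibble(id = sprintf("%s_%04d", id_prefix, seq_len(n)),
                 seq = substring(seq, starts, starts + read_len - 1))
}

expect_setequal_canon <- function(a, b) {
  expect_setequal(canon_seq(a), canon_seq(b))
}
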