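#' Simulate sexed sequencing reads from a synthetic genome
#'
#' Uniform-coverage, error-free (by default) single-end reads. Females are
#' sampled from two X haplotypes; males from one X and one Y, so expected
#' male depth over the MSY on the X coordinate system is half the female
#' depth. `depth` is the total diploid fold coverage (each haplotype
#' contributes `depth/2`). DNA reads carry their placement on the reference
#' (X) coordinate system: Y-derived reads inside the MSY are emitted as
#' unplaced (`chrom = NA`), since the region is non-homologous to the
#' reference. RNA reads are sampled from the sex's expressed transcripts
#' (females: two alleles of each X/autosomal transcript; males: one X and
#' one Y allele plus two autosomal alleles).
#'
#' @param genome an `msy_genome` from [simulate_genome()].
#' @param sex `"male"` or `"female"`.
#' @param kind `"DNA"` or `"RNA"`.
#' @param depth total fold coverage (> 0).
#' @param read_length read length in bp; must not exceed the shortest
#'   source sequence.
#' @param error_rate per-base substitution error probability (default 0;
#'   the downstream filters assume high-identity matching).
#' @param with_seq if `FALSE`, skip sequence extraction and return
#'   placements only (fast path for coverage work).
#' @param seed integer seed.
#' @return tibble with columns `id`, `sex`, `kind`, `hap`, `src`,
#'   `src_start`, `src_end`, `chrom`, `start`, `end` (0-based half-open
#'   reference placement, `NA` when unplaced), and `seq` (unless
#'   `with_seq = FALSE`).
#' @export
simulate_reads <- function(genome, sex = c("male", "female"),
                           kind = c("DNA", "RNA"), depth = 20,
                           read_length = 100, error_rate = 0,
                           with_seq = TRUE, seed = 1L) {
  stopifnot(inherits(genome, "msy_genome"), depth > 0, read_length > 0,
            error_rate >= 0, error_rate < 1)
  sex <- match.arg(sex)
  kind <- match.arg(kind)
  set.seed(as.integer(seed))

  if (kind == "DNA") {
    haps <- if (sex == "female") list(X1 = genome$x, X2 = genome$x)
            else list(X = genome$x, Y = genome$y)
    src_is_y <- c(FALSE, FALSE)
    if (sex == "male") src_is_y <- c(FALSE, TRUE)
  } else {
    tx <- if (sex == "female") {
      ft <- female_transcriptome(genome)
      setNames(ft$seq, ft$id)
    } else {
      mt <- male_transcripts(genome)
      # autosomal transcripts are diploid: duplicate them as a second allele
      extra <- mt[mt$source == "autosomal", ]
      setNames(c(mt$seq, extra$seq), c(mt$id, paste0(extra$id, "_b")))
    }
    haps <- if (sex == "female") list(T1 = tx, T2 = tx) else list(T1 = tx)
    src_is_y <- rep(FALSE, length(haps))
  }

  out <- list()
  for (h in seq_along(haps)) {
    hap_name <- names(haps)[h]
    seqs <- haps[[h]]
    lens <- nchar(seqs)
    if (read_length > min(lens))
      abort("read_length exceeds the shortest source sequence")
    per_hap_depth <- if (kind == "RNA" && sex == "male") depth / 2 else
      depth / length(haps)
    for (s in seq_along(seqs)) {
      L <- lens[s]
      n <- round(per_hap_depth * L / read_length)
      if (n == 0) next
      starts <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
      y_src <- kind == "DNA" && src_is_y[h]
      out[[length(out) + 1]] <- tibble(
        sex = sex, kind = kind, hap = hap_name,
        src = names(seqs)[s], src_start = starts,
        src_end = starts + read_length,
        is_y = y_src,
        seqtext = if (with_seq)
          substring(seqs[[s]], starts + 1L, starts + read_length)
        else NA_character_)
    }
  }
  reads <- bind_rows(out)
  reads$id <- sprintf("%s_%s_%s_%07d", tolower(sex), tolower(kind),
                      reads$hap, seq_len(nrow(reads)))

  # reference (X coordinate system) placement for DNA reads
  if (kind == "DNA") {
    reads$chrom <- reads$src
    reads$start <- reads$src_start
    reads$end <- reads$src_end
    if (!is.null(genome$msy)) {
      in_msy <- reads$is_y & reads$src == genome$msy$chrom &
        reads$src_end > genome$msy$start & reads$src_start < genome$msy$end
      reads$chrom[in_msy] <- NA_character_
      reads$start[in_msy] <- NA_real_
      reads$end[in_msy] <- NA_real_
    }
  } else {
    reads$chrom <- NA_character_
    reads$start <- NA_real_
    reads$end <- NA_real_
  }

  if (with_seq && error_rate > 0) {
    n_err <- stats::rbinom(nrow(reads), read_length, error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(read_length, n_err[i])
      for (p in pos) {
        cur <- substr(reads$seqtext[i], p, p)
        substr(reads$seqtext[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1)
      }
    }
  }

  res <- reads[, c("id", "sex", "kind", "hap", "src", "src_start", "src_end",
                   "chrom", "start", "end")]
  if (with_seq) res$seq <- reads$seqtext
  res
}
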