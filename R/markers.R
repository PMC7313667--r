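#' Simulate short sex-linked marker sequences
#'
#' Samples marker-length substrings (default 17-70 bp, the size range of
#' published Y-linked skink markers) from the reference genome: some inside
#' the planted MSY, some from outside it, plus random sequences verified
#' absent from the genome (unmapped truth).
#'
#' @param genome an `msy_genome` (needs a planted MSY for `n_msy > 0`).
#' @param n_msy,n_autosomal,n_unmapped marker counts per truth class.
#' @param length_range marker length range in bp.
#' @param seed integer seed.
#' @return tibble with `id`, `seq`, `truth`.
#' @export
simulate_markers <- function(genome, n_msy = 4, n_autosomal = 1,
                             n_unmapped = 4, length_range = c(17, 70),
                             seed = 1L) {
  stopifnot(inherits(genome, "msy_genome"))
  if (n_msy > 0 && is.null(genome$msy))
    abort("genome has no MSY to sample markers from")
  set.seed(as.integer(seed))
  lens <- function(n) sample(seq(length_range[1], length_range[2]), n,
                             replace = TRUE)
  out <- list()
  if (n_msy > 0) {
    L <- lens(n_msy)
    starts <- sample.int(diff(unlist(genome$msy[, c("start", "end")])) -
                           max(L), n_msy) + genome$msy$start
    out$msy <- tibble(
      id = sprintf("marker_msy_%02d", seq_len(n_msy)),
      seq = substring(genome$x[[genome$msy$chrom]], starts + 1, starts + L),
      truth = "msy")
  }
  if (n_autosomal > 0) {
    chs <- setdiff(names(genome$x),
                   if (is.null(genome$msy)) character(0) else genome$msy$chrom)
    if (length(chs) == 0) abort("no non-MSY chromosome for autosomal markers")
    ch <- sample(chs, n_autosomal, replace = TRUE)
    L <- lens(n_autosomal)
    starts <- vapply(seq_len(n_autosomal), function(i)
      sample.int(nchar(genome$x[[ch[i]]]) - L[i], 1), integer(1))
    out$auto <- tibble(
      id = sprintf("marker_auto_%02d", seq_len(n_autosomal)),
      seq = substring(genome$x[ch], starts + 1, starts + L),
      truth = "autosomal")
  }
  if (n_unmapped > 0) {
    subj <- Biostrings::DNAStringSet(genome$x)
    seqs <- character(n_unmapped)
    L <- lens(n_unmapped)
    for (i in seq_len(n_unmapped)) {
      repeat {
        cand <- random_dna(L[i], 0.5)
        n_hit <- sum(Biostrings::vcountPattern(cand, subj)) +
          sum(Biostrings::vcountPattern(revcomp(cand), subj))
        if (n_hit == 0) { seqs[i] <- cand; break }
      }
    }
    out$unmapped <- tibble(id = sprintf("marker_rand_%02d", seq_len(n_unmapped)),
                           seq = seqs, truth = "unmapped")
  }
  bind_rows(out)
}

#' Map marker sequences onto a genome
#'
#' Near-exact search on both strands: every occurrence at identity at least
#' `1 - max_mismatch_rate` (no indels) is collected; a marker is `unique`
#' with exactly one location, `multi` with several, `unmapped` with none.
#'
#' @param markers marker sequences (tibble `id`/`seq`, named character, or
#'   FASTA path).
#' @param genome reference sequences (named character vector,
#'   `DNAStringSet`, FASTA path, or an `msy_genome`, whose X haplotype is
#'   searched).
#' @param max_mismatch_rate maximum mismatch fraction (default 0.05).
#' @return tibble with `id`, `length`, `status`, `n_hits`, and (for unique
#'   hits) `chrom`, `start`, `end` (0-based half-open), `strand`.
#' @export
map_markers <- function(markers, genome, max_mismatch_rate = 0.05) {
  mk <- as_seq_tbl(markers, "markers")
  if (nrow(mk) == 0) abort("no markers to map")
  if (inherits(genome, "msy_genome")) genome <- genome$x
  gn <- as_seq_tbl(genome, "genome")
  subj <- Biostrings::DNAStringSet(setNames(gn$seq, gn$id))
  purrr::map_dfr(seq_len(nrow(mk)), function(i) {
    m <- mk$seq[i]
    mm <- floor(max_mismatch_rate * nchar(m))
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") m else revcomp(m)
      mt <- Biostrings::vmatchPattern(pat, subj, max.mismatch = mm)
      for (s in seq_along(mt)) {
        r <- mt[[s]]
        if (length(r) == 0) next
        hits[[length(hits) + 1]] <- tibble(
          chrom = gn$id[s], start = Biostrings::start(r) - 1,
          end = Biostrings::end(r), strand = strand)
      }
    }
    hits <- bind_rows(hits)
    if (nrow(hits) > 0)
      hits <- dplyr::distinct(hits, .data$chrom, .data$start, .data$end,
                              .keep_all = TRUE)
    n <- nrow(hits)
    status <- if (n == 0) "unmapped" else if (n == 1) "unique" else "multi"
    tibble(id = mk$id[i], length = nchar(m), status = status, n_hits = n,
           chrom = if (n == 1) hits$chrom else NA_character_,
           start = if (n == 1) hits$start else NA_real_,
           end = if (n == 1) hits$end else NA_real_,
           strand = if (n == 1) hits$strand else NA_character_)
  })
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact enumeration: with margins fixed, the two-sided p-value is the sum
#' of hypergeometric probabilities of all tables no more probable than the
#' observed one (a small relative tolerance guards floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative integers with at least one
#'   positive margin.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))  # 1
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    abort("tab must be a 2x2 matrix of non-negative integers")
  if (sum(tab) == 0) abort("all-zero table")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  k_obs <- tab[1, 1]
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(k_obs, c1, n - c1, r1)
  keep <- probs <= p_obs * (1 + 1e-7)
  if (all(keep)) return(1)
  min(sum(probs[keep]), 1)
}

#' Enrichment of unique marker hits inside the MSY call
#'
#' Builds the 2x2 table contrasting observed unique hits (inside vs outside
#' the MSY) against a length-proportional background in bin units (bins
#' overlapping the MSY vs all other bins) and attaches the two-sided Fisher
#' exact p-value. The bin-count background is an explicit modelling choice:
#' it asks whether hits concentrate in the MSY beyond what its share of the
#' genome predicts.
#'
#' @param hits output of [map_markers()].
#' @param msy one-row tibble with `chrom`, `start`, `end` (an MSY call or
#'   truth interval).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param bin_size background unit size in bp.
#' @return one-row tibble of class `msy_enrichment`: `hits_in`, `hits_out`,
#'   `bins_in`, `bins_out`, `p_value`.
#' @export
msy_enrichment <- function(hits, msy, chrom_lengths, bin_size = 1e5) {
  stopifnot(is.data.frame(hits), nrow(msy) == 1,
            !is.null(names(chrom_lengths)))
  uq <- dplyr::filter(hits, .data$status == "unique")
  if (nrow(uq) == 0) abort("no unique marker hits; enrichment undefined")
  inside <- uq$chrom == msy$chrom & uq$start >= msy$start & uq$end <= msy$end
  total_bins <- sum(ceiling(chrom_lengths / bin_size))
  # count of bins overlapping [start, end)
  bins_in <- floor((msy$end - 1) / bin_size) - floor(msy$start / bin_size) + 1
  tab <- matrix(c(sum(inside), sum(!inside),
                  bins_in, total_bins - bins_in), 2, byrow = TRUE)
  out <- tibble(hits_in = sum(inside), hits_out = sum(!inside),
                bins_in = as.integer(bins_in),
                bins_out = as.integer(total_bins - bins_in),
                p_value = fisher_exact_2x2(tab))
  class(out) <- c("msy_enrichment", class(out))
  out
}

#' @export
tidy.msy_enrichment <- function(x, ...) as_tibble(unclass(x))
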