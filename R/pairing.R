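#' Find the X gametolog of a candidate Y transcript
#'
#' Global (end-to-end) alignment of the Y transcript against every female
#' transcript, both orientations, with affine gaps (match 1, mismatch -1,
#' gap open 4, gap extend 1). The best full-length percent identity decides:
#' a pair is reported iff identity falls inside `window` (default
#' `[90, 99)` percent, bracketing the 95-97 percent typical of gametologs
#' that stopped recombining tens of Myr ago while excluding identical
#' alleles). Ties break by longest alignment, then lexicographic id.
#'
#' @param y_transcript a single sequence (character) or one-row tibble with
#'   `id`/`seq`.
#' @param female_transcriptome female transcripts (tibble `id`/`seq`, named
#'   character, or FASTA path).
#' @param window identity window `[low, high)` as fractions.
#' @return one-row tibble (`y_id`, `x_id`, `identity`, `aln_length`,
#'   `orientation`) or a zero-row tibble when nothing qualifies; a 100
#'   percent identity best hit is reported as zero-row with attribute
#'   `allelic = TRUE`.
#' @export
find_x_gametolog <- function(y_transcript, female_transcriptome,
                             window = c(0.90, 0.99)) {
  ytb <- as_seq_tbl(y_transcript, "y_transcript")
  stopifnot(nrow(ytb) == 1, length(window) == 2, window[1] < window[2])
  ftb <- as_seq_tbl(female_transcriptome, "female_transcriptome")
  empty <- tibble(y_id = character(0), x_id = character(0),
                  identity = numeric(0), aln_length = integer(0),
                  orientation = character(0))
  if (nrow(ftb) == 0) return(empty)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  score_all <- function(yseq, ori) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(ftb$seq),
      subject = Biostrings::DNAString(yseq),
      type = "global", substitutionMatrix = submat,
      gapOpening = 4, gapExtension = 1)
    tibble(x_id = ftb$id,
           identity = Biostrings::pid(pa, type = "PID1") / 100,
           aln_length = Biostrings::nchar(pa),
           orientation = ori)
  }
  hits <- bind_rows(score_all(ytb$seq, "+"),
                    score_all(revcomp(ytb$seq), "-"))
  hits <- hits |>
    group_by(.data$x_id) |>
    arrange(desc(.data$identity), desc(.data$aln_length)) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(desc(.data$identity), desc(.data$aln_length), .data$x_id)
  best <- hits[1, ]
  if (best$identity >= 1 - 1e-9) {
    out <- empty
    attr(out, "allelic") <- TRUE
    return(out)
  }
  if (best$identity < window[1] || best$identity >= window[2]) return(empty)
  tibble(y_id = ytb$id, x_id = best$x_id, identity = best$identity,
         aln_length = best$aln_length, orientation = best$orientation)
}

#' Pair every retained Y transcript with its X gametolog
#'
#' @param y_transcripts retained candidates (tibble `id`/`seq`).
#' @param female_transcriptome female transcripts.
#' @inheritParams find_x_gametolog
#' @return tibble with one row per paired transcript (`y_id`, `x_id`,
#'   `identity`, `aln_length`, `orientation`).
#' @export
pair_gametologs <- function(y_transcripts, female_transcriptome,
                            window = c(0.90, 0.99)) {
  ytb <- as_seq_tbl(y_transcripts, "y_transcripts")
  purrr::map_dfr(seq_len(nrow(ytb)), function(i)
    find_x_gametolog(ytb[i, ], female_transcriptome, window = window))
}

#' Copy-number consistency of a gametolog pair
#'
#' An XY pair is copy-number consistent when the X sequence shows a
#' female:male genomic depth ratio near 2 (two X copies in females, one in
#' males) and the Y sequence is covered by male reads only. Zero overall
#' depth yields an indeterminate verdict rather than an error.
#'
#' @param x_seq,y_seq the X and Y coding sequences (character).
#' @param male_dna,female_dna genomic read sets (tibbles with `seq`).
#' @param ratio_band acceptance band for the female:male X-depth ratio.
#' @param female_y_max maximum tolerated female depth on the Y sequence.
#' @param identity,k matching parameters (see
#'   [classify_by_genomic_coverage()]).
#' @return one-row tibble with the four depths, `x_ratio`, and `verdict`
#'   (consistent / inconsistent / indeterminate).
#' @export
check_copy_number <- function(x_seq, y_seq, male_dna, female_dna,
                              ratio_band = c(1.4, 2.6), female_y_max = 0,
                              identity = 0.99, k = 25) {
  targets <- tibble(id = c("X", "Y"), seq = c(x_seq, y_seq))
  md <- match_read_depth(targets, male_dna, identity = identity, k = k)
  fd <- match_read_depth(targets, female_dna, identity = identity, k = k)
  mx <- md$depth[1]; my <- md$depth[2]
  fx <- fd$depth[1]; fy <- fd$depth[2]
  if (mx + my + fx + fy == 0) {
    verdict <- "indeterminate"
    x_ratio <- NA_real_
  } else {
    x_ratio <- if (mx > 0) fx / mx else Inf
    x_ok <- is.finite(x_ratio) && x_ratio >= ratio_band[1] &&
      x_ratio <= ratio_band[2]
    y_ok <- my > 0 && fy <= female_y_max
    verdict <- if (x_ok && y_ok) "consistent" else "inconsistent"
  }
  tibble(male_x_depth = mx, female_x_depth = fx, male_y_depth = my,
         female_y_depth = fy, x_ratio = x_ratio, verdict = verdict)
}

#' Synteny report for a set of gametolog pairs
#'
#' Locates each pair's X gametolog on the reference annotation and reports
#' the fraction of pairs on the modal chromosome and, when an MSY call is
#' supplied, the fraction falling inside it.
#'
#' @param pairs tibble from [pair_gametologs()] (needs `x_id`).
#' @param annotation tibble mapping transcript ids to reference coordinates:
#'   columns `id`, `chrom`, `start`, `end`.
#' @param msy_call optional one-row tibble with `chrom`, `start`, `end`.
#' @return one-row tibble (`n_pairs`, `modal_chrom`, `n_on_modal`,
#'   `modal_fraction`, and with an MSY call `n_inside_msy`,
#'   `frac_inside_msy`, `all_inside_msy`); zero-row tibble for an empty
#'   pair list.
#' @export
synteny_check <- function(pairs, annotation, msy_call = NULL) {
  stopifnot(is.data.frame(annotation),
            all(c("id", "chrom", "start", "end") %in% names(annotation)))
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(tibble(n_pairs = integer(0), modal_chrom = character(0),
                  n_on_modal = integer(0), modal_fraction = numeric(0)))
  }
  loc <- dplyr::left_join(pairs, annotation, by = c(x_id = "id"))
  if (anyNA(loc$chrom))
    warn(sprintf("%d pair(s) missing from the annotation", sum(is.na(loc$chrom))))
  tab <- sort(table(loc$chrom), decreasing = TRUE)
  modal <- names(tab)[1]
  out <- tibble(n_pairs = nrow(loc), modal_chrom = modal,
                n_on_modal = as.integer(tab[1]),
                modal_fraction = as.integer(tab[1]) / nrow(loc))
  if (!is.null(msy_call) && nrow(msy_call) == 1) {
    inside <- !is.na(loc$chrom) & loc$chrom == msy_call$chrom &
      loc$start >= msy_call$start & loc$end <= msy_call$end
    out$n_inside_msy <- sum(inside)
    out$frac_inside_msy <- sum(inside) / nrow(loc)
    out$all_inside_msy <- all(inside)
  }
  out
}
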