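#' Canonical k-mer index of a sequence set
#'
#' Stores the canonical form (lexicographic minimum of a k-mer and its
#' reverse complement) of every k-mer in the input, making downstream
#' matching strand-agnostic. K-mers containing non-ACGT characters are
#' skipped and counted.
#'
#' @param sequences sequences (tibble with `id`/`seq`, named character
#'   vector, `DNAStringSet`, or FASTA path).
#' @param k k-mer size (>= 3; odd recommended so no k-mer is its own
#'   reverse complement). Default 25, the classic subtraction k.
#' @return object of class `msy_kmer_index`: list with `k`, `kmers`
#'   (sorted unique canonical k-mers), `n_skipped`.
#' @export
build_kmer_index <- function(sequences, k = 25) {
  stopifnot(k >= 3)
  if (k %% 2 == 0)
    inform("even k: palindromic k-mers are their own reverse complement; odd k recommended")
  tb <- as_seq_tbl(sequences, "sequences")
  kmers <- unlist(lapply(toupper(tb$seq), seq_kmers, k = k), use.names = FALSE)
  n_skipped <- 0L
  if (length(kmers) > 0) {
    ok <- grepl("^[ACGT]+$", kmers)
    n_skipped <- sum(!ok)
    if (n_skipped > 0)
      inform(sprintf("skipped %d k-mers containing non-ACGT characters", n_skipped))
    kmers <- kmers[ok]
  }
  structure(list(k = as.integer(k),
                 kmers = sort(unique(canonicalize(kmers))),
                 n_skipped = n_skipped),
            class = "msy_kmer_index")
}

#' @export
print.msy_kmer_index <- function(x, ...) {
  cat(sprintf("canonical %d-mer index: %d k-mers\n", x$k, length(x$kmers)))
  invisible(x)
}

# canonical k-mers of many same-purpose sequences, chunked to bound memory;
# returns a list parallel to `seqs` (character(0) for too-short sequences)
per_seq_canonical_kmers <- function(seqs, k, chunk = 2000L) {
  n <- length(seqs)
  out <- vector("list", n)
  lens <- nchar(seqs)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    nk <- pmax(lens[idx] - k + 1L, 0L)
    if (sum(nk) == 0) { out[idx] <- list(character(0)); next }
    text <- rep(seqs[idx], times = nk)
    first <- unlist(lapply(nk, seq_len), use.names = FALSE)
    km <- canonicalize(substring(text, first, first + k - 1L))
    out[idx] <- split(km, rep(idx, times = nk))[as.character(idx)]
    out[idx][nk == 0] <- list(character(0))
  }
  out
}

#' Subtract male RNA reads matching the female transcriptome
#'
#' A read survives iff it shares zero canonical k-mers with the female
#' index. Because any full-length exact match of a read (either strand)
#' inside a female transcript implies shared k-mers whenever the read is at
#' least k long, the strict no-shared-k-mer rule subsumes the
#' exact-match-removal rule; reads shorter than k are discarded and counted.
#' Surviving reads keep their input order.
#'
#' @param reads read set: tibble with `id`/`seq` (as from
#'   [simulate_reads()]) or a FASTQ path.
#' @param index an `msy_kmer_index` built from the female transcriptome.
#' @return tibble of retained reads (same columns as input), with
#'   attributes `n_input`, `n_short`, `n_removed`.
#' @export
subtract_reads <- function(reads, index) {
  stopifnot(inherits(index, "msy_kmer_index"))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_reads_fastq(reads)
  stopifnot(is.data.frame(reads), "seq" %in% names(reads))
  n_input <- nrow(reads)
  k <- index$k
  short <- nchar(reads$seq) < k
  if (any(short))
    inform(sprintf("discarded %d reads shorter than k = %d", sum(short), k))
  kept <- reads[!short, , drop = FALSE]
  if (nrow(kept) == 0 || length(index$kmers) == 0) {
    out <- kept
  } else {
    km <- per_seq_canonical_kmers(toupper(kept$seq), k)
    hit <- vapply(km, function(x) any(data.table::`%chin%`(x, index$kmers)),
                  logical(1))
    out <- kept[!hit, , drop = FALSE]
  }
  attr(out, "n_input") <- n_input
  attr(out, "n_short") <- sum(short)
  attr(out, "n_removed") <- n_input - sum(short) - nrow(out)
  out
}

#' Unitig assembly of retained reads
#'
#' Maximal non-branching paths in the de Bruijn graph of read k-mers (both
#' strands), deduplicated by canonical orientation. This is a deliberately
#' simple assembler for high-identity subtraction output, not a
#' general-purpose transcriptome assembler: it assumes error-free reads and
#' emits each unitig in its lexicographically smaller orientation, so output
#' is invariant to read order and strand.
#'
#' @param reads retained reads (tibble with `seq`, or FASTQ path).
#' @param k de Bruijn k-mer size.
#' @param min_len minimum contig length in bp (shorter unitigs dropped).
#' @return tibble with `id`, `seq`, `length`, sorted by decreasing length.
#' @export
assemble_candidates <- function(reads, k = 25, min_len = 200) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_reads_fastq(reads)
  stopifnot(is.data.frame(reads), "seq" %in% names(reads))
  empty <- tibble(id = character(0), seq = character(0), length = integer(0))
  if (nrow(reads) == 0) return(empty)
  seqs <- toupper(reads$seq)
  seqs <- seqs[nchar(seqs) >= k & grepl("^[ACGT]+$", seqs)]
  if (length(seqs) == 0) return(empty)
  fwd <- unlist(lapply(seqs, seq_kmers, k = k), use.names = FALSE)
  kms <- unique(c(fwd, revcomp(unique(fwd))))
  kms <- sort(kms)
  set <- new.env(hash = TRUE, size = 2L * length(kms), parent = emptyenv())
  for (km in kms) assign(km, TRUE, envir = set)
  in_set <- function(x) vapply(x, exists, logical(1), envir = set,
                               inherits = FALSE, USE.NAMES = FALSE)
  succs <- function(km) {
    cand <- paste0(substr(km, 2, k), DNA_BASES)
    cand[in_set(cand)]
  }
  preds <- function(km) {
    cand <- paste0(DNA_BASES, substr(km, 1, k - 1))
    cand[in_set(cand)]
  }
  visited <- new.env(hash = TRUE, size = 2L * length(kms), parent = emptyenv())
  seen <- function(km) exists(km, envir = visited, inherits = FALSE)
  walk <- function(start) {
    path <- start
    assign(start, TRUE, envir = visited)
    cur <- start
    repeat {
      s <- succs(cur)
      if (length(s) != 1) break
      nxt <- s
      if (length(preds(nxt)) != 1) break
      if (seen(nxt)) break
      path <- c(path, nxt)
      assign(nxt, TRUE, envir = visited)
      cur <- nxt
    }
    path
  }
  contigs <- character(0)
  starts <- kms[vapply(kms, function(km) {
    p <- preds(km)
    length(p) != 1 || length(succs(p)) != 1
  }, logical(1))]
  emit <- function(path) {
    seq <- paste0(path[1], paste(substr(path[-1], k, k), collapse = ""))
    min(seq, revcomp(seq))
  }
  for (s in starts) {
    if (seen(s)) next
    contigs <- c(contigs, emit(walk(s)))
  }
  # leftovers are perfect cycles; walk them from their smallest k-mer
  for (s in kms) {
    if (seen(s)) next
    contigs <- c(contigs, emit(walk(s)))
  }
  contigs <- unique(contigs)
  contigs <- contigs[nchar(contigs) >= min_len]
  if (length(contigs) == 0) return(empty)
  ord <- order(-nchar(contigs), contigs)
  contigs <- contigs[ord]
  tibble(id = sprintf("contig_%04d", seq_along(contigs)), seq = contigs,
         length = nchar(contigs))
}

# ---- read-to-sequence depth matching ---------------------------------------

# Mean per-base depth of `reads` on each target sequence, counting a read
# iff it matches ungapped at >= `identity` over >= `min_frac` of its length
# (either strand). Anchor-and-verify: a read and target sharing an
# alignment at <= floor((1-identity)*len) mismatches must share an exact
# k-mer in its first or last k bases when k <= len/2 and at most one
# mismatch is allowed; anchors are located via a canonical k-mer position
# map and candidates verified by direct comparison.
match_read_depth <- function(targets, reads, identity = 0.99,
                             min_frac = 0.9, k = 25) {
  tt <- as_seq_tbl(targets, "targets")
  depth <- setNames(numeric(nrow(tt)), tt$id)
  if (!is.data.frame(reads) || nrow(reads) == 0 || nrow(tt) == 0)
    return(tibble(id = tt$id, depth = unname(depth),
                  n_reads = integer(nrow(tt))))
  tseq <- toupper(tt$seq)
  tlen <- nchar(tseq)
  tmap <- data.table::rbindlist(lapply(seq_along(tseq), function(i) {
    km <- seq_kmers(tseq[i], k)
    if (length(km) == 0) return(NULL)
    data.table::data.table(canon = canonicalize(km), target = i,
                           tpos = seq_along(km) - 1L,
                           tfwd = km <= revcomp(km))
  }))
  if (is.null(tmap) || nrow(tmap) == 0)
    return(tibble(id = tt$id, depth = unname(depth),
                  n_reads = integer(nrow(tt))))
  rseq <- toupper(reads$seq)
  rlen <- nchar(rseq)
  usable <- rlen >= k & grepl("^[ACGT]+$", rseq)
  cands <- list()
  for (ori in c("fwd", "rev")) {
    sq <- if (ori == "fwd") rseq[usable] else revcomp(rseq[usable])
    ln <- rlen[usable]
    first_km <- substr(sq, 1L, k)
    last_km <- substr(sq, ln - k + 1L, ln)
    rt <- data.table::data.table(
      read = rep(which(usable), 2L),
      ori = ori,
      qpos = c(rep(0L, length(sq)), ln - k),
      km = c(first_km, last_km))
    rt[, c("canon", "rfwd") := {
      rc <- revcomp(km)
      list(pmin(km, rc), km <= rc)
    }]
    cands[[ori]] <- tmap[rt, on = "canon", allow.cartesian = TRUE,
                         nomatch = NULL][tfwd == rfwd]
  }
  cand <- data.table::rbindlist(cands)
  if (nrow(cand) == 0)
    return(tibble(id = tt$id, depth = unname(depth),
                  n_reads = integer(nrow(tt))))
  cand[, offset := tpos - qpos]
  cand <- unique(cand[, list(read, ori, target, offset)])
  # verify candidates
  rl <- rlen[cand$read]
  a0 <- pmax(cand$offset, 0L)                      # target start (0-based)
  a1 <- pmin(cand$offset + rl, tlen[cand$target])  # target end
  ov <- a1 - a0
  keep <- ov >= ceiling(min_frac * rl)
  cand <- cand[keep]; rl <- rl[keep]; a0 <- a0[keep]; a1 <- a1[keep]; ov <- ov[keep]
  if (nrow(cand) == 0)
    return(tibble(id = tt$id, depth = unname(depth),
                  n_reads = integer(nrow(tt))))
  q0 <- a0 - cand$offset  # read start of the overlap (0-based)
  rpart <- character(nrow(cand))
  f <- cand$ori == "fwd"
  rpart[f] <- substr(rseq[cand$read[f]], q0[f] + 1L, q0[f] + ov[f])
  if (any(!f)) {
    rcs <- revcomp(rseq[cand$read[!f]])
    rpart[!f] <- substr(rcs, q0[!f] + 1L, q0[!f] + ov[!f])
  }
  tpart <- substr(tseq[cand$target], a0 + 1L, a1)
  mm <- vapply(seq_len(nrow(cand)), function(i) {
    sum(charToRaw(rpart[i]) != charToRaw(tpart[i]))
  }, numeric(1))
  ok <- mm <= floor((1 - identity) * ov)
  cand <- cand[ok]; ov <- ov[ok]
  # a read may anchor at both ends / both orientations: count each
  # read-target pairing once (best = longest overlap)
  cand[, ov := ov]
  best <- cand[order(read, target, -ov)][!duplicated(paste(read, target))]
  agg <- best[, list(bases = sum(ov), n_reads = .N), by = "target"]
  depth[agg$target] <- agg$bases / tlen[agg$target]
  nr <- integer(nrow(tt)); nr[agg$target] <- agg$n_reads
  tibble(id = tt$id, depth = unname(depth), n_reads = nr)
}

#' Classify candidate transcripts by sexed genomic read depth
#'
#' Computes mean male and female genomic depth per contig (reads matching
#' ungapped at >= `identity` over >= 90 percent of their length, either
#' strand) and applies the Y-retention filter: retained iff male depth lies
#' in the retention window (default 4-14x, the one-copy band at 20x diploid
#' sequencing) and female depth is at (or below) `female_max`, default a
#' strict zero.
#'
#' @param contigs candidate contigs (tibble `id`/`seq` or FASTA path).
#' @param male_dna,female_dna genomic read sets (tibble with `seq` or
#'   FASTQ paths).
#' @param identity minimum match identity in `[0.99, 1]`.
#' @param male_window inclusive male-depth retention window.
#' @param female_max maximum tolerated female depth (epsilon for noisy
#'   data; 0 by default).
#' @param min_frac minimum matched fraction of the read length.
#' @param k anchor k-mer size for matching.
#' @return tibble with `id`, `seq`, `length`, `male_depth`, `female_depth`,
#'   `verdict` (one of retained, rejected_low_male, rejected_high_male,
#'   rejected_female_cov).
#' @export
classify_by_genomic_coverage <- function(contigs, male_dna, female_dna,
                                         identity = 0.99,
                                         male_window = c(4, 14),
                                         female_max = 0, min_frac = 0.9,
                                         k = 25) {
  tb <- as_seq_tbl(contigs, "contigs")
  if (nrow(tb) == 0) abort("no contigs to classify")
  stopifnot(identity >= 0.99, identity <= 1, length(male_window) == 2)
  md <- match_read_depth(tb, male_dna, identity = identity,
                         min_frac = min_frac, k = k)
  fd <- match_read_depth(tb, female_dna, identity = identity,
                         min_frac = min_frac, k = k)
  verdict <- dplyr::case_when(
    fd$depth > female_max ~ "rejected_female_cov",
    md$depth < male_window[1] ~ "rejected_low_male",
    md$depth > male_window[2] ~ "rejected_high_male",
    TRUE ~ "retained")
  tibble(id = tb$id, seq = tb$seq, length = nchar(tb$seq),
         male_depth = md$depth, female_depth = fd$depth, verdict = verdict)
}
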