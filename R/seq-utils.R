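#' Sequence utilities
#'
#' Small helpers shared by the simulators and the k-mer machinery. Sequences
#' are plain uppercase character strings of A/C/G/T throughout the package;
#' Biostrings does the heavy lifting (reverse complements, FASTA/FASTQ I/O).
#'
#' @name seq-utils
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T, any case).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA of given length and GC content
#'
#' Draws bases independently; G and C each with probability `gc/2`.
#' Uses the current RNG state (callers seed).
#'
#' @param n sequence length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return a single character string.
#' @export
random_dna <- function(n, gc = 0.4) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# All k-mers of one sequence as a character vector (empty if too short).
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# Canonical form: lexicographic min of a k-mer and its reverse complement.
canonicalize <- function(kmers) {
  if (length(kmers) == 0) return(character(0))
  pmin(kmers, revcomp(kmers))
}

# Coerce sequence input to a tibble with columns id, seq.
# Accepts: named/unnamed character vector, DNAStringSet, a tibble/data.frame
# with id+seq columns, or a path to a FASTA file.
as_seq_tbl <- function(x, arg = "x") {
  if (inherits(x, "DNAStringSet")) {
    return(tibble(id = names(x) %||% paste0("seq_", seq_along(x)),
                  seq = as.character(x)))
  }
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    ss <- Biostrings::readDNAStringSet(x)
    return(tibble(id = names(ss), seq = as.character(ss)))
  }
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq_", seq_along(x))
    ids[ids == ""] <- paste0("seq_", which(ids == ""))
    return(tibble(id = unname(ids), seq = toupper(unname(x))))
  }
  if (is.data.frame(x)) {
    stopifnot("id" %in% names(x), "seq" %in% names(x))
    return(as_tibble(x)[, c("id", "seq", setdiff(names(x), c("id", "seq")))])
  }
  abort(paste0("`", arg, "` must be sequences (character, DNAStringSet, ",
               "tibble with id/seq, or a FASTA path)."))
}

#' Write sequences to FASTA
#'
#' @param x sequences (tibble with `id`/`seq`, named character vector,
#'   or `DNAStringSet`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  tb <- as_seq_tbl(x)
  ss <- Biostrings::DNAStringSet(setNames(tb$seq, tb$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read FASTA into a tibble
#'
#' @param path FASTA file.
#' @return tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(ss)), seq = as.character(ss))
}

#' Write simulated reads to FASTQ
#'
#' Qualities are constant ("I", Phred 40): the simulator is error-free unless
#' an error rate is requested, and downstream matching is identity-based.
#'
#' @param reads tibble with columns `id` and `seq`.
#' @param path output FASTQ file (uncompressed).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  qual <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read FASTQ into a tibble
#'
#' @param path FASTQ file.
#' @return tibble with columns `id`, `seq`.
#' @export
read_reads_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(id = sub("\\s.*$", "", names(ss)), seq = as.character(ss))
}
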