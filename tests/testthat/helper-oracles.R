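# Independent brute-force oracles. Deliberately written in a plain,
# enumeration-first style, sharing no code with the package internals.

# strand-agnostic sequence comparison
canon_seq <- function(s) pmin(s, msyscan::revcomp(s))

# --- NG86 oracle ------------------------------------------------------------

oracle_translate <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

# synonymous sites of one codon: enumerate all nine single-nucleotide
# neighbours; a change is synonymous iff it yields a sense codon with the
# same amino acid
oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  n_syn <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      nb <- codon
      substr(nb, pos, pos) <- b
      if (oracle_translate(nb) != "*" && oracle_translate(nb) == aa)
        n_syn <- n_syn + 1
    }
  }
  n_syn / 3
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# average syn/nonsyn differences between two codons over all substitution
# orderings
oracle_codon_diffs <- function(a, b) {
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diff_pos) == 0) return(c(syn = 0, nonsyn = 0))
  totals <- c(0, 0)
  paths <- oracle_permutations(diff_pos)
  for (path in paths) {
    cur <- a
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      aa_from <- oracle_translate(cur)
      aa_to <- oracle_translate(nxt)
      if (aa_from != "*" && aa_to != "*" && aa_from == aa_to)
        totals[1] <- totals[1] + 1
      else totals[2] <- totals[2] + 1
      cur <- nxt
    }
  }
  c(syn = totals[1] / length(paths), nonsyn = totals[2] / length(paths))
}

# full NG86 on two equal-length in-frame sequences; returns list with S, N,
# Sd, Nd, ps, dS (dS NA when saturated)
oracle_ng86 <- function(a, b) {
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3 == 0)
  S <- N <- Sd <- Nd <- 0
  for (i in seq(1, nchar(a), by = 3)) {
    ca <- substr(a, i, i + 2)
    cb <- substr(b, i, i + 2)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (oracle_translate(ca) == "*" || oracle_translate(cb) == "*") next
    sa <- oracle_syn_sites(ca)
    sb <- oracle_syn_sites(cb)
    S <- S + (sa + sb) / 2
    N <- N + (3 - (sa + sb) / 2)
    d <- oracle_codon_diffs(ca, cb)
    Sd <- Sd + d[["syn"]]
    Nd <- Nd + d[["nonsyn"]]
  }
  ps <- Sd / S
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps,
       dS = if (ps < 0.75) -3 / 4 * log(1 - 4 * ps / 3) else NA_real_)
}

# --- subtraction oracle -----------------------------------------------------

# brute-force scanner: flat list of every female k-mer and its reverse
# complement; a read is kept iff none of its windows (either strand) occurs
# in that list
oracle_subtract <- function(read_seqs, female_seqs, k) {
  windows <- function(s) {
    if (nchar(s) < k) return(character(0))
    starts <- 1:(nchar(s) - k + 1)
    substring(s, starts, starts + k - 1)
  }
  female_kmers <- unique(unlist(lapply(female_seqs, function(s)
    c(windows(s), windows(msyscan::revcomp(s))))))
  vapply(read_seqs, function(r) {
    if (nchar(r) < k) return(FALSE)
    !any(windows(r) %in% female_kmers)
  }, logical(1), USE.NAMES = FALSE)
}

# --- alignment score oracle -------------------------------------------------

# exhaustive maximum alignment score over all codon-level global alignments
# (plain recursion; only usable for toy inputs)
oracle_codon_align_score <- function(ca, cb, gap = -4) {
  codon_score <- function(x, y)
    sum(strsplit(x, "")[[1]] == strsplit(y, "")[[1]]) * 2 - 3
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) + codon_score(ca[i], cb[j]))
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(ca), length(cb))
}

# --- misc -------------------------------------------------------------------

# independent median: sort and average the central pair
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# random in-frame CDS without stop codons, as a plain string
random_sense_cds <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
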