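#' Genetic-code tables for the NG86 estimator
#'
#' Built lazily once per session and cached. Conventions (documented in the
#' methods vignette): single-nucleotide changes to stop codons count as
#' nonsynonymous (each codon position contributes out of 3 possible changes);
#' multi-hit codon pairs average synonymous/nonsynonymous difference counts
#' over all orderings of the differing positions, a step being synonymous iff
#' both codons are sense codons encoding the same amino acid.
#'
#' @name genetic-code
#' @keywords internal
NULL

all_codons <- function() {
  g <- expand.grid(p3 = DNA_BASES, p2 = DNA_BASES, p1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

codon_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

is_stop_codon <- function(codons) codon_aa(codons) == "*"

# Synonymous site count per codon (NA for stop codons).
ng86_sites_per_codon <- function() {
  cods <- all_codons()
  aa <- codon_aa(cods)
  s <- numeric(64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { s[i] <- NA_real_; next }
    cnt <- 0
    for (pos in 1:3) {
      for (b in setdiff(DNA_BASES, substr(cods[i], pos, pos))) {
        mut <- cods[i]
        substr(mut, pos, pos) <- b
        maa <- codon_aa(mut)
        if (maa != "*" && maa == aa[i]) cnt <- cnt + 1
      }
    }
    s[i] <- cnt / 3
  }
  setNames(s, cods)
}

# Average synonymous/nonsynonymous differences over all substitution
# orderings between two codons. Returns c(sd, nd).
codon_pair_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(0, 0))
  perms <- switch(d,
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  tot <- c(0, 0)
  for (p in perms) {
    cur <- a
    for (k in p) {
      nxt <- cur
      substr(nxt, pos[k], pos[k]) <- substr(b, pos[k], pos[k])
      aa1 <- codon_aa(cur); aa2 <- codon_aa(nxt)
      if (aa1 != "*" && aa2 != "*" && aa1 == aa2) tot[1] <- tot[1] + 1
      else tot[2] <- tot[2] + 1
      cur <- nxt
    }
  }
  tot / length(perms)
}

# Cached tables: $sites (length-64), $sd and $nd (64 x 64 matrices).
ng86_tables <- function() {
  if (!is.null(the$ng86)) return(the$ng86)
  cods <- all_codons()
  sites <- ng86_sites_per_codon()
  sd_m <- matrix(0, 64, 64, dimnames = list(cods, cods))
  nd_m <- sd_m
  for (i in seq_len(64)) {
    for (j in seq_len(64)) {
      if (j <= i) next
      dd <- codon_pair_diffs(cods[i], cods[j])
      sd_m[i, j] <- sd_m[j, i] <- dd[1]
      nd_m[i, j] <- nd_m[j, i] <- dd[2]
    }
  }
  the$ng86 <- list(codons = cods, sites = sites, sd = sd_m, nd = nd_m)
  the$ng86
}

# Split an in-frame sequence into codons. Length must be divisible by 3.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) abort("sequence length is not divisible by 3")
  if (n == 0) return(character(0))
  starts <- seq(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

# Sense codons usable for dS between two aligned sequences: both codons free
# of gaps/ambiguity and neither a stop.
usable_codon_pairs <- function(ca, cb) {
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ok[ok] <- !is_stop_codon(ca[ok]) & !is_stop_codon(cb[ok])
  ok
}
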