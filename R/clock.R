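#' Nei-Gojobori (1986) synonymous divergence between two aligned sequences
#'
#' Counting estimator of synonymous substitutions per synonymous site with
#' Jukes-Cantor multiple-hit correction: synonymous site content per codon is
#' the fraction of single-nucleotide changes that preserve the amino acid
#' (changes to stop codons count as nonsynonymous); differences in multi-hit
#' codons are averaged over all substitution orderings. Codon columns with
#' gaps, ambiguity codes, or stop codons are excluded.
#'
#' @param seq_a,seq_b aligned in-frame sequences (same length, divisible by
#'   3; `-` marks gaps).
#' @return an object of class `msy_ds`: a list with `S`, `N` (site counts
#'   averaged over the two sequences), `Sd`, `Nd` (difference counts), `ps`,
#'   `pn` (proportions), `dS`, `dN` (Jukes-Cantor corrected), and
#'   `n_codons_used`.
#' @examples
#' ng86_ds("GGGGGGGGGTTT", "GGAGGGGGGTTT")$dS  # 0.3831...
#' @export
ng86_ds <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1, length(seq_b) == 1)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    abort("aligned sequences must have equal length")
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  ok <- usable_codon_pairs(ca, cb)
  if (!any(ok)) abort("no usable (gap- and stop-free) codons to compare")
  tab <- ng86_tables()
  ia <- match(ca[ok], tab$codons)
  ib <- match(cb[ok], tab$codons)
  S <- sum((tab$sites[ia] + tab$sites[ib]) / 2)
  N <- 3 * sum(ok) - S
  Sd <- sum(tab$sd[cbind(ia, ib)])
  Nd <- sum(tab$nd[cbind(ia, ib)])
  ps <- Sd / S
  pn <- Nd / N
  if (ps >= 0.75)
    abort(sprintf("synonymous divergence saturated (ps = %.3f >= 0.75)", ps))
  dS <- -0.75 * log(1 - 4 * ps / 3)
  dN <- if (pn < 0.75) -0.75 * log(1 - 4 * pn / 3) else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 dS = dS, dN = dN, n_codons_used = sum(ok)),
            class = "msy_ds")
}

#' @export
print.msy_ds <- function(x, ...) {
  cat(sprintf("NG86 divergence over %d codons: dS = %.4f (ps = %.4f, S = %.1f), dN = %s\n",
              x$n_codons_used, x$dS, x$ps,
              ifelse(is.na(x$dN), "NA", sprintf("%.4f", x$dN))))
  invisible(x)
}

#' @export
tidy.msy_ds <- function(x, ...) {
  tibble(S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd,
         ps = x$ps, pn = x$pn, dS = x$dS, dN = x$dN,
         n_codons = x$n_codons_used)
}

# Per-codon-column NG86 contributions for a pair of aligned sequences:
# columns s (sites), sd, nd; unusable columns get zero weight and are
# flagged. Used by the codon bootstrap.
ng86_column_stats <- function(seq_a, seq_b) {
  ca <- split_codons(toupper(seq_a))
  cb <- split_codons(toupper(seq_b))
  ok <- usable_codon_pairs(ca, cb)
  tab <- ng86_tables()
  s <- sd_ <- nd_ <- numeric(length(ca))
  ia <- match(ca[ok], tab$codons)
  ib <- match(cb[ok], tab$codons)
  s[ok] <- (tab$sites[ia] + tab$sites[ib]) / 2
  sd_[ok] <- tab$sd[cbind(ia, ib)]
  nd_[ok] <- tab$nd[cbind(ia, ib)]
  list(s = s, sd = sd_, nd = nd_, ok = ok)
}

ds_from_counts <- function(S, Sd) {
  ps <- Sd / S
  ifelse(ps < 0.75, -0.75 * log(1 - 4 * ps / 3), NA_real_)
}

#' Pairwise dS matrix over a codon alignment
#'
#' @param aln a codon alignment: tibble with `id`, `seq` (all equal length,
#'   in frame) as produced by [align_codons()], or a named character vector.
#' @return a symmetric matrix of NG86 dS values with taxon dimnames.
#' @export
ds_matrix <- function(aln) {
  tb <- as_seq_tbl(aln, "aln")
  n <- nrow(tb)
  m <- matrix(0, n, n, dimnames = list(tb$id, tb$id))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- ng86_ds(tb$seq[i], tb$seq[j])$dS
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

# ---- codon-aware global alignment ------------------------------------------

# Needleman-Wunsch on codon units. Codon-vs-codon score: +1 per matching
# nucleotide, -1 per mismatching one; a codon gap costs `gap` (linear).
# Tie-break order diagonal > up > left gives a deterministic, leftmost-gap
# alignment.
nw_codon_pair <- function(ca, cb, gap = -4) {
  score <- function(x, y) {
    m <- sum(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
    m - (3 - m)
  }
  n <- length(ca); m <- length(cb)
  S <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up (gap in b), 3 left (gap in a)
  S[1, ] <- gap * (0:m); P[1, -1] <- 3L
  S[, 1] <- gap * (0:n); P[-1, 1] <- 2L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + score(ca[i], cb[j])
      u <- S[i, j + 1] + gap
      l <- S[i + 1, j] + gap
      best <- max(d, u, l)
      S[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  i <- n + 1; j <- m + 1
  oa <- character(0); ob <- character(0)
  while (i > 1 || j > 1) {
    p <- P[i, j]
    if (p == 1L) { oa <- c(ca[i - 1], oa); ob <- c(cb[j - 1], ob); i <- i - 1; j <- j - 1 }
    else if (p == 2L) { oa <- c(ca[i - 1], oa); ob <- c("---", ob); i <- i - 1 }
    else { oa <- c("---", oa); ob <- c(cb[j - 1], ob); j <- j - 1 }
  }
  list(a = oa, b = ob, score = S[n + 1, m + 1])
}

#' Codon-aware global alignment of in-frame coding sequences
#'
#' Aligns on codon units (gaps inserted in multiples of 3) with a
#' Needleman-Wunsch dynamic program: codon-pair score is +1 per identical
#' nucleotide and -1 per differing one, a codon indel costs 4. With more than
#' two sequences, each is aligned to the first and the gap patterns merged
#' (adequate for gametolog sets, which are near-equal-length by construction).
#' Deterministic: ties resolve to the leftmost gap placement.
#'
#' @param cds coding sequences (tibble with `id`/`seq`, named character
#'   vector, or FASTA path); each length divisible by 3.
#' @param gap per-codon gap penalty (negative).
#' @return tibble with `id`, `seq` (aligned, equal lengths divisible by 3),
#'   carrying attribute `score` for the pairwise case; class
#'   `msy_codon_alignment`.
#' @export
align_codons <- function(cds, gap = -4) {
  tb <- as_seq_tbl(cds, "cds")
  if (nrow(tb) == 0) abort("no sequences to align")
  bad <- nchar(tb$seq) %% 3 != 0
  if (any(bad))
    abort(paste0("sequence length not divisible by 3: ",
                 paste(tb$id[bad], collapse = ", ")))
  cod <- lapply(tb$seq, split_codons)
  if (nrow(tb) == 1) {
    out <- tb
  } else if (nrow(tb) == 2) {
    al <- nw_codon_pair(cod[[1]], cod[[2]], gap = gap)
    out <- tibble(id = tb$id,
                  seq = c(paste(al$a, collapse = ""), paste(al$b, collapse = "")))
    attr(out, "score") <- al$score
  } else {
    # progressive: align each sequence to the first, merge reference gaps
    ref <- cod[[1]]
    pair_alns <- lapply(cod[-1], function(x) nw_codon_pair(ref, x, gap = gap))
    # insertions relative to ref: count of inserted codons before each ref
    # codon slot (slots 0..length(ref))
    ins_counts <- lapply(pair_alns, function(al) {
      slot <- integer(length(ref) + 1)
      ri <- 0L
      for (k in seq_along(al$a)) {
        if (al$a[k] == "---") slot[ri + 1L] <- slot[ri + 1L] + 1L
        else ri <- ri + 1L
      }
      slot
    })
    max_ins <- Reduce(pmax, ins_counts)
    pad <- function(al, ins) {
      # rebuild the aligned non-ref sequence onto the merged coordinate system
      out <- character(0)
      ri <- 0L; k <- 1L
      repeat {
        n_here <- 0L
        while (k <= length(al$a) && al$a[k] == "---") {
          out <- c(out, al$b[k]); n_here <- n_here + 1L; k <- k + 1L
        }
        out <- c(out, rep("---", max_ins[ri + 1L] - n_here))
        if (ri == length(ref)) break
        out <- c(out, al$b[k]); k <- k + 1L; ri <- ri + 1L
      }
      out
    }
    ref_merged <- character(0)
    for (ri in 0:length(ref)) {
      ref_merged <- c(ref_merged, rep("---", max_ins[ri + 1L]))
      if (ri < length(ref)) ref_merged <- c(ref_merged, ref[ri + 1L])
    }
    rows <- c(list(ref_merged),
              Map(pad, pair_alns, ins_counts))
    out <- tibble(id = tb$id,
                  seq = vapply(rows, paste, character(1), collapse = ""))
  }
  class(out) <- c("msy_codon_alignment", class(out))
  out
}

# ---- tree fitting and dating -----------------------------------------------

#' Concatenate gametolog alignments and fit dS branch lengths on a topology
#'
#' Concatenates per-gene codon alignments (shared taxon set), computes the
#' pairwise NG86 dS matrix, and fits branch lengths on the fixed topology by
#' non-negative least squares (negative estimates clamped at zero).
#'
#' @param alignments a single alignment or a list of alignments (each a
#'   tibble with `id`/`seq` over the same taxa).
#' @param topology an `ape::phylo` topology containing exactly the alignment
#'   taxa; with two taxa it may be `NULL`.
#' @return an object of class `msy_ds_tree`: list with `tree` (phylo with dS
#'   branch lengths), `ds` (matrix), `concatenation` (tibble `id`/`seq`).
#' @export
concatenate_and_tree <- function(alignments, topology = NULL) {
  if (is.data.frame(alignments) || is.character(alignments))
    alignments <- list(alignments)
  tbs <- lapply(alignments, as_seq_tbl, arg = "alignments")
  taxa <- tbs[[1]]$id
  for (tb in tbs) {
    if (!setequal(tb$id, taxa))
      abort("all alignments must cover the same taxon set")
  }
  concat <- tibble(
    id = taxa,
    seq = vapply(taxa, function(tx)
      paste(vapply(tbs, function(tb) tb$seq[match(tx, tb$id)], character(1)),
            collapse = ""), character(1), USE.NAMES = FALSE))
  dm <- ds_matrix(concat)
  if (length(taxa) == 2) {
    tree <- ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);", taxa[1],
                                          dm[1, 2] / 2, taxa[2], dm[1, 2] / 2))
  } else {
    if (is.null(topology)) abort("`topology` is required for > 2 taxa")
    if (!setequal(topology$tip.label, taxa))
      abort("topology tips must match alignment taxa")
    tree <- phangorn::nnls.tree(stats::as.dist(dm), ape::unroot(topology),
                                method = "unrooted")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  structure(list(tree = tree, ds = dm, concatenation = concat),
            class = "msy_ds_tree")
}

#' @export
print.msy_ds_tree <- function(x, ...) {
  cat(sprintf("dS tree over %d taxa (%d bp concatenation)\n",
              nrow(x$ds), nchar(x$concatenation$seq[1])))
  print(round(x$ds, 4))
  invisible(x)
}

# dS path length between two taxa: from the matrix (equals the fitted tree
# path for the projected metric; documented in the vignette).
ds_path <- function(ds, a, b) {
  if (!all(c(a, b) %in% rownames(ds)))
    abort(sprintf("taxa %s/%s not in dS matrix", a, b))
  ds[a, b]
}

#' Calibrate a dS tree against dated nodes and date the XY split
#'
#' The per-lineage synonymous rate is estimated from each calibration taxon
#' as `r_i = (dS(X, cal_i)/2) / T_i` where `T_i` is the known divergence time
#' (Myr) of that taxon from the X lineage; rates are averaged across
#' calibrations. The XY age is `(dS(X, Y)/2) / r`, clamped to
#' `[0, max(T_i)]`. The calibration ages bracketing the estimate are reported
#' alongside as a sanity annotation.
#'
#' @param ds_tree an `msy_ds_tree`, or a symmetric dS matrix with taxon
#'   dimnames.
#' @param calibration named numeric vector of node ages in Myr, names being
#'   calibration taxa (e.g. `c(OUT1 = 184.9)`).
#' @param x_taxon,y_taxon labels of the X and Y gametolog sequences.
#' @return an object of class `msy_age`: list with `age`, `rate`,
#'   `per_calibration` tibble, `ds_xy`, and NULL CI fields (filled by
#'   [bootstrap_age()]).
#' @export
calibrate_and_date <- function(ds_tree, calibration, x_taxon = "X",
                               y_taxon = "Y") {
  ds <- if (inherits(ds_tree, "msy_ds_tree")) ds_tree$ds else ds_tree
  stopifnot(is.matrix(ds), !is.null(names(calibration)),
            all(calibration > 0))
  rates <- vapply(names(calibration), function(tx)
    (ds_path(ds, x_taxon, tx) / 2) / calibration[[tx]], numeric(1))
  if (any(rates <= 0))
    abort("calibration path has zero dS; cannot estimate a rate")
  r <- mean(rates)
  ds_xy <- ds_path(ds, x_taxon, y_taxon)
  age <- min(max((ds_xy / 2) / r, 0), max(calibration))
  structure(list(
    age = age, rate = r, ds_xy = ds_xy,
    per_calibration = tibble(taxon = names(calibration),
                             age_myr = unname(calibration),
                             rate = unname(rates)),
    bracketing_ages = sort(unname(calibration)),
    lower = NA_real_, upper = NA_real_, n_bootstrap = 0L),
    class = "msy_age")
}

#' @export
print.msy_age <- function(x, ...) {
  cat(sprintf("XY split age: %.1f Myr", x$age))
  if (x$n_bootstrap > 0)
    cat(sprintf(" (95%% CI %.2f-%.2f, %d bootstrap rounds)",
                x$lower, x$upper, x$n_bootstrap))
  cat(sprintf("\n  dS(X,Y) = %.4f, per-lineage rate = %.5f /syn site/Myr\n",
              x$ds_xy, x$rate))
  invisible(x)
}

#' @export
tidy.msy_age <- function(x, ...) {
  tibble(term = "xy_split_age", estimate = x$age,
         conf.low = x$lower, conf.high = x$upper)
}

#' @export
glance.msy_age <- function(x, ...) {
  tibble(age = x$age, lower = x$lower, upper = x$upper,
         rate = x$rate, ds_xy = x$ds_xy, n_bootstrap = x$n_bootstrap)
}

#' Codon-column bootstrap confidence interval for the XY age
#'
#' Resamples codon columns of the concatenated alignment with replacement,
#' recomputes the NG86 dS values and the calibrated age per replicate, and
#' reports the 2.5/97.5 percentile interval around the full-data point
#' estimate.
#'
#' @param ds_tree an `msy_ds_tree` from [concatenate_and_tree()] (the
#'   concatenation is resampled).
#' @inheritParams calibrate_and_date
#' @param n number of bootstrap replicates.
#' @param seed integer seed for the resampling.
#' @return an `msy_age` with `lower`, `upper`, `n_bootstrap`, and a
#'   `replicates` vector of bootstrap ages.
#' @export
bootstrap_age <- function(ds_tree, calibration, x_taxon = "X", y_taxon = "Y",
                          n = 100, seed = 1) {
  stopifnot(inherits(ds_tree, "msy_ds_tree"))
  point <- calibrate_and_date(ds_tree, calibration, x_taxon, y_taxon)
  concat <- ds_tree$concatenation
  n_codons <- nchar(concat$seq[1]) / 3
  if (n_codons < 30)
    abort("concatenation too short to bootstrap (< 30 codons)")
  get_seq <- function(tx) concat$seq[match(tx, concat$id)]
  pair_stats <- c(
    list(xy = ng86_column_stats(get_seq(x_taxon), get_seq(y_taxon))),
    setNames(lapply(names(calibration), function(tx)
      ng86_column_stats(get_seq(x_taxon), get_seq(tx))),
      names(calibration)))
  set.seed(seed)
  reps <- vapply(seq_len(n), function(i) {
    idx <- sample.int(n_codons, n_codons, replace = TRUE)
    ds_xy <- ds_from_counts(sum(pair_stats$xy$s[idx]),
                            sum(pair_stats$xy$sd[idx]))
    rates <- vapply(names(calibration), function(tx) {
      st <- pair_stats[[tx]]
      d <- ds_from_counts(sum(st$s[idx]), sum(st$sd[idx]))
      (d / 2) / calibration[[tx]]
    }, numeric(1))
    if (any(is.na(rates)) || is.na(ds_xy) || mean(rates) <= 0)
      return(NA_real_)
    min(max((ds_xy / 2) / mean(rates), 0), max(calibration))
  }, numeric(1))
  reps_ok <- reps[!is.na(reps)]
  if (length(reps_ok) < n)
    warn(sprintf("%d bootstrap replicates were saturated and dropped",
                 n - length(reps_ok)))
  ci <- unname(quantile(reps_ok, c(0.025, 0.975), type = 7))
  point$lower <- ci[1]
  point$upper <- ci[2]
  point$n_bootstrap <- length(reps_ok)
  point$replicates <- reps_ok
  point$seed <- seed
  point
}

#' @export
autoplot.msy_age <- function(object, ...) {
  if (is.null(object$replicates))
    abort("run bootstrap_age() before plotting an age estimate")
  df <- tibble(age = object$replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$age, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(object$lower, object$upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "XY split age (Myr)", y = "bootstrap replicates",
                  title = sprintf("Age %.1f Myr (95%% CI %.1f-%.1f)",
                                  object$age, object$lower, object$upper)) +
    ggplot2::theme_minimal()
}
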