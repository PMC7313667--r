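#' Specification for the synthetic diploid genome
#'
#' Describes an XY genome with a planted male-specific Y region (MSY): the Y
#' haplotype equals the X haplotype everywhere except inside `msy_interval`,
#' where it carries diverged gametolog gene copies embedded in Y-specific
#' (non-homologous) sequence. Coordinates are 0-based half-open throughout
#' (BED convention).
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param msy_chrom chromosome carrying the MSY, or `NULL` for a genome
#'   without one (specificity controls).
#' @param msy_interval length-2 numeric, 0-based half-open `[start, end)`
#'   within `msy_chrom`; must be at least `min_msy_len` long.
#' @param n_gametolog_genes number of XY gametolog gene pairs planted inside
#'   the MSY (>= 1 when an MSY is present).
#' @param n_autosomal_genes background genes planted outside the MSY,
#'   identical between haplotypes; these populate the female transcriptome.
#' @param gene_length gene length in codons.
#' @param gc GC content of intergenic sequence, in `[0, 1]`.
#' @param clock a [clock_sim_spec()] giving the true gametolog divergence
#'   history (age, rate, outgroup calibrations).
#' @param min_msy_len minimum MSY length (defaults to the coverage-scan bin
#'   size so the planted region is detectable).
#' @param seed integer seed.
#' @return an object of class `msy_genome_spec`.
#' @export
genome_spec <- function(chrom_lengths = c(chr5 = 1e6, chr1 = 7e5, chr2 = 5e5),
                        msy_chrom = "chr5",
                        msy_interval = c(3e5, 6e5),
                        n_gametolog_genes = 14,
                        n_autosomal_genes = 10,
                        gene_length = 300,
                        gc = 0.4,
                        clock = clock_sim_spec(),
                        min_msy_len = 1e5,
                        seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0), gene_length > 0, gc >= 0, gc <= 1,
            inherits(clock, "msy_clock_spec"))
  if (!is.null(msy_chrom)) {
    if (!msy_chrom %in% names(chrom_lengths))
      abort("msy_chrom is not one of the chromosomes")
    if (length(msy_interval) != 2 || msy_interval[2] <= msy_interval[1])
      abort("msy_interval must be a non-empty 0-based half-open [start, end)")
    if (msy_interval[1] < 0 || msy_interval[2] > chrom_lengths[[msy_chrom]])
      abort("msy_interval lies outside its chromosome")
    if (diff(msy_interval) < min_msy_len)
      abort(sprintf("msy_interval is shorter than min_msy_len (%d bp)",
                    as.integer(min_msy_len)))
    if (n_gametolog_genes < 1)
      abort("a genome with an MSY needs n_gametolog_genes >= 1")
    if (n_gametolog_genes * gene_length * 3 > diff(msy_interval))
      abort("gametolog genes do not fit inside msy_interval")
  }
  structure(list(chrom_lengths = chrom_lengths, msy_chrom = msy_chrom,
                 msy_interval = if (is.null(msy_chrom)) NULL else as.numeric(msy_interval),
                 n_gametolog_genes = n_gametolog_genes,
                 n_autosomal_genes = n_autosomal_genes,
                 gene_length = gene_length, gc = gc, clock = clock,
                 seed = as.integer(seed)),
            class = "msy_genome_spec")
}

# Mean of min(Geom(p) + 1, mg); used to calibrate constrained substitution
# placement.
trunc_geom_mean <- function(p, mg) {
  j <- seq_len(mg - 1)
  sum(j * (1 - p)^(j - 1) * p) + mg * (1 - p)^(mg - 1)
}

# Place substituted third positions along a gene so that (a) the marginal
# density matches the Jukes-Cantor expected difference probability at the
# target divergence and (b) no run of max_gap codons is substitution-free,
# which guarantees every k-mer (k <= 3*max_gap + 4) distinguishes the X and
# Y copies. Returns the diverged codon vector.
place_diverged_copy <- function(codons, d_target, max_gap = 7L) {
  q <- 0.75 * (1 - exp(-4 * d_target / 3))  # expected per-site diff prob
  if (q <= 0) return(codons)
  if (1 / q >= max_gap) {
    warn(sprintf(paste0("target divergence %.3f is too low to keep every ",
                        "%d-codon window distinguishing; substitution density ",
                        "raised to 1/%d per codon"), d_target, max_gap, max_gap))
    p <- 1e-9
  } else {
    p <- uniroot(function(p) trunc_geom_mean(p, max_gap) - 1 / q,
                 c(1e-9, 1 - 1e-9))$root
  }
  L <- length(codons)
  pos <- integer(0)
  cur <- 0L
  repeat {
    gap <- min(stats::rgeom(1, p) + 1L, max_gap)
    cur <- cur + gap
    if (cur > L) break
    pos <- c(pos, cur)
  }
  for (i in pos) {
    alt <- setdiff(DNA_BASES, substr(codons[i], 3, 3))
    ok <- alt[vapply(alt, function(b) {
      m <- codons[i]; substr(m, 3, 3) <- b; !is_stop_codon(m)
    }, logical(1))]
    if (length(ok) == 0) next
    pick <- if (length(ok) == 1) ok else sample(ok, 1)
    substr(codons[i], 3, 3) <- pick
  }
  codons
}

#' Simulate a diploid genome with a planted male-specific Y region
#'
#' Generates the X haplotype, plants gametolog genes inside the MSY and
#' background genes outside it, and derives the Y haplotype: identical to X
#' outside the MSY; inside it, Y-specific sequence carrying gametolog copies
#' diverged at the synonymous level implied by the clock spec. Outgroup
#' orthologs of each gametolog are evolved at the calibration divergences
#' and recorded in the gene table (they stand in for orthologs a real
#' analysis would download).
#'
#' @param spec a [genome_spec()].
#' @return an object of class `msy_genome`: list with `x` and `y` (named
#'   character haplotypes), `msy` (one-row truth tibble or `NULL`), `genes`
#'   (annotation tibble with planted coordinates and sequences), and `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "msy_genome_spec"))
  set.seed(spec$seed)
  x <- vapply(spec$chrom_lengths, function(L) random_dna(L, spec$gc),
              character(1))
  glen <- spec$gene_length * 3L
  genes <- list()

  # background genes on non-MSY sequence, identical between haplotypes
  if (spec$n_autosomal_genes > 0) {
    auto_chroms <- names(spec$chrom_lengths)
    # keep autosomal genes off the MSY chromosome entirely when possible
    if (!is.null(spec$msy_chrom) && length(auto_chroms) > 1)
      auto_chroms <- setdiff(auto_chroms, spec$msy_chrom)
    slots <- data.frame(chrom = rep(auto_chroms,
                                    ceiling(spec$n_autosomal_genes / length(auto_chroms))))
    slots <- slots[seq_len(spec$n_autosomal_genes), , drop = FALSE]
    slots$idx <- stats::ave(seq_len(nrow(slots)), slots$chrom, FUN = seq_along)
    slots$n_on <- stats::ave(seq_len(nrow(slots)), slots$chrom, FUN = length)
    for (r in seq_len(nrow(slots))) {
      ch <- slots$chrom[r]
      L <- spec$chrom_lengths[[ch]]
      spacing <- L / slots$n_on[r]
      start <- floor(spacing * (slots$idx[r] - 1) + (spacing - glen) / 2)
      if (start < 0 || start + glen > L)
        abort("autosomal genes do not fit on their chromosome")
      if (!is.null(spec$msy_chrom) && ch == spec$msy_chrom &&
          start < spec$msy_interval[2] && start + glen > spec$msy_interval[1])
        abort("autosomal gene placement collides with the MSY; use more chromosomes")
      cds <- random_cds(spec$gene_length)
      substr(x[[ch]], start + 1, start + glen) <- cds
      genes[[length(genes) + 1]] <- tibble(
        gene_id = sprintf("auto_%02d", r), type = "autosomal", chrom = ch,
        start = start, end = start + glen, x_seq = cds, y_seq = NA_character_,
        target_ds = NA_real_)
    }
  }

  y <- x
  if (!is.null(spec$msy_chrom)) {
    mstart <- spec$msy_interval[1]; mend <- spec$msy_interval[2]
    mlen <- mend - mstart
    # degenerate Y: the MSY on Y is non-homologous to X outside gene copies
    substr(y[[spec$msy_chrom]], mstart + 1, mend) <- random_dna(mlen, spec$gc)
    d_xy <- 2 * spec$clock$true_age * spec$clock$rate
    d_out <- 2 * spec$clock$calibration * spec$clock$rate
    spacing <- mlen / spec$n_gametolog_genes
    for (i in seq_len(spec$n_gametolog_genes)) {
      start <- floor(mstart + spacing * (i - 1) + (spacing - glen) / 2)
      cds <- random_cds(spec$gene_length)
      x_cod <- split_codons(cds)
      y_cod <- place_diverged_copy(x_cod, d_xy)
      outs <- lapply(d_out, function(d) paste(
        evolve_third_positions(x_cod, d), collapse = ""))
      xs <- paste(x_cod, collapse = ""); ys <- paste(y_cod, collapse = "")
      substr(x[[spec$msy_chrom]], start + 1, start + glen) <- xs
      substr(y[[spec$msy_chrom]], start + 1, start + glen) <- ys
      row <- tibble(gene_id = sprintf("gam_%02d", i), type = "gametolog",
                    chrom = spec$msy_chrom, start = start, end = start + glen,
                    x_seq = xs, y_seq = ys, target_ds = d_xy)
      for (tx in names(outs)) row[[paste0("out_", tx)]] <- outs[[tx]]
      genes[[length(genes) + 1]] <- row
    }
  }
  genes <- bind_rows(genes)
  msy <- if (is.null(spec$msy_chrom)) NULL else
    tibble(chrom = spec$msy_chrom, start = spec$msy_interval[1],
           end = spec$msy_interval[2])
  structure(list(x = x, y = y, msy = msy, genes = genes, spec = spec),
            class = "msy_genome")
}

#' @export
print.msy_genome <- function(x, ...) {
  cat(sprintf("synthetic XY genome: %d chromosome(s), %s bp\n",
              length(x$x), format(sum(nchar(x$x)), big.mark = ",")))
  if (!is.null(x$msy))
    cat(sprintf("  planted MSY: %s:%d-%d with %d gametolog pair(s)\n",
                x$msy$chrom, x$msy$start, x$msy$end,
                sum(x$genes$type == "gametolog")))
  invisible(x)
}

#' Female transcriptome of a synthetic genome
#'
#' All X-borne transcripts: the X gametolog copies plus the autosomal genes.
#'
#' @param genome an `msy_genome`.
#' @return tibble with `id`, `seq`.
#' @export
female_transcriptome <- function(genome) {
  stopifnot(inherits(genome, "msy_genome"))
  tibble(id = paste0(genome$genes$gene_id, "_X"), seq = genome$genes$x_seq)
}

#' Male-expressed transcripts of a synthetic genome
#'
#' Autosomal and X transcripts plus the Y gametolog copies.
#'
#' @param genome an `msy_genome`.
#' @return tibble with `id`, `seq`, `source` (autosomal/X/Y).
#' @export
male_transcripts <- function(genome) {
  stopifnot(inherits(genome, "msy_genome"))
  g <- genome$genes
  xpart <- tibble(id = paste0(g$gene_id, "_X"), seq = g$x_seq,
                  source = ifelse(g$type == "autosomal", "autosomal", "X"))
  ypart <- g[g$type == "gametolog", ]
  bind_rows(xpart,
            tibble(id = paste0(ypart$gene_id, "_Y"), seq = ypart$y_seq,
                   source = "Y"))
}

#' Write a synthetic genome (and its truth files) to disk
#'
#' @param genome an `msy_genome`.
#' @param dir output directory (created if missing). Writes
#'   `genome_X.fasta`, `genome_Y.fasta`, `msy_truth.bed` (if an MSY is
#'   planted), and `genes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "msy_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(genome$x, file.path(dir, "genome_X.fasta"))
  write_fasta(genome$y, file.path(dir, "genome_Y.fasta"))
  if (!is.null(genome$msy))
    utils::write.table(genome$msy, file.path(dir, "msy_truth.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  utils::write.table(genome$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
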