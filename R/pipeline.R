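#' Pipeline configuration
#'
#' Assembles the full stage configuration with defaults mirroring the
#' analysis' canonical parameters: k = 25 subtraction, 100-kb coverage
#' bins, a 4-14x male depth retention window with strict zero female depth,
#' a [90, 99) percent gametolog identity window, and 100 bootstrap rounds
#' for dating. All randomness derives from `seed`.
#'
#' @param seed master integer seed.
#' @param ... named overrides merged (recursively) into the defaults, e.g.
#'   `genome = list(chrom_lengths = c(chr5 = 5e5))`.
#' @return nested list of class `msy_config`.
#' @export
msy_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    genome = list(
      chrom_lengths = c(chr5 = 1e6, chr1 = 7e5, chr2 = 5e5),
      msy_chrom = "chr5", msy_interval = c(3e5, 6e5),
      n_gametolog_genes = 14, n_autosomal_genes = 10,
      gene_length = 300, gc = 0.4),
    clock = list(true_age = 116, rate = 9e-4, calibration = c(OUT1 = 184.9)),
    reads = list(dna_depth = 20, rna_depth = 30, dna_read_length = 125,
                 rna_read_length = 100, error_rate = 0),
    subtraction = list(k = 25, min_contig_len = 200, identity = 0.99,
                       male_depth_window = c(4, 14), female_depth_max = 0),
    coverage = list(bin_size = 1e5, band = c(0.35, 0.65), min_bins = 3,
                    max_gap = 1),
    pairing = list(identity_window = c(0.90, 0.99)),
    dating = list(n_bootstrap = 100),
    climate = list(n_row = 25, n_col = 25, n_tsd = 101, n_gsd = 99,
                   tsd_mean = 27, tsd_sd = 4, gsd_mean = 22, gsd_sd = 5,
                   n_focal = 1, focal_offset_sd = -3),
    markers = list(n_msy = 4, n_autosomal = 1, n_unmapped = 4,
                   max_mismatch_rate = 0.05),
    stages = list(simulate = TRUE, subtract = TRUE, assemble = TRUE,
                  classify = TRUE, scan = TRUE, pair = TRUE, date = TRUE,
                  climate = TRUE, markers = TRUE),
    write_reads = FALSE)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(over[[nm]])))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_lists(defaults, list(...))
  structure(cfg, class = "msy_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys override [msy_config()]
#'   defaults.
#' @return an `msy_config`.
#' @export
read_msy_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML sequences arrive as lists; numeric-vector-valued fields need
  # flattening (unnamed sequences everywhere, named maps only where the
  # config holds a named numeric vector)
  flatten_unnamed <- function(x) {
    if (is.list(x) && length(x) > 0 && is.null(names(x)) &&
        all(vapply(x, is.numeric, logical(1))) && all(lengths(x) == 1))
      return(unlist(x))
    if (is.list(x)) return(lapply(x, flatten_unnamed))
    x
  }
  raw <- lapply(raw, flatten_unnamed)
  for (fld in list(c("genome", "chrom_lengths"), c("clock", "calibration"))) {
    v <- raw[[fld[1]]][[fld[2]]]
    if (is.list(v)) raw[[fld[1]]][[fld[2]]] <- unlist(v)
  }
  seed <- raw$seed %||% 1L
  raw$seed <- NULL
  do.call(msy_config, c(list(seed = seed), raw))
}

stage_seed <- function(cfg, offset) (cfg$seed * 1000L + offset) %% 2147483647L

#' Run the full MSY discovery pipeline
#'
#' Executes the stages in dependency order — simulate, subtract, assemble,
#' classify, scan, pair, date, climate, markers — and aggregates a
#' machine-readable report: retained transcript count, the detected MSY
#' interval and its distance to the planted truth, gametolog pair count and
#' synteny, the calibrated XY age with bootstrap CI, focal climate z-scores,
#' and the marker enrichment p-value. Re-running with the same config
#' reproduces the report bit-for-bit.
#'
#' @param config an [msy_config()].
#' @param outdir optional output directory for stage artifacts
#'   (FASTA/TSV/BED/CSV) and `report.json`.
#' @param quiet suppress stage progress messages.
#' @return the report, a list of class `msy_report`.
#' @export
run_msy_pipeline <- function(config = msy_config(), outdir = NULL,
                             quiet = FALSE) {
  stopifnot(inherits(config, "msy_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  on_stage <- function(s) isTRUE(config$stages[[s]])
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages_run = character(0))
  art <- list()

  if (on_stage("simulate")) {
    say("stage simulate: genome, reads, climate, markers")
    clock <- clock_sim_spec(true_age = config$clock$true_age,
                            rate = config$clock$rate,
                            calibration = config$clock$calibration,
                            seed = stage_seed(config, 1L))
    gspec <- genome_spec(chrom_lengths = config$genome$chrom_lengths,
                         msy_chrom = config$genome$msy_chrom,
                         msy_interval = config$genome$msy_interval,
                         n_gametolog_genes = config$genome$n_gametolog_genes,
                         n_autosomal_genes = config$genome$n_autosomal_genes,
                         gene_length = config$genome$gene_length,
                         gc = config$genome$gc, clock = clock,
                         min_msy_len = config$coverage$bin_size,
                         seed = stage_seed(config, 2L))
    art$genome <- simulate_genome(gspec)
    rd <- config$reads
    art$male_dna <- simulate_reads(art$genome, "male", "DNA",
                                   depth = rd$dna_depth,
                                   read_length = rd$dna_read_length,
                                   error_rate = rd$error_rate,
                                   seed = stage_seed(config, 3L))
    art$female_dna <- simulate_reads(art$genome, "female", "DNA",
                                     depth = rd$dna_depth,
                                     read_length = rd$dna_read_length,
                                     error_rate = rd$error_rate,
                                     seed = stage_seed(config, 4L))
    art$male_rna <- simulate_reads(art$genome, "male", "RNA",
                                   depth = rd$rna_depth,
                                   read_length = rd$rna_read_length,
                                   error_rate = rd$error_rate,
                                   seed = stage_seed(config, 5L))
    cl <- config$climate
    art$climate <- simulate_climate(climate_sim_spec(
      n_row = cl$n_row, n_col = cl$n_col, n_tsd = cl$n_tsd, n_gsd = cl$n_gsd,
      tsd_mean = cl$tsd_mean, tsd_sd = cl$tsd_sd, gsd_mean = cl$gsd_mean,
      gsd_sd = cl$gsd_sd, n_focal = cl$n_focal,
      focal_offset_sd = cl$focal_offset_sd, seed = stage_seed(config, 6L)))
    mk <- config$markers
    art$markers <- simulate_markers(art$genome, n_msy = mk$n_msy,
                                    n_autosomal = mk$n_autosomal,
                                    n_unmapped = mk$n_unmapped,
                                    seed = stage_seed(config, 7L))
    report$stages_run <- c(report$stages_run, "simulate")
    report$genome <- list(
      chrom_lengths = as.list(config$genome$chrom_lengths),
      msy_truth = if (is.null(art$genome$msy)) NULL else
        as.list(art$genome$msy),
      n_gametolog_genes = sum(art$genome$genes$type == "gametolog"))
    report$reads <- list(n_male_dna = nrow(art$male_dna),
                         n_female_dna = nrow(art$female_dna),
                         n_male_rna = nrow(art$male_rna))
    if (!is.null(outdir)) {
      write_genome(art$genome, file.path(outdir, "genome"))
      write_climate(art$climate, file.path(outdir, "climate"))
      write_fasta(setNames(art$markers$seq, art$markers$id),
                  file.path(outdir, "markers.fasta"))
      if (isTRUE(config$write_reads)) {
        write_reads_fastq(art$male_dna, file.path(outdir, "male_dna.fastq"))
        write_reads_fastq(art$female_dna, file.path(outdir, "female_dna.fastq"))
        write_reads_fastq(art$male_rna, file.path(outdir, "male_rna.fastq"))
      }
    }
  }

  if (on_stage("subtract") && !is.null(art$genome)) {
    say("stage subtract: k-mer filtering of male RNA")
    art$female_tx <- female_transcriptome(art$genome)
    idx <- build_kmer_index(art$female_tx, k = config$subtraction$k)
    art$retained_reads <- subtract_reads(art$male_rna, idx)
    report$stages_run <- c(report$stages_run, "subtract")
    report$subtraction <- list(
      n_input = attr(art$retained_reads, "n_input"),
      n_removed = attr(art$retained_reads, "n_removed"),
      n_retained = nrow(art$retained_reads))
  }

  if (on_stage("assemble") && !is.null(art$retained_reads)) {
    say("stage assemble: unitig assembly of retained reads")
    art$contigs <- assemble_candidates(art$retained_reads,
                                       k = config$subtraction$k,
                                       min_len = config$subtraction$min_contig_len)
    report$stages_run <- c(report$stages_run, "assemble")
    report$assembly <- list(n_contigs = nrow(art$contigs))
    if (!is.null(outdir) && nrow(art$contigs) > 0)
      write_fasta(art$contigs, file.path(outdir, "candidate_contigs.fasta"))
  }

  if (on_stage("classify") && !is.null(art$contigs) && nrow(art$contigs) > 0) {
    say("stage classify: sexed genomic depth filter")
    art$classified <- classify_by_genomic_coverage(
      art$contigs, art$male_dna, art$female_dna,
      identity = config$subtraction$identity,
      male_window = config$subtraction$male_depth_window,
      female_max = config$subtraction$female_depth_max,
      k = config$subtraction$k)
    art$candidates <- dplyr::filter(art$classified, .data$verdict == "retained")
    report$stages_run <- c(report$stages_run, "classify")
    report$classification <- list(
      n_retained = nrow(art$candidates),
      verdicts = as.list(table(art$classified$verdict)))
    if (!is.null(outdir))
      utils::write.table(dplyr::select(art$classified, -"seq"),
                         file.path(outdir, "classification.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  if (on_stage("scan") && !is.null(art$male_dna)) {
    say("stage scan: binned coverage ratio")
    art$profile <- coverage_profile(art$male_dna, art$female_dna,
                                    config$genome$chrom_lengths,
                                    bin_size = config$coverage$bin_size)
    art$calls <- detect_half_coverage(art$profile,
                                      band = config$coverage$band,
                                      min_bins = config$coverage$min_bins,
                                      max_gap = config$coverage$max_gap)
    report$stages_run <- c(report$stages_run, "scan")
    report$coverage <- list(n_calls = nrow(art$calls),
                            calls = lapply(seq_len(nrow(art$calls)), function(i)
                              as.list(art$calls[i, ])))
    if (!is.null(art$genome$msy) && nrow(art$calls) > 0) {
      on_chrom <- dplyr::filter(art$calls, .data$chrom == art$genome$msy$chrom)
      if (nrow(on_chrom) > 0)
        report$coverage$boundary_error_bins <- msy_boundary_error(
          on_chrom[1, ], art$genome$msy, config$coverage$bin_size)
    }
    if (!is.null(outdir)) {
      utils::write.table(as_tibble(art$profile),
                         file.path(outdir, "coverage_bins.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(art$calls, file.path(outdir, "msy_calls.bed"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }

  if (on_stage("pair") && !is.null(art$candidates) &&
      nrow(art$candidates) > 0) {
    say("stage pair: X gametolog search")
    art$pairs <- pair_gametologs(art$candidates, art$female_tx,
                                 window = config$pairing$identity_window)
    ann <- dplyr::transmute(art$genome$genes,
                            id = paste0(.data$gene_id, "_X"),
                            chrom = .data$chrom, start = .data$start,
                            end = .data$end)
    call1 <- if (!is.null(art$calls) && nrow(art$calls) > 0)
      art$calls[1, ] else NULL
    art$synteny <- synteny_check(art$pairs, ann, msy_call = call1)
    report$stages_run <- c(report$stages_run, "pair")
    report$pairing <- list(
      n_pairs = nrow(art$pairs),
      identity_range = if (nrow(art$pairs) > 0)
        c(min(art$pairs$identity), max(art$pairs$identity)) else NULL,
      synteny = if (nrow(art$synteny) > 0) as.list(art$synteny) else NULL)
    if (!is.null(outdir))
      utils::write.table(art$pairs, file.path(outdir, "gametolog_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (on_stage("date") && !is.null(art$pairs) && nrow(art$pairs) > 0) {
    say("stage date: NG86 dS dating with bootstrap")
    genes <- art$genome$genes
    out_cols <- grep("^out_", names(genes), value = TRUE)
    alns <- list()
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1,
                                                       baseOnly = TRUE)
    for (i in seq_len(nrow(art$pairs))) {
      pr <- art$pairs[i, ]
      gene_id <- sub("_X$", "", pr$x_id)
      g <- genes[genes$gene_id == gene_id, ]
      if (nrow(g) != 1) next
      yseq <- art$candidates$seq[art$candidates$id == pr$y_id]
      if (pr$orientation == "-") yseq <- revcomp(yseq)
      # place the (possibly end-trimmed) contig inside the X CDS to recover
      # the reading frame, then cut all taxa to the shared codon extent
      pa <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(yseq),
        subject = Biostrings::DNAString(g$x_seq),
        type = "global-local", substitutionMatrix = submat,
        gapOpening = 20, gapExtension = 2)
      o <- Biostrings::start(Biostrings::subject(pa)) - 1L  # 0-based offset
      lead <- (3L - (o %% 3L)) %% 3L
      n_cod <- (nchar(yseq) - lead) %/% 3L
      if (n_cod < 50) next
      yf <- substr(yseq, 1L + lead, lead + 3L * n_cod)
      x0 <- o + lead
      cut <- function(s) substr(s, x0 + 1L, x0 + 3L * n_cod)
      cds <- c(Y = yf, X = cut(g$x_seq),
               setNames(vapply(as.character(g[1, out_cols]), cut,
                               character(1), USE.NAMES = FALSE),
                        sub("^out_", "", out_cols)))
      alns[[gene_id]] <- align_codons(cds)
    }
    if (length(alns) > 0) {
      taxa <- alns[[1]]$id
      nwk <- "(X,Y)"
      for (tx in setdiff(taxa, c("X", "Y"))) nwk <- sprintf("(%s,%s)", nwk, tx)
      topo <- ape::read.tree(text = paste0(nwk, ";"))
      art$ds_tree <- concatenate_and_tree(alns, topo)
      art$age <- bootstrap_age(art$ds_tree, config$clock$calibration,
                               n = config$dating$n_bootstrap,
                               seed = stage_seed(config, 8L))
      report$stages_run <- c(report$stages_run, "date")
      report$dating <- list(
        n_genes = length(alns),
        n_codons = nchar(art$ds_tree$concatenation$seq[1]) / 3,
        ds_xy = art$age$ds_xy, rate = art$age$rate,
        age_myr = art$age$age, ci_lower = art$age$lower,
        ci_upper = art$age$upper, n_bootstrap = art$age$n_bootstrap,
        true_age_myr = config$clock$true_age)
      if (!is.null(outdir)) {
        ape::write.tree(art$ds_tree$tree, file.path(outdir, "ds_tree.nwk"))
        jsonlite::write_json(report$dating, file.path(outdir, "age_estimate.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }

  if (on_stage("climate") && !is.null(art$climate)) {
    say("stage climate: breeding-season temperatures and outlier scores")
    sp <- species_breeding_temperatures(art$climate$grid, art$climate$species)
    cohort <- dplyr::filter(sp, .data$system %in% c("TSD", "GSD"))
    art$classes <- class_distributions(cohort)
    focal <- dplyr::filter(sp, .data$system == "focal")
    report$stages_run <- c(report$stages_run, "climate")
    report$climate <- list(
      class_stats = lapply(seq_len(nrow(art$classes$stats)), function(i)
        as.list(art$classes$stats[i, ])))
    if (nrow(focal) > 0) {
      art$outliers <- bind_rows(
        outlier_score(focal, art$classes, reference = "TSD"),
        outlier_score(focal, art$classes, reference = "GSD"))
      report$climate$focal <- lapply(seq_len(nrow(art$outliers)), function(i)
        as.list(art$outliers[i, ]))
    }
    if (!is.null(outdir))
      utils::write.csv(dplyr::select(sp, -"months", -"cells"),
                       file.path(outdir, "species_temperatures.csv"),
                       row.names = FALSE)
  }

  if (on_stage("markers") && !is.null(art$markers)) {
    say("stage markers: mapping and MSY enrichment")
    art$marker_hits <- map_markers(art$markers, art$genome,
                                   max_mismatch_rate = config$markers$max_mismatch_rate)
    msy_iv <- if (!is.null(art$calls) && nrow(art$calls) > 0) art$calls[1, ]
      else art$genome$msy
    report$stages_run <- c(report$stages_run, "markers")
    report$markers <- list(status = as.list(table(art$marker_hits$status)))
    if (!is.null(msy_iv) && any(art$marker_hits$status == "unique")) {
      art$enrichment <- msy_enrichment(art$marker_hits, msy_iv,
                                       config$genome$chrom_lengths,
                                       bin_size = config$coverage$bin_size)
      report$markers$enrichment <- as.list(as_tibble(art$enrichment))
    }
    if (!is.null(outdir))
      utils::write.table(art$marker_hits, file.path(outdir, "marker_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- structure(report, class = "msy_report")
  if (!is.null(outdir)) write_msy_report(report, file.path(outdir, "report.json"))
  attr(report, "artifacts") <- art
  report
}

#' Write a pipeline report as canonical JSON
#'
#' @param report an `msy_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_msy_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.msy_report <- function(x, ...) {
  cat("MSY pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  stages: ", paste(x$stages_run, collapse = ", "), "\n", sep = "")
  if (!is.null(x$classification))
    cat(sprintf("  candidate Y transcripts retained: %d\n",
                x$classification$n_retained))
  if (!is.null(x$coverage) && x$coverage$n_calls > 0) {
    cl <- x$coverage$calls[[1]]
    cat(sprintf("  MSY call: %s:%d-%d (mean ratio %.2f)\n", cl$chrom,
                cl$start, cl$end, cl$mean_ratio))
  }
  if (!is.null(x$pairing))
    cat(sprintf("  gametolog pairs: %d\n", x$pairing$n_pairs))
  if (!is.null(x$dating))
    cat(sprintf("  XY age: %.1f Myr (95%% CI %.2f-%.2f)\n",
                x$dating$age_myr, x$dating$ci_lower, x$dating$ci_upper))
  if (!is.null(x$markers$enrichment))
    cat(sprintf("  marker enrichment p = %.4g\n",
                x$markers$enrichment$p_value))
  invisible(x)
}
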