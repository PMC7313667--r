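#' Binned read depth along chromosomes
#'
#' Tiles each chromosome with 0-based half-open bins (the last bin may be
#' short) and computes per-bin mean depth as total read-base overlap divided
#' by the bin width. Unplaced reads (`chrom` NA) are ignored.
#'
#' @param reads placed reads: tibble with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [simulate_reads()] or a placed-read TSV.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param bin_size bin width in bp (default 100,000).
#' @return tibble with `chrom`, `bin`, `start`, `end`, `depth`.
#' @export
bin_depth <- function(reads, chrom_lengths, bin_size = 1e5) {
  stopifnot(is.data.frame(reads), all(c("chrom", "start", "end") %in% names(reads)),
            !is.null(names(chrom_lengths)), bin_size > 0)
  bins <- dplyr::bind_rows(lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    n <- ceiling(L / bin_size)
    tibble(chrom = ch, bin = seq_len(n) - 1L,
           start = (seq_len(n) - 1) * bin_size,
           end = pmin(seq_len(n) * bin_size, L))
  }))
  rd <- dplyr::filter(reads, !is.na(.data$chrom))
  if (nrow(rd) == 0) {
    bins$depth <- 0
    return(bins)
  }
  dt <- data.table::data.table(chrom = rd$chrom, start = rd$start, end = rd$end)
  dt <- dt[chrom %in% names(chrom_lengths)]
  dt[, b1 := start %/% bin_size]
  dt[, b2 := (end - 1) %/% bin_size]
  simple <- dt[b1 == b2, list(bases = sum(end - start)), by = list(chrom, bin = b1)]
  span <- dt[b1 != b2]
  if (nrow(span) > 0) {
    span <- span[, list(bin = seq(b1, b2)), by = list(chrom, start, end, row = seq_len(nrow(span)))]
    span[, ov := pmin(end, (bin + 1) * bin_size) - pmax(start, bin * bin_size)]
    span <- span[, list(bases = sum(ov)), by = list(chrom, bin)]
  }
  agg <- data.table::rbindlist(list(simple,
                                    if (nrow(span) > 0) span else NULL))
  agg <- agg[, list(bases = sum(bases)), by = list(chrom, bin)]
  out <- dplyr::left_join(bins, as_tibble(agg), by = c("chrom", "bin"))
  out$bases[is.na(out$bases)] <- 0
  out$depth <- out$bases / (out$end - out$start)
  dplyr::select(out, -"bases")
}

#' Male/female coverage profile with normalized depth ratio
#'
#' Joins male and female binned depth and computes the normalized ratio
#' `r = (male / median(male)) / (female / median(female))`, where medians
#' are genome-wide per-sex bin medians (so autosomal background sits at
#' r = 1 regardless of library size). Bins with zero female depth get an
#' `NA` ratio and are flagged.
#'
#' @param male_reads,female_reads placed read tibbles (see [bin_depth()]).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param bin_size bin width in bp.
#' @return tibble of class `msy_coverage_profile` with `chrom`, `bin`,
#'   `start`, `end`, `male_depth`, `female_depth`, `ratio`.
#' @export
coverage_profile <- function(male_reads, female_reads, chrom_lengths,
                             bin_size = 1e5) {
  m <- bin_depth(male_reads, chrom_lengths, bin_size)
  f <- bin_depth(female_reads, chrom_lengths, bin_size)
  out <- dplyr::rename(m, male_depth = "depth")
  out$female_depth <- f$depth
  med_m <- median(out$male_depth)
  med_f <- median(out$female_depth)
  if (med_m <= 0 || med_f <= 0) {
    warn("zero median depth in one sex; ratios undefined")
    out$ratio <- NA_real_
  } else {
    out$ratio <- ifelse(out$female_depth > 0,
                        (out$male_depth / med_m) / (out$female_depth / med_f),
                        NA_real_)
  }
  attr(out, "bin_size") <- bin_size
  class(out) <- c("msy_coverage_profile", class(out))
  out
}

#' Detect half-coverage (hemizygous) segments
#'
#' Segments each chromosome into maximal runs of consecutive bins whose
#' normalized male:female ratio falls inside the half-coverage acceptance
#' band, allowing up to `max_gap` off-band bins between in-band runs. Runs
#' with at least `min_bins` in-band bins are reported as MSY calls;
#' autosomal background (ratio near 1) is never called.
#'
#' @param profile an `msy_coverage_profile` (or tibble with `chrom`, `bin`,
#'   `start`, `end`, `ratio`).
#' @param band acceptance band around 0.5 (default `c(0.35, 0.65)`,
#'   tolerant of sampling noise at 10-20x depth).
#' @param min_bins minimum number of in-band bins per call.
#' @param max_gap maximum off-band bins bridged inside a call.
#' @return tibble of class `msy_calls`: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_ratio`.
#' @export
detect_half_coverage <- function(profile, band = c(0.35, 0.65), min_bins = 3,
                                 max_gap = 1) {
  stopifnot(is.data.frame(profile),
            all(c("chrom", "bin", "start", "end", "ratio") %in% names(profile)),
            length(band) == 2, band[1] < band[2])
  empty <- tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  n_bins = integer(0), mean_ratio = numeric(0))
  class(empty) <- c("msy_calls", class(empty))
  if (all(is.na(profile$ratio))) {
    warn("all ratios undefined (zero female depth everywhere?); no calls")
    return(empty)
  }
  calls <- list()
  for (ch in unique(profile$chrom)) {
    p <- dplyr::arrange(dplyr::filter(profile, .data$chrom == ch), .data$bin)
    inband <- which(!is.na(p$ratio) & p$ratio >= band[1] & p$ratio <= band[2])
    if (length(inband) == 0) next
    grp <- cumsum(c(1, diff(inband) > max_gap + 1))
    for (g in unique(grp)) {
      idx <- inband[grp == g]
      if (length(idx) < min_bins) next
      calls[[length(calls) + 1]] <- tibble(
        chrom = ch, start = p$start[min(idx)], end = p$end[max(idx)],
        n_bins = length(idx), mean_ratio = mean(p$ratio[idx]))
    }
  }
  out <- if (length(calls) == 0) empty else bind_rows(calls)
  class(out) <- c("msy_calls", setdiff(class(out), "msy_calls"))
  out
}

#' Boundary error of an MSY call against a known interval, in bins
#'
#' @param call one-row tibble with `chrom`, `start`, `end`.
#' @param truth one-row tibble with `chrom`, `start`, `end`.
#' @param bin_size bin width used for the scan.
#' @return maximum of the start and end discrepancies, in bins (`Inf` if
#'   chromosomes differ).
#' @export
msy_boundary_error <- function(call, truth, bin_size = 1e5) {
  if (nrow(call) != 1 || nrow(truth) != 1 || call$chrom != truth$chrom)
    return(Inf)
  max(abs(call$start - truth$start), abs(call$end - truth$end)) / bin_size
}

#' @export
autoplot.msy_coverage_profile <- function(object, band = c(0.35, 0.65),
                                          calls = NULL, ...) {
  df <- as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$ratio)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = band[1],
                      ymax = band[2], alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = "normalized male:female depth ratio") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0)
    p <- p + ggplot2::geom_segment(
      data = calls,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6),
      y = 0.5, yend = 0.5, colour = "firebrick", linewidth = 1.5,
      inherit.aes = FALSE)
  p
}
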