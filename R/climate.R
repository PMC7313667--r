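#' Breeding-season ambient temperature of one species
#'
#' The median over the multiset of cell-month temperatures: every occupied
#' grid cell crossed with every breeding month (an even-cardinality median
#' is the mean of the central pair, as `stats::median` computes). Missing
#' cell-month values are excluded with a warning; if nothing remains, an
#' error is thrown. The mean is available as an option, since "average"
#' summaries of range temperatures are also in use.
#'
#' @param grid long-form climate grid: tibble with `cell`, `month`,
#'   `temp_c` (one value per cell-month).
#' @param cells integer vector of occupied cell ids.
#' @param months breeding months, subset of 1..12, non-empty.
#' @param stat `"median"` (default) or `"mean"`.
#' @return temperature in degrees C (length-1 numeric).
#' @export
species_breeding_temperature <- function(grid, cells, months,
                                         stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(grid), all(c("cell", "month", "temp_c") %in% names(grid)))
  if (length(months) == 0 || !all(months %in% 1:12))
    abort("breeding months must be a non-empty subset of 1..12")
  if (length(cells) == 0) abort("species must occupy at least one cell")
  want <- expand.grid(cell = cells, month = months)
  vals <- dplyr::inner_join(as_tibble(want), grid, by = c("cell", "month"))$temp_c
  n_expected <- length(cells) * length(months)
  if (length(vals) < n_expected || anyNA(vals)) {
    warn(sprintf("%d of %d cell-month values missing; excluded",
                 n_expected - sum(!is.na(vals)), n_expected))
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0) abort("no cell-month temperature values available")
  if (stat == "median") median(vals) else mean(vals)
}

#' Breeding-season temperatures for a species table
#'
#' @param grid long-form climate grid (see
#'   [species_breeding_temperature()]).
#' @param species tibble with `species`, `system`, and list-columns
#'   `cells` and `months` (as produced by [simulate_climate()]).
#' @inheritParams species_breeding_temperature
#' @return the species tibble with a `temp_c` column appended.
#' @export
species_breeding_temperatures <- function(grid, species,
                                          stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(species),
            all(c("species", "cells", "months") %in% names(species)))
  species$temp_c <- vapply(seq_len(nrow(species)), function(i)
    species_breeding_temperature(grid, species$cells[[i]],
                                 species$months[[i]], stat = stat),
    numeric(1))
  as_tibble(species)
}

#' Per-class temperature distributions
#'
#' Sample mean and SD (n - 1 denominator) of breeding-season temperature per
#' sex-determination class, plus a 1-degree-binned histogram table for
#' plotting. Classes with fewer than two species are dropped with a warning
#' (no SD is defined for them).
#'
#' @param records tibble with `species`, `system`, `temp_c`. Systems other
#'   than `"TSD"`/`"GSD"` (e.g. focal species under test) are ignored here;
#'   score them with [outlier_score()].
#' @return object of class `msy_climate_classes`: list with `stats`
#'   (tibble `system`, `n`, `mean`, `sd`) and `histogram` (tibble `system`,
#'   `bin_mid`, `count`).
#' @export
class_distributions <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("system", "temp_c") %in% names(records)))
  rec <- dplyr::filter(records, .data$system %in% c("TSD", "GSD"))
  if (nrow(rec) == 0) abort("no TSD/GSD records to summarise")
  cnt <- dplyr::count(rec, .data$system)
  small <- cnt$system[cnt$n < 2]
  if (length(small) > 0) {
    warn(paste0("dropping class(es) with < 2 species: ",
                paste(small, collapse = ", ")))
    rec <- dplyr::filter(rec, !.data$system %in% small)
  }
  if (nrow(rec) == 0) abort("no class with >= 2 species")
  stats <- rec |>
    group_by(.data$system) |>
    summarise(n = dplyr::n(), mean = mean(.data$temp_c),
              sd = sd(.data$temp_c), .groups = "drop")
  hist <- rec |>
    mutate(bin_mid = floor(.data$temp_c) + 0.5) |>
    dplyr::count(.data$system, .data$bin_mid, name = "count")
  structure(list(stats = stats, histogram = hist),
            class = "msy_climate_classes")
}

#' @export
print.msy_climate_classes <- function(x, ...) {
  print(x$stats)
  invisible(x)
}

#' Score species as climate outliers against a reference class
#'
#' Standard score `z = (x - mean) / SD` against the reference class'
#' realized distribution; `|z| >= threshold` flags an outlier. A viviparous
#' skink breeding at 15 C scores near -3 against a TSD cohort centred at
#' 27 +/- 4, while sitting comfortably inside the GSD distribution.
#'
#' @param x temperatures to score (numeric vector), or a tibble with
#'   `species` and `temp_c`.
#' @param classes an `msy_climate_classes` from [class_distributions()].
#' @param reference reference class, `"TSD"` or `"GSD"`.
#' @param threshold outlier flag threshold in SD units (default 3).
#' @return tibble with `species`, `temp_c`, `reference`, `class_mean`,
#'   `class_sd`, `z`, `outlier`.
#' @export
outlier_score <- function(x, classes, reference = "TSD", threshold = 3) {
  stopifnot(inherits(classes, "msy_climate_classes"))
  st <- dplyr::filter(classes$stats, .data$system == reference)
  if (nrow(st) != 1) abort(sprintf("no class stats for '%s'", reference))
  if (st$sd <= 0) abort("reference class SD must be positive")
  if (is.data.frame(x)) {
    sp <- x$species %||% paste0("species_", seq_len(nrow(x)))
    temps <- x$temp_c
  } else {
    sp <- names(x) %||% paste0("species_", seq_along(x))
    temps <- unname(x)
  }
  z <- (temps - st$mean) / st$sd
  # species sitting exactly on the threshold are outliers; the epsilon
  # guards the comparison against floating-point representation error
  tibble(species = sp, temp_c = temps, reference = reference,
         class_mean = st$mean, class_sd = st$sd, z = z,
         outlier = abs(z) >= threshold - 1e-8)
}

#' @export
autoplot.msy_climate_classes <- function(object, focal = NULL, ...) {
  p <- ggplot2::ggplot(object$histogram,
                       ggplot2::aes(x = .data$bin_mid, y = .data$count,
                                    fill = .data$system)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = 1) +
    ggplot2::labs(x = "breeding-season temperature (°C)",
                  y = "species", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(focal) && nrow(focal) > 0)
    p <- p + ggplot2::geom_vline(data = focal,
                                 ggplot2::aes(xintercept = .data$temp_c),
                                 colour = "firebrick", linetype = "dashed")
  p
}
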