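#' Specification for the synthetic climate cohort
#'
#' Emulates a gridded monthly temperature surface plus a cohort of reptile
#' species with known sex-determination systems: TSD (temperature-dependent)
#' species breed at temperatures drawn from one normal distribution, GSD
#' (genotypic) species from another, and optional focal species are planted
#' at a fixed number of sample standard deviations below the realized TSD
#' class mean (the outlier-recovery truth). Focal species are not members of
#' either reference class, mirroring how a species under test is scored
#' against cohorts it does not belong to.
#'
#' @param n_row,n_col grid dimensions.
#' @param n_tsd,n_gsd cohort sizes (defaults 101 and 99).
#' @param tsd_mean,tsd_sd,gsd_mean,gsd_sd class temperature distributions
#'   (degrees C); defaults place the TSD class near 27 +/- 4 and the GSD
#'   class near 22 +/- 5 so a 15 C breeder is a 3-SD TSD outlier but
#'   unremarkable under GSD.
#' @param within_sd within-range cell-to-cell/month-to-month SD (degrees C).
#' @param max_cells maximum range size in grid cells (ranges are 1 to
#'   `max_cells` cells, disjoint across species).
#' @param n_focal number of planted focal outlier species.
#' @param focal_offset_sd focal placement in TSD sample SD units (default -3).
#' @param seed integer seed.
#' @return an object of class `msy_climate_spec`.
#' @export
climate_sim_spec <- function(n_row = 25, n_col = 25, n_tsd = 101, n_gsd = 99,
                             tsd_mean = 27, tsd_sd = 4, gsd_mean = 22,
                             gsd_sd = 5, within_sd = 1.5, max_cells = 3,
                             n_focal = 1, focal_offset_sd = -3, seed = 1L) {
  stopifnot(n_row > 0, n_col > 0, n_tsd >= 2, n_gsd >= 2, tsd_sd > 0,
            gsd_sd > 0, within_sd >= 0, max_cells >= 1, n_focal >= 0)
  if (n_row * n_col < (n_tsd + n_gsd + n_focal) * max_cells)
    abort("grid too small for disjoint species ranges; increase n_row/n_col")
  structure(list(n_row = n_row, n_col = n_col, n_tsd = n_tsd, n_gsd = n_gsd,
                 tsd_mean = tsd_mean, tsd_sd = tsd_sd, gsd_mean = gsd_mean,
                 gsd_sd = gsd_sd, within_sd = within_sd,
                 max_cells = max_cells, n_focal = n_focal,
                 focal_offset_sd = focal_offset_sd, seed = as.integer(seed)),
            class = "msy_climate_spec")
}

#' Simulate a climate grid and species cohort with planted truth
#'
#' Each species gets a contiguous breeding season (2-5 months), a disjoint
#' set of grid cells, and cell-month temperatures drawn around its class
#' target; its true breeding-season temperature is recorded as the exact
#' median of the values it will be scored on. Focal species are planted at
#' `focal_offset_sd` sample SDs from the realized TSD cohort mean with
#' constant temperature over their range, so their truth is exact.
#'
#' @param spec a [climate_sim_spec()].
#' @return list of class `msy_climate_sim` with `grid` (tibble `row`, `col`,
#'   `month`, `temp_c`), `species` (tibble `species`, `system`, `months`
#'   and `cells` list-columns, `true_temp_c`), and `spec`.
#' @export
simulate_climate <- function(spec) {
  stopifnot(inherits(spec, "msy_climate_spec"))
  set.seed(spec$seed)
  n_cells <- spec$n_row * spec$n_col
  n_sp <- spec$n_tsd + spec$n_gsd + spec$n_focal
  systems <- c(rep("TSD", spec$n_tsd), rep("GSD", spec$n_gsd),
               rep("focal", spec$n_focal))
  names <- sprintf("%s_sp_%03d", tolower(systems),
                   stats::ave(seq_len(n_sp), systems, FUN = seq_along))
  targets <- c(rnorm(spec$n_tsd, spec$tsd_mean, spec$tsd_sd),
               rnorm(spec$n_gsd, spec$gsd_mean, spec$gsd_sd),
               rep(NA_real_, spec$n_focal))

  cell_pool <- sample.int(n_cells)
  cells_per <- sample.int(spec$max_cells, n_sp, replace = TRUE)
  offsets <- cumsum(c(0, cells_per[-n_sp]))
  cells <- lapply(seq_len(n_sp), function(i)
    sort(cell_pool[offsets[i] + seq_len(cells_per[i])]))
  season_len <- sample(2:5, n_sp, replace = TRUE)
  season_start <- sample.int(12, n_sp, replace = TRUE)
  months <- lapply(seq_len(n_sp), function(i)
    sort(((season_start[i] + seq_len(season_len[i]) - 2) %% 12) + 1))

  # base grid, then overwrite each species' range
  temp <- matrix(rnorm(n_cells * 12,
                       mean(c(spec$tsd_mean, spec$gsd_mean)), 6),
                 nrow = n_cells, ncol = 12)
  for (i in seq_len(n_sp)[systems != "focal"]) {
    temp[cells[[i]], ] <- rnorm(length(cells[[i]]) * 12, targets[i],
                                spec$within_sd)
  }
  truth <- vapply(seq_len(n_sp), function(i) {
    if (systems[i] == "focal") return(NA_real_)
    median(temp[cells[[i]], months[[i]]])
  }, numeric(1))

  if (spec$n_focal > 0) {
    tsd_truth <- truth[systems == "TSD"]
    focal_temp <- mean(tsd_truth) + spec$focal_offset_sd * sd(tsd_truth)
    for (i in which(systems == "focal")) {
      temp[cells[[i]], ] <- focal_temp
      truth[i] <- focal_temp
    }
  }

  grid <- tibble(
    cell = rep(seq_len(n_cells), 12),
    row = rep(rep(seq_len(spec$n_row), times = spec$n_col), 12),
    col = rep(rep(seq_len(spec$n_col), each = spec$n_row), 12),
    month = rep(1:12, each = n_cells),
    temp_c = as.vector(temp))
  species <- tibble(species = names, system = systems,
                    months = months, cells = cells, true_temp_c = truth)
  structure(list(grid = grid, species = species, spec = spec),
            class = "msy_climate_sim")
}

#' Write a climate simulation to CSV files
#'
#' The grid goes out long-form (`row`, `col`, `month`, `temp_c`); the
#' species table flattens months and cells into comma/semicolon-separated
#' strings.
#'
#' @param sim an `msy_climate_sim`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_climate <- function(sim, dir) {
  stopifnot(inherits(sim, "msy_climate_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$grid, file.path(dir, "climate_grid.csv"),
                   row.names = FALSE)
  sp <- sim$species
  flat <- tibble(species = sp$species, system = sp$system,
                 months = vapply(sp$months, paste, character(1), collapse = ","),
                 cells = vapply(sp$cells, paste, character(1), collapse = ";"),
                 true_temp_c = sp$true_temp_c)
  utils::write.csv(flat, file.path(dir, "species.csv"), row.names = FALSE)
  invisible(dir)
}
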