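#' Specification for the gametolog clock simulator
#'
#' Describes the true history a simulated XY gametolog pair evolves under:
#' the X and Y copies stop recombining `true_age` Myr ago and accumulate
#' synonymous substitutions independently at `rate` substitutions per
#' synonymous site per Myr; outgroup orthologs split from the X lineage at
#' the calibration ages.
#'
#' @param true_age XY split age in Myr (>= 0).
#' @param rate per-lineage synonymous substitution rate
#'   (substitutions/synonymous site/Myr, > 0).
#' @param calibration named numeric vector of outgroup divergence ages (Myr),
#'   all older than `true_age`; default the 184.9-Myr split used to calibrate
#'   skink gametologs.
#' @param seed integer seed.
#' @return an object of class `msy_clock_spec`.
#' @export
clock_sim_spec <- function(true_age = 116, rate = 9e-4,
                           calibration = c(OUT1 = 184.9), seed = 1L) {
  stopifnot(true_age >= 0, rate > 0, length(calibration) >= 1,
            !is.null(names(calibration)), all(calibration > 0))
  if (any(calibration <= true_age))
    abort("all calibration ages must exceed true_age (outgroups are older than the XY split)")
  structure(list(true_age = true_age, rate = rate,
                 calibration = calibration[order(calibration)],
                 seed = as.integer(seed)),
            class = "msy_clock_spec")
}

#' @export
print.msy_clock_spec <- function(x, ...) {
  cat(sprintf("clock simulation: XY split %.1f Myr, rate %.4g /syn site/Myr, calibrations: %s\n",
              x$true_age, x$rate,
              paste(sprintf("%s=%.1f", names(x$calibration), x$calibration),
                    collapse = ", ")))
  invisible(x)
}

# Random in-frame CDS of `n_codons` sense codons.
random_cds <- function(n_codons) {
  sense <- all_codons()[!is_stop_codon(all_codons())]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Evolve third codon positions for an expected `d` synonymous substitutions
# per synonymous site: each third position receives Poisson(d) substitution
# events, each to one of its three alternative bases chosen uniformly;
# events creating stop codons are redirected uniformly to a non-stop
# alternative (skipped if none exists). With a uniform per-position event
# rate the synonymous substitutions per synonymous site equal d and the
# per-position difference process is exactly Jukes-Cantor, which is what the
# NG86 correction inverts.
evolve_third_positions <- function(codons, d) {
  if (d <= 0 || length(codons) == 0) return(codons)
  n_events <- rpois(length(codons), d)
  for (i in which(n_events > 0)) {
    for (e in seq_len(n_events[i])) {
      cur <- codons[i]
      alt_bases <- setdiff(DNA_BASES, substr(cur, 3, 3))
      pick <- sample(alt_bases, 1)
      mut <- cur
      substr(mut, 3, 3) <- pick
      if (is_stop_codon(mut)) {
        ok <- alt_bases[vapply(alt_bases, function(b) {
          m <- cur; substr(m, 3, 3) <- b; !is_stop_codon(m)
        }, logical(1))]
        if (length(ok) == 0) next
        mut <- cur
        substr(mut, 3, 3) <- if (length(ok) == 1) ok else sample(ok, 1)
      }
      codons[i] <- mut
    }
  }
  codons
}

#' Simulate an XY gametolog pair with outgroup orthologs under a clock
#'
#' Draws a random ancestral CDS and evolves it down the rooted tree implied
#' by the spec: outgroups branch off at their calibration ages, the X and Y
#' copies split `true_age` Myr ago. Substitutions hit third codon positions
#' only, with stop codons rejected, so expected pairwise X-Y divergence is
#' `2 * true_age * rate` synonymous substitutions per synonymous site.
#'
#' @param clock an [clock_sim_spec()].
#' @param gene_length gene length in codons (>= 50 so dS is stable).
#' @return list of class `msy_gametolog_sim`: `sequences` (tibble `id`/`seq`
#'   for X, Y, and outgroups), `topology` (ape phylo), and `truth`
#'   (true age, rate, expected dS values).
#' @export
simulate_gametolog_pair <- function(clock, gene_length = 300) {
  stopifnot(inherits(clock, "msy_clock_spec"))
  if (gene_length < 50)
    abort("gene_length must be >= 50 codons for stable dS estimates")
  d_xy <- 2 * clock$true_age * clock$rate
  if (0.75 * (1 - exp(-4 * d_xy / 3)) >= 0.70)
    warn(sprintf(paste0("expected X-Y divergence (%.2f subs/site) is near ",
                        "NG86 saturation (ps >= 0.75)"), d_xy))
  set.seed(clock$seed)
  anc <- split_codons(random_cds(gene_length))
  # walk the caterpillar from the oldest calibration to the XY split
  ages <- sort(clock$calibration, decreasing = TRUE)
  trunk <- anc
  prev_age <- ages[[1]]
  out_seqs <- list()
  for (i in seq_along(ages)) {
    tx <- names(ages)[i]
    # trunk evolves from the previous split down to this one
    trunk <- evolve_third_positions(trunk, clock$rate * (prev_age - ages[[i]]))
    out_seqs[[tx]] <- evolve_third_positions(trunk, clock$rate * ages[[i]])
    prev_age <- ages[[i]]
  }
  trunk <- evolve_third_positions(trunk, clock$rate * (prev_age - clock$true_age))
  x_seq <- evolve_third_positions(trunk, clock$rate * clock$true_age)
  y_seq <- evolve_third_positions(trunk, clock$rate * clock$true_age)
  seqs <- tibble(
    id = c("X", "Y", names(ages)),
    seq = c(paste(x_seq, collapse = ""), paste(y_seq, collapse = ""),
            vapply(out_seqs[names(ages)], paste, character(1), collapse = "")))
  # rooted caterpillar topology ((X,Y), youngest out), next out, ...
  nwk <- "(X,Y)"
  for (tx in rev(names(ages))) nwk <- sprintf("(%s,%s)", nwk, tx)
  topology <- ape::read.tree(text = paste0(nwk, ";"))
  structure(list(
    sequences = seqs,
    topology = topology,
    truth = list(true_age = clock$true_age, rate = clock$rate,
                 expected_ds_xy = d_xy,
                 expected_ds_x_out = 2 * unname(clock$calibration) * clock$rate)),
    class = "msy_gametolog_sim")
}
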