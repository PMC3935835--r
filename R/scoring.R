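# The phenoseq scoring core: per-site mutation densities on GC vs AT
# sites, the expected mutational cross-section lambda of a gene or
# group, and the Poisson upper-tail score with Bonferroni correction.

#' Genome-wide per-site mutation densities on GC and AT sites
#'
#' The mutational-target null model assumes mutations fall uniformly
#' on sites of the same base class (chemical mutagens such as NTG are
#' strongly GC-biased, so the two classes are modelled separately):
#' `rho_gc` is the number of selected mutations whose reference base
#' is G or C divided by the number of G/C positions in the genome, and
#' `rho_at` likewise.
#'
#' `mode` selects which mutation class feeds the estimate: `"all"`
#' (default) uses every filtered variant -- the density of all
#' observed mutations over the whole genome -- while
#' `"nonsynonymous"` uses only variants with at least one
#' nonsynonymous CDS hit.  The default is deliberately the `"all"`
#' recipe: because nonsynonymous mutations can occur only inside
#' coding sequence while the site counts are genome-wide, the
#' `"nonsynonymous"` density under-estimates every unit's expected
#' count by roughly the non-coding genome fraction, which makes the
#' Poisson score anti-conservative; the `"all"` density instead
#' over-covers the nonsynonymous-only observed counts and yields
#' super-uniform null p-values (see the methods vignette).
#'
#' @param annotation a [annotate_variants()] result on the filtered
#'   calls.
#' @param genome the [phenoseq_genome()].
#' @param mode `"all"` or `"nonsynonymous"`.
#' @return list of class `site_densities`: `rho_gc`, `rho_at`,
#'   `n_mutations_used`, `mode`.
#' @export
estimate_densities <- function(annotation, genome,
                               mode = c("all", "nonsynonymous")) {
  mode <- match.arg(mode)
  if (genome$gc_count == 0 || genome$at_count == 0)
    stopf("genome has a zero GC or AT site count; densities undefined")
  v <- annotation$variants
  if (mode == "nonsynonymous") {
    ns_rows <- unique(annotation$hits$variant_row[
      annotation$hits$effect == "nonsynonymous"])
    v <- v[ns_rows, , drop = FALSE]
  }
  if (!nrow(v)) warnf("no mutations available for density estimation; densities are 0")
  n_gc <- sum(v$ref %in% c("G", "C"))
  n_at <- sum(v$ref %in% c("A", "T"))
  structure(list(rho_gc = n_gc / genome$gc_count,
                 rho_at = n_at / genome$at_count,
                 n_mutations_used = n_gc + n_at,
                 mode = mode),
            class = "site_densities")
}

#' @export
print.site_densities <- function(x, ...) {
  cat(sprintf("per-site mutation densities (%s mutations, n = %d): rho_gc = %.3g, rho_at = %.3g\n",
              x$mode, x$n_mutations_used, x$rho_gc, x$rho_at))
  invisible(x)
}

#' Expected mutational cross-section of a unit
#'
#' lambda = gc_sites * rho_gc + at_sites * rho_at: the expected number
#' of mutations falling in the unit under neutral mutagenesis, given
#' its base composition.  Additive over genes, so a group's lambda is
#' the sum of its members'.
#'
#' @param tallies `data.frame` with `gc_sites` and `at_sites` columns
#'   (from [tally_genes()] / [tally_groups()]).
#' @param densities a [estimate_densities()] result.
#' @return numeric vector of lambda values.
#' @export
cross_section <- function(tallies, densities) {
  tallies$gc_sites * densities$rho_gc + tallies$at_sites * densities$rho_at
}

#' Poisson upper-tail p-value
#'
#' P(X >= n_obs) for X ~ Poisson(lambda); the tail includes the
#' observed count, so `n_obs = 0` gives p = 1.
#'
#' @param n_obs observed mutation count(s).
#' @param lam expected count(s), must be positive.
#' @return p-value vector.
#' @export
poisson_pvalue <- function(n_obs, lam) {
  if (any(lam <= 0)) stopf("poisson_pvalue requires lambda > 0")
  if (any(n_obs < 0)) stopf("poisson_pvalue requires n_obs >= 0")
  stats::ppois(n_obs - 1, lam, lower.tail = FALSE)
}

#' Score genes or gene groups under the Poisson target model
#'
#' Only nonsynonymous counts feed the observed count.  Records are
#' ranked by raw p-value, ties broken by descending observed count
#' and then unit id, and Bonferroni-corrected by `n_tests` (which may
#' exceed the number of scored units, e.g. the size of the full group
#' database when only the groups that were hit are scored).
#'
#' @param tallies [tally_genes()] / [tally_groups()] output.
#' @param densities a [estimate_densities()] result.
#' @param n_tests Bonferroni correction factor; defaults to the number
#'   of units scored.
#' @return `data.frame` of class `phenoseq_scores`: `unit_id`,
#'   `n_obs`, `lam`, `p_raw`, `p_corr`, `rank`, ordered by rank.
#' @export
score_units <- function(tallies, densities, n_tests = nrow(tallies)) {
  lam <- cross_section(tallies, densities)
  p <- poisson_pvalue(tallies$ns, lam)
  out <- data.frame(unit_id = tallies$unit_id,
                    n_obs = tallies$ns, lam = lam,
                    p_raw = p, p_corr = pmin(1, p * n_tests),
                    stringsAsFactors = FALSE)
  ord <- order(out$p_raw, -out$n_obs, out$unit_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "mode") <- densities$mode
  attr(out, "n_tests") <- n_tests
  class(out) <- c("phenoseq_scores", "data.frame")
  out
}

#' @export
print.phenoseq_scores <- function(x, n = 10L, ...) {
  cat(sprintf("phenoseq scores: %d units, Bonferroni n = %d, density mode = %s\n",
              nrow(x), attr(x, "n_tests"), attr(x, "mode")))
  df <- as.data.frame(utils::head(x, n))
  df$lam <- signif(df$lam, 4)
  df$p_raw <- signif(df$p_raw, 3)
  df$p_corr <- signif(df$p_corr, 3)
  print(df, row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... %d more unit(s)\n", nrow(x) - n))
  invisible(x)
}
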