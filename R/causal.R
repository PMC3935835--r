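# Causal-mutation estimator: how many of a unit's mutations actually
# cause the phenotype, inferred from the excess nonsynonymous fraction.

#' Estimate the causal mutation fraction and count of a unit
#'
#' Assumes causal mutations are all nonsynonymous while non-causal
#' mutations follow the genome-wide background mixture, so the
#' observed nonsynonymous fraction `x = ns / (ns + syn)` of a unit is
#' the mixture `x = c + (1 - c) * f0` of causal fraction `c` against
#' background nonsynonymous fraction `f0`.  Inverting,
#' `c = (x - f0) / (1 - f0)`; the estimated causal count is `c * N`
#' rounded to the nearest integer (half away from zero).  Negative
#' estimates are clamped to 0 (the raw value is retained in
#' `c_raw`), and `x = 1` gives `c = 1`: every mutation estimated
#' causal.
#'
#' @param ns,syn nonsynonymous and synonymous counts of the unit(s);
#'   vectorised, `ns + syn >= 1`.
#' @param f0 genome-wide nonsynonymous fraction, in (0, 1); typically
#'   total nonsynonymous over total classified mutations of the
#'   filtered SNP set.
#' @param unit_id optional unit labels.
#' @return `data.frame`: `unit_id` (if given), `N`, `x`, `f0`,
#'   `c_raw`, `c` (clamped to `[0, 1]`), `n_causal`.
#' @export
estimate_causal <- function(ns, syn, f0, unit_id = NULL) {
  if (any(ns + syn < 1)) stopf("estimate_causal needs at least one mutation per unit")
  if (f0 <= 0 || f0 >= 1) stopf("f0 must lie strictly between 0 and 1")
  N <- ns + syn
  x <- ns / N
  c_raw <- (x - f0) / (1 - f0)
  cc <- pmin(1, pmax(0, c_raw))
  out <- data.frame(N = N, x = x, f0 = f0, c_raw = c_raw, c = cc,
                    n_causal = as.integer(round_half_up(cc * N)))
  if (!is.null(unit_id)) out <- cbind(data.frame(unit_id = unit_id,
                                                 stringsAsFactors = FALSE), out)
  out
}

#' Genome-wide nonsynonymous fraction from an annotation
#'
#' `f0` for [estimate_causal()]: nonsynonymous CDS hits over all
#' classified CDS hits of the (filtered) mutation set.
#'
#' @param annotation a [annotate_variants()] result.
#' @return scalar fraction.
#' @export
background_ns_fraction <- function(annotation) {
  ns <- sum(annotation$hits$effect == "nonsynonymous")
  tot <- nrow(annotation$hits)
  if (!tot) stopf("no classified CDS hits; background fraction undefined")
  ns / tot
}
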