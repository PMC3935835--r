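# Positive-selection evidence: one-tailed Fisher exact tests on
# nonsynonymous vs synonymous counts, per unit, cumulatively down a
# ranked pathway list, and with specified genes excluded.

#' One-tailed Fisher exact test for nonsynonymous excess
#'
#' Tests whether a set of mutations is more nonsynonymous-biased than
#' the genome-wide pool: the upper hypergeometric tail of observing at
#' least `ns_in` nonsynonymous among `ns_in + syn_in` draws from a
#' pool of `ns_tot` nonsynonymous and `syn_tot` synonymous mutations,
#' i.e. the one-tailed ("greater") Fisher exact p-value of the 2x2
#' table `[[ns_in, syn_in], [ns_tot - ns_in, syn_tot - syn_in]]`.
#'
#' @param ns_in,syn_in counts in the tested set.
#' @param ns_tot,syn_tot genome-wide totals (the tested set included).
#' @return p-value (vectorised over the arguments).
#' @export
fisher_ns_syn <- function(ns_in, syn_in, ns_tot, syn_tot) {
  if (any(c(ns_in, syn_in, ns_tot, syn_tot) < 0))
    stopf("counts must be nonnegative")
  if (any(ns_in > ns_tot) || any(syn_in > syn_tot))
    stopf("in-set counts exceed genome-wide totals")
  stats::phyper(ns_in - 1, ns_tot, syn_tot, ns_in + syn_in,
                lower.tail = FALSE)
}

ka_ks_like <- function(ns_in, syn_in, ns_tot, syn_tot) {
  ifelse(syn_in == 0, Inf, (ns_in / syn_in) / (ns_tot / syn_tot))
}

#' Cumulative positive-selection test down a ranked group list
#'
#' Result k tests the pooled nonsynonymous/synonymous counts of groups
#' 1..k against the genome-wide totals.  Two pooling modes:
#' `"union"` (default) pools each member gene's mutations once however
#' many of the listed groups contain it -- the natural bookkeeping
#' when nested groups (complex vs super-complex) appear in the same
#' ranking -- while `"sum"` adds per-group tallies so a shared gene
#' counts once per group.  No multiple-testing correction is applied:
#' the test is a single planned comparison on the ranked list.
#'
#' @param groups ranked [gene_groups()] table (resolved), best first.
#' @param gene_tallies [tally_genes()] output.
#' @param ns_tot,syn_tot genome-wide totals.
#' @param mode `"union"` or `"sum"`.
#' @param exclude gene ids whose mutations are dropped from the
#'   in-set counts (totals unchanged); unknown ids are ignored with a
#'   warning.
#' @return `data.frame`: `k`, `group_id` (the k-th group), `ns_in`,
#'   `syn_in`, `p`, `ka_ks_like`.
#' @export
cumulative_selection <- function(groups, gene_tallies, ns_tot, syn_tot,
                                 mode = c("union", "sum"),
                                 exclude = character()) {
  mode <- match.arg(mode)
  if (length(exclude)) {
    unknown <- setdiff(exclude, gene_tallies$unit_id)
    if (length(unknown))
      warnf("excluded gene(s) not found: %s", paste(unknown, collapse = ", "))
    gene_tallies <- gene_tallies[!(gene_tallies$unit_id %in% exclude), ,
                                 drop = FALSE]
  }
  idx <- stats::setNames(seq_len(nrow(gene_tallies)), gene_tallies$unit_id)
  count_set <- function(genes) {
    rows <- idx[genes]
    rows <- rows[!is.na(rows)]
    c(ns = sum(gene_tallies$ns[rows]), syn = sum(gene_tallies$syn[rows]))
  }
  n <- nrow(groups)
  ns_in <- syn_in <- integer(n)
  if (mode == "union") {
    for (k in seq_len(n)) {
      cs <- count_set(unique(unlist(groups$members[seq_len(k)])))
      ns_in[k] <- cs["ns"]; syn_in[k] <- cs["syn"]
    }
  } else {
    per <- t(vapply(groups$members, count_set, numeric(2)))
    ns_in <- cumsum(per[, "ns"]); syn_in <- cumsum(per[, "syn"])
  }
  data.frame(k = seq_len(n), group_id = groups$group_id,
             ns_in = ns_in, syn_in = syn_in,
             p = fisher_ns_syn(ns_in, syn_in, ns_tot, syn_tot),
             ka_ks_like = ka_ks_like(ns_in, syn_in, ns_tot, syn_tot),
             stringsAsFactors = FALSE)
}

#' Positive-selection test on a group set with genes excluded
#'
#' Pools the mutations of all member genes of the given groups
#' (union), drops the excluded genes' mutations from the in-set
#' counts (genome-wide totals unchanged), and applies
#' [fisher_ns_syn()].
#'
#' @inheritParams cumulative_selection
#' @param excluded_genes gene ids to drop.
#' @return one-row `data.frame`: `ns_in`, `syn_in`, `p`, `ka_ks_like`.
#' @export
selection_excluding <- function(groups, gene_tallies, ns_tot, syn_tot,
                                excluded_genes = character()) {
  res <- cumulative_selection(groups, gene_tallies, ns_tot, syn_tot,
                              mode = "union", exclude = excluded_genes)
  res[nrow(res), c("ns_in", "syn_in", "p", "ka_ks_like"), drop = FALSE]
}
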