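# Hypergeometric clustering of top-ranked genes within gene groups.

#' Group enrichment of a top gene list (hypergeometric test)
#'
#' Asks whether the top `K` genes of a ranking cluster within specific
#' gene groups: for each group intersecting the top list, the upper
#' hypergeometric tail of drawing at least `k_in_top` of its members
#' when `K_top` genes are drawn from the candidate universe.  Only
#' groups intersecting the top list are tested, and the Bonferroni
#' factor is the number of groups actually tested.
#'
#' @param top_genes character vector: the ranked gene list already
#'   truncated at K (e.g. top 50 gene-level hits).
#' @param groups a resolved [gene_groups()] table.
#' @param universe candidate gene universe (must contain
#'   `top_genes`); typically the genes with at least one
#'   nonsynonymous mutation.
#' @return `data.frame` of class `enrichment_result`: `group_id`,
#'   `k_in_top`, `group_size` (members in the universe), `K_top`,
#'   `n_candidates`, `p_raw`, `p_corr`, ordered by `p_raw`.
#' @export
enrich_groups <- function(top_genes, groups, universe) {
  top_genes <- unique(top_genes)
  universe <- unique(universe)
  if (!length(top_genes)) stopf("empty top gene list")
  missing <- setdiff(top_genes, universe)
  if (length(missing))
    stopf("top gene(s) outside the candidate universe: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  K <- length(top_genes)
  n_univ <- length(universe)
  memb <- lapply(groups$members, intersect, universe)
  k_in <- vapply(groups$members, function(m) length(intersect(m, top_genes)), 0L)
  tested <- k_in > 0L
  n_tested <- sum(tested)
  gsize <- lengths(memb)[tested]
  k <- k_in[tested]
  p <- stats::phyper(k - 1, gsize, n_univ - gsize, K, lower.tail = FALSE)
  out <- data.frame(group_id = groups$group_id[tested],
                    k_in_top = k, group_size = gsize,
                    K_top = K, n_candidates = n_univ,
                    p_raw = p, p_corr = pmin(1, p * n_tested),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, -out$k_in_top, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat(sprintf("group enrichment: %d group(s) intersect the top %d of %d candidate genes\n",
              attr(x, "n_tested"), x$K_top[1] %||% NA, x$n_candidates[1] %||% NA))
  df <- as.data.frame(utils::head(x, n))
  df$p_raw <- signif(df$p_raw, 3)
  df$p_corr <- signif(df$p_corr, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
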