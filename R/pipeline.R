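# End-to-end pipeline: filtered variants -> annotation -> gene and
# pathway scores -> positive-selection, enrichment and causal-count
# analyses, with TSV export and a run manifest.

#' Run the full pathway phenotype-sequencing pipeline
#'
#' Chains the module steps in their published order: read pooled VCFs
#' (or take an in-memory call table), apply the filter cascade, map
#' the kept SNPs onto CDS features and classify effects, estimate
#' GC/AT per-site mutation densities, score genes and gene groups
#' under the Poisson target model, run the cumulative
#' positive-selection test down the top-ranked groups, the
#' hypergeometric enrichment of the top genes, and the causal-count
#' estimator on the top groups.
#'
#' @param genome a [phenoseq_genome()] or path to a GenBank file.
#' @param groups a [gene_groups()] table or path to a groups TSV.
#' @param vcfs named character vector of per-pool VCF paths, or a
#'   variant call `data.frame` (e.g. from a [synth_experiment()]).
#' @param filter a [filter_config()].
#' @param density_mode `"all"` or `"nonsynonymous"`, see
#'   [estimate_densities()].
#' @param n_tests Bonferroni factor for group scores; default the
#'   total number of groups in the database.
#' @param top_groups number of top-ranked groups fed to the
#'   positive-selection and causal analyses (default 10).
#' @param top_k size of the top gene list for enrichment (default 50).
#' @param exclude_genes gene ids excluded in the second
#'   positive-selection column (default none).
#' @param af_key,sb_key INFO keys for [read_pool_vcf()].
#' @return object of class `phenoseq_run`: list with `filter`,
#'   `annotation`, `densities`, `gene_tallies`, `gene_scores`,
#'   `group_scores`, `selection`, `selection_excluding`, `enrichment`,
#'   `causal`, `f0` and `manifest`.
#' @export
run_phenoseq <- function(genome, groups, vcfs,
                         filter = filter_config(),
                         density_mode = c("all", "nonsynonymous"),
                         n_tests = NULL, top_groups = 10L, top_k = 50L,
                         exclude_genes = character(),
                         af_key = "AF1", sb_key = "PV4") {
  density_mode <- match.arg(density_mode)
  step <- function(name, expr) tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))

  if (is.character(genome)) genome <- step("load_genome", read_genbank(genome))
  if (is.character(groups)) groups <- step("load_groups", load_groups(groups))
  groups <- step("resolve_groups", suppressWarnings(resolve_groups(groups, genome)))
  calls <- if (is.data.frame(vcfs)) vcfs
           else step("read_vcfs", read_pools(vcfs, af_key = af_key, sb_key = sb_key))

  flt <- step("filter", filter_variants(calls, filter))
  ann <- step("annotate", annotate_variants(flt$kept, genome))
  dens <- step("densities", estimate_densities(ann, genome, mode = density_mode))

  gene_tallies <- step("tally", tally_genes(ann, genome))
  group_tallies <- step("tally", tally_groups(gene_tallies, groups))
  hit <- group_tallies$ns > 0
  n_tests <- n_tests %||% nrow(groups)
  gene_scores <- step("score", score_units(
    gene_tallies[gene_tallies$ns + gene_tallies$syn > 0 |
                   gene_tallies$ns > 0, , drop = FALSE],
    dens, n_tests = nrow(gene_tallies)))
  group_scores <- step("score", score_units(
    group_tallies[hit, , drop = FALSE], dens, n_tests = n_tests))

  ns_tot <- sum(gene_tallies$ns)
  syn_tot <- sum(gene_tallies$syn)
  top_ids <- utils::head(group_scores$unit_id, top_groups)
  ranked <- groups[match(top_ids, groups$group_id), , drop = FALSE]
  sel <- step("selection", cumulative_selection(ranked, gene_tallies,
                                                ns_tot, syn_tot))
  sel_ex <- if (length(exclude_genes))
    step("selection", cumulative_selection(ranked, gene_tallies, ns_tot,
                                           syn_tot, exclude = exclude_genes))
  else NULL

  universe <- gene_tallies$unit_id[gene_tallies$ns > 0]
  top_genes <- utils::head(intersect(gene_scores$unit_id, universe), top_k)
  enr <- step("enrichment", enrich_groups(top_genes, groups, universe))

  f0 <- ns_tot / (ns_tot + syn_tot)
  top_tal <- group_tallies[match(top_ids, group_tallies$unit_id), , drop = FALSE]
  top_tal <- top_tal[top_tal$ns + top_tal$syn > 0, , drop = FALSE]
  causal <- step("causal", estimate_causal(top_tal$ns, top_tal$syn, f0,
                                           unit_id = top_tal$unit_id))

  manifest <- c(
    n_calls = nrow(calls), n_kept = nrow(flt$kept),
    n_ns = ns_tot, n_syn = syn_tot,
    qual_min = filter$qual_min, af_max = filter$af_max,
    strand_bias_p_min = filter$strand_bias_p_min,
    max_pools = filter$max_pools,
    density_mode = density_mode, n_tests = n_tests,
    top_groups = top_groups, top_k = top_k,
    rho_gc = dens$rho_gc, rho_at = dens$rho_at
  )
  structure(list(filter = flt, annotation = ann, densities = dens,
                 gene_tallies = gene_tallies, group_tallies = group_tallies,
                 gene_scores = gene_scores, group_scores = group_scores,
                 selection = sel, selection_excluding = sel_ex,
                 enrichment = enr, causal = causal, f0 = f0,
                 manifest = manifest),
            class = "phenoseq_run")
}

#' @export
print.phenoseq_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("phenoseq run: %s/%s calls kept (%s nonsynonymous, %s synonymous hits)\n",
              m["n_kept"], m["n_calls"], m["n_ns"], m["n_syn"]))
  cat("top gene groups (Poisson target model):\n")
  print(x$group_scores, n = 5L)
  invisible(x)
}

#' @export
summary.phenoseq_run <- function(object, ...) {
  cat("== filter cascade ==\n"); print(object$filter)
  cat("== densities ==\n"); print(object$densities)
  cat("== top groups ==\n"); print(object$group_scores, n = 10L)
  cat("== cumulative positive selection ==\n")
  print(transform(object$selection, p = signif(p, 3),
                  ka_ks_like = signif(ka_ks_like, 3)), row.names = FALSE)
  cat("== enrichment of top genes ==\n"); print(object$enrichment, n = 5L)
  cat("== causal-count estimates ==\n")
  print(transform(object$causal, x = signif(x, 3), f0 = signif(f0, 3),
                  c_raw = signif(c_raw, 3), c = signif(c, 3)),
        row.names = FALSE)
  invisible(object)
}

#' Write the TSV report bundle of a pipeline run
#'
#' @param run a [run_phenoseq()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_phenoseq_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(
    w(run$filter$kept, "filtered_variants.tsv"),
    w(run$filter$report, "filter_report.tsv"),
    w(as.data.frame(run$annotation), "annotated_mutations.tsv"),
    w(as.data.frame(run$gene_scores), "gene_scores.tsv"),
    w(as.data.frame(run$group_scores), "group_scores.tsv"),
    w(run$selection, "selection.tsv"),
    w(as.data.frame(run$enrichment), "enrichment.tsv"),
    w(run$causal, "causal.tsv")
  )
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(data.frame(key = names(run$manifest),
                                value = unname(run$manifest)),
                     mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, mf))
}
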