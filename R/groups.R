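# Gene groups ("pathways"): loading functionally-associated-group
# definitions and tallying mutations per gene and per group.

#' Load gene-group (pathway) definitions
#'
#' Reads a flat TSV with one group per line: a group id, a tab, then
#' the member gene names separated by spaces and/or commas (the layout
#' of an EcoCyc functionally-associated-groups export).
#'
#' @param path group definition file.
#' @return `data.frame` of class `gene_groups` with columns `group_id`
#'   and `members` (list-column of character vectors).
#' @export
load_groups <- function(path) {
  if (!file.exists(path)) stopf("group file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stopf("malformed group line %d in %s (expected 'id<TAB>members')", bad[1], path)
  ids <- vapply(parts, `[`, character(1), 1)
  members <- lapply(parts, function(p)
    unlist(strsplit(trimws(p[2]), "[ ,]+"), use.names = FALSE))
  empty <- which(lengths(members) == 0L | !nzchar(ids))
  if (length(empty))
    stopf("group line %d in %s has no members or no id", empty[1], path)
  if (anyDuplicated(ids))
    stopf("duplicate group id '%s' in %s", ids[anyDuplicated(ids)], path)
  gene_groups(ids, members)
}

#' Construct a gene-group table
#'
#' @param group_id character vector of group names.
#' @param members list of character vectors of member gene names.
#' @return `gene_groups` data frame.
#' @export
gene_groups <- function(group_id, members) {
  stopifnot(length(group_id) == length(members),
            all(lengths(members) > 0))
  if (anyDuplicated(group_id))
    stopf("duplicate group id '%s'", group_id[anyDuplicated(group_id)])
  df <- data.frame(group_id = as.character(group_id), stringsAsFactors = FALSE)
  df$members <- lapply(members, as.character)
  class(df) <- c("gene_groups", "data.frame")
  df
}

#' Resolve group member names against a genome's gene models
#'
#' Matching is case-insensitive on the locus tag (`gene_id`) first,
#' then the gene symbol (`name`); unresolved members are dropped with
#' a warning.
#'
#' @param groups a [gene_groups()] table.
#' @param genome a [phenoseq_genome()].
#' @return the groups table with members replaced by resolved
#'   `gene_id`s; groups whose members all fail to resolve are kept
#'   with zero members removed but flagged via the warning.
#' @export
resolve_groups <- function(groups, genome) {
  g <- genome$genes
  by_id <- stats::setNames(g$gene_id, tolower(g$gene_id))
  by_name <- stats::setNames(g$gene_id, tolower(g$name))
  lut <- c(by_id, by_name[setdiff(names(by_name), names(by_id))])
  unresolved <- character()
  groups$members <- lapply(groups$members, function(m) {
    hit <- lut[tolower(m)]
    unresolved <<- c(unresolved, m[is.na(hit)])
    unique(unname(hit[!is.na(hit)]))
  })
  if (length(unresolved))
    warnf("%d group member name(s) did not resolve against the genome (e.g. %s)",
          length(unresolved), paste(utils::head(unique(unresolved), 3), collapse = ", "))
  groups
}

#' Write a gene-group table as TSV
#' @param groups a [gene_groups()] table.
#' @param path output file.
#' @export
write_groups <- function(groups, path) {
  writeLines(sprintf("%s\t%s", groups$group_id,
                     vapply(groups$members, paste, character(1), collapse = " ")),
             path)
  invisible(path)
}

#' Tally mutations per gene
#'
#' Counts nonsynonymous and synonymous CDS hits per gene model and
#' attaches the gene's genomic-span GC/AT site composition (the
#' quantities feeding the mutational cross-section).  All
#' effect-callable genes are reported, including unmutated ones.
#'
#' @param annotation a [annotate_variants()] result.
#' @param genome the [phenoseq_genome()] the annotation was made with.
#' @return `data.frame`: `unit_id`, `ns`, `syn`, `gc_sites`, `at_sites`.
#' @export
tally_genes <- function(annotation, genome) {
  g <- genome$genes[genome$genes$coding_ok, , drop = FALSE]
  h <- annotation$hits
  ns <- table(factor(h$gene_id[h$effect == "nonsynonymous"], levels = g$gene_id))
  sy <- table(factor(h$gene_id[h$effect == "synonymous"], levels = g$gene_id))
  data.frame(unit_id = g$gene_id,
             ns = as.integer(ns), syn = as.integer(sy),
             gc_sites = g$gc_sites, at_sites = g$at_sites,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tally mutations per gene group
#'
#' Group tallies are sums over member genes: counts, and the GC/AT
#' site composition.  A mutation altering two member genes of one
#' group therefore counts once per gene hit.  Members not present in
#' the gene tally (unresolved or non-callable) are ignored.
#'
#' @param gene_tallies output of [tally_genes()].
#' @param groups a (preferably resolved) [gene_groups()] table.
#' @return `data.frame` as [tally_genes()], one row per group.
#' @export
tally_groups <- function(gene_tallies, groups) {
  idx <- stats::setNames(seq_len(nrow(gene_tallies)), gene_tallies$unit_id)
  agg <- t(vapply(groups$members, function(m) {
    rows <- idx[m]
    rows <- rows[!is.na(rows)]
    if (!length(rows)) return(c(ns = 0, syn = 0, gc_sites = 0, at_sites = 0))
    colSums(gene_tallies[rows, c("ns", "syn", "gc_sites", "at_sites")])
  }, numeric(4)))
  data.frame(unit_id = groups$group_id,
             ns = as.integer(agg[, "ns"]), syn = as.integer(agg[, "syn"]),
             gc_sites = agg[, "gc_sites"], at_sites = agg[, "at_sites"],
             stringsAsFactors = FALSE, row.names = NULL)
}
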