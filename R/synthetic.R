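# Forward generator of synthetic mutagenesis experiments: a random
# annotated genome, a gene-group database, NTG-like mutagenized
# strains with optional implanted causal structure, and pooled
# variant calls -- everything the analysis pipeline consumes, with the
# generating truth retained for validation.

#' Configuration of a synthetic phenotype-sequencing experiment
#'
#' Defaults emulate the study design the package targets: 24
#' independently mutagenized strains carrying ~100 point mutations
#' each with a strong (95%) GC-site preference, pooled three strains
#' per library into 8 tagged pools, analysed against a compact
#' bacterial genome (500 CDSs, ~88% coding, GC 0.5) and a database of
#' 536 gene groups.
#'
#' @param n_genes number of CDS features.
#' @param gene_length_range min/max CDS length in bp (snapped to
#'   multiples of 3); drawn uniformly.
#' @param intergenic_mean mean intergenic gap in bp (Poisson).
#' @param gc_content genomic GC fraction.
#' @param n_groups number of gene groups in the database.
#' @param group_size_range min/max genes per group; sizes are drawn
#'   with probability decreasing in size (most real functional groups
#'   are small complexes/operons).
#' @param n_strains mutant strains (must equal `pool_size * n_pools`).
#' @param mutations_per_strain mean background mutations per strain
#'   (Poisson).
#' @param gc_mutation_bias fraction of mutations placed on G/C sites.
#' @param transition_prob probability a mutation is a transition.
#' @param pool_size strains per pool.
#' @param n_pools number of tagged pools.
#' @param af_jitter_sd Gaussian jitter of the pooled allele-frequency
#'   estimate around carrier-count / pool-size.
#' @param causal_spec `NULL`, or a list of causal-group requirements,
#'   each a list with `size` (genes in the implanted group) and
#'   `prob` (per-strain probability of carrying one forced
#'   nonsynonymous hit in the group; 1 = every strain).
#' @param n_lowqual,n_strandbias,n_highaf,n_parental numbers of
#'   injected artifact calls violating, respectively, the quality,
#'   strand-bias, allele-frequency and multi-pool filters (parental
#'   artifacts are written into every pool at an in-range allele
#'   frequency so the cascade attributes them to the multi-pool rule).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 500L, gene_length_range = c(750L, 1050L),
                         intergenic_mean = 120, gc_content = 0.5,
                         n_groups = 536L, group_size_range = c(2L, 8L),
                         n_strains = 24L, mutations_per_strain = 100,
                         gc_mutation_bias = 0.95, transition_prob = 0.9,
                         pool_size = 3L, n_pools = 8L,
                         af_jitter_sd = 0.03,
                         causal_spec = list(list(size = 2L, prob = 1)),
                         n_lowqual = 0L, n_strandbias = 0L,
                         n_highaf = 0L, n_parental = 0L) {
  stopifnot(pool_size * n_pools == n_strains,
            gc_mutation_bias >= 0, gc_mutation_bias <= 1,
            gc_content > 0, gc_content < 1)
  structure(as.list(environment()), class = "synth_config")
}

# random annotated genome: genes laid end to end with Poisson gaps
synth_genome <- function(cfg) {
  lens <- 3L * sample(seq(cfg$gene_length_range[1] %/% 3L,
                          cfg$gene_length_range[2] %/% 3L),
                      cfg$n_genes, replace = TRUE)
  gaps <- 1L + stats::rpois(cfg$n_genes + 1L, cfg$intergenic_mean)
  starts <- cumsum(gaps[seq_len(cfg$n_genes)] + c(0L, lens[-cfg$n_genes])) + 1L
  total <- starts[cfg$n_genes] + lens[cfg$n_genes] - 1L + gaps[cfg$n_genes + 1L]
  p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
         G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  sequence <- sample(BASES, total, replace = TRUE, prob = p[BASES])
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    name = sprintf("g%04d", seq_len(cfg$n_genes)),
    strand = sample(c(1L, -1L), cfg$n_genes, replace = TRUE),
    start = starts[seq_len(cfg$n_genes)],
    end = starts[seq_len(cfg$n_genes)] + lens - 1L,
    stringsAsFactors = FALSE
  )
  phenoseq_genome(sequence, genes, seqname = "synthchr")
}

# group database; the first length(causal_spec) groups get the causal
# sizes so implanted structure lives in ordinary database entries
synth_groups <- function(cfg, genome) {
  sizes <- seq(cfg$group_size_range[1], cfg$group_size_range[2])
  sz <- sample(sizes, cfg$n_groups, replace = TRUE, prob = 1 / sizes^1.5)
  for (i in seq_along(cfg$causal_spec))
    sz[i] <- cfg$causal_spec[[i]]$size
  members <- lapply(sz, function(k) sample(genome$genes$gene_id, k))
  gene_groups(sprintf("GRP%04d", seq_len(cfg$n_groups)), members)
}

mutate_alt <- function(ref, transition_prob) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  is_ts <- stats::runif(length(ref)) < transition_prob
  alt <- ifelse(is_ts, ts[ref], NA)
  if (any(!is_ts))
    alt[!is_ts] <- vapply(ref[!is_ts], function(b) sample(tv[[b]], 1), "")
  unname(alt)
}

# one forced nonsynonymous mutation in a member gene of the group:
# a random codon's middle base (retried until nonsynonymous)
implant_causal <- function(genome, member_ids, avoid_pos) {
  rows <- which(genome$genes$gene_id %in% member_ids & genome$genes$coding_ok)
  if (!length(rows)) stopf("causal group has no effect-callable genes")
  for (try in 1:50) {
    gr <- if (length(rows) > 1L) sample(rows, 1L) else rows
    g <- genome$genes[gr, ]
    codon <- sample.int(g$cds_len %/% 3L, 1L) - 1L
    idx <- codon * 3L + 1L                      # middle base, 0-based coding
    offset_fwd <- if (g$strand == 1L) idx else g$cds_len - 1L - idx
    pos <- g$start + offset_fwd
    if (pos %in% avoid_pos) next
    ref <- genome$seq[pos]
    for (alt in sample(setdiff(BASES, ref))) {
      eff <- classify_hits(genome, pos, ref, alt, gr, 0L, g$start)$effect
      if (eff == "nonsynonymous")
        return(data.frame(pos = pos, ref = ref, alt = alt,
                          stringsAsFactors = FALSE))
    }
  }
  stopf("failed to place a nonsynonymous causal mutation")
}

#' Generate a synthetic phenotype-sequencing experiment
#'
#' Draws the genome, the group database, per-strain GC-biased
#' background mutations, forced nonsynonymous causal mutations per
#' `causal_spec`, assigns strains to pools and forms pooled variant
#' calls (one record per pool and variant, with allele frequency
#' carrier-count/pool-size plus jitter, QUAL above threshold and an
#' unbiased strand-bias p-value), then injects the requested artifact
#' calls.
#'
#' @param cfg a [synth_config()].
#' @param seed optional RNG seed; generation is reproducible given the
#'   seed.
#' @return list of class `synth_experiment`: `genome`, `groups`,
#'   `causal_groups` (ids of groups carrying implants), `truth`
#'   (per-strain mutation list with `causal` flag and pool), `calls`
#'   (pooled variant records, artifact rows flagged in the `artifact`
#'   column), `truth_tallies` (per-gene tallies of the pooled
#'   records, the quantity the pipeline can recover), `annotation`
#'   (effect annotation of the distinct true variants) and `cfg`.
#' @export
synth_experiment <- function(cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- synth_genome(cfg)
  groups <- synth_groups(cfg, genome)
  causal_ids <- groups$group_id[seq_along(cfg$causal_spec)]

  gc_pos <- which(genome$seq %in% c("G", "C"))
  at_pos <- which(genome$seq %in% c("A", "T"))

  strains <- lapply(seq_len(cfg$n_strains), function(s) {
    n <- stats::rpois(1, cfg$mutations_per_strain)
    n_gc <- stats::rbinom(1, n, cfg$gc_mutation_bias)
    pos <- c(sample(gc_pos, n_gc), sample(at_pos, n - n_gc))
    ref <- genome$seq[pos]
    df <- data.frame(strain = s, pos = pos, ref = ref,
                     alt = mutate_alt(ref, cfg$transition_prob),
                     causal = FALSE, stringsAsFactors = FALSE)
    for (i in seq_along(cfg$causal_spec)) {
      spec <- cfg$causal_spec[[i]]
      if (stats::runif(1) <= spec$prob) {
        imp <- implant_causal(genome, groups$members[[i]], df$pos)
        df <- rbind(df, cbind(strain = s, imp, causal = TRUE))
      }
    }
    df
  })
  truth <- do.call(rbind, strains)
  truth$pool <- sprintf("P%d", (truth$strain - 1L) %/% cfg$pool_size + 1L)

  # pooled records: one call per pool x (pos, ref, alt)
  key <- paste(truth$pool, truth$pos, truth$ref, truth$alt, sep = "\r")
  carriers <- as.vector(table(key)[key])
  rec <- !duplicated(key)
  calls <- data.frame(
    chrom = genome$seqname,
    pos = truth$pos[rec], ref = truth$ref[rec], alt = truth$alt[rec],
    qual = stats::runif(sum(rec), 150, 500),
    pool_id = truth$pool[rec],
    allele_freq = pmin(0.99, pmax(0.02,
      carriers[rec] / cfg$pool_size +
        stats::rnorm(sum(rec), 0, cfg$af_jitter_sd))),
    strand_bias_p = stats::runif(sum(rec), 0.05, 1),
    artifact = "none",
    stringsAsFactors = FALSE
  )

  # artifact injection at novel sites
  pools <- sprintf("P%d", seq_len(cfg$n_pools))
  novel <- function(n) {
    pos <- sample(setdiff(seq_len(genome$length), truth$pos), n)
    ref <- genome$seq[pos]
    data.frame(chrom = genome$seqname, pos = pos, ref = ref,
               alt = mutate_alt(ref, cfg$transition_prob),
               qual = stats::runif(n, 150, 500),
               pool_id = sample(pools, n, replace = TRUE),
               allele_freq = 1 / cfg$pool_size,
               strand_bias_p = stats::runif(n, 0.05, 1),
               artifact = "none", stringsAsFactors = FALSE)
  }
  if (cfg$n_lowqual > 0) {
    a <- novel(cfg$n_lowqual)
    a$qual <- stats::runif(cfg$n_lowqual, 10, 89)
    a$artifact <- "lowqual"
    calls <- rbind(calls, a)
  }
  if (cfg$n_strandbias > 0) {
    a <- novel(cfg$n_strandbias)
    a$strand_bias_p <- stats::runif(cfg$n_strandbias, 1e-9, 1e-5)
    a$artifact <- "strandbias"
    calls <- rbind(calls, a)
  }
  if (cfg$n_highaf > 0) {
    a <- novel(cfg$n_highaf)
    a$allele_freq <- stats::runif(cfg$n_highaf, 0.55, 0.95)
    a$artifact <- "highaf"
    calls <- rbind(calls, a)
  }
  if (cfg$n_parental > 0) {
    a <- novel(cfg$n_parental)
    a <- a[rep(seq_len(cfg$n_parental), each = cfg$n_pools), ]
    a$pool_id <- rep(pools, cfg$n_parental)
    a$allele_freq <- 0.45
    a$artifact <- "parental"
    calls <- rbind(calls, a)
  }
  rownames(calls) <- NULL

  clean <- calls[calls$artifact == "none", , drop = FALSE]
  annotation <- annotate_variants(clean, genome)
  structure(list(genome = genome, groups = groups,
                 causal_groups = causal_ids, truth = truth, calls = calls,
                 truth_tallies = tally_genes(annotation, genome),
                 annotation = annotation, cfg = cfg),
            class = "synth_experiment")
}

#' @export
print.synth_experiment <- function(x, ...) {
  cat(sprintf("synthetic experiment: %d strains in %d pools, %d true mutations (%d causal in %s), %d pooled call(s)\n",
              x$cfg$n_strains, x$cfg$n_pools, nrow(x$truth),
              sum(x$truth$causal),
              paste(x$causal_groups, collapse = ","), nrow(x$calls)))
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Emits the bundle the pipeline front-end consumes: `genome.gb`
#' (GenBank), `groups.tsv`, one `POOL<i>.vcf` per pool, and
#' `truth.json`.
#'
#' @param x a [synth_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths.
#' @export
write_synth_bundle <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.gb"),
             groups = file.path(dir, "groups.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genbank(x$genome, paths["genome"])
  write_groups(x$groups, paths["groups"])
  pools <- sprintf("P%d", seq_len(x$cfg$n_pools))
  contig <- list(id = x$genome$seqname, length = x$genome$length)
  for (p in pools) {
    f <- file.path(dir, sprintf("%s.vcf", p))
    write_pool_vcf(x$calls[x$calls$pool_id == p, , drop = FALSE], f,
                   contig = contig)
    paths[p] <- f
  }
  jsonlite::write_json(list(causal_groups = x$causal_groups,
                            truth = x$truth),
                       paths["truth"], dataframe = "columns")
  invisible(paths)
}
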