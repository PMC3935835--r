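# Annotated reference genome: GenBank parsing, gene models, and
# synonymous/nonsynonymous classification of point mutations.
#
# Coordinates are 1-based closed throughout, the IRanges convention.
# A gene model keeps its CDS intervals in genomic order; the coding
# sequence is strand-corrected (reverse strand genes store the
# reverse complement of the concatenated intervals).

#' Construct an annotated genome object
#'
#' Low-level constructor used both by [read_genbank()] and by the
#' synthetic experiment generator.  Gene models of non-triplet CDS
#' length are kept but flagged (`coding_ok = FALSE`) and excluded from
#' effect calling, as expected for pseudogene-like annotations.
#'
#' @param sequence reference sequence: a single string or character
#'   vector of single bases.
#' @param genes `data.frame` with columns `gene_id`, `name` (gene
#'   symbol, may equal `gene_id`), `strand` (+1/-1), and either
#'   `start`/`end` columns (single-interval CDS) or an `intervals`
#'   list-column of two-column matrices (start, end) in genomic order.
#' @param seqname contig name used when matching variant records
#'   (default `"chr"`).
#' @param code_table NCBI genetic code identifier; `"11"` is the
#'   bacterial/plastid code.
#' @return an object of class `phenoseq_genome`: list with elements
#'   `seq` (character vector of bases), `seqname`, `length`,
#'   `gc_count`, `at_count`, `genes` (gene-model `data.frame` with
#'   per-gene `gc_sites`/`at_sites` span composition and
#'   strand-corrected `coding_seq`), and `code` (named codon table).
#' @export
phenoseq_genome <- function(sequence, genes, seqname = "chr",
                            code_table = "11") {
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  if (length(sequence) == 0L) stopf("genome sequence is empty")

  genes <- as.data.frame(genes)
  if (is.null(genes$name)) genes$name <- genes$gene_id
  if (is.null(genes$intervals)) {
    genes$intervals <- lapply(seq_len(nrow(genes)), function(i)
      cbind(start = genes$start[i], end = genes$end[i]))
  }
  genes$start <- vapply(genes$intervals, function(m) min(m[, 1]), 0)
  genes$end <- vapply(genes$intervals, function(m) max(m[, 2]), 0)
  if (any(genes$start < 1 | genes$end > length(sequence)))
    stopf("gene interval outside the reference sequence")

  extract <- function(m) unlist(lapply(seq_len(nrow(m)), function(i)
    sequence[m[i, 1]:m[i, 2]]), use.names = FALSE)
  comp <- lapply(genes$intervals, function(m) {
    b <- extract(m)
    gc <- sum(b == "G" | b == "C")
    c(len = length(b), gc = gc, at = sum(b == "A" | b == "T"))
  })
  genes$cds_len <- vapply(comp, `[[`, 0, "len")
  genes$gc_sites <- vapply(comp, `[[`, 0, "gc")
  genes$at_sites <- vapply(comp, `[[`, 0, "at")
  genes$coding_ok <- genes$cds_len %% 3L == 0L
  if (any(!genes$coding_ok))
    warnf("%d CDS feature(s) of non-triplet length excluded from effect calling: %s",
          sum(!genes$coding_ok),
          paste(utils::head(genes$gene_id[!genes$coding_ok], 5), collapse = ", "))

  fwd <- vapply(genes$intervals, function(m) paste(extract(m), collapse = ""),
                character(1))
  genes$coding_seq <- ifelse(genes$strand == 1L, fwd, revcomp(fwd))

  structure(list(
    seq = sequence,
    seqname = seqname,
    length = length(sequence),
    gc_count = sum(sequence == "G" | sequence == "C"),
    at_count = sum(sequence == "A" | sequence == "T"),
    genes = genes,
    code = Biostrings::getGeneticCode(code_table)
  ), class = "phenoseq_genome")
}

#' @export
print.phenoseq_genome <- function(x, ...) {
  cat(sprintf("phenoseq genome '%s': %d bp (GC %.1f%%), %d CDS features (%d effect-callable)\n",
              x$seqname, x$length, 100 * x$gc_count / x$length,
              nrow(x$genes), sum(x$genes$coding_ok)))
  invisible(x)
}

# ---- GenBank flat file ----------------------------------------------------

# parse a GenBank location string: "a..b", "a", "complement(...)",
# "join(a..b,c..d)"; partial markers (<, >) are dropped.
parse_gb_location <- function(loc) {
  loc <- gsub("[<> ]", "", loc)
  strand <- 1L
  while (grepl("^(complement|join|order)\\(", loc)) {
    op <- sub("\\(.*$", "", loc)
    loc <- sub("^[a-z]+\\(", "", loc)
    loc <- sub("\\)$", "", loc)
    if (op == "complement") strand <- -strand
  }
  parts <- strsplit(loc, ",")[[1]]
  iv <- t(vapply(parts, function(p) {
    xs <- as.numeric(strsplit(p, "\\.\\.")[[1]])
    if (anyNA(xs)) stopf("cannot parse GenBank location component '%s'", p)
    if (length(xs) == 1L) xs <- c(xs, xs)
    xs
  }, numeric(2)))
  dimnames(iv) <- list(NULL, c("start", "end"))
  list(intervals = iv[order(iv[, 1]), , drop = FALSE], strand = strand)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Parses the sequence (ORIGIN block) and all CDS features with their
#' locations (including `complement()` and `join()`) and `/gene` and
#' `/locus_tag` qualifiers.  One gene model is produced per CDS
#' feature; overlapping CDSs are allowed.
#'
#' @param path GenBank flat file.
#' @param code_table NCBI genetic code id (default `"11"`, bacterial).
#' @return a [phenoseq_genome()] object.
#' @export
read_genbank <- function(path, code_table = "11") {
  if (!file.exists(path)) stopf("GenBank file not found: %s", path)
  lines <- readLines(path, warn = FALSE)

  locus <- grep("^LOCUS", lines, value = TRUE)
  seqname <- if (length(locus)) strsplit(trimws(locus[1]), "[ ]+")[[1]][2] else "chr"

  o <- grep("^ORIGIN", lines)
  if (!length(o)) stopf("GenBank file %s has no ORIGIN sequence block", path)
  endl <- grep("^//", lines)
  endl <- if (length(endl)) endl[endl > o[1]][1] else length(lines) + 1L
  seq_lines <- lines[(o[1] + 1L):(endl - 1L)]
  sequence <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stopf("GenBank file %s has an empty sequence", path)

  f <- grep("^FEATURES", lines)
  feats <- if (length(f)) lines[(f[1] + 1L):(o[1] - 1L)] else character()

  # split the feature table into entries: a new entry starts when a
  # feature key appears at column 6
  key_at <- grepl("^ {5}[A-Za-z]", feats)
  genes <- list()
  idx <- which(key_at)
  for (k in seq_along(idx)) {
    block <- feats[idx[k]:(if (k < length(idx)) idx[k + 1L] - 1L else length(feats))]
    key <- strsplit(trimws(block[1]), "[ ]+")[[1]][1]
    if (key != "CDS") next
    body <- trimws(sub("^ {5}[A-Za-z'_0-9-]+", "", block))
    qual_start <- grep("^/", body)
    loc_str <- paste(body[seq_len(if (length(qual_start)) qual_start[1] - 1L else length(body))],
                     collapse = "")
    loc <- parse_gb_location(loc_str)
    qget <- function(q) {
      m <- grep(sprintf("^/%s=", q), body, value = TRUE)
      if (!length(m)) return(NA_character_)
      gsub('^/[a-z_]+="?|"$', "", m[1])
    }
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = NA_character_, name = qget("gene"),
      locus_tag = qget("locus_tag"), strand = loc$strand,
      stringsAsFactors = FALSE
    )
    genes[[length(genes)]]$intervals <- list(loc$intervals)
  }
  if (!length(genes)) stopf("GenBank file %s contains no CDS features", path)
  genes <- do.call(rbind, genes)
  genes$gene_id <- ifelse(!is.na(genes$locus_tag), genes$locus_tag, genes$name)
  genes$name <- ifelse(!is.na(genes$name), genes$name, genes$gene_id)
  if (anyNA(genes$gene_id))
    stopf("CDS feature without /gene or /locus_tag in %s", path)

  phenoseq_genome(sequence, genes, seqname = seqname, code_table = code_table)
}

#' Write a genome object as a GenBank flat file
#'
#' Emits a minimal single-record flat file (LOCUS, FEATURES with one
#' CDS per gene model, ORIGIN) that [read_genbank()] round-trips.
#'
#' @param genome a [phenoseq_genome()] object.
#' @param path output file.
#' @export
write_genbank <- function(genome, path) {
  g <- genome$genes
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %s %d bp    DNA     circular BCT 01-JAN-2000",
     genome$seqname, genome$length)
  wl("DEFINITION  synthetic mutagenesis reference genome.")
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", genome$length)
  for (i in seq_len(nrow(g))) {
    iv <- g$intervals[[i]]
    loc <- paste(sprintf("%d..%d", iv[, 1], iv[, 2]), collapse = ",")
    if (nrow(iv) > 1L) loc <- sprintf("join(%s)", loc)
    if (g$strand[i] == -1L) loc <- sprintf("complement(%s)", loc)
    wl("     CDS             %s", loc)
    wl("                     /gene=\"%s\"", g$name[i])
    wl("                     /locus_tag=\"%s\"", g$gene_id[i])
  }
  wl("ORIGIN")
  s <- tolower(paste(genome$seq, collapse = ""))
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    wl("%9d %s", st, paste(blocks, collapse = " "))
  }
  wl("//")
  invisible(path)
}

# ---- effect classification ------------------------------------------------

# flatten gene CDS intervals for indexed lookup; cum_before is the
# 0-based coding offset (genomic order) of each interval's first base
flatten_intervals <- function(genes) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    m <- genes$intervals[[i]]
    lens <- m[, 2] - m[, 1] + 1
    data.frame(gene_row = i, start = m[, 1], end = m[, 2],
               cum_before = cumsum(c(0, lens))[seq_len(nrow(m))])
  })
  do.call(rbind, rows)
}

#' Classify point mutations falling in gene models
#'
#' Vectorised worker behind [annotate_variants()] and
#' [classify_effect()]: for parallel vectors of genomic positions,
#' alt alleles and gene rows, substitutes the mutated base into the
#' affected codon of the strand-corrected coding sequence and compares
#' translations under the genome's codon table.  Mutations creating a
#' stop codon are nonsynonymous.
#'
#' @noRd
classify_hits <- function(genome, pos, ref, alt, gene_row, cum_before, int_start) {
  genes <- genome$genes
  gref <- genome$seq[pos]
  bad <- gref != ref
  if (any(bad))
    stopf("variant ref allele disagrees with the reference at position %d (%s vs %s); wrong reference genome?",
          pos[which(bad)[1]], ref[which(bad)[1]], gref[which(bad)[1]])
  offset_fwd <- cum_before + (pos - int_start)      # 0-based, genomic order
  strand <- genes$strand[gene_row]
  cds_len <- genes$cds_len[gene_row]
  idx <- ifelse(strand == 1L, offset_fwd, cds_len - 1L - offset_fwd)
  codon_index <- idx %/% 3L
  within <- idx %% 3L
  cs <- genes$coding_seq[gene_row]
  codon <- substring(cs, codon_index * 3L + 1L, codon_index * 3L + 3L)
  newbase <- ifelse(strand == 1L, alt, complement_bases(alt))
  mut <- paste0(
    ifelse(within > 0L, substring(codon, 1L, within), ""),
    newbase,
    ifelse(within < 2L, substring(codon, within + 2L, 3L), "")
  )
  aa_ref <- unname(genome$code[codon])
  aa_alt <- unname(genome$code[mut])
  data.frame(
    gene_id = genes$gene_id[gene_row],
    codon_index = codon_index,
    ref_codon = codon, alt_codon = mut,
    ref_aa = aa_ref, alt_aa = aa_alt,
    effect = ifelse(aa_ref == aa_alt, "synonymous", "nonsynonymous"),
    stringsAsFactors = FALSE
  )
}

#' Classify the coding effect of one substitution in one gene
#'
#' @param genome a [phenoseq_genome()].
#' @param pos 1-based genomic position (must lie in the gene's CDS).
#' @param ref,alt reference and alternate base (genomic strand).
#' @param gene_id id of the gene model to classify against.
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @examples
#' g <- phenoseq_genome("ATGGATAAATAA",
#'   data.frame(gene_id = "g1", strand = 1, start = 1, end = 12))
#' classify_effect(g, 6, "T", "A")   # GAT -> GAA, Asp -> Glu
#' @export
classify_effect <- function(genome, pos, ref, alt, gene_id = NULL) {
  genes <- genome$genes
  iv <- flatten_intervals(genes)
  sel <- iv$start <= pos & iv$end >= pos & genes$coding_ok[iv$gene_row]
  if (!is.null(gene_id)) sel <- sel & genes$gene_id[iv$gene_row] == gene_id
  if (!any(sel)) stopf("position %d is not inside a callable CDS%s", pos,
                       if (is.null(gene_id)) "" else sprintf(" of gene %s", gene_id))
  iv <- iv[sel, , drop = FALSE]
  res <- classify_hits(genome, rep(pos, nrow(iv)), rep(ref, nrow(iv)),
                       rep(alt, nrow(iv)), iv$gene_row, iv$cum_before, iv$start)
  if (is.null(gene_id) && nrow(res) > 1L) res$effect else res$effect[1]
}

#' Annotate filtered variants against all gene models
#'
#' Maps every variant onto the CDS intervals of the genome (indexed
#' lookup via [GenomicRanges::findOverlaps()]) and classifies each
#' gene hit as synonymous or nonsynonymous.  A variant overlapping k
#' callable CDSs yields k hits; variants hitting none are flagged
#' non-coding.
#'
#' @param variants variant `data.frame` (columns `pos`, `ref`, `alt`,
#'   and optionally `pool_id`), e.g. the `kept` element of
#'   [filter_variants()].
#' @param genome a [phenoseq_genome()].
#' @return object of class `phenoseq_annotation`: list with
#'   `variants` (input plus `noncoding` flag and `n_hits`) and `hits`
#'   (`data.frame` with `variant_row`, `gene_id`, `codon_index`,
#'   `effect` and codon detail columns).
#' @export
annotate_variants <- function(variants, genome) {
  variants <- as.data.frame(variants)
  genes <- genome$genes
  iv <- flatten_intervals(genes)
  iv <- iv[genes$coding_ok[iv$gene_row], , drop = FALSE]

  if (nrow(variants) && nrow(iv)) {
    q <- GenomicRanges::GRanges(genome$seqname,
                                IRanges::IRanges(variants$pos, variants$pos))
    s <- GenomicRanges::GRanges(genome$seqname,
                                IRanges::IRanges(iv$start, iv$end))
    ov <- GenomicRanges::findOverlaps(q, s)
    vrow <- S4Vectors::queryHits(ov)
    irow <- S4Vectors::subjectHits(ov)
  } else {
    vrow <- irow <- integer()
  }

  if (length(vrow)) {
    hits <- classify_hits(genome,
                          pos = variants$pos[vrow],
                          ref = variants$ref[vrow],
                          alt = variants$alt[vrow],
                          gene_row = iv$gene_row[irow],
                          cum_before = iv$cum_before[irow],
                          int_start = iv$start[irow])
    hits <- cbind(data.frame(variant_row = vrow,
                             pos = variants$pos[vrow],
                             ref = variants$ref[vrow],
                             alt = variants$alt[vrow]), hits)
  } else {
    hits <- data.frame(variant_row = integer(), pos = integer(),
                       ref = character(), alt = character(),
                       gene_id = character(), codon_index = integer(),
                       ref_codon = character(), alt_codon = character(),
                       ref_aa = character(), alt_aa = character(),
                       effect = character(), stringsAsFactors = FALSE)
  }
  variants$n_hits <- tabulate(hits$variant_row, nbins = nrow(variants))
  variants$noncoding <- variants$n_hits == 0L
  structure(list(variants = variants, hits = hits),
            class = "phenoseq_annotation")
}

#' @export
print.phenoseq_annotation <- function(x, ...) {
  cat(sprintf("phenoseq annotation: %d variants, %d CDS hits (%d nonsynonymous, %d synonymous), %d non-coding variants\n",
              nrow(x$variants), nrow(x$hits),
              sum(x$hits$effect == "nonsynonymous"),
              sum(x$hits$effect == "synonymous"),
              sum(x$variants$noncoding)))
  invisible(x)
}

#' Flatten an annotation to one row per CDS hit
#'
#' @param x a `phenoseq_annotation`.
#' @param ... unused.
#' @return `data.frame` suitable for TSV export.
#' @export
as.data.frame.phenoseq_annotation <- function(x, ...) {
  v <- x$variants[x$hits$variant_row, , drop = FALSE]
  out <- cbind(v[setdiff(names(v), c("n_hits", "noncoding"))],
               x$hits[c("gene_id", "codon_index", "effect")])
  rownames(out) <- NULL
  out
}
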