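# Pooled variant calls: VCF input and the four-stage filter cascade
# (call quality, strand bias, pool allele frequency, multi-pool
# parental sites).

#' Filter configuration for pooled variant calls
#'
#' @param qual_min phred-scaled QUAL threshold; calls must be strictly
#'   greater (default 90).
#' @param af_max per-pool alternate-allele frequency ceiling; calls
#'   strictly above it are removed (default 0.5: in a 3-strain pool an
#'   independent mutation is carried by one strain, so its frequency
#'   should be near 1/3).
#' @param strand_bias_p_min minimum acceptable strand-bias p-value
#'   (smaller = more biased); calls below it are removed.  The value is
#'   a tunable with default 1e-4; calls lacking the field pass.
#' @param max_pools maximum number of distinct pools a site may occur
#'   in before it is called parental (default 1: each mutant strain is
#'   an independent mutagenesis experiment).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(qual_min = 90, af_max = 0.5,
                          strand_bias_p_min = 1e-4, max_pools = 1L) {
  stopifnot(qual_min >= 0, af_max > 0, af_max <= 1,
            strand_bias_p_min >= 0, max_pools >= 1)
  structure(list(qual_min = qual_min, af_max = af_max,
                 strand_bias_p_min = strand_bias_p_min,
                 max_pools = as.integer(max_pools)),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf("phenoseq filter config: QUAL > %g, AF <= %g, strand-bias p >= %g, <= %d pool(s)\n",
              x$qual_min, x$af_max, x$strand_bias_p_min, x$max_pools))
  invisible(x)
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), pool_id = character(),
             allele_freq = numeric(), strand_bias_p = numeric(),
             stringsAsFactors = FALSE)
}

#' Read single-nucleotide variant calls for one pool from a VCF
#'
#' Reads a samtools/bcftools-dialect VCF and returns one row per
#' alternate allele of each single-nucleotide substitution record,
#' tagged with the pool identifier.  Indels and MNPs are skipped with
#' a message.  The pool allele frequency is taken from an INFO key
#' (default `AF1`) and the strand-bias p-value from the first
#' component of another (default `PV4`, whose components are the
#' strand bias, baseQ bias, mapQ bias and tail-distance bias
#' p-values); records lacking either field get `NA` there, with a
#' single warning per file.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param pool_id identifier of the library tag/pool.
#' @param af_key INFO key holding the allele-frequency estimate.
#' @param sb_key INFO key whose first comma-separated component is the
#'   strand-bias p-value.
#' @return variant `data.frame` (`chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `pool_id`, `allele_freq`, `strand_bias_p`).
#' @export
read_pool_vcf <- function(path, pool_id, af_key = "AF1", sb_key = "PV4") {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- t(as.matrix(fx))   # single-record file
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty_variants())

  af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = af_key)))
  sb_raw <- vcfR::extract.info(vcf, element = sb_key)
  sb <- suppressWarnings(as.numeric(vapply(
    strsplit(ifelse(is.na(sb_raw), "NA", sb_raw), ","),
    `[`, character(1), 1)))
  if (all(is.na(af)))
    warnf("%s: INFO key '%s' absent; allele-frequency filter will not apply", path, af_key)
  if (all(is.na(sb)))
    warnf("%s: INFO key '%s' absent; strand-bias filter will not apply", path, sb_key)

  alts <- strsplit(fix$ALT, ",")
  n_alt <- lengths(alts)
  row <- rep(seq_len(nrow(fix)), n_alt)
  out <- data.frame(
    chrom = fix$CHROM[row],
    pos = as.integer(fix$POS[row]),
    ref = toupper(fix$REF[row]),
    alt = toupper(unlist(alts)),
    qual = suppressWarnings(as.numeric(fix$QUAL[row])),
    pool_id = as.character(pool_id),
    allele_freq = af[row],
    strand_bias_p = sb[row],
    stringsAsFactors = FALSE
  )
  snp <- is_single_base(out$ref) & is_single_base(out$alt)
  if (any(!snp))
    message(sprintf("%s: skipped %d non-SNP allele record(s)", path, sum(!snp)))
  out <- out[snp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and combine VCFs from several pools
#'
#' @param paths named character vector of VCF paths; names are used as
#'   pool ids (file base names when unnamed).
#' @inheritParams read_pool_vcf
#' @return combined variant `data.frame`.
#' @export
read_pools <- function(paths, af_key = "AF1", sb_key = "PV4") {
  ids <- names(paths) %||% NULL
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sub("\\.vcf(\\.gz)?$", "", basename(paths))
  do.call(rbind, Map(read_pool_vcf, paths, ids,
                     MoreArgs = list(af_key = af_key, sb_key = sb_key)))
}

#' Apply the four-stage filter cascade to pooled variant calls
#'
#' Filters are applied in order -- (1) call quality, (2) strand bias,
#' (3) pool allele frequency, (4) multi-pool (parental) sites -- and
#' each removed call is attributed to the first filter that rejects
#' it.  The multi-pool stage counts, among calls surviving the first
#' three stages, the number of distinct pools each site
#' (chrom, pos, ref, alt) occurs in; sites in more than `max_pools`
#' pools are treated as parental-strain differences from the
#' reference.
#'
#' Calls lacking the strand-bias or allele-frequency field pass the
#' corresponding stage.
#'
#' @param calls variant `data.frame` from [read_pools()] (or any frame
#'   with the same columns; `pool_id` required).
#' @param cfg a [filter_config()].
#' @return list of class `filter_result`: `kept` (surviving calls),
#'   `report` (`data.frame` of per-stage removal counts) and `cfg`.
#' @export
filter_variants <- function(calls, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  calls <- as.data.frame(calls)
  n0 <- nrow(calls)
  stage <- function(df, keep) list(kept = df[keep, , drop = FALSE],
                                   removed = sum(!keep))
  s1 <- stage(calls, !is.na(calls$qual) & calls$qual > cfg$qual_min)
  s2 <- stage(s1$kept, is.na(s1$kept$strand_bias_p) |
                         s1$kept$strand_bias_p >= cfg$strand_bias_p_min)
  s3 <- stage(s2$kept, is.na(s2$kept$allele_freq) |
                         s2$kept$allele_freq <= cfg$af_max)
  k <- s3$kept
  if (nrow(k)) {
    key <- paste(k$chrom, k$pos, k$ref, k$alt, sep = "\r")
    npools <- vapply(split(k$pool_id, key), function(p) length(unique(p)), 0L)
    s4 <- stage(k, npools[key] <= cfg$max_pools)
  } else {
    s4 <- list(kept = k, removed = 0L)
  }
  kept <- s4$kept
  rownames(kept) <- NULL
  report <- data.frame(
    filter = c("qual", "strand_bias", "allele_freq", "multi_pool"),
    removed = c(s1$removed, s2$removed, s3$removed, s4$removed)
  )
  stopifnot(sum(report$removed) == n0 - nrow(kept))
  structure(list(kept = kept, report = report, cfg = cfg),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("phenoseq filter: %d call(s) kept, %d removed\n",
              nrow(x$kept), sum(x$report$removed)))
  for (i in seq_len(nrow(x$report)))
    cat(sprintf("  %-12s %d\n", x$report$filter[i], x$report$removed[i]))
  invisible(x)
}

#' Write variant calls as a minimal VCF
#'
#' Emits a VCF 4.2 file in the samtools dialect consumed by
#' [read_pool_vcf()] (QUAL column, `AF1` and `PV4` INFO keys).
#'
#' @param calls variant `data.frame` for a single pool.
#' @param path output file.
#' @param contig contig name length attribute for the header, optional.
#' @export
write_pool_vcf <- function(calls, path, contig = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=phenoseqr",
    if (!is.null(contig))
      sprintf("##contig=<ID=%s,length=%d>", contig$id, contig$length),
    "##INFO=<ID=AF1,Number=1,Type=Float,Description=\"Estimated alternate allele frequency\">",
    "##INFO=<ID=PV4,Number=4,Type=Float,Description=\"P-values for strand bias, baseQ bias, mapQ bias and tail distance bias\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(calls)) {
    info <- sprintf("AF1=%.4g;PV4=%.3g,1,1,1", calls$allele_freq,
                    ifelse(is.na(calls$strand_bias_p), 1, calls$strand_bias_p))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.6g\t.\t%s",
                       calls$chrom, calls$pos, calls$ref, calls$alt,
                       calls$qual, info), con)
  }
  invisible(path)
}
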