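# Shared fixture builders: everything is generated in code at test time.

# compact synthetic experiment configuration for fast unit tests
small_cfg <- function(...) {
  synth_config(n_genes = 60L, gene_length_range = c(300L, 450L),
               intergenic_mean = 40, n_groups = 40L,
               n_strains = 6L, mutations_per_strain = 30,
               pool_size = 3L, n_pools = 2L, causal_spec = NULL, ...)
}

# variant call rows with defaults that pass every filter
make_calls <- function(n = 1, pos = seq_len(n), ref = "G", alt = "A",
                       qual = 200, pool_id = "P1", allele_freq = 0.33,
                       strand_bias_p = 0.5, chrom = "chr") {
  data.frame(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             qual = rep_len(qual, n), pool_id = rep_len(pool_id, n),
             allele_freq = rep_len(allele_freq, n),
             strand_bias_p = rep_len(strand_bias_p, n),
             stringsAsFactors = FALSE)
}

# a minimal single-gene genome: one forward-strand ORF spanning the
# given coding sequence with 6 bp of A padding on both sides
one_gene_genome <- function(coding, strand = 1L, pad = "AAAAAA") {
  genomic <- if (strand == 1L) coding else
    paste(rev(strsplit(chartr("ACGT", "TGCA", coding), "")[[1]]), collapse = "")
  seq <- paste0(pad, genomic, pad)
  phenoseq_genome(seq, data.frame(gene_id = "g1", strand = strand,
                                  start = nchar(pad) + 1L,
                                  end = nchar(pad) + nchar(coding)))
}

# independent oracle for the one-tailed Fisher test: exhaustive
# hypergeometric tail summation over all achievable tables
fisher_oracle <- function(ns_in, syn_in, ns_tot, syn_tot) {
  n <- ns_in + syn_in
  js <- ns_in:min(ns_tot, n)
  sum(choose(ns_tot, js) * choose(syn_tot, n - js)) / choose(ns_tot + syn_tot, n)
}

# write a small VCF body with given data lines (header included)
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF1,Number=1,Type=Float,Description=\"af\">",
    "##INFO=<ID=PV4,Number=4,Type=Float,Description=\"pv\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    lines), path)
  path
}
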