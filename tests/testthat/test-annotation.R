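# GenBank parsing and synonymous/nonsynonymous effect classification.

toy_gb <- system.file("extdata", "synthetic_toy.gb", package = "phenoseqr")

test_that("GenBank parser recovers sequence, strands and strand-corrected CDSs", {
  expect_warning(g <- read_genbank(toy_gb), "non-triplet")
  expect_equal(g$length, 240L)
  expect_equal(nrow(g$genes), 4L)
  expect_equal(g$genes$gene_id, sprintf("t%04d", 1:4))
  expect_equal(g$genes$name, c("toyA", "toyB", "toyC", "toyD"))
  expect_equal(g$genes$strand, c(1L, -1L, 1L, 1L))
  # values independently derived with Biopython when the fixture was built
  expect_equal(g$genes$coding_seq[1], "AATTACATAACATACACGTCAGCACGAAAC")
  expect_equal(g$genes$coding_seq[2], "CGTATGCATCACACTTACTTAACCCTTAAG")
  expect_equal(g$genes$coding_seq[3], "CTGTGTCCACTGGCATTT")  # join() location
  expect_false(g$genes$coding_ok[4])                         # length 10
  expect_equal(g$gc_count + g$at_count, g$length)
})

test_that("GenBank writer output is re-read identically", {
  g <- suppressWarnings(read_genbank(toy_gb))
  f <- tempfile(fileext = ".gb")
  write_genbank(g, f)
  g2 <- suppressWarnings(read_genbank(f))
  expect_identical(g2$seq, g$seq)
  expect_identical(g2$genes$coding_seq, g$genes$coding_seq)
  expect_identical(g2$genes$strand, g$genes$strand)
})

test_that("a GenBank file without sequence is fatal", {
  f <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp", "FEATURES",
               "     CDS             1..9", "//"), f)
  expect_error(read_genbank(f), "ORIGIN")
})

test_that("forward-strand codon substitutions classify by translation", {
  g <- one_gene_genome("ATGGATCTGTAA")          # Met Asp Leu Stop, span 7..18
  expect_equal(classify_effect(g, 12, "T", "A"), "nonsynonymous") # GAT->GAA Asp->Glu
  expect_equal(classify_effect(g, 15, "G", "A"), "synonymous")    # CTG->CTA Leu->Leu
  expect_equal(classify_effect(g, 11, "A", "T"), "nonsynonymous") # GAT->GTT Asp->Val
  # creating a stop codon counts as nonsynonymous
  g2 <- one_gene_genome("ATGTACAAA")
  expect_equal(classify_effect(g2, 12, "C", "A"), "nonsynonymous") # TAC->TAA
})

test_that("reverse-strand genes complement ref/alt before codon substitution", {
  # coding strand reads GAT ...; genomic strand holds its reverse complement,
  # so the genomic C opposite the coding G mutating C->T reads G->A on the
  # coding strand: GAT -> AAT (Asp -> Asn)
  g <- one_gene_genome("GATCCCTAA", strand = -1L)
  pos_of_coding_G <- g$genes$end[1]             # first coding base maps to span end
  expect_equal(g$seq[pos_of_coding_G], "C")
  expect_equal(classify_effect(g, pos_of_coding_G, "C", "T"), "nonsynonymous")
  # third codon position of the same codon: GAT->GAC is synonymous;
  # coding index 2 maps to genomic position end-2, coding T (genomic A)
  expect_equal(g$seq[g$genes$end[1] - 2L], "A")
  expect_equal(classify_effect(g, g$genes$end[1] - 2L, "A", "G"), "synonymous")
})

test_that("ref allele disagreeing with the reference is an error naming the position", {
  g <- one_gene_genome("ATGGATCTGTAA")
  expect_error(classify_effect(g, 12, "G", "A"), "position 12")
})

test_that("effect calls partition all point mutations identically to a brute-force oracle", {
  set.seed(42)
  for (strand in c(1L, -1L)) {
    coding <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                    collapse = "")
    g <- one_gene_genome(coding, strand = strand)
    span <- g$genes$start[1]:g$genes$end[1]
    code <- Biostrings::getGeneticCode("11")
    translate_all <- function(s) {
      cs <- paste(s[span], collapse = "")
      if (strand == -1L)
        cs <- paste(rev(strsplit(chartr("ACGT", "TGCA", cs), "")[[1]]),
                    collapse = "")
      paste(code[substring(cs, seq(1, nchar(cs), 3), seq(3, nchar(cs), 3))],
            collapse = "")
    }
    prot_ref <- translate_all(g$seq)
    for (pos in span) {
      for (alt in setdiff(c("A", "C", "G", "T"), g$seq[pos])) {
        mut <- g$seq
        mut[pos] <- alt
        oracle <- if (translate_all(mut) == prot_ref) "synonymous" else "nonsynonymous"
        expect_equal(classify_effect(g, pos, g$seq[pos], alt), oracle,
                     info = sprintf("strand %d pos %d alt %s", strand, pos, alt))
      }
    }
  }
})

test_that("a gene and its reverse-complemented twin give mirrored effect calls", {
  set.seed(7)
  coding <- paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE), collapse = "")
  fwd <- one_gene_genome(coding, strand = 1L)
  rev <- one_gene_genome(coding, strand = -1L)
  L <- fwd$length
  for (pos in fwd$genes$start[1]:fwd$genes$end[1]) {
    mirror <- L - pos + 1L
    for (alt in setdiff(c("A", "C", "G", "T"), fwd$seq[pos])) {
      expect_equal(
        classify_effect(fwd, pos, fwd$seq[pos], alt),
        classify_effect(rev, mirror, rev$seq[mirror],
                        chartr("ACGT", "TGCA", alt)))
    }
  }
})

test_that("annotation flags non-coding variants and reports overlapping CDS hits", {
  seq <- paste(rep("ACGT", 30), collapse = "")
  genes <- data.frame(gene_id = c("gA", "gB"), strand = 1L,
                      start = c(11L, 20L), end = c(31L, 40L))
  g <- phenoseq_genome(seq, genes)
  calls <- make_calls(3, pos = c(5L, 25L, 115L), chrom = "chr")
  calls$ref <- g$seq[calls$pos]
  calls$alt <- ifelse(calls$ref == "A", "G", "A")
  ann <- annotate_variants(calls, g)
  expect_true(ann$variants$noncoding[1] && ann$variants$noncoding[3])
  expect_equal(ann$variants$n_hits[2], 2L)     # inside both gA and gB
  expect_setequal(ann$hits$gene_id, c("gA", "gB"))
})

test_that("non-triplet CDSs are excluded from effect calling", {
  seq <- paste(rep("ACGT", 20), collapse = "")
  g <- suppressWarnings(phenoseq_genome(
    seq, data.frame(gene_id = c("ok", "bad"), strand = 1L,
                    start = c(1L, 31L), end = c(12L, 40L))))
  calls <- make_calls(1, pos = 35L, ref = g$seq[35], alt = "C")
  ann <- annotate_variants(calls, g)
  expect_true(ann$variants$noncoding[1])
})
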