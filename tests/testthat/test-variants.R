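# VCF input and the four-stage filter cascade.

test_that("read_pool_vcf keeps SNPs, splits multi-allelic records, skips indels", {
  p <- write_test_vcf(c(
    "chr\t10\t.\tG\tA\t220\t.\tAF1=0.31;PV4=0.4,1,1,1",
    "chr\t20\t.\tGT\tG\t200\t.\tAF1=0.3;PV4=0.5,1,1,1",   # indel
    "chr\t30\t.\tA\tC,T\t150\t.\tAF1=0.25;PV4=0.2,1,1,1", # multi-allelic
    "chr\t40\t.\tC\tCAT\t150\t.\tAF1=0.2;PV4=0.2,1,1,1"   # insertion
  ))
  calls <- suppressMessages(read_pool_vcf(p, "P3"))
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$pos, c(10L, 30L, 30L))
  expect_equal(calls$alt, c("A", "C", "T"))
  expect_equal(unique(calls$pool_id), "P3")
  expect_equal(calls$qual[1], 220)
  expect_equal(calls$allele_freq[2], 0.25)
  expect_equal(calls$strand_bias_p[1], 0.4)
})

test_that("empty VCF body yields an empty call table; missing file is fatal", {
  p <- write_test_vcf(character())
  expect_equal(nrow(suppressWarnings(read_pool_vcf(p, "P1"))), 0L)
  expect_error(read_pool_vcf(tempfile(), "P1"), "not found")
})

test_that("missing INFO keys leave fields NA with a warning, and such calls pass", {
  p <- write_test_vcf("chr\t10\t.\tG\tA\t220\t.\tDP=5")
  expect_warning(expect_warning(calls <- read_pool_vcf(p, "P1"), "AF1"), "PV4")
  expect_true(is.na(calls$allele_freq) && is.na(calls$strand_bias_p))
  flt <- filter_variants(calls, filter_config())
  expect_equal(nrow(flt$kept), 1L)
})

test_that("QUAL threshold is strict and AF ceiling inclusive", {
  calls <- make_calls(4, pos = 1:4,
                      qual = c(89, 91, 200, 200),
                      allele_freq = c(0.33, 0.33, 0.60, 0.33))
  flt <- filter_variants(calls, filter_config())
  expect_equal(flt$kept$pos, c(2L, 4L))
  expect_equal(flt$report$removed, c(1L, 0L, 1L, 0L))
  # boundary values: qual exactly 90 removed, af exactly 0.5 kept
  b <- filter_variants(make_calls(2, pos = 1:2, qual = c(90, 91),
                                  allele_freq = c(0.5, 0.5)))
  expect_equal(b$kept$pos, 2L)
})

test_that("sites in more than max_pools distinct pools are excluded as parental", {
  parental <- make_calls(8, pos = 100, pool_id = sprintf("P%d", 1:8))
  private <- make_calls(2, pos = c(5, 6), pool_id = "P1")
  flt <- filter_variants(rbind(parental, private), filter_config())
  expect_equal(sort(flt$kept$pos), c(5L, 6L))
  expect_equal(flt$report$removed[4], 8L)
  # same site in <= max_pools pools survives
  flt2 <- filter_variants(parental[1, ], filter_config())
  expect_equal(nrow(flt2$kept), 1L)
  # max_pools is configurable
  flt3 <- filter_variants(parental, filter_config(max_pools = 8))
  expect_equal(nrow(flt3$kept), 8L)
})

test_that("strand-bias filter removes biased calls and passes absent fields", {
  calls <- make_calls(3, pos = 1:3, strand_bias_p = c(1e-6, NA, 0.2))
  flt <- filter_variants(calls, filter_config())
  expect_equal(flt$kept$pos, c(2L, 3L))
  expect_equal(flt$report$removed, c(0L, 1L, 0L, 0L))
})

test_that("each removed call is attributed to the first failing stage", {
  # fails both qual and AF: must count under qual only
  calls <- make_calls(1, qual = 50, allele_freq = 0.9)
  flt <- filter_variants(calls)
  expect_equal(flt$report$removed, c(1L, 0L, 0L, 0L))
})

test_that("filtering is idempotent, order-insensitive, and report sums reconcile", {
  set.seed(11)
  n <- 200
  calls <- make_calls(n, pos = sample(1000, n, replace = TRUE),
                      qual = runif(n, 60, 300),
                      pool_id = sample(sprintf("P%d", 1:8), n, TRUE),
                      allele_freq = runif(n, 0, 1),
                      strand_bias_p = 10^runif(n, -8, 0))
  flt <- filter_variants(calls)
  expect_equal(sum(flt$report$removed), n - nrow(flt$kept))
  again <- filter_variants(flt$kept)
  expect_equal(again$kept, flt$kept)
  expect_equal(sum(again$report$removed), 0L)
  shuffled <- filter_variants(calls[sample(n), ])
  key <- function(df) sort(paste(df$pos, df$pool_id, df$alt))
  expect_equal(key(shuffled$kept), key(flt$kept))
})

test_that("pool VCF writer round-trips through the reader", {
  set.seed(3)
  calls <- make_calls(5, pos = c(10, 25, 40, 41, 90), ref = "C", alt = "T",
                      qual = runif(5, 100, 400),
                      allele_freq = round(runif(5, 0.1, 0.5), 3),
                      strand_bias_p = round(runif(5, 0.1, 1), 3))
  f <- tempfile(fileext = ".vcf")
  write_pool_vcf(calls, f)
  back <- read_pool_vcf(f, "P1")
  expect_equal(back$pos, calls$pos)
  expect_equal(back$allele_freq, calls$allele_freq, tolerance = 1e-3)
  expect_equal(back$strand_bias_p, calls$strand_bias_p, tolerance = 1e-2)
})
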