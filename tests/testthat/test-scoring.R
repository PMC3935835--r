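# Site densities, mutational cross-section and the Poisson score.

densities <- function(rho_gc, rho_at, mode = "all")
  structure(list(rho_gc = rho_gc, rho_at = rho_at,
                 n_mutations_used = NA, mode = mode),
            class = "site_densities")

test_that("site densities are class counts over genome site counts", {
  # genome of 100 GC + 100 AT sites, 10 mutations all on GC sites
  seq <- c(rep(c("G", "C"), 50), rep(c("A", "T"), 50))
  g <- phenoseq_genome(seq, data.frame(gene_id = "g1", strand = 1L,
                                       start = 1L, end = 99L))
  calls <- make_calls(10, pos = seq(1, 19, 2), ref = "G", alt = "A")
  calls <- rbind(calls, make_calls(0))
  ann <- annotate_variants(calls, g)
  expect_warning(d <- estimate_densities(ann, g), NA)
  expect_equal(d$rho_gc, 0.1)
  expect_equal(d$rho_at, 0)
  expect_equal(d$n_mutations_used, 10L)
})

test_that("density mode selects the mutation class and empty input warns", {
  x <- synth_experiment(small_cfg(), seed = 5)
  d_all <- estimate_densities(x$annotation, x$genome, mode = "all")
  d_ns <- estimate_densities(x$annotation, x$genome, mode = "nonsynonymous")
  expect_equal(d_all$n_mutations_used, nrow(x$annotation$variants))
  ns_rows <- unique(x$annotation$hits$variant_row[
    x$annotation$hits$effect == "nonsynonymous"])
  expect_equal(d_ns$n_mutations_used, length(ns_rows))
  expect_lt(d_ns$rho_gc, d_all$rho_gc)
  empty <- annotate_variants(make_calls(0), x$genome)
  expect_warning(d0 <- estimate_densities(empty, x$genome), "no mutations")
  expect_equal(d0$rho_gc + d0$rho_at, 0)
})

test_that("cross-section is the composition-weighted density sum, additive over genes", {
  d <- densities(0.01, 0.005)
  expect_equal(cross_section(data.frame(gc_sites = 300, at_sites = 0),
                             densities(0.01, 0)), 3.0)
  expect_equal(cross_section(data.frame(gc_sites = 200, at_sites = 100),
                             densities(0.02, 0.005)), 4.5)
  genes <- data.frame(gc_sites = c(120, 80), at_sites = c(30, 60))
  group <- data.frame(gc_sites = 200, at_sites = 90)
  expect_equal(sum(cross_section(genes, d)), cross_section(group, d))
})

test_that("poisson_pvalue matches closed forms and direct pmf summation", {
  expect_equal(poisson_pvalue(0, 2.3), 1)
  expect_equal(poisson_pvalue(3, 0.5),
               1 - exp(-0.5) * (1 + 0.5 + 0.125), tolerance = 1e-12)
  expect_equal(poisson_pvalue(2, 1), 1 - 2 * exp(-1), tolerance = 1e-12)
  # oracle: direct summation of the upper-tail pmf
  tail_sum <- function(n, lam) {
    ks <- n:(n + 3000)
    sum(exp(ks * log(lam) - lam - lgamma(ks + 1)))
  }
  for (lam in c(0.1, 0.5, 1, 5, 20, 50)) {
    for (n in c(1, 2, 3, 10, 50, 200)) {
      expect_equal(poisson_pvalue(n, lam), tail_sum(n, lam),
                   tolerance = 1e-12,
                   info = sprintf("lambda=%g n=%d", lam, n))
    }
  }
  expect_error(poisson_pvalue(3, 0), "lambda")
})

test_that("poisson_pvalue is monotone in n_obs and in lambda", {
  lam <- 4
  p <- poisson_pvalue(0:30, lam)
  expect_true(all(diff(p) < 0))
  lams <- seq(0.5, 30, by = 0.5)
  p2 <- poisson_pvalue(5, lams)
  expect_true(all(diff(p2) > 0))
})

test_that("score_units ranks by p with deterministic tie-breaking and corrects by n_tests", {
  tal <- data.frame(unit_id = c("b", "a", "c"),
                    ns = c(1L, 5L, 5L), syn = 0L,
                    gc_sites = 100, at_sites = 100)
  sc <- score_units(tal, densities(0.005, 0.005), n_tests = 536)
  expect_equal(sc$unit_id, c("a", "c", "b"))   # same lambda: more hits first, then id
  expect_equal(sc$rank, 1:3)
  expect_equal(sc$p_corr, pmin(1, sc$p_raw * 536))
  expect_equal(score_units(data.frame(unit_id = "u", ns = 0L, syn = 0L,
                                      gc_sites = 10, at_sites = 10),
                           densities(0.001, 0.001))$p_raw, 1)
})

test_that("scoring is invariant to unit order", {
  set.seed(8)
  tal <- data.frame(unit_id = sprintf("u%02d", 1:20),
                    ns = rpois(20, 3), syn = rpois(20, 1),
                    gc_sites = sample(100:500, 20),
                    at_sites = sample(100:500, 20))
  d <- densities(0.004, 0.001)
  s1 <- score_units(tal, d)
  s2 <- score_units(tal[sample(20), ], d)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})
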