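# Wright-Fisher diversity-loss simulator: a mutagenized founder
# population grown to carrying capacity and resampled under selection,
# tracking distinct-strain counts and Shannon entropy.  Motivates
# non-competitive screening of mutant strains: under competitive
# culture most founder strains are lost within a few generations.

#' Shannon entropy of a population distribution, in bits
#'
#' `-sum(p * log2(p))` with `0 * log(0) := 0`.
#'
#' @param proportions nonnegative vector summing to 1.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(proportions) {
  if (any(proportions < 0)) stopf("proportions must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-8) stopf("proportions must sum to 1")
  p <- proportions[proportions > 0]
  -sum(p * log2(p))
}

#' One Wright-Fisher resampling step
#'
#' Draws the next generation multinomially with probabilities
#' proportional to `counts * fitnesses`.  Extinct strains stay
#' extinct (no mutation, no back-migration).
#'
#' @param counts integer vector of per-strain counts.
#' @param fitnesses positive relative fitness per strain.
#' @param pop_size population size of the next generation.
#' @return integer vector of next-generation counts.
#' @export
wf_step <- function(counts, fitnesses, pop_size = sum(counts)) {
  if (all(counts == 0)) stopf("population is extinct (all counts zero)")
  if (any(fitnesses <= 0)) stopf("fitnesses must be positive")
  w <- counts * fitnesses
  as.vector(stats::rmultinom(1, pop_size, w / sum(w)))
}

#' Simulate diversity loss of a mutagenized population under selection
#'
#' Each replicate starts from `n_strains` founders of one cell each.
#' During the growth phase the population doubles each generation
#' until it reaches the carrying capacity -- deterministically by
#' default, or with Wright-Fisher resampling at the growing size when
#' `resample_growth = TRUE` (small-population drift then removes
#' strains already during growth).  After capacity is reached, the
#' population is resampled multinomially at fixed size for
#' `n_generations` generations with probabilities proportional to
#' count times fitness.
#'
#' Fitnesses are drawn per replicate from a lognormal distribution
#' with `sdlog = fitness_sdlog` (a stand-in for the unknown fitness
#' spectrum of a randomly mutagenized population) unless a fixed
#' `fitnesses` vector is supplied.
#'
#' @param n_strains founder strain count (default 26).
#' @param carrying_capacity population ceiling (default 1e6).
#' @param n_generations generations simulated after capacity is
#'   reached (default 30).
#' @param n_replicates independent replicate populations (default 1000).
#' @param fitnesses fixed per-strain fitness vector, or `NULL` to draw
#'   lognormal fitnesses per replicate.
#' @param fitness_sdlog sdlog of the lognormal fitness draw; 0 gives a
#'   neutral population.
#' @param resample_growth apply Wright-Fisher resampling during the
#'   growth phase as well.
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `wf_sim`: list with `generation`
#'   (0 = capacity reached), `mean_distinct`, `mean_entropy`,
#'   `half_diversity_gen` (first generation with mean distinct count
#'   at or below half the founders, `NA` if never), the per-replicate
#'   trajectory matrices `distinct` and `entropy`, and the call
#'   parameters.
#' @export
simulate_wf <- function(n_strains = 26L, carrying_capacity = 1e6,
                        n_generations = 30L, n_replicates = 1000L,
                        fitnesses = NULL, fitness_sdlog = 0.05,
                        resample_growth = FALSE, seed = NULL) {
  stopifnot(carrying_capacity >= n_strains, n_generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  ngen <- n_generations + 1L   # include generation 0 (capacity reached)
  distinct <- matrix(0L, n_replicates, ngen)
  entropy <- matrix(0, n_replicates, ngen)
  for (r in seq_len(n_replicates)) {
    w <- fitnesses %||% stats::rlnorm(n_strains, 0, fitness_sdlog)
    counts <- rep(1L, n_strains)
    while (sum(counts) < carrying_capacity) {
      target <- min(2 * sum(counts), carrying_capacity)
      counts <- if (resample_growth) wf_step(counts, w, target)
                else counts * 2L
    }
    if (sum(counts) > carrying_capacity)   # deterministic overshoot
      counts <- wf_step(counts, rep(1, n_strains), carrying_capacity)
    for (g in seq_len(ngen)) {
      if (g > 1L) counts <- wf_step(counts, w, carrying_capacity)
      distinct[r, g] <- sum(counts > 0L)
      entropy[r, g] <- shannon_entropy(counts / sum(counts))
    }
  }
  mean_distinct <- colMeans(distinct)
  half <- which(mean_distinct <= n_strains / 2)
  structure(list(
    generation = 0:(ngen - 1L),
    mean_distinct = mean_distinct,
    mean_entropy = colMeans(entropy),
    half_diversity_gen = if (length(half)) half[1] - 1L else NA_integer_,
    distinct = distinct, entropy = entropy,
    n_strains = n_strains, carrying_capacity = carrying_capacity,
    n_replicates = n_replicates, fitness_sdlog = fitness_sdlog,
    resample_growth = resample_growth
  ), class = "wf_sim")
}

#' @export
print.wf_sim <- function(x, ...) {
  cat(sprintf("Wright-Fisher simulation: %d strains, capacity %g, %d replicates, %d post-capacity generations\n",
              x$n_strains, x$carrying_capacity, x$n_replicates,
              length(x$generation) - 1L))
  cat(sprintf("  mean distinct strains: %.1f -> %.1f; mean entropy: %.2f -> %.2f bits\n",
              x$mean_distinct[1], x$mean_distinct[length(x$mean_distinct)],
              x$mean_entropy[1], x$mean_entropy[length(x$mean_entropy)]))
  if (!is.na(x$half_diversity_gen))
    cat(sprintf("  half of the strains lost by generation %d\n", x$half_diversity_gen))
  invisible(x)
}

#' Plot mean diversity trajectories of a Wright-Fisher simulation
#'
#' @param x a [simulate_wf()] result.
#' @param ... passed to [plot()].
#' @export
plot.wf_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$generation, x$mean_distinct, type = "l",
       xlab = "generation after reaching capacity",
       ylab = "mean distinct strains", ...)
  graphics::abline(h = x$n_strains / 2, lty = 3)
  plot(x$generation, x$mean_entropy, type = "l",
       xlab = "generation after reaching capacity",
       ylab = "mean Shannon entropy (bits)", ...)
  invisible(x)
}
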