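# A compact real+binary genetic algorithm (maximization). Chromosomes carry
# bounded real genes and a tail of bits; operators are tournament selection,
# simulated-binary crossover (SBX) with uniform bit crossover, polynomial
# mutation with bit flips, and elitism.

#' Genetic algorithm settings
#'
#' @param population Population size (>= 10).
#' @param generations Number of generations (>= 1).
#' @param crossover Crossover probability per parent pair.
#' @param mutation Per-gene mutation probability.
#' @param elitism Number of best individuals copied unchanged.
#' @param seed Integer seed (required: inversions are reproducible by
#'   construction).
#' @param eta_c,eta_m SBX and polynomial-mutation distribution indices.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 80L, generations = 60L, crossover = 0.9,
                      mutation = 0.1, elitism = 2L, seed,
                      eta_c = 10, eta_m = 20) {
  if (missing(seed)) stop("ga_config requires an explicit seed")
  stopifnot(population >= 10, generations >= 1,
            crossover >= 0, crossover <= 1, mutation >= 0, mutation <= 1,
            elitism >= 0, elitism < population)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover = crossover, mutation = mutation,
                 elitism = as.integer(elitism), seed = as.integer(seed),
                 eta_c = eta_c, eta_m = eta_m),
            class = "ga_config")
}

# fitness: function(real_vector, bit_vector) -> scalar (larger is better)
# init: optional list(reals, bits) seeding the population (e.g. the final
# population of a previous, coarser stage)
.ga_optimize <- function(fitness, lower, upper, n_bits, cfg, init = NULL,
                         reseed = TRUE) {
  np <- cfg$population
  nr <- length(lower)
  if (reseed) set.seed(cfg$seed)
  if (is.null(init)) {
    # Latin-hypercube style initialization: stratified in every dimension
    reals <- matrix(0, np, nr)
    for (j in seq_len(nr)) {
      strata <- (sample.int(np) - stats::runif(np)) / np
      reals[, j] <- lower[j] + strata * (upper[j] - lower[j])
    }
    bits <- matrix(stats::runif(np * n_bits) < 0.5, nrow = np)
  } else {
    reals <- init$reals; bits <- init$bits
  }
  evaluate <- function(R, B) {
    vapply(seq_len(nrow(R)), function(i) fitness(R[i, ], B[i, ]), 0)
  }
  fit <- evaluate(reals, bits)
  best_i <- which.max(fit)
  best <- list(real = reals[best_i, ], bits = bits[best_i, ],
               value = fit[best_i])
  history <- numeric(cfg$generations)
  tournament <- function() {
    cand <- sample.int(np, 3L, replace = TRUE)
    cand[which.max(fit[cand])]
  }
  for (gen in seq_len(cfg$generations)) {
    idx_elite <- order(fit, decreasing = TRUE)[seq_len(cfg$elitism)]
    nr_new <- np - cfg$elitism
    R2 <- matrix(0, nr_new, nr); B2 <- matrix(FALSE, nr_new, n_bits)
    i <- 1L
    while (i <= nr_new) {
      p1 <- tournament(); p2 <- tournament()
      c1r <- reals[p1, ]; c2r <- reals[p2, ]
      c1b <- bits[p1, ]; c2b <- bits[p2, ]
      if (stats::runif(1) < cfg$crossover) {
        # SBX per real gene
        u <- stats::runif(nr)
        beta <- ifelse(u <= 0.5, (2 * u)^(1 / (cfg$eta_c + 1)),
                       (1 / (2 * (1 - u)))^(1 / (cfg$eta_c + 1)))
        m <- (c1r + c2r) / 2; h <- abs(c1r - c2r) / 2
        c1r <- m - beta * h; c2r <- m + beta * h
        swap <- stats::runif(n_bits) < 0.5
        tmp <- c1b[swap]; c1b[swap] <- c2b[swap]; c2b[swap] <- tmp
      }
      for (child in list(list(r = c1r, b = c1b), list(r = c2r, b = c2b))) {
        if (i > nr_new) break
        r <- child$r; b <- child$b
        mut <- stats::runif(nr) < cfg$mutation
        if (any(mut)) {
          u <- stats::runif(sum(mut))
          delta <- ifelse(u < 0.5, (2 * u)^(1 / (cfg$eta_m + 1)) - 1,
                          1 - (2 * (1 - u))^(1 / (cfg$eta_m + 1)))
          r[mut] <- r[mut] + delta * (upper[mut] - lower[mut])
        }
        r <- pmin(pmax(r, lower), upper)
        flip <- stats::runif(n_bits) < cfg$mutation
        b[flip] <- !b[flip]
        R2[i, ] <- r; B2[i, ] <- b
        i <- i + 1L
      }
    }
    fit2 <- evaluate(R2, B2)
    reals <- rbind(reals[idx_elite, , drop = FALSE], R2)
    bits <- rbind(bits[idx_elite, , drop = FALSE], B2)
    fit <- c(fit[idx_elite], fit2)
    gi <- which.max(fit)
    if (fit[gi] > best$value) {
      best <- list(real = reals[gi, ], bits = bits[gi, ], value = fit[gi])
    }
    history[gen] <- best$value
  }
  c(best, list(history = history, pop_reals = reals, pop_bits = bits))
}
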