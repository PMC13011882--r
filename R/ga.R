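## Real-coded genetic algorithm with optional binary genes.
## Simulated-binary crossover + polynomial mutation for the continuous part,
## uniform crossover + bit-flip for the binary part, tournament selection,
## elitist survivor selection.  Used for Halbach geometry and passive-shim
## placement optimization.

#' Genetic-algorithm hyperparameters
#'
#' @param population population size (>= 4).
#' @param generations maximum number of generations.
#' @param crossover_rate probability a selected pair is crossed (SBX on the
#'   continuous genes, uniform crossover on the binary genes).
#' @param mutation_rate per-gene polynomial-mutation probability for the
#'   continuous part; `NULL` means `1 / n_continuous`.
#' @param bit_mutation_rate per-bit flip probability; `NULL` means `1/n_bits`.
#' @param eta_crossover,eta_mutation SBX / polynomial distribution indices.
#' @param patience stop early after this many generations without improvement
#'   of the best objective.
#' @param seed integer seed; every optimization run requires one so results
#'   are reproducible.
#' @param eval_grid optional evaluation-grid specification passed through to
#'   the objective (e.g. a DSV grid from [dsv_grid()]).
#' @return an object of class `ga_params`.
#' @export
ga_params <- function(population = 40L, generations = 150L,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      bit_mutation_rate = NULL,
                      eta_crossover = 15, eta_mutation = 20,
                      patience = 40L, seed = NULL, eval_grid = NULL) {
  if (population < 4) stop("population must be >= 4")
  if (crossover_rate < 0 || crossover_rate > 1) stop("crossover_rate in [0,1]")
  if (!is.null(mutation_rate) && (mutation_rate < 0 || mutation_rate > 1))
    stop("mutation_rate in [0,1]")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 bit_mutation_rate = bit_mutation_rate,
                 eta_crossover = eta_crossover, eta_mutation = eta_mutation,
                 patience = as.integer(patience), seed = seed,
                 eval_grid = eval_grid),
            class = "ga_params")
}

# SBX crossover of two bounded real vectors
.sbx <- function(p1, p2, lower, upper, eta) {
  n <- length(p1)
  c1 <- p1; c2 <- p2
  do_x <- runif(n) < 0.5 & abs(p1 - p2) > 1e-14
  if (any(do_x)) {
    u <- runif(sum(do_x))
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    x1 <- p1[do_x]; x2 <- p2[do_x]
    c1[do_x] <- 0.5 * ((1 + beta) * x1 + (1 - beta) * x2)
    c2[do_x] <- 0.5 * ((1 - beta) * x1 + (1 + beta) * x2)
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

# polynomial mutation in place
.poly_mutate <- function(x, lower, upper, pm, eta) {
  n <- length(x)
  do_m <- runif(n) < pm
  if (any(do_m)) {
    u <- runif(sum(do_m))
    span <- (upper - lower)[do_m]
    delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                    1 - (2 * (1 - u))^(1 / (eta + 1)))
    x[do_m] <- pmin(pmax(x[do_m] + delta * span, lower[do_m]), upper[do_m])
  }
  x
}

#' Minimize an objective with a mixed real/binary genetic algorithm
#'
#' @param fn objective `function(x, bits)` returning a scalar to minimize
#'   (`bits` is an integer 0/1 vector, absent genes give `integer(0)`).
#' @param lower,upper bounds of the continuous genes (equal length; may be
#'   length 0 for a purely binary problem).
#' @param n_bits number of binary genes.
#' @param params a [ga_params()] object; `params$seed` must be set.
#' @param init optional list of individuals (`list(x =, bits =)`) injected
#'   into the initial population.
#' @param repair optional `function(x)` projecting a continuous vector onto
#'   the feasible set (applied after crossover/mutation).
#' @return list with `par`, `bits`, `value`, `trace` (best objective per
#'   generation, non-increasing), and `evaluations`.
#' @export
ga_minimize <- function(fn, lower = numeric(0), upper = numeric(0),
                        n_bits = 0L, params = ga_params(), init = NULL,
                        repair = NULL) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  if (is.null(params$seed)) stop("ga_params$seed must be set for reproducibility")
  set.seed(params$seed)
  d <- length(lower)
  n_bits <- as.integer(n_bits)
  pm <- if (is.null(params$mutation_rate)) 1 / max(1, d) else params$mutation_rate
  pb <- if (is.null(params$bit_mutation_rate)) 1 / max(1, n_bits) else params$bit_mutation_rate
  np <- params$population

  fix <- function(x) if (!is.null(repair) && d > 0) repair(x) else x
  pop_x <- vector("list", np)
  pop_b <- vector("list", np)
  for (i in seq_len(np)) {
    pop_x[[i]] <- fix(lower + runif(d) * (upper - lower))
    pop_b[[i]] <- if (n_bits > 0) as.integer(runif(n_bits) < 0.5) else integer(0)
  }
  if (!is.null(init)) {
    for (i in seq_along(init)) {
      if (i > np) break
      if (!is.null(init[[i]]$x)) pop_x[[i]] <- fix(init[[i]]$x)
      if (n_bits > 0 && !is.null(init[[i]]$bits))
        pop_b[[i]] <- as.integer(init[[i]]$bits)
    }
  }
  fit <- vapply(seq_len(np), function(i) fn(pop_x[[i]], pop_b[[i]]), 0)
  evals <- np
  best_i <- which.min(fit)
  best <- list(x = pop_x[[best_i]], b = pop_b[[best_i]], f = fit[best_i])
  trace <- numeric(0)
  stall <- 0L

  for (gen in seq_len(params$generations)) {
    # binary tournament selection of parents
    sel <- function() {
      a <- sample.int(np, 2)
      if (fit[a[1]] <= fit[a[2]]) a[1] else a[2]
    }
    off_x <- vector("list", np)
    off_b <- vector("list", np)
    i <- 1L
    while (i <= np) {
      p1 <- sel(); p2 <- sel()
      x1 <- pop_x[[p1]]; x2 <- pop_x[[p2]]
      b1 <- pop_b[[p1]]; b2 <- pop_b[[p2]]
      if (runif(1) < params$crossover_rate) {
        if (d > 0) {
          cx <- .sbx(x1, x2, lower, upper, params$eta_crossover)
          x1 <- cx[[1]]; x2 <- cx[[2]]
        }
        if (n_bits > 0) {
          swap <- runif(n_bits) < 0.5
          t1 <- b1
          b1[swap] <- b2[swap]; b2[swap] <- t1[swap]
        }
      }
      if (d > 0) {
        x1 <- fix(.poly_mutate(x1, lower, upper, pm, params$eta_mutation))
        x2 <- fix(.poly_mutate(x2, lower, upper, pm, params$eta_mutation))
      }
      if (n_bits > 0) {
        f1 <- runif(n_bits) < pb
        f2 <- runif(n_bits) < pb
        b1[f1] <- 1L - b1[f1]
        b2[f2] <- 1L - b2[f2]
      }
      off_x[[i]] <- x1; off_b[[i]] <- b1
      if (i + 1L <= np) { off_x[[i + 1L]] <- x2; off_b[[i + 1L]] <- b2 }
      i <- i + 2L
    }
    off_fit <- vapply(seq_len(np), function(j) fn(off_x[[j]], off_b[[j]]), 0)
    evals <- evals + np
    # elitist survivor selection: best np of parents + offspring
    all_fit <- c(fit, off_fit)
    keep <- order(all_fit)[seq_len(np)]
    all_x <- c(pop_x, off_x); all_b <- c(pop_b, off_b)
    pop_x <- all_x[keep]; pop_b <- all_b[keep]
    fit <- all_fit[keep]
    if (fit[1] < best$f - 1e-15) {
      best <- list(x = pop_x[[1]], b = pop_b[[1]], f = fit[1])
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- c(trace, best$f)
    if (stall >= params$patience) break
  }
  list(par = best$x, bits = best$b, value = best$f, trace = trace,
       evaluations = evals)
}
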