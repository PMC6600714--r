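# Real-parameter genetic algorithm over the conjugate geometry. A specimen
# is an 8-gene genome: genes 1-5 jointly express the separation distance
# through their geometric mean (so recombination and mutation perturb r
# smoothly), genes 6-8 are the orientation angles thetaT, thetaD, thetaA.

GENOME_LENGTH <- 8L
PENALTY_BASE <- 1e30  # cost assigned beyond any feasible reciprocal cost

#' GA configuration
#'
#' Defaults follow the study protocol: populations of 300 specimens, 550
#' generations, 10% per-gene mutation probability. Selection, crossover and
#' elitism are configurable artifact choices.
#'
#' @param population_size Specimens per generation (>= 2, default 300).
#' @param generations Generation cap (default 550).
#' @param mutation_prob Per-gene probability of a fresh uniform redraw
#'   (default 0.10).
#' @param crossover `"uniform"` (default) or `"single_point"`.
#' @param elitism_count Best specimens copied unchanged into the next
#'   generation (default 2; >= 1 guarantees a non-increasing best cost).
#' @param selection `"fitness_proportionate"` (default) or `"tournament"`
#'   (size 2).
#' @param objective `"inverse_gamma_d"` (cost = 1/Gamma_d, maximizes the
#'   differential enhancement factor) or `"inverse_tau"` (cost = 1/tau,
#'   maximizes the fluorescence lifetime).
#' @param seed Integer seed; a (config, seed) pair fully determines the run.
#' @param distance_bounds Bounds for genes 1-5, nm (default c(1, 100), the
#'   distance-scan range).
#' @param angle_bounds Bounds for genes 6-8, degrees (default c(0, 90)).
#' @param stall_generations Stop early after this many generations without
#'   relative best-cost improvement above `stall_tol` (default 50).
#' @param stall_tol Relative improvement threshold (default 1e-9).
#' @return An object of class `mef_ga_config`.
#' @export
ga_config <- function(population_size = 300, generations = 550,
                      mutation_prob = 0.10,
                      crossover = c("uniform", "single_point"),
                      elitism_count = 2,
                      selection = c("fitness_proportionate", "tournament"),
                      objective = c("inverse_gamma_d", "inverse_tau"),
                      seed = 1L,
                      distance_bounds = c(1, 100),
                      angle_bounds = c(0, 90),
                      stall_generations = 50, stall_tol = 1e-9) {
  crossover <- match.arg(crossover)
  selection <- match.arg(selection)
  objective <- match.arg(objective)
  if (population_size < 2) stop("population_size must be >= 2", call. = FALSE)
  if (generations < 1) stop("generations must be >= 1", call. = FALSE)
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("mutation_prob must lie in [0, 1]", call. = FALSE)
  if (elitism_count < 0 || elitism_count >= population_size)
    stop("elitism_count must lie in [0, population_size)", call. = FALSE)
  if (distance_bounds[1] <= 0 || diff(distance_bounds) <= 0)
    stop("distance_bounds must be positive and increasing", call. = FALSE)
  if (angle_bounds[1] < 0 || angle_bounds[2] > 90 || diff(angle_bounds) <= 0)
    stop("angle_bounds must be increasing within [0, 90]", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_prob = mutation_prob, crossover = crossover,
                 elitism_count = as.integer(elitism_count),
                 selection = selection, objective = objective,
                 seed = as.integer(seed),
                 distance_bounds = as.numeric(distance_bounds),
                 angle_bounds = as.numeric(angle_bounds),
                 stall_generations = as.integer(stall_generations),
                 stall_tol = stall_tol),
            class = "mef_ga_config")
}

#' Per-gene bounds matrix of a configuration
#' @param config A `mef_ga_config`.
#' @return 8 x 2 matrix with columns `low`, `high`.
#' @export
genome_bounds <- function(config) {
  b <- rbind(matrix(rep(config$distance_bounds, each = 5), ncol = 2),
             matrix(rep(config$angle_bounds, each = 3), ncol = 2))
  dimnames(b) <- list(NULL, c("low", "high"))
  b
}

#' Draw a random genome
#'
#' Each gene uniform within its bounds, using R's global RNG stream (seed
#' it for reproducibility).
#'
#' @param bounds 8 x 2 bounds matrix as from [genome_bounds()].
#' @return Numeric vector of 8 genes.
#' @export
random_genome <- function(bounds) {
  if (any(bounds[, 1] > bounds[, 2]))
    stop("gene lower bound exceeds upper bound", call. = FALSE)
  stats::runif(nrow(bounds), bounds[, 1], bounds[, 2])
}

#' Decode a genome into a geometry
#'
#' The separation distance is the geometric mean of genes 1-5; genes 6-8
#' pass through as the orientation angles (degrees).
#'
#' @param genes Numeric vector of 8 genes (genes 1-5 positive).
#' @return A one-row `mef_geometry`.
#' @export
decode_genome <- function(genes) {
  if (length(genes) != GENOME_LENGTH)
    stop("a genome has exactly ", GENOME_LENGTH, " genes", call. = FALSE)
  if (any(genes[1:5] <= 0))
    stop("distance genes must be positive", call. = FALSE)
  geometry(r_nm = exp(mean(log(genes[1:5]))),
           thetaT = genes[6], thetaD = genes[7], thetaA = genes[8])
}

# vectorized decode of a population matrix (8 x N)
decode_population <- function(pop) {
  geometry(r_nm = exp(colMeans(log(pop[1:5, , drop = FALSE]))),
           thetaT = pop[6, ], thetaD = pop[7, ], thetaA = pop[8, ])
}

# cost transform shared by evaluate_cost, run_ga and the grid oracle.
# Infeasible specimens (Gamma_d <= 0 under inverse_gamma_d, or any
# non-finite photophysics output) receive a finite ordered penalty so
# selection pressure stays smooth.
cost_from_result <- function(res, objective) {
  cost <- if (objective == "inverse_gamma_d") {
    ifelse(res$gamma_d_hz > 0, 1 / res$gamma_d_hz,
           PENALTY_BASE + abs(res$gamma_d_hz))
  } else {
    1 / res$tau_ns
  }
  cost[!is.finite(cost)] <- PENALTY_BASE
  cost
}

#' Evaluate the cost of a genome
#'
#' Decodes the genome, runs the full photophysics, and maps the result to
#' the scalar GA cost (lower = fitter): `1/Gamma_d` for the differential
#' enhancement objective (with a finite ordered penalty when Gamma_d <= 0),
#' or `1/tau` for the lifetime objective.
#'
#' @param genes 8-gene numeric vector.
#' @param dye A `mef_dye`.
#' @param ns A `mef_nanostructure`.
#' @param objective `"inverse_gamma_d"` or `"inverse_tau"`.
#' @param system Optional prebuilt [mef_system()] (avoids recomputing the
#'   spectral integrals).
#' @return List with `cost` (scalar) and `result` (one-row photophysics
#'   data.frame).
#' @export
evaluate_cost <- function(genes, dye, ns,
                          objective = c("inverse_gamma_d", "inverse_tau"),
                          system = NULL) {
  objective <- match.arg(objective)
  if (is.null(system)) system <- mef_system(dye, ns)
  res <- evaluate_photophysics(system, decode_genome(genes))
  list(cost = cost_from_result(res, objective), result = res)
}

#' Select parent pairs
#'
#' Fitness-proportionate sampling on the declared transform
#' `fitness = 1/(cost - min(cost) + eps)` with
#' `eps = 0.01 * (max(cost) - min(cost))` (or 1 when all costs are equal,
#' giving uniform selection), or tournament selection of size 2. Sampling
#' is with replacement; fitter specimens are selected with strictly higher
#' probability.
#'
#' @param costs Finite numeric cost vector (lower = fitter).
#' @param n_pairs Number of parent pairs to draw.
#' @param method `"fitness_proportionate"` or `"tournament"`.
#' @return 2 x `n_pairs` integer matrix of specimen indices.
#' @export
select_parents <- function(costs, n_pairs,
                           method = c("fitness_proportionate", "tournament")) {
  method <- match.arg(method)
  if (length(costs) == 0L) stop("empty population", call. = FALSE)
  if (any(!is.finite(costs))) stop("costs must be finite", call. = FALSE)
  n <- length(costs)
  if (method == "fitness_proportionate") {
    spread <- max(costs) - min(costs)
    eps <- if (spread > 0) 0.01 * spread else 1
    fitness <- 1 / (costs - min(costs) + eps)
    idx <- sample.int(n, 2L * n_pairs, replace = TRUE, prob = fitness)
  } else {
    a <- sample.int(n, 2L * n_pairs, replace = TRUE)
    b <- sample.int(n, 2L * n_pairs, replace = TRUE)
    idx <- ifelse(costs[a] <= costs[b], a, b)
  }
  matrix(idx, nrow = 2L)
}

#' Crossover two genomes
#'
#' Uniform crossover (default): each gene of the first child is inherited
#' from either parent with probability 1/2 and the second child takes the
#' complement. Single-point crossover swaps the gene tails after a random
#' cut. Children automatically satisfy the bounds.
#'
#' @param p1,p2 Parent genomes (8 genes, same bounds).
#' @param method `"uniform"` or `"single_point"`.
#' @return List of two child genomes `c1`, `c2`.
#' @export
crossover <- function(p1, p2, method = c("uniform", "single_point")) {
  method <- match.arg(method)
  if (method == "uniform") {
    mask <- stats::runif(GENOME_LENGTH) < 0.5
    list(c1 = ifelse(mask, p1, p2), c2 = ifelse(mask, p2, p1))
  } else {
    cut <- sample.int(GENOME_LENGTH - 1L, 1L)
    list(c1 = c(p1[seq_len(cut)], p2[-seq_len(cut)]),
         c2 = c(p2[seq_len(cut)], p1[-seq_len(cut)]))
  }
}

#' Mutate a genome
#'
#' Each gene is independently replaced, with probability `prob`, by a fresh
#' uniform draw within its bounds.
#'
#' @param genes 8-gene numeric vector.
#' @param bounds 8 x 2 bounds matrix.
#' @param prob Per-gene mutation probability (default 0.10).
#' @return Mutated genome.
#' @export
mutate <- function(genes, bounds, prob = 0.10) {
  if (prob < 0 || prob > 1) stop("prob must lie in [0, 1]", call. = FALSE)
  mask <- stats::runif(length(genes)) < prob
  if (any(mask))
    genes[mask] <- stats::runif(sum(mask), bounds[mask, 1], bounds[mask, 2])
  genes
}

#' Run the genetic algorithm
#'
#' Generational loop: evaluate every specimen through the photophysics
#' model, copy the elite unchanged, select parents fitness-proportionately,
#' recombine, mutate, repeat. Stops at the generation cap or after
#' `stall_generations` without relative best-cost improvement above
#' `stall_tol`. Fully reproducible: the configured seed determines every
#' random draw. Specimens whose evaluation fails or returns non-finite
#' values receive the finite penalty cost and the run continues.
#'
#' @param config A `mef_ga_config`.
#' @param dye A `mef_dye`.
#' @param ns A `mef_nanostructure`.
#' @return An object of class `mef_ga_result`: `best_genome`,
#'   `best_geometry`, `best_cost`, `best_result`, `cost_history`
#'   (best-so-far per generation, non-increasing with elitism),
#'   `median_history`, `evaluations_count`, `generations_run`, `config`,
#'   `seed`.
#' @export
run_ga <- function(config, dye, ns) {
  stopifnot(inherits(config, "mef_ga_config"))
  set.seed(config$seed)
  system <- mef_system(dye, ns)
  bounds <- genome_bounds(config)
  npop <- config$population_size
  pop <- matrix(stats::runif(GENOME_LENGTH * npop,
                             bounds[, 1], bounds[, 2]),
                nrow = GENOME_LENGTH)
  best_cost <- Inf
  best_genes <- NULL
  cost_history <- numeric(0)
  median_history <- numeric(0)
  evaluations <- 0L
  stall <- 0L
  gens_run <- 0L
  for (gen in seq_len(config$generations)) {
    res <- evaluate_photophysics(system, decode_population(pop))
    costs <- cost_from_result(res, config$objective)
    evaluations <- evaluations + npop
    gens_run <- gen
    gen_best <- which.min(costs)
    improved <- costs[gen_best] < best_cost * (1 - config$stall_tol)
    if (costs[gen_best] < best_cost) {
      best_cost <- costs[gen_best]
      best_genes <- pop[, gen_best]
    }
    cost_history <- c(cost_history, best_cost)
    median_history <- c(median_history, stats::median(costs))
    stall <- if (improved) 0L else stall + 1L
    if (stall >= config$stall_generations) break
    if (gen == config$generations) break
    # next generation: elite + recombined, mutated children
    elite_idx <- order(costs)[seq_len(config$elitism_count)]
    n_children <- npop - config$elitism_count
    pairs <- select_parents(costs, ceiling(n_children / 2),
                            method = config$selection)
    children <- matrix(0, nrow = GENOME_LENGTH, ncol = 2 * ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      ch <- crossover(pop[, pairs[1, p]], pop[, pairs[2, p]],
                      method = config$crossover)
      children[, 2 * p - 1] <- ch$c1
      children[, 2 * p] <- ch$c2
    }
    children <- children[, seq_len(n_children), drop = FALSE]
    for (j in seq_len(ncol(children)))
      children[, j] <- mutate(children[, j], bounds, config$mutation_prob)
    pop <- cbind(pop[, elite_idx, drop = FALSE], children)
  }
  best_eval <- evaluate_cost(best_genes, dye, ns, config$objective,
                             system = system)
  stopifnot(isTRUE(all.equal(best_eval$cost, best_cost)))
  structure(list(best_genome = best_genes,
                 best_geometry = decode_genome(best_genes),
                 best_cost = best_cost,
                 best_result = best_eval$result,
                 cost_history = cost_history,
                 median_history = median_history,
                 evaluations_count = evaluations,
                 generations_run = gens_run,
                 config = config, seed = config$seed),
            class = "mef_ga_result")
}

#' @export
print.mef_ga_result <- function(x, ...) {
  g <- x$best_geometry
  cat(sprintf(paste0("<mef_ga_result> %s objective: best cost %.6g after %d",
                     " generations (%d evaluations)\n",
                     "  r=%.4g nm, thetaT=%.4g, thetaD=%.4g, thetaA=%.4g deg\n"),
              x$config$objective, x$best_cost, x$generations_run,
              x$evaluations_count, g$r_nm, g$thetaT, g$thetaD, g$thetaA))
  invisible(x)
}

#' Exhaustive grid-search reference optimizer
#'
#' Evaluates the full cost surface on a finite grid and returns the exact
#' argmin, with ties broken toward smaller r, then smaller thetaT, thetaD,
#' thetaA. Used as the convergence reference for the GA.
#'
#' @param dye A `mef_dye`.
#' @param ns A `mef_nanostructure`.
#' @param objective `"inverse_gamma_d"` or `"inverse_tau"`.
#' @param grid List with numeric vectors `r`, `thetaT`, `thetaD`, `thetaA`.
#' @return List with `best_geometry` (one-row `mef_geometry`) and
#'   `best_cost`.
#' @export
grid_search_oracle <- function(dye, ns,
                               objective = c("inverse_gamma_d", "inverse_tau"),
                               grid) {
  objective <- match.arg(objective)
  system <- mef_system(dye, ns)
  full <- expand.grid(r_nm = grid$r, thetaT = grid$thetaT,
                      thetaD = grid$thetaD, thetaA = grid$thetaA,
                      KEEP.OUT.ATTRS = FALSE)
  geom <- geometry(full$r_nm, full$thetaT, full$thetaD, full$thetaA)
  costs <- cost_from_result(evaluate_photophysics(system, geom), objective)
  ord <- order(costs, full$r_nm, full$thetaT, full$thetaD, full$thetaA)
  best <- ord[1L]
  list(best_geometry = geometry(full$r_nm[best], full$thetaT[best],
                                full$thetaD[best], full$thetaA[best]),
       best_cost = costs[best])
}
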