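#' Simulation parameters
#'
#' Constructs and validates the full parameter set of one simulation run.
#' Defaults are the reference configuration used throughout the package:
#' `N = 2000`, `W1 = 3`, `W2 = 10`, `Pm = 0.001`, `Fd = 0.008`, `Tf = 0.02`,
#' `F = 0.001`, with 10000 generations.
#'
#' @param N Number of agents (constant through a run). Must be >= 2.
#' @param W1 Weight of the communication benefit in the fitness function
#'   (dimensionless, >= 0).
#' @param W2 Weight of the plasticity (learning) cost in the fitness function
#'   (dimensionless, >= 0).
#' @param Pm Per-genotype mutation probability in `[0, 1]`. Applied
#'   independently to each of the two genotypes `a` and `p` of each offspring.
#' @param mut_var Variance of the Gaussian mutation increment `R(0, mut_var)`.
#' @param F Cultural displacement unit: each user of a language pulls it by
#'   `F / n_i` toward its own innate ability, where `n_i` is the number of
#'   languages inside that user's plasticity interval.
#' @param Fd Division threshold: a language splits when it is pulled by more
#'   than `Fd` in both directions at once.
#' @param Tf Fusion threshold: two languages closer than `Tf` merge at their
#'   midpoint.
#' @param generations Number of generations to simulate (>= 0).
#' @param init_num_languages Number of languages in the initial population,
#'   drawn uniformly from `[0, 1]` like the initial genotypes. The source
#'   model does not state this number; 100 is large enough that division,
#'   fusion and extinction dynamics start immediately.
#' @param seed Integer RNG seed. Every stochastic draw of the run
#'   (initialisation, per-pair language choice, selection, mutation) consumes
#'   a single generator seeded with this value, so a run is a pure function
#'   of `params`.
#' @param fitness_floor Small positive additive floor applied to the
#'   rank-preserving shifted selection weights `fitness - min(fitness)`,
#'   keeping roulette-wheel weights strictly positive even when all shifted
#'   weights are zero.
#'
#' @return An object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params(N = 50, generations = 100, seed = 1)
#' p$Fd
#' @export
sim_params <- function(N = 2000, W1 = 3, W2 = 10, Pm = 0.001, mut_var = 2,
                       F = 0.001, Fd = 0.008, Tf = 0.02,
                       generations = 10000, init_num_languages = 100,
                       seed = 1L, fitness_floor = 1e-6) {
  p <- list(N = as.integer(N), W1 = W1, W2 = W2, Pm = Pm, mut_var = mut_var,
            F = F, Fd = Fd, Tf = Tf, generations = as.integer(generations),
            init_num_languages = as.integer(init_num_languages),
            seed = as.integer(seed), fitness_floor = fitness_floor)
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(
    p$N >= 2,
    p$W1 >= 0, p$W2 >= 0,
    p$Pm >= 0, p$Pm <= 1,
    p$mut_var >= 0,
    p$F >= 0, p$Fd > 0, p$Tf > 0,
    p$generations >= 0,
    p$init_num_languages >= 1,
    p$fitness_floor > 0
  )
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters\n")
  cat(sprintf("  N = %d agents, %d generations, seed = %d\n",
              x$N, x$generations, x$seed))
  cat(sprintf("  fitness: W1 = %g, W2 = %g\n", x$W1, x$W2))
  cat(sprintf("  mutation: Pm = %g, var = %g\n", x$Pm, x$mut_var))
  cat(sprintf("  culture: F = %g, Fd = %g, Tf = %g, initial languages = %d\n",
              x$F, x$Fd, x$Tf, x$init_num_languages))
  invisible(x)
}
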