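#' Configuration for a Wright-Fisher evolutionary simulation
#'
#' Defaults mirror the study protocol: 1000 groups of 10 cells evolved for
#' 1000 generations, a 2% per-group per-generation mutation probability, and
#' mutation kernels that are truncated Gaussians with standard deviation 10%
#' of the current value.
#'
#' @param population_size Number of groups (constant over time).
#' @param group_size Cells per group; must match the topology.
#' @param generations Number of generations to simulate.
#' @param mutation_probability Per-group per-generation chance that a
#'   mutation hits the developmental program.
#' @param mutation_sd_fraction Mutation-kernel standard deviation as a
#'   fraction of the current value.
#' @param mode `"fixed_sharing"` (a single `beta` for everyone, forever) or
#'   `"evolving_sharing"` (per-cell `beta` values starting at 0 that mutate
#'   one cell at a time).
#' @param alpha Return-on-investment exponent.
#' @param beta Interaction strength (fixed-sharing mode only).
#' @param beta_sd_floor Minimum mutation standard deviation for `beta`.
#'   Because the kernel sd is 10% of the current value, `beta = 0` would be
#'   an absorbing state; the floor (default 0.01) lets sharing arise from
#'   nothing. Set to 0 for the strictly degenerate kernel.
#' @param seed Optional integer seed; runs are bit-reproducible given a seed.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(population_size = 1000, group_size = 10,
                             generations = 1000,
                             mutation_probability = 0.02,
                             mutation_sd_fraction = 0.1,
                             mode = c("fixed_sharing", "evolving_sharing"),
                             alpha = 1, beta = 1, beta_sd_floor = 0.01,
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(population_size >= 1, group_size >= 1, generations >= 0,
            mutation_probability >= 0, mutation_probability <= 1,
            mutation_sd_fraction >= 0, alpha > 0,
            beta >= 0, beta <= 1, beta_sd_floor >= 0)
  structure(list(population_size = as.integer(population_size),
                 group_size = as.integer(group_size),
                 generations = as.integer(generations),
                 mutation_probability = mutation_probability,
                 mutation_sd_fraction = mutation_sd_fraction,
                 mode = mode, alpha = alpha, beta = beta,
                 beta_sd_floor = beta_sd_floor, seed = seed),
            class = "evolution_config")
}

#' Initialize a population of groups
#'
#' Strategies are i.i.d. uniform on `[0, 1]`. In evolving-sharing mode every
#' cell starts with `beta = 0`: no sharing until it evolves.
#'
#' @param cfg An [evolution_config()].
#' @return A `population_state`: list with `strategies`
#'   (population x group_size matrix), `cell_betas` (same shape, or `NULL`
#'   in fixed mode), `fitnesses`, `generation`.
#' @export
initialize_population <- function(cfg) {
  P <- cfg$population_size; N <- cfg$group_size
  structure(list(
    strategies = matrix(stats::runif(P * N), nrow = P),
    cell_betas = if (cfg$mode == "evolving_sharing")
      matrix(0, nrow = P, ncol = N) else NULL,
    fitnesses = rep(NA_real_, P),
    generation = 0L
  ), class = "population_state")
}

#' Mutate an investment strategy
#'
#' Each component is redrawn from a Gaussian centered at its current value
#' with standard deviation `sd_fraction * v_i`, truncated to `[0, 1]`
#' (rejection sampling, 100-draw cap, then clamping). A component at exactly
#' 0 has zero standard deviation and stays put.
#'
#' @param v Strategy vector.
#' @param sd_fraction Kernel sd as a fraction of the current value.
#' @return Mutated strategy in `[0, 1]`.
#' @export
mutate_strategy <- function(v, sd_fraction = 0.1) {
  rtruncnorm01(v, sd_fraction * v)
}

#' Mutate the sharing strength of one cell
#'
#' Picks one cell uniformly at random and redraws its `beta` from a Gaussian
#' centered on the current value with standard deviation
#' `max(sd_fraction * current, sd_floor)`, truncated to `[0, 1]`.
#'
#' @param betas Per-cell `beta` vector for one group.
#' @param sd_fraction Kernel sd as a fraction of the current value.
#' @param sd_floor Minimum kernel sd (escape from `beta = 0`).
#' @return Updated vector; exactly one component may differ.
#' @export
mutate_beta <- function(betas, sd_fraction = 0.1, sd_floor = 0.01) {
  i <- sample.int(length(betas), 1)
  betas[i] <- rtruncnorm01(betas[i],
                           max(sd_fraction * betas[i], sd_floor))
  betas
}

# componentwise truncated-to-[0,1] gaussian: rejection with a 100-draw cap,
# then clamp
rtruncnorm01 <- function(mean, sd) {
  out <- stats::rnorm(length(mean), mean, sd)
  for (iter in seq_len(100)) {
    bad <- out < 0 | out > 1
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  pmin(pmax(out, 0), 1)
}

#' Rank-weighted offspring selection
#'
#' Groups are ranked by fitness (worst rank 1, best rank `P`, ties given the
#' average rank) and `P` offspring are drawn with replacement from a
#' multinomial with probabilities proportional to rank. With all fitnesses
#' equal, selection is uniform.
#'
#' @param fitnesses Nonnegative fitness vector.
#' @return Integer vector of selected parent indices (length `P`).
#' @export
select_offspring <- function(fitnesses) {
  ranks <- rank(fitnesses, ties.method = "average")
  sample.int(length(fitnesses), length(fitnesses), replace = TRUE,
             prob = ranks)
}

# vectorized fitness of every group in the population.
# fixed sharing: vtilde rows = V^alpha %*% cmat.
# evolving sharing: cell j of group g gives beta_gj/n_j to each neighbor and
# keeps 1 - beta_gj + beta_gj/n_j, so vtilde = (Va * B/n) %*% A + Va*(1-B+B/n).
population_fitness <- function(V, cfg, t, cmat = NULL, B = NULL) {
  Va <- V^cfg$alpha
  Ba <- (1 - V)^cfg$alpha
  if (cfg$mode == "fixed_sharing") {
    Vt <- Va %*% cmat
  } else {
    ni <- rep(degrees_with_self(t), each = nrow(V)) |>
      matrix(nrow = nrow(V))
    share <- B / ni
    Vt <- (Va * share) %*% (t$adjacency * 1) + Va * (1 - B + share)
  }
  rowSums(Ba * Vt)
}

#' Run a Wright-Fisher evolutionary simulation
#'
#' Per generation: each group independently has probability
#' `mutation_probability` of a strategy mutation (and, in evolving-sharing
#' mode, independently the same probability of a single-cell `beta`
#' mutation); fitnesses are recomputed; the next generation is drawn by
#' [select_offspring()]. Population size is exactly constant. Runs are
#' bit-reproducible from `cfg$seed`.
#'
#' @param cfg An [evolution_config()]; `cfg$group_size` must equal the
#'   topology size.
#' @param t A [topology][make_topology].
#' @return An `evolution_result`: list with `state` (final
#'   `population_state`) and `trajectory` (tibble with one row per
#'   generation 0..G: `generation`, `mean_fitness`, `max_fitness`,
#'   `mean_specialization`, `mean_beta`). Has `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @examples
#' cfg <- evolution_config(population_size = 50, generations = 20,
#'                         alpha = 1.2, seed = 1)
#' run_evolution(cfg, make_topology("ring", 10))
#' @export
run_evolution <- function(cfg, t) {
  stopifnot(inherits(cfg, "evolution_config"), inherits(t, "topology"))
  if (cfg$group_size != t$n_cells) {
    stop("cfg$group_size must equal the topology's cell count.",
         call. = FALSE)
  }
  run <- function() run_evolution_impl(cfg, t)
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

run_evolution_impl <- function(cfg, t) {
  P <- cfg$population_size
  cmat <- if (cfg$mode == "fixed_sharing") build_sharing(t, cfg$beta)
  state <- initialize_population(cfg)
  V <- state$strategies
  B <- state$cell_betas
  fit <- population_fitness(V, cfg, t, cmat, B)

  record <- function(gen) {
    tibble::tibble(generation = gen,
                   mean_fitness = mean(fit),
                   max_fitness = max(fit),
                   mean_specialization = mean(2 * abs(V - 0.5)),
                   mean_beta = if (is.null(B)) NA_real_ else mean(B))
  }
  traj <- vector("list", cfg$generations + 1L)
  traj[[1]] <- record(0L)

  for (gen in seq_len(cfg$generations)) {
    hit <- which(stats::runif(P) < cfg$mutation_probability)
    for (g in hit) {
      V[g, ] <- mutate_strategy(V[g, ], cfg$mutation_sd_fraction)
    }
    if (!is.null(B)) {
      hit_b <- which(stats::runif(P) < cfg$mutation_probability)
      for (g in hit_b) {
        B[g, ] <- mutate_beta(B[g, ], cfg$mutation_sd_fraction,
                              cfg$beta_sd_floor)
      }
    }
    fit <- population_fitness(V, cfg, t, cmat, B)
    idx <- select_offspring(fit)
    V <- V[idx, , drop = FALSE]
    if (!is.null(B)) B <- B[idx, , drop = FALSE]
    fit <- fit[idx]
    traj[[gen + 1L]] <- record(gen)
  }

  state$strategies <- V
  state$cell_betas <- B
  state$fitnesses <- fit
  state$generation <- cfg$generations
  structure(list(state = state, trajectory = dplyr::bind_rows(traj),
                 config = cfg),
            class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  fin <- dplyr::slice_tail(x$trajectory, n = 1)
  cat(sprintf(paste0("<evolution_result: %d groups of %d cells, ",
                     "%d generations (%s)>\n",
                     "  final mean W = %.4g, mean S = %.3f%s\n"),
              x$config$population_size, x$config$group_size,
              x$config$generations, x$config$mode,
              fin$mean_fitness, fin$mean_specialization,
              if (is.na(fin$mean_beta)) "" else
                sprintf(", mean beta = %.3f", fin$mean_beta)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.evolution_result <- function(x, ...) x$trajectory

#' @exportS3Method generics::glance
glance.evolution_result <- function(x, ...) {
  fin <- dplyr::slice_tail(x$trajectory, n = 1)
  tibble::tibble(population_size = x$config$population_size,
                 group_size = x$config$group_size,
                 generations = x$config$generations,
                 mode = x$config$mode,
                 alpha = x$config$alpha,
                 beta = if (x$config$mode == "fixed_sharing")
                   x$config$beta else fin$mean_beta,
                 final_mean_fitness = fin$mean_fitness,
                 final_mean_specialization = fin$mean_specialization)
}

#' @exportS3Method ggplot2::autoplot
autoplot.evolution_result <- function(object, ...) {
  long <- object$trajectory |>
    tidyr::pivot_longer(-"generation", names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}
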