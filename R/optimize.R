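#' Specialization score of a strategy
#'
#' `S = (2/N) * sum_i (max(v_i, 1 - v_i) - 1/2)`, i.e. the mean distance of
#' investments from 1/2 rescaled to `[0, 1]`: 0 for a group of pure
#' generalists (all `v = 1/2`), 1 for complete specialists (all `v` in
#' `{0, 1}`).
#'
#' @param v Strategy vector of investments in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @examples
#' specialization_score(c(0.5, 0.5, 0.5, 0.5))  # 0
#' specialization_score(c(0, 1, 0, 1))          # 1
#' @export
specialization_score <- function(v) {
  if (any(is.na(v)) || any(v < 0 | v > 1)) {
    stop("investments must lie in [0, 1].", call. = FALSE)
  }
  mean(2 * abs(v - 0.5))
}

#' Numerically maximize group fitness over investment strategies
#'
#' Multi-start bounded local search over `v` in `[0, 1]^n`. Each start is
#' polished by L-BFGS-B with the analytic gradient, with coordinates clamped
#' to `[1e-9, 1 - 1e-9]` because the gradient is singular at the boundary for
#' `alpha < 1`. Because optima frequently sit *on* the boundary, every
#' polished point is additionally snapped coordinate-wise to `{0, 1}` (full
#' rounding, and rounding of near-boundary coordinates only) and the snapped
#' candidates are scored exactly. The candidate set always includes the
#' generalist strategy and the two alternating binary strategies, so the
#' result is never worse than the generalist.
#'
#' @param t A [topology][make_topology].
#' @param alpha Return-on-investment exponent.
#' @param beta Interaction strength in `[0, 1]`.
#' @param restarts Number of uniform-random starts (`>= 1`, default 20).
#' @param seed Optional integer seed; results are deterministic given a seed.
#' @return An `optimization_result`: list with `best_strategy`,
#'   `best_fitness`, `specialization`, `n_restarts`, `converged`.
#' @examples
#' maximize_fitness(make_topology("ring", 4), alpha = 1, beta = 1, seed = 1)
#' @export
maximize_fitness <- function(t, alpha, beta = 1, restarts = 20, seed = NULL) {
  stopifnot(inherits(t, "topology"), restarts >= 1)
  run <- function() maximize_fitness_impl(t, alpha, beta, restarts)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

maximize_fitness_impl <- function(t, alpha, beta, restarts) {
  n <- t$n_cells
  cmat <- build_sharing(t, beta)
  eps <- 1e-9
  wfun <- function(v) group_fitness(v, cmat, alpha)

  starts <- c(
    list(rep(0.5, n),
         rep_len(c(0, 1), n),
         rep_len(c(1, 0), n),
         as.numeric(stats::runif(n) < 0.5)),
    purrr::map(seq_len(restarts), \(i) stats::runif(n))
  )

  polish <- function(v0) {
    v0 <- pmin(pmax(v0, eps), 1 - eps)
    fit <- tryCatch(
      stats::optim(v0,
                   fn = function(v) -group_fitness(v, cmat, alpha),
                   gr = function(v) -fitness_gradient(v, cmat, alpha),
                   method = "L-BFGS-B", lower = eps, upper = 1 - eps,
                   control = list(maxit = 200)),
      error = function(e) list(par = v0, convergence = 1L)
    )
    fit
  }

  best <- list(v = rep(0.5, n), w = wfun(rep(0.5, n)), conv = TRUE)
  for (v0 in starts) {
    fit <- polish(v0)
    # score the interior optimum and boundary-snapped versions of it
    candidates <- list(fit$par,
                       round(fit$par),
                       snap_near_boundary(fit$par, 0.05))
    for (v in candidates) {
      w <- wfun(v)
      if (w > best$w + 1e-12) {
        best <- list(v = v, w = w, conv = fit$convergence == 0)
      }
    }
  }

  structure(list(best_strategy = best$v,
                 best_fitness = best$w,
                 specialization = specialization_score(best$v),
                 n_restarts = restarts,
                 converged = best$conv),
            class = "optimization_result")
}

snap_near_boundary <- function(v, margin) {
  v[v < margin] <- 0
  v[v > 1 - margin] <- 1
  v
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(paste0("<optimization_result: W = %.6g, S = %.3f, ",
                     "%d restarts%s>\n  v = (%s)\n"),
              x$best_fitness, x$specialization, x$n_restarts,
              if (x$converged) "" else ", not converged",
              paste(sprintf("%.3g", x$best_strategy), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.optimization_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 specialization = x$specialization,
                 n_restarts = x$n_restarts,
                 converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.optimization_result <- function(x, ...) {
  tibble::tibble(cell = seq_along(x$best_strategy) - 1L,
                 viability_investment = x$best_strategy)
}

#' Sparsity sweep over random graphs
#'
#' For each (connection fraction, alpha) grid cell, generates `replicates`
#' Erdős–Rényi graphs on `n` cells with edge probability equal to the
#' connection fraction, maximizes group fitness at `beta = 1`, and records
#' the mean specialization score and mean fitness of the optima. The sweep
#' probes the central sparsity result: intermediate connectivity favors
#' specialization even for saturating returns (`alpha < 1`), while fully
#' disconnected and fully connected groups favor generalists for all
#' `alpha < 1`.
#'
#' @param n Group size.
#' @param connection_fractions Grid of fractions of possible edges present.
#' @param alphas Grid of return exponents.
#' @param replicates Random graphs per grid cell.
#' @param seed Integer seed; the sweep is deterministic given a seed.
#' @param restarts Restarts passed to [maximize_fitness()] (default 10 keeps
#'   a full default grid to a desk-scale run).
#' @return A tibble of class `sweep_grid` with columns `fraction`, `alpha`,
#'   `mean_S`, `mean_W`, `replicates`; plot with [autoplot()].
#' @export
sparsity_sweep <- function(n = 10,
                           connection_fractions = seq(0, 1, by = 0.1),
                           alphas = seq(0.5, 1.5, by = 0.1),
                           replicates = 10, seed = NULL, restarts = 10) {
  stopifnot(length(connection_fractions) > 0, length(alphas) > 0)
  run <- function() {
    grid <- tidyr::expand_grid(fraction = connection_fractions,
                               alpha = alphas)
    res <- purrr::pmap(grid, function(fraction, alpha) {
      opt <- purrr::map(seq_len(replicates), function(r) {
        g <- make_topology("erdos_renyi", n, p = fraction)
        maximize_fitness(g, alpha, beta = 1, restarts = restarts)
      })
      tibble::tibble(mean_S = mean(purrr::map_dbl(opt, "specialization")),
                     mean_W = mean(purrr::map_dbl(opt, "best_fitness")))
    })
    dplyr::bind_cols(grid, dplyr::bind_rows(res)) |>
      dplyr::mutate(replicates = replicates)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("sweep_grid", class(out))
  attr(out, "axis") <- "fraction"
  out
}

#' Phase map of specialization over (alpha, beta)
#'
#' For each grid cell, either numerically maximizes fitness
#' (`mode = "optimize"`) or runs a Wright–Fisher simulation
#' (`mode = "evolve"`, final-generation population mean) and records the
#' specialization score. Reproduces the phase structure in which the
#' specialist region is bounded by the analytic threshold on the product
#' `alpha * beta` for the regular named topologies.
#'
#' @param t A [topology][make_topology].
#' @param alphas,betas Parameter grids (defaults span alpha 0.5–1.5 and
#'   beta 0–1 in steps of 0.1).
#' @param mode `"optimize"` or `"evolve"`.
#' @param seed Integer seed.
#' @param restarts Restarts per cell in optimize mode.
#' @param ... In evolve mode, overrides passed to [evolution_config()]
#'   (e.g. `population_size`, `generations`).
#' @return A tibble of class `sweep_grid` with columns `alpha`, `beta`,
#'   `mean_S`, `mean_W`.
#' @export
phase_map <- function(t, alphas = seq(0.5, 1.5, by = 0.1),
                      betas = seq(0, 1, by = 0.1),
                      mode = c("optimize", "evolve"),
                      seed = NULL, restarts = 10, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "topology"), length(alphas) > 0, length(betas) > 0)
  run <- function() {
    grid <- tidyr::expand_grid(alpha = alphas, beta = betas)
    res <- purrr::pmap(grid, function(alpha, beta) {
      if (mode == "optimize") {
        opt <- maximize_fitness(t, alpha, beta, restarts = restarts)
        tibble::tibble(mean_S = opt$specialization, mean_W = opt$best_fitness)
      } else {
        cfg <- evolution_config(group_size = t$n_cells, alpha = alpha,
                                beta = beta, ...)
        ev <- run_evolution(cfg, t)
        fin <- dplyr::slice_tail(ev$trajectory, n = 1)
        tibble::tibble(mean_S = fin$mean_specialization,
                       mean_W = fin$mean_fitness)
      }
    })
    dplyr::bind_cols(grid, dplyr::bind_rows(res))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("sweep_grid", class(out))
  attr(out, "axis") <- "beta"
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.sweep_grid <- function(object, ...) {
  xvar <- attr(object, "axis") %||% "beta"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[xvar]], y = .data$alpha,
                               fill = .data$mean_S)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "mean S") +
    ggplot2::labs(x = if (xvar == "fraction")
      "fraction of possible connections" else "interaction strength beta",
      y = "return exponent alpha") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
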