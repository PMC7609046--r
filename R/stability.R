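#' Hessian of group fitness at the generalist strategy
#'
#' Evaluates [fitness_hessian()] at `v = (1/2, ..., 1/2)` for a uniform
#' interaction strength. For symmetric sharing the generalist strategy is a
#' critical point, and this Hessian decides whether it is a maximum (all
#' eigenvalues negative) or a saddle.
#'
#' @param t A [topology][make_topology].
#' @param alpha Return-on-investment exponent (`> 0`).
#' @param beta Interaction strength in `[0, 1]`.
#' @return Symmetric `n x n` matrix.
#' @export
hessian_at_generalist <- function(t, alpha, beta = 1) {
  cmat <- build_sharing(t, beta)
  fitness_hessian(rep(0.5, t$n_cells), cmat, alpha)
}

#' Stability analysis of the generalist strategy
#'
#' Computes the largest eigenvalue of the generalist-strategy Hessian and
#' whether it is negative definite. When the sharing matrix is asymmetric
#' (unequal degrees), the generalist is not even a critical point; the report
#' is then advisory and flagged.
#'
#' @inheritParams hessian_at_generalist
#' @param tol Negative-definiteness tolerance; eigenvalues must fall below
#'   `-tol`. Defaults to `1e-10 * n`.
#' @return A `stability_report`: list with `largest_eigenvalue`,
#'   `negative_definite`, `alpha`, `beta`, `alpha_star`, `symmetric_sharing`,
#'   and `eigenvalues`. Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @examples
#' stability_report(make_topology("ring", 10), alpha = 0.7)
#' @export
stability_report <- function(t, alpha, beta = 1, tol = NULL) {
  tol <- tol %||% (1e-10 * t$n_cells)
  cmat <- build_sharing(t, beta)
  sym <- isTRUE(all.equal(cmat, base::t(cmat), tolerance = 1e-12))
  ev <- eigen(hessian_at_generalist(t, alpha, beta), symmetric = TRUE,
              only.values = TRUE)$values
  structure(
    list(largest_eigenvalue = max(ev),
         negative_definite = all(ev < -tol),
         alpha = alpha, beta = beta,
         alpha_star = alpha_star(t),
         symmetric_sharing = sym,
         eigenvalues = ev,
         n_cells = t$n_cells),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<stability_report: n = %d, alpha = %g, beta = %g>\n",
    "  largest Hessian eigenvalue: %.6g\n",
    "  generalist %s\n  alpha* = %s%s\n"),
    x$n_cells, x$alpha, x$beta, x$largest_eigenvalue,
    if (x$negative_definite) "is a local fitness maximum" else
      "is NOT a fitness maximum (saddle or non-critical)",
    if (is.na(x$alpha_star)) "undefined in bracket" else
      sprintf("%.4f", x$alpha_star),
    if (x$symmetric_sharing) "" else
      "\n  note: asymmetric sharing; generalist is not a critical point"))
  invisible(x)
}

#' Is the generalist strategy optimal?
#'
#' `TRUE` when the generalist-strategy Hessian is negative definite, in which
#' case (for symmetric sharing) the all-1/2 strategy is a fitness maximum.
#' For asymmetric sharing a warning is attached: the generalist is not a
#' critical point there and the answer is only advisory.
#'
#' @inheritParams stability_report
#' @return Logical scalar with attribute `symmetric_sharing`.
#' @export
generalist_is_optimal <- function(t, alpha, beta = 1, tol = NULL) {
  rep_ <- stability_report(t, alpha, beta, tol)
  if (!rep_$symmetric_sharing) {
    warning("sharing matrix is asymmetric; the generalist strategy is not ",
            "a critical point and this verdict is advisory.", call. = FALSE)
  }
  structure(rep_$negative_definite, symmetric_sharing = rep_$symmetric_sharing)
}

#' Specialization amenability metric alpha*
#'
#' The value of `alpha` at which the largest eigenvalue of the
#' generalist-strategy Hessian crosses zero at full sharing (`beta = 1`).
#' Below `alpha*` complete generalization is locally stable (for regular
#' topologies it is then optimal); above it, some degree of specialization
#' must pay. The smaller `alpha*`, the more amenable the topology is to
#' specialization — notably, `alpha*` can fall well below 1 for sparse
#' topologies, meaning specialization is favored even with saturating
#' returns. For irregular topologies `alpha*` remains a useful proxy even
#' though the generalist is not a critical point.
#'
#' Found by bisection of the largest eigenvalue over `alpha` in `bracket`.
#'
#' @param t A [topology][make_topology].
#' @param bracket Search interval for `alpha`.
#' @param tol Bisection tolerance on `alpha`.
#' @return Scalar root, or `NA` if the eigenvalue does not change sign in the
#'   bracket.
#' @examples
#' alpha_star(make_topology("ring", 10))        # 0.75
#' alpha_star(make_topology("complete", 10))    # 1
#' @export
alpha_star <- function(t, bracket = c(0.01, 3.0), tol = 1e-6) {
  lam <- function(a) {
    max(eigen(hessian_at_generalist(t, a, beta = 1), symmetric = TRUE,
              only.values = TRUE)$values)
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- lam(lo); fhi <- lam(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- lam(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Analytic generalist-instability thresholds for named topologies
#'
#' For the complete, nearest-neighbor ring, and balanced bipartite networks
#' the largest Hessian eigenvalue at the generalist strategy has the closed
#' forms `alpha (1/2)^(2 alpha - 3) * (-1 + k alpha beta)` with
#' `k = 1`, `4/3`, and `2N/(N+2)` respectively, so generalists lose
#' stability when the product `alpha * beta` exceeds `1`, `3/4`, or
#' `(N+2)/(2N)`.
#'
#' @param kind `"complete"`, `"ring"`, or `"balanced_bipartite"`.
#' @param n Group size (needed, and even, for `balanced_bipartite`).
#' @return The critical `alpha * beta` product.
#' @examples
#' analytic_threshold("ring")                     # 0.75
#' analytic_threshold("balanced_bipartite", 10)   # 0.6
#' @export
analytic_threshold <- function(kind = c("complete", "ring",
                                        "balanced_bipartite"), n = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    complete = 1,
    ring = 3 / 4,
    balanced_bipartite = {
      if (is.null(n) || n %% 2 != 0) {
        stop("balanced_bipartite threshold needs an even `n`.", call. = FALSE)
      }
      (n + 2) / (2 * n)
    }
  )
}

#' Closed-form largest Hessian eigenvalue for named topologies
#'
#' @inheritParams analytic_threshold
#' @param alpha,beta Model parameters.
#' @return `alpha (1/2)^(2 alpha - 3) * (-1 + k alpha beta)` with the
#'   topology-specific coefficient `k` (see [analytic_threshold()]).
#' @export
analytic_lambda_max <- function(kind = c("complete", "ring",
                                         "balanced_bipartite"),
                                n = NULL, alpha = 1, beta = 1) {
  kind <- match.arg(kind)
  k <- switch(kind,
    complete = 1,
    ring = 4 / 3,
    balanced_bipartite = {
      if (is.null(n) || n %% 2 != 0) {
        stop("balanced_bipartite eigenvalue needs an even `n`.", call. = FALSE)
      }
      2 * n / (n + 2)
    }
  )
  alpha * 0.5^(2 * alpha - 3) * (-1 + k * alpha * beta)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.stability_report <- function(x, ...) {
  tibble::tibble(eigenvalue = x$eigenvalues,
                 rank = seq_along(x$eigenvalues))
}

#' @exportS3Method generics::glance
glance.stability_report <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells, alpha = x$alpha, beta = x$beta,
                 largest_eigenvalue = x$largest_eigenvalue,
                 negative_definite = x$negative_definite,
                 alpha_star = x$alpha_star,
                 symmetric_sharing = x$symmetric_sharing)
}
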