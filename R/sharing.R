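#' Build the weighted viability-sharing matrix
#'
#' Each cell takes a fraction `beta` of its viability returns and splits it
#' equally among its `n_i = degree + 1` neighbors, itself included, keeping
#' the remaining `1 - beta` outright. Entry `c[i, j]` is the fraction of cell
#' `i`'s viability returns delivered to cell `j` (giver-indexed rows):
#' `c[i, i] = 1 - beta_i + beta_i / n_i`, `c[i, j] = beta_i / n_i` when `i`
#' and `j` are adjacent, 0 otherwise. Rows sum to exactly 1 — a cell cannot
#' give away more than it has — and the diagonal is strictly positive, so a
#' cell always retains some viability. `beta = 0` yields the identity (no
#' sharing); `beta = 1` shares everything equally across the closed
#' neighborhood.
#'
#' @param t A [topology][make_topology].
#' @param beta Interaction strength in `[0, 1]`; a scalar (broadcast) or a
#'   length-`n` vector of per-cell values, as used when sharing itself
#'   evolves.
#' @return An `n x n` numeric matrix with unit row sums.
#' @examples
#' build_sharing(make_topology("ring", 4), beta = 1)
#' @export
build_sharing <- function(t, beta) {
  stopifnot(inherits(t, "topology"))
  n <- t$n_cells
  beta <- rep_len(as.numeric(beta), n)
  if (any(is.na(beta)) || any(beta < 0 | beta > 1)) {
    stop("`beta` components must lie in [0, 1].", call. = FALSE)
  }
  ni <- degrees_with_self(t)
  cmat <- (beta / ni) * (t$adjacency * 1)   # row i scaled by beta_i / n_i
  diag(cmat) <- 1 - beta + beta / ni
  cmat
}

#' Incoming viability returns per cell
#'
#' Cell `i`'s realized viability is the column sum of incoming shares,
#' `vtilde_i = sum_j v_j^alpha c[j, i]`: its own retained returns plus
#' whatever neighbors pass along. `0^alpha` is taken as 0 for all
#' `alpha > 0`, so pure fecundity specialists are well defined even for
#' saturating returns.
#'
#' @param v Strategy vector of viability investments in `[0, 1]`.
#' @param cmat Sharing matrix from [build_sharing()].
#' @param alpha Return-on-investment exponent (`> 0`); `alpha > 1` gives
#'   accelerating (convex) returns, `alpha < 1` saturating (concave) returns.
#' @return Nonnegative numeric vector of length `n`.
#' @export
viability_returns <- function(v, cmat, alpha) {
  check_strategy(v, cmat)
  as.vector(crossprod(cmat, pow0(v, alpha)))
}

#' Group fitness
#'
#' The group-level reproduction rate: each cell contributes the product of its
#' fecundity returns `b_i^alpha` (with `b = 1 - v`, not shareable) and its
#' realized viability `vtilde_i`, summed over cells:
#' `W = sum_i (1 - v_i)^alpha * sum_j v_j^alpha c[j, i]`.
#'
#' @inheritParams viability_returns
#' @return Nonnegative scalar.
#' @examples
#' cmat <- build_sharing(make_topology("ring", 4), beta = 1)
#' group_fitness(rep(1 / 2, 4), cmat, alpha = 1)   # 1
#' group_fitness(c(1, 0, 1, 0), cmat, alpha = 1)   # 4/3
#' @export
group_fitness <- function(v, cmat, alpha) {
  check_strategy(v, cmat)
  sum(pow0(1 - v, alpha) * as.vector(crossprod(cmat, pow0(v, alpha))))
}

#' Group fitness with two shareable goods
#'
#' Generalization in which fecundity returns are also distributed, through a
#' second sharing matrix: `W = sum_i (sum_j b_j^alpha cf[j, i]) *
#' (sum_j v_j^alpha cv[j, i])`. With `c_fecundity` equal to the identity
#' (fecundity kept entirely by its producer) this reduces exactly to
#' [group_fitness()]. Specialization with saturating returns stays adaptive
#' as long as the two goods are shared sufficiently asymmetrically.
#'
#' @inheritParams viability_returns
#' @param c_viability,c_fecundity Sharing matrices on the same topology.
#' @return Nonnegative scalar.
#' @export
group_fitness_two_goods <- function(v, c_viability, c_fecundity, alpha) {
  check_strategy(v, c_viability)
  if (!identical(dim(c_viability), dim(c_fecundity))) {
    stop("sharing matrices must have identical dimensions.", call. = FALSE)
  }
  vt <- as.vector(crossprod(c_viability, pow0(v, alpha)))
  bt <- as.vector(crossprod(c_fecundity, pow0(1 - v, alpha)))
  sum(bt * vt)
}

#' Closed-form fitness of reference configurations
#'
#' * `ring_specialist`: alternating complete specialists
#'   `v = (0, 1, 0, 1, ...)` on the nearest-neighbor ring, `W = beta * N / 3`
#'   (independent of `alpha`: specialist investments are 0 or 1).
#' * `ring_generalist`: all cells at `v = 1/2` on the ring,
#'   `W = N (1/2)^(2 alpha)` (independent of `beta`: on a regular graph a
#'   uniform strategy redistributes nothing net).
#' * `disconnected_optimum`: the best achievable for isolated cells, also
#'   `N (1/2)^(2 alpha)`.
#'
#' @param kind `"ring_specialist"`, `"ring_generalist"`, or
#'   `"disconnected_optimum"`.
#' @param n Group size (even for `ring_specialist`).
#' @param alpha,beta Model parameters.
#' @return Scalar fitness.
#' @export
closed_form_fitness <- function(kind = c("ring_specialist", "ring_generalist",
                                         "disconnected_optimum"),
                                n, alpha = 1, beta = 1) {
  kind <- match.arg(kind)
  switch(kind,
    ring_specialist = {
      if (n %% 2 != 0) {
        stop("alternating specialists need an even ring.", call. = FALSE)
      }
      beta * n / 3
    },
    ring_generalist = n * 0.5^(2 * alpha),
    disconnected_optimum = n * 0.5^(2 * alpha)
  )
}

#' Analytic gradient of group fitness
#'
#' Component `k` is
#' `alpha * (v_k^(alpha-1) * sum_j c[k, j] (1 - v_j)^alpha -
#' (1 - v_k)^(alpha-1) * sum_j c[j, k] v_j^alpha)`.
#' For symmetric sharing (`c == t(c)`) the generalist strategy `v = 1/2` is a
#' critical point; for asymmetric sharing it is not. For `alpha < 1` the
#' gradient diverges at `v_k` in `{0, 1}`; signed infinities are returned
#' rather than an error, and optimizers are expected to clamp.
#'
#' @inheritParams viability_returns
#' @return Numeric vector of length `n` (possibly infinite at the boundary).
#' @export
fitness_gradient <- function(v, cmat, alpha) {
  check_strategy(v, cmat)
  va <- pow0(v, alpha)
  ba <- pow0(1 - v, alpha)
  out_fec <- as.vector(cmat %*% ba)       # sum_j c_kj (1-v_j)^alpha
  in_via <- as.vector(crossprod(cmat, va)) # sum_j c_jk v_j^alpha
  alpha * (powm1(v, alpha) * out_fec - powm1(1 - v, alpha) * in_via)
}

#' Analytic Hessian of group fitness
#'
#' Second derivatives of the group fitness with respect to the investment
#' vector. Diagonal:
#' `alpha (alpha - 1) [v_k^(alpha-2) sum_j c_kj (1-v_j)^alpha +
#'  (1-v_k)^(alpha-2) sum_j c_jk v_j^alpha]
#'  - 2 alpha^2 c_kk v_k^(alpha-1) (1-v_k)^(alpha-1)`.
#' Off-diagonal `(k, l)`:
#' `-alpha^2 [v_k^(alpha-1) c_kl (1-v_l)^(alpha-1) +
#'  (1-v_k)^(alpha-1) c_lk v_l^(alpha-1)]`, which is symmetric in `(k, l)`.
#' Interior strategies keep all terms finite for `alpha < 2`.
#'
#' @inheritParams viability_returns
#' @return Symmetric `n x n` matrix.
#' @export
fitness_hessian <- function(v, cmat, alpha) {
  check_strategy(v, cmat)
  va <- pow0(v, alpha)
  ba <- pow0(1 - v, alpha)
  v1 <- powm1(v, alpha)          # v^(alpha-1)
  b1 <- powm1(1 - v, alpha)      # (1-v)^(alpha-1)
  v2 <- powm1(v, alpha - 1)      # v^(alpha-2)
  b2 <- powm1(1 - v, alpha - 1)  # (1-v)^(alpha-2)
  out_fec <- as.vector(cmat %*% ba)
  in_via <- as.vector(crossprod(cmat, va))
  h <- -alpha^2 * (outer(v1, b1) * cmat + t(outer(v1, b1) * cmat))
  diag(h) <- alpha * (alpha - 1) * (v2 * out_fec + b2 * in_via) -
    2 * alpha^2 * diag(cmat) * v1 * b1
  h
}

# x^a with 0^a := 0 for a > 0 (R already does this; kept explicit for clarity)
pow0 <- function(x, a) x^a

# x^(a-1), the derivative factor: diverges to +Inf at x = 0 when a < 1
powm1 <- function(x, a) x^(a - 1)

check_strategy <- function(v, cmat) {
  n <- nrow(cmat)
  if (!is.numeric(v) || length(v) != n) {
    stop("strategy length must match the sharing matrix.", call. = FALSE)
  }
  if (any(is.na(v)) || any(v < 0 | v > 1)) {
    stop("investments must lie in [0, 1].", call. = FALSE)
  }
  invisible(TRUE)
}
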