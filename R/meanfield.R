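#' Mean-field fitness of a group of generalists
#'
#' In the mean-field theory (large `N`, every cell with `z` neighbors,
#' `alpha = 1`, `beta = 1`) a generalist group has `W_G = N / 4`: every cell
#' keeps `v = b = 1/2` before and after sharing.
#'
#' @param N Group size.
#' @return `N / 4`.
#' @export
generalist_fitness_mf <- function(N) {
  stopifnot(N >= 1)
  N / 4
}

#' Mean-field fitness of a group of complete specialists
#'
#' With a fraction `X` of cells as fecundity specialists (`v = 0, b = 1`) and
#' the rest viability specialists (`v = 1, b = 0`), each viability specialist
#' shares `1 / (z + 1)` with each neighbor; a fecundity specialist whose
#' neighbors are viability specialists with probability `f` therefore
#' receives `z f / (z + 1)` on average, giving
#' `W_S = z f X N / (z + 1)` (and `z f N / (2 (z + 1))` at the balanced
#' split `X = 1/2`).
#'
#' @param N Group size.
#' @param z Neighbors per cell.
#' @param f Assortment: mean fraction of a fecundity specialist's neighbors
#'   that are viability specialists, in `[0, 1]`.
#' @param X Fraction of fecundity specialists, in `[0, 1]` (default balanced).
#' @return Scalar fitness.
#' @export
specialist_fitness_mf <- function(N, z, f, X = 0.5) {
  stopifnot(N >= 1, z >= 0, f >= 0, f <= 1, X >= 0, X <= 1)
  z * f * X * N / (z + 1)
}

#' Assortment threshold for specialists to beat generalists
#'
#' Specialists out-compete generalists in the mean field (at `alpha = 1`,
#' `beta = 1`) iff `W_S / W_G > 1`, i.e. iff
#' `f > 1/(4X) + 1/(4Xz)`; at the balanced split this is
#' `f > 1/2 + 1/(2z)`. Since `f <= 1`, a fully connected group
#' (`f = 1/2` under random mixing) never satisfies it — the classical result
#' that well-mixed groups need accelerating returns.
#'
#' @param z Neighbors per cell (`>= 1`).
#' @param X Fraction of fecundity specialists, in `(0, 1]`.
#' @return The threshold value of `f`.
#' @examples
#' f_threshold(3)  # 2/3
#' f_threshold(4)  # 5/8
#' @export
f_threshold <- function(z, X = 0.5) {
  stopifnot(z >= 1, X > 0, X <= 1)
  1 / (4 * X) + 1 / (4 * X * z)
}

#' Minimum fecundity-specialist fraction for specialization to be possible
#'
#' The assortment threshold must stay at or below the attainable maximum
#' `f = 1`, which requires `X > 1/4 + 1/(4z)`: specialization with
#' saturating returns is impossible when fewer than a quarter of cells are
#' fecundity specialists.
#'
#' @param z Neighbors per cell (`>= 1`).
#' @return `1/4 + 1/(4z)`.
#' @export
min_fecundity_fraction <- function(z) {
  stopifnot(z >= 1)
  1 / 4 + 1 / (4 * z)
}

#' Are specialists favored in the mean field?
#'
#' Strict comparison `W_S > W_G`, equivalently `f > f_threshold(z, X)`.
#'
#' @inheritParams specialist_fitness_mf
#' @return Logical scalar.
#' @export
specialists_favored_mf <- function(N, z, f, X = 0.5) {
  specialist_fitness_mf(N, z, f, X) > generalist_fitness_mf(N)
}

#' Measure the assortment parameter f on a concrete graph
#'
#' Given per-cell specialist labels, `f` is the mean over fecundity-labeled
#' cells of the fraction of their neighbors labeled viability. On irregular
#' graphs each cell's own degree replaces the mean-field `z` (an extension of
#' the regular-graph definition, flagged in the result's
#' `"irregular"` attribute). Fecundity cells of degree 0 are excluded with a
#' warning.
#'
#' @param t A [topology][make_topology].
#' @param labels Character vector of `"viability"` / `"fecundity"`, one per
#'   cell.
#' @return Scalar in `[0, 1]` with attribute `irregular`.
#' @examples
#' t10 <- make_topology("balanced_bipartite", 10)
#' measure_f(t10, rep(c("viability", "fecundity"), each = 5))  # 1
#' @export
measure_f <- function(t, labels) {
  stopifnot(inherits(t, "topology"))
  labels <- match.arg(labels, c("viability", "fecundity"),
                      several.ok = TRUE)
  if (length(labels) != t$n_cells) {
    stop("need one label per cell.", call. = FALSE)
  }
  deg <- rowSums(t$adjacency)
  fec <- which(labels == "fecundity")
  if (length(fec) == 0) stop("no fecundity-labeled cells.", call. = FALSE)
  isolated <- fec[deg[fec] == 0]
  if (length(isolated) > 0) {
    warning(length(isolated),
            " fecundity cell(s) with no neighbors excluded from f.",
            call. = FALSE)
    fec <- setdiff(fec, isolated)
  }
  if (length(fec) == 0) {
    stop("no fecundity-labeled cells with neighbors.", call. = FALSE)
  }
  via <- labels == "viability"
  per_cell <- vapply(fec, function(i) {
    sum(t$adjacency[i, ] & via) / deg[i]
  }, numeric(1))
  structure(mean(per_cell), irregular = length(unique(deg)) > 1)
}
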