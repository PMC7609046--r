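# Independent oracles: naive double-loop fitness evaluation and
# finite-difference derivatives. These deliberately avoid the package's
# vectorized code paths.

brute_fitness <- function(v, cmat, alpha) {
  n <- length(v)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      total <- total + (1 - v[i])^alpha * cmat[j, i] * v[j]^alpha
    }
  }
  total
}

brute_viability_returns <- function(v, cmat, alpha) {
  n <- length(v)
  sapply(seq_len(n), function(i) {
    sum(sapply(seq_len(n), function(j) v[j]^alpha * cmat[j, i]))
  })
}

fd_gradient <- function(v, cmat, alpha, h = 1e-6) {
  sapply(seq_along(v), function(k) {
    vp <- v; vm <- v
    vp[k] <- v[k] + h; vm[k] <- v[k] - h
    (group_fitness(vp, cmat, alpha) - group_fitness(vm, cmat, alpha)) / (2 * h)
  })
}

fd_hessian <- function(v, cmat, alpha, h = 1e-6) {
  cols <- sapply(seq_along(v), function(k) {
    vp <- v; vm <- v
    vp[k] <- v[k] + h; vm[k] <- v[k] - h
    (fitness_gradient(vp, cmat, alpha) -
       fitness_gradient(vm, cmat, alpha)) / (2 * h)
  })
  (cols + t(cols)) / 2
}

# random interior strategy bounded away from 0/1 so derivatives stay finite
random_interior_strategy <- function(n, margin = 0.1) {
  stats::runif(n, margin, 1 - margin)
}
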