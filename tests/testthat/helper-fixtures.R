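# Small ground-truthed fixtures built in code.

# random valid signal/factorization pair on a shared grid
random_instance <- function(M = 4, N = 3, R = 2, seed = 1) {
  withr::with_seed(seed, {
    g <- time_grid(sort(runif(M, 0.5, 50)))
    taus <- sort(runif(R, 1, 60))
    H <- matrix(runif(R * N), R, N)
    I <- signal_matrix(basis_matrix(taus, g) %*% H + matrix(runif(M * N, 0, 0.2), M, N), g)
    list(I = I, f = factorization(taus, H, g), g = g)
  })
}

# noise-free multi-exponential data with known components
clean_signal <- function(taus, n_seq = 6, dims = 50,
                         t_min = min(taus) / 10, t_max = max(taus) * 50) {
  g <- log_time_grid(dims, t_min, t_max)
  H <- matrix(1 / length(taus), length(taus), n_seq)
  list(signal = signal_matrix(basis_matrix(taus, g) %*% H, g),
       taus = taus, H = H, g = g)
}

# central finite difference of an objective with respect to tau_r
fd_tau_gradient <- function(I, f, r, objective, h_rel = 1e-6) {
  h <- h_rel * f$taus[r]
  fp <- f; fp$taus[r] <- f$taus[r] + h
  fm <- f; fm$taus[r] <- f$taus[r] - h
  obj <- if (objective == "lse") lse_objective else
    function(...) as.numeric(kl_objective(...))
  (obj(I, fp) - obj(I, fm)) / (2 * h)
}

# analytic tau gradients implied by the model (independent loop oracle)
loop_tau_gradient <- function(I, f, r, objective) {
  W <- basis_matrix(f$taus, f$g %||% f$times)
  WH <- W %*% f$coeffs
  tot <- 0
  for (j in seq_along(f$times)) for (i in seq_len(ncol(f$coeffs))) {
    common <- f$coeffs[r, i] * W[j, r] * f$times[j] / f$taus[r]^2
    tot <- tot + if (objective == "lse") {
      -2 * (I$values[j, i] - WH[j, i]) * common
    } else {
      (1 - I$values[j, i] / max(WH[j, i], 1e-12)) * common
    }
  }
  tot
}

`%||%` <- function(a, b) if (is.null(a)) b else a
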