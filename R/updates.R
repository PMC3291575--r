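# Multiplicative update rules.
#
# Both objectives admit multiplicative updates obtained from gradient
# descent with a step width chosen so that the step becomes a ratio
# rescaling of the current parameter, which preserves positivity
# automatically.  The single-step functions below are the plain-R
# reference forms; bznmf_fit() runs the same iteration in compiled code.

#' Coefficient update, least-squares objective
#'
#' One multiplicative update of the coefficient matrix H under the
#' sum-of-squares objective (the classic non-negative matrix factorization
#' rule): \eqn{h_{ri} \leftarrow h_{ri} (W^T I)_{ri} / (W^T W H)_{ri}}.
#' Zeros are absorbing, non-negativity is preserved, and an exact fit is a
#' fixed point.
#'
#' @param I A `bz_signal`.
#' @param f A `bz_factorization` on the same grid.
#' @return Updated R x N coefficient matrix.
#' @export
update_coeffs_lse <- function(I, f) {
  .bz_check_shapes(I, f)
  W <- basis_matrix(f$taus, f$times)
  num <- crossprod(W, I$values)
  den <- crossprod(W) %*% f$coeffs
  f$coeffs * num / pmax(den, .bz_eps)
}

#' Time-constant update, least-squares objective
#'
#' One multiplicative update of the time constants under the
#' sum-of-squares objective.  The gradient is
#' \deqn{\partial D/\partial \tau_r =
#'   -2 \sum_{ji} (I_{ji} - (WH)_{ji}) h_{ri} w_{jr} t_j / \tau_r^2,}
#' and with step width \eqn{\eta_r = \tau_r^3 /
#' (2 \sum_{ji} (WH)_{ji} h_{ri} w_{jr} t_j)} the gradient-descent step
#' collapses to the ratio form
#' \deqn{\tau_r \leftarrow \tau_r \frac{\sum_{ji} I_{ji} h_{ri} w_{jr} t_j}
#'   {\sum_{ji} (WH)_{ji} h_{ri} w_{jr} t_j}.}
#' A component whose denominator vanishes (no coefficient mass) is left
#' unchanged and flagged in the `"degenerate"` attribute.
#'
#' @inheritParams update_coeffs_lse
#' @return Updated tau vector with logical attribute `degenerate`.
#' @export
update_taus_lse <- function(I, f) {
  .bz_check_shapes(I, f)
  W <- basis_matrix(f$taus, f$times)
  WH <- W %*% f$coeffs
  TW <- f$times * W                       # t_j * w_jr
  num <- colSums(TW * (I$values %*% t(f$coeffs)))
  den <- colSums(TW * (WH %*% t(f$coeffs)))
  degenerate <- den <= .bz_eps
  tau <- ifelse(degenerate, f$taus, f$taus * num / pmax(den, .bz_eps))
  attr(tau, "degenerate") <- degenerate
  tau
}

#' Coefficient update, generalized KL objective
#'
#' One multiplicative update of H under the generalized Kullback-Leibler
#' divergence (the standard Poisson-noise rule):
#' \eqn{h_{ri} \leftarrow h_{ri} \sum_j w_{jr} I_{ji}/(WH)_{ji} /
#' \sum_j w_{jr}}.
#'
#' @inheritParams update_coeffs_lse
#' @return Updated R x N coefficient matrix.
#' @export
update_coeffs_kl <- function(I, f) {
  .bz_check_shapes(I, f)
  W <- basis_matrix(f$taus, f$times)
  WH <- pmax(W %*% f$coeffs, .bz_eps)
  num <- crossprod(W, I$values / WH)
  den <- pmax(colSums(W), .bz_eps)
  f$coeffs * num / den
}

#' Time-constant update, generalized KL objective
#'
#' One multiplicative update of the time constants under the generalized
#' Kullback-Leibler divergence.  The gradient is
#' \eqn{\partial D/\partial \tau_r = \sum_{ji} (1 - I_{ji}/(WH)_{ji})
#' h_{ri} w_{jr} t_j / \tau_r^2}; with step width
#' \eqn{\eta_r = \tau_r^3 / \sum_{ji} h_{ri} w_{jr} t_j} the step becomes
#' \deqn{\tau_r \leftarrow \tau_r
#'   \frac{\sum_{ji} (I_{ji}/(WH)_{ji}) h_{ri} w_{jr} t_j}
#'        {\sum_{ji} h_{ri} w_{jr} t_j}.}
#'
#' @inheritParams update_coeffs_lse
#' @return Updated tau vector with logical attribute `degenerate`.
#' @export
update_taus_kl <- function(I, f) {
  .bz_check_shapes(I, f)
  W <- basis_matrix(f$taus, f$times)
  WH <- pmax(W %*% f$coeffs, .bz_eps)
  TW <- f$times * W
  num <- colSums(TW * ((I$values / WH) %*% t(f$coeffs)))
  den <- colSums(TW) * rowSums(f$coeffs)
  degenerate <- den <= .bz_eps
  tau <- ifelse(degenerate, f$taus, f$taus * num / pmax(den, .bz_eps))
  attr(tau, "degenerate") <- degenerate
  tau
}

#' Fitting configuration
#'
#' Bundles the optimizer settings shared by [bznmf_fit()],
#' [select_rank()] and [kfold_cv_rank()].
#'
#' @param objective `"lse"` or `"kl"`.
#' @param max_iterations Maximum alternating iterations per restart.
#' @param rel_tolerance Stop when the relative decrease of the objective
#'   over one iteration falls below this value.
#' @param n_restarts Number of random restarts; the best final objective
#'   wins.
#' @param seed Integer seed driving initialization (and any fold
#'   shuffling downstream).
#' @param tau_floor,tau_ceiling Clipping bounds for the time constants;
#'   `NULL` means `t_1` and `1e3 * t_M`.  A decay faster than the first
#'   measurement time is not identifiable on the grid (its basis vector
#'   degenerates towards a one-point spike), so the floor sits at `t_1`;
#'   the ceiling keeps unused slow components from drifting to infinity.
#' @return A list of class `bz_fit_config`.
#' @export
fit_config <- function(objective = c("lse", "kl"),
                       max_iterations = 5000L,
                       rel_tolerance = 1e-8,
                       n_restarts = 3L,
                       seed = 1L,
                       tau_floor = NULL,
                       tau_ceiling = NULL) {
  objective <- match.arg(objective)
  max_iterations <- as.integer(max_iterations)
  stopifnot(max_iterations >= 1L,
            rel_tolerance > 0, rel_tolerance < 1,
            n_restarts >= 1L)
  if (!is.null(tau_floor) && !is.null(tau_ceiling) &&
      tau_floor >= tau_ceiling)
    stop("tau_floor must be below tau_ceiling", call. = FALSE)
  structure(list(objective = objective,
                 max_iterations = max_iterations,
                 rel_tolerance = rel_tolerance,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed),
                 tau_floor = tau_floor,
                 tau_ceiling = tau_ceiling),
            class = "bz_fit_config")
}

# all taus start at the log-center of the grid, each jittered by
# x10^U(-0.25, 0.25) per restart: components separate only under data
# pressure, so surplus components end as duplicates of real ones instead
# of wandering into noise-fitting corners of the landscape; H ~ U(0,1)
# rescaled so its column sums match the input column sums
.bz_init <- function(I, rank) {
  M <- nrow(I$values); N <- ncol(I$values)
  lt1 <- log10(I$times[1]); ltM <- log10(I$times[M])
  tau0 <- 10^((lt1 + ltM) / 2 + runif(rank, -0.25, 0.25))
  H0 <- matrix(runif(rank * N), rank, N)
  target <- colSums(I$values)
  H0 <- sweep(H0, 2, target / pmax(colSums(H0), .bz_eps), "*")
  list(tau = tau0, H = H0)
}

#' Fit a Boltzmann-constrained factorization at a fixed rank
#'
#' Alternates the time-constant and coefficient multiplicative updates
#' until the relative objective change drops below `rel_tolerance` or
#' `max_iterations` is reached, over `n_restarts` random initializations,
#' and returns the restart with the lowest final objective.  All time
#' constants start at the logarithmic center of the grid span (each
#' jittered by a quarter decade per restart) and separate as the data
#' demand; they are clipped to `[tau_floor, tau_ceiling]` during fitting.
#' Components whose coefficients collapse below 1e-12 total mass are
#' frozen and reported in `degenerate`.
#'
#' When `init` is given (a `bz_factorization` with at most `rank`
#' components, typically the converged fit at the previous rank of a
#' sweep), its components seed the fit as-is and only the missing
#' components are drawn fresh at the grid center.  Warm-starting a rank
#' sweep this way lets a genuinely missing component be pulled straight
#' into the residual structure while leaving converged components in
#' place, and is how [select_rank()] traverses its sweep.
#'
#' @param I A `bz_signal`.
#' @param rank Number of components R (>= 1).
#' @param config A [fit_config()].
#' @param init Optional `bz_factorization` with `<= rank` components used
#'   to warm-start every restart.
#' @return An object of class `bz_fit` with elements `factorization`,
#'   `objective_value`, `objective_trace` (initial value followed by one
#'   value per iteration), `iterations_run`, `converged`, `restart_index`,
#'   `degenerate`, `objective` and `rank`.
#' @examples
#' g <- log_time_grid(40, 1, 1e4)
#' I <- signal_matrix(basis_matrix(100, g) %*% matrix(1, 1, 5), g)
#' fit <- bznmf_fit(I, rank = 1, fit_config(seed = 7))
#' fit$factorization$taus
#' @export
bznmf_fit <- function(I, rank, config = fit_config(), init = NULL) {
  stopifnot(inherits(I, "bz_signal"), inherits(config, "bz_fit_config"))
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be at least 1", call. = FALSE)
  if (all(I$values == 0))
    stop("input matrix is identically zero; nothing to factorize",
         call. = FALSE)
  if (!is.null(init)) {
    stopifnot(inherits(init, "bz_factorization"))
    if (length(init$taus) > rank)
      stop("warm-start factorization has more components than `rank`",
           call. = FALSE)
    if (!isTRUE(all.equal(init$times, I$times)))
      stop("warm-start factorization uses a different time grid",
           call. = FALSE)
  }
  M <- nrow(I$values)
  tau_floor <- config$tau_floor %||% I$times[1]
  tau_ceiling <- config$tau_ceiling %||% (1e3 * I$times[M])
  obj_code <- if (config$objective == "lse") 0L else 1L
  lt_mid <- (log10(I$times[1]) + log10(I$times[M])) / 2

  best <- NULL
  withr::with_seed(config$seed, {
    for (s in seq_len(config$n_restarts)) {
      start <- if (is.null(init)) {
        .bz_init(I, rank)
      } else {
        extra <- rank - length(init$taus)
        list(tau = c(init$taus, 10^(lt_mid + runif(extra, -0.25, 0.25))),
             H = rbind(init$coeffs,
                       matrix(runif(extra * ncol(I$values)), extra) *
                         mean(init$coeffs)))
      }
      res <- bznmf_fit_cpp(I$values, I$times, start$tau, start$H, obj_code,
                           config$max_iterations, config$rel_tolerance,
                           tau_floor, tau_ceiling)
      if (!is.finite(res$objective)) {
        warning("restart ", s, " produced a non-finite objective; discarded",
                call. = FALSE)
        next
      }
      if (is.null(best) || res$objective < best$objective) {
        best <- res
        best$restart_index <- s
      }
    }
  })
  if (is.null(best))
    stop("all restarts failed with non-finite objectives", call. = FALSE)

  f <- factorization(best$tau, best$H, I$times, reorder = FALSE)
  ord <- order(f$taus, -rowMeans(f$coeffs))
  f$taus <- f$taus[ord]
  f$coeffs <- f$coeffs[ord, , drop = FALSE]
  structure(list(factorization = f,
                 objective_value = best$objective,
                 objective_trace = as.numeric(best$trace),
                 iterations_run = best$iterations,
                 converged = best$converged,
                 restart_index = best$restart_index,
                 degenerate = as.logical(best$degenerate)[ord],
                 objective = config$objective,
                 rank = rank),
            class = "bz_fit")
}

#' @export
print.bz_fit <- function(x, ...) {
  cat(sprintf("<bz_fit> rank %d, objective %s = %.6g (%d iterations%s)\n",
              x$rank, x$objective, x$objective_value, x$iterations_run,
              if (x$converged) ", converged" else ""))
  cat("  tau:", format(x$factorization$taus, digits = 6), "\n")
  invisible(x)
}

#' Free-basis non-negative matrix factorization (baseline)
#'
#' Classic multiplicative-update NMF under the sum-of-squares objective
#' with an unconstrained non-negative basis W.  Provided as the comparison
#' baseline: unlike the Boltzmann-constrained fit, its basis columns carry
#' no parametric shape and no time constants, so the components need not
#' be exponential decays.
#'
#' @inheritParams bznmf_fit
#' @return A list with elements `W`, `H`, `objective_value`,
#'   `objective_trace`, `iterations_run`, `converged`, `restart_index`.
#' @export
nmf_fit_lse <- function(I, rank, config = fit_config()) {
  stopifnot(inherits(I, "bz_signal"), inherits(config, "bz_fit_config"))
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be at least 1", call. = FALSE)
  if (all(I$values == 0))
    stop("input matrix is identically zero; nothing to factorize",
         call. = FALSE)
  M <- nrow(I$values); N <- ncol(I$values)
  best <- NULL
  withr::with_seed(config$seed, {
    for (s in seq_len(config$n_restarts)) {
      W0 <- matrix(runif(M * rank), M, rank)
      H0 <- matrix(runif(rank * N), rank, N)
      res <- nmf_lse_fit_cpp(I$values, W0, H0,
                             config$max_iterations, config$rel_tolerance)
      if (!is.finite(res$objective)) next
      if (is.null(best) || res$objective < best$objective) {
        best <- res
        best$restart_index <- s
      }
    }
  })
  if (is.null(best))
    stop("all restarts failed with non-finite objectives", call. = FALSE)
  list(W = best$W, H = best$H,
       objective_value = best$objective,
       objective_trace = as.numeric(best$trace),
       iterations_run = best$iterations,
       converged = best$converged,
       restart_index = best$restart_index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
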