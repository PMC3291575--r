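#' @useDynLib bznmf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif sd
NULL

# numerical floor used for guarded divisions and logarithms throughout
.bz_eps <- 1e-12

#' Validate a measurement-time grid
#'
#' A time grid is the vector of measurement times \eqn{t_1 < \dots < t_M}
#' (all strictly positive) at which every signal sequence is sampled.  In
#' fluorescence correlation spectroscopy these are the lag times of the
#' correlation curve, typically log-spaced over several decades.
#'
#' @param times Numeric vector of strictly positive, strictly increasing
#'   measurement times, length at least 2.
#' @return The validated numeric vector of times.
#' @examples
#' time_grid(c(1, 10, 100))
#' @export
time_grid <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L)
    stop("a time grid needs at least 2 points", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("time grid contains non-finite values", call. = FALSE)
  if (any(times <= 0))
    stop("all measurement times must be strictly positive", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("measurement times must be strictly increasing", call. = FALSE)
  times
}

#' Construct a signal matrix
#'
#' Bundles an M x N matrix of non-negative intensities (M time points in
#' rows, N measured sequences in columns) with its time grid.  This is the
#' input object of the factorization: each column is one measured decay
#' curve sampled on the common grid.
#'
#' @param values Numeric M x N matrix with non-negative entries.
#' @param times Time grid of length M (see [time_grid()]).
#' @return An object of class `bz_signal` with elements `values` and
#'   `times`.
#' @examples
#' g <- time_grid(c(1, 10, 100))
#' signal_matrix(cbind(exp(-g / 20)), g)
#' @export
signal_matrix <- function(values, times) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  times <- time_grid(times)
  if (nrow(values) != length(times))
    stop("row count of `values` (", nrow(values),
         ") does not match grid length (", length(times), ")", call. = FALSE)
  if (ncol(values) < 1L)
    stop("signal matrix needs at least one sequence (column)", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("signal matrix contains non-finite values", call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("signal matrix has negative entries, first at row ", neg[1, 1],
         ", column ", neg[1, 2], call. = FALSE)
  structure(list(values = values, times = times), class = "bz_signal")
}

#' @export
print.bz_signal <- function(x, ...) {
  cat(sprintf("<bz_signal> %d time points x %d sequences, t in [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' @export
dim.bz_signal <- function(x) dim(x$values)

#' Construct a factorization
#'
#' A rank-R factorization of a signal matrix consists of R time constants
#' tau (which determine the exponential basis on the given grid) and an
#' R x N non-negative coefficient matrix H.  Components are stored in
#' canonical order: ascending tau, ties broken by descending mean
#' coefficient.
#'
#' @param taus Numeric vector of strictly positive time constants,
#'   length R.
#' @param coeffs Numeric R x N matrix of non-negative coefficients.
#' @param times Time grid (see [time_grid()]).
#' @param reorder Canonically reorder components (default `TRUE`).
#' @return An object of class `bz_factorization` with elements `taus`,
#'   `coeffs` and `times`.
#' @examples
#' g <- time_grid(c(1, 10, 100))
#' factorization(c(10, 100), matrix(0.5, 2, 3), g)
#' @export
factorization <- function(taus, coeffs, times, reorder = TRUE) {
  taus <- as.numeric(taus)
  coeffs <- as.matrix(coeffs)
  storage.mode(coeffs) <- "double"
  times <- time_grid(times)
  if (length(taus) < 1L)
    stop("factorization needs at least one component", call. = FALSE)
  if (anyNA(taus) || any(!is.finite(taus)) || any(taus <= 0))
    stop("all time constants must be finite and strictly positive",
         call. = FALSE)
  if (nrow(coeffs) != length(taus))
    stop("coefficient matrix must have one row per component", call. = FALSE)
  if (anyNA(coeffs) || any(!is.finite(coeffs)) || any(coeffs < 0))
    stop("coefficients must be finite and non-negative", call. = FALSE)
  f <- structure(list(taus = taus, coeffs = coeffs, times = times),
                 class = "bz_factorization")
  if (reorder) canonical_order(f) else f
}

#' Canonically order the components of a factorization
#'
#' Sorts components by ascending time constant (fast to slow); exact ties
#' are broken by descending mean coefficient, so the dominant component of
#' a tied pair comes first.
#'
#' @param f A `bz_factorization`.
#' @return The reordered factorization.
#' @export
canonical_order <- function(f) {
  stopifnot(inherits(f, "bz_factorization"))
  ord <- order(f$taus, -rowMeans(f$coeffs))
  f$taus <- f$taus[ord]
  f$coeffs <- f$coeffs[ord, , drop = FALSE]
  f
}

#' @export
print.bz_factorization <- function(x, ...) {
  cat(sprintf("<bz_factorization> rank %d, %d sequences\n",
              length(x$taus), ncol(x$coeffs)))
  cat("  tau:", format(x$taus, digits = 6), "\n")
  cat("  mean coeff:", format(rowMeans(x$coeffs), digits = 4), "\n")
  invisible(x)
}

#' Exponential (Boltzmann) basis matrix
#'
#' Builds the M x R basis matrix with entries
#' \eqn{w_{jr} = \exp(-t_j / \tau_r)}: each column is a normalized
#' exponential decay with time constant \eqn{\tau_r} evaluated on the
#' measurement grid.  This parametric basis is the constraint that
#' distinguishes the factorization from free NMF, and corresponds to the
#' Boltzmann energy distribution of component r.
#'
#' Entries lie in (0, 1] mathematically; for very large \eqn{t/\tau}
#' (beyond roughly 745) the double-precision value underflows to 0.
#'
#' @param taus Strictly positive time constants, length R.
#' @param times Time grid (see [time_grid()]).
#' @return M x R numeric matrix.
#' @examples
#' basis_matrix(c(10, 100), time_grid(c(1.002, 10, 1000)))
#' @export
basis_matrix <- function(taus, times) {
  times <- time_grid(times)
  taus <- as.numeric(taus)
  if (length(taus) < 1L || anyNA(taus) || any(!is.finite(taus)) ||
      any(taus <= 0))
    stop("all time constants must be finite and strictly positive",
         call. = FALSE)
  exp(outer(times, taus, function(t, tau) -t / tau))
}

#' Reconstruct the signal matrix implied by a factorization
#'
#' Computes W H, where W is the exponential basis determined by the time
#' constants and H is the coefficient matrix: the model's approximation of
#' the input matrix.
#'
#' @param f A `bz_factorization`.
#' @return M x N non-negative numeric matrix.
#' @export
reconstruct <- function(f) {
  stopifnot(inherits(f, "bz_factorization"))
  basis_matrix(f$taus, f$times) %*% f$coeffs
}

.bz_check_shapes <- function(I, f) {
  stopifnot(inherits(I, "bz_signal"), inherits(f, "bz_factorization"))
  if (!isTRUE(all.equal(I$times, f$times)))
    stop("signal matrix and factorization use different time grids",
         call. = FALSE)
  if (ncol(I$values) != ncol(f$coeffs))
    stop("signal matrix has ", ncol(I$values), " sequences but the ",
         "factorization has ", ncol(f$coeffs), call. = FALSE)
  invisible(TRUE)
}

#' Least-squares objective
#'
#' The sum of squared residuals \eqn{D = \sum_{j,i} (I_{ji} - (WH)_{ji})^2}
#' between the signal matrix and its reconstruction.  This is the plain
#' (unhalved) sum of squares; it is zero exactly at a perfect fit.
#'
#' @param I A `bz_signal`.
#' @param f A `bz_factorization` on the same grid.
#' @return Non-negative scalar.
#' @export
lse_objective <- function(I, f) {
  .bz_check_shapes(I, f)
  sum((I$values - reconstruct(f))^2)
}

#' Generalized Kullback-Leibler (I-divergence) objective
#'
#' \eqn{D = \sum_{j,i} [ I_{ji} \ln(I_{ji}/(WH)_{ji}) - I_{ji} + (WH)_{ji} ]}
#' with the limit convention \eqn{0 \ln(0/x) = 0}.  This is the
#' non-normalized Kullback-Leibler cost appropriate for Poisson-distributed
#' errors; it is non-negative and zero exactly at a perfect fit.
#' Reconstruction values (and log arguments) are floored at 1e-12 so that
#' zero model values with positive data do not produce infinities; such
#' floored cells are reported via the `"n_floored"` attribute.
#'
#' @inheritParams lse_objective
#' @return Non-negative scalar with attribute `n_floored` (count of
#'   epsilon-guarded cells).
#' @export
kl_objective <- function(I, f) {
  .bz_check_shapes(I, f)
  wh <- reconstruct(f)
  x <- I$values
  floored <- sum(wh < .bz_eps & x > 0)
  wh <- pmax(wh, .bz_eps)
  logterm <- ifelse(x > 0, x * log(pmax(x, .bz_eps) / wh), 0)
  d <- sum(logterm - x + wh)
  attr(d, "n_floored") <- floored
  d
}

#' Evaluate an objective by name
#'
#' @inheritParams lse_objective
#' @param objective `"lse"` (sum of squared residuals) or `"kl"`
#'   (generalized Kullback-Leibler divergence).
#' @return Non-negative scalar.
#' @export
objective_value <- function(I, f, objective = c("lse", "kl")) {
  objective <- match.arg(objective)
  if (objective == "lse") lse_objective(I, f) else as.numeric(kl_objective(I, f))
}
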