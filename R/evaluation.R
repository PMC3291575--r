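# Parameter-recovery evaluation: matching estimated components to
# ground truth and the relative error-rate summaries D_tau and D_h.

#' Per-sequence existence ratios
#'
#' Normalizes each coefficient column so components sum to 1 within a
#' sequence: `ratio_ri = h_ri / sum_r h_ri`.  The existence ratio is the
#' relative weight of component r in sequence i.  Sequences whose
#' coefficients are all zero have undefined ratios; they are set to `NA`,
#' excluded from the summaries and reported.
#'
#' @param f A `bz_factorization`.
#' @return A list with `ratios` (R x N), `mean` and `sd` (per component,
#'   across sequences) and `excluded` (indices of all-zero sequences).
#' @examples
#' g <- time_grid(c(1, 10))
#' f <- factorization(c(10, 100), rbind(c(1, 2), c(1, 2)), g)
#' existence_ratios(f)$ratios
#' @export
existence_ratios <- function(f) {
  stopifnot(inherits(f, "bz_factorization"))
  tot <- colSums(f$coeffs)
  excluded <- which(tot <= 0)
  ratios <- sweep(f$coeffs, 2, tot, "/")
  if (length(excluded)) ratios[, excluded] <- NA_real_
  keep <- ratios[, setdiff(seq_len(ncol(ratios)), excluded), drop = FALSE]
  list(ratios = ratios,
       mean = rowMeans(keep),
       sd = apply(keep, 1, sd),
       excluded = excluded)
}

#' Match estimated components to true components
#'
#' Finds the bijection between estimated and true components minimizing
#' the total absolute log10 time-constant discrepancy
#' \eqn{\sum_r |\log_{10}\hat\tau_{\pi(r)} - \log_{10}\tau^*_r|}.  For
#' points on a line with absolute-difference cost the optimal assignment
#' pairs order statistics, so the match is computed by sorting both
#' vectors; this is exact and deterministic.
#'
#' @param estimated,true Positive tau vectors of equal length.
#' @return Integer permutation `p` such that `estimated[p[r]]` is the
#'   estimate matched to `true[r]`.
#' @examples
#' match_components(c(95, 11), c(10, 100))
#' @export
match_components <- function(estimated, true) {
  if (length(estimated) != length(true))
    stop("estimated and true component counts differ", call. = FALSE)
  stopifnot(all(estimated > 0), all(true > 0))
  # pair the r-th smallest estimate with the r-th smallest truth
  perm <- integer(length(true))
  perm[order(true)] <- order(estimated)
  perm
}

#' Parameter error rates across a simulation study
#'
#' The time-constant error rate averages relative absolute deviations over
#' components and input-matrix sets,
#' \deqn{D_\tau = \frac{1}{RS} \sum_{s=1}^{S} \sum_{r=1}^{R}
#'   \frac{|\hat\tau_r^{(s)} - \tau_r^*|}{\tau_r^*},}
#' while the existence-ratio error rate averages over components and all
#' \eqn{\tilde N = N \times S} individual sequences,
#' \deqn{D_h = \frac{1}{R\tilde N} \sum_{i=1}^{\tilde N} \sum_{r=1}^{R}
#'   \frac{|\hat h_{ri} - h_r^*|}{h_r^*}.}
#' Estimated components are matched to the truth with
#' [match_components()] before the deviations are taken, so the rates are
#' invariant to the ordering of fitted components.  Both are returned as
#' fractions (multiply by 100 for percent).
#'
#' @param fits List of `bz_factorization` objects, one per input-matrix
#'   set, each of the true rank.
#' @param taus_true True time constants (length R, all positive).
#' @param ratios_true True existence ratios (length R, all positive).
#' @return A list of class `bz_evaluation` with `d_tau`, `d_h`, `n_sets`,
#'   `n_total_sequences`, `per_set_tau_dev` (R x S relative deviations)
#'   and `matchings`.
#' @export
error_rates <- function(fits, taus_true, ratios_true) {
  if (inherits(fits, "bz_factorization")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(taus_true > 0), all(ratios_true > 0),
            length(taus_true) == length(ratios_true))
  R <- length(taus_true)
  S <- length(fits)
  tau_dev <- matrix(NA_real_, R, S)
  h_terms <- 0
  n_seq <- 0L
  matchings <- vector("list", S)
  for (s in seq_len(S)) {
    f <- fits[[s]]
    stopifnot(inherits(f, "bz_factorization"))
    if (length(f$taus) != R)
      stop("fit for set ", s, " has rank ", length(f$taus),
           " but truth has rank ", R, call. = FALSE)
    p <- match_components(f$taus, taus_true)
    matchings[[s]] <- p
    tau_dev[, s] <- abs(f$taus[p] - taus_true) / taus_true
    er <- existence_ratios(f)$ratios[p, , drop = FALSE]
    ok <- colSums(is.na(er)) == 0
    h_terms <- h_terms +
      sum(abs(er[, ok, drop = FALSE] - ratios_true) / ratios_true)
    n_seq <- n_seq + sum(ok)
  }
  structure(list(d_tau = mean(tau_dev),
                 d_h = h_terms / (R * n_seq),
                 n_sets = S,
                 n_total_sequences = n_seq,
                 per_set_tau_dev = tau_dev,
                 matchings = matchings),
            class = "bz_evaluation")
}

#' @export
print.bz_evaluation <- function(x, ...) {
  cat(sprintf(
    "<bz_evaluation> %d set(s), %d sequences: D_tau = %.3f%%, D_h = %.3f%%\n",
    x$n_sets, x$n_total_sequences, 100 * x$d_tau, 100 * x$d_h))
  invisible(x)
}
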