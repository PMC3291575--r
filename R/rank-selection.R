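# Model-order (rank) selection.
#
# Under the least-squares objective the residuals are treated as Gaussian
# with the signal sequence as the sampling unit, so -2 ln L reduces to
# N ln(D / N) up to constants; under the generalized KL divergence errors
# are treated as Poisson and Stirling's approximation gives -2 ln L = 2 D
# up to constants.  In both cases the degrees of freedom are counted as
# the rank R itself, and R-independent constants are dropped since they
# cannot change the argmin.

#' Gaussian AIC for a least-squares fit
#'
#' \eqn{AIC = N \ln(D / N) + 2R}, where `N` is the number of signal
#' sequences (the sampling unit of the Gaussian likelihood, as in the
#' finite-sample correction of [aicc()]) and additive constants fixed
#' across ranks are dropped.  `D` is floored at 1e-300 so that a perfect
#' fit on noise-free data yields a finite score.
#'
#' @param D Sum-of-squares objective value at rank `R`.
#' @param N Number of signal sequences.
#' @param R Rank of the fit.
#' @return AIC score (lower is better).
#' @export
aic_lse <- function(D, N, R) {
  stopifnot(D >= 0, N >= 1, R >= 1)
  N * log(max(D, 1e-300) / N) + 2 * R
}

#' Poisson AIC for a generalized-KL fit
#'
#' \eqn{AIC = 2 D_{KL} + 2R}, the Stirling-approximated Poisson deviance
#' plus the rank penalty, with R-independent constants dropped.
#'
#' @param D_kl Generalized Kullback-Leibler objective value at rank `R`.
#' @param R Rank of the fit.
#' @return AIC score (lower is better).
#' @export
aic_kl <- function(D_kl, R) {
  stopifnot(D_kl >= 0, R >= 1)
  2 * D_kl + 2 * R
}

#' Finite-sample correction (AICc)
#'
#' Adds the small-sample correction \eqn{2R(R+1)/(N-R-1)} to an AIC score,
#' where `N` is the number of signal sequences.  Undefined when
#' `N <= R + 1`; such ranks score `+Inf`.
#'
#' @param aic AIC score.
#' @param R Rank.
#' @param N Number of signal sequences.
#' @return Corrected score; `+Inf` where the correction is undefined.
#' @export
aicc <- function(aic, R, N) {
  stopifnot(R >= 1, N >= 1)
  ifelse(N > R + 1, aic + 2 * R * (R + 1) / (N - R - 1), Inf)
}

.bz_criterion_tags <- c("aic_lse", "aicc_lse", "aic_kl", "aicc_kl", "cv")

.bz_score <- function(criterion, D, N, R) {
  switch(criterion,
         aic_lse  = aic_lse(D, N, R),
         aicc_lse = aicc(aic_lse(D, N, R), R, N),
         aic_kl   = aic_kl(D, R),
         aicc_kl  = aicc(aic_kl(D, R), R, N),
         stop("unknown criterion: ", criterion, call. = FALSE))
}

.bz_new_ranksel <- function(criterion, ranks, scores, fits, extra = list()) {
  sel <- ranks[which.min(scores)]      # which.min takes the first minimum,
  out <- c(list(criterion = criterion, # i.e. ties break to the lower rank
                ranks = ranks,
                scores = scores,
                selected_rank = sel,
                fits = fits),
           extra)
  structure(out, class = "bz_rank_selection")
}

#' @export
print.bz_rank_selection <- function(x, ...) {
  cat(sprintf("<bz_rank_selection> criterion %s over ranks %d..%d\n",
              x$criterion, min(x$ranks), max(x$ranks)))
  cat("  selected rank:", x$selected_rank, "\n")
  invisible(x)
}

#' Select the number of components by information criterion
#'
#' Fits the Boltzmann-constrained factorization at every rank in
#' `rank_range` with [bznmf_fit()] and scores each fit with the requested
#' information criterion: Gaussian AIC/AICc when the configured objective
#' is `"lse"`, Poisson AIC/AICc when it is `"kl"`.  The selected rank
#' minimizes the score; exact ties break to the smaller rank (parsimony).
#' A rank whose fit fails scores `+Inf` and the failure is recorded.
#'
#' The sweep is incremental: the smallest rank is fitted from scratch and
#' every subsequent rank warm-starts from the previous rank's converged
#' fit plus one freshly seeded component (see [bznmf_fit()]).  A missing
#' real component is pulled directly into the residual structure it must
#' explain, which markedly improves fit quality at higher ranks, while a
#' surplus component added to an already-adequate fit has no residual
#' structure to claim — so the objective flattens beyond the true rank,
#' which is precisely the shape an information criterion needs.
#' `warm_start = FALSE` fits every rank independently instead.
#'
#' @param I A `bz_signal`.
#' @param criterion `"aic"` or `"aicc"`.
#' @param rank_range Integer vector `c(R_min, R_max)` (default `c(1, 20)`).
#' @param config A [fit_config()]; its `objective` decides the AIC flavor.
#' @param warm_start Warm-start each rank from the previous rank's fit
#'   (default `TRUE`).
#' @return An object of class `bz_rank_selection` with the per-rank
#'   `scores`, all per-rank `fits`, `selected_rank` and the per-rank
#'   objective values `objective_values`.
#' @examples
#' sim <- simulate_signals(sim_config(sim_rank = 1, dims = 30,
#'                                    n_sequences = 5, seed = 3))
#' sel <- select_rank(sim$signal, "aic", c(1, 3),
#'                    fit_config(n_restarts = 1, seed = 3))
#' sel$selected_rank
#' @export
select_rank <- function(I, criterion = c("aic", "aicc"),
                        rank_range = c(1L, 20L),
                        config = fit_config(), warm_start = TRUE) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(I, "bz_signal"), inherits(config, "bz_fit_config"))
  rank_range <- as.integer(rank_range)
  if (length(rank_range) != 2L || rank_range[1] < 1L ||
      rank_range[2] < rank_range[1])
    stop("rank_range must be c(R_min, R_max) with 1 <= R_min <= R_max",
         call. = FALSE)
  ranks <- seq.int(rank_range[1], rank_range[2])
  N <- ncol(I$values)
  tag <- paste0(criterion, "_", config$objective)

  fits <- vector("list", length(ranks))
  scores <- numeric(length(ranks))
  objs <- rep(NA_real_, length(ranks))
  errors <- rep(NA_character_, length(ranks))
  prev <- NULL
  for (k in seq_along(ranks)) {
    cfg_k <- config
    cfg_k$seed <- (config$seed + 131L * ranks[k]) %% .Machine$integer.max
    fit <- tryCatch(bznmf_fit(I, ranks[k], cfg_k,
                              init = if (warm_start) prev),
                    error = identity)
    if (inherits(fit, "error")) {
      scores[k] <- Inf
      errors[k] <- conditionMessage(fit)
      next
    }
    fits[[k]] <- fit
    prev <- fit$factorization
    objs[k] <- fit$objective_value
    scores[k] <- .bz_score(tag, fit$objective_value, N, ranks[k])
  }
  .bz_new_ranksel(tag, ranks, scores, fits,
                  list(objective_values = objs, fit_errors = errors))
}

#' Select the number of components by k-fold cross-validation
#'
#' The baseline selector: sequences (columns) are shuffled into `k` folds
#' with the seed from `config`.  For each rank and fold, the time
#' constants are fitted on the training folds; the held-out sequences are
#' then fitted coefficients-only at those fixed time constants, and the
#' held-out mean squared residual per matrix element is recorded.  The CV
#' score of a rank is the mean over folds, and the rank minimizing it is
#' selected (ties to the smaller rank).  Within each fold the rank sweep
#' is warm-started incrementally, as in [select_rank()].
#'
#' @inheritParams select_rank
#' @param k Number of folds (default 3; must satisfy `2 <= k <= N`).
#' @return A `bz_rank_selection` with tag `"cv"` and per-fold scores in
#'   `fold_scores` (ranks x folds).
#' @export
kfold_cv_rank <- function(I, rank_range = c(1L, 20L), k = 3L,
                          config = fit_config()) {
  stopifnot(inherits(I, "bz_signal"), inherits(config, "bz_fit_config"))
  k <- as.integer(k)
  N <- ncol(I$values)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (N < k) stop("need at least k sequences for k folds", call. = FALSE)
  rank_range <- as.integer(rank_range)
  ranks <- seq.int(rank_range[1], rank_range[2])
  M <- nrow(I$values)
  obj_code <- if (config$objective == "lse") 0L else 1L

  folds <- withr::with_seed(config$seed, {
    split(sample.int(N), rep_len(seq_len(k), N))
  })
  if (any(lengths(folds) == 0L))
    stop("a fold received zero sequences", call. = FALSE)

  fold_scores <- matrix(NA_real_, length(ranks), k)
  for (fold in seq_len(k)) {
    hold <- folds[[fold]]
    train <- signal_matrix(I$values[, -hold, drop = FALSE], I$times)
    test_vals <- I$values[, hold, drop = FALSE]
    prev <- NULL
    for (kk in seq_along(ranks)) {
      cfg_k <- config
      cfg_k$seed <- (config$seed + 131L * ranks[kk] + 7919L * fold) %%
        .Machine$integer.max
      fit <- tryCatch(bznmf_fit(train, ranks[kk], cfg_k, init = prev),
                      error = identity)
      if (inherits(fit, "error")) { fold_scores[kk, fold] <- Inf; next }
      prev <- fit$factorization
      tau <- fit$factorization$taus
      H0 <- withr::with_seed(config$seed + 1000L * fold + ranks[kk], {
        H0 <- matrix(runif(ranks[kk] * length(hold)), ranks[kk])
        sweep(H0, 2, colSums(test_vals) / pmax(colSums(H0), .bz_eps), "*")
      })
      ref <- fit_coeffs_cpp(test_vals, I$times, tau, H0, obj_code,
                            config$max_iterations, config$rel_tolerance)
      fold_scores[kk, fold] <- ref$objective / (M * length(hold))
    }
  }
  scores <- rowMeans(fold_scores)
  .bz_new_ranksel("cv", ranks, scores, vector("list", length(ranks)),
                  list(fold_scores = fold_scores, k = k, folds = folds))
}
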