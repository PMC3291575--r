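# Reading/writing delimited signal matrices and the two high-level
# pipeline drivers used by the command-line interface.
#
# File convention: delimited text (TSV by default, CSV accepted), first
# column the measurement times, remaining columns one sequence each, with
# an optional header row.  Times are rows, sequences are columns.

#' Read a signal matrix from delimited text
#'
#' @param path Path to a TSV (default) or CSV file whose first column
#'   holds the measurement times and whose remaining columns hold the
#'   signal sequences.
#' @param sep Field separator; `"\t"` or `","`.
#' @param header Whether the file has a header row (auto-detected when
#'   `NULL`: a first line whose second field is non-numeric is treated as
#'   a header).
#' @return A `bz_signal`.
#' @export
read_signal_matrix <- function(path, sep = "\t", header = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first))
    stop("empty file: ", path, call. = FALSE)
  if (is.null(header)) {
    cells <- strsplit(first, sep, fixed = TRUE)[[1]]
    header <- length(cells) >= 2L && is.na(suppressWarnings(
      as.numeric(cells[2])))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "numeric", check.names = FALSE)
  if (ncol(df) < 2L)
    stop("expected a time column plus at least one sequence column",
         call. = FALSE)
  times <- df[[1]]
  if (any(diff(times) <= 0))
    stop("time column is not strictly increasing (first violation after ",
         "row ", which(diff(times) <= 0)[1], ")", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative entry at data row ", neg[1, 1], ", sequence column ",
         neg[1, 2], call. = FALSE)
  signal_matrix(vals, times)
}

#' Write a signal matrix (and optional ground truth) to delimited text
#'
#' Writes the times-plus-sequences table; when `truth` is supplied a JSON
#' sidecar `<path>.json` records the generating parameters so simulated
#' data can round-trip with its ground truth.
#'
#' @param I A `bz_signal`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @param truth Optional `bz_factorization` or list with `taus_true`,
#'   `ratios_true` and `seed` to store in the sidecar.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(I, path, sep = "\t", truth = NULL) {
  stopifnot(inherits(I, "bz_signal"))
  df <- data.frame(time = I$times, I$values, check.names = FALSE)
  colnames(df) <- c("time", paste0("seq", seq_len(ncol(I$values))))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    side <- if (inherits(truth, "bz_factorization")) {
      list(taus_true = truth$taus,
           ratios_true = as.numeric(existence_ratios(truth)$mean))
    } else truth
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Decompose a signal matrix end to end
#'
#' The main pipeline: sweep the rank range, fit the Boltzmann-constrained
#' factorization at every rank, select the rank with the requested
#' criterion, and summarize the winning fit (time constants, existence
#' ratios as mean +/- sd across sequences, residuals).  When `out_dir` is
#' given, a machine-readable JSON report and TSV tables of the criterion
#' sweep and the fitted parameters are written there.
#'
#' @param I A `bz_signal`.
#' @param criterion `"aic"`, `"aicc"` or `"cv"`.
#' @param rank_range `c(R_min, R_max)`; default `c(1, 20)`.
#' @param config A [fit_config()] (its `objective` picks LSE vs KL).
#' @param k Folds for `criterion = "cv"`.
#' @param out_dir Optional output directory for the report artifacts.
#' @param verbose Print progress.
#' @return A list of class `bz_report`: `selected_rank`, `criterion`,
#'   `scores` (per-rank table), `fit` (the winning `bz_fit`), `taus`,
#'   `ratio_mean`, `ratio_sd`, `rmse`, `seed` and `config_hash`.
#' @export
run_decompose <- function(I, criterion = c("aic", "aicc", "cv"),
                          rank_range = c(1L, 20L),
                          config = fit_config(), k = 3L,
                          out_dir = NULL, verbose = FALSE) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(I, "bz_signal"))
  if (rank_range[2] > 50L)
    stop("rank range above 50 is not supported", call. = FALSE)
  sel <- if (criterion == "cv") {
    kfold_cv_rank(I, rank_range, k = k, config = config)
  } else {
    select_rank(I, criterion, rank_range, config)
  }
  best_fit <- sel$fits[[match(sel$selected_rank, sel$ranks)]]
  if (is.null(best_fit))   # cv keeps no full-data fits; refit at R_e
    best_fit <- bznmf_fit(I, sel$selected_rank, config)
  er <- existence_ratios(best_fit$factorization)
  resid <- I$values - reconstruct(best_fit$factorization)
  report <- structure(list(
    selected_rank = sel$selected_rank,
    criterion = sel$criterion,
    scores = data.frame(rank = sel$ranks, score = sel$scores),
    fit = best_fit,
    taus = best_fit$factorization$taus,
    ratio_mean = as.numeric(er$mean),
    ratio_sd = as.numeric(er$sd),
    rmse = sqrt(mean(resid^2)),
    seed = config$seed,
    config_hash = .bz_config_hash(config, criterion, rank_range, k)
  ), class = "bz_report")
  if (verbose) {
    message("selected rank ", report$selected_rank, " by ", report$criterion,
            "; tau = ", paste(signif(report$taus, 6), collapse = ", "))
  }
  if (!is.null(out_dir)) .bz_write_report(report, out_dir)
  report
}

#' @export
print.bz_report <- function(x, ...) {
  cat(sprintf("<bz_report> criterion %s selected rank %d (rmse %.4g)\n",
              x$criterion, x$selected_rank, x$rmse))
  tab <- data.frame(tau = signif(x$taus, 6),
                    ratio_mean = round(x$ratio_mean, 4),
                    ratio_sd = round(x$ratio_sd, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

# stable short hash of the run configuration (no external digest dep)
.bz_config_hash <- function(config, criterion, rank_range, k) {
  s <- paste(criterion, rank_range[1], rank_range[2], k,
             config$objective, config$max_iterations, config$rel_tolerance,
             config$n_restarts, config$seed, sep = "|")
  v <- utf8ToInt(s)
  h <- 5381
  for (c in v) h <- (h * 33 + c) %% 2^31
  sprintf("%08x", as.integer(h))
}

.bz_write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$scores, file.path(out_dir, "criterion_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  params <- data.frame(component = seq_along(report$taus),
                       tau = report$taus,
                       ratio_mean = report$ratio_mean,
                       ratio_sd = report$ratio_sd)
  utils::write.table(params, file.path(out_dir, "components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(schema_version = 1L,
               selected_rank = report$selected_rank,
               criterion = report$criterion,
               seed = report$seed,
               config_hash = report$config_hash,
               rmse = report$rmse,
               taus = report$taus,
               ratio_mean = report$ratio_mean,
               ratio_sd = report$ratio_sd,
               sweep = report$scores)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run a (possibly reduced) simulation study end to end
#'
#' For every cell of the factorial `{sim_ranks} x {dims_grid}` design,
#' simulates `n_sets` input matrices, runs rank selection on each, fits
#' the true-rank factorization, and aggregates selected ranks, parameter
#' means/standard deviations and error rates.
#'
#' @inheritParams simulate_study
#' @param criterion `"aic"` or `"aicc"`.
#' @param config A [fit_config()].
#' @param rank_range Rank sweep for selection.
#' @param verbose Print per-cell progress.
#' @return A data.frame with one row per cell: simulated rank, dims, the
#'   per-set selected ranks (comma-separated), their mean, tau and ratio
#'   means/sds at the true rank, and error rates `d_tau` / `d_h`.  The
#'   per-cell detail (fits, evaluations) is attached as attribute
#'   `"cells"`.
#' @export
run_reproduce_study <- function(sim_ranks = 2:3, dims_grid = 145L,
                                n_sets = 3L, seed = 1L,
                                criterion = c("aic", "aicc"),
                                config = fit_config(),
                                rank_range = c(1L, 20L),
                                verbose = FALSE, ...) {
  criterion <- match.arg(criterion)
  cells <- simulate_study(sim_ranks, dims_grid, n_sets, seed, ...)
  if (length(cells) == 0L) return(invisible(data.frame()))
  rows <- list()
  detail <- list()
  for (cell in cells) {
    sel_ranks <- integer(0)
    fits_true <- list()
    for (st in cell$sets) {
      res <- tryCatch({
        sel <- select_rank(st$signal, criterion, rank_range, config)
        true_idx <- match(cell$sim_rank, sel$ranks)
        fit_true <- if (!is.na(true_idx) && !is.null(sel$fits[[true_idx]]))
          sel$fits[[true_idx]] else bznmf_fit(st$signal, cell$sim_rank, config)
        list(sel = sel, fit = fit_true)
      }, error = identity)
      if (inherits(res, "error")) {
        warning("cell (R_s=", cell$sim_rank, ", dim=", cell$dims,
                ") set failed: ", conditionMessage(res), call. = FALSE)
        next
      }
      sel_ranks <- c(sel_ranks, res$sel$selected_rank)
      fits_true <- c(fits_true, list(res$fit$factorization))
    }
    cfg <- cell$sets[[1]]$config
    ev <- error_rates(fits_true, cfg$taus_true, cfg$ratios_true)
    taus_mat <- sapply(fits_true, function(f)
      f$taus[match_components(f$taus, cfg$taus_true)])
    ratio_means <- sapply(fits_true, function(f) {
      p <- match_components(f$taus, cfg$taus_true)
      existence_ratios(f)$mean[p]
    })
    taus_mat <- matrix(taus_mat, nrow = cell$sim_rank)
    ratio_means <- matrix(ratio_means, nrow = cell$sim_rank)
    rows[[length(rows) + 1L]] <- data.frame(
      sim_rank = cell$sim_rank,
      dims = cell$dims,
      selected_ranks = paste(sel_ranks, collapse = ","),
      mean_selected_rank = mean(sel_ranks),
      tau_mean = paste(signif(rowMeans(taus_mat), 6), collapse = ","),
      tau_sd = paste(signif(apply(taus_mat, 1, sd), 4), collapse = ","),
      ratio_mean = paste(signif(rowMeans(ratio_means), 4), collapse = ","),
      d_tau = ev$d_tau,
      d_h = ev$d_h)
    detail[[length(detail) + 1L]] <- list(cell = cell, selected = sel_ranks,
                                          fits = fits_true, evaluation = ev)
    if (verbose)
      message(sprintf("R_s=%d dim=%d: selected %s; D_tau=%.3f%% D_h=%.3f%%",
                      cell$sim_rank, cell$dims,
                      paste(sel_ranks, collapse = ","),
                      100 * ev$d_tau, 100 * ev$d_h))
  }
  out <- do.call(rbind, rows)
  attr(out, "cells") <- detail
  out
}
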