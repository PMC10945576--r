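#' Extract characteristic features of a temporal generalisation matrix
#'
#' Operationalises the features typically discussed for TGMs:
#'
#' * `diagonal` — the time-resolved cross-validated accuracy profile;
#' * `t_star` — the training time of maximum diagonal accuracy (earliest
#'   maximiser if tied);
#' * `vertical_slice` — the generalisation profile of the decoder trained
#'   at `t_star`, i.e. row `t_star` of the TGM;
#' * `late_width` — the longest contiguous run (samples) of diagonal
#'   accuracy above `chance + offset` within the late window (the last
#'   `late_window` fraction of the trial): the "broadening" of accuracy
#'   late in the trial;
#' * `row_periodicity` — the dominant normalised spectral peak of the
#'   mean-detrended TGM rows (peak power over total power, DC excluded),
#'   plus the corresponding frequency: the "chequer" regularity statistic.
#'
#' @param tgm A `tgm` object or a square numeric accuracy matrix.
#' @param chance Chance accuracy level (0.5 for two balanced classes).
#' @param offset Above-chance offset defining "above threshold" for the
#'   late-width feature.
#' @param late_window Fraction of the trial (from the end) forming the late
#'   window.
#' @return Object of class `tgm_features`: a list with the fields above;
#'   `periodicity_freq` is in radians/sample.
#' @export
extract_features <- function(tgm, chance = 0.5, offset = 0.05,
                             late_window = 0.4) {
  acc <- if (inherits(tgm, "tgm")) tgm$accuracy else as.matrix(tgm)
  stopifnot(nrow(acc) == ncol(acc), late_window > 0, late_window <= 1)
  Tt <- nrow(acc)
  dg <- diag(acc)
  t_star <- which.max(dg)  # ties broken to the earliest time
  if (all(dg == dg[1])) {
    message("flat TGM diagonal: t_star tie broken to the earliest time point")
  }
  late_start <- Tt - floor(late_window * Tt) + 1
  above <- dg[late_start:Tt] > (chance + offset)
  late_width <- if (any(above)) max(rle(above)$lengths[rle(above)$values]) else 0L
  # row periodicity: mean periodogram of mean-detrended rows
  rows <- acc - rowMeans(acc)
  spec <- Mod(stats::mvfft(t(rows)))^2  # columns = rows of the TGM
  power <- rowMeans(spec)[seq_len(floor(Tt / 2) + 1)]
  power <- power[-1]  # drop DC
  total <- sum(power)
  peak_bin <- which.max(power)
  periodicity <- if (total > 0) power[peak_bin] / total else 0
  structure(list(
    diagonal = dg,
    t_star = t_star,
    vertical_slice = acc[t_star, ],
    late_width = as.integer(late_width),
    row_periodicity = periodicity,
    periodicity_freq = 2 * pi * peak_bin / Tt,
    chance = chance, offset = offset, late_window = late_window
  ), class = "tgm_features")
}

#' @export
print.tgm_features <- function(x, ...) {
  cat("<tgm_features>\n")
  cat(sprintf("  t_star = %d (diagonal accuracy %.3f)\n",
              x$t_star, x$diagonal[x$t_star]))
  cat(sprintf("  late_width = %d samples above %.2f in the last %.0f%% of the trial\n",
              x$late_width, x$chance + x$offset, 100 * x$late_window))
  cat(sprintf("  row_periodicity = %.3f at %.3f rad/sample\n",
              x$row_periodicity, x$periodicity_freq))
  invisible(x)
}

#' Correlate a simulated TGM with a reference TGM
#'
#' Pearson correlation over the vectorised entries of the two matrices.
#'
#' @param simulated,reference `tgm` objects or numeric matrices of equal
#'   dimensions.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
correlate_tgms <- function(simulated, reference) {
  a <- if (inherits(simulated, "tgm")) simulated$accuracy else as.matrix(simulated)
  b <- if (inherits(reference, "tgm")) reference$accuracy else as.matrix(reference)
  if (!all(dim(a) == dim(b))) {
    stop("TGMs have different dimensions (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"),
         "); crop or resample before correlating", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: one of the TGMs has zero variance",
         call. = FALSE)
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' Read a reference TGM from a CSV matrix
#'
#' Accepts any square numeric CSV (no header, or a header row of column
#' names which is then discarded).
#'
#' @param path CSV file path.
#' @return Numeric square matrix.
#' @export
read_tgm_csv <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1)
  header <- !all(vapply(first, is.numeric, TRUE))
  m <- as.matrix(utils::read.csv(path, header = header))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop("reference TGM must be square; got ", nrow(m), "x", ncol(m),
         call. = FALSE)
  }
  unname(m)
}

#' Write a TGM as a CSV matrix
#'
#' @param tgm A `tgm` object or numeric matrix.
#' @param path CSV file path.
#' @export
write_tgm_csv <- function(tgm, path) {
  acc <- if (inherits(tgm, "tgm")) tgm$accuracy else as.matrix(tgm)
  utils::write.table(acc, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Sweep the response-function rise/fall durations against a reference TGM
#'
#' For every cell of a (`delta2`, `delta3`) grid, re-parametrises the
#' oscillatory response shape of `config`, generates `runs` datasets (one
#' derived seed each), decodes each into a TGM, averages the TGMs, and
#' correlates the average with the reference TGM. This is the
#' correlation-fitting procedure for matching a simulated TGM to an
#' observed one.
#'
#' @param config A [sim_config()] providing every other hyperparameter.
#' @param delta2_grid,delta3_grid Numeric vectors of rise/fall durations
#'   (samples).
#' @param reference A `tgm` object or square matrix with the same number of
#'   time points as `config`.
#' @param runs Datasets (and TGMs) per grid cell (>= 1).
#' @param n_folds Cross-validation folds for each TGM.
#' @param seed Master seed; each (cell, run) uses a derived seed.
#' @return A tibble of class `tgm_sweep` with columns `delta2`, `delta3`,
#'   `correlation` (NA for failed cells, with the error in `error`), and
#'   attribute `argmax` (row of the best cell).
#' @export
sweep_response_shape <- function(config, delta2_grid, delta3_grid, reference,
                                 runs = 10, n_folds = 10, seed = 1L) {
  validate_config(config)
  stopifnot(length(delta2_grid) >= 1, length(delta3_grid) >= 1, runs >= 1)
  ref <- if (inherits(reference, "tgm")) reference$accuracy else as.matrix(reference)
  grid <- tidyr::expand_grid(delta2 = delta2_grid, delta3 = delta3_grid)
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max, nrow(grid) * runs),
                      nrow(grid), runs)
  res <- purrr::pmap(
    list(grid$delta2, grid$delta3, seq_len(nrow(grid))),
    function(d2, d3, i) {
      tryCatch({
        cfg <- config
        sh <- unclass(config$shape)
        sh$delta2 <- d2
        sh$delta3 <- d3
        cfg$shape <- do.call(response_shape, sh)  # re-validate the shape
        validate_config(cfg)
        tgms <- lapply(seq_len(runs), function(r) {
          ds <- sample_dataset(cfg, seed = run_seeds[i, r])
          compute_tgm(ds, n_folds = n_folds, seed = run_seeds[i, r])
        })
        list(correlation = correlate_tgms(average_tgms(tgms), ref),
             error = NA_character_)
      }, error = function(e) {
        list(correlation = NA_real_, error = conditionMessage(e))
      })
    })
  out <- dplyr::mutate(
    grid,
    correlation = vapply(res, `[[`, 0, "correlation"),
    error = vapply(res, `[[`, "", "error")
  )
  best <- which.max(out$correlation)
  out <- tibble::new_tibble(out, class = "tgm_sweep",
                            argmax = if (length(best)) out[best, ] else NULL,
                            runs = runs)
  out
}

#' @export
print.tgm_sweep <- function(x, ...) {
  NextMethod()
  am <- attr(x, "argmax")
  if (!is.null(am)) {
    cat(sprintf("# best cell: delta2 = %g, delta3 = %g (r = %.3f, %d runs/cell)\n",
                am$delta2, am$delta3, am$correlation, attr(x, "runs")))
  }
  invisible(x)
}
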