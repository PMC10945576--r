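#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an epoched dataset into a long tibble
#'
#' @param x An `epoched_data` object.
#' @param ... Unused.
#' @return Tibble with columns `trial`, `condition`, `time` (seconds,
#'   relative to epoch start), `channel`, `value`.
#' @method tidy epoched_data
#' @export
tidy.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    condition = rep(x$labels, times = d[2] * d[3]),
    time = rep(rep((0:(d[2] - 1)) / x$fs, each = d[1]), times = d[3]),
    channel = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' One-row summary of an epoched dataset
#'
#' @param x An `epoched_data` object.
#' @param ... Unused.
#' @method glance epoched_data
#' @export
glance.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(n_trials = d[1], n_times = d[2], n_channels = d[3],
                 fs = x$fs, tau = x$tau, n_conditions = length(unique(x$labels)),
                 seed = x$seed)
}

#' Tidy a TGM into a long tibble
#'
#' @param x A `tgm` object.
#' @param ... Unused.
#' @return Tibble with `train_time`, `test_time` (seconds) and `accuracy`.
#' @method tidy tgm
#' @export
tidy.tgm <- function(x, ...) {
  Tt <- nrow(x$accuracy)
  tibble::tibble(
    train_time = rep(x$times, times = Tt),
    test_time = rep(x$times, each = Tt),
    accuracy = as.vector(x$accuracy)
  )
}

#' One-row summary of a TGM
#'
#' @param x A `tgm` object.
#' @param ... Unused.
#' @return Tibble with mean/max accuracy, the diagonal maximum and its
#'   time, and the cross-validation geometry.
#' @method glance tgm
#' @export
glance.tgm <- function(x, ...) {
  dg <- diag(x$accuracy)
  tibble::tibble(
    mean_accuracy = mean(x$accuracy),
    max_accuracy = max(x$accuracy),
    max_diag_accuracy = max(dg),
    t_star = x$times[which.max(dg)],
    n_folds = x$n_folds, n_trials = x$n_trials
  )
}

#' Tidy TGM features
#'
#' @param x A `tgm_features` object ([extract_features()]).
#' @param ... Unused.
#' @return Long tibble with the `diagonal` and `vertical_slice` profiles
#'   (`profile`, `time_index`, `accuracy`).
#' @method tidy tgm_features
#' @export
tidy.tgm_features <- function(x, ...) {
  Tt <- length(x$diagonal)
  tibble::tibble(
    profile = rep(c("diagonal", "vertical_slice"), each = Tt),
    time_index = rep(seq_len(Tt), 2),
    accuracy = c(x$diagonal, x$vertical_slice)
  )
}

#' One-row summary of TGM features
#'
#' @param x A `tgm_features` object.
#' @param ... Unused.
#' @method glance tgm_features
#' @export
glance.tgm_features <- function(x, ...) {
  tibble::tibble(
    t_star = x$t_star,
    peak_accuracy = x$diagonal[x$t_star],
    vertical_mean = mean(x$vertical_slice),
    late_width = x$late_width,
    row_periodicity = x$row_periodicity,
    periodicity_freq = x$periodicity_freq
  )
}
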