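#' @export
print.ab_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s): %d components, %d times over [0, %g]\n",
              x$model, ncol(x$states), length(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.ab_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Write a trajectory as CSV
#'
#' Header `time` followed by the component labels (`x, y, z` for the
#' single-antibody model; `x_1..x_m, y_1..y_m, z` otherwise), full double
#' precision.
#'
#' @param traj An `ab_trajectory`.
#' @param file Path or connection; `""` writes to standard output.
#' @return The exported data frame, invisibly.
#' @export
write_trajectory_csv <- function(traj, file = "") {
  stopifnot(inherits(traj, "ab_trajectory"))
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 17, trim = TRUE), file = file,
                   row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a trajectory CSV back into an `ab_trajectory`
#'
#' @param file Path to a CSV written by [write_trajectory_csv()].
#' @param model Model tag to attach (not stored in the CSV).
#' @return An `ab_trajectory`.
#' @export
read_trajectory_csv <- function(file, model = "model2") {
  df <- utils::read.csv(file, check.names = FALSE)
  states <- as.matrix(df[, -1, drop = FALSE])
  ycols <- grep("^y_", colnames(states))
  traj <- list(times = df$time, states = states, labels = colnames(states),
               model = model,
               n_classes = if (length(ycols)) length(ycols) else NA_integer_)
  class(traj) <- "ab_trajectory"
  traj
}

traj_y_matrix <- function(traj) {
  if (!inherits(traj, "ab_trajectory") || traj$model != "model2") {
    stop("metrics require a repertoire (model 2) trajectory with ",
         "per-class antibody columns", call. = FALSE)
  }
  traj$states[, grep("^y_", colnames(traj$states)), drop = FALSE]
}

#' Summary metrics of a repertoire trajectory
#'
#' Computes, at every sample time: the total free antibody
#' `sum_i y_i`; the per-class composition `y_i / total` (rows are `NA`
#' when the total is not positive); the dominant class
#' `argmax_i y_i` (ties broken toward the lower index); and the mean
#' class index `sum_i i * y_i / sum_i y_i`.
#'
#' @param traj An `ab_trajectory` from [integrate_shm()].
#' @return A `summary_metrics` list with `times`, `total_antibody`,
#'   `composition` (times x classes matrix), `dominant_class`,
#'   `mean_class_index`.
#' @seealso [time_to_fraction()]
#' @export
trajectory_metrics <- function(traj) {
  y <- traj_y_matrix(traj)
  n <- ncol(y)
  total <- rowSums(y)
  comp <- y / total
  comp[total <= 0, ] <- NA_real_
  dominant <- apply(y, 1, which.max)          # which.max takes the first tie
  mean_idx <- as.vector(y %*% seq_len(n)) / total
  mean_idx[total <= 0] <- NA_real_
  out <- list(times = traj$times, total_antibody = total,
              composition = comp, dominant_class = as.integer(dominant),
              mean_class_index = mean_idx, n_classes = n)
  class(out) <- "summary_metrics"
  out
}

#' @export
print.summary_metrics <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf(paste0(
    "Repertoire metrics over %d times: total %.4g -> %.4g, ",
    "dominant class %d -> %d\n"),
    nt, x$total_antibody[1], x$total_antibody[nt],
    x$dominant_class[1], x$dominant_class[nt]))
  invisible(x)
}

#' First time a class falls to a fraction of its initial level
#'
#' @param traj An `ab_trajectory` from [integrate_shm()].
#' @param class Class index.
#' @param fraction Target fraction of the class's initial free-antibody
#'   level.
#' @return The first sample time `t` with `y_class(t) <= fraction *
#'   y_class(0)`, or `NA` if never reached.
#' @export
time_to_fraction <- function(traj, class, fraction) {
  y <- traj_y_matrix(traj)
  if (class < 1 || class > ncol(y)) {
    stop("class index out of range", call. = FALSE)
  }
  stopifnot(fraction >= 0)
  hit <- which(y[, class] <= fraction * y[1, class])
  if (length(hit)) traj$times[hit[1]] else NA_real_
}
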