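#' Spike-train ensembles
#'
#' A `spike_train_set` holds an ensemble of presynaptic spike-time sequences
#' sharing a common observation duration. Spike times are in milliseconds,
#' sorted, and lie in `[0, duration)`.
#'
#' @param trains list of numeric vectors of spike times (ms).
#' @param duration observation duration (ms).
#' @param provenance optional list describing how the ensemble was generated
#'   (generator name, parameters, seed).
#' @return An object of class `spike_train_set` with elements `trains`,
#'   `duration`, `n_trains` and `provenance`.
#' @export
spike_train_set <- function(trains, duration, provenance = list()) {
  if (!is.list(trains)) stop("`trains` must be a list of numeric vectors")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a positive scalar (ms)")
  trains <- lapply(trains, function(tt) {
    tt <- as.numeric(tt)
    if (is.unsorted(tt)) tt <- sort(tt)
    if (length(tt) && (tt[1L] < 0 || tt[length(tt)] >= duration))
      stop("spike times must lie in [0, duration)")
    tt
  })
  structure(
    list(trains = trains, duration = duration, n_trains = length(trains),
         provenance = provenance),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_spk <- sum(lengths(x$trains))
  cat("spike_train_set:", x$n_trains, "trains,", x$duration, "ms,",
      n_spk, "spikes")
  if (!is.null(x$provenance$generator))
    cat(" [", x$provenance$generator, "]", sep = "")
  cat("\n")
  invisible(x)
}

# single homogeneous Poisson realization on [0, duration) (rate per ms)
.rpoisson_train <- function(rate_ms, duration) {
  n <- stats::rpois(1L, rate_ms * duration)
  sort(stats::runif(n, 0, duration))
}

#' Generate independent homogeneous Poisson spike trains
#'
#' @param rate firing rate in events per second.
#' @param duration duration in ms.
#' @param n_trains number of independent trains.
#' @param seed optional integer seed (set via [set.seed()]).
#' @return a [spike_train_set()].
#' @examples
#' s <- generate_poisson(10, 1000, 5, seed = 1)
#' sum(lengths(s$trains)) / (5 * 1) # approx 10 spikes per second per train
#' @export
generate_poisson <- function(rate, duration, n_trains, seed = NULL) {
  if (rate < 0) stop("`rate` must be nonnegative")
  if (duration <= 0) stop("`duration` must be positive")
  if (!is.null(seed)) set.seed(seed)
  rate_ms <- rate / 1000
  trains <- replicate(n_trains, .rpoisson_train(rate_ms, duration),
                      simplify = FALSE)
  spike_train_set(trains, duration,
                  provenance = list(generator = "poisson", rate = rate,
                                    seed = seed))
}

#' Generate correlated spike trains via a Multiple Interaction Process
#'
#' A Poisson "mother" train is generated at rate `rate`; each of the
#' `n_trains` child trains keeps each mother spike independently with
#' probability `f` and adds an independent Poisson train at rate
#' `(1 - f) * rate`, so every child has expected rate `rate` and the pairwise
#' spike-count correlation coefficient is `c = f^2`. `f = 0` gives
#' uncorrelated Poisson trains, `f = 1` identical copies of the mother.
#'
#' @param rate target firing rate of each child train (events per second).
#' @param f per-spike copy probability in `[0, 1]`.
#' @inheritParams generate_poisson
#' @return a [spike_train_set()].
#' @export
generate_mip <- function(rate, f, duration, n_trains, seed = NULL) {
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]")
  if (rate < 0) stop("`rate` must be nonnegative")
  if (duration <= 0) stop("`duration` must be positive")
  if (!is.null(seed)) set.seed(seed)
  rate_ms <- rate / 1000
  mother <- .rpoisson_train(rate_ms, duration)
  trains <- replicate(n_trains, {
    kept <- mother[stats::runif(length(mother)) < f]
    if (f < 1) {
      extra <- .rpoisson_train((1 - f) * rate_ms, duration)
      sort(c(kept, extra))
    } else kept
  }, simplify = FALSE)
  spike_train_set(trains, duration,
                  provenance = list(generator = "mip", rate = rate, f = f,
                                    seed = seed))
}

#' Bin the population rate of a spike ensemble
#'
#' Counts spikes of all trains in bins of width `dt` and normalizes by `dt`,
#' yielding the population rate in spikes per ms. A trailing partial bin is
#' dropped.
#'
#' @param spikes a [spike_train_set()].
#' @param dt bin width (ms).
#' @param per_neuron_hz if `TRUE`, return the per-neuron rate in s^-1 instead
#'   of the summed population rate in spikes/ms.
#' @return numeric vector of length `floor(duration / dt)`.
#' @export
bin_population_rate <- function(spikes, dt, per_neuron_hz = FALSE) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (dt <= 0) stop("`dt` must be positive")
  nb <- floor(spikes$duration / dt + 1e-9)
  tt <- unlist(spikes$trains, use.names = FALSE)
  counts <- .bin_counts(tt, dt, nb)
  r <- counts / dt
  if (per_neuron_hz) r <- r / spikes$n_trains * 1000
  r
}

# bin spike times into nb bins of width dt (counts)
.bin_counts <- function(times, dt, nb) {
  if (!length(times)) return(numeric(nb))
  idx <- floor(times / dt) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  tabulate(idx, nbins = nb)
}

# binned count matrix [n_trains x nb]
.bin_count_matrix <- function(spikes, dt) {
  nb <- floor(spikes$duration / dt + 1e-9)
  t(vapply(spikes$trains, .bin_counts, numeric(nb), dt = dt, nb = nb))
}

#' Pairwise spike-count correlation of an ensemble
#'
#' Bins each train into counting windows of width `window` ms and averages the
#' Pearson correlation coefficient over all distinct pairs. For a multiple
#' interaction process the expected value is `f^2`, independent of the window.
#'
#' @param spikes a [spike_train_set()].
#' @param window counting-window width (ms), default 100.
#' @return list with `mean` (pair-averaged correlation), `se` (its standard
#'   error, from a delete-one-window jackknife — pairs share trains and, for
#'   correlated processes, a common source, so averaging over counting
#'   windows rather than pairs gives an honest uncertainty) and `n_pairs`.
#' @export
count_correlation <- function(spikes, window = 100) {
  stopifnot(inherits(spikes, "spike_train_set"))
  x <- .bin_count_matrix(spikes, window)
  n <- nrow(x); W <- ncol(x)
  if (n < 2L) stop("need at least two trains")
  keep <- apply(x, 1L, stats::sd) > 0
  if (sum(keep) < 2L) stop("fewer than two trains with nonconstant counts")
  x <- x[keep, , drop = FALSE]
  n <- nrow(x)
  S <- tcrossprod(x)                       # sum_w x_i x_j
  m <- rowSums(x)
  off <- upper.tri(S)
  pair_cor <- function(S, m, W) {
    cov <- (S - tcrossprod(m) / W) / W
    v <- pmax(diag(cov), 0)
    cm <- cov / sqrt(outer(v, v))
    vals <- cm[off]
    mean(vals[is.finite(vals)])
  }
  theta_full <- pair_cor(S, m, W)
  theta_w <- vapply(seq_len(W), function(w)
    pair_cor(S - tcrossprod(x[, w]), m - x[, w], W - 1L), numeric(1L))
  se <- sqrt((W - 1L) / W * sum((theta_w - mean(theta_w))^2))
  list(mean = theta_full, se = se, n_pairs = sum(off))
}

#' Write / read spike-train ensembles as delimited text
#'
#' Two-column text (`train_id`, `spike_time_ms`) with a commented metadata
#' header carrying duration, number of trains and provenance.
#'
#' @param spikes a [spike_train_set()].
#' @param path file path.
#' @return `write_spike_trains` returns `path` invisibly; `read_spike_trains`
#'   returns a [spike_train_set()].
#' @export
write_spike_trains <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  con <- file(path, "w")
  on.exit(close(con))
  prov <- spikes$provenance
  prov_str <- paste(names(prov), vapply(prov, function(v)
    paste(format(v), collapse = ","), character(1L)),
    sep = "=", collapse = "; ")
  writeLines(c(sprintf("# duration_ms=%.17g", spikes$duration),
               sprintf("# n_trains=%d", spikes$n_trains),
               sprintf("# provenance: %s", prov_str),
               "train_id\tspike_time_ms"), con)
  ids <- rep(seq_len(spikes$n_trains), lengths(spikes$trains))
  tt <- unlist(spikes$trains, use.names = FALSE)
  if (length(tt))
    writeLines(sprintf("%d\t%.17g", ids, tt), con)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  hdr <- readLines(path, n = 3L)
  duration <- as.numeric(sub("# duration_ms=", "", hdr[1L], fixed = TRUE))
  n_trains <- as.integer(sub("# n_trains=", "", hdr[2L], fixed = TRUE))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  trains <- vector("list", n_trains)
  if (nrow(df)) {
    sp <- split(df$spike_time_ms, factor(df$train_id, levels = seq_len(n_trains)))
    trains <- lapply(sp, as.numeric)
  } else {
    trains <- replicate(n_trains, numeric(0), simplify = FALSE)
  }
  spike_train_set(trains, duration,
                  provenance = list(generator = "file", path = path))
}
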