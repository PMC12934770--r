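# Streams whose binarized activity defines the N = 10 CLAW network state,
# most-significant bit first.
claw_state_streams <- function() {
  c("dSPN_L", "iSPN_L", "GPi_L", "GPeP_L", "Th_L",
    "dSPN_R", "iSPN_R", "GPi_R", "GPeP_R", "Th_R")
}

#' Bin a rate time series
#'
#' Averages a rate matrix within consecutive bins of width \code{delta_t}.
#' A trailing partial bin is dropped.
#'
#' @param rates matrix [time step x stream].
#' @param delta_t bin width in ms (default 10).
#' @param dt time step of \code{rates} in ms; must divide \code{delta_t}.
#' @return Matrix [bin x stream] of within-bin mean rates.
#' @export
bin_rates <- function(rates, delta_t = 10, dt = 1) {
  steps <- delta_t / dt
  if (abs(steps - round(steps)) > 1e-9)
    stop("delta_t must be a multiple of the time step dt")
  steps <- as.integer(round(steps))
  n_bins <- nrow(rates) %/% steps
  if (n_bins == 0L)
    return(matrix(numeric(0), 0L, ncol(rates),
                  dimnames = list(NULL, colnames(rates))))
  idx <- rep(seq_len(n_bins), each = steps)
  out <- apply(rates[seq_len(n_bins * steps), , drop = FALSE], 2,
               function(x) tapply(x, idx, mean))
  if (n_bins == 1L) out <- matrix(out, 1L, dimnames = list(NULL, colnames(rates)))
  out
}

# Freedman-Diaconis histogram counts on an exactly scale-equivariant grid
# (no "pretty" rounding, so doubling the data doubles every break).
fd_hist <- function(x) {
  n <- length(x)
  bw <- 2 * stats::IQR(x) / n^(1 / 3)
  if (bw <= 0) return(NULL)
  breaks <- seq(min(x), max(x) + bw, by = bw)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(counts = counts, mids = mids)
}

# running-mean smoothing of histogram counts; width scales with the number
# of bins so that noise wiggles inside a mode are not counted as modes
smooth_counts <- function(counts, width = NULL) {
  n <- length(counts)
  if (is.null(width)) width <- max(3L, round(n / 15))
  if (width %% 2L == 0L) width <- width + 1L
  half <- width %/% 2L
  padded <- c(rep(counts[1L], half), counts, rep(counts[n], half))
  stats::filter(padded, rep(1 / width, width))[(half + 1L):(half + n)]
}

# local maxima of a count vector (plateau-tolerant)
local_modes <- function(counts) {
  n <- length(counts)
  if (n == 1L) return(1L)
  left <- c(-Inf, counts[-n]); right <- c(counts[-1], -Inf)
  which(counts > left & counts >= right)
}

#' Derive binarization thresholds from pooled firing-rate samples
#'
#' For each state-defining stream, places the threshold at the
#' minimum-density antimode between the two largest modes of the
#' Freedman-Diaconis histogram of the pooled binned rates.  When the
#' histogram is unimodal the threshold falls back to
#' \code{median + 2 * MAD}; when all samples are identical the threshold is
#' that value and the stream is flagged degenerate.  Deterministic given the
#' samples.
#'
#' @param samples matrix [sample x stream] of binned rates pooled across
#'   trials; needs >= 1000 rows for stable histograms.
#' @param delta_t bin width (ms) recorded on the scheme.
#' @param min_samples minimum pooled sample count required per stream.
#' @return A \code{claw_scheme}: list with \code{delta_t},
#'   \code{thresholds} (named per stream), \code{degenerate} flags and the
#'   bit order (\code{state_streams}).
#' @export
compute_thresholds <- function(samples, delta_t = 10, min_samples = 1000) {
  if (is.null(dim(samples)) || nrow(samples) == 0L)
    stop("no samples supplied")
  if (nrow(samples) < min_samples)
    warning("fewer than ", min_samples, " pooled samples per stream")
  streams <- colnames(samples)
  if (is.null(streams)) stop("samples must have stream column names")
  thr <- numeric(length(streams)); names(thr) <- streams
  degen <- logical(length(streams)); names(degen) <- streams
  for (s in streams) {
    x <- samples[, s]
    x <- x[is.finite(x)]
    if (length(x) == 0L) stop("stream ", s, " has no finite samples")
    h <- fd_hist(x)
    if (is.null(h)) {            # zero IQR: (near-)constant samples
      thr[s] <- stats::median(x) + 2 * stats::mad(x)
      degen[s] <- TRUE
      next
    }
    sm <- as.numeric(smooth_counts(h$counts))
    modes <- local_modes(sm)
    modes <- modes[sm[modes] > 0]
    if (length(modes) >= 2L) {
      top2 <- sort(modes[order(sm[modes], decreasing = TRUE)][1:2])
      between <- seq(top2[1] + 1L, length.out = max(0L, top2[2] - top2[1] - 1L))
      if (length(between) > 0L) {
        anti <- between[which.min(sm[between])]
        thr[s] <- h$mids[anti]
        next
      }
    }
    thr[s] <- stats::median(x) + 2 * stats::mad(x)
  }
  structure(list(delta_t = delta_t, thresholds = thr, degenerate = degen,
                 state_streams = intersect(claw_state_streams(), streams)),
            class = "claw_scheme")
}

#' @export
print.claw_scheme <- function(x, ...) {
  cat(sprintf("CLAW binarization scheme (delta_t = %g ms, %d streams)\n",
              x$delta_t, length(x$thresholds)))
  print(round(x$thresholds, 2))
  invisible(x)
}

#' Binarize a binned rate matrix
#'
#' @param binned matrix [bin x stream].
#' @param scheme a \code{claw_scheme}; only its \code{state_streams} are
#'   used, in bit order.
#' @return Integer 0/1 matrix [bin x state stream].
#' @export
binarize_rates <- function(binned, scheme) {
  ss <- scheme$state_streams
  missing <- setdiff(ss, colnames(binned))
  if (length(missing) > 0L)
    stop("missing streams: ", paste(missing, collapse = ", "))
  out <- matrix(0L, nrow(binned), length(ss), dimnames = list(NULL, ss))
  for (s in ss) out[, s] <- as.integer(binned[, s] > scheme$thresholds[[s]])
  out
}
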