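# Element order of the 18-dimensional activity summary: channel sums (L+R)
# for the eight channelized cell types, channel differences (L-R) for the
# same types, then the two shared interneuron populations.
SUMMARY_TYPES <- c("Cx", "dSPN", "iSPN", "GPeP", "GPeA", "STN", "GPi", "Th")

summary_element_names <- function() {
  c(paste0(SUMMARY_TYPES, "_sum"), paste0(SUMMARY_TYPES, "_diff"),
    "CxI", "FSI")
}

#' Summarize CBGT activity into the 18-element CCA vector
#'
#' Computes, for a time window of a trial, the time-mean rate of every
#' stream and assembles channel sums (L+R) and channel differences (L-R)
#' for the eight channelized cell types plus the CxI and FSI rates.
#'
#' @param rates matrix [time x 18 streams] (canonical stream columns).
#' @param t_ms time axis of \code{rates} (ms relative to cue onset).
#' @param window \code{c(from, to)} in ms; defaults to the whole trace.
#' @return Named numeric vector of length 18 in the documented element
#'   order.
#' @export
summarize_activity <- function(rates, t_ms = NULL, window = NULL) {
  missing <- setdiff(stream_names(), colnames(rates))
  if (length(missing) > 0L)
    stop("missing streams: ", paste(missing, collapse = ", "))
  if (!is.null(window)) {
    if (is.null(t_ms)) stop("t_ms required when window is given")
    sel <- t_ms >= window[1] & t_ms <= window[2]
    if (!any(sel)) stop("window outside trial")
    rates <- rates[sel, , drop = FALSE]
  }
  m <- colMeans(rates)
  out <- c(m[paste0(SUMMARY_TYPES, "_L")] + m[paste0(SUMMARY_TYPES, "_R")],
           m[paste0(SUMMARY_TYPES, "_L")] - m[paste0(SUMMARY_TYPES, "_R")],
           m["CxI"], m["FSI"])
  names(out) <- summary_element_names()
  out
}

#' Per-network activity summary for ensemble identification
#'
#' The cross-network CCA uses one activity vector per network: the
#' trial-and-time mean of the 18-element summary over the decision period
#' (cue onset to decision) of decided trials.
#'
#' @param trials list of \code{cbgt_trial} from one network.
#' @return Named numeric vector of length 18.
#' @export
network_activity_summary <- function(trials) {
  rows <- lapply(trials, function(tr) {
    if (tr$choice == "none") return(NULL)
    summarize_activity(tr$rates, tr$t_ms, c(0, tr$decision_time))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) stop("no decided trials")
  colMeans(do.call(rbind, rows))
}

# symmetric inverse square root with ridge regularization
inv_sqrt <- function(S, ridge = 0) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- e$values + ridge
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' Identify control ensembles by canonical correlation analysis
#'
#' Finds the first three canonical components linking per-network CBGT
#' activity summaries to static drift-diffusion parameters.  Both matrices
#' are column-standardized internally; reported loadings are structure
#' correlations (correlation of each variable with its canonical variate).
#' Components are labelled by their loading signature: \emph{choice} is the
#' component dominated by channel-difference elements and drift rate v
#' (sign fixed so it correlates positively with leftward drift);
#' of the remaining two (sign fixed so their loading on onset time is
#' negative, i.e. engagement speeds onset), \emph{responsiveness} loads
#' negatively and \emph{pliancy} positively on boundary height a.
#'
#' @param activity matrix [networks x 18] (columns in summary element
#'   order).
#' @param ddm matrix [networks x 4] with columns \code{a}, \code{v},
#'   \code{tr}, \code{z}.
#' @param n_components number of components retained (default 3).
#' @param labels optional manual override, character vector of length
#'   \code{n_components}.
#' @return A \code{cca_loadings}: list with \code{U} [18 x 3] and \code{V}
#'   [4 x 3] structure-correlation loadings, canonical \code{cor},
#'   \code{labels}, and the standardization (\code{center_x},
#'   \code{scale_x}, \code{sd_W}) needed to project new data.
#' @export
fit_cca <- function(activity, ddm, n_components = 3L, labels = NULL) {
  stopifnot(nrow(activity) == nrow(ddm))
  if (nrow(activity) < 5L) stop("too few networks for CCA")
  if (nrow(activity) < 30L)
    warning("fewer than 30 networks; canonical correlations may be inflated")
  if (is.null(colnames(ddm))) colnames(ddm) <- c("a", "v", "tr", "z")
  if (is.null(colnames(activity))) colnames(activity) <- summary_element_names()

  sx <- apply(activity, 2, stats::sd); sy <- apply(ddm, 2, stats::sd)
  sx[sx == 0] <- 1; sy[sy == 0] <- 1
  X <- scale(activity, scale = sx); Y <- scale(ddm, scale = sy)
  n <- nrow(X)
  Sxx <- crossprod(X) / (n - 1); Syy <- crossprod(Y) / (n - 1)
  Sxy <- crossprod(X, Y) / (n - 1)
  tol <- 1e-10
  ridge <- 0
  if (min(eigen(Sxx, only.values = TRUE, symmetric = TRUE)$values) < tol ||
      min(eigen(Syy, only.values = TRUE, symmetric = TRUE)$values) < tol) {
    ridge <- 1e-8
    warning("rank-deficient input; using regularized CCA solve")
  }
  Kx <- inv_sqrt(Sxx, ridge); Ky <- inv_sqrt(Syy, ridge)
  M <- Kx %*% Sxy %*% Ky
  sv <- svd(M)
  k <- min(n_components, length(sv$d))
  A <- Kx %*% sv$u[, seq_len(k), drop = FALSE]  # canonical weights (X)
  B <- Ky %*% sv$v[, seq_len(k), drop = FALSE]  # canonical weights (Y)
  Wx <- X %*% A; Wy <- Y %*% B                  # canonical variates
  U <- stats::cor(X, Wx)                        # structure correlations
  V <- stats::cor(Y, Wy)
  rownames(U) <- colnames(activity); rownames(V) <- colnames(ddm)

  # --- label components by loading signature ---
  diff_idx <- grepl("_diff$", rownames(U))
  diff_dom <- colSums(abs(U[diff_idx, , drop = FALSE])) -
              colSums(abs(U[grepl("_sum$", rownames(U)), , drop = FALSE]))
  v_load <- abs(V["v", ])
  i_choice <- which.max(rank(diff_dom) + rank(v_load))
  rest <- setdiff(seq_len(k), i_choice)
  # sign conventions
  if (V["v", i_choice] < 0) {
    A[, i_choice] <- -A[, i_choice]; U[, i_choice] <- -U[, i_choice]
    V[, i_choice] <- -V[, i_choice]; Wx[, i_choice] <- -Wx[, i_choice]
  }
  for (j in rest) {
    if (V["tr", j] > 0) {
      A[, j] <- -A[, j]; U[, j] <- -U[, j]
      V[, j] <- -V[, j]; Wx[, j] <- -Wx[, j]
    }
  }
  lab <- character(k)
  lab[i_choice] <- "choice"
  if (length(rest) == 2L) {
    # responsiveness lowers the boundary when engaged; pliancy raises it
    i_resp <- rest[which.min(V["a", rest])]
    i_pli <- setdiff(rest, i_resp)
    lab[i_resp] <- "responsiveness"; lab[i_pli] <- "pliancy"
  } else lab[rest] <- paste0("component", rest)
  if (!is.null(labels)) lab <- labels
  colnames(U) <- lab; colnames(V) <- lab

  structure(list(U = U, V = V, cor = sv$d[seq_len(k)], labels = lab,
                 weights_x = A, center_x = attr(X, "scaled:center"),
                 scale_x = sx, scale_y = stats::setNames(sy, colnames(ddm)),
                 sd_W = apply(Wx, 2, stats::sd)),
            class = "cca_loadings")
}

#' @export
print.cca_loadings <- function(x, ...) {
  cat("Control-ensemble CCA loadings\n")
  cat("  canonical correlations:",
      paste(round(x$cor, 3), collapse = ", "), "\n")
  cat("  components:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Project a trial onto the control ensembles over time
#'
#' Converts a trial's binned rates into the within-trial time course of
#' ensemble engagement \eqn{W_k = \Delta F_k^T U} and its image in DDM
#' parameter space \eqn{P_k = W_k V^T}, where \eqn{\Delta F_k} is the
#' change of the 18-element activity summary from the cue-onset bin
#' (standardized with the scales used when fitting).  \eqn{\Delta F_0 = 0}
#' by construction.  Engagement is reported as percent of the cross-network
#' standard deviation of the corresponding canonical variate.
#'
#' @param trial a \code{cbgt_trial}.
#' @param loadings a \code{cca_loadings}.
#' @param delta_t bin width (ms).
#' @return An \code{ensemble_timecourse}: list with \code{time} (bin-end
#'   times, ms after onset), \code{W} [bins x 3] percent engagement,
#'   \code{P} [bins x 4] projected DDM-parameter change, and
#'   \code{decision_time}.
#' @export
project_timecourse <- function(trial, loadings, delta_t = 10) {
  dt <- diff(trial$t_ms[1:2])
  upto <- if (is.na(trial$decision_time)) max(trial$t_ms)
          else trial$decision_time
  sel <- trial$t_ms > 0 & trial$t_ms <= upto
  rates <- trial$rates[sel, , drop = FALSE]
  binned <- bin_rates(rates, delta_t, dt)
  n_bins <- nrow(binned)
  if (n_bins == 0L) stop("trial shorter than one bin")
  S <- t(vapply(seq_len(n_bins), function(k) {
    i0 <- (k - 1L) * (delta_t / dt) + 1L
    summarize_activity(rates[i0:(i0 + delta_t / dt - 1L), , drop = FALSE])
  }, numeric(18L)))
  ref <- S[1L, ]
  dF <- sweep(S, 2, ref) / rep(loadings$scale_x, each = n_bins)
  W <- dF %*% loadings$U
  P <- W %*% t(loadings$V)
  W_pct <- 100 * sweep(W, 2, loadings$sd_W, "/")
  structure(list(time = seq_len(n_bins) * delta_t, W = W_pct, P = P,
                 decision_time = trial$decision_time),
            class = "ensemble_timecourse")
}

#' Average ensemble time courses across trials under an alignment
#'
#' Averages per-trial engagement traces aligned either to cue onset
#' (restricted to the launching window, first 50 ms) or to decision time
#' (restricted to the committed window, final 30 ms); the variable-duration
#' intermediate period is omitted.  Trials shorter than the window are
#' excluded with a notice.
#'
#' @param timecourses list of \code{ensemble_timecourse}.
#' @param alignment \code{"cue_onset"} or \code{"decision"}.
#' @param window_ms window length (ms): 50 for launching, 30 for committed.
#' @param what \code{"W"} (ensembles) or \code{"P"} (DDM parameters).
#' @return Data frame with \code{time} (ms from the alignment point),
#'   \code{component}, \code{mean}, \code{ci_lo}, \code{ci_hi}, \code{n}.
#' @export
average_aligned <- function(timecourses, alignment = c("cue_onset", "decision"),
                            window_ms = if (alignment[1] == "cue_onset") 50 else 30,
                            what = c("W", "P")) {
  alignment <- match.arg(alignment)
  what <- match.arg(what)
  delta_t <- timecourses[[1L]]$time[1L]
  n_bins <- as.integer(window_ms / delta_t)
  keep <- vapply(timecourses, function(tc) nrow(tc$W) >= n_bins, TRUE)
  if (any(!keep))
    message(sum(!keep), " trial(s) shorter than the window were excluded")
  tcs <- timecourses[keep]
  if (length(tcs) == 0L) stop("no trials long enough for the window")
  comp <- colnames(if (what == "W") tcs[[1L]]$W else tcs[[1L]]$P)
  slices <- lapply(tcs, function(tc) {
    M <- if (what == "W") tc$W else tc$P
    if (alignment == "cue_onset") M[seq_len(n_bins), , drop = FALSE]
    else M[(nrow(M) - n_bins + 1L):nrow(M), , drop = FALSE]
  })
  arr <- simplify2array(slices)          # bins x comp x trials
  mu <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(length(tcs))
  time <- if (alignment == "cue_onset") seq_len(n_bins) * delta_t
          else (seq_len(n_bins) - n_bins) * delta_t
  out <- expand.grid(time = time, component = comp,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean <- as.vector(mu)
  out$ci_lo <- as.vector(mu - 1.96 * se)
  out$ci_hi <- as.vector(mu + 1.96 * se)
  out$n <- length(tcs)
  out
}

#' Relative contributions of responsiveness and pliancy to boundary height
#'
#' At each time bin, each ensemble's contribution to boundary height is its
#' engagement multiplied by its loading on \code{a}; the two magnitudes are
#' normalized to proportions.  Returns the responsiveness proportion (the
#' complement is pliancy).  Bins where both contributions vanish are
#' \code{NA}.
#'
#' @param W matrix [bins x components] of ensemble engagement with labelled
#'   columns.
#' @param loadings a \code{cca_loadings}.
#' @return Numeric vector of responsiveness fractions in [0, 1] per bin.
#' @export
boundary_contributions <- function(W, loadings) {
  if (!all(c("responsiveness", "pliancy") %in% colnames(W)))
    stop("responsiveness and pliancy components must be labelled")
  c_resp <- abs(W[, "responsiveness"] * loadings$V["a", "responsiveness"])
  c_pli <- abs(W[, "pliancy"] * loadings$V["a", "pliancy"])
  tot <- c_resp + c_pli
  out <- c_resp / tot
  out[tot == 0] <- NA_real_
  out
}
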