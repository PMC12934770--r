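#' Wiener first-passage-time density
#'
#' Density of the first passage time through the upper or lower decision
#' boundary for a drift-diffusion process with symmetric boundaries
#' \eqn{\pm a}, drift \eqn{v}, diffusion \eqn{\sigma = 1}, non-decision
#' (onset) time \eqn{tr} and starting point \eqn{a(-1 + 2z)}.  Computed
#' with the standard small-time / large-time series expansions, choosing
#' per time point the representation that needs fewer terms for an
#' absolute truncation error below \code{eps}.
#'
#' @param t time(s) in seconds (density is 0 for \code{t <= tr}).
#' @param a boundary height (evidence units), > 0.
#' @param v drift rate (evidence/s).
#' @param tr onset time (s).
#' @param z starting bias in (0, 1); 0.5 is unbiased.
#' @param bound \code{"upper"} or \code{"lower"}.
#' @param eps absolute series truncation error.
#' @return Vector of densities (1/s).
#' @export
wfpt_density <- function(t, a, v, tr, z, bound = c("upper", "lower"),
                         eps = 1e-8) {
  bound <- match.arg(bound)
  stopifnot(a > 0, z > 0, z < 1, tr >= 0)
  # map to a standard Wiener process with separation alpha = 2a, relative
  # start w measured from the lower bound; the upper-bound density is the
  # lower-bound density of the sign-flipped process
  alpha <- 2 * a
  if (bound == "lower") { w <- z; drift <- v }
  else { w <- 1 - z; drift <- -v }
  out <- numeric(length(t))
  tt <- t - tr
  ok <- tt > 0
  if (!any(ok)) return(out)
  ts <- tt[ok] / alpha^2                      # normalized time
  f_star <- vapply(ts, wfpt_f_star, numeric(1), w = w, eps = eps)
  out[ok] <- f_star / alpha^2 *
    exp(-drift * alpha * w - drift^2 * tt[ok] / 2)
  out
}

# density of the normalized process (unit separation, zero drift, start w)
wfpt_f_star <- function(ts, w, eps = 1e-8) {
  # number of terms needed (Navarro & Fuss 2009 bounds)
  K_small <- if (2 * sqrt(2 * pi * ts) * eps < 1) {
    ceiling(2 + sqrt(-2 * ts * log(2 * sqrt(2 * pi * ts) * eps)))
  } else 2
  K_small <- max(K_small, ceiling(sqrt(ts)) + 1)
  K_large <- if (pi * ts * eps < 1) {
    ceiling(max(sqrt(-2 * log(pi * ts * eps) / (pi^2 * ts)), 1 / (pi * sqrt(ts))))
  } else ceiling(1 / (pi * sqrt(ts)))
  if (K_small <= K_large) {
    k <- -floor((K_small - 1) / 2):ceiling((K_small - 1) / 2)
    sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * ts))) / sqrt(2 * pi * ts^3)
  } else {
    k <- seq_len(ceiling(K_large))
    pi * sum(k * exp(-k^2 * pi^2 * ts / 2) * sin(k * pi * w))
  }
}

# joint log-likelihood of (choice, rt) pairs; upper bound = left choice
wfpt_loglik <- function(par, rt, upper) {
  a <- par[1]; v <- par[2]; tr <- par[3]; z <- par[4]
  if (a <= 0 || z <= 0 || z >= 1 || tr < 0) return(-Inf)
  d <- numeric(length(rt))
  if (any(upper))
    d[upper] <- wfpt_density(rt[upper], a, v, tr, z, "upper")
  if (any(!upper))
    d[!upper] <- wfpt_density(rt[!upper], a, v, tr, z, "lower")
  d[!is.finite(d)] <- 0
  # floor instead of -Inf so box-constrained optimizers see finite values
  sum(log(pmax(d, 1e-300)))
}

#' Fit the static drift-diffusion model by maximum likelihood
#'
#' Fits the four static DDM parameters (boundary height a, drift rate v,
#' onset time tr, starting bias z; diffusion fixed at 1) to choices and
#' response times by bounded multistart optimization (L-BFGS-B, 5 starts
#' with fixed seeds).  The upper boundary is the left choice.
#'
#' @param choice character vector of \code{"L"} / \code{"R"}.
#' @param rt response times in seconds (decision time, plus consolidation
#'   when the response-time convention includes it).
#' @param n_starts number of optimizer starts.
#' @param seed seed for the start draws.
#' @return A \code{ddm_fit}: list with \code{par} (named a, v, tr, z),
#'   \code{loglik}, \code{n}, \code{convergence} and \code{boundary_flag}
#'   (TRUE when a parameter sits at its box bound).
#' @export
fit_static <- function(choice, rt, n_starts = 5L, seed = 1L) {
  keep <- choice %in% c("L", "R") & is.finite(rt)
  choice <- choice[keep]; rt <- rt[keep]
  n <- length(rt)
  if (n < 10L) stop("too few decided trials to fit")
  upper <- choice == "L"
  lo <- c(a = 0.1, v = -8, tr = 1e-4, z = 0.05)
  hi <- c(a = 5, v = 8, tr = max(min(rt) - 1e-4, 2e-4), z = 0.95)
  set.seed(as.integer(seed))
  starts <- list(c(a = 1, v = 2 * (mean(upper) - 0.5), tr = 0.5 * min(rt),
                   z = 0.5))
  for (i in seq_len(n_starts - 1L)) {
    starts[[i + 1L]] <- c(a = stats::runif(1, 0.3, 2.5),
                          v = stats::runif(1, -3, 3),
                          tr = stats::runif(1, 0.2, 0.9) * min(rt),
                          z = stats::runif(1, 0.3, 0.7))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lo + 1e-6), hi - 1e-6),
                   function(p) -wfpt_loglik(p, rt, upper),
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("static DDM fit failed to converge from any start")
  par <- best$par; names(par) <- c("a", "v", "tr", "z")
  at_bound <- any(abs(par - lo) < 1e-6) || any(abs(par - hi) < 1e-6)
  structure(list(par = par, loglik = -best$value, n = n,
                 convergence = best$convergence,
                 boundary_flag = at_bound, sigma = 1),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Static DDM fit (sigma = 1, upper = left)\n")
  print(round(x$par, 4))
  cat(sprintf("  log-likelihood %.2f on %d trials%s\n", x$loglik, x$n,
              if (x$boundary_flag) " [parameter at bound]" else ""))
  invisible(x)
}
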