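#' Phase schedule of a zone-constrained piecewise DDM
#'
#' Describes how a decision trajectory passes through 2 or 3 CLAW zones:
#' the mean dwell time in each zone and the percent change of boundary
#' height and drift rate at each zone transition.
#'
#' @param zones character vector of zone labels (length 2 or 3; length 1
#'   gives the degenerate single-phase, i.e. static, schedule).
#' @param dwell mean dwell times per zone (ms); their sum is the mean
#'   decision time DT.
#' @param pct_a,pct_v percent changes (e.g. 10 for -10\%... positive values
#'   mean a \emph{decrease} of x\%, matching the chain relation
#'   \eqn{a_{i+1} = (1 - 0.01 x) a_i}); length \code{length(zones) - 1}.
#' @return A \code{phase_schedule}.
#' @export
phase_schedule <- function(zones, dwell, pct_a, pct_v) {
  stopifnot(length(zones) %in% c(1L, 2L, 3L), length(dwell) == length(zones),
            all(dwell > 0),
            length(pct_a) == length(zones) - 1L,
            length(pct_v) == length(zones) - 1L,
            all(pct_a < 100), all(pct_v < 100))
  structure(list(zones = zones, dwell = dwell, DT = sum(dwell),
                 pct_a = pct_a, pct_v = pct_v),
            class = "phase_schedule")
}

#' Solve for per-phase DDM parameters under the time-weighted constraint
#'
#' Given percent changes of boundary height (and drift rate) at each zone
#' transition, finds the per-phase values whose time-weighted average over
#' the decision period equals the static fit:
#' \deqn{\frac{t_1}{DT} a_1 + \frac{t_2}{DT} a_2 + \frac{t_3}{DT} a_3 =
#'   a_{static}, \quad a_2 = (1 - 0.01x) a_1, \quad a_3 = (1 - 0.01y) a_2.}
#' The same algebra applies to the drift rate.  With all percent changes
#' zero every phase equals the static value.
#'
#' @param schedule a \code{phase_schedule}.
#' @param static a \code{ddm_fit} (or list with \code{par}).
#' @return A \code{dynamic_params}: list with vectors \code{a} and
#'   \code{v} (one value per phase), the schedule and the static fit.
#' @export
solve_phase_params <- function(schedule, static) {
  w <- schedule$dwell / schedule$DT
  solve_one <- function(x0, pct) {
    mult <- cumprod(c(1, 1 - 0.01 * pct))
    denom <- sum(w * mult)
    if (denom <= 0) stop("infeasible schedule: non-positive denominator")
    x1 <- x0 / denom
    x1 * mult
  }
  a <- solve_one(static$par[["a"]], schedule$pct_a)
  if (any(a <= 0)) stop("infeasible schedule: non-positive boundary")
  v <- solve_one(static$par[["v"]], schedule$pct_v)
  structure(list(a = unname(a), v = unname(v), schedule = schedule,
                 static = static),
            class = "dynamic_params")
}

#' @export
print.dynamic_params <- function(x, ...) {
  cat("Piecewise DDM parameters (per phase)\n")
  print(data.frame(zone = x$schedule$zones, dwell_ms = x$schedule$dwell,
                   a = round(x$a, 4), v = round(x$v, 4)))
  invisible(x)
}

#' Percent parameter changes implied by zone-to-zone activity changes
#'
#' Projects the change of the 18-element activity summary between
#' consecutive zones of a path through the control-ensemble loadings
#' (\eqn{\Delta F^T U} then \eqn{V^T}) into DDM-parameter space, and
#' expresses each projected change as a percent of the static fitted value
#' of that parameter (positive = decrease, matching the chain-relation
#' convention).
#'
#' @param zone_summaries matrix [zones x 18] of zone-mean activity
#'   summaries along the path, in summary element order.
#' @param loadings a \code{cca_loadings} fitted with
#'   \code{\link{fit_cca}}.
#' @param static a \code{ddm_fit}.
#' @return List with \code{pct_a} and \code{pct_v}, each of length
#'   \code{nrow(zone_summaries) - 1}.
#' @export
derive_percent_changes <- function(zone_summaries, loadings, static) {
  if (nrow(zone_summaries) < 2L) stop("need at least two zones on the path")
  if (is.null(loadings$scale_y))
    stop("loadings must carry the DDM standardization (refit with fit_cca)")
  dF <- diff(zone_summaries) / rep(loadings$scale_x,
                                   each = nrow(zone_summaries) - 1L)
  W <- dF %*% loadings$U
  P <- W %*% t(loadings$V)          # standardized DDM units
  dpar <- sweep(P, 2, loadings$scale_y[colnames(P)], "*")
  pct_of <- function(param) {
    ref <- static$par[[param]]
    if (abs(ref) < 1e-12)
      stop("static ", param, " is (near) zero; percent change undefined")
    # positive percent = decrease of the parameter across the transition
    as.numeric(-100 * dpar[, param] / abs(ref))
  }
  list(pct_a = pct_of("a"), pct_v = pct_of("v"))
}

#' Simulate the zone-constrained piecewise DDM
#'
#' Simulates evidence paths \eqn{d\theta_t = v_i dt + \sigma dW_t}
#' (Euler-Maruyama, 1 ms step, \eqn{\sigma = 1}) whose drift and symmetric
#' boundaries \eqn{\pm a_i} switch at stochastic phase-transition times.
#' Each path's zone-index sequence is drawn per 10 ms slot from the
#' categorical distribution weighted by relative dwell times; the phase
#' boundaries implied by that sequence are the transition times.  Paths
#' held at \eqn{\theta = a_{static}(-1 + 2 z_{static})} until
#' \eqn{tr_{static}}.  A path crossing its boundary before its sampled
#' transition into the next phase is discarded; at a transition, a path
#' with \eqn{|\theta|} between the new and old boundary registers an
#' immediate boundary-collapse decision; in the final phase a boundary
#' crossing is a decision.
#'
#' @param params a \code{dynamic_params} from
#'   \code{\link{solve_phase_params}}.
#' @param n_paths number of simulated paths.
#' @param seed integer seed.
#' @param max_time_factor simulation horizon for the final phase, as a
#'   multiple of the mean decision time.
#' @return A \code{ddm_sim}: list with \code{outcome}
#'   (\code{upper}/\code{lower}/\code{discarded} per path), \code{rt}
#'   (decision times in seconds, \code{NA} for discarded), \code{collapse}
#'   (logical; decision registered at a boundary collapse), and
#'   \code{discard_rate}.
#' @export
simulate_dynamic <- function(params, n_paths = 1000L, seed = 1L,
                             max_time_factor = 10) {
  stopifnot(n_paths >= 1L)
  set.seed(as.integer(seed))
  sched <- params$schedule
  n_ph <- length(params$a)
  static <- params$static$par
  dt_ms <- 1; dt_s <- dt_ms / 1000
  slot_ms <- 10

  # per-path transition times from the sampled zone-index sequence
  n_slots <- max(1L, round(sched$DT / slot_ms))
  p <- sched$dwell / sched$DT
  counts <- stats::rmultinom(n_paths, n_slots, p)   # zones x paths
  trans_ms <- apply(counts, 2, function(cc) cumsum(cc) * slot_ms)
  trans_ms <- matrix(trans_ms, nrow = n_ph)         # cumulative, per path

  # a crossing in phase i is a decision (not a discard) when no later
  # phase changes the parameters: a no-op transition cannot contradict the
  # inferred dynamics
  if (n_ph > 1L) {
    noop <- vapply(seq_len(n_ph - 1L), function(i)
      isTRUE(all.equal(params$a[i + 1L], params$a[i])) &&
      isTRUE(all.equal(params$v[i + 1L], params$v[i])), TRUE)
    eff_final <- vapply(seq_len(n_ph), function(i)
      i == n_ph || all(noop[i:(n_ph - 1L)]), TRUE)
  } else eff_final <- TRUE

  theta <- rep(static[["a"]] * (-1 + 2 * static[["z"]]), n_paths)
  phase <- rep(1L, n_paths)
  outcome <- rep(NA_character_, n_paths)
  rt <- rep(NA_real_, n_paths)
  collapse <- rep(FALSE, n_paths)
  t_max_ms <- sched$DT * max_time_factor
  active <- rep(TRUE, n_paths)
  t_ms <- 0

  while (any(active) && t_ms < t_max_ms) {
    t_ms <- t_ms + dt_ms
    idx <- which(active)
    theta[idx] <- theta[idx] + params$v[phase[idx]] * dt_s +
      sqrt(dt_s) * stats::rnorm(length(idx))
    a_now <- params$a[phase[idx]]
    hit <- abs(theta[idx]) >= a_now
    last <- eff_final[phase[idx]]
    # crossing in the final phase: decision; earlier: discard
    dec <- idx[hit & last]
    if (length(dec) > 0L) {
      outcome[dec] <- ifelse(theta[dec] > 0, "upper", "lower")
      rt[dec] <- static[["tr"]] + t_ms / 1000
      active[dec] <- FALSE
    }
    dis <- idx[hit & !last]
    if (length(dis) > 0L) {
      outcome[dis] <- "discarded"
      active[dis] <- FALSE
    }
    # phase transitions for still-active paths
    idx <- which(active)
    if (length(idx) > 0L) {
      moving <- idx[phase[idx] < n_ph &
                    t_ms >= trans_ms[cbind(phase[idx], idx)]]
      if (length(moving) > 0L) {
        new_phase <- phase[moving] + 1L
        a_new <- params$a[new_phase]
        caught <- abs(theta[moving]) >= a_new
        if (any(caught)) {
          # immediate boundary collapse counts as a decision
          cid <- moving[caught]
          outcome[cid] <- ifelse(theta[cid] > 0, "upper", "lower")
          rt[cid] <- static[["tr"]] + t_ms / 1000
          collapse[cid] <- TRUE
          active[cid] <- FALSE
        }
        keep <- moving[!caught]
        phase[keep] <- new_phase[!caught]
      }
    }
  }
  outcome[is.na(outcome)] <- "discarded"
  structure(list(outcome = outcome, rt = rt, collapse = collapse,
                 discard_rate = mean(outcome == "discarded"),
                 params = params),
            class = "ddm_sim")
}

#' @export
print.ddm_sim <- function(x, ...) {
  cat(sprintf(
    "Piecewise DDM simulation: %d paths, %.1f%% discarded, P(upper) = %.3f\n",
    length(x$outcome), 100 * x$discard_rate,
    mean(x$outcome[x$outcome != "discarded"] == "upper")))
  invisible(x)
}

#' Simulate the static DDM (single-phase reference)
#'
#' @param static a \code{ddm_fit}.
#' @param n_paths,seed as in \code{\link{simulate_dynamic}}.
#' @param horizon_s simulation horizon in seconds.
#' @return A \code{ddm_sim} (discards are paths that never cross within
#'   the horizon).
#' @export
simulate_static <- function(static, n_paths = 1000L, seed = 1L,
                            horizon_s = 10) {
  sched <- phase_schedule("static", 1000, pct_a = numeric(0),
                          pct_v = numeric(0))
  params <- solve_phase_params(sched, static)
  simulate_dynamic(params, n_paths, seed,
                   max_time_factor = horizon_s * 1000 / sched$DT)
}

#' Compare static and dynamic DDM accounts of the same trials
#'
#' Evaluates both models on observed (choice, response-time) data: the
#' static likelihood analytically via the Wiener first-passage density,
#' the dynamic likelihood by simulation (kernel density of simulated
#' response times per boundary with Silverman's bandwidth, weighted by
#' outcome probabilities).  Reports BIC for both (k = 4 static;
#' k = 4 + 2 (phases - 1) dynamic) and each model's deviation from the
#' observed mean response time.
#'
#' @param static a \code{ddm_fit}.
#' @param dynamic a \code{dynamic_params}.
#' @param choice,rt observed choices (\code{"L"} = upper) and response
#'   times (s).
#' @param n_paths simulated paths for the dynamic likelihood.
#' @param seed integer seed.
#' @return A list with \code{bic_static}, \code{bic_dynamic},
#'   \code{delta_bic} (dynamic - static), log-likelihoods, and mean-RT
#'   errors \code{rt_err_static}, \code{rt_err_dynamic}.
#' @export
compare_models <- function(static, dynamic, choice, rt,
                           n_paths = 1e5, seed = 1L) {
  keep <- choice %in% c("L", "R") & is.finite(rt)
  choice <- choice[keep]; rt <- rt[keep]
  n <- length(rt)
  if (n == 0L) stop("no decided trials supplied")
  upper <- choice == "L"

  ll_static <- wfpt_loglik(static$par, rt, upper)
  sim <- simulate_dynamic(dynamic, n_paths = n_paths, seed = seed)
  ok <- sim$outcome != "discarded"
  if (!any(ok)) stop("dynamic model discarded every path")
  p_up <- mean(sim$outcome[ok] == "upper")
  eps <- 1e-12
  dens_of <- function(side_rt, eval_at, w) {
    if (length(side_rt) < 5L) return(rep(eps, length(eval_at)))
    d <- stats::density(side_rt, bw = "nrd0")
    w * pmax(stats::approx(d$x, d$y, xout = eval_at, rule = 2)$y, eps)
  }
  f_up <- dens_of(sim$rt[ok & sim$outcome == "upper"], rt, p_up)
  f_lo <- dens_of(sim$rt[ok & sim$outcome == "lower"], rt, 1 - p_up)
  ll_dynamic <- sum(log(ifelse(upper, f_up, f_lo) + eps))

  n_ph <- length(dynamic$a)
  k_s <- 4; k_d <- 4 + 2 * (n_ph - 1)
  bic_s <- k_s * log(n) - 2 * ll_static
  bic_d <- k_d * log(n) - 2 * ll_dynamic
  sim_s <- simulate_static(static, n_paths = min(n_paths, 2e4),
                           seed = seed + 1L)
  list(bic_static = bic_s, bic_dynamic = bic_d,
       delta_bic = bic_d - bic_s,
       loglik_static = ll_static, loglik_dynamic = ll_dynamic,
       rt_err_static = abs(mean(sim_s$rt, na.rm = TRUE) - mean(rt)),
       rt_err_dynamic = abs(mean(sim$rt, na.rm = TRUE) - mean(rt)),
       discard_rate = sim$discard_rate)
}
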