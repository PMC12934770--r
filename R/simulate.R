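#' Simulate a single two-choice trial
#'
#' Integrates the stochastic firing-rate dynamics
#' \deqn{\tau_p \, dr_p = \left(-r_p + \phi\left(\sum_q w_{q\to p} r_q + I_p
#'   + \xi_p\right)\right) dt}
#' with rectifying gain \eqn{\phi(x) = \max(0, x)} and Ornstein-Uhlenbeck
#' noise \eqn{\xi_p}, by Euler-Maruyama at the configured step.  The trial
#' starts from the baseline equilibrium, a constant stimulus is applied
#' equally to Cx-L and Cx-R from cue onset (t = 0), and an action is selected
#' when the instantaneous thalamic rate of one channel first reaches the
#' decision threshold (30 Hz by default).  The post-decision consolidation
#' interval is drawn from a normal distribution (mean 250 ms, SD 1.5 ms).
#'
#' @param config a \code{cbgt_config}.
#' @param learning optional \code{cbgt_learning} state whose corticostriatal
#'   weights override the configured ones.
#' @param seed optional integer seed; if \code{NULL} the current RNG stream
#'   is used (as \code{\link{run_session}} does).
#' @param learning_stage integer tag stored on the record (training trials
#'   completed; 0 before learning).
#' @return A \code{cbgt_trial}: list with \code{rates} (matrix time x 18
#'   streams, Hz), \code{t_ms} (times relative to cue onset; a short
#'   pre-onset segment is kept), \code{choice} (\code{"L"}, \code{"R"} or
#'   \code{"none"}), \code{decision_time} (ms from onset; \code{NA} when no
#'   threshold crossing occurred), \code{consolidation_time} and
#'   \code{learning_stage}.
#' @export
simulate_trial <- function(config, learning = NULL, seed = NULL,
                           learning_stage = 0L) {
  validate_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sn <- stream_names()
  W <- expand_weights(config$edges)
  if (!is.null(learning)) {
    W["dSPN_L", "Cx_L"] <- learning$w[["dSPN_L"]]
    W["dSPN_R", "Cx_R"] <- learning$w[["dSPN_R"]]
    W["iSPN_L", "Cx_L"] <- learning$w[["iSPN_L"]]
    W["iSPN_R", "Cx_R"] <- learning$w[["iSPN_R"]]
  }
  # baseline input keeps the configured baseline rates as the pre-stimulus
  # equilibrium of the (possibly learned) network
  I0 <- as.numeric(config$baseline_rate - W %*% config$baseline_rate)

  dt <- config$dt
  n_pre <- round(config$baseline_duration / dt)
  n_max <- round(config$max_duration / dt)
  n_post <- round((config$post_record %||% 10) / dt)
  n_tot <- n_pre + n_max + n_post
  i_rec0 <- n_pre - round(config$record_pre / dt) + 1L
  i_th_L <- match("Th_L", sn); i_th_R <- match("Th_R", sn)
  i_cx <- match(c("Cx_L", "Cx_R"), sn)

  tau <- config$tau
  sd_ou <- config$noise_sd
  tau_n <- config$noise_tau
  ou_a <- 1 - dt / tau_n
  ou_b <- sd_ou * sqrt(2 * dt / tau_n)
  z <- matrix(stats::rnorm(18L * n_tot), 18L, n_tot)

  r <- as.numeric(config$baseline_rate)
  xi <- stats::rnorm(18L) * sd_ou  # stationary start
  rec <- matrix(NA_real_, n_tot - i_rec0 + 1L, 18L,
                dimnames = list(NULL, sn))
  choice <- "none"; dec_step <- NA_integer_
  stop_step <- n_pre + n_max
  stim <- numeric(18L)

  for (k in seq_len(n_tot)) {
    if (k > stop_step) break
    if (k == n_pre + 1L) stim[i_cx] <- config$stim_amp
    drive <- pmax(0, as.numeric(W %*% r) + I0 + stim + xi)
    r <- r + (drive - r) * (dt / tau)
    xi <- ou_a * xi + ou_b * z[, k]
    if (anyNA(r) || any(!is.finite(r)))
      stop("numerical instability in stream ",
           sn[which(!is.finite(r))[1L]])
    if (k >= i_rec0) rec[k - i_rec0 + 1L, ] <- r
    if (k > n_pre && is.na(dec_step)) {
      hit_L <- r[i_th_L] >= config$threshold
      hit_R <- r[i_th_R] >= config$threshold
      if (hit_L || hit_R) {
        choice <- if (hit_L && hit_R) {
          if (r[i_th_L] > r[i_th_R]) "L"
          else if (r[i_th_R] > r[i_th_L]) "R"
          else sample(c("L", "R"), 1L)
        } else if (hit_L) "L" else "R"
        dec_step <- k - n_pre
        # keep integrating briefly so the decision bin is complete
        stop_step <- k + n_post
      }
    }
  }

  n_rec <- (if (is.na(dec_step)) n_pre + n_max
            else min(n_pre + dec_step + n_post, n_tot)) - i_rec0 + 1L
  rec <- rec[seq_len(n_rec), , drop = FALSE]
  t_ms <- (seq(i_rec0, length.out = n_rec) - n_pre - 1L) * dt + dt
  structure(list(
    rates = rec,
    t_ms = t_ms,
    choice = choice,
    decision_time = if (is.na(dec_step)) NA_real_ else dec_step * dt,
    consolidation_time = stats::rnorm(1, config$consolidation_mean,
                                      config$consolidation_sd),
    learning_stage = as.integer(learning_stage)
  ), class = "cbgt_trial")
}

#' @export
print.cbgt_trial <- function(x, ...) {
  cat(sprintf("CBGT trial: choice %s, DT %s ms, stage %d, %d x %d rate bins\n",
              x$choice,
              if (is.na(x$decision_time)) "NA" else format(x$decision_time),
              x$learning_stage, nrow(x$rates), ncol(x$rates)))
  invisible(x)
}

#' Session plan for a learning experiment
#'
#' A session is \code{n_pre} baseline trials with plasticity off, then
#' \code{n_train} training trials with dopamine-dependent plasticity on and
#' rewards drawn from \code{reward_rule}, then \code{n_post} trials with the
#' trained weights frozen.
#'
#' @param n_pre,n_train,n_post block sizes (defaults 50 / 30 / 50; the study
#'   design uses \code{n_train} in \{1, 3, 8, 15, 30\}).
#' @param reward_rule named probability vector \code{c(L=, R=)}; the default
#'   rewards left deterministically.
#' @param seed integer seed governing the entire session.
#' @return A \code{cbgt_plan}.
#' @export
session_plan <- function(n_pre = 50L, n_train = 30L, n_post = 50L,
                         reward_rule = c(L = 1.0, R = 0.0), seed = 1L) {
  stopifnot(n_pre >= 0, n_train >= 0, n_post >= 0,
            all(c("L", "R") %in% names(reward_rule)),
            all(reward_rule >= 0 & reward_rule <= 1))
  structure(list(n_pre = as.integer(n_pre), n_train = as.integer(n_train),
                 n_post = as.integer(n_post), reward_rule = reward_rule,
                 seed = as.integer(seed)),
            class = "cbgt_plan")
}

#' Run a full pre/train/post session
#'
#' Executes the session described by \code{plan} on a network configuration:
#' plasticity is enabled only during the training block, the value estimate
#' and corticostriatal weights are carried forward across training trials,
#' and the post block runs with the trained weights frozen.  Fully
#' reproducible from \code{plan$seed}.
#'
#' @param config a \code{cbgt_config}.
#' @param plan a \code{cbgt_plan}.
#' @return A \code{cbgt_session}: list of \code{cbgt_trial}s (each tagged
#'   with \code{learning_stage} and \code{trial_index}), with the final
#'   \code{cbgt_learning} state and the plan as attributes.
#' @export
run_session <- function(config, plan = session_plan()) {
  validate_config(config)
  set.seed(plan$seed)
  learning <- init_learning(config)
  pl <- config$plasticity
  trials <- vector("list", plan$n_pre + plan$n_train + plan$n_post)
  idx <- 0L
  run_one <- function(stage) {
    tr <- simulate_trial(config, learning, seed = NULL,
                         learning_stage = stage)
    idx <<- idx + 1L
    tr$trial_index <- idx
    trials[[idx]] <<- tr
    tr
  }
  for (i in seq_len(plan$n_pre)) run_one(0L)
  for (i in seq_len(plan$n_train)) {
    tr <- run_one(i - 1L)
    if (tr$choice != "none") {
      p_rew <- plan$reward_rule[[tr$choice]]
      reward <- if (p_rew >= 1) 1L else if (p_rew <= 0) 0L
                else stats::rbinom(1L, 1L, p_rew)
      upd <- reward_prediction_error(reward, learning, pl$alpha_v)
      learning <- apply_plasticity(upd$learning, upd$delta, tr$choice,
                                   eligibility_from_trial(tr),
                                   eta = pl$eta,
                                   w_min = pl$w_min, w_max = pl$w_max)
    }
  }
  for (i in seq_len(plan$n_post)) run_one(plan$n_train)
  structure(trials, class = "cbgt_session",
            learning = learning, plan = plan)
}

#' Behavioral summary of a session
#'
#' @param session a \code{cbgt_session} (or plain list of \code{cbgt_trial}).
#' @return Data frame with one row per trial: \code{trial}, \code{stage},
#'   \code{block} (\code{pre}/\code{train}/\code{post}), \code{choice},
#'   \code{decision_time_ms}, \code{consolidation_ms}.
#' @export
session_behavior <- function(session) {
  plan <- attr(session, "plan")
  n <- length(session)
  block <- rep("post", n)
  if (!is.null(plan)) {
    block <- rep(c("pre", "train", "post"),
                 c(plan$n_pre, plan$n_train, plan$n_post))
  }
  data.frame(
    trial = seq_len(n),
    stage = vapply(session, function(t) t$learning_stage, integer(1)),
    block = block,
    choice = vapply(session, function(t) t$choice, character(1)),
    decision_time_ms = vapply(session, function(t)
      if (is.na(t$decision_time)) NA_real_ else t$decision_time, numeric(1)),
    consolidation_ms = vapply(session, function(t) t$consolidation_time,
                              numeric(1)),
    stringsAsFactors = FALSE
  )
}
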