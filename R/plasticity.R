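#' Initial learning state
#'
#' The learning state carries the value estimate \eqn{V} of the task and the
#' four plastic corticostriatal weights (Cx to dSPN and iSPN, per channel).
#' \eqn{V} starts at 0 and is shared across channels.
#'
#' @param config a \code{cbgt_config}; the plastic weights are initialized
#'   from its type-level Cx->dSPN and Cx->iSPN weights.
#' @return An object of class \code{cbgt_learning} with fields \code{V} and
#'   \code{w} (named vector \code{dSPN_L, dSPN_R, iSPN_L, iSPN_R}).
#' @export
init_learning <- function(config) {
  e <- config$edges
  w_d <- e$weight[e$src == "Cx" & e$dst == "dSPN"]
  w_i <- e$weight[e$src == "Cx" & e$dst == "iSPN"]
  structure(list(
    V = 0,
    w = c(dSPN_L = w_d, dSPN_R = w_d, iSPN_L = w_i, iSPN_R = w_i)
  ), class = "cbgt_learning")
}

#' Reward prediction error and value update
#'
#' Computes the phasic dopamine signal \eqn{\delta = r - V} (received minus
#' expected reward) and advances the value estimate by
#' \eqn{V \leftarrow V + \alpha_V \delta}.
#'
#' @param reward 0 or 1.
#' @param learning a \code{cbgt_learning} state.
#' @param alpha_v value learning rate.
#' @return A list with \code{delta} and the updated \code{learning} state.
#' @export
reward_prediction_error <- function(reward, learning, alpha_v = 0.25) {
  stopifnot(reward %in% c(0, 1))
  delta <- reward - learning$V
  learning$V <- learning$V + alpha_v * delta
  list(delta = delta, learning = learning)
}

#' Dopamine-modulated corticostriatal weight update
#'
#' Trial-level abstraction of dopamine-dependent corticostriatal plasticity:
#' positive phasic dopamine potentiates Cx->dSPN synapses and depresses
#' Cx->iSPN synapses, in proportion to each channel's eligibility trace.
#' For each channel \eqn{c}: \eqn{\Delta w_{dSPN_c} = +\eta\,\delta\,e_c} and
#' \eqn{\Delta w_{iSPN_c} = -\eta\,\delta\,e_c}.  Weights are clipped to the
#' configured bounds.
#'
#' @param learning a \code{cbgt_learning} state.
#' @param delta reward prediction error (signed).
#' @param chosen_channel \code{"L"} or \code{"R"} (recorded; the update
#'   itself is driven by the per-channel eligibilities).
#' @param eligibility named non-negative vector \code{c(L=, R=)}, e.g. the
#'   normalized trial-mean dSPN rate of each channel.
#' @param eta plasticity learning rate.
#' @param w_min,w_max clip bounds on the plastic weights.
#' @return The updated \code{cbgt_learning} state.
#' @export
apply_plasticity <- function(learning, delta, chosen_channel, eligibility,
                             eta = 0.06, w_min = 0.2, w_max = 2.5) {
  stopifnot(all(c("L", "R") %in% names(eligibility)),
            all(eligibility >= 0))
  w <- learning$w
  for (ch in c("L", "R")) {
    e_c <- eligibility[[ch]]
    w[paste0("dSPN_", ch)] <- w[paste0("dSPN_", ch)] + eta * delta * e_c
    w[paste0("iSPN_", ch)] <- w[paste0("iSPN_", ch)] - eta * delta * e_c
  }
  learning$w <- pmin(pmax(w, w_min), w_max)
  learning
}

# Per-channel eligibility from a trial.  The activity part is the
# baseline-subtracted mean dSPN rate over the decision period, rectified and
# normalized to sum 1.  Because partial cortical input to the *selected*
# channel is sustained through the post-decision consolidation phase, the
# chosen channel's corticostriatal synapses stay coactive with the dopamine
# signal; `consolidation_gate` mixes a choice indicator into the trace to
# capture that (0 = pure activity trace, 1 = fully choice-gated).
eligibility_from_trial <- function(trial, consolidation_gate = 0.7) {
  t_ms <- trial$t_ms
  upto <- if (trial$choice == "none") max(t_ms) else trial$decision_time
  sel <- t_ms >= 0 & t_ms <= upto
  base <- t_ms < 0
  e <- c(L = max(0, mean(trial$rates[sel, "dSPN_L"]) -
                    mean(trial$rates[base, "dSPN_L"])),
         R = max(0, mean(trial$rates[sel, "dSPN_R"]) -
                    mean(trial$rates[base, "dSPN_R"])))
  s <- sum(e)
  e <- if (s <= 0) c(L = 0.5, R = 0.5) else e / s
  if (trial$choice %in% c("L", "R")) {
    ind <- c(L = 0, R = 0)
    ind[trial$choice] <- 1
    e <- (1 - consolidation_gate) * e + consolidation_gate * ind
  }
  e
}
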