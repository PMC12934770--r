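#' Full CLAW analysis of a set of trials
#'
#' Convenience wrapper running the whole discrete-state analysis on
#' simulated (or imported) trials: bins and thresholds, binarization,
#' per-trial state sequences (from the pre-stimulus segment up to the
#' decision bin), the pooled transition matrix, the high-probability CLAW
#' graph, the zone partition and per-trial trajectory classes.
#'
#' @param trials list of \code{cbgt_trial}.
#' @param delta_t bin width (ms).
#' @param scheme optional pre-computed \code{claw_scheme}; when \code{NULL}
#'   thresholds are derived from the pooled binned rates of these trials.
#' @param min_edge_prob,min_visits CLAW extraction thresholds.
#' @param zone_override optional user state-to-zone map (see
#'   \code{\link{assign_zones}}).
#' @return A \code{claw_analysis}: list with \code{scheme},
#'   \code{sequences}, \code{behavior}, \code{tm}, \code{graph},
#'   \code{zones}, \code{baseline_state}, \code{zone_paths},
#'   \code{classes} and \code{zone_tm}.
#' @export
claw_analysis <- function(trials, delta_t = 10, scheme = NULL,
                          min_edge_prob = 0.01, min_visits = 20,
                          zone_override = NULL) {
  stopifnot(length(trials) > 0L)
  dt <- diff(trials[[1L]]$t_ms[1:2])
  binned <- lapply(trials, function(tr) {
    b <- bin_rates(tr$rates, delta_t, dt)
    # truncate at the decision bin
    n_pre <- sum(tr$t_ms <= 0) %/% (delta_t / dt)
    if (!is.na(tr$decision_time)) {
      last <- n_pre + ceiling(tr$decision_time / delta_t)
      b <- b[seq_len(min(nrow(b), last)), , drop = FALSE]
    }
    attr(b, "n_pre") <- n_pre
    b
  })
  if (is.null(scheme)) {
    pooled <- do.call(rbind, binned)[, claw_state_streams(), drop = FALSE]
    scheme <- compute_thresholds(pooled, delta_t = delta_t)
  }
  binaries <- lapply(binned, binarize_rates, scheme = scheme)
  pre_bins <- attr(binned[[1L]], "n_pre")
  baseline <- baseline_state_of(binaries, pre_bins = max(1L, pre_bins))
  sequences <- lapply(binaries, state_sequence)
  behavior <- data.frame(
    choice = vapply(trials, function(t) t$choice, character(1)),
    decision_time_ms = vapply(trials, function(t)
      if (is.na(t$decision_time)) NA_real_ else t$decision_time, numeric(1)),
    stage = vapply(trials, function(t) t$learning_stage, integer(1)),
    stringsAsFactors = FALSE)
  tm <- transition_matrix(sequences)
  graph <- extract_claw(tm, min_edge_prob, min_visits)
  zones <- assign_zones(graph, scheme, baseline, override = zone_override)
  # Per-trial zone path: the launching point is the modal pre-stimulus
  # state of the trial (robust to single-bin noise flips), followed by the
  # post-onset zone sequence.
  nb <- length(scheme$state_streams)
  base_bits <- decode_state(baseline, nb)
  paths <- lapply(seq_along(sequences), function(i) {
    bins <- expand_sequence(sequences[[i]])
    pre <- seq_len(min(pre_bins, length(bins)))
    start <- as.integer(names(sort(table(bins[pre]), decreasing = TRUE))[1L])
    z0 <- unclass(zones)[as.character(start)]
    # a single noise-flipped bit of the launching state still launches
    if (is.na(z0) || z0 == "other") {
      if (sum(decode_state(start, nb) != base_bits) <= 1L) z0 <- "I"
      else z0 <- "other"
    }
    z <- c(z0, unclass(zones)[as.character(bins[-pre])])
    z[is.na(z)] <- "other"
    z <- z[z != "other"]
    if (length(z) == 0L) return(character(0))
    z <- rle(z)$values
    # commitment is history-dependent: once a trajectory has committed to
    # one channel, a later committed pattern of the *opposite* channel is a
    # reversal (zone VI), not a fresh commitment
    first_commit <- which(z %in% c("III", "IV"))[1L]
    if (!is.na(first_commit)) {
      if (first_commit < length(z)) {
        opp <- if (z[first_commit] == "III") "IV" else "III"
        later <- seq(first_commit + 1L, length(z))
        z[later][z[later] == opp] <- "VI"
        z <- rle(z)$values
      }
      # a decision for the channel opposite to the first commitment is a
      # dominance flip even when the flipped committed pattern is too brief
      # to fill a 10 ms bin
      commit_ch <- if (z[first_commit] == "III") "L" else "R"
      choice_i <- trials[[i]]$choice
      if (choice_i %in% c("L", "R") && choice_i != commit_ch &&
          z[length(z)] != "VI")
        z <- c(z, "VI")
    }
    z
  })
  classes <- vapply(paths, classify_trajectory, character(1))
  structure(list(scheme = scheme, sequences = sequences, behavior = behavior,
                 tm = tm, graph = graph, zones = zones,
                 baseline_state = baseline, zone_paths = paths,
                 classes = classes,
                 zone_tm = zone_transition_matrix(sequences, zones)),
            class = "claw_analysis")
}

#' @export
print.claw_analysis <- function(x, ...) {
  cat(sprintf("CLAW analysis: %d trials, %d visited states, baseline %d\n",
              length(x$sequences), length(x$tm$visits), x$baseline_state))
  print(table(factor(x$classes,
                     levels = c("A", "B", "C", "D", "unclassified"))))
  invisible(x)
}
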