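ZONE_LEVELS <- c("I", "II", "III", "IV", "V", "VI", "other")

bit_of <- function(k, stream, scheme) {
  bits <- decode_state(k, length(scheme$state_streams))
  bits[match(stream, scheme$state_streams)]
}

#' Partition CLAW states into functional zones
#'
#' Rule-based classifier of the six functional zones of the decision
#' process: I (launching; the pre-stimulus baseline state), II (initial
#' deliberation), III / IV (left / right commitment: that channel's dSPN
#' and Th bits on, its GPi bit off, the opposite dSPN off), V (deep
#' deliberation: cycles of length >= 3 among non-committed states reached
#' only after II), and VI (reversal: states reached from a committed zone in
#' which dominance flips to the opposite channel).  Remaining non-baseline
#' states with bilateral iSPN engagement or no channel dominance fall in II;
#' anything else is labelled \code{"other"}.  A user-supplied map overrides
#' the classifier.
#'
#' @param claw a \code{claw_graph}.
#' @param scheme a \code{claw_scheme} (declares the bit order).
#' @param baseline_state integer index of the pre-stimulus state (e.g. from
#'   \code{\link{baseline_state_of}}).
#' @param override optional named vector \code{state index -> zone label}
#'   returned verbatim (after validation) instead of the classifier result.
#' @return A \code{claw_zones}: named character vector, one zone label per
#'   state in \code{claw$states}.
#' @export
assign_zones <- function(claw, scheme, baseline_state, override = NULL) {
  states <- claw$states
  if (!is.null(override)) {
    if (!all(override %in% ZONE_LEVELS))
      stop("override contains unknown zone labels")
    out <- override[as.character(states)]
    if (anyNA(out)) stop("override must cover every CLAW state")
    return(structure(stats::setNames(unname(out), states),
                     class = "claw_zones"))
  }
  if (!baseline_state %in% states)
    stop("baseline state ", baseline_state, " is not in the CLAW graph")
  nb <- length(scheme$state_streams)
  B <- t(vapply(states, decode_state, integer(nb), n_bits = nb))
  colnames(B) <- scheme$state_streams
  zone <- rep(NA_character_, length(states))
  names(zone) <- states
  zone[as.character(baseline_state)] <- "I"

  is_III <- B[, "dSPN_L"] == 1 & B[, "GPi_L"] == 0 & B[, "Th_L"] == 1 &
            B[, "dSPN_R"] == 0
  is_IV <- B[, "dSPN_R"] == 1 & B[, "GPi_R"] == 0 & B[, "Th_R"] == 1 &
           B[, "dSPN_L"] == 0
  zone[is.na(zone) & is_III] <- "III"
  zone[is.na(zone) & is_IV] <- "IV"

  # reversal: dominance flipped after commitment.  A committed-pattern
  # state whose CLAW-graph entries all come from the *opposite* committed
  # zone (never from launching or deliberation) is a reversal state: the
  # previously dominant channel's dSPN/Th have turned off and the opposite
  # channel's have turned on.
  e <- claw$edges
  repeat {
    changed <- FALSE
    for (i in seq_along(states)) {
      if (!(zone[i] %in% c("III", "IV"))) next
      opp <- if (zone[i] == "III") "IV" else "III"
      preds <- e$from[e$to == states[i] & e$from != states[i]]
      pz <- zone[as.character(preds)]
      if (any(pz == opp | pz == "VI", na.rm = TRUE) &&
          !any(pz %in% c("I", "II", zone[i]), na.rm = TRUE)) {
        zone[i] <- "VI"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (i in which(is.na(zone))) {
    s <- states[i]
    preds <- e$from[e$to == s]
    pre_zone <- zone[as.character(preds)]
    from_III <- any(pre_zone == "III", na.rm = TRUE)
    from_IV <- any(pre_zone == "IV", na.rm = TRUE)
    flip_to_R <- B[i, "dSPN_L"] == 0 & B[i, "dSPN_R"] == 1 & B[i, "Th_R"] == 1
    flip_to_L <- B[i, "dSPN_R"] == 0 & B[i, "dSPN_L"] == 1 & B[i, "Th_L"] == 1
    if ((from_III && flip_to_R) || (from_IV && flip_to_L)) zone[i] <- "VI"
  }

  # candidate deliberation states: bilateral iSPN engagement or no dominance
  cand_II <- is.na(zone) &
    (B[, "iSPN_L"] == 1 & B[, "iSPN_R"] == 1 | B[, "dSPN_L"] == B[, "dSPN_R"])
  zone[cand_II] <- "II"
  zone[is.na(zone)] <- "other"

  # deep deliberation: cycles (SCCs) of length >= 3 among deliberation
  # states, not entered directly from the baseline state
  ii_states <- states[zone == "II"]
  if (length(ii_states) >= 3L) {
    sub <- e[e$from %in% ii_states & e$to %in% ii_states, ]
    if (nrow(sub) > 0L) {
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(sub$from), to = as.character(sub$to)),
        directed = TRUE,
        vertices = data.frame(name = as.character(ii_states)))
      comp <- igraph::components(g, mode = "strong")
      for (ci in which(comp$csize >= 3L)) {
        members <- as.integer(names(comp$membership)[comp$membership == ci])
        direct <- e$to[e$from == baseline_state]
        deep <- members[!members %in% direct]
        if (length(deep) == length(members))  # reached only via II
          zone[as.character(members)] <- "V"
      }
    }
  }
  structure(zone, class = "claw_zones")
}

#' @export
print.claw_zones <- function(x, ...) {
  cat("CLAW zone map:\n")
  print(table(factor(unclass(x), levels = ZONE_LEVELS)))
  invisible(x)
}

#' Most frequent pre-stimulus state
#'
#' @param binaries list of binarized trial matrices (bins x state streams).
#' @param pre_bins how many leading bins of each trial are pre-stimulus.
#' @return The modal state index over the pre-stimulus bins.
#' @export
baseline_state_of <- function(binaries, pre_bins = 1L) {
  idx <- unlist(lapply(binaries, function(b) {
    n <- min(pre_bins, nrow(b))
    if (n == 0L) return(integer(0))
    apply(b[seq_len(n), , drop = FALSE], 1, encode_state)
  }))
  if (length(idx) == 0L) stop("no pre-stimulus bins available")
  as.integer(names(sort(table(idx), decreasing = TRUE))[1L])
}

#' Map a state sequence to its zone path
#'
#' @param seq a \code{claw_sequence}.
#' @param zones a \code{claw_zones} map.
#' @param drop_other drop states outside the six zones (default TRUE).
#' @return Character vector of zone labels with consecutive repeats merged.
#' @export
zone_path <- function(seq, zones, drop_other = TRUE) {
  z <- unclass(zones)[as.character(seq$state)]
  z[is.na(z)] <- "other"
  if (drop_other) z <- z[z != "other"]
  if (length(z) == 0L) return(character(0))
  rle(z)$values
}

#' Classify a decision trajectory from its zone path
#'
#' Classes: A (deliberative; no committed zone visited), B (deliberative
#' then committed; II precedes III/IV), C (committed; III/IV without II) and
#' D (committed then reversal; VI after III/IV).  Paths not starting in the
#' launching zone are flagged unclassified.
#'
#' @param path character vector of zone labels (collapsed).
#' @return One of \code{"A"}, \code{"B"}, \code{"C"}, \code{"D"} or
#'   \code{"unclassified"}.
#' @export
classify_trajectory <- function(path) {
  if (length(path) == 0L || path[1L] != "I") return("unclassified")
  i_commit <- which(path %in% c("III", "IV"))
  if (length(i_commit) == 0L) return("A")
  i_vi <- which(path == "VI")
  if (any(i_vi > i_commit[1L])) return("D")
  i_ii <- which(path == "II")
  if (any(i_ii < i_commit[1L])) return("B")
  "C"
}

#' Zone-level transition table
#'
#' Pools per-bin transitions across trials at the zone level (self
#' transitions included).
#'
#' @param sequences list of \code{claw_sequence}.
#' @param zones a \code{claw_zones} map.
#' @return Row-stochastic matrix over the zone labels that occur.
#' @export
zone_transition_matrix <- function(sequences, zones) {
  lv <- ZONE_LEVELS
  counts <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (s in sequences) {
    z <- unclass(zones)[as.character(expand_sequence(s))]
    z[is.na(z)] <- "other"
    if (length(z) >= 2L)
      for (k in seq_len(length(z) - 1L))
        counts[z[k], z[k + 1L]] <- counts[z[k], z[k + 1L]] + 1
  }
  seen <- rowSums(counts) > 0 | colSums(counts) > 0
  counts <- counts[seen, seen, drop = FALSE]
  P <- counts
  rs <- rowSums(counts)
  P[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  attr(P, "counts") <- counts
  P
}

#' Compare zone transition tables between learning stages
#'
#' Flags zone-to-zone transition probabilities whose relative change
#' exceeds \code{rel_threshold} (default 10\%), signed as increase or
#' decrease.  A transition absent before but present after is flagged
#' \code{"new transition"} rather than divided by zero.
#'
#' @param p_old,p_new row-stochastic zone transition matrices on the same
#'   zone set (e.g. from \code{\link{zone_transition_matrix}}).
#' @param rel_threshold relative-change threshold.
#' @return Data frame with \code{from}, \code{to}, \code{p_old},
#'   \code{p_new}, \code{rel_change} and \code{flag} in
#'   \{\code{increase}, \code{decrease}, \code{new transition}\}.
#' @export
compare_claws <- function(p_old, p_new, rel_threshold = 0.10) {
  zones <- union(rownames(p_old), rownames(p_new))
  if (!setequal(rownames(p_old), rownames(p_new)))
    stop("zone sets differ between the two tables")
  out <- list()
  for (a in zones) for (b in zones) {
    po <- p_old[a, b]; pn <- p_new[a, b]
    if (po == 0 && pn == 0) next
    if (po == 0 && pn > 0) {
      out[[length(out) + 1L]] <- data.frame(
        from = a, to = b, p_old = po, p_new = pn, rel_change = NA_real_,
        flag = "new transition", stringsAsFactors = FALSE)
      next
    }
    rel <- (pn - po) / po
    if (abs(rel) > rel_threshold) {
      out[[length(out) + 1L]] <- data.frame(
        from = a, to = b, p_old = po, p_new = pn, rel_change = rel,
        flag = if (rel > 0) "increase" else "decrease",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      p_old = numeric(0), p_new = numeric(0),
                      rel_change = numeric(0), flag = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
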