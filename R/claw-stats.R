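# KL divergence between two samples on a shared histogram grid with
# additive smoothing (natural log, nats).
kl_divergence <- function(x, y, n_breaks = 20, eps = 1e-9) {
  rng <- range(c(x, y))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_breaks + 1L)
  px <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_breaks) + eps
  py <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE), n_breaks) + eps
  px <- px / sum(px); py <- py / sum(py)
  sum(px * log(px / py))
}

#' Per-state (or per-zone) decision statistics
#'
#' For every state visited by at least one decided trial: the mean decision
#' time of visiting trials, the probability that they chose left, and the
#' Kullback-Leibler divergence (nats) between the decision-time
#' distributions of left- versus right-choice visitors, computed on a
#' shared histogram grid with additive smoothing.
#'
#' @param behavior data frame with one row per trial: \code{choice}
#'   (\code{"L"}/\code{"R"}) and \code{decision_time_ms}.
#' @param sequences list of \code{claw_sequence}, parallel to
#'   \code{behavior} rows.
#' @param by \code{"state"} or \code{"zone"}.
#' @param zones a \code{claw_zones} map (required when \code{by = "zone"}).
#' @param eps additive smoothing mass per histogram cell.
#' @return Data frame with \code{unit}, \code{n_trials}, \code{mean_dt},
#'   \code{p_left}, \code{kl_dt}; never-visited units are absent.
#' @export
state_statistics <- function(behavior, sequences, by = c("state", "zone"),
                             zones = NULL, eps = 1e-9) {
  by <- match.arg(by)
  stopifnot(length(sequences) == nrow(behavior))
  if (by == "zone" && is.null(zones)) stop("zones map required")
  decided <- behavior$choice %in% c("L", "R")
  units <- list()
  for (i in which(decided)) {
    u <- unique(sequences[[i]]$state)
    if (by == "zone") {
      u <- unique(unclass(zones)[as.character(u)])
      u <- u[!is.na(u) & u != "other"]
    }
    for (v in as.character(u)) units[[v]] <- c(units[[v]], i)
  }
  rows <- lapply(names(units), function(v) {
    idx <- units[[v]]
    dt <- behavior$decision_time_ms[idx]
    ch <- behavior$choice[idx]
    kl <- if (any(ch == "L") && any(ch == "R"))
      kl_divergence(dt[ch == "L"], dt[ch == "R"], eps = eps) else NA_real_
    data.frame(unit = v, n_trials = length(idx), mean_dt = mean(dt),
               p_left = mean(ch == "L"), kl_dt = kl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$unit), , drop = FALSE]
}

#' @rdname state_statistics
#' @export
zone_statistics <- function(behavior, sequences, zones, eps = 1e-9) {
  state_statistics(behavior, sequences, by = "zone", zones = zones, eps = eps)
}
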