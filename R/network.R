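#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Canonical stream order used everywhere in the package.  CxI and FSI are
# shared across action channels; all other cell types are duplicated L/R.
CELL_TYPES <- c("Cx", "CxI", "FSI", "dSPN", "iSPN", "GPeP", "GPeA",
                "STN", "GPi", "Th")
SHARED_TYPES <- c("CxI", "FSI")

#' Population streams of the CBGT model
#'
#' Returns the 18 population streams of the two-channel CBGT circuit: eight
#' channelized cell types (Cx, dSPN, iSPN, GPeP, GPeA, STN, GPi, Th) with a
#' left and a right copy, plus the two interneuron types (CxI, FSI) shared
#' across channels.
#'
#' @return A data frame with columns \code{stream}, \code{cell_type} and
#'   \code{channel} (\code{"L"}, \code{"R"} or \code{"shared"}), 18 rows, in
#'   the canonical stream order.
#' @export
population_streams <- function() {
  rows <- list()
  for (ct in CELL_TYPES) {
    if (ct %in% SHARED_TYPES) {
      rows[[length(rows) + 1L]] <- data.frame(
        stream = ct, cell_type = ct, channel = "shared",
        stringsAsFactors = FALSE)
    } else {
      for (ch in c("L", "R")) {
        rows[[length(rows) + 1L]] <- data.frame(
          stream = paste(ct, ch, sep = "_"), cell_type = ct, channel = ch,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

stream_names <- function() population_streams()$stream

# Type-level connectivity of the circuit.  Signs follow the pathway diagram:
# corticostriatal / corticothalamic / thalamocortical / STN outputs are
# excitatory; pallidal, striatal and interneuron outputs are inhibitory.
# "rule" says how a type-level edge expands to streams: "within" connects
# L->L and R->R, "to_shared" both channels onto a shared target, and
# "from_shared" a shared source onto both channels.
default_edge_table <- function() {
  e <- function(src, dst, w, rule) {
    data.frame(src = src, dst = dst, weight = w, rule = rule,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    e("Cx",   "dSPN", 1.00, "within"),
    e("Cx",   "iSPN", 1.00, "within"),
    e("Cx",   "Th",   0.22, "within"),
    e("Th",   "Cx",   0.60, "within"),
    e("Cx",   "CxI",  0.40, "to_shared"),
    e("Cx",   "FSI",  0.12, "to_shared"),
    e("CxI",  "Cx",  -0.60, "from_shared"),
    e("FSI",  "dSPN", -0.40, "from_shared"),
    e("FSI",  "iSPN", -0.40, "from_shared"),
    e("dSPN", "GPi",  -1.60, "within"),
    e("iSPN", "GPeP", -1.20, "within"),
    e("GPeP", "STN",  -0.35, "within"),
    e("GPeP", "GPi",  -0.25, "within"),
    e("GPeP", "GPeA", -0.45, "within"),
    e("GPeA", "dSPN", -0.25, "within"),
    e("GPeA", "iSPN", -0.25, "within"),
    e("STN",  "GPi",   0.30, "within"),
    e("STN",  "GPeP",  0.25, "within"),
    e("GPi",  "Th",   -0.80, "within")
  ))
}

# Expand the type-level edge table to the 18 x 18 stream weight matrix
# W[target, source].  L and R copies of a "within" edge share one weight, so
# pre-learning configurations are channel-symmetric by construction.
expand_weights <- function(edges) {
  sn <- stream_names()
  W <- matrix(0, 18L, 18L, dimnames = list(sn, sn))
  for (i in seq_len(nrow(edges))) {
    src <- edges$src[i]; dst <- edges$dst[i]; w <- edges$weight[i]
    switch(edges$rule[i],
      within = for (ch in c("L", "R")) {
        W[paste(dst, ch, sep = "_"), paste(src, ch, sep = "_")] <- w
      },
      to_shared = for (ch in c("L", "R")) {
        W[dst, paste(src, ch, sep = "_")] <- W[dst, paste(src, ch, sep = "_")] + w
      },
      from_shared = for (ch in c("L", "R")) {
        W[paste(dst, ch, sep = "_"), src] <- w
      },
      stop("unknown expansion rule: ", edges$rule[i]))
  }
  W
}

expand_per_stream <- function(x) {
  st <- population_streams()
  out <- x[st$cell_type]
  names(out) <- st$stream
  out
}

#' Default reduced CBGT network configuration
#'
#' The shipped, calibrated configuration of the reduced stochastic
#' firing-rate network.  Baseline inputs are chosen so that the configured
#' baseline firing rates are an equilibrium of the noise-free dynamics;
#' the decision threshold is the 30 Hz thalamic rule.
#'
#' @param threshold decision threshold on thalamic rate (Hz).
#' @param max_duration maximum post-stimulus trial duration (ms).
#' @param dt integration step (ms).
#' @return An object of class \code{cbgt_config}.
#' @export
default_config <- function(threshold = 30, max_duration = 1000, dt = 1) {
  baseline <- c(Cx = 8, CxI = 10, FSI = 15, dSPN = 4, iSPN = 4,
                GPeP = 40, GPeA = 8, STN = 15, GPi = 60, Th = 16)
  tau <- c(Cx = 15, CxI = 10, FSI = 10, dSPN = 15, iSPN = 15,
           GPeP = 12, GPeA = 15, STN = 12, GPi = 12, Th = 14)
  noise_sd <- c(Cx = 2.0, CxI = 1.0, FSI = 1.0, dSPN = 1.5, iSPN = 1.5,
                GPeP = 1.0, GPeA = 1.0, STN = 1.0, GPi = 1.0, Th = 1.5)
  cfg <- list(
    edges = default_edge_table(),
    baseline_rate = expand_per_stream(baseline),
    tau = expand_per_stream(tau),
    noise_sd = expand_per_stream(noise_sd),
    noise_tau = 20,
    stim_amp = 11.25,
    threshold = threshold,
    max_duration = max_duration,
    baseline_duration = 200,
    record_pre = 50,
    dt = dt,
    post_record = 10,
    consolidation_mean = 250,
    consolidation_sd = 1.5,
    plasticity = list(alpha_v = 0.25, eta = 0.024,
                      w_min = 0.2, w_max = 2.5)
  )
  class(cfg) <- "cbgt_config"
  validate_config(cfg)
  cfg
}

#' @export
print.cbgt_config <- function(x, ...) {
  cat("Reduced CBGT network configuration\n")
  cat(sprintf("  streams: 18; dt = %g ms; threshold = %g Hz (Th)\n",
              x$dt, x$threshold))
  cat(sprintf("  stimulus = %g Hz to Cx L/R; max duration = %g ms\n",
              x$stim_amp, x$max_duration))
  cat(sprintf("  %d type-level edges; plasticity eta = %g, alpha_V = %g\n",
              nrow(x$edges), x$plasticity$eta, x$plasticity$alpha_v))
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cbgt_config"))
  sn <- stream_names()
  for (f in c("baseline_rate", "tau", "noise_sd")) {
    if (!identical(names(cfg[[f]]), sn))
      stop("config field '", f, "' must be named by the 18 canonical streams")
    if (any(!is.finite(cfg[[f]])))
      stop("config field '", f, "' contains non-finite values")
  }
  if (any(cfg$tau <= 0)) stop("time constants must be positive")
  if (cfg$dt <= 0) stop("dt must be positive")
  # sign constraints of the pathway diagram
  pos <- c("Cx->dSPN", "Cx->iSPN", "Cx->Th", "Th->Cx", "STN->GPi", "STN->GPeP")
  neg <- c("dSPN->GPi", "iSPN->GPeP", "GPeP->STN", "GPeP->GPi", "GPeP->GPeA",
           "GPeA->dSPN", "GPeA->iSPN", "FSI->dSPN", "FSI->iSPN",
           "CxI->Cx", "GPi->Th")
  key <- paste0(cfg$edges$src, "->", cfg$edges$dst)
  bad_pos <- key %in% pos & cfg$edges$weight <= 0
  bad_neg <- key %in% neg & cfg$edges$weight >= 0
  if (any(bad_pos) || any(bad_neg))
    stop("edge signs violate the pathway diagram: ",
         paste(key[bad_pos | bad_neg], collapse = ", "))
  invisible(cfg)
}

#' Sample a jittered network instance
#'
#' Draws a network configuration around a base configuration by multiplying
#' every type-level connection weight by an independent factor uniform on
#' \eqn{[1 - j, 1 + j]}.  Because jitter acts on type-level edges, the left
#' and right copies of each connection stay exactly equal, preserving
#' pre-learning channel symmetry.
#'
#' @param base_config a \code{cbgt_config}.
#' @param jitter_scale relative jitter half-width \eqn{j \in [0, 0.5]}.
#' @param seed integer seed; the draw is fully reproducible.
#' @return A new \code{cbgt_config}.
#' @export
sample_network <- function(base_config, jitter_scale = 0.1, seed = 1L) {
  validate_config(base_config)
  if (!is.numeric(jitter_scale) || length(jitter_scale) != 1L ||
      jitter_scale < 0 || jitter_scale > 0.5)
    stop("jitter_scale must be a single number in [0, 0.5]")
  cfg <- base_config
  if (jitter_scale > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      set.seed(as.integer(seed))
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    }
    f <- stats::runif(nrow(cfg$edges), 1 - jitter_scale, 1 + jitter_scale)
    cfg$edges$weight <- cfg$edges$weight * f
  }
  cfg
}

# Weight matrix and the baseline input that makes baseline_rate a fixed
# point of the noise-free dynamics: I = r* - W r*.
config_matrices <- function(cfg) {
  W <- expand_weights(cfg$edges)
  I0 <- as.numeric(cfg$baseline_rate - W %*% cfg$baseline_rate)
  names(I0) <- stream_names()
  list(W = W, I0 = I0)
}
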