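#' Write / read trial rate tables as tidy CSV
#'
#' One row per (trial, time bin, cell type, channel) with columns
#' \code{trial}, \code{stage}, \code{t_ms}, \code{cell_type},
#' \code{channel}, \code{rate_hz}.
#'
#' @param trials list of \code{cbgt_trial}.
#' @param path output CSV path.
#' @param delta_t bin width (ms) used to thin the time axis (default 10).
#' @return \code{path}, invisibly.
#' @export
write_rates_csv <- function(trials, path, delta_t = 10) {
  st <- population_streams()
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    dt <- diff(tr$t_ms[1:2])
    b <- bin_rates(tr$rates, delta_t, dt)
    t_bin <- tr$t_ms[1] - dt + seq_len(nrow(b)) * delta_t
    data.frame(
      trial = i, stage = tr$learning_stage,
      t_ms = rep(t_bin, times = 18L),
      cell_type = rep(st$cell_type, each = nrow(b)),
      channel = rep(st$channel, each = nrow(b)),
      rate_hz = as.vector(b),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates_csv
#' @param behavior data frame from \code{\link{session_behavior}}.
#' @export
write_behavior_csv <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy rate CSV back into per-trial matrices
#'
#' @param path CSV written by \code{\link{write_rates_csv}} (or
#'   user-supplied in the same dialect).
#' @return List of \code{cbgt_trial}-like records (rates at the stored bin
#'   resolution).
#' @export
read_rates_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "stage", "t_ms", "cell_type", "channel", "rate_hz")
  if (!all(need %in% names(d)))
    stop("rates CSV must have columns ", paste(need, collapse = ", "))
  d$stream <- ifelse(d$channel == "shared", d$cell_type,
                     paste(d$cell_type, d$channel, sep = "_"))
  lapply(split(d, d$trial), function(g) {
    tw <- sort(unique(g$t_ms))
    m <- matrix(NA_real_, length(tw), 18L,
                dimnames = list(NULL, stream_names()))
    for (s in unique(g$stream)) {
      gs <- g[g$stream == s, ]
      m[match(gs$t_ms, tw), s] <- gs$rate_hz
    }
    structure(list(rates = m, t_ms = tw, choice = NA_character_,
                   decision_time = NA_real_,
                   consolidation_time = NA_real_,
                   learning_stage = g$stage[1L]),
              class = "cbgt_trial")
  })
}

#' Write / read a network configuration as YAML
#'
#' @param config a \code{cbgt_config}.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  validate_config(config)
  obj <- unclass(config)
  for (f in c("baseline_rate", "tau", "noise_sd"))
    obj[[f]] <- as.list(config[[f]])
  obj$edges <- lapply(seq_len(nrow(config$edges)), function(i)
    list(src = config$edges$src[i], dst = config$edges$dst[i],
         weight = config$edges$weight[i], rule = config$edges$rule[i]))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_config_yaml
#' @return \code{read_config_yaml}: the restored \code{cbgt_config}.
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$edges <- do.call(rbind, lapply(obj$edges, function(e)
    data.frame(src = e$src, dst = e$dst, weight = e$weight, rule = e$rule,
               stringsAsFactors = FALSE)))
  for (f in c("baseline_rate", "tau", "noise_sd"))
    obj[[f]] <- unlist(obj[[f]])
  class(obj) <- "cbgt_config"
  validate_config(obj)
  obj
}

stage_seed <- function(master, stage_offset) {
  (as.integer(master) * 1000L + as.integer(stage_offset)) %% .Machine$integer.max
}

#' Run the full analysis pipeline end to end
#'
#' Orchestrates the five stages on simulated data: (1) simulate learning
#' sessions for several jittered network instances; (2) CLAW analysis of
#' pre- and post-learning trials; (3) control-ensemble identification
#' (per-network activity summaries against static DDM fits) and
#' within-trial projection; (4) zone-constrained piecewise DDM for the
#' dominant committed path; (5) mixed-effects learning tests on the
#' engagement time courses.  All artifacts are written to \code{out_dir}
#' as CSV/JSON together with a JSON run manifest (seeds, sizes, file
#' hashes).  Identical \code{config} + \code{seed} give identical outputs.
#'
#' @param config a \code{cbgt_config} (the shipped default if omitted).
#' @param out_dir output directory (created if missing).
#' @param seed master seed; every stage derives its own seed from it.
#' @param n_networks number of jittered network instances.
#' @param n_train training trials per session.
#' @param n_pre,n_post block sizes.
#' @param jitter_scale between-network weight jitter.
#' @return Invisibly, a list with the main stage results.
#' @export
pipeline_run <- function(config = default_config(), out_dir, seed = 1L,
                         n_networks = 8L, n_train = 30L,
                         n_pre = 20L, n_post = 30L, jitter_scale = 0.03) {
  validate_config(config)
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- stage 1: simulate -------------------------------------------------
  sessions <- lapply(seq_len(n_networks), function(i) {
    cfg_i <- sample_network(config, jitter_scale, seed = stage_seed(seed, i))
    run_session(cfg_i, session_plan(n_pre, n_train, n_post,
                                    seed = stage_seed(seed, 100L + i)))
  })
  behav <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    b <- session_behavior(sessions[[i]])
    b$network <- i
    b
  }))
  write_behavior_csv(behav, file.path(out_dir, "behavior.csv"))

  pre_trials <- unlist(lapply(sessions, function(s)
    s[seq_len(n_pre)]), recursive = FALSE)
  post_trials <- unlist(lapply(sessions, function(s)
    s[(length(s) - n_post + 1L):length(s)]), recursive = FALSE)

  # --- stage 2: CLAW -----------------------------------------------------
  claw_pre <- claw_analysis(pre_trials)
  claw_post <- claw_analysis(post_trials, scheme = claw_pre$scheme)
  zone_change <- compare_claws(claw_pre$zone_tm, claw_post$zone_tm)
  utils::write.csv(claw_pre$tm$transitions,
                   file.path(out_dir, "transition_matrix_pre.csv"),
                   row.names = FALSE)
  utils::write.csv(zone_change, file.path(out_dir, "zone_changes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(zones = as.list(unclass(claw_pre$zones)),
         baseline_state = claw_pre$baseline_state,
         classes_pre = as.list(table(claw_pre$classes)),
         classes_post = as.list(table(claw_post$classes))),
    file.path(out_dir, "claw.json"), auto_unbox = TRUE)

  # --- stage 3: ensembles ------------------------------------------------
  acts <- t(vapply(seq_along(sessions), function(i)
    network_activity_summary(sessions[[i]][seq_len(n_pre)]),
    numeric(18L)))
  fits <- lapply(seq_along(sessions), function(i) {
    b <- session_behavior(sessions[[i]])
    b <- b[b$block == "pre" & b$choice %in% c("L", "R"), ]
    fit_static(b$choice,
               (b$decision_time_ms + b$consolidation_ms) / 1000,
               seed = stage_seed(seed, 200L + i))
  })
  ddm_mat <- t(vapply(fits, function(f) f$par, numeric(4L)))
  colnames(ddm_mat) <- c("a", "v", "tr", "z")
  loadings <- fit_cca(acts, ddm_mat)
  utils::write.csv(
    data.frame(element = rownames(loadings$U), round(loadings$U, 4)),
    file.path(out_dir, "loadings_activity.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(parameter = rownames(loadings$V), round(loadings$V, 4)),
    file.path(out_dir, "loadings_ddm.csv"), row.names = FALSE)

  tc_pre <- lapply(pre_trials[vapply(pre_trials, function(t)
    t$choice != "none", TRUE)], project_timecourse, loadings = loadings)
  launch <- average_aligned(tc_pre, "cue_onset", 50)
  commit <- average_aligned(tc_pre, "decision", 30)
  utils::write.csv(rbind(cbind(alignment = "cue_onset", launch),
                         cbind(alignment = "decision", commit)),
                   file.path(out_dir, "engagement_timecourse.csv"),
                   row.names = FALSE)

  # --- stage 4: dynamic DDM for the dominant committed path --------------
  pooled_static <- fit_static(
    behav$choice[behav$block == "pre"],
    (behav$decision_time_ms[behav$block == "pre"] +
       behav$consolidation_ms[behav$block == "pre"]) / 1000,
    seed = stage_seed(seed, 300L))
  dyn <- NULL
  zone_stats <- zone_statistics(
    claw_pre$behavior[claw_pre$behavior$choice %in% c("L", "R"), ],
    claw_pre$sequences[claw_pre$behavior$choice %in% c("L", "R")],
    claw_pre$zones)
  candidates <- list(c("I", "II", "III"), c("I", "III"),
                     c("I", "II", "IV"), c("I", "IV"))
  for (path_zones in candidates) {
    if (!all(path_zones %in% zone_stats$unit)) next
    zs <- zone_mean_summaries(pre_trials, claw_pre, path_zones)
    if (!is.null(zs)) {
      pct <- derive_percent_changes(zs$summaries, loadings, pooled_static)
      sched <- phase_schedule(path_zones, zs$dwell_ms,
                              pct_a = pct$pct_a, pct_v = pct$pct_v)
      dyn_par <- solve_phase_params(sched, pooled_static)
      dyn <- simulate_dynamic(dyn_par, n_paths = 5000L,
                              seed = stage_seed(seed, 301L))
      jsonlite::write_json(
        list(schedule = unclass(sched), a = dyn_par$a, v = dyn_par$v,
             discard_rate = dyn$discard_rate),
        file.path(out_dir, "dynamic_ddm.json"), auto_unbox = TRUE)
      break
    }
  }

  # --- stage 5: learning-effect statistics -------------------------------
  long <- engagement_long_table(sessions, loadings, n_pre, n_post,
                                component = "choice")
  report <- tryCatch(fit_learning_model(long),
                     error = function(e) NULL)
  if (!is.null(report)) {
    jsonlite::write_json(
      list(selected = report$selected, bic = as.list(report$bic),
           p = as.list(report$p_interactions),
           threshold = report$threshold),
      file.path(out_dir, "learning_effect.json"), auto_unbox = TRUE)
  }

  # --- manifest ----------------------------------------------------------
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "cbgtclaw",
    r_version = as.character(getRversion()),
    seed = seed,
    n_networks = n_networks,
    blocks = c(pre = n_pre, train = n_train, post = n_post),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sessions = sessions, claw_pre = claw_pre,
                 claw_post = claw_post, loadings = loadings,
                 static = pooled_static, dynamic = dyn, report = report))
}

# Zone-mean activity summaries and dwell times along a zone path, for
# trials whose collapsed zone path equals `path_zones`.
zone_mean_summaries <- function(trials, ca, path_zones, min_trials = 5L) {
  delta_t <- ca$scheme$delta_t
  match_i <- which(vapply(ca$zone_paths, function(p)
    identical(p, path_zones), TRUE))
  if (length(match_i) < min_trials) return(NULL)
  sums <- array(NA_real_, c(length(match_i), length(path_zones), 18L))
  dwell <- matrix(NA_real_, length(match_i), length(path_zones))
  for (j in seq_along(match_i)) {
    i <- match_i[j]
    tr <- trials[[i]]
    dt <- diff(tr$t_ms[1:2])
    bins <- expand_sequence(ca$sequences[[i]])
    zl <- unclass(ca$zones)[as.character(bins)]
    b <- bin_rates(tr$rates, delta_t, dt)
    for (k in seq_along(path_zones)) {
      sel <- which(!is.na(zl) & zl == path_zones[k])
      sel <- sel[sel <= nrow(b)]
      if (length(sel) == 0L) next
      sums[j, k, ] <- summarize_activity(b[sel, , drop = FALSE])
      dwell[j, k] <- length(sel) * delta_t
    }
  }
  ok <- stats::complete.cases(dwell)
  if (sum(ok) < min_trials) return(NULL)
  list(summaries = apply(sums[ok, , , drop = FALSE], c(2, 3), mean),
       dwell_ms = colMeans(dwell[ok, , drop = FALSE]),
       n_trials = sum(ok))
}

# Long-format engagement table (mean launching-window engagement per
# network x stage) for the mixed-effects stage.
engagement_long_table <- function(sessions, loadings, n_pre, n_post,
                                  component = "choice", window_bins = 5L) {
  rows <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    blocks <- list(pre = s[seq_len(n_pre)],
                   post = s[(length(s) - n_post + 1L):length(s)])
    for (bl in names(blocks)) {
      for (tr in blocks[[bl]]) {
        if (tr$choice == "none") next
        tc <- project_timecourse(tr, loadings)
        nb <- min(window_bins, nrow(tc$W))
        for (k in seq_len(nb)) {
          rows[[length(rows) + 1L]] <- data.frame(
            network_id = i,
            trajectory_type = tr$choice,
            learning_stage = tr$learning_stage,
            time_bin = k,
            value = tc$W[k, component],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
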