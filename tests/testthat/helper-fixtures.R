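# Shared fixtures, memoised so expensive simulations run once per session.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# pre-learning trials from the shipped calibrated configuration
pre_trials_fixture <- function(n = 300, seed0 = 20000) {
  memo(paste0("pre_", n, "_", seed0), {
    cfg <- default_config()
    lapply(seq_len(n), function(i) simulate_trial(cfg, seed = seed0 + i))
  })
}

claw_fixture <- function(n = 300) {
  memo(paste0("claw_", n), claw_analysis(pre_trials_fixture(n)))
}

# 20 jittered network instances run through the full 50/30/50 session
# protocol (shared by the behavioral acceptance checks)
sessions_fixture <- function(n_networks = 20) {
  memo(paste0("sessions_", n_networks), {
    cfg0 <- default_config()
    lapply(seq_len(n_networks), function(i) {
      cfg <- sample_network(cfg0, 0.03, seed = i)
      run_session(cfg, session_plan(50, 30, 50, seed = 1000 + i))
    })
  })
}

sessions_behavior_fixture <- function(n_networks = 20) {
  memo(paste0("behav_", n_networks), {
    do.call(rbind, lapply(sessions_fixture(n_networks), session_behavior))
  })
}

# minimal binarization scheme for hand-built state tests
scheme_fixture <- function() {
  structure(list(
    delta_t = 10,
    thresholds = stats::setNames(rep(0.5, 10), claw_state_streams()),
    degenerate = stats::setNames(rep(FALSE, 10), claw_state_streams()),
    state_streams = claw_state_streams()),
    class = "claw_scheme")
}

# claw graph from explicit edges (states inferred)
graph_fixture <- function(edges_df) {
  states <- sort(unique(c(edges_df$from, edges_df$to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges_df$from),
               to = as.character(edges_df$to)),
    directed = TRUE, vertices = data.frame(name = as.character(states)))
  structure(list(states = states, edges = edges_df, graph = g),
            class = "claw_graph")
}

# state index from named bits (all other bits zero)
state_from_bits <- function(...) {
  on <- c(...)
  bits <- stats::setNames(rep(0L, 10), claw_state_streams())
  bits[on] <- 1L
  encode_state(bits)
}
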