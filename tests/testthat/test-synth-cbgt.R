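test_that("the population stream set has the expected structure", {
  st <- population_streams()
  expect_equal(nrow(st), 18L)
  expect_setequal(st$channel[st$cell_type %in% c("CxI", "FSI")], "shared")
  expect_equal(sum(st$channel == "L"), 8L)
  expect_equal(sum(st$channel == "R"), 8L)
})

test_that("sample_network jitters weights reproducibly and symmetrically", {
  cfg <- default_config()
  expect_equal(sample_network(cfg, 0, seed = 1)$edges, cfg$edges)
  a <- sample_network(cfg, 0.1, seed = 42)
  b <- sample_network(cfg, 0.1, seed = 42)
  expect_identical(a$edges$weight, b$edges$weight)
  expect_false(identical(a$edges$weight,
                         sample_network(cfg, 0.1, seed = 43)$edges$weight))
  # L and R copies of every within-channel edge stay exactly equal
  W <- cbgtclaw:::expand_weights(a$edges)
  expect_equal(W["dSPN_L", "Cx_L"], W["dSPN_R", "Cx_R"])
  expect_equal(W["GPi_L", "dSPN_L"], W["GPi_R", "dSPN_R"])
  expect_equal(W["Th_L", "GPi_L"], W["Th_R", "GPi_R"])
  expect_error(sample_network(cfg, 0.6), "jitter_scale")
})

test_that("configuration validation enforces the pathway sign structure", {
  cfg <- default_config()
  cfg$edges$weight[cfg$edges$src == "dSPN"] <- 0.5  # should be inhibitory
  expect_error(validate_config(cfg), "sign")
})

test_that("reward prediction error follows the delta rule", {
  L <- init_learning(default_config())
  expect_equal(reward_prediction_error(1, L)$delta, 1)      # max surprise
  L$V <- 1
  expect_equal(reward_prediction_error(1, L)$delta, 0)      # fully predicted
  # repeated reward drives V monotonically to 1 along the geometric
  # recursion V_t = 1 - (1 - alpha)^t
  L$V <- 0
  vals <- numeric(10)
  for (t in 1:10) {
    L <- reward_prediction_error(1, L, alpha_v = 0.3)$learning
    vals[t] <- L$V
  }
  expect_equal(vals, 1 - 0.7^(1:10), tolerance = 1e-12)
  expect_true(all(diff(vals) > 0))
})

test_that("plasticity updates have the dopaminergic sign structure", {
  L0 <- init_learning(default_config())
  # zero prediction error: no change
  L <- apply_plasticity(L0, 0, "L", c(L = 0.6, R = 0.4))
  expect_equal(L$w, L0$w)
  # positive dopamine with left eligibility dominant: dSPN_L potentiated
  # more than dSPN_R, iSPN_L depressed
  L <- apply_plasticity(L0, 1, "L", c(L = 0.8, R = 0.2), eta = 0.1)
  expect_gt(L$w[["dSPN_L"]] - L0$w[["dSPN_L"]],
            L$w[["dSPN_R"]] - L0$w[["dSPN_R"]])
  expect_lt(L$w[["iSPN_L"]], L0$w[["iSPN_L"]])
  # alternating +1/-1 with equal eligibility returns to the start
  L <- L0
  for (d in rep(c(1, -1), 5))
    L <- apply_plasticity(L, d, "L", c(L = 0.5, R = 0.5), eta = 0.1)
  expect_equal(L$w, L0$w, tolerance = 1e-12)
})

test_that("an unreachable threshold yields a no-decision trial", {
  cfg <- default_config(threshold = 1e6, max_duration = 150)
  tr <- simulate_trial(cfg, seed = 1)
  expect_equal(tr$choice, "none")
  expect_true(is.na(tr$decision_time))
})

test_that("trials record positive decision times and plausible dynamics", {
  trials <- pre_trials_fixture(300)
  dec <- vapply(trials, function(t) t$choice, character(1)) != "none"
  dts <- vapply(trials[dec], function(t) t$decision_time, numeric(1))
  expect_true(all(dts > 0))
  expect_true(all(vapply(trials, function(t) all(t$rates >= 0), TRUE)))
  # consolidation interval: N(250, 1.5) ms
  cons <- vapply(trials, function(t) t$consolidation_time, numeric(1))
  expect_equal(mean(cons), 250, tolerance = 0.5)
  expect_lt(sd(cons), 3)
})

test_that("channel-symmetric networks choose left at chance", {
  trials <- pre_trials_fixture(300)
  ch <- vapply(trials, function(t) t$choice, character(1))
  p_l <- mean(ch[ch != "none"] == "L")
  se <- sqrt(0.25 / sum(ch != "none"))
  expect_lt(abs(p_l - 0.5), 3 * se + 1e-12)
})

test_that("sessions are reproducible and carry plasticity forward", {
  cfg <- default_config()
  plan <- session_plan(3, 3, 3, seed = 11)
  s1 <- run_session(cfg, plan)
  s2 <- run_session(cfg, plan)
  expect_identical(session_behavior(s1), session_behavior(s2))
  expect_identical(attr(s1, "learning")$w, attr(s2, "learning")$w)
  # training with deterministic left reward potentiates the left direct
  # pathway relative to the right
  s3 <- run_session(cfg, session_plan(0, 20, 0, seed = 12))
  w <- attr(s3, "learning")$w
  expect_gt(w[["dSPN_L"]], w[["dSPN_R"]])
  expect_lt(w[["iSPN_L"]], w[["iSPN_R"]])
  expect_gt(attr(s3, "learning")$V, 0.5)
  # stages are tagged by completed training trials
  b <- session_behavior(s3)
  expect_equal(b$stage, 0:19)
})

test_that("learning monotonically increases the rewarded choice", {
  cfg0 <- default_config()
  p_post <- vapply(c(0L, 8L, 30L), function(k) {
    post <- unlist(lapply(1:5, function(i) {
      cfg <- sample_network(cfg0, 0.03, seed = i)
      b <- session_behavior(
        run_session(cfg, session_plan(0, k, 25, seed = 300 + i)))
      b$choice[b$block == "post"]
    }))
    mean(post == "L")
  }, numeric(1))
  # non-decreasing up to sampling error (n = 125 per stage)
  expect_true(all(diff(p_post) > -0.08))
  expect_gt(p_post[3], p_post[1] + 0.2)
})
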