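test_that("the first-passage density is symmetric, normalized and exact", {
  tt <- seq(0.001, 20, by = 0.001)
  up <- wfpt_density(tt, a = 1, v = 0, tr = 0, z = 0.5, "upper")
  lo <- wfpt_density(tt, a = 1, v = 0, tr = 0, z = 0.5, "lower")
  expect_equal(up, lo, tolerance = 1e-10)          # drift-free symmetry
  expect_equal(sum(up + lo) * 0.001, 1, tolerance = 1e-4)
  # classical first-exit mean from (-a, a): E[T] = a^2 (sigma = 1)
  expect_equal(sum(tt * (up + lo)) * 0.001, 1, tolerance = 1e-3)
  expect_equal(wfpt_density(0.1, 1, 1, 0.2, 0.5), 0)  # t <= tr
})

test_that("the density matches an Euler first-passage simulation", {
  fitpar <- structure(list(par = c(a = 1, v = 1, tr = 0, z = 0.5)),
                      class = "ddm_fit")
  sim <- simulate_static(fitpar, n_paths = 30000, seed = 9)
  ok <- sim$outcome != "discarded"
  p_up_sim <- mean(sim$outcome[ok] == "upper")
  tt <- seq(5e-4, 20, by = 5e-4)
  p_up <- sum(wfpt_density(tt, 1, 1, 0, 0.5, "upper")) * 5e-4
  expect_equal(p_up_sim, p_up, tolerance = 0.015)
  expect_equal(mean(sim$rt[ok & sim$outcome == "upper"]),
               sum(tt * wfpt_density(tt, 1, 1, 0, 0.5, "upper")) * 5e-4 / p_up,
               tolerance = 0.03)
})

test_that("static fitting recovers known parameters from simulated data", {
  truth <- structure(list(par = c(a = 1.2, v = 1.5, tr = 0.25, z = 0.5)),
                     class = "ddm_fit")
  sim <- simulate_static(truth, n_paths = 2000, seed = 3)
  ok <- sim$outcome != "discarded"
  fit <- fit_static(ifelse(sim$outcome[ok] == "upper", "L", "R"),
                    sim$rt[ok])
  rel <- abs(fit$par - truth$par) / abs(truth$par)
  expect_true(all(rel < 0.10))
  # self-consistency: refitting data simulated from the fit recovers a
  # similar likelihood per trial
  sim2 <- simulate_static(fit, n_paths = 2000, seed = 4)
  ok2 <- sim2$outcome != "discarded"
  fit2 <- fit_static(ifelse(sim2$outcome[ok2] == "upper", "L", "R"),
                     sim2$rt[ok2])
  expect_lt(abs(fit2$loglik / fit2$n - fit$loglik / fit$n), 0.25)
})

test_that("degenerate one-sided data drives the fit to its bounds", {
  rt <- rep(0.5, 60) + stats::runif(60, 0, 0.001)
  fit <- fit_static(rep("L", 60), rt)
  expect_true(fit$boundary_flag)
})

test_that("phase-parameter solving satisfies the time-weighted constraint", {
  static <- structure(list(par = c(a = 1.0, v = 1.0, tr = 0.25, z = 0.5)),
                      class = "ddm_fit")
  # no percent change: all phases equal the static value
  s0 <- phase_schedule(c("I", "II", "III"), c(50, 30, 20),
                       pct_a = c(0, 0), pct_v = c(0, 0))
  p0 <- solve_phase_params(s0, static)
  expect_equal(p0$a, rep(1, 3))
  expect_equal(p0$v, rep(1, 3))
  # direct-substitution oracle: DT=100, t=(50,30,20), x=10, y=20
  s1 <- phase_schedule(c("I", "II", "III"), c(50, 30, 20),
                       pct_a = c(10, 20), pct_v = c(0, 0))
  p1 <- solve_phase_params(s1, static)
  expect_equal(p1$a, c(1.09409190, 0.98468271, 0.78774617), tolerance = 1e-6)
  # residual property over random schedules
  set.seed(5)
  for (i in 1:200) {
    n_ph <- sample(2:3, 1)
    dwell <- stats::runif(n_ph, 5, 200)
    pct <- stats::runif(n_ph - 1, -40, 60)
    sc <- phase_schedule(rep("I", n_ph), dwell, pct_a = pct,
                         pct_v = stats::runif(n_ph - 1, -40, 60))
    pp <- solve_phase_params(sc, static)
    expect_lt(abs(sum(dwell / sum(dwell) * pp$a) - 1), 1e-12)
    expect_lt(abs(sum(dwell / sum(dwell) * pp$v) - 1), 1e-12)
  }
  expect_error(solve_phase_params(
    phase_schedule(c("I", "II"), c(10, 90), pct_a = 150, pct_v = 0),
    static))
})

test_that("percent changes derive linearly from zone activity changes", {
  d_seed <- 11
  set.seed(d_seed)
  X <- matrix(rnorm(60 * 18), 60, 18,
              dimnames = list(NULL, cbgtclaw:::summary_element_names()))
  Y <- cbind(a = -X[, "Cx_sum"] + 0.5 * X[, "iSPN_sum"],
             v = X[, "dSPN_diff"],
             tr = -0.7 * X[, "Cx_sum"] - 0.4 * X[, "Th_sum"],
             z = 0.5 + 0.1 * X[, "GPeA_sum"])
  f <- fit_cca(X, Y)
  static <- structure(list(par = c(a = 1, v = 1, tr = 0.3, z = 0.5)),
                      class = "ddm_fit")
  zs0 <- matrix(0, 2, 18, dimnames = list(NULL, colnames(X)))
  out0 <- derive_percent_changes(zs0, f, static)
  expect_equal(out0$pct_a, 0)
  expect_equal(out0$pct_v, 0)
  # doubling the activity change doubles the percent change
  zs1 <- zs0; zs1[2, ] <- rnorm(18)
  zs2 <- zs0; zs2[2, ] <- 2 * zs1[2, ]
  o1 <- derive_percent_changes(zs1, f, static)
  o2 <- derive_percent_changes(zs2, f, static)
  expect_equal(o2$pct_a, 2 * o1$pct_a, tolerance = 1e-10)
  expect_equal(o2$pct_v, 2 * o1$pct_v, tolerance = 1e-10)
  expect_error(derive_percent_changes(
    zs1, f, structure(list(par = c(a = 1, v = 0, tr = 0.3, z = 0.5)),
                      class = "ddm_fit")), "zero")
})

test_that("the piecewise simulator reduces to the static one when x=y=0", {
  static <- structure(list(par = c(a = 0.8, v = 0.6, tr = 0.3, z = 0.5)),
                      class = "ddm_fit")
  sched <- phase_schedule(c("I", "II", "III"), c(60, 40, 30),
                          pct_a = c(0, 0), pct_v = c(0, 0))
  dyn <- solve_phase_params(sched, static)
  sim_d <- simulate_dynamic(dyn, n_paths = 5000, seed = 21,
                            max_time_factor = 80)
  sim_s <- simulate_static(static, n_paths = 5000, seed = 22)
  rt_d <- sim_d$rt[sim_d$outcome != "discarded"]
  rt_s <- sim_s$rt[sim_s$outcome != "discarded"]
  expect_equal(sim_d$discard_rate, 0, tolerance = 1e-3)
  ks <- suppressWarnings(stats::ks.test(rt_d, rt_s))
  expect_gt(ks$p.value, 0.01)
})

test_that("a drift-free unbiased walk selects each boundary equally", {
  static <- structure(list(par = c(a = 1, v = 0, tr = 0.2, z = 0.5)),
                      class = "ddm_fit")
  sim <- simulate_static(static, n_paths = 3000, seed = 6)
  ok <- sim$outcome != "discarded"
  p_up <- mean(sim$outcome[ok] == "upper")
  expect_lt(abs(p_up - 0.5), 3 * sqrt(0.25 / sum(ok)))
})

test_that("a strong boundary collapse registers decisions at the transition", {
  static <- structure(list(par = c(a = 1, v = 0, tr = 0.1, z = 0.5)),
                      class = "ddm_fit")
  # a3 << a2: mass between the boundaries is caught by the collapse
  sched <- phase_schedule(c("I", "II", "III"), c(100, 100, 100),
                          pct_a = c(5, 80), pct_v = c(0, 0))
  dyn <- solve_phase_params(sched, static)
  sim <- simulate_dynamic(dyn, n_paths = 3000, seed = 7)
  expect_gt(sum(sim$collapse), 0)
  expect_true(all(sim$rt[sim$outcome != "discarded"] > static$par[["tr"]]))
})

test_that("model comparison prefers the generating model", {
  static <- structure(list(par = c(a = 1.0, v = 0.8, tr = 0.25, z = 0.5)),
                      class = "ddm_fit")
  sched <- phase_schedule(c("I", "II", "III"), c(80, 60, 60),
                          pct_a = c(-30, 60), pct_v = c(-60, -40))
  dyn <- solve_phase_params(sched, static)
  gen <- simulate_dynamic(dyn, n_paths = 6000, seed = 31)
  ok <- gen$outcome != "discarded"
  choice <- ifelse(gen$outcome[ok] == "upper", "L", "R")
  rt <- gen$rt[ok]
  refit <- fit_static(choice, rt, seed = 32)
  cmp <- compare_models(refit, dyn, choice, rt, n_paths = 3e4, seed = 33)
  expect_lt(cmp$bic_dynamic, cmp$bic_static)
  expect_error(compare_models(refit, dyn, character(0), numeric(0)),
               "no decided")
})
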