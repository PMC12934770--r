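test_that("bin_rates averages within bins and drops partial tails", {
  x <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(nrow(bin_rates(x, 10, 1)), 10L)
  expect_equal(bin_rates(x, 10, 1)[1, "a"], mean(x[1:10, "a"]))
  # constant trace reproduces its value in every bin
  const <- matrix(20, 50, 1, dimnames = list(NULL, "a"))
  expect_true(all(bin_rates(const, 10, 1) == 20))
  # 105 ms trace: the 5 ms remainder is dropped
  expect_equal(nrow(bin_rates(matrix(1, 105, 1), 10, 1)), 10L)
  expect_error(bin_rates(x, 10, 3), "multiple")
})

test_that("thresholds fall at the antimode and scale with the data", {
  set.seed(1)
  x <- c(rnorm(3000, 5, 1), rnorm(2000, 40, 4))
  samples <- cbind(dSPN_L = x)
  sch <- compute_thresholds(samples, min_samples = 1000)
  expect_gt(sch$thresholds[["dSPN_L"]], 5)
  expect_lt(sch$thresholds[["dSPN_L"]], 40)
  expect_false(sch$degenerate[["dSPN_L"]])
  # scale equivariance: doubling all rates doubles the threshold
  sch2 <- compute_thresholds(cbind(dSPN_L = 2 * x), min_samples = 1000)
  expect_equal(sch2$thresholds[["dSPN_L"]],
               2 * sch$thresholds[["dSPN_L"]], tolerance = 1e-10)
  # identical samples: degenerate fallback at the common value
  sch3 <- suppressWarnings(compute_thresholds(cbind(Th_L = rep(7, 50))))
  expect_true(sch3$degenerate[["Th_L"]])
  expect_equal(sch3$thresholds[["Th_L"]], 7)
})

test_that("state encoding is the base-2 bijection on 10 bits", {
  expect_equal(encode_state(rep(1, 10)), 1023)
  expect_equal(encode_state(c(rep(0, 9), 1)), 1)
  expect_equal(encode_state(c(1, rep(0, 9))), 512)
  for (k in 0:1023) expect_equal(encode_state(decode_state(k)), k)
  expect_error(encode_state(c(0, 2)), "0 or 1")
  expect_error(decode_state(1024), "range")
})

test_that("binarization of a binary trace is idempotent", {
  set.seed(2)
  b <- matrix(sample(0:1, 200, TRUE), 20, 10,
              dimnames = list(NULL, claw_state_streams()))
  expect_equal(unname(binarize_rates(b, scheme_fixture())), unname(b))
})

test_that("state sequences collapse runs and conserve dwell time", {
  const <- matrix(1L, 7, 10, dimnames = list(NULL, claw_state_streams()))
  s <- state_sequence(const)
  expect_equal(s$state, 1023)
  expect_equal(s$dwell, 7L)
  # alternating pattern: alternating sequence with dwell 1 each
  alt <- const; alt[seq(2, 7, 2), ] <- 0L
  s2 <- state_sequence(alt)
  expect_equal(s2$state, rep(c(1023, 0), length.out = 7))
  expect_true(all(s2$dwell == 1L))
  # dwell conservation on random input
  set.seed(3)
  rnd <- matrix(sample(0:1, 300, TRUE, prob = c(0.8, 0.2)), 30, 10,
                dimnames = list(NULL, claw_state_streams()))
  s3 <- state_sequence(rnd)
  expect_equal(sum(s3$dwell), 30L)
})

test_that("transition matrices are empirical conditional probabilities", {
  seqs <- list(state_sequence(rbind(a = c(0, rep(1, 9)),
                                    b = c(0, rep(1, 9)),
                                    c = c(1, rep(0, 9)))))
  tm <- transition_matrix(seqs)
  # [s1, s1, s2]: two transitions out of s1, half dwell, half onward
  s1 <- encode_state(c(0, rep(1, 9))); s2 <- encode_state(c(1, rep(0, 9)))
  tr <- tm$transitions
  expect_equal(tr$prob[tr$from == s1 & tr$to == s1], 0.5)
  expect_equal(tr$prob[tr$from == s1 & tr$to == s2], 0.5)
  expect_error(transition_matrix(list()), "no sequences")
})

test_that("visited transition rows are stochastic and counts pool additively", {
  ca <- claw_fixture(300)
  tr <- ca$tm$transitions
  sums <- tapply(tr$prob, tr$from, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # pooled counts equal the sum of per-trial counts
  half1 <- transition_matrix(ca$sequences[1:150])
  half2 <- transition_matrix(ca$sequences[151:300])
  key <- function(tm) stats::setNames(tm$transitions$count,
                                      paste(tm$transitions$from,
                                            tm$transitions$to))
  pooled <- key(ca$tm)
  parts <- key(half1)
  k2 <- key(half2)
  all_keys <- union(names(parts), names(k2))
  merged <- stats::setNames(rep(0L, length(all_keys)), all_keys)
  merged[names(parts)] <- merged[names(parts)] + parts
  merged[names(k2)] <- merged[names(k2)] + k2
  expect_equal(merged[names(pooled)], pooled)
})

test_that("CLAW extraction filters by visits and edge probability", {
  # 3-state chain with one rare edge
  seqs <- list()
  set.seed(4)
  for (i in 1:200) {
    bins <- c(rep(1, 5), rep(2, 5))
    if (i <= 1) bins <- c(bins, 3)       # rare edge 2 -> 3 (p ~ 0.005)
    b <- t(vapply(bins, function(k) decode_state(k), integer(10)))
    colnames(b) <- claw_state_streams()
    seqs[[i]] <- state_sequence(b)
  }
  tm <- transition_matrix(seqs)
  g <- extract_claw(tm, min_edge_prob = 0.01, min_visits = 20)
  expect_false(any(g$edges$from == 2 & g$edges$to == 3))
  # lowering the threshold never removes edges
  g2 <- extract_claw(tm, min_edge_prob = 0.001, min_visits = 20)
  expect_true(all(paste(g$edges$from, g$edges$to) %in%
                  paste(g2$edges$from, g2$edges$to)))
  # only deterministic edges survive at probability 1
  g3 <- extract_claw(tm, min_edge_prob = 1.0, min_visits = 1)
  expect_true(all(g3$edges$prob == 1))
})

test_that("zone assignment implements the rule-based classifier", {
  sch <- scheme_fixture()
  baseline <- state_from_bits("GPi_L", "GPi_R", "GPeP_L", "GPeP_R")
  committed_L <- state_from_bits("dSPN_L", "Th_L", "GPi_R", "GPeP_L", "GPeP_R")
  committed_R <- state_from_bits("dSPN_R", "Th_R", "GPi_L", "GPeP_L", "GPeP_R")
  delib <- state_from_bits("iSPN_L", "iSPN_R", "GPi_L", "GPi_R")
  g <- graph_fixture(data.frame(
    from = c(baseline, baseline, baseline, delib),
    to = c(delib, committed_L, committed_R, committed_L),
    count = 10, prob = 0.3))
  z <- assign_zones(g, sch, baseline)
  expect_equal(unname(unclass(z)[as.character(baseline)]), "I")
  expect_equal(unname(unclass(z)[as.character(committed_L)]), "III")
  expect_equal(unname(unclass(z)[as.character(committed_R)]), "IV")
  expect_equal(unname(unclass(z)[as.character(delib)]), "II")
  # user override is returned verbatim
  ov <- stats::setNames(rep("II", length(g$states)), g$states)
  z2 <- assign_zones(g, sch, baseline, override = ov)
  expect_true(all(unclass(z2) == "II"))
  expect_error(assign_zones(g, sch, baseline_state = 999), "not in")
})

test_that("trajectory classification follows the canonical zone paths", {
  expect_equal(classify_trajectory(c("I", "II")), "A")
  expect_equal(classify_trajectory(c("I", "II", "V")), "A")
  expect_equal(classify_trajectory(c("I", "II", "V", "II")), "A")
  expect_equal(classify_trajectory(c("I", "II", "III")), "B")
  expect_equal(classify_trajectory(c("I", "II", "IV")), "B")
  expect_equal(classify_trajectory(c("I", "III")), "C")
  expect_equal(classify_trajectory(c("I", "IV")), "C")
  expect_equal(classify_trajectory(c("I", "III", "VI")), "D")
  expect_equal(classify_trajectory(c("I", "IV", "VI")), "D")
  expect_equal(classify_trajectory(c("II", "III")), "unclassified")
})

test_that("state statistics give valid probabilities and divergences", {
  ca <- claw_fixture(300)
  dec <- ca$behavior$choice %in% c("L", "R")
  st <- state_statistics(ca$behavior[dec, ], ca$sequences[dec])
  expect_true(all(st$p_left >= 0 & st$p_left <= 1))
  expect_true(all(st$kl_dt >= 0, na.rm = TRUE))
  expect_true(all(st$mean_dt > 0))
  # identical L and R samples: KL at the smoothing floor
  expect_lt(cbgtclaw:::kl_divergence(1:100, 1:100), 1e-8)
  # degenerate choice
  b1 <- data.frame(choice = c("L", "L"), decision_time_ms = c(50, 70))
  sq <- list(state_sequence(matrix(1L, 2, 10,
               dimnames = list(NULL, claw_state_streams()))),
             state_sequence(matrix(1L, 3, 10,
               dimnames = list(NULL, claw_state_streams()))))
  st2 <- state_statistics(b1, sq)
  expect_equal(st2$p_left, 1)
})

test_that("zone-table comparison flags relative changes asymmetrically", {
  p_old <- matrix(c(0.8, 0.2, 0.0, 1.0), 2, 2, byrow = TRUE,
                  dimnames = list(c("I", "II"), c("I", "II")))
  expect_equal(nrow(compare_claws(p_old, p_old)), 0L)
  p_new <- p_old; p_new["I", "I"] <- 0.5; p_new["I", "II"] <- 0.5
  out <- compare_claws(p_old, p_new)
  expect_equal(out$flag[out$from == "I" & out$to == "II"], "increase")
  # 0.20 -> 0.21 (+5%) is below the 10% default
  p_small <- p_old; p_small["I", "II"] <- 0.21; p_small["I", "I"] <- 0.79
  out2 <- compare_claws(p_old, p_small)
  expect_false(any(out2$from == "I" & out2$to == "II"))
  # appearance from zero probability is reported as new, not divided
  p_appear <- p_old; p_appear["II", "I"] <- 0.1; p_appear["II", "II"] <- 0.9
  out3 <- compare_claws(p_old, p_appear)
  expect_equal(out3$flag[out3$from == "II" & out3$to == "I"],
               "new transition")
})

test_that("pre-learning committed-zone entries are left/right balanced", {
  ca <- claw_fixture(300)
  zt <- ca$zone_tm
  has <- function(z) z %in% rownames(zt)
  if (has("III") && has("IV")) {
    counts <- attr(zt, "counts")
    into_III <- sum(counts[setdiff(rownames(counts), "III"), "III"])
    into_IV <- sum(counts[setdiff(rownames(counts), "IV"), "IV"])
    tot <- into_III + into_IV
    # binomial symmetry within 3 SE
    expect_lt(abs(into_III / tot - 0.5), 3 * sqrt(0.25 / tot) + 0.02)
  }
  # the zone partition is exhaustive and exclusive on visited states
  z <- unclass(ca$zones)
  expect_true(all(z %in% c("I", "II", "III", "IV", "V", "VI", "other")))
  expect_equal(length(z), length(ca$graph$states))
})
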