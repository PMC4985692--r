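test_that("unconditioned simulation honors absorption and the neutral martingale", {
  spec <- model_spec("moran", 54, 1)
  tr <- simulate_unconditioned(spec, 0, 10, seed = 1)
  expect_equal(tr$states, rep(0L, 11))
  # neutral martingale: mean endpoint stays at the start
  set.seed(42)
  ends <- replicate(2000, {
    tail(simulate_unconditioned(spec, 27, 20)$states, 1)
  })
  se <- sd(ends) / sqrt(length(ends))
  expect_lt(abs(mean(ends) - 27), 3 * se)
  # Moran increments are at most one
  tr <- simulate_unconditioned(model_spec("moran", 54, 2), 27, 200, seed = 3)
  expect_true(all(abs(diff(tr$states)) <= 1))
})

test_that("one WF generation moves the mean to N * p'_B", {
  spec <- model_spec("wright_fisher", 54, 2)
  set.seed(7)
  ends <- replicate(4000, tail(simulate_unconditioned(spec, 27, 1)$states, 1))
  want <- 54 * wf_gamete_freq(54, 2, 27)   # 22.5
  se <- sd(ends) / sqrt(length(ends))
  expect_lt(abs(mean(ends) - want), 3 * se)
})

test_that("bridges are reproducible and hit their endpoint by construction", {
  spec <- model_spec("moran", 54, 2)
  cs <- case_spec("I", 54, 27, 120, 40)
  t1 <- simulate_conditioned(spec, cs, seed = 11)
  t2 <- simulate_conditioned(spec, cs, seed = 11)
  expect_identical(t1$states, t2$states)
  expect_equal(t1$final_state, 40L)
  expect_equal(t1$T_F, 121L)
  # the last recorded state must be one Moran step away from the endpoint
  expect_lte(abs(tail(t1$states, 1) - 40L), 1L)
  # case II: once fixed, stays fixed
  cs2 <- case_spec("II", 54, 27, 120)
  t3 <- simulate_conditioned(spec, cs2, seed = 12)
  if (any(t3$states == 54L)) {
    first <- which(t3$states == 54L)[1]
    expect_true(all(t3$states[first:length(t3$states)] == 54L))
  }
  # case IV (asymptotic, absorbing endpoint) behaves the same way
  cs4 <- case_spec("IV", 54, 27, 120)
  t4 <- simulate_conditioned(spec, cs4, seed = 13)
  expect_true(is.na(t4$T_F))
  expect_equal(t4$final_state, 54L)
  if (any(t4$states == 54L)) {
    first <- which(t4$states == 54L)[1]
    expect_true(all(t4$states[first:length(t4$states)] == 54L))
  }
  # case III keeps the path away from the boundaries
  cs3 <- case_spec("III", 54, 27, 120, 40)
  t5 <- simulate_conditioned(spec, cs3, seed = 14)
  expect_true(all(t5$states > 0 & t5$states < 54))
  expect_error(simulate_conditioned(spec, case_spec("I", 54, 27, 3, 40)),
               "infeasible bridge")
})

test_that("finite-horizon bridge law matches enumeration-and-renormalization", {
  # exact check on an enumerable instance: all conditioned-path probabilities
  # from the package rows against brute-force renormalization
  P <- transition_matrix(model_spec("moran", 4, 2))
  i0 <- 2; k <- 2; TF <- 4
  want <- enum_bridge_law(P, i0, k, TF)
  logH <- hitting_logprofile(P, k, TF)
  got <- vapply(names(want), function(key) {
    st <- as.integer(strsplit(key, ",")[[1]])
    p <- 1
    for (t in seq_len(TF)) {
      row <- conditional_transition_row(P, st[t], k, TF - t + 1L, logH)
      p <- p * row[st[t + 1] + 1L]
    }
    p
  }, numeric(1))
  expect_lt(sum(abs(got - want)) / 2, 1e-10)   # total variation
  expect_equal(sum(got), 1, tolerance = 1e-12)
})

test_that("case-IV first steps follow the absorption-conditioned row", {
  spec <- model_spec("moran", 54, 2)
  cs <- case_spec("IV", 54, 27, 1)
  set.seed(5)
  firsts <- replicate(4000, simulate_conditioned(spec, cs)$states[2])
  P <- transition_matrix(spec)
  row <- asymptotic_conditional_row(P, 27, 54)
  p_up <- row[29]
  phat <- mean(firsts == 28L)
  se <- sqrt(p_up * (1 - p_up) / 4000)
  expect_lt(abs(phat - p_up), 3 * se)
})

test_that("transition encoding counts every consecutive step exactly once", {
  tr <- new_trajectory_for_test(c(27, 28, 28, 27), "moran", 54)
  enc <- encode_transitions(tr)
  expect_equal(enc$counts,
               data.frame(i = c(27L, 28L, 28L), j = c(28L, 27L, 28L),
                          n = c(1L, 1L, 1L)))
  # constant path
  tr2 <- new_trajectory_for_test(rep(10L, 6), "moran", 54)
  enc2 <- encode_transitions(tr2)
  expect_equal(enc2$counts, data.frame(i = 10L, j = 10L, n = 5L))
  # conservation on a random path
  tr3 <- simulate_unconditioned(model_spec("moran", 20, 1.5), 10, 73, seed = 2)
  expect_equal(sum(encode_transitions(tr3)$counts$n), 73)
  # non-consecutive Moran states are a format error
  bad <- new_trajectory_for_test(c(10L, 13L), "moran", 54)
  expect_error(encode_transitions(bad), "non-consecutive")
})

test_that("trajectory TSV round-trips for both horizon kinds", {
  spec <- model_spec("moran", 20, 2)
  tr <- simulate_conditioned(spec, case_spec("I", 20, 10, 15, 14), seed = 4)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f), add = TRUE)
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_identical(back$states, tr$states)
  expect_identical(back$final_state, tr$final_state)
  expect_identical(back$T_F, tr$T_F)
  expect_identical(back$horizon, "finite")
  lines <- readLines(f)
  expect_true(any(grepl("^# family=moran", lines)))
  expect_match(tail(lines, 1), "^16\t14$")
  tr4 <- simulate_conditioned(spec, case_spec("IV", 20, 10, 15), seed = 5)
  write_trajectory(tr4, f)
  back4 <- read_trajectory(f)
  expect_identical(back4$states, tr4$states)
  expect_identical(back4$horizon, "asymptotic")
  expect_true(is.na(back4$T_F))
  expect_match(tail(readLines(f), 1), "^present\t20$")
})
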