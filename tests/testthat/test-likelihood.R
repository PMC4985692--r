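test_that("unconditioned likelihood reduces to hand values on one step", {
  # single Moran up-step from 27: P_27(s) = [1 / (1 + s)] * 27 / 54
  tr <- new_trajectory_for_test(c(27L, 28L), "moran", 54)
  for (s in c(0.5, 1, 2, 5))
    expect_equal(loglik_unconditional(tr, s), log(0.5 / (1 + s)),
                 tolerance = 1e-12)
  # constant path at an absorbing state carries no information
  trN <- new_trajectory_for_test(rep(54L, 5), "moran", 54)
  for (s in c(0.5, 2)) expect_equal(loglik_unconditional(trN, s), 0)
  # zero-probability transition gives -Inf, not an error: down-step at s = 0
  trd <- new_trajectory_for_test(c(27L, 26L), "moran", 54)
  expect_identical(loglik_unconditional(trd, 0), -Inf)
})

test_that("score of the unconditioned likelihood centers at the true s", {
  # under neutral-generated data the mean derivative of log L at s = 1 is 0
  spec <- model_spec("moran", 20, 1)
  set.seed(9)
  eps <- 1e-5
  scores <- replicate(400, {
    tr <- simulate_unconditioned(spec, 10, 60)
    (loglik_unconditional(tr, 1 + eps) - loglik_unconditional(tr, 1 - eps)) /
      (2 * eps)
  })
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se)
})

test_that("conditional likelihood equals the exact bridge path probability", {
  # enumeration oracle on a small finite-horizon instance
  for (s in c(0.5, 1, 2)) {
    P <- transition_matrix(model_spec("moran", 4, s))
    i0 <- 2; k <- 2; TF <- 4
    law <- enum_bridge_law(P, i0, k, TF)
    for (key in names(law)) {
      st <- as.integer(strsplit(key, ",")[[1]])
      tr <- selbridge:::new_trajectory(st[1:TF], "moran", 4L, case = "I",
                                       horizon = "finite", T_F = as.integer(TF),
                                       final_state = as.integer(k))
      # recorded block has T = TF - 1 consecutive states; the forced last
      # step contributes probability one, so L_c equals the full bridge law
      expect_equal(exp(loglik_conditional(tr, s)), unname(law[key]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the h-transform identity L_c = Phi * L holds on both horizons", {
  spec <- model_spec("moran", 54, 2)
  tr1 <- simulate_conditioned(spec, case_spec("I", 54, 27, 40, 40), seed = 21)
  tr4 <- simulate_conditioned(spec, case_spec("IV", 54, 27, 40), seed = 22)
  # independent Phi for the finite horizon: direct matrix powers
  for (s in c(0.5, 1.3, 2, 6)) {
    P <- transition_matrix(model_spec("moran", 54, s))
    pows <- vector("list", tr1$T_F + 1)
    pows[[1]] <- diag(55)
    for (m in seq_len(tr1$T_F)) pows[[m + 1]] <- pows[[m]] %*% P
    st <- tr1$states
    log_phi <- 0
    for (t in seq_len(tr1$T_len)) {
      m <- tr1$T_F - (t - 1)
      log_phi <- log_phi + log(pows[[m]][st[t + 1] + 1, 41]) -
        log(pows[[m + 1]][st[t] + 1, 41])
    }
    lhs <- loglik_conditional(tr1, s)
    rhs <- unname(loglik_unconditional(tr1, s) + log_phi)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # independent Phi for the absorbing asymptotic horizon: closed-form u
  for (s in c(0.5, 1.3, 2, 6)) {
    u <- vapply(0:54, function(i) moran_fixation_closed_form(54, s, i),
                numeric(1))
    st <- tr4$states
    log_phi <- sum(log(u[st[-1] + 1]) - log(u[st[-length(st)] + 1]))
    expect_equal(loglik_conditional(tr4, s),
                 loglik_unconditional(tr4, s) + log_phi, tolerance = 1e-9)
  }
  # phi_functional agrees with the likelihood ratio by construction
  expect_equal(phi_functional(tr1, 2),
               loglik_conditional(tr1, 2) - loglik_unconditional(tr1, 2))
})

test_that("likelihood-ratio curve equals the conditioning functional", {
  spec <- model_spec("wright_fisher", 20, 2)
  tr <- simulate_conditioned(spec, case_spec("I", 20, 10, 25, 14), seed = 31)
  grid <- c(0.5, 1, 2, 4)
  rc <- likelihood_ratio_curve(tr, grid)
  want <- vapply(grid, function(s) phi_functional(tr, s), numeric(1))
  expect_equal(rc$loglik, want, tolerance = 1e-12)
})

test_that("the grid-plus-golden maximizer finds known optima", {
  # optimizer sanity on an injected smooth unimodal function
  opt <- selbridge:::golden_max(function(x) -(x - 1.234567)^2, 0, 3, 1e-8)
  expect_equal(opt$x, 1.234567, tolerance = 1e-6)
  # monotone one-step likelihood maximizes at the lower bound
  tr <- new_trajectory_for_test(c(27L, 28L), "moran", 54)
  fit <- maximize(tr, "unconditional", s_min = 0.1, s_max = 10, n_grid = 50)
  expect_true(fit$boundary)
  expect_equal(fit$s_hat, 0.1, tolerance = 1e-9)
  # flat curve (absorbed path) is flagged as a failure, not an error
  trN <- new_trajectory_for_test(rep(54L, 5), "moran", 54)
  flat <- maximize(trN, "unconditional")
  expect_true(flat$failed)
  expect_true(is.na(flat$s_hat))
})

test_that("conditional MLE recovers the generating coefficient on one bridge", {
  spec <- model_spec("moran", 54, 2)
  tr <- simulate_conditioned(spec, case_spec("I", 54, 27, 200, 40), seed = 8)
  cache <- new_cache()
  fit_c <- maximize(tr, "conditional", cache = cache)
  fit_u <- maximize(tr, "unconditional")
  expect_false(fit_c$failed)
  # conditional estimate lands in a broad band around 2; the unconditioned
  # estimate of the same endpoint-pinned record sits far below it
  expect_gt(fit_c$s_hat, 1)
  expect_lt(fit_u$s_hat, fit_c$s_hat)
})
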