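test_that("transition rows are stochastic with absorbing boundaries", {
  p <- baseline_params()
  r0 <- transition_row(p, 0)
  rN <- transition_row(p, p$N)
  expect_equal(r0, list(i = 0L, up = 0, down = 0, stay = 1))
  expect_equal(rN, list(i = p$N, up = 0, down = 0, stay = 1))

  set.seed(31)
  for (rep in 1:10) {
    q <- random_params(chain_safe = TRUE)
    for (i in 0:q$N) {
      r <- transition_row(q, i)
      expect_equal(r$up + r$down + r$stay, 1, tolerance = 1e-12)
      expect_true(all(c(r$up, r$down, r$stay) >= 0))
    }
  }
  expect_error(transition_row(p, -1), class = "morangame_out_of_range")
  expect_error(transition_row(p, p$N + 1), class = "morangame_out_of_range")
})

test_that("transition probabilities reproduce the fitness-weighted sampling", {
  # neutral chain: up = down = i(N - i)/N^2
  p <- baseline_params(xi = 0)
  for (i in 1:(p$N - 1)) {
    r <- transition_row(p, i)
    expect_equal(r$up, i * (p$N - i) / p$N^2)
    expect_equal(r$down, r$up)
  }
  # up/down ratio equals the fitness ratio e_I/e_T (common factor cancels)
  pb <- baseline_params()
  r1 <- transition_row(pb, 1)
  expect_equal(r1$up / r1$down, 0.5 / 1.14, tolerance = 1e-12)
  # full matrix is row-stochastic and tridiagonal
  M <- transition_matrix(pb)
  expect_equal(rowSums(M), rep(1, pb$N + 1), ignore_attr = TRUE)
  expect_true(all(M[abs(row(M) - col(M)) > 1] == 0))
})

test_that("neutral and equal-payoff chains fix with probability 1/N", {
  for (N in c(2, 5, 50, 200)) {
    fx <- fixation_recursive(baseline_params(xi = 0, N = N))
    expect_equal(fx$rho_I, 1 / N, tolerance = 1e-14)
    expect_equal(fx$rho_T, 1 / N, tolerance = 1e-14)
    expect_equal(fx$q, (0:N) / N, tolerance = 1e-13)
  }
  # equal payoffs at xi > 0: choose eta2 = eta1 and match a_II to a_TT
  # a_II = eta1*RI - Cph = 2.4 = a_TT with eta1 = 0.4, RI = 35, Cph = 11.6
  pe <- game_params(Cpl = 13, Cph = 11.6, RT = 22, RI = 35, eta1 = 0.4,
                    eta2 = 0.4, lam = 0.3, N = 7, xi = 0.4)
  fe <- fixation_recursive(pe)
  expect_equal(fe$rho_I, 1 / 7, tolerance = 1e-12)
  expect_equal(fe$rho_T, 1 / 7, tolerance = 1e-12)
})

test_that("N = 2 reduces to the single-interior-state formula", {
  p <- baseline_params(N = 2)
  f <- fitness(p, 1)
  fx <- fixation_recursive(p)
  expect_equal(fx$rho_I, 1 / (1 + f$e_T / f$e_I))
  expect_equal(fx$rho_T, 1 / (1 + f$e_I / f$e_T))
  expect_equal(fx$rho_I + fx$rho_T, 1)  # only at N = 2
})

test_that("recursive and linear-solve fixation agree to 1e-10", {
  set.seed(41)
  for (rep in 1:60) {
    p <- random_params(chain_safe = TRUE)
    fr <- fixation_recursive(p, "linear")
    fs <- fixation_linear_solve(p, "linear")
    expect_lt(max(abs(fr$q - fs$q)), 1e-10)
    # exponential regime: bound the spread of the cumulative fitness-ratio
    # products so the dense solve stays well conditioned
    repeat {
      pe <- update_params(p, xi = runif(1, 1.01, 2.5))
      cum <- c(0, cumsum(fitness_ratio_log(pe, seq_len(pe$N - 1L),
                                           "exponential")))
      if (max(cum) - min(cum) < 20) break
      p <- random_params(chain_safe = TRUE)
    }
    fre <- fixation_recursive(pe, "exponential")
    fse <- fixation_linear_solve(pe, "exponential")
    expect_lt(max(abs(fre$q - fse$q)), 1e-10)
  }
})

test_that("N = 3 matches hand elimination of the 2x2 absorption system", {
  p <- baseline_params(N = 3)
  r1 <- transition_row(p, 1)
  r2 <- transition_row(p, 2)
  # q1 (u1+d1) = u1 q2 ; q2 (u2+d2) = d2 q1 + u2
  det <- (r1$up + r1$down) * (r2$up + r2$down) - r1$up * r2$down
  q1 <- r1$up * r2$up / det
  q2 <- (r1$up + r1$down) * r2$up / det
  fx <- fixation_recursive(p)
  expect_equal(fx$q[2], q1, tolerance = 1e-12)
  expect_equal(fx$q[3], q2, tolerance = 1e-12)
})

test_that("q is monotone and dominance pushes rho past 1/N", {
  set.seed(51)
  for (rep in 1:20) {
    p <- random_params(chain_safe = TRUE)
    fx <- fixation_recursive(p)
    expect_true(!is.unsorted(fx$q))
    er <- expected_revenues(p, seq_len(p$N - 1L))
    if (all(er$E_I > er$E_T)) {
      expect_gt(fx$rho_I, 1 / p$N)
      expect_lt(fx$rho_T, 1 / p$N)
    }
    if (all(er$E_I < er$E_T)) {
      expect_lt(fx$rho_I, 1 / p$N)
      expect_gt(fx$rho_T, 1 / p$N)
    }
  }
})

test_that("log-space products survive extreme exponential selection", {
  # xi*E spans hundreds of log units; naive products would overflow
  p <- baseline_params(xi = 30, N = 40)
  fx <- fixation_recursive(p, "exponential")
  expect_true(all(is.finite(fx$q)))
  expect_true(fx$rho_I >= 0 && fx$rho_I <= 1)
  expect_true(fx$rho_T >= 0 && fx$rho_T <= 1)
})

test_that("fixation probabilities respond monotonically to success rates", {
  p <- builtin_scenarios()$fig2
  etas <- seq(0.1, 0.9, by = 0.2)
  rho_I <- vapply(etas, function(e)
    fixation_recursive(update_params(p, eta1 = e, N = 12))$rho_I, numeric(1))
  rho_T <- vapply(etas, function(e)
    fixation_recursive(update_params(p, eta2 = e, N = 12))$rho_T, numeric(1))
  expect_true(all(diff(rho_I) >= -1e-12))
  expect_true(all(diff(rho_T) <= 1e-12))
})
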