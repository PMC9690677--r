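test_that("invasion differences evaluate the edge-state formulas", {
  p <- update_params(builtin_scenarios()$fig3a, N = 5)
  d <- invasion_diffs(p)
  expect_equal(d$h1, 0.3 * 35 + 0.2 * 22 + 13 - 18 - 22)  # -12.1
  expect_equal(d$hN1, (3 / 4) * 0.7 * 35 + (1 / 4) * 0.3 * 35 +
                 0.2 * 22 + 13 - 18 - 22)
  # hN1 must equal the expected-revenue difference at i = N - 1, xi = 1
  er <- expected_revenues(p, p$N - 1L)
  expect_equal(d$hN1, er$E_I - er$E_T, tolerance = 1e-12)
  expect_equal(d$h1, with(expected_revenues(p, 1), E_I - E_T))

  # equal success rates collapse the i-dependence
  pe <- update_params(p, eta1 = 0.3)
  de <- invasion_diffs(pe)
  expect_equal(de$hN1, de$h1)

  # sign(g) = sign(h) through the exponential map
  expect_equal(sign(d$g1), sign(d$h1))
  expect_equal(sign(d$gN1), sign(d$hN1))
  expect_equal(d$f1, exp(p$xi * d$h1))
})

test_that("strong-selection classification maps the h-sign cases", {
  # both negative: non-R&D strategy takes over (fig3a at small N)
  p <- update_params(builtin_scenarios()$fig3a, N = 5)
  cl <- classify_strong(p)
  expect_equal(cl$label, "T_replaces_I")
  expect_equal(cl$basis, "h_signs")

  # above the threshold N0 = 15.9/1.9 ~ 8.37, hN1 > 0 but h1 < 0: bistable
  expect_equal(classify_strong(update_params(p, N = 12))$label, "bistable")

  # constructed (+,+): lone innovators already out-earn non-innovators
  pp <- game_params(Cpl = 13, Cph = 14, RT = 22, RI = 35, eta1 = 0.9,
                    eta2 = 0.8, lam = 0.3, N = 6, xi = 1)
  expect_equal(classify_strong(pp)$label, "I_replaces_T")

  # constructed (+,-) needs eta2 > eta1 (innovating alone beats cooperating)
  pm <- game_params(Cpl = 13, Cph = 14, RT = 22, RI = 35, eta1 = 0.2,
                    eta2 = 0.8, lam = 0.3, N = 6, xi = 1)
  dm <- invasion_diffs(pm)
  expect_true(dm$h1 > 0 && dm$hN1 < 0)
  expect_equal(classify_strong(pm)$label, "coexist")

  # exact double zero ties
  pz <- game_params(Cpl = 0, Cph = 0, RT = 0, RI = 10, eta1 = 0, eta2 = 0,
                    lam = 0, N = 6, xi = 1)
  expect_equal(classify_strong(pz)$label, "tie")
})

test_that("the group-size threshold is the real root of hN1", {
  th <- threshold_N0(builtin_scenarios()$fig3a)
  expect_equal(th$N0, 15.9 / 1.9, tolerance = 1e-12)
  expect_lt(th$applicability, 0)

  set.seed(71)
  for (rep in 1:60) {
    p <- random_params()
    th <- tryCatch(threshold_N0(p), error = function(e) NULL)
    if (is.null(th)) next
    # hN1 with N treated as real vanishes at N0
    hN1_real <- function(N) ((N - 2) * p$eta1 * p$RI + p$eta2 * p$RI) /
      (N - 1) + p$lam * p$RT + p$Cpl - p$Cph - p$RT
    if (abs(th$N0 - 1) > 1e-8)  # N0 = 1 puts the root at the formula's pole region
      expect_lt(abs(hN1_real(th$N0)), 1e-10)
    # eta1 = eta2 collapses the threshold to 1
    pe <- update_params(p, eta2 = p$eta1)
    the <- tryCatch(threshold_N0(pe), error = function(e) NULL)
    if (!is.null(the)) expect_equal(the$N0, 1, tolerance = 1e-9)
  }

  # degenerate denominator: eta1*RI + lam*RT - RT - Cph + Cpl = 0
  pd <- game_params(Cpl = 13, Cph = 13, RT = 20, RI = 35, eta1 = 4 / 7,
                    eta2 = 0.3, lam = 0, N = 6, xi = 1)
  expect_error(threshold_N0(pd), class = "morangame_degenerate_threshold")
})

test_that("threshold logic partitions integer N when applicability > 0", {
  # the monotone partition needs the cooperation premise eta1 >= eta2:
  # dh(N)/dN - h1 = (eta1 - eta2)*RI, so h1 > 0 only forces the slope
  # positive when cooperating is at least as successful as innovating alone
  set.seed(72)
  found <- 0
  while (found < 40) {
    p <- random_params()
    if (p$eta1 <= p$eta2) next
    if (invasion_diffs(p)$h1 <= 0) next
    th <- tryCatch(threshold_N0(p), error = function(e) NULL)
    if (is.null(th)) next
    found <- found + 1
    expect_gt(th$applicability, 0)
    hs <- vapply(2:40, function(N)
      invasion_diffs(update_params(p, N = N))$hN1, numeric(1))
    expect_true(all(diff(hs) > -1e-12))           # increasing in N
    expect_equal(hs > 0, (2:40) > th$N0)          # crossing exactly at N0
  }
})

test_that("super-expected-revenue classification equals the xi = 1 one", {
  set.seed(73)
  for (rep in 1:334) {
    p <- random_params()
    strong <- classify_strong(update_params(p, xi = 1))
    for (xi in c(1.1, 1.5, 5)) {
      sup <- classify_super(update_params(p, xi = xi))
      expect_identical(sup$label, strong$label)
    }
    # same group-size threshold: N1 = N0 (one and the same formula root)
    th <- tryCatch(threshold_N0(p), error = function(e) NULL)
    if (!is.null(th))
      expect_identical(threshold_N0(update_params(p, xi = 1.5))$N0, th$N0)
  }
})

test_that("hN1 limits: h1 at N = 2, cooperation payoff difference at large N", {
  p <- builtin_scenarios()$fig4
  d2 <- invasion_diffs(update_params(p, N = 2))
  expect_equal(d2$hN1, d2$h1)
  dInf <- invasion_diffs(update_params(p, N = 10000))
  lim <- p$eta1 * p$RI + p$lam * p$RT + p$Cpl - p$Cph - p$RT
  expect_equal(dInf$hN1, lim, tolerance = 1e-2)
})
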