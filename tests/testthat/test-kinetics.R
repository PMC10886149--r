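# Kinetic core: rate laws, right-hand sides, variants and their limits.

test_that("release rates match hand-evaluated Michaelis-Menten values", {
  p <- ref_params(kS = 0.134, kR = 0.00212, K = 0.001)
  s <- release_state(S = 40, WS = 0.464, E = 10, V = 0.011)
  # independent hand evaluation: SS = 18.56, SR = 21.44
  SS <- 0.464 * 40; SR <- (1 - 0.464) * 40
  expect_equal(unname(release_rates(s, p)),
               c(0.134 * 10 * SS / (40 + 0.001),
                 0.00212 * 10 * SR / (40 + 0.001)),
               tolerance = 1e-12)
  expect_equal(release_rates(s, p)[["rS"]], 0.6217, tolerance = 1e-4)
  expect_equal(release_rates(s, p)[["rR"]], 0.011363, tolerance = 1e-4)
})

test_that("no enzyme or no substrate means no reaction", {
  p <- ref_params()
  expect_equal(unname(release_rates(release_state(S = 40, WS = 0.5, E = 0,
                                                  V = 0.01), p)),
               c(0, 0))
  expect_equal(unname(release_rates(release_state(S = 0, WS = 0.5, E = 10,
                                                  V = 0.01), p)),
               c(0, 0))
})

test_that("saturation limit: WS = 1 and S >> K gives rS ~ kS E, rR = 0", {
  p <- ref_params()
  s <- release_state(S = 50, WS = 1, E = 10, V = 0.01)
  r <- release_rates(s, p)
  expect_equal(r[["rS"]], p$kS * 10, tolerance = 1e-4)
  expect_identical(r[["rR"]], 0)
})

test_that("right-hand side reproduces the hand-evaluated glucose derivative", {
  p <- ref_params(r_evap = 0)
  s <- release_state(S = 40, WS = 0.464, E = 10, V = 0.011)
  d <- release_rhs(s, p)
  expect_equal(d[["dP"]], 1.111 * sum(release_rates(s, p)), tolerance = 1e-12)
  expect_equal(d[["dP"]], 0.7034, tolerance = 1e-4)
  expect_equal(d[["dS"]], -sum(release_rates(s, p)), tolerance = 1e-12)
  expect_identical(d[["dE"]], 0)
  expect_identical(d[["dV"]], 0)
})

test_that("evaporation concentrates: dilution terms carry the right sign", {
  p <- ref_params(r_evap = 3e-5)
  s <- release_state(P = 5, S = 40, WS = 0.464, E = 10, V = 0.011)
  d <- release_rhs(s, p)
  expect_equal(d[["dV"]], -3e-5)
  expect_equal(d[["dE"]], 3e-5 / 0.011 * 10, tolerance = 1e-12)
})

test_that("WS dynamics vanish at the boundaries and under equal constants", {
  p <- ref_params()
  for (ws in c(0, 1)) {
    s <- release_state(S = 40, WS = ws, E = 10, V = 0.01)
    expect_identical(release_rhs(s, p)[["dWS"]], 0)
  }
  peq <- ref_params(kS = 0.05, kR = 0.05)
  for (ws in c(0.2, 0.5, 0.9)) {
    s <- release_state(S = 25, WS = ws, E = 15, V = 0.01)
    expect_equal(release_rhs(s, peq)[["dWS"]], 0, tolerance = 1e-15)
  }
  # degenerate state: zero substrate must not divide by zero
  s0 <- release_state(S = 0, WS = 0.5, E = 10, V = 0.01)
  expect_identical(release_rhs(s0, p)[["dWS"]], 0)
})

test_that("maximal release applies the anhydroglucose conversion factor", {
  expect_equal(max_release(15), 16.665)
  expect_equal(round(max_release(15), 1), 16.7)
  expect_equal(round(max_release(37.5), 1), 41.7)
  expect_identical(max_release(0), 0)
  expect_error(max_release(-1), "must be")
})

test_that("variant rates: inhibition terms and their limits", {
  p <- ref_params(k_single = 0.1, KiP = 5, KiS = 50)
  s0 <- release_state(P = 0, S = 40, WS = 0.5, E = 10, V = 0.01)
  sP <- release_state(P = 10, S = 40, WS = 0.5, E = 10, V = 0.01)

  # zero-order limit of simple MM
  expect_equal(variant_rate(s0, p, "simple_mm"), 0.1 * 10,
               tolerance = 1e-4)
  # product inhibition vanishes at P = 0 ...
  expect_equal(variant_rate(s0, p, "simple_mm_pi"),
               variant_rate(s0, p, "simple_mm"))
  # ... and reduces the rate at P > 0
  expect_lt(variant_rate(sP, p, "simple_mm_pi"),
            variant_rate(sP, p, "simple_mm"))
  # substrate inhibition disappears as KiS -> Inf
  p_inf <- ref_params(k_single = 0.1, KiS = 1e12)
  expect_equal(variant_rate(s0, p_inf, "simple_mm_si"),
               variant_rate(s0, p, "simple_mm"), tolerance = 1e-9)
  expect_lt(variant_rate(s0, p, "simple_mm_si"),
            variant_rate(s0, p, "simple_mm"))
  # inhibition variants demand finite constants
  expect_error(variant_rate(s0, ref_params(), "simple_mm_pi"), "KiP")
  expect_error(variant_rate(s0, ref_params(), "two_substrate_pi_si"), "Ki")
})

test_that("variant family has exactly the seven canonical members", {
  expect_length(model_variants(), 7)
  expect_identical(variant_code("two_substrate"), 5L)
  expect_identical(variant_free_parameters("simple_mm"), "k_single")
  expect_setequal(variant_free_parameters("two_substrate_pi_si"),
                  c("kS", "kR", "WS0", "KiP", "KiS"))
})

test_that("invalid states and parameters are rejected", {
  expect_error(release_state(P = -1))
  expect_error(release_state(WS = 1.2))
  expect_error(release_state(V = 0))
  expect_error(release_parameters(kS = -0.1))
  expect_error(release_parameters(WS0 = 1.5))
  expect_error(release_parameters(nu = 0.9))
})

test_that("glucose-equivalent mass is conserved along random trajectories", {
  # evaporation removes water only, so V (P/nu + S) is a first integral
  set.seed(11)
  for (i in 1:5) {
    p <- ref_params(kS = runif(1, 0.05, 0.3), kR = runif(1, 0.001, 0.01),
                    WS0 = runif(1, 0.2, 0.8), r_evap = runif(1, 0, 5e-5))
    d <- small_design(S = runif(1, 10, 40), WS = p$WS0, E = runif(1, 5, 25),
                      P = runif(1, 0, 10), horizon = 30)
    df <- simulate_release(d, p)$states
    m <- df$V_L * (df$P_gL / p$nu + df$S_gL)
    expect_lt(max(abs(m / m[1] - 1)), 1e-7)
  }
})

test_that("glucose rises and substrate falls monotonically between events", {
  d <- small_design(S = 30, E = 20, horizon = 30)
  df <- simulate_release(d, ref_params())$states
  expect_true(all(diff(df$P_gL) >= -1e-10))
  expect_true(all(diff(df$S_gL) <= 1e-10))
  expect_true(all(df$WS >= 0 & df$WS <= 1))
})

test_that("two-substrate model with equal constants reduces to simple MM", {
  k <- 0.09
  p2 <- ref_params(kS = k, kR = k, WS0 = 0.37)
  p1 <- ref_params(k_single = k)
  d <- small_design(S = 25, WS = 0.37, E = 12, horizon = 20)
  t2 <- simulate_release(d, p2, "two_substrate")$states
  t1 <- simulate_release(d, p1, "simple_mm")$states
  expect_equal(t2$P_gL, t1$P_gL, tolerance = 1e-8)
  expect_equal(t2$S_gL, t1$S_gL, tolerance = 1e-8)
})

test_that("closed-form limits: zero-order release and first-order decay", {
  # WS0 = 1, S >> K: P grows linearly at nu kS E
  p <- ref_params(r_evap = 0)
  d <- small_design(S = 30, WS = 1, E = 10, horizon = 1)
  df <- simulate_release(d, p, times = c(0, 1))$states
  expect_equal(diff(df$P_gL), p$nu * p$kS * 10, tolerance = 1e-3)
  expect_equal(diff(df$P_gL), 1.489, tolerance = 1e-3)
  # S << K: exponential decay of S at rate k E / K (single substrate)
  p1 <- ref_params(k_single = 0.1, K = 5, r_evap = 0)
  dd <- small_design(S = 0.01, WS = 1, E = 2, horizon = 10)
  df1 <- simulate_release(dd, p1, "simple_mm", times = c(0, 5))$states
  lambda <- 0.1 * 2 / 5  # k E / K
  expect_equal(df1$S_gL[2] / df1$S_gL[1], exp(-lambda * 5), tolerance = 1e-3)
})
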