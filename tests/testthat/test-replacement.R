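test_that("dg_pmf matches closed-form cases and rejects bad inputs", {
  expect_equal(dg_pmf(1, 4, 1, 1), rep(0.25, 4))
  expect_equal(dg_pmf(3, 3, 4, 1.5), 1)
  # frozen from direct evaluation of h^3 * (5 - h)^0.5 normalized over h = 1..4
  expect_equal(dg_pmf(1, 4, 4, 1.5),
               c(0.01694338423, 0.11738720937, 0.32348111095, 0.54218829544),
               tolerance = 1e-9)
  expect_equal(sum(dg_pmf(1, 10, 2.3, 0.7)), 1, tolerance = 1e-12)
  expect_error(dg_pmf(4, 3, 1, 1), "empty support")
  expect_error(dg_pmf(1, 4, 0, 1), "must be > 0")
  expect_error(dg_pmf(1, 4, 1, -2), "must be > 0")
})

test_that("scenario_params returns canonical shapes and rejects unknown names", {
  p <- scenario_params("uninformative", 0.25)
  expect_equal(c(p$gamma, p$delta, p$pi), c(1, 1, 0.25))
  p <- scenario_params("extreme", 1)
  expect_equal(c(p$gamma, p$delta, p$pi), c(1.5, 4, 1))
  p <- scenario_params("slight", 0.5)
  expect_equal(c(p$gamma, p$delta), c(4, 1.5))
  # forward swaps the shape pair so the scenario keeps its meaning
  pf <- scenario_params("slight", 0.5, direction = "forward")
  expect_equal(c(pf$gamma, pf$delta), c(1.5, 4))
  expect_error(scenario_params("moderate", 0.5), "unknown scenario")
  expect_error(replacement_params(1, 1, 1.2), "probability")
})

test_that("replacement_pmf honors the boundary and retention cases", {
  p <- scenario_params("slight", 0.7)
  expect_equal(replacement_pmf(1, p, 5), c(1, 0, 0, 0, 0))
  p0 <- scenario_params("extreme", 0)
  pm <- replacement_pmf(4, p0, 5)
  expect_equal(pm, c(0, 0, 0, 1, 0))
  pu <- replacement_pmf(5, scenario_params("uninformative", 0.6), 5)
  expect_equal(pu, c(0.15, 0.15, 0.15, 0.15, 0.40))
  # forward absorbing top, mass only above k
  pf <- replacement_pmf(5, scenario_params("slight", 0.9, "forward"), 5)
  expect_equal(pf, c(0, 0, 0, 0, 1))
  pf2 <- replacement_pmf(2, scenario_params("slight", 0.4, "forward"), 5)
  expect_equal(pf2[1], 0)
  expect_equal(pf2[2], 0.6)
  expect_equal(sum(pf2), 1, tolerance = 1e-12)
  expect_error(replacement_pmf(0, p, 5), "integer in")
  expect_error(replacement_pmf(6, p, 5), "integer in")
})

test_that("replacement_pmf normalizes and retains 1 - pi across the full grid", {
  for (q in 2:7) for (sc in all_scenarios) for (pi in c(0, 0.25, 0.5, 0.75, 1)) {
    for (k in 1:q) for (dir in c("reverse", "forward")) {
      pm <- replacement_pmf(k, scenario_params(sc, pi, dir), q)
      expect_equal(sum(pm), 1, tolerance = 1e-12)
      absorbing <- (dir == "reverse" && k == 1) || (dir == "forward" && k == q)
      if (!absorbing) expect_identical(pm[k], 1 - pi)
    }
  }
})

test_that("slight concentrates adjacent to k, extreme far from k", {
  for (k in 3:5) {
    ps <- replacement_pmf(k, scenario_params("slight", 0.8), 5)[1:(k - 1)]
    expect_true(all(diff(ps) > 0))  # increasing toward k
    pe <- replacement_pmf(k, scenario_params("extreme", 0.8), 5)[1:(k - 1)]
    expect_true(all(diff(pe) < 0))  # decreasing away from 1... i.e. mass far from k
  }
})

test_that("forward pmf is the exact reflection of the reverse pmf", {
  # analytic mirror identity: P_fwd(h | k) = P_rev(q + 1 - h | q + 1 - k)
  for (q in c(4, 5, 7)) for (sc in all_scenarios) for (k in 1:q) {
    fwd <- replacement_pmf(k, scenario_params(sc, 0.6, "forward"), q)
    rev_ <- replacement_pmf(q + 1 - k, scenario_params(sc, 0.6, "reverse"), q)
    expect_equal(fwd, rev(rev_), tolerance = 1e-12)
  }
})

test_that("perturb_matrix is the identity at pi = 0 and on absorbing input", {
  f <- random_ordinal(40, 8, 5, seed = 11)
  out <- perturb_matrix(f, scenario_params("slight", 0), seed = 2)
  expect_identical(unclass(out), unclass(f))
  ones <- ordinal_matrix(matrix(1L, 30, 4), q = 5)
  out <- perturb_matrix(ones, scenario_params("extreme", 1), seed = 3)
  expect_true(all(out == 1L))
})

test_that("perturb_matrix respects direction ordering and seed determinism", {
  for (seed in 1:10) {
    f <- random_ordinal(25, 6, 5, seed = seed)
    d <- perturb_matrix(f, scenario_params("extreme", 0.7), seed = seed + 100)
    expect_true(all(d <= f))
    g <- perturb_matrix(f, scenario_params("extreme", 0.7, "forward"), seed = seed + 100)
    expect_true(all(g >= f))
  }
  f <- random_ordinal(50, 10, 5, seed = 42)
  p <- scenario_params("slight", 0.5)
  expect_identical(perturb_matrix(f, p, seed = 7), perturb_matrix(f, p, seed = 7))
})

test_that("empirical replacement frequencies match the pmf", {
  # uniform case: 1200 draws from a matrix of 5s at pi = 1; each lower
  # category should be ~0.25 within 3 binomial standard errors
  f <- ordinal_matrix(matrix(5L, 100, 12), q = 5)
  d <- perturb_matrix(f, replacement_params(1, 1, 1), seed = 99)
  freqs <- tabulate(as.integer(d), nbins = 5) / 1200
  se <- sqrt(0.25 * 0.75 / 1200)
  expect_true(all(abs(freqs[1:4] - 0.25) < 3 * se))
  expect_equal(freqs[5], 0)
  # skewed case: goodness-of-fit against the analytic pmf on 2e4 draws
  f <- ordinal_matrix(matrix(4L, 200, 100), q = 5)
  p <- scenario_params("slight", 0.6)
  d <- perturb_matrix(f, p, seed = 123)
  counts <- tabulate(as.integer(d), nbins = 5)
  gof <- suppressWarnings(stats::chisq.test(counts[replacement_pmf(4, p, 5) > 0],
                                            p = replacement_pmf(4, p, 5)[replacement_pmf(4, p, 5) > 0]))
  expect_gt(gof$p.value, 0.01)
})
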