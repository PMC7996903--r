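test_that("DVH has the right shape for enumerable fields", {
  # uniform field: full volume up to the dose, nothing above
  d <- compute_dvh(rep(5, 10), n_bins = 10)
  expect_equal(d$volume_fraction[d$dose < 5], rep(1, sum(d$dose < 5)))
  expect_equal(d$volume_fraction[d$dose == 5], 1)  # >= threshold
  expect_equal(d$volume_fraction[1], 1)

  # two voxels at 2 and 4 Gy
  d2 <- compute_dvh(c(2, 4), n_bins = 8)
  at <- function(x) d2$volume_fraction[which.min(abs(d2$dose - x))]
  expect_equal(at(1), 1)
  expect_equal(at(3), 0.5)
  expect_equal(d2$volume_fraction[d2$dose > 2 & d2$dose <= 4],
               rep(0.5, sum(d2$dose > 2 & d2$dose <= 4)))
})

test_that("DVH equals brute-force thresholding on a random 1000-voxel field", {
  set.seed(21)
  doses <- rgamma(1000, shape = 4, scale = 2)
  dvh <- compute_dvh(doses, n_bins = 64)
  for (i in seq_len(nrow(dvh))) {
    n_ge <- 0
    for (d in doses) if (d >= dvh$dose[i]) n_ge <- n_ge + 1
    expect_equal(dvh$volume_fraction[i],
                 if (i == 1) 1 else n_ge / 1000)
  }
  expect_true(all(diff(dvh$volume_fraction) <= 0))
  expect_error(compute_dvh(doses, mask = rep(FALSE, 1000)), "empty")
})

test_that("Poisson-LQ TCP matches hand computation and limits", {
  p <- tcp_params(alpha = 0.3, beta = 0.03, clonogen_density = 1e5)
  # no dose: exp(-rho V)
  expect_equal(tcp(rep(0, 4), p, voxel_volume = 0.5),
               exp(-1e5 * 2))
  # saturating dose
  expect_equal(tcp(rep(1e4, 4), p, voxel_volume = 0.5), 1)
  # 3-voxel toy case, term-by-term oracle
  d <- c(5, 10, 20)
  v <- 0.2
  oracle <- exp(-sum(1e5 * v * exp(-0.3 * d - 0.03 * d^2)))
  expect_equal(tcp(d, p, voxel_volume = v), oracle)
  # monotone non-decreasing in every voxel dose
  expect_gte(tcp(c(6, 10, 20), p, v), tcp(c(5, 10, 20), p, v))
})

test_that("TCP is invariant under voxel subdivision and matches the uniform closed form", {
  p <- tcp_params()
  expect_equal(tcp(c(12, 25), p, voxel_volume = 1),
               tcp(c(12, 12, 25, 25), p, voxel_volume = 0.5))
  # uniform dose: single-voxel closed form
  D <- 18
  V <- 33.5
  closed <- exp(-p$clonogen_density * V *
                  exp(-p$alpha * D - p$beta * D^2))
  expect_equal(tcp(rep(D, 67), p, voxel_volume = V / 67), closed)
})

test_that("logistic NTCP hits its midpoint, tails and slope convention", {
  p <- ntcp_params(d50 = 8, gamma50 = 1)
  expect_equal(ntcp(8, p), 0.5)
  expect_equal(ntcp(0, p), 1 / (1 + exp(4)))
  expect_equal(ntcp(1e6, p), 1, tolerance = 1e-9)
  doses <- seq(0, 30, by = 0.5)
  expect_true(all(diff(ntcp(doses, p)) > 0))
})

test_that("UTCP is the product with the complication complement", {
  expect_equal(utcp(0.58, 0.18), 0.58 * 0.82)
  expect_equal(utcp(0.54, 0.17), 0.4482)
  expect_equal(utcp(0.9, 1), 0)
  expect_equal(utcp(0, 0.2), 0)
  expect_error(utcp(1.2, 0.1))
  expect_error(utcp(0.5, -0.1))
})

test_that("time to reach a dose limit is the plain quotient", {
  expect_equal(time_for_dose_limit(0.25, 6), 24)
  expect_equal(time_for_dose_limit(6, 6), 1)
  set.seed(8)
  r <- runif(20, 0.01, 2)
  l <- runif(20, 1, 10)
  expect_equal(time_for_dose_limit(r, l), l / r)
  expect_error(time_for_dose_limit(0, 6), "positive")
})

test_that("the time optimizer matches exhaustive grid search", {
  p_t <- tcp_params(clonogen_density = 1e6)
  p_n <- ntcp_params(d50 = 8, gamma50 = 1.5)
  rates <- c(0.6, 0.8, 1.0)
  hrate <- 0.25
  v <- 4
  f <- function(t) utcp(tcp(rates * t, p_t, v), ntcp(hrate * t, p_n))
  ts <- seq(0, 120, by = 0.5)
  us <- vapply(ts, f, numeric(1))
  res <- optimize_time(rates, hrate, p_t, p_n, v, refine = FALSE)
  expect_equal(res$t_irr, ts[which.max(us)])
  expect_equal(res$utcp, max(us))
  # refinement can only improve, and stays consistent with the model
  res2 <- optimize_time(rates, hrate, p_t, p_n, v, refine = TRUE)
  expect_gte(res2$utcp, res$utcp)
  expect_equal(res2$utcp, f(res2$t_irr))
  expect_equal(res2$d_max_healthy, hrate * res2$t_irr)
})

test_that("degenerate outcome curves drive the optimum to the bracket ends", {
  v <- 1
  # no complication risk anywhere: TCP monotone, go to the upper end
  res_hi <- optimize_time(c(0.5, 0.7), healthy_rate = 0.2,
                          tcp_params(), ntcp_params(d50 = 1e9),
                          voxel_volume = v, t_range = c(0, 60))
  expect_equal(res_hi$t_irr, 60)
  # tumor control saturated from the start: NTCP monotone, stay low
  res_lo <- optimize_time(c(1e5, 1e5), healthy_rate = 0.2,
                          tcp_params(), ntcp_params(d50 = 8),
                          voxel_volume = v, t_range = c(5, 60))
  expect_equal(res_lo$t_irr, 5)
  expect_equal(res_lo$tcp, 1)
  # all-zero tumor rates flag the flat case
  expect_warning(
    res0 <- optimize_time(c(0, 0), healthy_rate = 0.2,
                          tcp_params(), ntcp_params(),
                          voxel_volume = v),
    "all-zero")
  expect_true(res0$flat_tumor_warning)
})

test_that("in-phantom evaluation produces a coherent outcome", {
  out <- evaluate_phantom_outcome(default_spectrum(),
                                  phantom = coarse_phantom,
                                  t_step = 1)
  expect_s3_class(out, "outcome_result")
  expect_true(out$utcp >= 0 && out$utcp <= 1)
  expect_equal(out$utcp, out$tcp * (1 - out$ntcp))
  expect_gt(out$t_irr, 0)
  expect_equal(sum(out$percent_dose), 100)
  # boron-capture dose dominates at the mucosal limiting point
  expect_gt(out$percent_dose[["boron"]], 50)
  expect_true(all(diff(out$dvh$volume_fraction) <= 0))
})

test_that("two identical half-weighted fields reproduce the single-field outcome", {
  sp <- default_spectrum()
  one <- evaluate_phantom_outcome(sp, phantom = coarse_phantom,
                                  t_step = 1)
  two <- evaluate_phantom_outcome(list(sp, sp),
                                  phantom = coarse_phantom, t_step = 1)
  expect_equal(two$t_irr, one$t_irr)
  expect_equal(two$utcp, one$utcp)
})
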