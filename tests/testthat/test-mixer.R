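test_that("mixing is the weighted average of expert distributions", {
  d1 <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(mix_distributions(rbind(d1), 1), d1) # single expert: identity
  expect_equal(mix_distributions(rbind(d1, rep(0.25, 4)), c(0.75, 0.25)),
               c(0.5875, 0.1375, 0.1375, 0.1375))
  expect_equal(mix_distributions(rbind(d1, c(0.1, 0.1, 0.1, 0.7)), c(0, 1)),
               c(0.1, 0.1, 0.1, 0.7)) # all weight on expert 2
  # repeat-class worked case: q = 0.8 expert plus uniform at equal weight
  expect_equal(
    mix_distributions(rbind(c(0.8, 1 / 15, 1 / 15, 1 / 15), rep(0.25, 4)),
                      c(0.5, 0.5)),
    c(0.525, 1 / 30 + 0.125, 1 / 30 + 0.125, 1 / 30 + 0.125),
    tolerance = 1e-12)
  expect_error(mix_distributions(rbind(d1), c(0.5, 0.5)), "one weight per")
})

test_that("the forgetting-factor update reproduces worked examples", {
  # gamma = 0: weights track the last step only, w' proportional to P(true)
  expect_equal(update_mix_weights(c(0.5, 0.5), c(0, 0), c(0.8, 0.2)), c(0.8, 0.2))
  # sqrt(0.9) : sqrt(0.1) = 3 : 1
  expect_equal(update_mix_weights(c(0.9, 0.1), c(0.5, 0.5), c(0.5, 0.5)),
               c(0.75, 0.25))
  # full symmetry leaves weights unchanged
  expect_equal(update_mix_weights(c(0.5, 0.5), c(0.7, 0.7), c(0.3, 0.3)),
               c(0.5, 0.5))
})

test_that("updated weights are normalised, positive, and reward the better expert", {
  with_seed(11, {
    for (r in 1:30) {
      m <- sample(2:6, 1)
      w <- runif(m); w <- w / sum(w)
      g <- runif(m)
      p <- runif(m, 0.01, 1)
      w2 <- update_mix_weights(w, g, p)
      expect_equal(sum(w2), 1, tolerance = 1e-12)
      expect_true(all(w2 > 0))
      expect_equal(w2, o_mix_update(w, g, p), tolerance = 1e-14)
    }
    # monotonicity at equal priors and gammas
    w2 <- update_mix_weights(c(0.5, 0.5), c(0.8, 0.8), c(0.6, 0.4))
    expect_gt(w2[1], w2[2])
  })
})

test_that("gamma near one freezes weights; gamma zero makes them jump", {
  gam <- 0.999
  w <- c(0.7, 0.3)
  with_seed(12, {
    # likelihood log-ratios bounded by (1 - gamma): drift per step is O(1-gamma)
    for (r in 1:200) {
      p2 <- runif(1, 0.4, 0.6)
      p1 <- p2 * exp(runif(1, -(1 - gam), 1 - gam))
      w_new <- update_mix_weights(w, c(gam, gam), c(p1, p2))
      expect_lt(max(abs(w_new - w)), (1 - gam) * 2)
      w <- w_new
    }
  })
  jump <- update_mix_weights(c(0.999, 0.001), c(0, 0), c(0.1, 0.9))
  expect_equal(jump, c(0.1, 0.9)) # memoryless limit
})

test_that("preset forgetting factors follow the order-dependent bands", {
  for (lev in 1:15) {
    cfg <- level_preset(lev)
    ks <- vapply(cfg$cms, function(m) m$k, 0L)
    gs <- vapply(cfg$cms, function(m) m$gamma_pm / 1000, 0)
    expect_true(all(gs[ks <= 5] < 0.9))          # shallow models forget fast
    expect_true(all(gs[ks >= 10] >= 0.94))       # deep models remember
    if (lev >= 3) {
      expect_true(any(ks == 6))
      expect_true(all(gs[ks == 6] >= 0.75 & gs[ks == 6] <= 0.85))
    }
  }
})
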