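test_that("DIC components follow the deviance mean and half-variance", {
  expect_equal(compute_dic(c(10, 12)), list(dbar = 11, pv = 1, dic = 12))
  d <- compute_dic(rep(42.5, 20))
  expect_equal(d, list(dbar = 42.5, pv = 0, dic = 42.5))
  # adding a constant shifts dbar and dic, leaves pv unchanged
  set.seed(2)
  dev <- rnorm(500, 1000, 5)
  d1 <- compute_dic(dev)
  d2 <- compute_dic(dev + 123)
  expect_equal(d2$dbar, d1$dbar + 123)
  expect_equal(d2$pv, d1$pv)
  expect_equal(d2$dic, d1$dic + 123)
  expect_error(compute_dic(1), "at least 2")
})

test_that("bias and RMSE behave as moment summaries", {
  x <- c(0.2, -0.4, 1.1, 0.8)
  expect_equal(unlist(bias_rmse(x, x)[c("bias", "rmse")]),
               c(bias = 0, rmse = 0))
  br <- bias_rmse(x + 0.1, x)
  expect_equal(br$bias, 0.1)
  expect_equal(br$rmse, 0.1)
  br2 <- bias_rmse(x + c(0.1, -0.1, 0.1, -0.1), x)
  expect_equal(br2$bias, 0)
  expect_equal(br2$rmse, 0.1)
  # rmse^2 = bias^2 + variance of errors (population variance)
  set.seed(9)
  est <- rnorm(400); tru <- rnorm(400)
  br3 <- bias_rmse(est, tru)
  err <- est - tru
  expect_equal(br3$rmse^2, br3$bias^2 + mean((err - mean(err))^2),
               tolerance = 1e-10)
  # grouped averaging
  br4 <- bias_rmse(c(1, 2, 3, 4), c(0, 0, 0, 0), by = c("a", "a", "b", "b"))
  expect_equal(br4$bias, c(1.5, 3.5))
  expect_error(bias_rmse(1:3, 1:4), "equal length")
})

test_that("hit rate counts per-class correct assignments", {
  hr <- hit_rate(c(1, 2, 2, 2), c(1, 1, 2, 2))
  expect_equal(hr$hit_rate[1:2], c(0.5, 1.0))
  expect_true(all(is.na(hr$hit_rate[3:4])))  # absent classes undefined
  expect_equal(hr$n_true, c(2L, 2L, 0L, 0L))
  perfect <- hit_rate(rep(1:4, 5), rep(1:4, 5))
  expect_equal(perfect$hit_rate, rep(1, 4))
  # equals the diagonal of a confusion-matrix oracle
  set.seed(3)
  zt <- sample(1:4, 200, TRUE); zh <- ifelse(runif(200) < 0.8, zt,
                                             sample(1:4, 200, TRUE))
  cm <- table(factor(zt, 1:4), factor(zh, 1:4))
  oracle <- diag(cm) / rowSums(cm)
  expect_equal(hit_rate(zh, zt)$hit_rate, unname(oracle))
})

test_that("certainty averages the assigned-class probability", {
  Pz <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  ct <- certainty(Pz)
  expect_equal(ct$certainty[c(1, 4)], c(1, 1))
  expect_true(all(is.na(ct$certainty[2:3])))
  Pz2 <- rbind(c(0.8, 0.1, 0.05, 0.05), c(0.6, 0.2, 0.1, 0.1))
  expect_equal(certainty(Pz2)$certainty[1], 0.7)
  # argmax of a 4-simplex row is always at least 0.25
  set.seed(5)
  Pz3 <- matrix(rgamma(400, 1), 100)
  Pz3 <- Pz3 / rowSums(Pz3)
  ct3 <- certainty(Pz3)
  expect_true(all(ct3$certainty >= 0.25, na.rm = TRUE))
})

test_that("modal assignment takes the argmax with low-index ties", {
  expect_equal(modal_assignment(rbind(c(0.1, 0.2, 0.6, 0.1))), 3L)
  expect_equal(modal_assignment(rbind(rep(0.25, 4))), 1L)
  expect_equal(modal_assignment(rbind(c(0.5, 0.5, 0, 0))), 1L)
})

test_that("theta differences subtract per person and group by class", {
  fa <- structure(list(model = "mm", person = 1:3, n_persons = 3L,
                       eta_mean = cbind(c(1, 2, 3), 0, 0)),
                  class = "irtree_fit")
  fb <- structure(list(model = "0rs", person = 1:3, n_persons = 3L,
                       eta_mean = cbind(c(1.5, 2.5, 3.5), 0, 0)),
                  class = "irtree_fit")
  td <- theta_difference(fa, fb, z = c(1, 1, 2))
  expect_equal(td$theta_diff, rep(-0.5, 3))
  expect_equal(td$class, c(1L, 1L, 2L))
  expect_equal(theta_difference(fa, fa)$theta_diff, rep(0, 3))
  fb$person <- 4:6
  expect_error(theta_difference(fa, fb), "same persons")
})

test_that("rhat separates mixed from disjoint chains", {
  set.seed(8)
  base <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(compute_rhat(list(base, base))$rhat, 1, tolerance = 1e-3)
  mixed <- replicate(4, matrix(rnorm(1000), ncol = 1,
                               dimnames = list(NULL, "x")),
                     simplify = FALSE)
  expect_equal(compute_rhat(mixed)$rhat, 1, tolerance = 0.02)
  apart <- list(base, base + 10)
  expect_gt(compute_rhat(apart)$rhat, 1.1)
  expect_error(compute_rhat(list(base)), "2 chains")
})

test_that("summaries report means and SDs of pooled draws", {
  m <- cbind(a = c(1, 2, 3), b = rep(5, 3))
  s <- summarize_draws(m)
  expect_equal(s$mean, c(2, 5))
  expect_equal(s$sd[2], 0)
  set.seed(10)
  big <- matrix(rnorm(20000, 3, 2), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(summarize_draws(big)$mean, 3, tolerance = 3 * 2 / sqrt(20000))
  expect_error(summarize_draws(matrix(0, 0, 1)), "no draws")
})
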