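test_that("trait draws have the generating moments and correlations", {
  tr <- draw_person_traits(100000, seed = 2)
  eta <- as.matrix(tr[c("theta", "eta_ers", "eta_mrs")])
  expect_true(all(abs(colMeans(eta)) < 0.02))
  expect_true(all(abs(apply(eta, 2, var) - 1) < 0.03))
  S <- cor(eta)
  expect_equal(S[1, 2], 0.20, tolerance = 0.02)
  expect_equal(S[1, 3], 0.00, tolerance = 0.02)
  expect_equal(S[2, 3], -0.40, tolerance = 0.02)
  expect_identical(draw_person_traits(50, seed = 7),
                   draw_person_traits(50, seed = 7))
  expect_error(draw_person_traits(5, R = matrix(c(1, 2, 2, 1), 2)), "")
})

test_that("item parameters respect the generating supports and masks", {
  items <- draw_item_parameters(200, seed = 3)
  expect_true(all(items$omega == 0.50))
  expect_true(all(items$alpha_theta >= 0.75 & items$alpha_theta <= 1.75))
  free_ers <- items$alpha_ers[items$class %in% c(1, 3)]
  expect_true(all(free_ers >= 0.75 & free_ers <= 1.25))
  free_mrs <- items$alpha_mrs[items$class %in% c(2, 3)]
  expect_true(all(free_mrs >= 0.50 & free_mrs <= 0.75))
  expect_true(all(items$alpha_ers[items$class %in% c(2, 4)] == 0))
  expect_true(all(items$alpha_mrs[items$class %in% c(1, 4)] == 0))
  betas <- unlist(items[c("beta0", "beta1", "beta2")])
  expect_true(all(betas >= -2 & betas <= 2))
  # supports are filled out as J grows
  expect_lt(min(items$alpha_theta), 0.80)
  expect_gt(max(items$alpha_theta), 1.70)
  # difficulties differ between classes for the same item and node
  wide <- tidyr::pivot_wider(items[c("item", "class", "beta0")],
                             names_from = "class", values_from = "beta0")
  expect_false(any(wide$`1` == wide$`2`))
})

test_that("memberships are assigned in deterministic contiguous blocks", {
  z <- assign_memberships(2000, c(.25, .25, .25, .25))
  expect_identical(z, rep(1:4, each = 500))
  expect_identical(assign_memberships(2000, c(1, 0, 0, 0)), rep(1L, 2000))
  expect_identical(assign_memberships(10, c(.70, .10, .10, .10)),
                   rep(1:4, times = c(7, 1, 1, 1)))
  expect_identical(assign_memberships(10, c(.70, .10, .10, .10)),
                   assign_memberships(10, c(.70, .10, .10, .10)))
})

test_that("simulated response frequencies match the analytic probabilities", {
  # one person per class, many replicate items via repeated simulation
  persons <- data.frame(theta = c(0.3, -0.5, 1.1, 0),
                        eta_ers = c(1.2, 0.4, -0.3, 0.8),
                        eta_mrs = c(-0.2, 0.9, 0.5, -1))
  items <- random_items(5, seed = 8)
  z <- 1:4
  counts <- matrix(0, 20, 5)
  n_rep <- 1000  # 20 cells x 1000 draws = 2e4 per check, 1e5 total draws
  for (b in 1:n_rep) {
    r <- simulate_responses(persons, items, z, seed = 5000 + b)
    y <- as.matrix(r[-1])
    idx <- cbind(as.vector(row(y) + (col(y) - 1) * 4), as.vector(y))
    counts[idx] <- counts[idx] + 1
  }
  cp <- mixture_category_probabilities(persons, items, z)
  probs <- matrix(cp$prob, nrow = 20)
  freq <- counts / n_rep
  expect_true(all(abs(freq - probs) < 0.05))
  # chi-square goodness of fit per cell at alpha = 0.001
  pvals <- vapply(1:20, function(i) {
    suppressWarnings(chisq.test(counts[i, ], p = probs[i, ])$p.value)
  }, 0)
  expect_gt(min(pvals), 0.001)
  expect_true(all(as.matrix(r[-1]) %in% 1:5))
})

test_that("a strongly agreeing 0RS person mostly answers 4 or 5", {
  persons <- data.frame(theta = 6, eta_ers = 0, eta_mrs = 0)
  items <- random_items(20, seed = 13)
  hits <- vapply(1:50, function(b) {
    y <- as.matrix(simulate_responses(persons, items, 4L, seed = b)[-1])
    mean(y >= 4)
  }, 0)
  expect_gt(mean(hits), 0.95)
})

test_that("condition bundles are reproducible and share item parameters", {
  cond <- sim_condition("ers_dominated", n_persons = 40, n_items = 6,
                        n_replications = 3, master_seed = 99)
  b1 <- generate_condition(cond)
  b2 <- generate_condition(cond)
  expect_identical(b1, b2)
  expect_length(b1, 3)
  expect_identical(b1[[1]]$items, b1[[2]]$items)
  expect_identical(b1[[1]]$persons, b1[[3]]$persons)
  expect_false(identical(b1[[1]]$ratings, b1[[2]]$ratings))
  expect_identical(b1[[1]]$z, assign_memberships(40, c(.7, .1, .1, .1)))
  # redraw_persons regenerates traits per replication
  b3 <- generate_condition(cond, redraw_persons = TRUE)
  expect_false(identical(b3[[1]]$persons, b3[[2]]$persons))
  expect_error(sim_condition("no_such_condition"), "unknown condition")
})
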