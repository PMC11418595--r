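test_that("node probabilities match hand-evaluated logistic values", {
  items <- one_item_pars()
  person <- data.frame(theta = 1, eta_ers = 1, eta_mrs = 0)
  np <- node_probabilities(person, items, "2rs")
  # logistic at -1, -1, +0.5, +1.5
  expect_equal(np$p0, plogis(-1), tolerance = 1e-12)
  expect_equal(np$p1, plogis(-1), tolerance = 1e-12)
  expect_equal(np$p2_disagree, plogis(0.5), tolerance = 1e-12)
  expect_equal(np$p2_agree, plogis(1.5), tolerance = 1e-12)
  expect_equal(round(unlist(np[c("p0", "p1", "p2_disagree", "p2_agree")]), 4),
               c(p0 = 0.2689, p1 = 0.2689, p2_disagree = 0.6225,
                 p2_agree = 0.8176))

  zero <- data.frame(theta = 0, eta_ers = 0, eta_mrs = 0)
  np0 <- node_probabilities(zero, items, "2rs")
  expect_equal(unname(unlist(np0[c("p0", "p1", "p2_disagree", "p2_agree")])),
               rep(0.5, 4))
})

test_that("category probabilities are the tree-path products", {
  items <- one_item_pars()
  person <- data.frame(theta = 1, eta_ers = 1, eta_mrs = 0)
  cp <- category_probabilities(person, items, "2rs")
  expect_equal(round(cp$prob, 4), c(0.1674, 0.1015, 0.1966, 0.0975, 0.4369))
  expect_equal(sum(cp$prob), 1, tolerance = 1e-12)

  zero <- data.frame(theta = 0, eta_ers = 0, eta_mrs = 0)
  cp0 <- category_probabilities(zero, items, "2rs")
  expect_equal(cp0$prob, c(0.25, 0.25, 0.25, 0.125, 0.125))

  # limit: a huge trait value concentrates all mass on category 5
  hi <- data.frame(theta = 50, eta_ers = 0, eta_mrs = 0)
  cph <- category_probabilities(hi, items, "0rs")
  expect_gt(cph$prob[5], 0.999)
})

test_that("five category probabilities sum to 1 for random draws in every class", {
  set.seed(11)
  persons <- data.frame(theta = rnorm(250, 0, 2), eta_ers = rnorm(250, 0, 2),
                        eta_mrs = rnorm(250, 0, 2))
  items <- random_items(2, seed = 3)
  for (cl in 1:4) {
    cp <- category_probabilities(persons, items, cl)
    sums <- tapply(cp$prob, list(cp$person, cp$item), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(cp$prob > 0 & cp$prob < 1))
  }
})

test_that("inactive styles mask loadings exactly (class equivalences)", {
  persons <- random_persons(40, seed = 5)
  items <- random_items(3, seed = 6)
  a <- mmirtree:::items_arrays(items)
  # force identical free parameters in all classes, differing only in masks
  a$aers[, c(1, 3)] <- a$aers[, 1]
  a$amrs[, c(2, 3)] <- a$amrs[, 2]
  a$beta[, , 1:4] <- a$beta[, , 1]
  a$aers[, c(2, 4)] <- 0
  a$amrs[, c(1, 4)] <- 0
  items_eq <- mmirtree:::arrays_to_items(a)
  p2rs <- category_probabilities(persons, items_eq, "2rs")$prob

  ers0 <- persons; ers0$eta_mrs <- 0
  expect_identical(category_probabilities(persons, items_eq, "ers")$prob,
                   category_probabilities(ers0, items_eq, "2rs")$prob)
  mrs0 <- persons; mrs0$eta_ers <- 0
  expect_identical(category_probabilities(persons, items_eq, "mrs")$prob,
                   category_probabilities(mrs0, items_eq, "2rs")$prob)
  both0 <- persons; both0$eta_ers <- 0; both0$eta_mrs <- 0
  expect_identical(category_probabilities(persons, items_eq, "0rs")$prob,
                   category_probabilities(both0, items_eq, "2rs")$prob)
})

test_that("monotonicity in the latent traits", {
  items <- random_items(1, seed = 9)
  grid <- seq(-2, 2, length.out = 9)
  # P(5) increases and P(1) decreases in theta
  pers <- data.frame(theta = grid, eta_ers = 0, eta_mrs = 0)
  cp <- category_probabilities(pers, items, "2rs")
  p <- matrix(cp$prob, nrow = 9)
  expect_true(all(diff(p[, 5]) > 0))
  expect_true(all(diff(p[, 1]) < 0))
  # P(3) increases in eta_mrs
  pers <- data.frame(theta = 0, eta_ers = 0, eta_mrs = grid)
  for (cl in c("mrs", "2rs")) {
    p <- matrix(category_probabilities(pers, items, cl)$prob, nrow = 9)
    expect_true(all(diff(p[, 3]) > 0))
  }
  # P(1) + P(5) increases in eta_ers
  pers <- data.frame(theta = 0, eta_ers = grid, eta_mrs = 0)
  for (cl in c("ers", "2rs")) {
    p <- matrix(category_probabilities(pers, items, cl)$prob, nrow = 9)
    expect_true(all(diff(p[, 1] + p[, 5]) > 0))
  }
})

test_that("mixture probabilities select the component of each membership", {
  persons <- random_persons(8, seed = 21)
  items <- random_items(2, seed = 22)
  z <- rep(c(4L, 3L), 4)
  mx <- mixture_category_probabilities(persons, items, z)
  for (cl in c(3L, 4L)) {
    direct <- category_probabilities(persons, items, cl)
    sel <- rep(z == cl, 2 * 5)
    expect_identical(mx$prob[sel], direct$prob[sel])
  }
  # class-specific difficulties: class 1 evaluation uses class-1 beta only
  a <- mmirtree:::items_arrays(items)
  a$beta[, , 2:4] <- a$beta[, , 2:4] + 5
  shifted <- mmirtree:::arrays_to_items(a)
  expect_identical(
    mixture_category_probabilities(persons, shifted, rep(1L, 8))$prob,
    category_probabilities(persons, items, 1)$prob)
  expect_error(mixture_category_probabilities(persons, items, rep(5L, 8)),
               "1..4")
})

test_that("log-likelihood matches a brute-force per-category oracle", {
  for (seed in 1:4) {
    persons <- random_persons(3, seed = seed)
    items <- random_items(2, seed = seed + 50)
    z <- c(1L, 3L, 4L)
    r <- simulate_responses(persons, items, z, seed = seed + 100)
    ll <- log_likelihood(r, persons, items, z)
    # oracle: enumerate the 5 category probabilities of every cell directly
    # from the node models and pick the observed one
    y <- as.matrix(r[-1])
    manual <- 0
    for (p in 1:3) {
      np <- node_probabilities(persons[p, ], items, z[p])
      for (j in 1:2) {
        with_np <- np[j, ]
        probs <- c(with_np$p0 * with_np$p2_disagree,
                   with_np$p0 * (1 - with_np$p2_disagree),
                   (1 - with_np$p0) * with_np$p1,
                   (1 - with_np$p0) * (1 - with_np$p1) * (1 - with_np$p2_agree),
                   (1 - with_np$p0) * (1 - with_np$p1) * with_np$p2_agree)
        manual <- manual + log(probs[y[p, j]])
      }
    }
    expect_equal(ll, manual, tolerance = 1e-10)
  }
})

test_that("log-likelihood equals the Bernoulli sum over observed pseudo-items", {
  persons <- random_persons(6, seed = 31)
  items <- random_items(3, seed = 32)
  z <- rep(1:3, 2)
  r <- simulate_responses(persons, items, z, seed = 33)
  ll <- log_likelihood(r, persons, items, z)
  tab <- decompose_responses(r)
  bern <- 0
  for (p in 1:6) {
    np <- node_probabilities(persons[p, ], items, z[p])
    for (j in 1:3) {
      nm <- paste0("item", j)
      y0 <- tab[[paste0(nm, "_node0")]][p]
      y1 <- tab[[paste0(nm, "_node1")]][p]
      y2 <- tab[[paste0(nm, "_node2")]][p]
      bern <- bern + dbinom(y0, 1, np$p0[j], log = TRUE)
      if (!is.na(y1)) bern <- bern + dbinom(y1, 1, np$p1[j], log = TRUE)
      if (!is.na(y2)) {
        p2 <- if (y0 == 1) np$p2_disagree[j] else np$p2_agree[j]
        bern <- bern + dbinom(y2, 1, p2, log = TRUE)
      }
    }
  }
  expect_equal(ll, bern, tolerance = 1e-10)
})

test_that("simple closed forms: one response, all-zero parameters", {
  items <- one_item_pars()
  person <- data.frame(theta = 0, eta_ers = 0, eta_mrs = 0)
  r <- data.frame(i1 = 3L)
  expect_equal(log_likelihood(r, person, items, 4L), log(0.25))
  # mean per-observation likelihood is a probability
  persons <- random_persons(10, seed = 41)
  items2 <- random_items(4, seed = 42)
  r2 <- simulate_responses(persons, items2, rep(2L, 10), seed = 43)
  ll <- log_likelihood(r2, persons, items2, rep(2L, 10))
  expect_true(exp(ll / 40) > 0 && exp(ll / 40) < 1)
})
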