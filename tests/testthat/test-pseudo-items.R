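test_that("decomposition follows the node coding for every category", {
  ratings <- data.frame(i1 = 1:5)
  tab <- decompose_responses(ratings)
  expect_equal(tab$i1_node0, c(1L, 1L, 0L, 0L, 0L))
  expect_equal(tab$i1_node1, c(NA, NA, 1L, 0L, 0L))
  expect_equal(tab$i1_node2, c(1L, 0L, NA, 0L, 1L))
})

test_that("missingness is a pure function of the response value", {
  set.seed(4)
  r <- as_ratings(data.frame(a = sample(1:5, 50, TRUE),
                             b = sample(1:5, 50, TRUE)))
  tab <- decompose_responses(r)
  for (it in c("a", "b")) {
    expect_identical(is.na(tab[[paste0(it, "_node1")]]), r[[it]] <= 2)
    expect_identical(is.na(tab[[paste0(it, "_node2")]]), r[[it]] == 3)
    expect_false(anyNA(tab[[paste0(it, "_node0")]]))
  }
})

test_that("recomposition inverts decomposition on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    r <- as_ratings(as.data.frame(matrix(sample(1:5, 60, TRUE), 12, 5)))
    expect_identical(recompose_responses(decompose_responses(r)), r)
  }
})

test_that("recompose maps the coding table rows back to categories", {
  tab <- tibble::tibble(
    i1_node0 = c(0L, 1L, 0L), i1_node1 = c(1L, NA, 0L),
    i1_node2 = c(NA, 0L, 0L))
  expect_equal(recompose_responses(tab)$i1, c(3L, 2L, 4L))
})

test_that("invalid responses and inconsistent patterns are rejected", {
  expect_error(decompose_responses(data.frame(i1 = c(1, 6))), "person 2")
  expect_error(decompose_responses(data.frame(i1 = c(2.5))), "invalid response")
  bad <- tibble::tibble(i1_node0 = 1L, i1_node1 = 1L, i1_node2 = 1L)
  expect_error(recompose_responses(bad), "inconsistent")
})
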