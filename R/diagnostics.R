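# Convergence diagnostics and posterior summaries.

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed per scalar parameter from two or more chains of equal length:
#' with within-chain variance W and between-chain variance B, the pooled
#' variance estimate is `(n-1)/n W + (1 + 1/m) B/n` and Rhat its square
#' root over W. Identical chains give values of 1 up to the finite-sample
#' factor `(n-1)/n`.
#'
#' @param chains A list of numeric matrices (iterations x parameters, equal
#'   shapes, named columns) or a list of numeric vectors for a single
#'   parameter.
#' @return A tibble with columns `term` and `rhat`.
#' @export
compute_rhat <- function(chains) {
  if (is.list(chains) && !is.data.frame(chains) && is.numeric(chains[[1]]) &&
      is.null(dim(chains[[1]]))) {
    chains <- lapply(chains, function(v) matrix(v, ncol = 1,
                                                dimnames = list(NULL, "x")))
  }
  m <- length(chains)
  if (m < 2) stop("at least 2 chains are required", call. = FALSE)
  n <- nrow(chains[[1]])
  if (n < 10) stop("need at least 10 draws per chain", call. = FALSE)
  stopifnot(all(vapply(chains, nrow, 0L) == n))
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(chains, function(ch) apply(ch, 2, var),
                 numeric(ncol(chains[[1]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B_n <- apply(means, 1, var)  # = B/n
  vplus <- (n - 1) / n * W + (1 + 1 / m) * B_n
  rhat <- sqrt(vplus / W)
  rhat[W == 0 & B_n == 0] <- 1  # constant (e.g. structurally fixed) parameter
  tibble::tibble(term = colnames(chains[[1]]), rhat = unname(rhat))
}

#' Posterior means and standard deviations
#'
#' Pooled post-burn-in summaries of all monitored scalar parameters. Class
#' memberships are not summarised here — they are classified by
#' [modal_assignment()] from posterior class probabilities instead of
#' posterior expectations.
#'
#' @param draws An `irtree_fit`, a list of draw matrices, or one matrix.
#' @return A tibble with columns `term`, `mean`, `sd`.
#' @export
summarize_draws <- function(draws) {
  if (inherits(draws, "irtree_fit")) draws <- draws$draws
  if (is.list(draws) && !is.data.frame(draws)) draws <- do.call(rbind, draws)
  draws <- as.matrix(draws)
  if (nrow(draws) == 0) stop("no draws to summarise", call. = FALSE)
  tibble::tibble(term = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
                 mean = unname(colMeans(draws)),
                 sd = unname(apply(draws, 2, sd)))
}

#' Posterior class-membership probabilities
#'
#' For each respondent, the probability of belonging to each class is the
#' proportion of post-burn-in MCMC iterations in which the sampler assigned
#' that respondent to the class. Rows sum to 1.
#'
#' @param fit An `irtree_fit` of the mixture model.
#' @return A tibble with columns `person`, `p_ers`, `p_mrs`, `p_2rs`,
#'   `p_0rs`.
#' @export
posterior_class_probabilities <- function(fit) {
  stopifnot(inherits(fit, "irtree_fit"))
  if (fit$model != "mm") {
    stop("class probabilities are only defined for the mixture model",
         call. = FALSE)
  }
  pz <- fit$pz
  tibble::tibble(person = fit$person, p_ers = pz[, 1], p_mrs = pz[, 2],
                 p_2rs = pz[, 3], p_0rs = pz[, 4])
}

pz_matrix <- function(Pz) {
  if (inherits(Pz, "irtree_fit")) Pz <- posterior_class_probabilities(Pz)
  if (is.data.frame(Pz)) {
    Pz <- as.matrix(Pz[setdiff(names(Pz), "person")])
  }
  Pz <- as.matrix(Pz)
  stopifnot(ncol(Pz) == 4, all(Pz >= 0))
  Pz
}

#' Modal class assignment
#'
#' Assigns each respondent to the class with the highest posterior class
#' probability; exact ties are broken towards the lowest class index.
#'
#' @param Pz A matrix or tibble of posterior class probabilities (one row
#'   per person, four class columns), or a mixture `irtree_fit`.
#' @return Integer vector of class indices (1 = "ERS only", 2 = "MRS only",
#'   3 = "2RS", 4 = "0RS").
#' @export
modal_assignment <- function(Pz) {
  Pz <- pz_matrix(Pz)
  unname(apply(Pz, 1, which.max))  # which.max takes the first maximum
}

#' Posterior-mean person-parameter estimates
#'
#' @param fit An `irtree_fit`.
#' @return A tibble with `person`, posterior means `theta`, `eta_ers`,
#'   `eta_mrs` and their posterior SDs (`*_sd`). Traits outside the fitted
#'   model (e.g. the MRS trait under the "ers" model) are reported as 0.
#' @export
person_estimates <- function(fit) {
  stopifnot(inherits(fit, "irtree_fit"))
  tibble::tibble(
    person = fit$person,
    theta = fit$eta_mean[, 1], eta_ers = fit$eta_mean[, 2],
    eta_mrs = fit$eta_mean[, 3],
    theta_sd = fit$eta_sd[, 1], eta_ers_sd = fit$eta_sd[, 2],
    eta_mrs_sd = fit$eta_sd[, 3]
  )
}

#' @rdname glance.irtree_fit
#' @method tidy irtree_fit
#' @export
tidy.irtree_fit <- function(x, ...) x$summary

#' Broom-style accessors for fitted IRTree models
#'
#' `tidy()` returns the posterior summary of all monitored scalar
#' parameters; `glance()` a one-row model overview.
#'
#' @param x An `irtree_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method glance irtree_fit
#' @export
glance.irtree_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n_persons = x$n_persons, n_items = x$n_items,
    chains = x$chains, iterations = x$iterations, burnin = x$burnin,
    dic = x$dic$dic, dbar = x$dic$dbar, pv = x$dic$pv,
    max_rhat = max(x$summary$rhat, na.rm = TRUE), converged = x$converged,
    runtime = x$runtime
  )
}
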