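# DIC model comparison and the recovery / classification metrics.

#' Deviance information criterion
#'
#' `DIC = Dbar + pV`, where `Dbar` is the posterior mean of the deviance
#' and the effective number of parameters `pV` is half the posterior
#' variance of the deviance (sample variance, n-1 denominator). The
#' deviance draws are `-2 log` mixture likelihood evaluated at each
#' iteration's sampled parameters and memberships.
#'
#' @param deviance Numeric vector of post-burn-in deviance draws, or an
#'   `irtree_fit`.
#' @return A list with elements `dbar`, `pv`, `dic`.
#' @export
compute_dic <- function(deviance) {
  if (inherits(deviance, "irtree_fit")) return(deviance$dic)
  deviance <- as.numeric(deviance)
  if (length(deviance) < 2) stop("need at least 2 deviance draws", call. = FALSE)
  dbar <- mean(deviance)
  pv <- var(deviance) / 2
  list(dbar = dbar, pv = pv, dic = dbar + pv)
}

#' Compare fitted models by DIC
#'
#' @param fits A named list of `irtree_fit` objects estimated on the same
#'   data (names default to the model codes).
#' @return A tibble with one row per model (`model`, `dic`, `dbar`, `pv`,
#'   `best` flag), sorted as given; the model with the smallest DIC is
#'   marked best. An attribute `"best"` carries its name.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "irtree_fit")))
  np <- vapply(fits, `[[`, 0L, "n_persons")
  ni <- vapply(fits, `[[`, 0L, "n_items")
  if (length(unique(np)) > 1 || length(unique(ni)) > 1) {
    stop("fits were not estimated on the same data", call. = FALSE)
  }
  nm <- names(fits) %||% vapply(fits, `[[`, "", "model")
  if (is.null(names(fits))) names(fits) <- nm
  tab <- tibble::tibble(
    model = nm,
    dic = vapply(fits, function(f) f$dic$dic, 0),
    dbar = vapply(fits, function(f) f$dic$dbar, 0),
    pv = vapply(fits, function(f) f$dic$pv, 0)
  )
  tab$best <- tab$dic == min(tab$dic)
  attr(tab, "best") <- tab$model[which.min(tab$dic)]
  tab
}

#' Bias and RMSE of parameter estimates
#'
#' `bias = mean(estimate - truth)`, `rmse = sqrt(mean((estimate -
#' truth)^2))`, averaged over whatever the inputs span (items, nodes,
#' replications). With `by` given, the averages are computed within groups.
#'
#' @param estimate,truth Aligned numeric vectors.
#' @param by Optional grouping vector (e.g. parameter block or class).
#' @return A tibble with columns `by` (if given), `bias`, `rmse`, `n`.
#' @export
bias_rmse <- function(estimate, truth, by = NULL) {
  if (length(estimate) != length(truth)) {
    stop("estimate and truth must have equal length", call. = FALSE)
  }
  err <- estimate - truth
  df <- tibble::tibble(err = err,
                       by = if (is.null(by)) "all" else as.character(by))
  out <- dplyr::summarise(dplyr::group_by(df, .data$by),
                          bias = mean(.data$err),
                          rmse = sqrt(mean(.data$err^2)),
                          n = dplyr::n(), .groups = "drop")
  if (is.null(by)) out$by <- NULL
  out
}

#' Per-class hit rate of the classification
#'
#' Proportion of respondents whose modal class equals their true class,
#' per true class. Classes absent from `z_true` are reported with `NA`.
#'
#' @param z_hat,z_true Integer class vectors (1–4) of equal length.
#' @return A tibble with columns `class`, `label`, `n_true`, `hit_rate`.
#' @export
hit_rate <- function(z_hat, z_true) {
  stopifnot(length(z_hat) == length(z_true),
            all(z_hat %in% 1:4), all(z_true %in% 1:4))
  tibble::tibble(
    class = 1:4, label = CLASS_LABELS,
    n_true = vapply(1:4, function(c0) sum(z_true == c0), 0L),
    hit_rate = vapply(1:4, function(c0) {
      n <- sum(z_true == c0)
      if (n == 0) NA_real_ else sum(z_hat == c0 & z_true == c0) / n
    }, 0)
  )
}

#' Classification certainty per assigned class
#'
#' Mean posterior probability of the assigned class across the members
#' assigned to it. Always at least 0.25 for four classes; classes with no
#' assigned members are reported with `NA`.
#'
#' @param Pz Posterior class probabilities (matrix, tibble or mixture fit).
#' @param z_hat Modal assignments; computed from `Pz` when omitted.
#' @return A tibble with columns `class`, `label`, `n_assigned`,
#'   `certainty`.
#' @export
certainty <- function(Pz, z_hat = NULL) {
  Pz <- pz_matrix(Pz)
  if (is.null(z_hat)) z_hat <- modal_assignment(Pz)
  stopifnot(length(z_hat) == nrow(Pz))
  own <- Pz[cbind(seq_len(nrow(Pz)), z_hat)]
  tibble::tibble(
    class = 1:4, label = CLASS_LABELS,
    n_assigned = vapply(1:4, function(c0) sum(z_hat == c0), 0L),
    certainty = vapply(1:4, function(c0) {
      if (!any(z_hat == c0)) NA_real_ else mean(own[z_hat == c0])
    }, 0)
  )
}

#' Per-person difference in substantive-trait estimates between two fits
#'
#' Computes `theta(fit_a) - theta(fit_b)` per person — e.g. mixture-model
#' estimates minus single-class estimates — optionally grouped by a class
#' assignment.
#'
#' @param fit_a,fit_b Two `irtree_fit` objects on the same persons.
#' @param z Optional class vector for grouping summaries.
#' @return A tibble with columns `person`, `theta_a`, `theta_b`,
#'   `theta_diff` and, when `z` is given, `class`.
#' @export
theta_difference <- function(fit_a, fit_b, z = NULL) {
  stopifnot(inherits(fit_a, "irtree_fit"), inherits(fit_b, "irtree_fit"))
  if (fit_a$n_persons != fit_b$n_persons ||
      !identical(fit_a$person, fit_b$person)) {
    stop("fits are not on the same persons", call. = FALSE)
  }
  out <- tibble::tibble(
    person = fit_a$person,
    theta_a = fit_a$eta_mean[, 1], theta_b = fit_b$eta_mean[, 1],
    theta_diff = fit_a$eta_mean[, 1] - fit_b$eta_mean[, 1]
  )
  if (!is.null(z)) out$class <- as.integer(z)
  out
}
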