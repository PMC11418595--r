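# Node and category probabilities for the five response models. Each node
# is a 2PL Bernoulli: P(endorse) = g^-1(linear predictor), with g^-1 the
# logistic link by default (probit available). The linear predictors are
#
#   disagreement:  -alpha_theta*theta - alpha_mrs*eta_mrs - beta0
#   neutrality:    -alpha_theta*theta + alpha_mrs*eta_mrs - beta1
#   extremity:     +/- omega*alpha_theta*theta + alpha_ers*eta_ers - beta2
#
# with the sign of the substantive trait at the extremity node negative on
# the disagreement branch and positive on the agreement branch. A class's
# inactive response styles have zero loadings, so its node probabilities are
# those of the 2RS model with the corresponding loadings masked.

LP_CLIP <- 35

inv_link <- function(x, link = "logit") {
  x <- pmin(pmax(x, -LP_CLIP), LP_CLIP)
  if (link == "logit") plogis(x) else pnorm(x)
}

# Internal vectorised kernel: P x J matrices of the four node-endorsement
# probabilities for persons with class indices `cl` (recycled if scalar).
node_prob_mats <- function(eta, a, cl, link = "logit") {
  P <- nrow(eta); J <- a$J
  cl <- rep_len(as.integer(cl), P)
  th <- eta[, 1]; ers <- eta[, 2]; mrs <- eta[, 3]
  ath <- matrix(a$ath, P, J, byrow = TRUE)
  aers <- matrix(a$aers[, cl], nrow = J)   # J x P
  amrs <- matrix(a$amrs[, cl], nrow = J)
  if (J == 1) {
    b0 <- matrix(a$beta[, 1, cl], 1); b1 <- matrix(a$beta[, 2, cl], 1)
    b2 <- matrix(a$beta[, 3, cl], 1)
  } else {
    b0 <- matrix(a$beta[, 1, ][, cl], nrow = J)
    b1 <- matrix(a$beta[, 2, ][, cl], nrow = J)
    b2 <- matrix(a$beta[, 3, ][, cl], nrow = J)
  }
  thm <- th * ath                       # P x J
  ersm <- t(aers) * ers                 # P x J
  mrsm <- t(amrs) * mrs
  list(
    p0 = inv_link(-thm - mrsm - t(b0), link),
    p1 = inv_link(-thm + mrsm - t(b1), link),
    p2d = inv_link(-a$omega * thm + ersm - t(b2), link),
    p2a = inv_link(a$omega * thm + ersm - t(b2), link)
  )
}

# Internal: P x J x 5 array of category probabilities.
cat_prob_array <- function(eta, a, cl, link = "logit") {
  np <- node_prob_mats(eta, a, cl, link)
  P <- nrow(np$p0); J <- ncol(np$p0)
  pr <- array(0, c(P, J, 5))
  pr[, , 1] <- np$p0 * np$p2d
  pr[, , 2] <- np$p0 * (1 - np$p2d)
  pr[, , 3] <- (1 - np$p0) * np$p1
  pr[, , 4] <- (1 - np$p0) * (1 - np$p1) * (1 - np$p2a)
  pr[, , 5] <- (1 - np$p0) * (1 - np$p1) * np$p2a
  pr
}

check_class_arg <- function(class) {
  cl <- match_class(class)
  if (length(cl) != 1) stop("class must be a single value", call. = FALSE)
  cl
}

#' Node endorsement probabilities
#'
#' Probability of endorsing each decision node (disagreement, neutrality,
#' extremity on the disagreement and agreement branches) for every person and
#' item, under one response-strategy class.
#'
#' @param persons A data frame with columns `theta`, `eta_ers`, `eta_mrs`
#'   (and optionally `person`).
#' @param items An item-parameter table (see [irtree_items()]).
#' @param class Class index (1–4), code (`"ers"`, `"mrs"`, `"2rs"`, `"0rs"`)
#'   or label.
#' @param link Link function for the node models: `"logit"` (default) or
#'   `"probit"`.
#' @return A tibble with columns `person`, `item`, `p0`, `p1`, `p2_disagree`,
#'   `p2_agree`.
#' @export
node_probabilities <- function(persons, items, class, link = c("logit", "probit")) {
  link <- match.arg(link)
  cl <- check_class_arg(class)
  pp <- persons_parts(persons)
  a <- items_arrays(items)
  np <- node_prob_mats(pp$eta, a, cl, link)
  tibble::tibble(
    person = rep(pp$person, a$J),
    item = rep(a$item_ids, each = length(pp$person)),
    p0 = as.vector(np$p0), p1 = as.vector(np$p1),
    p2_disagree = as.vector(np$p2d), p2_agree = as.vector(np$p2a)
  )
}

#' Category probabilities of one response model
#'
#' Probability of each original response category 1–5, obtained as the
#' product of the node probabilities along the tree path leading to that
#' category:
#' `P(1) = p0*p2d`, `P(2) = p0*(1-p2d)`, `P(3) = (1-p0)*p1`,
#' `P(4) = (1-p0)*(1-p1)*(1-p2a)`, `P(5) = (1-p0)*(1-p1)*p2a`.
#'
#' @inheritParams node_probabilities
#' @return A tibble with columns `person`, `item`, `category` (1–5), `prob`;
#'   the five probabilities of a person-item cell sum to 1.
#' @export
category_probabilities <- function(persons, items, class,
                                   link = c("logit", "probit")) {
  link <- match.arg(link)
  cl <- check_class_arg(class)
  pp <- persons_parts(persons)
  a <- items_arrays(items)
  pr <- cat_prob_array(pp$eta, a, cl, link)
  P <- length(pp$person)
  tibble::tibble(
    person = rep(pp$person, a$J * 5L),
    item = rep(rep(a$item_ids, each = P), 5L),
    category = rep(1:5, each = P * a$J),
    prob = as.vector(pr)
  )
}

#' Category probabilities under the mixture model
#'
#' Evaluates, for each person, the component response model selected by that
#' person's class membership, using the class-specific item parameters.
#'
#' @inheritParams node_probabilities
#' @param z Integer vector of class memberships (1–4), one per person.
#' @return A tibble as in [category_probabilities()].
#' @export
mixture_category_probabilities <- function(persons, items, z,
                                           link = c("logit", "probit")) {
  link <- match.arg(link)
  pp <- persons_parts(persons)
  z <- as.integer(z)
  if (length(z) != nrow(pp$eta)) stop("length(z) must equal nrow(persons)",
                                      call. = FALSE)
  if (any(z < 1L | z > 4L)) stop("class memberships must be in 1..4",
                                 call. = FALSE)
  a <- items_arrays(items)
  pr <- cat_prob_array(pp$eta, a, z, link)
  P <- length(pp$person)
  tibble::tibble(
    person = rep(pp$person, a$J * 5L),
    item = rep(rep(a$item_ids, each = P), 5L),
    category = rep(1:5, each = P * a$J),
    prob = as.vector(pr)
  )
}

#' Mixture log-likelihood of observed ratings
#'
#' Sum over persons and items of the log probability of the observed
#' response under each person's component model. Pseudo-items that are
#' missing by design contribute no factor.
#'
#' @param ratings A ratings tibble (see [as_ratings()]).
#' @inheritParams mixture_category_probabilities
#' @return A single number. `-Inf` (with a warning) only if some observed
#'   response has probability numerically zero, which requires effectively
#'   infinite parameters.
#' @export
log_likelihood <- function(ratings, persons, items, z,
                           link = c("logit", "probit")) {
  link <- match.arg(link)
  parts <- ratings_parts(ratings)
  pp <- persons_parts(persons)
  if (nrow(parts$y) != nrow(pp$eta)) {
    stop("ratings and persons disagree in number of persons", call. = FALSE)
  }
  a <- items_arrays(items)
  z <- rep_len(as.integer(z), nrow(pp$eta))
  pr <- cat_prob_array(pp$eta, a, z, link)
  P <- nrow(parts$y); J <- ncol(parts$y)
  idx <- cbind(rep(seq_len(P), J), rep(seq_len(J), each = P),
               as.vector(parts$y))
  p_obs <- pmax(pr[idx], 1e-300)
  ll <- sum(log(p_obs))
  if (any(pr[idx] == 0)) warning("zero response probability; log-likelihood floored")
  ll
}
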