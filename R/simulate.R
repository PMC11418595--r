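# Synthetic-data generator reproducing the recovery-study design:
# trivariate normal traits with unit variances and fixed correlations,
# uniform loadings and difficulties, deterministic block class assignment
# under nine class-proportion conditions, multinomial responses.

# Default generating correlations: cor(theta, eta_ers) = .20,
# cor(theta, eta_mrs) = .00, cor(eta_ers, eta_mrs) = -.40.
default_trait_cor <- function() {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.20
  R[1, 3] <- R[3, 1] <- 0.00
  R[2, 3] <- R[3, 2] <- -0.40
  dimnames(R) <- rep(list(c("theta", "eta_ers", "eta_mrs")), 2)
  R
}

#' The nine class-proportion conditions of the simulation design
#'
#' Five mixture conditions (equal proportions and four conditions dominated
#' by one class at 70%) and four non-mixture conditions in which a single
#' class makes up the whole population.
#'
#' @return A named list of length-4 class-proportion vectors in the class
#'   order (ERS only, MRS only, 2RS, 0RS).
#' @export
condition_registry <- function() {
  list(
    equal = c(.25, .25, .25, .25),
    ers_dominated = c(.70, .10, .10, .10),
    mrs_dominated = c(.10, .70, .10, .10),
    `2rs_dominated` = c(.10, .10, .70, .10),
    `0rs_dominated` = c(.10, .10, .10, .70),
    ers_only = c(1, 0, 0, 0),
    mrs_only = c(0, 1, 0, 0),
    `2rs_only` = c(0, 0, 1, 0),
    `0rs_only` = c(0, 0, 0, 1)
  )
}

#' Define a simulation condition
#'
#' @param name Either a registered condition name (see
#'   [condition_registry()]) or an arbitrary label if `pi_true` is supplied.
#' @param pi_true Length-4 class proportions summing to 1; defaults to the
#'   registered proportions for `name`.
#' @param n_persons,n_items,n_replications Design sizes; defaults 2000, 20
#'   and 10 match the full-scale recovery study.
#' @param master_seed Integer master seed; all stage seeds derive from it.
#' @return A list of class `sim_condition`.
#' @export
sim_condition <- function(name, pi_true = NULL, n_persons = 2000,
                          n_items = 20, n_replications = 10,
                          master_seed = 1L) {
  reg <- condition_registry()
  if (is.null(pi_true)) {
    if (!name %in% names(reg)) {
      stop("unknown condition '", name, "'; registered: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    }
    pi_true <- reg[[name]]
  }
  if (length(pi_true) != 4 || abs(sum(pi_true) - 1) > 1e-8 || any(pi_true < 0)) {
    stop("pi_true must be 4 non-negative proportions summing to 1", call. = FALSE)
  }
  structure(list(name = name, pi_true = pi_true, n_persons = n_persons,
                 n_items = n_items, n_replications = n_replications,
                 master_seed = as.integer(master_seed)),
            class = "sim_condition")
}

# Stage seeds derived from the master seed; kept below 2^31.
derive_seed <- function(master_seed, ...) {
  h <- as.double(master_seed %% 2147483647L)
  for (tok in c(...)) {
    for (ch in utf8ToInt(as.character(tok))) {
      h <- (h * 31 + ch) %% 2147483629
    }
  }
  as.integer(h)
}

#' Draw person traits from the generating population
#'
#' Traits (substantive, ERS, MRS) are multivariate normal with zero means,
#' unit variances and correlation matrix `R`.
#'
#' @param n Number of persons.
#' @param R 3x3 correlation matrix; defaults to the study's generating
#'   correlations (.20 between substantive and ERS, 0 between substantive
#'   and MRS, -.40 between ERS and MRS).
#' @param seed Integer seed.
#' @return A tibble with columns `person`, `theta`, `eta_ers`, `eta_mrs`.
#' @export
draw_person_traits <- function(n, R = default_trait_cor(), seed = 1L) {
  R <- as.matrix(R)
  if (!isSymmetric(unname(R)) || any(abs(diag(R) - 1) > 1e-12)) {
    stop("R must be a symmetric correlation matrix with unit diagonal",
         call. = FALSE)
  }
  L <- tryCatch(chol(R), error = function(e)
    stop("R is not positive definite", call. = FALSE))
  eta <- withr::with_seed(seed, matrix(rnorm(n * 3), n, 3) %*% L)
  tibble::tibble(person = seq_len(n), theta = eta[, 1],
                 eta_ers = eta[, 2], eta_mrs = eta[, 3])
}

#' Draw item parameters from the generating distributions
#'
#' Substantive-trait loadings from U(0.75, 1.75) with the proportionality
#' constant fixed at `omega = 0.50`; ERS loadings (classes where ERS is
#' active) from U(0.75, 1.25); MRS loadings (classes where MRS is active)
#' from U(0.50, 0.75); all node difficulties from U(-2, 2), independently
#' per class; masked loadings exactly 0.
#'
#' @param J Number of items.
#' @param seed Integer seed.
#' @param omega Proportionality constant of the substantive trait at the
#'   extremity node (fixed, not drawn).
#' @return An [irtree_items()] tibble covering all four classes.
#' @export
draw_item_parameters <- function(J, seed = 1L, omega = 0.50) {
  withr::with_seed(seed, {
    ath <- runif(J, 0.75, 1.75)
    aers <- matrix(0, J, 4)
    aers[, 1] <- runif(J, 0.75, 1.25)
    aers[, 3] <- runif(J, 0.75, 1.25)
    amrs <- matrix(0, J, 4)
    amrs[, 2] <- runif(J, 0.50, 0.75)
    amrs[, 3] <- runif(J, 0.50, 0.75)
    beta <- array(runif(J * 3 * 4, -2, 2), c(J, 3, 4))
    arrays_to_items(list(item_ids = paste0("item", seq_len(J)), J = J,
                         ath = ath, omega = omega, aers = aers,
                         amrs = amrs, beta = beta, classes = 1:4))
  })
}

#' Deterministic block assignment of class memberships
#'
#' The first `round(n * pi[1])` persons are assigned to the "ERS only"
#' class, the next block to "MRS only", then "2RS", with the remainder
#' absorbed by the "0RS" class. No randomness is involved.
#'
#' @param n Number of persons.
#' @param pi_true Length-4 class proportions.
#' @return Integer vector of class indices.
#' @export
assign_memberships <- function(n, pi_true) {
  if (length(pi_true) != 4 || abs(sum(pi_true) - 1) > 1e-8) {
    stop("pi_true must be 4 proportions summing to 1", call. = FALSE)
  }
  sizes <- round(n * pi_true[1:3])
  sizes <- c(sizes, n - sum(sizes))
  if (sizes[4] < 0) stop("rounding left a negative final block", call. = FALSE)
  rep(1:4, times = sizes)
}

#' Simulate multinomial responses
#'
#' Each response is drawn from the 5-category distribution implied by the
#' person's component model (class-specific item parameters selected by
#' `z`).
#'
#' @param persons Trait tibble from [draw_person_traits()].
#' @param items Item-parameter table covering the classes present in `z`.
#' @param z Integer class memberships.
#' @param seed Integer seed.
#' @return A ratings tibble.
#' @export
simulate_responses <- function(persons, items, z, seed = 1L) {
  pp <- persons_parts(persons)
  a <- items_arrays(items)
  z <- as.integer(z)
  stopifnot(length(z) == nrow(pp$eta))
  pr <- cat_prob_array(pp$eta, a, z)
  P <- nrow(pp$eta); J <- a$J
  y <- withr::with_seed(seed, {
    u <- matrix(runif(P * J), P, J)
    cum <- pr[, , 1, drop = FALSE]
    out <- matrix(1L, P, J)
    acc <- pr[, , 1]
    for (k in 2:5) {
      out <- out + (u > acc)
      if (k < 5) acc <- acc + pr[, , k]
    }
    out
  })
  colnames(y) <- a$item_ids
  as_ratings(tibble::as_tibble(as.data.frame(y)))
}

#' Generate all replications of a simulation condition
#'
#' Person traits, item parameters and block memberships are drawn once per
#' condition; responses are re-drawn for each replication (the repeated
#' steps of the generating design). Set `redraw_persons = TRUE` to
#' regenerate traits per replication instead.
#'
#' @param condition A [sim_condition()].
#' @param R Generating trait correlation matrix.
#' @param redraw_persons Redraw person traits for every replication.
#' @return A list of datasets, each a list with elements `ratings`,
#'   `persons`, `items`, `z`, `pi_true`, `condition`, `replication`, `seeds`.
#' @export
generate_condition <- function(condition, R = default_trait_cor(),
                               redraw_persons = FALSE) {
  stopifnot(inherits(condition, "sim_condition"))
  ms <- condition$master_seed
  item_seed <- derive_seed(ms, condition$name, "items")
  items <- draw_item_parameters(condition$n_items, seed = item_seed)
  trait_seed <- derive_seed(ms, condition$name, "traits")
  persons <- draw_person_traits(condition$n_persons, R, seed = trait_seed)
  z <- assign_memberships(condition$n_persons, condition$pi_true)
  lapply(seq_len(condition$n_replications), function(r) {
    if (redraw_persons && r > 1) {
      trait_seed <- derive_seed(ms, condition$name, "traits", r)
      persons <- draw_person_traits(condition$n_persons, R, seed = trait_seed)
    }
    resp_seed <- derive_seed(ms, condition$name, "responses", r)
    list(
      ratings = simulate_responses(persons, items, z, seed = resp_seed),
      persons = persons, items = items, z = z,
      pi_true = condition$pi_true, condition = condition$name,
      replication = r,
      seeds = list(master = ms, items = item_seed, traits = trait_seed,
                   responses = resp_seed)
    )
  })
}
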