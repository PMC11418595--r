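# Bayesian estimation of the MM-IRTree and the four single-class IRTree
# benchmarks via the package's Polya-Gamma Gibbs sampler.

#' Prior specification
#'
#' Defaults: factor loadings ~ N(0, 2) truncated to be positive; node
#' difficulties ~ N(0, 2); proportionality constant ~ U(0, 2); trait
#' correlations elementwise U(-1, 1) restricted to positive-definite
#' matrices; class proportions ~ Dirichlet(1, 1, 1, 1).
#'
#' @param loading_var,beta_var Prior variances of loadings / difficulties.
#' @param omega_range Support of the uniform prior on omega.
#' @param dirichlet Dirichlet concentration for the class proportions.
#' @param cor_prop_sd Random-walk proposal SD of the correlation updates.
#' @return A list of class `irtree_priors`.
#' @export
prior_spec <- function(loading_var = 2, beta_var = 2, omega_range = c(0, 2),
                       dirichlet = rep(1, 4), cor_prop_sd = 0.06) {
  stopifnot(loading_var > 0, beta_var > 0, length(omega_range) == 2,
            omega_range[1] < omega_range[2], length(dirichlet) == 4,
            all(dirichlet > 0), cor_prop_sd > 0)
  structure(list(loading_var = loading_var, beta_var = beta_var,
                 omega_range = omega_range, dirichlet = dirichlet,
                 cor_prop_sd = cor_prop_sd), class = "irtree_priors")
}

model_classes <- function(model) if (model == "mm") 1:4 else model_to_class(model)

model_traits <- function(model) {
  switch(model,
         mm = c(TRUE, TRUE, TRUE), `2rs` = c(TRUE, TRUE, TRUE),
         ers = c(TRUE, TRUE, FALSE), mrs = c(TRUE, FALSE, TRUE),
         `0rs` = c(TRUE, FALSE, FALSE))
}

TRAIT_NAMES <- c("theta", "eta_ers", "eta_mrs")

# Canonical parameter (column) order of a chain's draw matrix; must match
# the recording order of the C++ sampler exactly.
par_names <- function(item_ids, model) {
  classes <- model_classes(model)
  traits <- model_traits(model)
  nm <- c(paste0("alpha_theta[", item_ids, "]"), "omega")
  for (c0 in classes[ers_active(classes)]) {
    nm <- c(nm, paste0("alpha_ers[", item_ids, ",", c0, "]"))
  }
  for (c0 in classes[mrs_active(classes)]) {
    nm <- c(nm, paste0("alpha_mrs[", item_ids, ",", c0, "]"))
  }
  for (c0 in classes) {
    for (k in 0:2) nm <- c(nm, paste0("beta", k, "[", item_ids, ",", c0, "]"))
  }
  act <- which(traits)
  if (length(act) > 1) {
    pairs <- utils::combn(act, 2)
    nm <- c(nm, paste0("cor(", TRAIT_NAMES[pairs[1, ]], ",",
                       TRAIT_NAMES[pairs[2, ]], ")"))
  }
  if (model == "mm") nm <- c(nm, paste0("pi[", 1:4, "]"))
  c(nm, "deviance")
}

# Profile-based starting memberships: medians of the middle-category share
# (MRS signal) and of the extreme share among non-middle responses (ERS
# signal, mechanically independent of the middle share) split respondents
# into the four style patterns. Only a seed partition — the class signal in
# this model comes mostly from class-specific difficulties, so mode
# exploration (see fit_irtree) matters more than this heuristic.
heuristic_z <- function(y) {
  nm <- rowSums(y != 3L)
  enm <- ifelse(nm > 0, rowSums(y == 1L | y == 5L) / nm, 0.5)
  mid <- rowMeans(y == 3L)
  he <- enm > stats::median(enm)
  hm <- mid > stats::median(mid)
  ifelse(he & hm, 3L, ifelse(he, 1L, ifelse(hm, 2L, 4L)))
}

heuristic_eta <- function(y) {
  sc <- function(x) {
    r <- rank(x, ties.method = "average")
    qnorm(r / (length(x) + 1))
  }
  cbind(sc(rowMeans(y)), sc(rowMeans(y == 1L | y == 5L)), sc(rowMeans(y == 3L)))
}

# Exchange the class labels a and b in a membership partition.
swap_partition <- function(z, a, b) {
  zz <- z
  zz[z == a] <- b
  zz[z == b] <- a
  zz
}

#' Fit an IRTree model by Gibbs sampling
#'
#' Estimates the mixture multidimensional IRTree (`model = "mm"`) or one of
#' its single-class benchmarks (`"ers"`, `"mrs"`, `"2rs"`, `"0rs"`) with a
#' Gibbs sampler that augments every logistic decision node with
#' Polya-Gamma latent variables. Loadings and difficulties then have
#' conjugate (truncated) normal updates, person traits multivariate normal
#' updates, omega a truncated-normal update under its uniform prior, class
#' memberships categorical updates and class proportions a Dirichlet
#' update; trait correlations use elementwise random-walk Metropolis with
#' rejection of non-positive-definite proposals. Mixture components are
#' structurally identified by their zero-loading patterns, so no relabeling
#' is needed.
#'
#' @param ratings A ratings tibble or data frame (see [as_ratings()]).
#' @param model `"mm"` (four-class mixture) or a single-class model code.
#' @param chains Number of chains; default 10 for `"mm"`, 5 otherwise.
#' @param iterations,burnin Iterations per chain and discarded burn-in;
#'   defaults 3000 and 1000.
#' @param seed Integer seed; every chain derives its own sub-seed from it.
#' @param priors A [prior_spec()].
#' @param init `"explore"` (default for the mixture model): several short
#'   exploratory chains are run from random partitions and the long chains
#'   are warm-started from the state with the smallest mean deviance, which
#'   guards against chains settling in a minor (label-permuted) mode of the
#'   mixture posterior. `"heuristic"` seeds memberships from observed
#'   response profiles; `"random"` from a uniform partition. Initialization
#'   does not change the stationary distribution.
#' @param explore_starts,explore_iterations Number and length of the
#'   exploratory chains used when `init = "explore"`.
#' @param warm_start Iterations during which memberships are held at their
#'   initial partition (within the burn-in). Default 0: item parameters are
#'   updated before the first membership draw in every iteration, and
#'   freezing a random partition only lets superfluous loadings shrink
#'   before the data can sort respondents.
#' @param store_z Keep per-iteration membership draws (mixture model only).
#' @param rhat_threshold Convergence is flagged (not fatal) when any
#'   monitored potential scale reduction factor exceeds this; 1.05 default.
#' @param verbose Print per-chain progress.
#' @return An object of class `irtree_fit`; see [tidy.irtree_fit()],
#'   [glance.irtree_fit()], [posterior_class_probabilities()],
#'   [person_estimates()], [compute_dic()].
#' @export
fit_irtree <- function(ratings, model = c("mm", "ers", "mrs", "2rs", "0rs"),
                       chains = NULL, iterations = 3000, burnin = 1000,
                       seed = 1L, priors = prior_spec(),
                       init = c("explore", "heuristic", "random"),
                       explore_starts = 4, explore_iterations = 400,
                       warm_start = 0, store_z = TRUE,
                       rhat_threshold = 1.05, verbose = FALSE) {
  model <- match.arg(model)
  init <- match.arg(init)
  stopifnot(burnin < iterations, burnin >= 0)
  if (is.null(chains)) chains <- if (model == "mm") 10L else 5L
  if (chains < 2) stop("at least 2 chains are required for convergence checks",
                       call. = FALSE)
  parts <- ratings_parts(ratings)
  y <- parts$y
  P <- nrow(y); J <- ncol(y)
  if (any(apply(y, 2, function(col) length(unique(col))) == 1)) {
    warning("some item has a constant response column; estimates may be degenerate")
  }
  classes <- model_classes(model)
  traits <- model_traits(model)
  mixture <- model == "mm"
  if (!mixture) init <- "heuristic"
  nm <- par_names(parts$items, model)
  warm_start <- min(warm_start, max(burnin - 1L, 0L))

  default_items <- function() list(
    ath = pmax(0.1, 1 + rnorm(J, 0, 0.2)),
    omega = runif(1, 0.3, 0.7),
    aers = matrix(rep(as.numeric(ers_active(1:4)), each = J) *
                    pmax(0.1, 1 + rnorm(J * 4, 0, 0.2)), J, 4),
    amrs = matrix(rep(as.numeric(mrs_active(1:4)), each = J) *
                    pmax(0.1, 0.6 + rnorm(J * 4, 0, 0.1)), J, 4),
    beta = array(rnorm(J * 3 * 4, 0, 0.3), c(J, 3, 4))
  )
  run_chain <- function(z0, eta0, item0, pi0, R0, n_iter, n_burn, n_fix_z,
                        keep_z) {
    gibbs_irtree_chain(
      y = y, classes0 = as.integer(classes - 1L), mixture = mixture,
      z_init0 = as.integer(z0 - 1L), eta_init = eta0, item_init = item0,
      R_init = R0, pi_init = pi0,
      trait_active = traits, loading_var = priors$loading_var,
      beta_var = priors$beta_var, omega_lo = priors$omega_range[1],
      omega_hi = priors$omega_range[2], dir_alpha = priors$dirichlet,
      cor_prop_sd = priors$cor_prop_sd, n_iter = as.integer(n_iter),
      n_burn = as.integer(n_burn), n_fix_z = as.integer(n_fix_z),
      store_z = keep_z
    )
  }

  t0 <- Sys.time()
  # Mode exploration. The mixture posterior has near-degenerate minor modes
  # in which the *contents* of two classes are exchanged: a class whose
  # loading masks nest another's (the "2RS" class nests all others, "ERS
  # only" and "MRS only" nest "0RS") can impersonate it by shrinking the
  # surplus loadings to zero, at essentially no deviance cost. Ordinary
  # Gibbs moves cannot exchange whole class contents, so: (1) several short
  # chains are run from random partitions and the smallest-deviance state
  # is kept; (2) a greedy repair step tries all pairwise class-content
  # swaps, accepting a swap when it clearly lowers the deviance or when it
  # is deviance-neutral and moves content into the structurally simpler
  # class (an Occam tie-break that resolves the label degeneracy the same
  # way the full marginal likelihood would).
  mode_state <- NULL
  if (mixture && init == "explore" && explore_starts > 0) {
    keep_tail <- min(100L, explore_iterations %/% 4L)
    dev_col <- function(res, n_iter) {
      mean(res$draws[seq.int(n_iter - keep_tail + 1L, n_iter),
                     ncol(res$draws)])
    }
    # Candidate arrangements (partitions) are scored by a *fresh* fit with
    # memberships held fixed for the whole evaluation run: neutral item
    # starting values and profile-based trait starting values, so every
    # arrangement is judged from the same unbiased context. Re-adapting
    # an evolved sampler state instead is unreliable — trait scores and
    # correlations that absorbed a misplaced block's style are metastable
    # and mask the fit gain of the corrected arrangement; and releasing
    # memberships mid-evaluation lets a flexible-class arrangement
    # reassert itself and credits its deviance to the candidate. Within a
    # repair round the baseline and all candidates share one RNG seed
    # (common random numbers), which cancels most of the deviance drift
    # out of the comparisons.
    eval_tail <- 250L
    neutral_items <- list(
      ath = rep(1, J), omega = 0.5,
      aers = matrix(rep(as.numeric(ers_active(1:4)), each = J), J, 4),
      amrs = 0.6 * matrix(rep(as.numeric(mrs_active(1:4)), each = J), J, 4),
      beta = array(0, c(J, 3, 4))
    )
    neutral_eta <- heuristic_eta(y)
    neutral_eta[, !traits] <- 0
    # An arrangement is scored by the *best* (smallest) mean deviance over
    # two independently seeded evaluation runs: a run occasionally fails
    # to form a newly activated loading-by-latent pair and settles above
    # the arrangement's mode, and such failures only ever bias the score
    # upward, so the minimum is the robust summary.
    eval_partition <- function(zpart, es) {
      n_ev <- 150L + eval_tail
      out <- NULL
      for (rep in 1:2) {
        res <- withr::with_seed(derive_seed(es, "ev", rep),
                                run_chain(zpart, neutral_eta, neutral_items,
                                          rep(0.25, 4), diag(3), n_ev,
                                          n_ev - eval_tail, n_ev, FALSE))
        dev <- mean(res$draws[seq.int(n_ev - eval_tail + 1L, n_ev),
                              ncol(res$draws)])
        if (is.null(out) || dev < out$dev) {
          out <- list(dev = dev, state = res$state)
        }
      }
      out
    }
    # complexity load: number of free response-style loading blocks of the
    # class occupied by each respondent
    cplx <- c(1, 1, 2, 0)
    complexity <- function(z) sum(cplx[z])
    best <- Inf
    for (s in seq_len(explore_starts)) {
      es <- derive_seed(seed, "explore", model, s)
      res <- withr::with_seed(es, {
        z0 <- sample.int(4L, P, replace = TRUE)
        eta0 <- heuristic_eta(y) + matrix(rnorm(P * 3, 0, 0.3), P, 3)
        eta0[, !traits] <- 0
        run_chain(z0, eta0, default_items(), rep(0.25, 4), diag(3),
                  explore_iterations, explore_iterations - keep_tail,
                  0L, FALSE)
      })
      dev <- dev_col(res, explore_iterations)
      if (verbose) message(sprintf("explore %d: mean deviance %.1f", s, dev))
      if (dev < best) { best <- dev; mode_state <- res$state }
    }
    # Re-evaluate the selected state with the same procedure used for the
    # swap candidates, then greedily repair. Acceptance margins encode the
    # prior-volume (Occam) penalty that the conditional deviance cannot
    # see: a swap towards lower complexity is accepted unless the fit
    # clearly degrades, an equal-complexity swap must clearly improve the
    # fit, and a swap towards higher complexity must improve it by more
    # than the spurious-loading gain it could obtain from noise alone.
    # Repair and refinement alternate: swap repair needs clean blocks
    # (respondents individually stuck in a wrong class shift the fixed-z
    # deviance comparisons by tens of units), and membership refinement
    # needs the right arrangement. Each cycle runs up to two repair
    # rounds, then a free-membership refinement pass; the loop stops once
    # a cycle accepts no swap and the refinement no longer moves anyone.
    pairs <- utils::combn(4L, 2L)
    part <- mode_state$z
    for (cycle in 1:3) {
      any_swap <- FALSE
      for (round in 1:2) {
        rs <- derive_seed(seed, "repair", cycle, round)
        base <- eval_partition(part, rs)
        mode_state <- base$state
        picked <- NULL
        picked_margin <- 0
        for (q in seq_len(ncol(pairs))) {
          cand <- swap_partition(part, pairs[1, q], pairs[2, q])
          dcx <- complexity(cand) - complexity(part)
          ev <- eval_partition(cand, rs)
          # Margins per unit of complexity moved: a spurious style in an
          # occupied class lowers the conditional deviance by roughly
          # 0.4 per member (its person-side latents absorb
          # overdispersion), while a genuinely used style that goes
          # unmodelled costs roughly 1.2 per member at 20 items; 0.8
          # sits between the two.
          thr <- if (dcx == 0) -25 else (15 + 0.8 * abs(dcx)) * sign(-dcx)
          margin <- thr - (ev$dev - base$dev)  # > 0 means acceptable
          if (verbose) message(sprintf(
            "repair %d.%d: swap %d<->%d dev %.1f vs %.1f (dcx %d) -> %s",
            cycle, round, pairs[1, q], pairs[2, q], ev$dev, base$dev, dcx,
            if (margin > 0) "acceptable" else "reject"))
          if (margin > picked_margin) {
            picked <- list(part = cand, state = ev$state)
            picked_margin <- margin
          }
        }
        if (is.null(picked)) break
        part <- picked$part
        mode_state <- picked$state
        any_swap <- TRUE
      }
      ref <- withr::with_seed(
        derive_seed(seed, "refine", cycle),
        run_chain(mode_state$z, mode_state$eta, mode_state$items,
                  mode_state$pi, mode_state$R, 400L, 399L, 0L, FALSE))
      moved <- mean(ref$state$z != part)
      if (verbose) message(sprintf(
        "refine %d: %.1f%% of memberships moved", cycle, 100 * moved))
      mode_state <- ref$state
      part <- ref$state$z
      if (!any_swap && moved < 0.01) break
    }
  }

  chain_res <- lapply(seq_len(chains), function(k) {
    chain_seed <- derive_seed(seed, "chain", model, k)
    res <- withr::with_seed(chain_seed, {
      if (!is.null(mode_state)) {
        run_chain(mode_state$z, mode_state$eta, mode_state$items,
                  mode_state$pi, mode_state$R, iterations, burnin, 0L,
                  store_z)
      } else {
        if (init == "random") {
          z0 <- if (mixture) sample.int(4L, P, replace = TRUE)
                else rep(model_to_class(model), P)
          eta0 <- matrix(rnorm(P * 3), P, 3)
        } else {
          z0 <- if (mixture) heuristic_z(y) else rep(model_to_class(model), P)
          eta0 <- heuristic_eta(y) + matrix(rnorm(P * 3, 0, 0.3), P, 3)
        }
        eta0[, !traits] <- 0
        run_chain(z0, eta0, default_items(), rep(0.25, 4), diag(3),
                  iterations, burnin, if (mixture) warm_start else 0L,
                  store_z)
      }
    })
    colnames(res$draws) <- nm
    if (verbose) message("chain ", k, " done")
    res
  })
  runtime <- as.numeric(Sys.time() - t0, units = "secs")

  keep <- seq.int(burnin + 1L, iterations)
  post <- lapply(chain_res, function(ch) ch$draws[keep, , drop = FALSE])
  pooled <- do.call(rbind, post)

  rhat <- compute_rhat(post)
  est <- colMeans(pooled)
  sds <- apply(pooled, 2, sd)

  pz <- Reduce(`+`, lapply(chain_res, `[[`, "pz")) / chains
  eta_mean <- Reduce(`+`, lapply(chain_res, `[[`, "eta_mean")) / chains
  # pooled posterior SD: within-chain variance + dispersion of chain means
  eta_var_w <- Reduce(`+`, lapply(chain_res, function(ch) ch$eta_sd^2)) / chains
  eta_var_b <- Reduce(`+`, lapply(chain_res, function(ch)
    (ch$eta_mean - eta_mean)^2)) / chains
  eta_sd <- sqrt(pmax(eta_var_w + eta_var_b, 0))
  colnames(eta_mean) <- colnames(eta_sd) <- TRAIT_NAMES
  colnames(pz) <- CLASS_CODES

  dev <- pooled[, "deviance"]
  fit <- structure(list(
    model = model, person = parts$person, item_ids = parts$items,
    n_persons = P, n_items = J, classes = classes, traits = traits,
    chains = chains, iterations = iterations, burnin = burnin, seed = seed,
    priors = priors, init = init,
    draws = post, z_draws = if (store_z && mixture)
      lapply(chain_res, `[[`, "z") else NULL,
    init_partition = if (!is.null(mode_state)) mode_state$z else NULL,
    pz = pz, eta_mean = eta_mean, eta_sd = eta_sd,
    summary = tibble::tibble(term = nm, estimate = est, std.error = sds,
                             rhat = rhat$rhat[match(nm, rhat$term)]),
    pi_hat = if (mixture) est[paste0("pi[", 1:4, "]")] else NULL,
    dic = compute_dic(dev),
    cor_accept = mean(vapply(chain_res, `[[`, 0, "cor_accept_rate")),
    rhat_threshold = rhat_threshold,
    converged = all(rhat$rhat <= rhat_threshold, na.rm = TRUE),
    runtime = runtime
  ), class = "irtree_fit")
  if (!fit$converged) {
    warning(sprintf("max Rhat %.3f exceeds threshold %.2f; treat results with caution",
                    max(rhat$rhat, na.rm = TRUE), rhat_threshold))
  }
  fit
}

#' @export
print.irtree_fit <- function(x, ...) {
  cat(sprintf("<irtree_fit> model=%s  persons=%d items=%d  chains=%d x %d (burn-in %d)\n",
              x$model, x$n_persons, x$n_items, x$chains, x$iterations, x$burnin))
  cat(sprintf("  DIC %.1f (Dbar %.1f, pV %.1f)  max Rhat %.3f  %.1fs\n",
              x$dic$dic, x$dic$dbar, x$dic$pv,
              max(x$summary$rhat, na.rm = TRUE), x$runtime))
  if (!is.null(x$pi_hat)) {
    cat("  class proportions:",
        paste(sprintf("%s=%.3f", CLASS_CODES, x$pi_hat), collapse = " "), "\n")
  }
  invisible(x)
}
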