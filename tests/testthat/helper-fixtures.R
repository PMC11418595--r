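# Shared helpers: small parameter sets built in code, and a cache so that
# expensive MCMC fits are computed once per test run and reused across
# test files.

one_item_pars <- function(alpha_theta = 1, omega = 0.5, alpha_ers = 1,
                          alpha_mrs = 0.5, beta = c(0, 0, 0)) {
  irtree_items(data.frame(
    item = "i1", class = 1:4,
    alpha_theta = alpha_theta, omega = omega,
    alpha_ers = alpha_ers * c(1, 0, 1, 0),
    alpha_mrs = alpha_mrs * c(0, 1, 1, 0),
    beta0 = beta[1], beta1 = beta[2], beta2 = beta[3]
  ))
}

random_items <- function(J, seed) draw_item_parameters(J, seed = seed)

random_persons <- function(n, seed) draw_person_traits(n, seed = seed)

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# Desk-scale study datasets and fits shared by the acceptance tests.
equal_data <- function() cached("equal_data", {
  generate_condition(sim_condition("equal", n_persons = 450, n_items = 20,
                                   n_replications = 1, master_seed = 1))[[1]]
})

zerors_data <- function() cached("zerors_data", {
  generate_condition(sim_condition("0rs_only", n_persons = 450, n_items = 20,
                                   n_replications = 1, master_seed = 1))[[1]]
})

twors_data <- function() cached("twors_data", {
  generate_condition(sim_condition("2rs_only", n_persons = 500, n_items = 20,
                                   n_replications = 1, master_seed = 1))[[1]]
})

fit_equal_mm <- function() cached("fit_equal_mm", suppressWarnings(
  fit_irtree(equal_data()$ratings, "mm", chains = 2, iterations = 1200,
             burnin = 400, seed = 1)))

fit_zerors_mm <- function() cached("fit_zerors_mm", suppressWarnings(
  fit_irtree(zerors_data()$ratings, "mm", chains = 2, iterations = 1200,
             burnin = 400, seed = 1)))

dominated_data <- function() cached("dominated_data", {
  generate_condition(sim_condition("ers_dominated", n_persons = 450,
                                   n_items = 20, n_replications = 1,
                                   master_seed = 1))[[1]]
})

fit_dominated_mm <- function() cached("fit_dominated_mm", suppressWarnings(
  fit_irtree(dominated_data()$ratings, "mm", chains = 2, iterations = 1200,
             burnin = 400, seed = 1)))

fit_single <- function(data_key, model) {
  d <- switch(data_key, equal = equal_data(), zerors = zerors_data(),
              twors = twors_data())
  cached(paste0("fit_", data_key, "_", model), suppressWarnings(
    fit_irtree(d$ratings, model, chains = 2, iterations = 1200,
               burnin = 400, seed = 1)))
}
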