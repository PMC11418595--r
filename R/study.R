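# Top-level simulation-study harness: simulate -> fit all five models ->
# evaluate -> aggregate, with a manifest and resumability.

#' Small deterministic example datasets
#'
#' Tiny generated datasets for examples and tests, with ground truth
#' attached.
#'
#' @param kind `"mixture_small"` (60 persons x 8 items, equal proportions)
#'   or `"single_class_small"` (60 x 8, all "0RS").
#' @param seed Integer seed.
#' @return A dataset list as returned by [generate_condition()].
#' @export
make_fixture <- function(kind = c("mixture_small", "single_class_small"),
                         seed = 1L) {
  kind <- match.arg(kind)
  cond <- switch(kind,
    mixture_small = sim_condition("equal", n_persons = 60, n_items = 8,
                                  n_replications = 1, master_seed = seed),
    single_class_small = sim_condition("0rs_only", n_persons = 60, n_items = 8,
                                       n_replications = 1, master_seed = seed))
  generate_condition(cond)[[1]]
}

#' Configure a simulation study
#'
#' Defaults reproduce the full-scale recovery study: nine class-proportion
#' conditions with ten replications of 2000 persons by 20 items; the
#' mixture model estimated with 10 chains of 3000 iterations (burn-in
#' 1000), single-class models with 5 chains. `scale` shrinks persons,
#' replications, chains and iterations proportionally for desk-scale runs
#' and is recorded in the manifest.
#'
#' @param conditions Character vector of registered condition names.
#' @param models Models fitted to every dataset.
#' @param n_persons,n_items,n_replications Design sizes.
#' @param mm_chains,chains,iterations,burnin MCMC settings (mixture /
#'   single-class chains).
#' @param scale Proportional reduction factor in (0, 1].
#' @param seed Master seed.
#' @param out_dir Output directory (created); results of completed units
#'   are reused on re-run.
#' @return A list of class `study_config`.
#' @export
study_config <- function(conditions = names(condition_registry()),
                         models = c("mm", "ers", "mrs", "2rs", "0rs"),
                         n_persons = 2000, n_items = 20, n_replications = 10,
                         mm_chains = 10, chains = 5, iterations = 3000,
                         burnin = 1000, scale = 1, seed = 1L,
                         out_dir = NULL) {
  stopifnot(scale > 0, scale <= 1,
            all(conditions %in% names(condition_registry())),
            all(models %in% MODEL_CODES))
  shrink <- function(x, lo) max(lo, as.integer(round(x * scale)))
  structure(list(
    conditions = conditions, models = models,
    n_persons = shrink(n_persons, 50L), n_items = n_items,
    n_replications = shrink(n_replications, 1L),
    mm_chains = shrink(mm_chains, 2L), chains = shrink(chains, 2L),
    iterations = shrink(iterations, 400L),
    burnin = shrink(burnin, 150L),
    scale = scale, seed = as.integer(seed), out_dir = out_dir
  ), class = "study_config")
}

#' Run a simulation study
#'
#' For every condition and replication: generate the dataset, fit the
#' requested models, compare them by DIC, and score classification and
#' parameter recovery against the generating truth. When `config$out_dir`
#' is set, each unit's result is written as JSON and reused on re-runs,
#' together with a manifest of settings and seeds.
#'
#' @param config A [study_config()].
#' @param verbose Print progress.
#' @return A list with elements `results` (tibble: one row per condition x
#'   replication x model, DIC and recovery summaries), `hit_rates` (tibble
#'   per condition x replication x class) and `config`.
#' @export
run_study <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  use_dir <- !is.null(config$out_dir)
  if (use_dir) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- config[setdiff(names(config), "out_dir")]
    manifest$package_version <- as.character(utils::packageVersion("mmirtree"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  rows <- list(); hits <- list()
  for (cname in config$conditions) {
    cond <- sim_condition(cname, n_persons = config$n_persons,
                          n_items = config$n_items,
                          n_replications = config$n_replications,
                          master_seed = config$seed)
    datasets <- generate_condition(cond)
    for (r in seq_along(datasets)) {
      d <- datasets[[r]]
      unit_file <- if (use_dir)
        file.path(config$out_dir, sprintf("unit_%s_rep%d.json", cname, r))
      unit <- NULL
      if (use_dir && file.exists(unit_file)) {
        unit <- jsonlite::read_json(unit_file, simplifyVector = TRUE)
        if (verbose) message("reusing ", basename(unit_file))
      }
      if (is.null(unit)) {
        unit <- run_study_unit(d, config, cname, r, verbose)
        if (use_dir) jsonlite::write_json(unit, unit_file, auto_unbox = TRUE,
                                          digits = NA)
      }
      rows[[length(rows) + 1]] <- tibble::as_tibble(unit$models)
      if (!is.null(unit$hit_rates)) {
        hits[[length(hits) + 1]] <- tibble::as_tibble(unit$hit_rates)
      }
    }
  }
  list(results = dplyr::bind_rows(rows), hit_rates = dplyr::bind_rows(hits),
       config = config)
}

run_study_unit <- function(d, config, cname, r, verbose) {
  a <- items_arrays(d$items)
  fits <- list()
  for (m in config$models) {
    if (verbose) message(sprintf("[%s rep %d] fitting %s", cname, r, m))
    nch <- if (m == "mm") config$mm_chains else config$chains
    fit <- tryCatch(
      suppressWarnings(fit_irtree(
        d$ratings, m, chains = nch, iterations = config$iterations,
        burnin = config$burnin,
        seed = derive_seed(config$seed, "fit", cname, r, m))),
      error = function(e) {
        warning(sprintf("fit %s failed for %s rep %d: %s", m, cname, r,
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(fit)) fits[[m]] <- fit
  }
  model_rows <- lapply(names(fits), function(m) {
    fit <- fits[[m]]
    td <- fit$summary
    est_ath <- td$estimate[grep("^alpha_theta\\[", td$term)]
    br <- bias_rmse(est_ath, a$ath)
    list(condition = cname, replication = r, model = m,
         dic = fit$dic$dic, dbar = fit$dic$dbar, pv = fit$dic$pv,
         max_rhat = max(td$rhat, na.rm = TRUE),
         alpha_theta_bias = br$bias, alpha_theta_rmse = br$rmse,
         omega_est = td$estimate[td$term == "omega"],
         runtime = fit$runtime)
  })
  unit <- list(models = dplyr::bind_rows(model_rows))
  if ("mm" %in% names(fits)) {
    zh <- modal_assignment(fits$mm)
    hr <- hit_rate(zh, d$z)
    ct <- certainty(fits$mm, zh)
    unit$hit_rates <- dplyr::mutate(
      dplyr::left_join(hr, ct[c("class", "n_assigned", "certainty")],
                       by = "class"),
      condition = cname, replication = r,
      pi_true = d$pi_true, pi_est = fits$mm$pi_hat)
  }
  unit
}
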