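# Orchestration across a tree sample: model-fitting suite, stochastic
# mapping, D-test, trend-BM, simulation-recovery mode, deterministic
# seeding and an output manifest.

#' Derive a reproducible sub-stream seed
#'
#' Stable integer hash of a stage name and index combined with the master
#' seed; all package randomness in [run_full()] flows through this.
#'
#' @param master master seed (integer).
#' @param stage stage name (string).
#' @param index replicate/tree index (default 0).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% m
  as.integer((h + (master %% m) * 7919 + index * 104729) %% (m - 1) + 1)
}

#' Read a run configuration (JSON or YAML)
#'
#' Required fields: `trees` (newick file, one or more trees), `tip_table`,
#' `clade_table`, `output_dir`, `seed`. Optional: `models` (default all
#' seven), `maps_per_tree` (10), `dtest` (list: `n_maps`, `n_null`),
#' `trend` (list: `iterations`, `burnin`, `thin`, `hyperprior`),
#' `n_starts` (3).
#'
#' @param path config file path (`.json`, `.yml` or `.yaml`).
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("trees", "tip_table", "clade_table", "output_dir", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in c("trees", "tip_table", "clade_table"))
    if (!file.exists(cfg[[f]]))
      stop("config path does not exist: ", cfg[[f]], call. = FALSE)
  cfg$models <- cfg$models %||% MK_MODEL_NAMES
  cfg$maps_per_tree <- cfg$maps_per_tree %||% 10
  cfg$n_starts <- cfg$n_starts %||% 3
  cfg$dtest <- utils::modifyList(list(n_maps = 100, n_null = 1000),
                                 as.list(cfg$dtest))
  cfg$trend <- utils::modifyList(
    list(iterations = 50000, burnin = 10000, thin = 10, hyperprior = TRUE),
    as.list(cfg$trend))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the model suite across a sample of trees
#'
#' Fits the listed model structures to every tree, computes per-tree AICc,
#' per-tree delta-AICc and per-tree Akaike weights, and summarizes across
#' trees as means and standard deviations. The cross-tree weight summary is
#' the mean of the per-tree weights (not the weight of the mean AICc).
#'
#' @param trees list of `phylo` objects (or a `multiPhylo`).
#' @param states named tip-state vector (shared taxon set across trees).
#' @param models character vector of model names (default all seven).
#' @param n_starts optimizer starts per fit.
#' @param seed master seed for the per-fit random starts.
#' @return list with `per_tree` (list of per-tree fit lists), `aicc`
#'   (tree x model matrix), `summary` (data frame of mean/SD delta-AICc and
#'   mean/SD weight per model) and `best` (per-tree best model names).
#' @export
run_mk_suite <- function(trees, states, models = MK_MODEL_NAMES,
                         n_starts = 3, seed = 1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree", call. = FALSE)
  per_tree <- vector("list", length(trees))
  aicc_mat <- matrix(NA_real_, length(trees), length(models),
                     dimnames = list(NULL, models))
  w_mat <- aicc_mat
  failed <- logical(length(trees))
  for (i in seq_along(trees)) {
    fits <- list()
    ok <- TRUE
    for (m in models) {
      f <- tryCatch(
        fit_mk(trees[[i]], states, build_structure(m),
               n_starts = n_starts,
               seed = derive_seed(seed, paste0("fit_", m), i)),
        error = function(e) e)
      if (inherits(f, "error")) {
        warning("tree ", i, " model ", m, " failed: ",
                conditionMessage(f), call. = FALSE)
        ok <- FALSE
        break
      }
      fits[[m]] <- f
    }
    if (!ok) {
      failed[i] <- TRUE
      next
    }
    per_tree[[i]] <- fits
    aicc_mat[i, ] <- vapply(fits, function(f) f$aicc, numeric(1))
    w_mat[i, ] <- akaike_weights(aicc_mat[i, ])
  }
  keep <- !failed
  if (!any(keep)) stop("all trees failed to fit", call. = FALSE)
  delta <- aicc_mat[keep, , drop = FALSE] -
    apply(aicc_mat[keep, , drop = FALSE], 1, min)
  summary <- data.frame(
    model = models,
    mean_delta_aicc = colMeans(delta),
    sd_delta_aicc = apply(delta, 2, stats::sd),
    mean_weight = colMeans(w_mat[keep, , drop = FALSE]),
    sd_weight = apply(w_mat[keep, , drop = FALSE], 2, stats::sd),
    row.names = NULL)
  best <- rep(NA_character_, length(trees))
  for (i in which(keep)) best[i] <- best_fit(per_tree[[i]])$structure$name
  list(per_tree = per_tree, aicc = aicc_mat, weights = w_mat,
       summary = summary, best = best, failed = failed)
}

#' Run the full analysis pipeline
#'
#' Data mode: reads trees and tables from the config, fits the model suite,
#' draws stochastic maps under each tree's best-model rate matrix,
#' summarizes transitions and clade-wise empirical rates, runs the
#' aquatic-state/diet D-test, and fits the trend-BM model on the first
#' tree. All outputs land in `output_dir` with a `manifest.json` recording
#' input hashes, seeds and the package version.
#'
#' @param config a config list from [read_run_config()] (or equivalent).
#' @return invisible list of in-memory results.
#' @export
run_full <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- ape::read.tree(config$trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(tr) {
    tr$tip.label <- normalize_species(tr$tip.label)
    validate_phylogeny(tr)
    tr
  })
  tips <- read_tip_table(config$tip_table, tree = trees[[1]])
  clades <- read_clade_table(config$clade_table)
  states <- stats::setNames(tips$state, tips$species)
  seed <- config$seed

  ## (1) model suite
  suite <- run_mk_suite(trees, states, models = config$models,
                        n_starts = config$n_starts, seed = seed)
  utils::write.table(suite$summary,
                     file.path(config$output_dir, "mk_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  first_ok <- which(!suite$failed)[1]
  write_rate_matrix(model_average_Q(suite$per_tree[[first_ok]]),
                    file.path(config$output_dir, "model_averaged_Q.tsv"))
  write_mk_fits(suite$per_tree[[first_ok]],
                file.path(config$output_dir, "mk_fits.json"))

  ## (2) stochastic maps under each tree's best model; pooled summaries
  maps <- list()
  for (i in seq_along(trees)) {
    if (suite$failed[i]) next
    bf <- best_fit(suite$per_tree[[i]])
    for (j in seq_len(config$maps_per_tree)) {
      maps[[length(maps) + 1]] <-
        sample_map(trees[[i]], states, bf$Q,
                   seed = derive_seed(seed, "map", i * 1000 + j))
    }
  }
  trans <- summarize_transitions(maps)
  write_transition_summary(trans,
                           file.path(config$output_dir, "transitions.tsv"))
  partition <- assign_clades(trees[[1]], clades)
  first_tree_maps <- maps[seq_len(min(length(maps), config$maps_per_tree))]
  rates <- clade_empirical_rates(first_tree_maps, partition)
  rate_rows <- do.call(rbind, lapply(dimnames(rates)[[1]], function(cl) {
    cells <- which(rates[cl, , ] >= 0, arr.ind = TRUE)
    data.frame(clade = cl,
               from = dimnames(rates)[[2]][cells[, 1]],
               to = dimnames(rates)[[3]][cells[, 2]],
               rate = rates[cl, , ][cells])
  }))
  utils::write.table(rate_rows,
                     file.path(config$output_dir, "clade_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## (3) D-test: aquatic state vs diet on the first tree
  diet <- diet_classify(stats::setNames(tips$vert, tips$species),
                        stats::setNames(tips$invert, tips$species))
  bfX <- best_fit(suite$per_tree[[which(!suite$failed)[1]]])
  dietQ <- fit_mk(trees[[1]], diet,
                  mk_structure(diet_states(), "ARD"),
                  n_starts = config$n_starts,
                  seed = derive_seed(seed, "diet_fit"))$Q
  dres <- dtest(trees[[1]], states, diet, bfX$Q, dietQ,
                n_maps = config$dtest$n_maps,
                n_null = config$dtest$n_null,
                seed = derive_seed(seed, "dtest"))
  write_dtest(dres, file.path(config$output_dir, "dtest.tsv"))

  ## (4) trend-BM on the first tree
  probs <- marginal_ancestral_probs(trees[[1]], states, bfX$Q)
  assignment <- assign_branch_states(trees[[1]], probs, tip_states = states,
                                     partition = partition)
  post <- mcmc_run(trees[[1]],
                   stats::setNames(tips$log10_mass, tips$species),
                   assignment,
                   spec = trend_model_spec(hyperprior =
                                             config$trend$hyperprior),
                   settings = mcmc_settings(config$trend$iterations,
                                            config$trend$burnin,
                                            config$trend$thin,
                                            seed = derive_seed(seed,
                                                               "trend")))
  write_trend_log(post, file.path(config$output_dir, "trend_samples.tsv"))
  tr_sum <- lapply(stats::setNames(post$trend_names, post$trend_names),
                   function(s) {
                     sm <- summarize_trend(post, s)
                     list(mean = sm$mean, ci95 = sm$ci95,
                          p_positive = sm$p_positive,
                          percent_per_myr_of_mean =
                            percent_change_per_myr(sm$mean),
                          mean_percent_per_myr =
                            mean(percent_change_per_myr(
                              post$samples[[paste0("mu_", s)]])))
                   })
  jsonlite::write_json(tr_sum,
                       file.path(config$output_dir, "trend_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  ## manifest
  manifest <- list(
    inputs = list(trees = unname(tools::md5sum(config$trees)),
                  tip_table = unname(tools::md5sum(config$tip_table)),
                  clade_table = unname(tools::md5sum(config$clade_table))),
    seed = seed,
    package_version = as.character(utils::packageVersion("aquaevol")),
    n_trees = length(trees), maps_per_tree = config$maps_per_tree)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(suite = suite, maps = maps, transitions = trans,
                 clade_rates = rates, dtest = dres, trend = post,
                 manifest = manifest))
}

#' Run a simulation-recovery study
#'
#' Builds scenario bundles, runs the trend-BM MCMC on each (with and/or
#' without the hyperprior), classifies every state-group credible interval
#' against the truth, and tabulates the outcome proportions.
#'
#' @param scenario scenario id (1, 2 or 3).
#' @param n_replicates number of simulated bundles (default 20).
#' @param n_tips tips per simulated tree (default 300).
#' @param hyperprior logical vector of hyperprior settings to run
#'   (default `c(TRUE, FALSE)`).
#' @param iterations,burnin,thin MCMC settings per run.
#' @param seed master seed.
#' @return list with `records` (one row per replicate x group x setting)
#'   and `tables` (per-setting recovery tables).
#' @export
run_recovery <- function(scenario, n_replicates = 20, n_tips = 300,
                         hyperprior = c(TRUE, FALSE),
                         iterations = 50000, burnin = 10000, thin = 10,
                         seed = 1) {
  records <- list()
  for (r in seq_len(n_replicates)) {
    bundle <- build_scenario(scenario, n_tips = n_tips,
                             seed = derive_seed(seed, "bundle",
                                                scenario * 1000 + r))
    for (h in hyperprior) {
      post <- mcmc_run(bundle$tree, bundle$tip_values, bundle$assignment,
                       spec = trend_model_spec(hyperprior = h),
                       settings = mcmc_settings(iterations, burnin, thin,
                                                seed = derive_seed(
                                                  seed, "mcmc",
                                                  r * 10 + h)))
      for (s in post$trend_names) {
        sm <- summarize_trend(post, s)
        truth <- bundle$trends[[s]]
        records[[length(records) + 1]] <- data.frame(
          replicate = r, group = s, hyperprior = h, true_trend = truth,
          mean = sm$mean, lo95 = sm$ci95[1], hi95 = sm$ci95[2],
          classification = classify_outcome(truth, sm$ci95),
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  tables <- lapply(stats::setNames(unique(records$hyperprior),
                                   paste0("hyperprior_",
                                          unique(records$hyperprior))),
                   function(h) recovery_table(records[records$hyperprior == h, ]))
  list(records = records, tables = tables)
}
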