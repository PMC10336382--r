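# Bayesian Brownian-motion model of log body mass with clade-specific
# evolutionary rates and aquatic-state-specific trend parameters under
# hierarchical priors, sampled by MCMC (Gibbs for ancestral values and
# trends, Metropolis-Hastings for rates and the trend-prior scale,
# conjugate Gamma for the rate-prior parameter).

#' Assign branch states and clades
#'
#' Each branch is labelled with the state of its child node: tips use their
#' observed state, internal nodes use the modal state from marginal
#' ancestral probabilities (or the sampled node state of a stochastic map).
#' Branch clades come from the clade of the child node in the partition.
#'
#' @param tree a validated `phylo`.
#' @param inference either a node-by-state probability matrix from
#'   [marginal_ancestral_probs()] or a `stoch_map`.
#' @param tip_states named tip-state vector (observed states; required with
#'   a probability matrix, optional with a map).
#' @param partition a `clade_partition` for the same tree.
#' @return object of class `branch_assignment`: list with `state` and
#'   `clade` (one per row of `tree$edge`) and `states`/`clades` levels.
#' @export
assign_branch_states <- function(tree, inference, tip_states = NULL,
                                 partition = NULL) {
  validate_phylogeny(tree)
  nt <- n_tips(tree)
  nn <- n_nodes(tree)
  if (inherits(inference, "stoch_map")) {
    if (!identical(dim(inference$tree$edge), dim(tree$edge)))
      stop("map tree does not match", call. = FALSE)
    node_state <- inference$labels[inference$node_state]
  } else {
    if (!is.matrix(inference) || nrow(inference) != nn)
      stop("inference must be a node-by-state probability matrix for this tree",
           call. = FALSE)
    node_state <- colnames(inference)[max.col(inference, ties.method = "first")]
  }
  if (!is.null(tip_states)) {
    st <- align_tip_states(tree, tip_states)
    node_state[seq_len(nt)] <- as.character(st)
  }
  state <- node_state[tree$edge[, 2]]
  clade <- if (is.null(partition)) rep("background", nrow(tree$edge))
           else partition$node_clade[tree$edge[, 2]]
  structure(list(state = state, clade = clade,
                 states = sort(unique(state)),
                 clades = sort(unique(clade))),
            class = "branch_assignment")
}

#' Trend model specification
#'
#' @param variant one of `"full"` (partition-specific rates, one trend per
#'   aquatic state), `"single_rate_shared_trend"`, `"multi_rate_shared_trend"`
#'   (partition rates, one shared aquatic trend), `"single_rate_multi_trend"`.
#' @param hyperprior if `TRUE`, the trend-prior scale `sigma_trend` is free
#'   under an exponential hyperprior; otherwise it is fixed.
#' @param sigma_trend fixed trend-prior scale (default 0.1), also the MCMC
#'   initial value when free.
#' @param sigma_trend_hyper_rate rate of the exponential hyperprior on
#'   `sigma_trend` (default 10, i.e. prior mean 0.1).
#' @param lambda_free if `TRUE` (default), the rate-prior parameter
#'   `lambda` is free under an `Exp(1)` hyperprior.
#' @param lambda initial (or fixed) value of `lambda`.
#' @return object of class `trend_model_spec`.
#' @export
trend_model_spec <- function(variant = c("full", "single_rate_shared_trend",
                                         "multi_rate_shared_trend",
                                         "single_rate_multi_trend"),
                             hyperprior = TRUE, sigma_trend = 0.1,
                             sigma_trend_hyper_rate = 10,
                             lambda_free = TRUE, lambda = 1) {
  variant <- match.arg(variant)
  if (sigma_trend <= 0 || sigma_trend_hyper_rate <= 0 || lambda <= 0)
    stop("scales and rates must be positive", call. = FALSE)
  structure(list(variant = variant, hyperprior = hyperprior,
                 sigma_trend = sigma_trend,
                 sigma_trend_hyper_rate = sigma_trend_hyper_rate,
                 lambda_free = lambda_free, lambda = lambda),
            class = "trend_model_spec")
}

#' MCMC settings for the trend model
#'
#' @param iterations total MCMC iterations (default 500000, suited to
#'   empirical-scale trees; use ~50000 for small validation trees).
#' @param burnin number of discarded initial iterations (default 20% of
#'   `iterations`).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed integer seed.
#' @return list of settings.
#' @export
mcmc_settings <- function(iterations = 500000,
                          burnin = floor(0.2 * iterations),
                          thin = 100, seed = NULL) {
  if (iterations < 1 || burnin < 0 || burnin >= iterations || thin < 1)
    stop("invalid MCMC settings", call. = FALSE)
  list(iterations = as.integer(iterations), burnin = as.integer(burnin),
       thin = as.integer(thin), seed = seed)
}

#' Log-likelihood of trait values under the trend-BM model
#'
#' Sum over branches of the normal density
#' `x_child ~ N(x_parent + mu[state] * t, sigma2[clade] * t)`.
#' A zero-length branch contributes 0 when the endpoint values agree and
#' `-Inf` otherwise.
#'
#' @param tree a validated `phylo`.
#' @param tip_values named numeric vector of tip trait values.
#' @param node_values numeric vector of internal-node values (ape node
#'   order, root first).
#' @param assignment a `branch_assignment`.
#' @param rates named positive rates (trait variance per Myr) by clade.
#' @param trends named trends (trait units per Myr) by state; states absent
#'   from `trends` (e.g. A0) contribute no drift.
#' @return log-likelihood.
#' @export
bm_trend_loglik <- function(tree, tip_values, node_values, assignment,
                            rates, trends) {
  validate_phylogeny(tree)
  if (any(rates <= 0) || !all(is.finite(rates)))
    stop("rates must be positive", call. = FALSE)
  nt <- n_tips(tree)
  tip_values <- tip_values[tree$tip.label]
  if (anyNA(tip_values))
    stop("tip values missing for some tips", call. = FALSE)
  x <- c(unname(tip_values), unname(node_values))
  if (length(x) != n_nodes(tree))
    stop("need one value per node", call. = FALSE)
  mu_of <- function(s) {
    m <- trends[s]
    ifelse(is.na(m), 0, m)
  }
  ll <- 0
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    mu <- unname(mu_of(assignment$state[e]))
    s2 <- rates[[assignment$clade[e]]]
    if (is.null(s2) || is.na(s2))
      stop("no rate supplied for clade '", assignment$clade[e], "'",
           call. = FALSE)
    if (t == 0) {
      if (x[ch] != x[p]) return(-Inf)
      next
    }
    ll <- ll + stats::dnorm(x[ch], x[p] + mu * t, sqrt(s2 * t), log = TRUE)
  }
  ll
}

## map a branch assignment + model variant onto the sampler's group indices
trend_groups <- function(assignment, spec) {
  multi_trend <- spec$variant %in% c("full", "single_rate_multi_trend")
  multi_rate <- spec$variant %in% c("full", "multi_rate_shared_trend")
  aquatic <- c("A1", "A2", "A3")
  if (multi_trend) {
    grp_names <- aquatic
    trend_grp <- match(assignment$state, aquatic)
    trend_grp[is.na(trend_grp)] <- 0L
  } else {
    grp_names <- "aquatic"
    trend_grp <- ifelse(assignment$state %in% aquatic, 1L, 0L)
  }
  if (multi_rate) {
    rate_names <- sort(unique(assignment$clade))
    rate_grp <- match(assignment$clade, rate_names)
  } else {
    rate_names <- "global"
    rate_grp <- rep(1L, length(assignment$clade))
  }
  list(trend_grp = as.integer(trend_grp), rate_grp = as.integer(rate_grp),
       grp_names = grp_names, rate_names = rate_names)
}

## crude ancestral initialization: each internal node = mean of its children
init_node_values <- function(tree, tip_values) {
  nn <- n_nodes(tree)
  nt <- n_tips(tree)
  x <- numeric(nn)
  x[seq_len(nt)] <- tip_values[tree$tip.label]
  kids <- child_list(tree)
  for (v in postorder_nodes(tree)) x[v] <- mean(x[kids[[v]]])
  x
}

#' Run the trend-BM MCMC
#'
#' Samples clade rates, state trends, hyperparameters and ancestral values.
#' Ancestral values and trends are updated by Gibbs draws from their
#' conditional normals; rates and the trend-prior scale by
#' Metropolis-Hastings on the log scale (proposals adapted during burn-in
#' only); the rate-prior parameter `lambda` by its conjugate Gamma draw.
#'
#' @param tree a validated `phylo`.
#' @param tip_values named numeric tip trait values (log10 grams).
#' @param assignment a `branch_assignment` (see [assign_branch_states()]).
#' @param spec a `trend_model_spec`.
#' @param settings output of [mcmc_settings()].
#' @param root_prior optional list with `mean` and `sd`; defaults to a
#'   diffuse normal (mean = tip average, sd = 10 x tip standard deviation).
#' @param prior_only if `TRUE`, sample from the prior (no data term).
#' @return object of class `trend_posterior`: `samples` (data frame of
#'   retained draws), `node_mean`/`node_sd` (posterior summaries of node
#'   values), `trend_names`, `rate_names`, `spec`, `settings`.
#' @export
mcmc_run <- function(tree, tip_values, assignment,
                     spec = trend_model_spec(),
                     settings = mcmc_settings(), root_prior = NULL,
                     prior_only = FALSE) {
  validate_phylogeny(tree)
  nt <- n_tips(tree)
  nn <- n_nodes(tree)
  if (length(assignment$state) != nrow(tree$edge))
    stop("assignment does not match the tree", call. = FALSE)
  tip_values <- tip_values[tree$tip.label]
  if (anyNA(tip_values) || !all(is.finite(tip_values)))
    stop("tip values must be finite for every tip", call. = FALSE)
  g <- trend_groups(assignment, spec)
  ## per-node (branch-to-parent) arrays
  parent <- integer(nn)
  blen <- numeric(nn)
  trend_grp <- integer(nn)
  rate_grp <- rep(1L, nn)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    parent[ch] <- tree$edge[e, 1]
    blen[ch] <- tree$edge.length[e]
    trend_grp[ch] <- g$trend_grp[e]
    rate_grp[ch] <- g$rate_grp[e]
  }
  is_tip <- seq_len(nn) <= nt
  x0 <- init_node_values(tree, tip_values)
  if (is.null(root_prior))
    root_prior <- list(mean = mean(tip_values),
                       sd = max(10 * stats::sd(tip_values), 1e-3))
  height <- max(ape::node.depth.edgelength(tree))
  s2_init <- max(stats::var(tip_values) / max(height, 1e-6), 1e-6)
  R <- length(g$rate_names)
  G <- length(g$grp_names)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  init_rates <- stats::setNames(rep(s2_init,
                                    length(unique(assignment$clade))),
                                unique(assignment$clade))
  if (!prior_only &&
      !is.finite(bm_trend_loglik(tree, tip_values, x0[(nt + 1):nn],
                                 assignment, init_rates,
                                 stats::setNames(numeric(G),
                                                 g$grp_names))))
    stop("non-finite likelihood at initialization (check branch lengths ",
         "and trait values)", call. = FALSE)
  res <- trend_mcmc_cpp(parent, blen, trend_grp, rate_grp, is_tip, x0,
                        G, R, root_prior$mean, root_prior$sd,
                        FALSE,
                        spec$hyperprior, spec$sigma_trend,
                        spec$sigma_trend_hyper_rate,
                        spec$lambda_free, spec$lambda,
                        rep(s2_init, R),
                        FALSE,
                        prior_only,
                        settings$iterations, settings$burnin, settings$thin)
  cols <- c("logLik", paste0("sigma2_", g$rate_names),
            paste0("mu_", g$grp_names), "sigma_trend", "lambda", "root")
  samples <- as.data.frame(res$samples)
  names(samples) <- cols
  structure(list(samples = samples,
                 node_mean = res$node_mean, node_sd = res$node_sd,
                 trend_names = g$grp_names, rate_names = g$rate_names,
                 spec = spec, settings = settings,
                 root_prior = root_prior),
            class = "trend_posterior")
}

#' @export
print.trend_posterior <- function(x, ...) {
  cat("Trend-BM posterior:", nrow(x$samples), "retained samples;",
      length(x$rate_names), "rate partition(s),",
      length(x$trend_names), "trend group(s)\n")
  for (s in x$trend_names) {
    sm <- summarize_trend(x, s)
    cat(sprintf("  mu_%s: mean %.4f, 95%% CI [%.4f, %.4f], P(>0) = %.3f\n",
                s, sm$mean, sm$ci95[1], sm$ci95[2], sm$p_positive))
  }
  invisible(x)
}

#' Summarize a trend parameter
#'
#' @param posterior a `trend_posterior`.
#' @param state trend group name (e.g. `"A3"`, or `"aquatic"` for
#'   shared-trend variants).
#' @return list with `mean`, `ci95` (central 2.5-97.5% quantiles) and
#'   `p_positive` (posterior probability that the trend is positive).
#' @export
summarize_trend <- function(posterior, state) {
  col <- paste0("mu_", state)
  if (!col %in% names(posterior$samples))
    stop("no trend group '", state, "'; available: ",
         paste(posterior$trend_names, collapse = ", "), call. = FALSE)
  v <- posterior$samples[[col]]
  if (length(v) < 100)
    stop("too few retained samples (", length(v), " < 100)", call. = FALSE)
  list(mean = mean(v),
       ci95 = unname(stats::quantile(v, c(0.025, 0.975))),
       p_positive = mean(v > 0))
}

#' Convert a trend to percent change per Myr
#'
#' A trend `mu` on a log-scale trait corresponds to a relative change of
#' `(base^mu - 1) * 100` percent per Myr.
#'
#' @param mu trend in trait units per Myr.
#' @param base logarithm base of the trait scale: 10 (default) or `exp(1)`.
#' @return percent change per Myr.
#' @export
percent_change_per_myr <- function(mu, base = 10) {
  if (!is.numeric(base) || length(base) != 1 || !is.finite(base) || base <= 1)
    stop("base must be a finite number > 1 (10 or exp(1))", call. = FALSE)
  if (any(!is.finite(mu))) stop("mu must be finite", call. = FALSE)
  (base^mu - 1) * 100
}

#' Write the posterior sample log to TSV
#'
#' One row per retained sample.
#'
#' @param posterior a `trend_posterior`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trend_log <- function(posterior, path) {
  out <- cbind(iteration = seq_len(nrow(posterior$samples)),
               posterior$samples)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
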