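test_that("branch states come from child nodes, tips from observations", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  part <- assign_clades(tr, data.frame(species = c("A", "B", "C"),
                                       clade = c("X", "X", "Y")))
  ## near-zero rates, all tips A0: every branch A0
  Q <- assemble_Q(build_structure("ER"), 1e-12)
  st <- c(A = "A0", B = "A0", C = "A0")
  probs <- marginal_ancestral_probs(tr, st, Q)
  asg <- assign_branch_states(tr, probs, tip_states = st, partition = part)
  expect_true(all(asg$state == "A0"))
  expect_equal(asg$clade, part$node_clade[tr$edge[, 2]])
  ## an observed A3 tip keeps its state whatever the marginals say
  st2 <- c(A = "A3", B = "A0", C = "A0")
  probs2 <- marginal_ancestral_probs(tr, st2, default_sim_Q())
  asg2 <- assign_branch_states(tr, probs2, tip_states = st2,
                               partition = part)
  tipA_edge <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
  expect_equal(asg2$state[tipA_edge], "A3")
})

test_that("branch-state assignment recovers a strong-signal history", {
  tr <- simulate_tree(200, seed = 61)
  Q <- default_sim_Q()
  sim <- simulate_discrete(tr, Q, "A0", seed = 62)
  probs <- marginal_ancestral_probs(tr, sim$tip_states, Q)
  part <- partition_clades(tr, 6)
  asg <- assign_branch_states(tr, probs, tip_states = sim$tip_states,
                              partition = part)
  truth <- assign_branch_states(tr, sim$map, tip_states = sim$tip_states,
                                partition = part)
  agreement <- mean(asg$state == truth$state)
  expect_gte(agreement, 0.9)
})

test_that("trend-BM log-likelihood shifts means by mu * t", {
  tr <- read_newick("(A:10,B:10);")
  part <- assign_clades(tr, data.frame(species = c("A", "B"), clade = "X"))
  asg <- assign_branch_states(
    tr, matrix(c(1, 0, 0, 0), 3, 4, byrow = TRUE,
               dimnames = list(NULL, aquatic_states())),
    tip_states = c(A = "A3", B = "A0"), partition = part)
  rates <- c(X = 0.04, background = 0.04)
  trends <- c(A3 = 0.1)
  ## branch to A has trend 0.1 over t = 10: expected child mean = root + 1
  root_val <- 2
  ll <- function(xa) bm_trend_loglik(tr, c(A = xa, B = 2), root_val,
                                     asg, rates, trends)
  grid <- seq(2, 4, by = 0.01)
  expect_equal(grid[which.max(vapply(grid, ll, numeric(1)))], 3,
               tolerance = 0.02)
  ## doubling rates and branch lengths rescales the density consistently
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  ll1 <- bm_trend_loglik(tr, c(A = 3, B = 2), root_val, asg,
                         rates, trends = c(A3 = 0))
  ll2 <- bm_trend_loglik(tr2, c(A = 3, B = 2), root_val, asg,
                         rates / 2, trends = c(A3 = 0))
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("marginalized trend-BM likelihood matches the MVN closed form", {
  ## integrate the two internal-node values of a 3-tip tree numerically
  tr <- read_newick("((A:2,B:3):1.5,C:4);")
  part <- assign_clades(tr, data.frame(species = c("A", "B", "C"),
                                       clade = "X"))
  st <- c(A = "A0", B = "A0", C = "A0")
  asg <- assign_branch_states(
    tr, marginal_ancestral_probs(tr, st, assemble_Q(build_structure("ER"),
                                                    1e-9)),
    tip_states = st, partition = part)
  sigma2 <- 0.3
  rates <- c(X = sigma2, background = sigma2)
  tipv <- c(A = 0.4, B = -0.2, C = 0.9)
  root_val <- 0.1
  ## node order: 4 = root (fixed), 5 = (A,B) ancestor (integrated)
  f <- Vectorize(function(x5)
    exp(bm_trend_loglik(tr, tipv, c(root_val, x5), asg, rates,
                        trends = c(A3 = 0))))
  marg <- stats::integrate(f, -10, 10, rel.tol = 1e-10)$value
  want <- mvn_bm_loglik(tr, tipv, root_val, sigma2,
                        edge_mu = rep(0, nrow(tr$edge)))
  expect_equal(log(marg), want, tolerance = 1e-6)
})

test_that("single-branch trend posterior matches the conjugate closed form", {
  t <- 10; sig2 <- 0.04; x_parent <- 1.0; x_child <- 1.8; s_mu <- 0.1
  set.seed(301)
  res <- aquaevol:::trend_mcmc_cpp(
    parent = c(0L, 1L), blen = c(0, t), trend_grp = c(0L, 1L),
    rate_grp = c(1L, 1L), is_tip = c(FALSE, TRUE),
    x_init = c(x_parent, x_child), G = 1L, R = 1L,
    root_mean = 0, root_sd = 10, root_fixed = TRUE,
    s_mu_free = FALSE, s_mu_init = s_mu, s_mu_hyper_rate = 10,
    lambda_free = FALSE, lambda_init = 1, sigma2_init = sig2,
    rates_fixed = TRUE, prior_only = FALSE,
    iterations = 55000L, burnin = 5000L, thin = 1L)
  mu <- res$samples[, 3]
  prec <- t / sig2 + 1 / s_mu^2
  post_mean <- ((x_child - x_parent) / sig2) / prec
  post_sd <- 1 / sqrt(prec)
  expect_equal(mean(mu), post_mean, tolerance = 0.02 * post_sd / post_mean)
  expect_equal(sd(mu), post_sd, tolerance = 0.02)
})

test_that("prior-only runs reproduce the trend prior", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  part <- assign_clades(tr, data.frame(species = c("A", "B", "C"),
                                       clade = "X"))
  st <- c(A = "A1", B = "A0", C = "A0")
  asg <- assign_branch_states(
    tr, marginal_ancestral_probs(tr, st, default_sim_Q()),
    tip_states = st, partition = part)
  post <- mcmc_run(tr, c(A = 1, B = 2, C = 3), asg,
                   spec = trend_model_spec(hyperprior = FALSE,
                                           sigma_trend = 0.1),
                   settings = mcmc_settings(30000, 3000, 3, seed = 5),
                   prior_only = TRUE)
  mu <- post$samples$mu_A1
  expect_equal(mean(mu), 0, tolerance = 0.005)
  expect_equal(sd(mu), 0.1, tolerance = 0.005)
  expect_equal(mean(mu > 0), 0.5, tolerance = 0.03)
})

test_that("ancestral-value posterior matches the analytic Gaussian", {
  ## mu = 0, one fixed rate: node values | tips are exactly Gaussian.
  ## 3-tip tree ((A:2,B:3):1.5,C:4); nodes 1..3 tips, 4 root, 5 = (A,B).
  sig2 <- 0.3
  tipv <- c(A = 0.4, B = -0.2, C = 0.9)
  root_prior <- list(mean = 0, sd = 2)
  set.seed(401)
  res <- aquaevol:::trend_mcmc_cpp(
    parent = c(5L, 5L, 4L, 0L, 4L),
    blen = c(2, 3, 4, 0, 1.5),
    trend_grp = integer(5), rate_grp = rep(1L, 5),
    is_tip = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    x_init = c(tipv, 0, 0), G = 1L, R = 1L,
    root_mean = root_prior$mean, root_sd = root_prior$sd,
    root_fixed = FALSE,
    s_mu_free = FALSE, s_mu_init = 0.1, s_mu_hyper_rate = 10,
    lambda_free = FALSE, lambda_init = 1, sigma2_init = sig2,
    rates_fixed = TRUE, prior_only = FALSE,
    iterations = 60000L, burnin = 10000L, thin = 1L)
  ## exact conditional precision/mean for (x4, x5)
  v <- function(t) sig2 * t
  P <- matrix(0, 2, 2); b <- numeric(2)
  P[1, 1] <- 1 / root_prior$sd^2 + 1 / v(1.5) + 1 / v(4)
  P[2, 2] <- 1 / v(1.5) + 1 / v(2) + 1 / v(3)
  P[1, 2] <- P[2, 1] <- -1 / v(1.5)
  b[1] <- root_prior$mean / root_prior$sd^2 + tipv["C"] / v(4)
  b[2] <- tipv["A"] / v(2) + tipv["B"] / v(3)
  S <- solve(P)
  exact_mean <- drop(S %*% b)
  exact_sd <- sqrt(diag(S))
  expect_equal(res$node_mean[4:5], exact_mean, tolerance = 0.02)
  expect_equal(res$node_sd[4:5], exact_sd, tolerance = 0.05)
})

test_that("trend recovery covers a known positive trend", {
  ## strong signal: one clade, many A3 branches with mu = 0.05
  covered <- 0
  for (rep in 1:10) {
    tr <- simulate_tree(120, seed = 500 + rep)
    part <- partition_clades(tr, 2)
    nt <- 120
    state <- ifelse(tr$edge[, 2] %% 2 == 0, "A3", "A0")
    asg <- structure(list(state = state,
                          clade = part$node_clade[tr$edge[, 2]],
                          states = c("A0", "A3"),
                          clades = c(part$clades, "background")),
                     class = "branch_assignment")
    sim <- simulate_continuous(tr, asg,
                               clade_rates = c(C1 = 0.05, C2 = 0.08,
                                               background = 0.05),
                               state_trends = c(A3 = 0.05),
                               root_value = 2, seed = 600 + rep)
    post <- mcmc_run(tr, sim$tip_values, asg,
                     spec = trend_model_spec(hyperprior = TRUE),
                     settings = mcmc_settings(20000, 4000, 10,
                                              seed = 700 + rep))
    sm <- summarize_trend(post, "A3")
    if (sm$ci95[1] <= 0.05 && 0.05 <= sm$ci95[2]) covered <- covered + 1
  }
  expect_gte(covered, 9)
})

test_that("the hyperprior makes true-zero trend intervals no wider", {
  tr <- simulate_tree(150, seed = 91)
  part <- partition_clades(tr, 4)
  sim <- simulate_discrete(tr, default_sim_Q(), "A0", seed = 92)
  asg <- assign_branch_states(tr, sim$map, tip_states = sim$tip_states,
                              partition = part)
  cont <- simulate_continuous(tr, asg,
                              clade_rates = setNames(
                                rep(0.05, 5), c(part$clades, "background")),
                              state_trends = c(A1 = 0, A2 = 0, A3 = 0),
                              root_value = 2, seed = 93)
  widths <- sapply(c(TRUE, FALSE), function(h) {
    post <- mcmc_run(tr, cont$tip_values, asg,
                     spec = trend_model_spec(hyperprior = h),
                     settings = mcmc_settings(20000, 4000, 10, seed = 94))
    sm <- summarize_trend(post, "A1")
    sm$ci95[2] - sm$ci95[1]
  })
  expect_lte(widths[1], widths[2] * 1.15)
})

test_that("trend summaries and percent conversion behave", {
  fake <- structure(list(samples = data.frame(mu_A3 = rep(0.05, 200)),
                         trend_names = "A3"), class = "trend_posterior")
  sm <- summarize_trend(fake, "A3")
  expect_equal(sm$mean, 0.05)
  expect_equal(sm$ci95, c(0.05, 0.05))
  expect_equal(sm$p_positive, 1)
  set.seed(2)
  fake2 <- structure(list(samples = data.frame(mu_A1 = rnorm(20000)),
                          trend_names = "A1"), class = "trend_posterior")
  sm2 <- summarize_trend(fake2, "A1")
  expect_equal(sm2$ci95, c(-1.96, 1.96), tolerance = 0.05)
  expect_equal(sm2$p_positive, 0.5, tolerance = 0.02)
  expect_error(summarize_trend(fake, "A9"), "no trend group")
  short <- structure(list(samples = data.frame(mu_A3 = rep(1, 10)),
                          trend_names = "A3"), class = "trend_posterior")
  expect_error(summarize_trend(short, "A3"), "too few")

  expect_equal(percent_change_per_myr(0), 0)
  expect_equal(percent_change_per_myr(1, 10), 900)
  expect_equal(percent_change_per_myr(0.047, 10), 11.43, tolerance = 0.01)
  expect_equal(percent_change_per_myr(0.1, exp(1)),
               (exp(0.1) - 1) * 100)
  expect_error(percent_change_per_myr(0.1, base = -2), "base")
})

test_that("model variants collapse groups as specified", {
  tr <- simulate_tree(60, seed = 55)
  part <- partition_clades(tr, 3)
  sim <- simulate_discrete(tr, default_sim_Q(), "A0", seed = 56)
  asg <- assign_branch_states(tr, sim$map, tip_states = sim$tip_states,
                              partition = part)
  cont <- simulate_continuous(tr, asg,
                              clade_rates = setNames(
                                rep(0.1, 4), c(part$clades, "background")),
                              state_trends = c(A1 = 0, A2 = 0, A3 = 0),
                              root_value = 2, seed = 57)
  p1 <- mcmc_run(tr, cont$tip_values, asg,
                 spec = trend_model_spec("single_rate_shared_trend"),
                 settings = mcmc_settings(2000, 500, 5, seed = 58))
  expect_equal(p1$rate_names, "global")
  expect_equal(p1$trend_names, "aquatic")
  p2 <- mcmc_run(tr, cont$tip_values, asg,
                 spec = trend_model_spec("multi_rate_shared_trend"),
                 settings = mcmc_settings(2000, 500, 5, seed = 59))
  expect_equal(length(p2$rate_names), 4)
  expect_equal(p2$trend_names, "aquatic")
  p3 <- mcmc_run(tr, cont$tip_values, asg,
                 spec = trend_model_spec("single_rate_multi_trend"),
                 settings = mcmc_settings(2000, 500, 5, seed = 60))
  expect_equal(p3$rate_names, "global")
  expect_equal(length(p3$trend_names), 3)
})
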