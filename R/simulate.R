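# Synthetic-data generation with known truth: birth-death trees, discrete
# histories under a chosen rate matrix, continuous traits under
# clade-specific-rate BM with state-specific trends, the three validation
# scenarios, and credible-interval outcome classification.

#' Simulate a pure-birth tree rescaled to root age 100 Myr
#'
#' @param n_tips number of tips (>= 3).
#' @param seed optional integer seed.
#' @return an ultrametric `phylo` with root age 100.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 3) stop("n_tips must be >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 0.1, death = 0)
  height <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (100 / height)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  validate_phylogeny(tree)
  tree
}

#' Forward-simulate a discrete character down a tree
#'
#' Simulates the continuous-time Markov chain with generator `Q` from the
#' root state, recording the full piecewise-constant history.
#'
#' @param tree a validated `phylo`.
#' @param Q rate matrix with state labels as dimnames.
#' @param root_state root state label (default: first state).
#' @param seed optional integer seed.
#' @return list with `tip_states` (named by tip label) and `map` (the true
#'   history as a `stoch_map`).
#' @export
simulate_discrete <- function(tree, Q, root_state = rownames(Q)[1],
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prep <- sim_prep(tree)
  labels <- rownames(Q)
  res <- sim_discrete_flat(prep, Q, root_state)
  nt <- n_tips(tree)
  maps <- Map(function(s, d) list(state = labels[s], duration = d),
              split(res$st, factor(res$br, levels = seq_len(nrow(tree$edge)))),
              split(res$du, factor(res$br, levels = seq_len(nrow(tree$edge)))))
  names(maps) <- NULL
  map <- structure(list(tree = tree, labels = labels,
                        node_state = res$node_state, maps = maps),
                   class = "stoch_map")
  tips <- stats::setNames(labels[res$node_state[seq_len(nt)]],
                          tree$tip.label)
  list(tip_states = tips, map = map)
}

## precomputed preorder edge representation for repeated forward simulation
sim_prep <- function(tree) {
  validate_phylogeny(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  orig <- match(paste(po$edge[pre, 1], po$edge[pre, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  list(edge_pre = po$edge[pre, , drop = FALSE],
       elen_pre = po$edge.length[pre], orig_idx = orig,
       n_node = n_nodes(tree), n_tip = n_tips(tree),
       n_edge = nrow(tree$edge))
}

## flattened forward simulation (internal fast path)
sim_discrete_flat <- function(prep, Q, root_state) {
  validate_rate_matrix(Q)
  rs <- match(root_state, rownames(Q))
  if (is.na(rs)) stop("unknown root state: ", root_state, call. = FALSE)
  sim_discrete_cpp(prep$edge_pre, prep$elen_pre, prep$orig_idx,
                   prep$n_node, prep$n_tip, Q, rs)
}

#' Simulate a continuous trait under trend-BM
#'
#' Recursive sampling `x_child ~ N(x_parent + mu_b * t, sigma2_b * t)` with
#' per-branch trend and rate taken from the assignment.
#'
#' @param tree a validated `phylo`.
#' @param assignment a `branch_assignment`.
#' @param clade_rates named positive rates by clade (trait variance / Myr).
#' @param state_trends named trends by state (trait units / Myr); states
#'   absent from the vector (e.g. A0) evolve without drift.
#' @param root_value trait value at the root.
#' @param edge_trend optional per-edge trend vector overriding the
#'   state-based lookup (used for scenario 3's random background trends).
#' @param seed optional integer seed.
#' @return list with `tip_values` (named) and `node_values` (internal
#'   nodes, ape order).
#' @export
simulate_continuous <- function(tree, assignment, clade_rates, state_trends,
                                root_value, edge_trend = NULL, seed = NULL) {
  validate_phylogeny(tree)
  if (any(clade_rates <= 0)) stop("rates must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nn <- n_nodes(tree)
  nt <- n_tips(tree)
  x <- numeric(nn)
  x[nt + 1L] <- root_value
  po <- ape::reorder.phylo(tree, "postorder")
  idx <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in rev(seq_len(nrow(po$edge)))) {  # preorder
    a <- po$edge[e, 1]; b <- po$edge[e, 2]
    t <- po$edge.length[e]
    i <- idx[e]
    mu <- if (!is.null(edge_trend)) edge_trend[i] else {
      m <- state_trends[assignment$state[i]]
      if (is.na(m)) 0 else unname(m)
    }
    s2 <- clade_rates[[assignment$clade[i]]]
    x[b] <- x[a] + mu * t + stats::rnorm(1, 0, sqrt(s2 * t))
  }
  list(tip_values = stats::setNames(x[seq_len(nt)], tree$tip.label),
       node_values = x[(nt + 1L):nn])
}

#' Partition a tree's tips into monophyletic clades
#'
#' Deterministically splits the tree into `n_clades` monophyletic tip
#' groups by repeatedly splitting the largest group at its crown node.
#'
#' @param tree a validated `phylo`.
#' @param n_clades number of clades (>= 2, <= tips).
#' @return a `clade_partition` (clades named `C1`, `C2`, ...).
#' @export
partition_clades <- function(tree, n_clades = 8) {
  validate_phylogeny(tree)
  nt <- n_tips(tree)
  if (n_clades < 2 || n_clades > nt)
    stop("n_clades must lie in [2, number of tips]", call. = FALSE)
  below <- tips_under(tree)
  kids <- child_list(tree)
  groups <- kids[[root_node(tree)]]
  while (length(groups) < n_clades) {
    sizes <- vapply(groups, function(v) length(below[[v]]), numeric(1))
    splittable <- which(groups > nt)  # internal nodes only
    if (!length(splittable)) break
    pick <- splittable[which.max(sizes[splittable])]
    v <- groups[pick]
    groups <- c(groups[-pick], kids[[v]])
  }
  tab <- do.call(rbind, lapply(seq_along(groups), function(i)
    data.frame(species = tree$tip.label[below[[groups[i]]]],
               clade = paste0("C", i), stringsAsFactors = FALSE)))
  assign_clades(tree, tab)
}

#' Default discrete-evolution rate matrix for simulations
#'
#' An IR_2132-structure matrix (reversals only between A0 and A1)
#' calibrated so that a lineage starting at A0 has roughly a 4% chance of
#' being aquatic (A1-A3) after 100 Myr, emulating the mammalian state
#' composition.
#'
#' @return 4 x 4 rate matrix.
#' @export
default_sim_Q <- function() {
  assemble_Q(build_structure("IR_2132"),
             c(6e-4, 8e-3, 6e-3, 2e-2))
}

#' Default clade-rate sampler
#'
#' Log-uniform on `[0.01, 0.5]` (trait variance per Myr), standing in for
#' the posterior rate distributions of the empirical analysis.
#'
#' @param n number of rates to draw.
#' @return numeric vector of rates.
#' @export
default_rate_sampler <- function(n) {
  10^stats::runif(n, log10(0.01), log10(0.5))
}

#' Build a validation-scenario bundle
#'
#' Scenario 1: neutral evolution (all trends zero), clade rates from the
#' sampler. Scenario 2: independent trends `U(-0.1, 0.1)` for A1-A3,
#' neutral terrestrial (A0) branches. Scenario 3: as scenario 2, plus an
#' independent `U(-0.1, 0.1)` trend for the A0 branches of each clade.
#'
#' @param id scenario 1, 2 or 3.
#' @param n_tips tips of the simulated tree (default 400).
#' @param n_clades clades in the rate partition (default 8; background
#'   added automatically).
#' @param tree,partition optionally reuse an existing tree and partition.
#' @param rate_sampler function drawing clade rates
#'   (default [default_rate_sampler()]).
#' @param Q discrete-evolution rate matrix (default [default_sim_Q()]).
#' @param root_value trait root value (default 2, i.e. 100 g).
#' @param seed integer seed; the bundle is fully reproducible from it.
#' @return object of class `scenario_bundle` with the tree, partition, true
#'   discrete history, tip states, true branch assignment, true clade rates
#'   and trends, trait values, scenario id and seed.
#' @export
build_scenario <- function(id, n_tips = 400, n_clades = 8, tree = NULL,
                           partition = NULL,
                           rate_sampler = default_rate_sampler,
                           Q = default_sim_Q(), root_value = 2,
                           seed = NULL) {
  if (!id %in% 1:3) stop("scenario id must be 1, 2 or 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- simulate_tree(n_tips)
  if (is.null(partition)) partition <- partition_clades(tree, n_clades)
  disc <- simulate_discrete(tree, Q, root_state = "A0")
  assignment <- assign_branch_states(tree, disc$map,
                                     tip_states = disc$tip_states,
                                     partition = partition)
  clade_names <- c(partition$clades, "background")
  clade_rates <- stats::setNames(rate_sampler(length(clade_names)),
                                 clade_names)
  aquatic <- c("A1", "A2", "A3")
  trends <- stats::setNames(numeric(3), aquatic)
  if (id >= 2) trends[] <- stats::runif(3, -0.1, 0.1)
  edge_trend <- NULL
  background_trends <- NULL
  if (id == 3) {
    background_trends <- stats::setNames(
      stats::runif(length(clade_names), -0.1, 0.1), clade_names)
    edge_trend <- numeric(nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      s <- assignment$state[e]
      edge_trend[e] <- if (s %in% aquatic) trends[[s]]
                       else background_trends[[assignment$clade[e]]]
    }
  }
  cont <- simulate_continuous(tree, assignment, clade_rates, trends,
                              root_value, edge_trend = edge_trend)
  structure(list(tree = tree, partition = partition,
                 history = disc$map, tip_states = disc$tip_states,
                 assignment = assignment, clade_rates = clade_rates,
                 trends = trends, background_trends = background_trends,
                 tip_values = cont$tip_values,
                 node_values = cont$node_values,
                 root_value = root_value, scenario = id, seed = seed),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("Scenario", x$scenario, "bundle:", length(x$tip_states), "tips,",
      length(x$partition$clades), "clades; aquatic tips:",
      sum(x$tip_states != "A0"), "\n")
  invisible(x)
}

#' Classify a credible interval against the true trend
#'
#' With a zero true trend: interval containing 0 is a `true_negative`,
#' entirely positive an `overestimate`, entirely negative an
#' `underestimate`. With a nonzero true trend: interval covering the truth
#' is a `true_positive`, entirely above it an `overestimate`, entirely
#' below an `underestimate`.
#'
#' @param true_trend true trend value.
#' @param ci95 numeric length-2 interval (lower, upper).
#' @return one of `"underestimate"`, `"true_negative"`, `"overestimate"`,
#'   `"true_positive"`.
#' @export
classify_outcome <- function(true_trend, ci95) {
  if (ci95[1] > ci95[2]) stop("CI lower bound exceeds upper", call. = FALSE)
  covers <- ci95[1] <= true_trend && true_trend <= ci95[2]
  if (true_trend == 0) {
    if (covers) return("true_negative")
    return(if (ci95[1] > 0) "overestimate" else "underestimate")
  }
  if (covers) return("true_positive")
  if (ci95[1] > true_trend) "overestimate" else "underestimate"
}

#' Per-group proportions of outcome classifications
#'
#' @param records data frame with columns `group` and `classification`.
#' @return matrix of proportions (groups x classifications); rows sum to 1.
#' @export
recovery_table <- function(records) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  lv <- c("underestimate", "true_negative", "overestimate", "true_positive")
  tab <- table(factor(records$group),
               factor(records$classification, levels = lv))
  if (any(rowSums(tab) == 0)) stop("empty group", call. = FALSE)
  prop <- tab / rowSums(tab)
  unclass(prop)
}

#' Serialize a scenario bundle to a directory
#'
#' Writes `tree.nwk`, `history.simmap`, `tips.tsv` (states and trait
#' values) and `truth.json` (rates, trends, scenario, seed).
#'
#' @param bundle a `scenario_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  write_simmap(bundle$history, file.path(dir, "history.simmap"))
  tips <- data.frame(species = names(bundle$tip_states),
                     state = unname(bundle$tip_states),
                     value = unname(bundle$tip_values),
                     clade = unname(bundle$partition$tip_clade[
                       names(bundle$tip_states)]))
  utils::write.table(tips, file.path(dir, "tips.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(scenario = bundle$scenario, seed = bundle$seed,
                clade_rates = as.list(bundle$clade_rates),
                trends = as.list(bundle$trends),
                background_trends = as.list(bundle$background_trends),
                root_value = bundle$root_value)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
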