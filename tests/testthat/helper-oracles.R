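# Shared fixtures and independent oracles used across the test files.

## random rooted binary tree with positive branch lengths
rand_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

## random rate matrix with all off-diagonal rates positive
random_Q <- function(K, labels = paste0("s", seq_len(K)), max_rate = 1) {
  Q <- matrix(stats::runif(K * K, 0.05, max_rate), K, K,
              dimnames = list(labels, labels))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

## exhaustive-enumeration likelihood oracle with the FitzJohn-Maddison
## root rule: sums transition-probability products over every assignment
## of internal-node states (feasible for <= 5 tips)
enum_root_conditionals <- function(tree, states, Q) {
  K <- nrow(Q)
  labels <- rownames(Q)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  tip_idx <- match(states[tree$tip.label], labels)
  internal <- (nt + 1):nn
  m <- length(internal)
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) transition_probs(Q, tree$edge.length[e]))
  root <- nt + 1
  L <- numeric(K)
  grid <- as.matrix(expand.grid(rep(list(1:K), m)))
  for (g in seq_len(nrow(grid))) {
    assign <- integer(nn)
    assign[seq_len(nt)] <- tip_idx
    assign[internal] <- grid[g, ]
    pr <- 1
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      pr <- pr * P[[e]][assign[a], assign[b]]
    }
    L[assign[root]] <- L[assign[root]] + pr
  }
  L
}

enum_pruning <- function(tree, states, Q) {
  L <- enum_root_conditionals(tree, states, Q)
  log(sum(L^2) / sum(L))
}

## per-node marginal posterior by enumeration under the same root rule
enum_marginals <- function(tree, states, Q) {
  K <- nrow(Q)
  labels <- rownames(Q)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  tip_idx <- match(states[tree$tip.label], labels)
  internal <- (nt + 1):nn
  m <- length(internal)
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) transition_probs(Q, tree$edge.length[e]))
  Lroot <- enum_root_conditionals(tree, states, Q)
  pi_root <- Lroot / sum(Lroot)
  root <- nt + 1
  M <- matrix(0, nn, K, dimnames = list(NULL, labels))
  grid <- as.matrix(expand.grid(rep(list(1:K), m)))
  for (g in seq_len(nrow(grid))) {
    assign <- integer(nn)
    assign[seq_len(nt)] <- tip_idx
    assign[internal] <- grid[g, ]
    pr <- pi_root[assign[root]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      pr <- pr * P[[e]][assign[a], assign[b]]
    }
    for (v in seq_len(nn)) M[v, assign[v]] <- M[v, assign[v]] + pr
  }
  M / rowSums(M)
}

## analytic log-likelihood of tip values under single-rate BM with
## per-branch drift, conditioned on the root value: multivariate normal
## with mean root + sum of drift along each root-to-tip path and
## covariance sigma2 * shared path length
mvn_bm_loglik <- function(tree, tip_values, root_value, sigma2, edge_mu) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  parent <- integer(nn); elen <- numeric(nn); emu <- numeric(nn)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
    emu[tree$edge[e, 2]] <- edge_mu[e]
  }
  path_nodes <- function(v) {
    out <- integer(0)
    while (parent[v] != 0) {
      out <- c(out, v)
      v <- parent[v]
    }
    out
  }
  paths <- lapply(seq_len(nt), path_nodes)
  mu <- root_value + vapply(paths, function(p) sum(emu[p] * elen[p]),
                            numeric(1))
  C <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sigma2 * sum(elen[shared])
  }
  x <- tip_values[tree$tip.label] - mu
  -0.5 * (nt * log(2 * pi) + determinant(C)$modulus[1] +
            drop(x %*% solve(C, x)))
}

## two-state symmetric chain: exact stay probability
two_state_stay <- function(r, t) (1 + exp(-2 * r * t)) / 2

## construct a stoch_map by hand from a tree and per-edge segment lists
hand_map <- function(tree, labels, segs) {
  node_state <- integer(length(tree$tip.label) + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    node_state[tree$edge[e, 2]] <- match(segs[[e]]$state[
      length(segs[[e]]$state)], labels)
  }
  rt <- length(tree$tip.label) + 1L
  e1 <- which(tree$edge[, 1] == rt)[1]
  node_state[rt] <- match(segs[[e1]]$state[1], labels)
  structure(list(tree = tree, labels = labels, node_state = node_state,
                 maps = segs), class = "stoch_map")
}
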