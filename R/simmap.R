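# Stochastic character mapping: joint ancestral sampling by backward
# filtering / forward sampling, endpoint-conditioned branch histories by
# uniformization, transition counts, clade-wise empirical rates, and the
# phytools-style simmap newick dialect.

## Backward (pruning) pass. Returns scaled per-node conditional likelihoods
## of the data below each node, per-edge transition matrices (postorder),
## and the FitzJohn-Maddison root weights.
pruning_pass <- function(tree, states, Q) {
  validate_rate_matrix(Q)
  labels <- rownames(Q)
  st <- align_tip_states(tree, states)
  si <- state_indices(st, labels)
  K <- length(labels)
  po <- ape::reorder.phylo(tree, "postorder")
  nn <- n_nodes(tree)
  nt <- n_tips(tree)
  D <- matrix(1, nn, K)
  for (i in seq_len(nt)) {
    D[i, ] <- 0
    D[i, si[i]] <- 1
  }
  es <- q_eigen(Q)
  E <- nrow(po$edge)
  P <- vector("list", E)
  for (e in seq_len(E)) {
    a <- po$edge[e, 1]; b <- po$edge[e, 2]
    P[[e]] <- probs_from_eigen(es, Q, po$edge.length[e])
    w <- as.vector(P[[e]] %*% D[b, ])
    m <- max(w)
    if (m <= 0)
      stop("tip data have probability 0 under Q", call. = FALSE)
    D[a, ] <- D[a, ] * (w / m)
  }
  root <- nt + 1L
  pi_root <- D[root, ] / sum(D[root, ])
  list(tree = po, D = D, P = P, pi_root = pi_root, labels = labels)
}

#' Marginal ancestral state probabilities
#'
#' Posterior marginal state probabilities at every node under the
#' FitzJohn-Maddison root treatment (root weights proportional to the root
#' conditional likelihoods).
#'
#' @param tree a validated `phylo`.
#' @param states named tip-state vector.
#' @param Q rate matrix with state labels as dimnames.
#' @return matrix (tips + internal nodes) x K of probabilities; each row
#'   sums to 1. Row order follows ape node numbering.
#' @export
marginal_ancestral_probs <- function(tree, states, Q) {
  pp <- pruning_pass(tree, states, Q)
  po <- pp$tree
  K <- length(pp$labels)
  nn <- n_nodes(tree)
  nt <- n_tips(tree)
  root <- nt + 1L
  O <- matrix(NA_real_, nn, K)
  O[root, ] <- pp$pi_root
  E <- nrow(po$edge)
  ## sibling edge index for each edge (binary tree)
  sib <- integer(E)
  for (e in seq_len(E)) {
    same <- which(po$edge[, 1] == po$edge[e, 1])
    sib[e] <- same[same != e]
  }
  ## preorder over postorder edges = reverse order
  for (e in rev(seq_len(E))) {
    a <- po$edge[e, 1]; b <- po$edge[e, 2]
    ws <- as.vector(pp$P[[sib[e]]] %*% pp$D[po$edge[sib[e], 2], ])
    up <- O[a, ] * ws
    O[b, ] <- as.vector(up %*% pp$P[[e]])
  }
  M <- O * pp$D
  M <- M / rowSums(M)
  colnames(M) <- pp$labels
  M
}

## cache of powers of the uniformized jump matrix
rpow_env <- function(Rmat) {
  env <- new.env(parent = emptyenv())
  env$pows <- list(diag(nrow(Rmat)), Rmat)  # R^0, R^1
  env$get <- function(n) {
    while (length(env$pows) < n + 1)
      env$pows[[length(env$pows) + 1]] <-
        env$pows[[length(env$pows)]] %*% Rmat
    env$pows[[n + 1]]
  }
  env
}

## Endpoint-conditioned CTMC path on one branch by uniformization.
## Returns list(state, duration) ordered rootward -> tipward,
## states as integer indices.
sample_branch_history <- function(Q, a, b, t, P_t = NULL, cache = NULL) {
  K <- nrow(Q)
  Omega <- max(-diag(Q))
  if (Omega <= 0 || t == 0) {
    if (a != b)
      stop("endpoint pair unreachable on branch (zero rates)", call. = FALSE)
    return(list(state = a, duration = t))
  }
  if (is.null(P_t)) P_t <- transition_probs(Q, t)
  pab <- P_t[a, b]
  if (pab <= 0)
    stop("endpoint pair unreachable under Q (probability 0)", call. = FALSE)
  Rmat <- diag(K) + Q / Omega
  if (is.null(cache)) cache <- rpow_env(Rmat)
  ## sample number of uniformized jumps
  u <- stats::runif(1)
  n <- -1L
  cum <- 0
  lpois_const <- -Omega * t
  repeat {
    n <- n + 1L
    pn <- exp(lpois_const + n * log(Omega * t) - lfactorial(n)) *
      cache$get(n)[a, b] / pab
    cum <- cum + pn
    if (u <= cum || n > 5000L) break
  }
  if (n == 0L) return(list(state = a, duration = t))
  times <- sort(stats::runif(n, 0, t))
  s <- integer(n + 1)
  s[1] <- a
  s[n + 1] <- b
  if (n > 1) {
    for (k in 2:n) {
      w <- Rmat[s[k - 1], ] * cache$get(n + 1 - k)[, b]
      s[k] <- sample.int(K, 1, prob = w)
    }
  } else {
    ## n == 1: single jump, endpoint already fixed
  }
  ## collapse virtual (self) jumps into segments
  bounds <- c(0, times, t)
  keep <- c(TRUE, s[-1] != s[-length(s)])
  seg_state <- s[keep]
  seg_start <- bounds[-length(bounds)][keep]
  seg_end <- c(seg_start[-1], t)
  list(state = seg_state, duration = seg_end - seg_start)
}

#' Sample a stochastic character map
#'
#' Draws a full character history consistent with the tip data and `Q`:
#' joint node states by backward filtering / forward sampling, then
#' endpoint-conditioned branch histories by uniformization.
#'
#' @param tree a validated `phylo`.
#' @param states named tip-state vector.
#' @param Q rate matrix with state labels as dimnames.
#' @param seed optional integer seed.
#' @return an object of class `stoch_map`: list with `tree`, `labels`,
#'   `node_state` (integer indices per node) and `maps` (per edge of
#'   `tree$edge`, a list of `state`/`duration` segment vectors ordered
#'   rootward to tipward, states as labels).
#' @export
sample_map <- function(tree, states, Q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pp <- pruning_pass(tree, states, Q)
  po <- pp$tree
  nt <- n_tips(tree)
  nn <- n_nodes(tree)
  root <- nt + 1L
  K <- length(pp$labels)
  node_state <- integer(nn)
  w_root <- pp$pi_root * pp$D[root, ]
  node_state[root] <- sample.int(K, 1, prob = w_root)
  E <- nrow(po$edge)
  for (e in rev(seq_len(E))) {  # preorder
    a <- po$edge[e, 1]; b <- po$edge[e, 2]
    w <- pp$P[[e]][node_state[a], ] * pp$D[b, ]
    node_state[b] <- sample.int(K, 1, prob = w)
  }
  Omega <- max(-diag(Q))
  cache <- if (Omega > 0) rpow_env(diag(K) + Q / Omega) else NULL
  ## build per-edge histories in the original tree's edge order
  maps <- vector("list", nrow(tree$edge))
  po_index <- match(paste(tree$edge[, 1], tree$edge[, 2]),
                    paste(po$edge[, 1], po$edge[, 2]))
  for (i in seq_len(nrow(tree$edge))) {
    e <- po_index[i]
    a <- po$edge[e, 1]; b <- po$edge[e, 2]
    h <- sample_branch_history(Q, node_state[a], node_state[b],
                               po$edge.length[e], P_t = pp$P[[e]],
                               cache = cache)
    maps[[i]] <- list(state = pp$labels[h$state],
                      duration = h$duration)
  }
  structure(list(tree = tree, labels = pp$labels,
                 node_state = node_state, maps = maps),
            class = "stoch_map")
}

#' @export
print.stoch_map <- function(x, ...) {
  nt <- length(x$tree$tip.label)
  cat("Stochastic map on", nt, "tips;",
      sum(count_transitions(x)), "transitions\n")
  invisible(x)
}

#' Count state transitions in a stochastic map
#'
#' @param map a `stoch_map`.
#' @return K x K integer matrix; entry (i, j) counts i -> j segment
#'   boundaries over all branches.
#' @export
count_transitions <- function(map) {
  K <- length(map$labels)
  M <- matrix(0L, K, K, dimnames = list(map$labels, map$labels))
  for (seg in map$maps) {
    ns <- length(seg$state)
    if (ns < 2) next
    for (i in seq_len(ns - 1)) {
      a <- seg$state[i]; b <- seg$state[i + 1]
      M[a, b] <- M[a, b] + 1L
    }
  }
  M
}

#' Summarize transition counts across stochastic maps
#'
#' Median and central 95% interval of the per-cell transition counts across
#' a pool of maps.
#'
#' @param maps list of `stoch_map` objects on the same state space.
#' @return data.frame with columns `from`, `to`, `median`, `lo95`, `hi95`
#'   (off-diagonal cells only), plus a `"median_matrix"` attribute.
#' @export
summarize_transitions <- function(maps) {
  if (!length(maps)) stop("need at least one map", call. = FALSE)
  labels <- maps[[1]]$labels
  K <- length(labels)
  counts <- vapply(maps, function(m) count_transitions(m),
                   matrix(0L, K, K))
  med <- apply(counts, c(1, 2), stats::median)
  lo <- apply(counts, c(1, 2), stats::quantile, probs = 0.025)
  hi <- apply(counts, c(1, 2), stats::quantile, probs = 0.975)
  cells <- which(row(med) != col(med), arr.ind = TRUE)
  out <- data.frame(from = labels[cells[, 1]], to = labels[cells[, 2]],
                    median = med[cells], lo95 = lo[cells], hi95 = hi[cells],
                    stringsAsFactors = FALSE)
  dimnames(med) <- list(labels, labels)
  attr(out, "median_matrix") <- med
  out
}

#' Clade-wise empirical transition rates
#'
#' Mean transition count within each clade across maps, divided by the
#' clade's total branch length; a transition belongs to the clade of the
#' branch it occurs on (branches belong to the clade of their child node).
#'
#' @param maps list of `stoch_map` objects on the same tree.
#' @param partition a `clade_partition` for that tree.
#' @param include_background include the background partition (default TRUE).
#' @return 3-d array `[clade, from, to]` of rates per Myr.
#' @export
clade_empirical_rates <- function(maps, partition, include_background = TRUE) {
  if (!length(maps)) stop("need at least one map", call. = FALSE)
  tree <- maps[[1]]$tree
  labels <- maps[[1]]$labels
  K <- length(labels)
  clades <- partition$clades
  edge_clade <- partition$node_clade[tree$edge[, 2]]
  if (include_background && any(edge_clade == "background"))
    clades <- c(clades, "background")
  out <- array(0, dim = c(length(clades), K, K),
               dimnames = list(clades, labels, labels))
  for (cl in clades) {
    tl <- total_branch_length(tree, partition, cl)
    if (tl <= 0)
      stop("clade '", cl, "' has zero total branch length", call. = FALSE)
    acc <- matrix(0, K, K)
    for (m in maps) {
      for (i in which(edge_clade == cl)) {
        seg <- m$maps[[i]]
        ns <- length(seg$state)
        if (ns < 2) next
        for (s in seq_len(ns - 1)) {
          a <- match(seg$state[s], labels)
          b <- match(seg$state[s + 1], labels)
          acc[a, b] <- acc[a, b] + 1
        }
      }
    }
    out[cl, , ] <- acc / length(maps) / tl
  }
  out
}

## simmap annotation for one edge: {s1,d1:s2,d2} rootward -> tipward
simmap_annot <- function(seg, digits = 10) {
  paste0("{", paste(sprintf("%s,%s", seg$state,
                            formatC(seg$duration, digits = digits,
                                    format = "g")),
                    collapse = ":"), "}")
}

#' Write a stochastic map in simmap newick dialect
#'
#' Branch annotations `:{state,duration:state,duration}` ordered rootward
#' to tipward, as used by phytools.
#'
#' @param map a `stoch_map`.
#' @param file optional path; if empty the string is returned.
#' @param digits significant digits for durations (default 10).
#' @return the simmap string (invisibly when writing to file).
#' @export
write_simmap <- function(map, file = "", digits = 10) {
  tree <- map$tree
  nt <- n_tips(tree)
  kids <- child_list(tree)
  eoc <- edge_of_child(tree)
  rec <- function(v) {
    core <- if (v <= nt) tree$tip.label[v]
            else paste0("(", paste(vapply(kids[[v]], rec, character(1)),
                                   collapse = ","), ")")
    e <- eoc[v]
    if (is.na(e)) return(core)  # root
    paste0(core, ":", simmap_annot(map$maps[[e]], digits))
  }
  s <- paste0(rec(root_node(tree)), ";")
  if (nzchar(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read a stochastic map from simmap newick dialect
#'
#' @param text simmap string (or use `file`).
#' @param file path to a simmap file.
#' @param tree optional reference tree; if supplied, segment durations must
#'   sum to its branch lengths (relative tolerance 1e-8).
#' @return a `stoch_map` (without node-state indices for internal nodes;
#'   these are implied by the segment endpoints).
#' @export
read_simmap <- function(text = NULL, file = NULL, tree = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'text' or 'file'", call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  m <- gregexpr("\\{[^}]*\\}", text)[[1]]
  if (m[1] == -1) stop("no simmap annotations found", call. = FALSE)
  blocks <- regmatches(text, gregexpr("\\{[^}]*\\}", text))[[1]]
  ## replace i-th block with sentinel length i, parse topology with ape
  plain <- text
  for (i in seq_along(blocks))
    plain <- sub("\\{[^}]*\\}", as.character(i), plain)
  ptree <- tryCatch(ape::read.tree(text = plain), error = function(e)
    stop("malformed simmap annotation: ", conditionMessage(e),
         call. = FALSE))
  if (is.null(ptree)) stop("malformed simmap string", call. = FALSE)
  segs <- lapply(blocks, function(b) {
    b <- substr(b, 2, nchar(b) - 1)
    parts <- strsplit(b, ":", fixed = TRUE)[[1]]
    st <- character(length(parts)); du <- numeric(length(parts))
    for (j in seq_along(parts)) {
      kv <- strsplit(parts[j], ",", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        stop("malformed simmap annotation: '", parts[j], "'", call. = FALSE)
      st[j] <- kv[1]
      du[j] <- as.numeric(kv[2])
    }
    if (anyNA(du) || any(du < 0))
      stop("malformed simmap durations", call. = FALSE)
    list(state = st, duration = du)
  })
  maps <- vector("list", nrow(ptree$edge))
  for (e in seq_len(nrow(ptree$edge))) {
    i <- as.integer(round(ptree$edge.length[e]))
    maps[[e]] <- segs[[i]]
    ptree$edge.length[e] <- sum(segs[[i]]$duration)
  }
  if (!is.null(tree)) {
    ## identify edges across the two numberings by the set of tip labels
    ## descending from the child node
    edge_key <- function(tr) {
      below <- tips_under(tr)
      vapply(seq_len(nrow(tr$edge)), function(e)
        paste(sort(tr$tip.label[below[[tr$edge[e, 2]]]]), collapse = "|"),
        character(1))
    }
    idx <- match(edge_key(tree), edge_key(ptree))
    if (anyNA(idx))
      stop("simmap topology does not match the reference tree",
           call. = FALSE)
    maps <- maps[idx]
    lens <- vapply(maps, function(s) sum(s$duration), numeric(1))
    if (max(abs(lens - tree$edge.length)) >
        1e-8 * max(1, max(tree$edge.length)))
      stop("segment durations do not sum to the reference branch lengths",
           call. = FALSE)
    ptree <- tree
  }
  labels <- sort(unique(unlist(lapply(maps, function(s) s$state))))
  nt <- length(ptree$tip.label)
  node_state <- integer(nt + ptree$Nnode)
  for (e in seq_len(nrow(ptree$edge)))
    node_state[ptree$edge[e, 2]] <- match(maps[[e]]$state[length(maps[[e]]$state)],
                                          labels)
  rt <- nt + 1L
  e1 <- which(ptree$edge[, 1] == rt)[1]
  node_state[rt] <- match(maps[[e1]]$state[1], labels)
  structure(list(tree = ptree, labels = labels, node_state = node_state,
                 maps = maps), class = "stoch_map")
}

#' Write a transition summary to TSV
#'
#' @param summary output of [summarize_transitions()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_transition_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
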