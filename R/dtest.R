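# Diet classification and the D-test of correlated evolution between two
# discrete characters, based on stochastic character maps with significance
# from posterior predictive simulation.

#' Classify diet from vertebrate and invertebrate fractions
#'
#' The animal fraction (vertebrate + invertebrate) determines the category:
#' below 20% herbivore, 20-80% (inclusive) omnivore, above 80% carnivore.
#'
#' @param vert,invert diet fractions in `[0, 1]` (vectorized).
#' @return character vector of `"herbivore"`, `"omnivore"`, `"carnivore"`.
#' @export
diet_classify <- function(vert, invert) {
  if (any(vert < 0 | vert > 1 | invert < 0 | invert > 1, na.rm = FALSE))
    stop("diet fractions must lie in [0, 1]", call. = FALSE)
  animal <- vert + invert
  if (any(animal > 1 + 1e-9))
    stop("vert + invert exceeds 1", call. = FALSE)
  out <- ifelse(animal < 0.20, "herbivore",
                ifelse(animal > 0.80, "carnivore", "omnivore"))
  names(out) <- names(vert)
  out
}

#' Diet state labels
#' @return the three diet categories, ordered herbivore < omnivore <
#'   carnivore.
#' @export
diet_states <- function() c("herbivore", "omnivore", "carnivore")

## flatten a map's segments: branch ids, state indices, durations
flatten_map <- function(map) {
  sts <- lapply(map$maps, `[[`, "state")
  ns <- lengths(sts)
  list(br = rep(seq_along(ns), ns),
       st = match(unlist(sts, use.names = FALSE), map$labels),
       du = unlist(lapply(map$maps, `[[`, "duration"), use.names = FALSE))
}

#' Joint occupancy of two stochastic maps
#'
#' Fraction of total tree time jointly spent in each state pair `(i, j)`,
#' computed by overlaying segment boundaries branch by branch.
#'
#' @param mapX,mapY `stoch_map` objects on the same tree.
#' @return matrix `a` with `a[i, j] >= 0` and `sum(a) == 1`; rows are X
#'   states, columns Y states.
#' @export
joint_occupancy <- function(mapX, mapY) {
  tx <- mapX$tree; ty <- mapY$tree
  if (!identical(dim(tx$edge), dim(ty$edge)) ||
      !identical(tx$edge, ty$edge) ||
      max(abs(tx$edge.length - ty$edge.length)) >
        1e-8 * max(1, max(tx$edge.length)))
    stop("maps are not on the same tree", call. = FALSE)
  fx <- flatten_map(mapX)
  fy <- flatten_map(mapY)
  A <- overlay_occupancy_cpp(fx$br, fx$st, fx$du, fy$br, fy$st, fy$du,
                             length(mapX$labels), length(mapY$labels),
                             nrow(tx$edge))
  dimnames(A) <- list(mapX$labels, mapY$labels)
  A / sum(A)
}

## time fraction per state of one map
state_time_fractions <- function(map) {
  f <- flatten_map(map)
  tot <- numeric(length(map$labels))
  for (i in seq_along(f$st)) tot[f$st[i]] <- tot[f$st[i]] + f$du[i]
  stats::setNames(tot / sum(tot), map$labels)
}

## association matrix of one pair of histories: joint occupancy minus the
## product of marginal time fractions (= products of a's margins)
d_stat <- function(mapX, mapY) {
  a <- joint_occupancy(mapX, mapY)
  a - outer(rowSums(a), colSums(a))
}

#' D-test of correlated evolution between two discrete characters
#'
#' The observed association `d[i, j]` is the joint time fraction in state
#' pair `(i, j)` minus the product of the marginal time fractions, averaged
#' over `n_maps` pairs of stochastic maps (each trait mapped conditional on
#' its own tip data). The null distribution comes from `n_null` pairs of
#' unconditioned forward simulations of the two traits evolved
#' independently under `QX` and `QY` (root states drawn from each trait's
#' FitzJohn-Maddison root weights), scored identically. The cellwise
#' predictive p-value is the upper tail `P(d_null >= d_obs)`: p near 0
#' indicates positive association, p near 1 negative association.
#'
#' @param tree a validated `phylo`.
#' @param traitX,traitY named tip-state vectors.
#' @param QX,QY rate matrices with state labels as dimnames.
#' @param n_maps number of paired stochastic maps for the observed statistic
#'   (default 100).
#' @param n_null number of null simulation pairs (default 1000).
#' @param seed optional integer seed.
#' @return object of class `dtest_result`: list with `d` (association
#'   matrix, sums to 0), `p` (cellwise predictive p-values), `n_maps`,
#'   `n_null`.
#' @export
dtest <- function(tree, traitX, traitY, QX, QY, n_maps = 100,
                  n_null = 1000, seed = NULL) {
  if (n_maps < 1 || n_null < 1)
    stop("n_maps and n_null must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  validate_phylogeny(tree)
  d_acc <- NULL
  for (m in seq_len(n_maps)) {
    mx <- sample_map(tree, traitX, QX)
    my <- sample_map(tree, traitY, QY)
    dm <- d_stat(mx, my)
    d_acc <- if (is.null(d_acc)) dm else d_acc + dm
  }
  d_obs <- d_acc / n_maps
  ## posterior root weights for the null simulations
  rootX <- pruning_pass(tree, traitX, QX)$pi_root
  rootY <- pruning_pass(tree, traitY, QY)$pi_root
  labX <- rownames(QX); labY <- rownames(QY)
  prep <- sim_prep(tree)
  exceed <- matrix(0, nrow(d_obs), ncol(d_obs))
  for (r in seq_len(n_null)) {
    rx <- labX[sample.int(length(labX), 1, prob = rootX)]
    ry <- labY[sample.int(length(labY), 1, prob = rootY)]
    hx <- sim_discrete_flat(prep, QX, rx)
    hy <- sim_discrete_flat(prep, QY, ry)
    A <- overlay_occupancy_cpp(hx$br, hx$st, hx$du, hy$br, hy$st, hy$du,
                               length(labX), length(labY), prep$n_edge)
    a <- A / sum(A)
    dn <- a - outer(rowSums(a), colSums(a))
    exceed <- exceed + (dn >= d_obs)
  }
  p <- exceed / n_null
  dimnames(p) <- dimnames(d_obs)
  structure(list(d = d_obs, p = p, n_maps = n_maps, n_null = n_null),
            class = "dtest_result")
}

#' @export
print.dtest_result <- function(x, ...) {
  cat("D-test (", x$n_maps, "maps,", x$n_null, "null simulations )\n")
  cat("association d:\n"); print(round(x$d, 4))
  cat("predictive p (upper tail):\n"); print(round(x$p, 3))
  invisible(x)
}

#' Write a D-test result to TSV
#'
#' @param result a `dtest_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dtest <- function(result, path) {
  cells <- which(!is.na(result$d), arr.ind = TRUE)
  out <- data.frame(stateX = rownames(result$d)[cells[, 1]],
                    stateY = colnames(result$d)[cells[, 2]],
                    d = result$d[cells], p = result$p[cells])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
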