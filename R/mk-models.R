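# Constrained Markov models of the ordered aquatic-adaptation character:
# model structures, pruning likelihood, maximum-likelihood fitting, AICc
# ranking and Akaike-weight model averaging.

MK_MODEL_NAMES <- c("ER", "SYM", "ORD", "ARD", "IR_32", "IR_2132", "IR_102132")

#' Build one of the seven transition-model structures
#'
#' The structures operate on the ordered states A0 < A1 < A2 < A3:
#' \describe{
#'   \item{ER}{one shared rate for all 12 transitions (k = 1)}
#'   \item{SYM}{symmetric rates, `q_ij = q_ji` (k = 6)}
#'   \item{ORD}{transitions only between adjacent states (k = 6)}
#'   \item{IR_32}{ORD with A3->A2 forbidden (k = 5)}
#'   \item{IR_2132}{ORD with A3->A2 and A2->A1 forbidden, i.e. reversals
#'     only between A0 and A1 (k = 4)}
#'   \item{IR_102132}{ORD with all backward transitions forbidden (k = 3)}
#'   \item{ARD}{all 12 rates free (k = 12)}
#' }
#'
#' @param name one of `"ER"`, `"SYM"`, `"ORD"`, `"ARD"`, `"IR_32"`,
#'   `"IR_2132"`, `"IR_102132"`.
#' @return an object of class `mk_structure`: list with `name`, `states`,
#'   `index` (K x K integer matrix; 0 = forbidden, equal positive integers
#'   share a rate) and `k` (number of free parameters).
#' @export
build_structure <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% MK_MODEL_NAMES)
    stop("unknown model name; valid names: ",
         paste(MK_MODEL_NAMES, collapse = ", "), call. = FALSE)
  states <- aquatic_states()
  K <- length(states)
  idx <- matrix(0L, K, K, dimnames = list(states, states))
  fill_adjacent <- function(idx, forbid = character()) {
    cells <- list(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3))
    labs <- c("A0->A1", "A1->A0", "A1->A2", "A2->A1", "A2->A3", "A3->A2")
    p <- 0L
    for (i in seq_along(cells)) {
      if (labs[i] %in% forbid) next
      p <- p + 1L
      idx[cells[[i]][1], cells[[i]][2]] <- p
    }
    idx
  }
  idx <- switch(name,
    ER = { idx[row(idx) != col(idx)] <- 1L; idx },
    SYM = {
      p <- 0L
      for (i in 1:(K - 1)) for (j in (i + 1):K) {
        p <- p + 1L
        idx[i, j] <- p
        idx[j, i] <- p
      }
      idx
    },
    ARD = { idx[row(idx) != col(idx)] <- seq_len(K * (K - 1)); idx },
    ORD = fill_adjacent(idx),
    IR_32 = fill_adjacent(idx, forbid = "A3->A2"),
    IR_2132 = fill_adjacent(idx, forbid = c("A2->A1", "A3->A2")),
    IR_102132 = fill_adjacent(idx, forbid = c("A1->A0", "A2->A1", "A3->A2"))
  )
  structure(list(name = name, states = states, index = idx,
                 k = max(idx)), class = "mk_structure")
}

#' Generic model structure for an arbitrary state set
#'
#' ER, SYM, ORD and ARD structures over any ordered label set; used e.g. for
#' the three-level diet character in the D-test.
#'
#' @param states character vector of state labels (order matters for ORD).
#' @param type one of `"ER"`, `"SYM"`, `"ORD"`, `"ARD"`.
#' @return an `mk_structure`.
#' @export
mk_structure <- function(states, type = c("ER", "SYM", "ORD", "ARD")) {
  type <- match.arg(type)
  K <- length(states)
  if (K < 2) stop("need at least two states", call. = FALSE)
  idx <- matrix(0L, K, K, dimnames = list(states, states))
  if (type == "ER") idx[row(idx) != col(idx)] <- 1L
  if (type == "ARD") idx[row(idx) != col(idx)] <- seq_len(K * (K - 1))
  if (type == "SYM") {
    p <- 0L
    for (i in 1:(K - 1)) for (j in (i + 1):K) {
      p <- p + 1L; idx[i, j] <- p; idx[j, i] <- p
    }
  }
  if (type == "ORD") {
    p <- 0L
    for (i in 1:(K - 1)) {
      p <- p + 1L; idx[i, i + 1] <- p
      p <- p + 1L; idx[i + 1, i] <- p
    }
  }
  structure(list(name = paste0(type, "_", K, "state"), states = states,
                 index = idx, k = max(idx)), class = "mk_structure")
}

#' @export
print.mk_structure <- function(x, ...) {
  cat("Mk model structure '", x$name, "' (k = ", x$k, ")\n", sep = "")
  print(x$index)
  invisible(x)
}

#' Assemble a rate matrix from a structure and parameter values
#'
#' @param structure an `mk_structure`.
#' @param params numeric vector of `structure$k` positive rates (per Myr).
#' @return K x K rate matrix Q with rows summing to zero; forbidden cells
#'   are exactly 0.
#' @export
assemble_Q <- function(structure, params) {
  if (!inherits(structure, "mk_structure"))
    stop("'structure' must be an mk_structure", call. = FALSE)
  if (length(params) != structure$k)
    stop("expected ", structure$k, " rates, got ", length(params),
         call. = FALSE)
  if (!all(is.finite(params)) || any(params <= 0))
    stop("rates must be positive and finite", call. = FALSE)
  idx <- structure$index
  Q <- matrix(0, nrow(idx), ncol(idx), dimnames = dimnames(idx))
  Q[idx > 0] <- params[idx[idx > 0]]
  diag(Q) <- -rowSums(Q)
  Q
}

validate_rate_matrix <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("Q must be a square matrix", call. = FALSE)
  off <- Q[row(Q) != col(Q)]
  if (any(off < 0) || !all(is.finite(Q)))
    stop("off-diagonal rates must be finite and >= 0", call. = FALSE)
  if (max(abs(rowSums(Q))) > 1e-8 * max(1, max(abs(Q))))
    stop("rows of Q must sum to 0", call. = FALSE)
  invisible(Q)
}

## P(t) = exp(Qt) via Taylor with scaling-and-squaring (fallback path)
expm_ss <- function(M) {
  nrm <- max(abs(M))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  A <- M / 2^s
  P <- diag(nrow(M))
  term <- diag(nrow(M))
  for (i in 1:14) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

## eigen system of Q for repeated exp(Qt); NULL when unreliable
q_eigen <- function(Q) {
  es <- tryCatch(eigen(Q), error = function(e) NULL)
  if (is.null(es)) return(NULL)
  Vi <- tryCatch(solve(es$vectors), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  recon <- Re(es$vectors %*% (es$values * Vi))
  if (max(abs(recon - Q)) > 1e-9 * max(1, max(abs(Q)))) return(NULL)
  list(values = es$values, V = es$vectors, Vi = Vi)
}

probs_from_eigen <- function(es, Q, t) {
  P <- if (is.null(es)) expm_ss(Q * t)
       else Re(es$V %*% (exp(es$values * t) * es$Vi))
  P[P < 0] <- 0
  P[P > 1] <- 1
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Transition probability matrix of the chain after time t
#'
#' @param Q rate matrix (rows sum to 0).
#' @param t elapsed time in Myr, `t >= 0`.
#' @return K x K stochastic matrix `exp(Qt)`.
#' @export
transition_probs <- function(Q, t) {
  validate_rate_matrix(Q)
  if (!is.finite(t) || t < 0) stop("t must be >= 0", call. = FALSE)
  probs_from_eigen(q_eigen(Q), Q, t)
}

## internal: postorder edge representation + integer tip states
mk_data <- function(tree, states, state_labels) {
  validate_phylogeny(tree)
  st <- align_tip_states(tree, states)
  si <- state_indices(st, state_labels)
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, edge_length = po$edge.length,
       n_tip = n_tips(tree), tip_state = unname(si))
}

#' Pruning log-likelihood of tip states under a rate matrix
#'
#' Felsenstein pruning with the FitzJohn-Maddison root treatment: root
#' weights are proportional to the conditional likelihoods at the root,
#' `pi_i = L_i / sum_j L_j`, and the total likelihood is `sum_i pi_i L_i`.
#'
#' @param tree a validated `phylo`.
#' @param states named character (or factor) vector of tip states.
#' @param Q rate matrix with state labels as dimnames.
#' @return natural-log likelihood.
#' @export
pruning_loglik <- function(tree, states, Q) {
  validate_rate_matrix(Q)
  labels <- rownames(Q)
  if (is.null(labels)) stop("Q needs state labels as dimnames", call. = FALSE)
  d <- mk_data(tree, states, labels)
  mk_pruning_loglik_cpp(Q, d$edge, d$edge_length, d$n_tip, d$tip_state)
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param lnL log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (here, number of tips).
#' @return AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1", call. = FALSE)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values numeric vector (at least 2 values; `Inf` allowed,
#'   `NaN`/`NA` rejected).
#' @return vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 2)
    stop("need at least two AICc values", call. = FALSE)
  if (any(is.na(aicc_values)))
    stop("AICc values must not be NA/NaN", call. = FALSE)
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Fit an Mk model by maximum likelihood
#'
#' Optimizes the pruning log-likelihood over the structure's free rates on
#' the log scale (L-BFGS-B, rates bounded to `[1e-9, 1e3]` per Myr) from
#' `n_starts` initializations: one heuristic start at 1/tree-height plus
#' random log-normal perturbations.
#'
#' @param tree a validated `phylo`.
#' @param states named tip-state vector.
#' @param structure an `mk_structure`.
#' @param n_starts number of optimizer starts (default 5).
#' @param seed optional integer seed for the random starts.
#' @return an object of class `mk_fit`: list with `structure`, `rates`,
#'   `Q`, `loglik`, `k`, `n`, `aicc`, `convergence`.
#' @export
fit_mk <- function(tree, states, structure, n_starts = 5, seed = NULL) {
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  d <- mk_data(tree, states, structure$states)
  k <- structure$k
  idx <- structure$index
  pos <- which(idx > 0)
  par_of <- idx[pos]
  K <- length(structure$states)
  base <- matrix(0, K, K)
  negll <- function(logr) {
    r <- exp(logr)
    Q <- base
    Q[pos] <- r[par_of]
    diag(Q) <- -rowSums(Q)
    ll <- mk_pruning_loglik_cpp(Q, d$edge, d$edge_length, d$n_tip,
                                d$tip_state)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  height <- max(ape::node.depth.edgelength(tree))
  r0 <- log(max(1 / height, 1e-6))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  starts <- c(list(rep(r0, k)),
              replicate(n_starts - 1,
                        r0 + stats::rnorm(k, 0, 1.5), simplify = FALSE))
  best <- NULL
  failures <- character()
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = log(1e-9), upper = log(1e3),
                   control = list(maxit = 500)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("Mk fit failed for all starts: ",
         paste(unique(failures), collapse = "; "), call. = FALSE)
  rates <- exp(best$par)
  Q <- assemble_Q(structure, rates)
  lnL <- -best$value
  n <- d$n_tip
  structure(list(structure = structure, rates = rates, Q = Q,
                 loglik = lnL, k = k, n = n,
                 aicc = aicc(lnL, k, n),
                 convergence = best$convergence),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit:", x$structure$name,
      sprintf("| lnL = %.4f, k = %d, n = %d, AICc = %.4f\n",
              x$loglik, x$k, x$n, x$aicc))
  invisible(x)
}

#' Akaike-weight model average of rate matrices
#'
#' Entrywise weighted average of the fitted rate matrices, with weights
#' computed from the fits' AICc values.
#'
#' @param fits list of `mk_fit` objects on the same state space.
#' @return averaged rate matrix (rows sum to 0) with attribute `"weights"`.
#' @export
model_average_Q <- function(fits) {
  if (!length(fits)) stop("need at least one fit", call. = FALSE)
  K <- nrow(fits[[1]]$Q)
  if (!all(vapply(fits, function(f) nrow(f$Q) == K, logical(1))))
    stop("fits have mismatched state spaces", call. = FALSE)
  if (length(fits) == 1) {
    Q <- fits[[1]]$Q
    attr(Q, "weights") <- 1
    return(Q)
  }
  w <- akaike_weights(vapply(fits, function(f) f$aicc, numeric(1)))
  Q <- Reduce(`+`, Map(function(f, wi) wi * f$Q, fits, w))
  attr(Q, "weights") <- stats::setNames(
    w, vapply(fits, function(f) f$structure$name, character(1)))
  Q
}

#' Select the best fit by AICc (ties broken by fewer parameters)
#'
#' @param fits list of `mk_fit` objects.
#' @return the selected `mk_fit`.
#' @export
best_fit <- function(fits) {
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  fits[[order(a, k)[1]]]
}

#' Write a rate matrix to TSV with state-labelled rows and columns
#'
#' @param Q rate matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rate_matrix <- function(Q, path) {
  utils::write.table(cbind(state = rownames(Q), as.data.frame(Q)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize Mk fits to JSON
#'
#' @param fits list of `mk_fit` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mk_fits <- function(fits, path) {
  out <- lapply(fits, function(f)
    list(model = f$structure$name, rates = f$rates, loglik = f$loglik,
         k = f$k, n = f$n, aicc = f$aicc))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
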