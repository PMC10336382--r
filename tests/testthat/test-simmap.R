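test_that("marginal ancestral probabilities match the enumeration oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    K <- sample(2:3, 1)
    tr <- rand_tree(n)
    Q <- random_Q(K)
    states <- setNames(sample(rownames(Q), n, replace = TRUE),
                       tr$tip.label)
    got <- marginal_ancestral_probs(tr, states, Q)
    want <- enum_marginals(tr, states, Q)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("marginals collapse to the tip data when rates vanish", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  Q <- assemble_Q(build_structure("ER"), 1e-12)
  st <- c(A = "A0", B = "A0", C = "A0")
  M <- marginal_ancestral_probs(tr, st, Q)
  expect_equal(unname(M[, "A0"]), rep(1, 5), tolerance = 1e-6)
  ## invariance to child order
  tr2 <- read_newick("((B:1,A:1):1,C:2);")
  Q2 <- assemble_Q(build_structure("SYM"), runif(6, 0.05, 0.5))
  st2 <- c(A = "A0", B = "A1", C = "A2")
  M1 <- marginal_ancestral_probs(tr, st2, Q2)
  M2 <- marginal_ancestral_probs(tr2, st2, Q2)
  ## root row (node 4) must agree regardless of child order
  expect_equal(M1[4, ], M2[4, ], tolerance = 1e-12)
})

test_that("sampled node states reproduce the exact marginals", {
  tr <- rand_tree(4, seed = 5)
  Q <- random_Q(3, labels = c("x", "y", "z"), max_rate = 0.4)
  states <- setNames(c("x", "y", "x", "z"), tr$tip.label)
  M <- marginal_ancestral_probs(tr, states, Q)
  n_maps <- 4000
  root <- 5L
  set.seed(71)
  counts <- matrix(0, 3, 3)  # internal nodes 5:7 x states
  for (i in seq_len(n_maps)) {
    m <- sample_map(tr, states, Q)
    for (v in 5:7)
      counts[v - 4, m$node_state[v]] <- counts[v - 4, m$node_state[v]] + 1
  }
  freq <- counts / n_maps
  for (v in 5:7) for (s in 1:3) {
    se <- sqrt(M[v, s] * (1 - M[v, s]) / n_maps)
    expect_lt(abs(freq[v - 4, s] - M[v, s]), 3 * se + 1e-3)
  }
})

test_that("maps honour tip data, branch lengths and forbidden cells", {
  tr <- simulate_tree(60, seed = 9)
  Q <- assemble_Q(build_structure("IR_102132"), c(0.01, 0.02, 0.02))
  sim <- simulate_discrete(tr, Q, "A0", seed = 10)
  for (k in 1:5) {
    m <- sample_map(tr, sim$tip_states, Q, seed = 100 + k)
    ## durations sum to branch lengths
    lens <- vapply(m$maps, function(s) sum(s$duration), numeric(1))
    expect_equal(lens, tr$edge.length, tolerance = 1e-9)
    ## terminal segment state equals the observed tip state
    for (e in seq_len(nrow(tr$edge))) {
      ch <- tr$edge[e, 2]
      if (ch <= 60) {
        last <- m$maps[[e]]$state[length(m$maps[[e]]$state)]
        expect_equal(last, unname(sim$tip_states[tr$tip.label[ch]]))
      }
    }
    ## no backward transitions under full irreversibility
    cnt <- count_transitions(m)
    expect_equal(sum(cnt[lower.tri(cnt)]), 0)
    ## adjacent segments always differ in state
    for (seg in m$maps)
      if (length(seg$state) > 1)
        expect_true(all(seg$state[-1] != seg$state[-length(seg$state)]))
  }
})

test_that("zero-rate maps carry zero transitions", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  Q <- assemble_Q(build_structure("ER"), 1e-12)
  st <- c(A = "A0", B = "A0", C = "A0")
  m <- sample_map(tr, st, Q, seed = 1)
  expect_equal(sum(count_transitions(m)), 0)
})

test_that("transition counting matches a constructed fixture", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  lab <- aquatic_states()
  segs <- list(list(state = c("A0", "A1"), duration = c(0.4, 0.6)),  # ->A
               list(state = "A0", duration = 1),                     # ->B
               list(state = c("A1", "A2"), duration = c(0.2, 0.8)),  # ->(A,B)
               list(state = "A0", duration = 2))                     # ->C
  ## edge order of this tree: (4,5),(5,1),(5,2),(4,3)
  m <- hand_map(tr, lab, list(segs[[3]], segs[[1]], segs[[2]], segs[[4]]))
  cnt <- count_transitions(m)
  expect_equal(cnt["A0", "A1"], 1L)
  expect_equal(cnt["A1", "A2"], 1L)
  expect_equal(sum(cnt), 2L)
  ## bookkeeping identity: transitions = segments - branches
  expect_equal(sum(cnt),
               sum(lengths(lapply(m$maps, `[[`, "state"))) - length(m$maps))
})

test_that("transition summaries use medians and central intervals", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  lab <- c("A0", "A1")
  mk1 <- function(n01) {
    segs <- list(list(state = "A0", duration = 1),
                 if (n01) list(state = c("A0", "A1"), duration = c(0.5, 0.5))
                 else list(state = "A0", duration = 1),
                 list(state = "A0", duration = 1),
                 list(state = "A0", duration = 2))
    hand_map(tr, lab, segs)
  }
  ## identical maps: zero-width interval at the shared counts
  s_same <- summarize_transitions(list(mk1(TRUE), mk1(TRUE), mk1(TRUE)))
  row <- s_same[s_same$from == "A0" & s_same$to == "A1", ]
  expect_equal(row$median, 1)
  expect_equal(row$lo95, 1)
  expect_equal(row$hi95, 1)
  ## counts (0,1,1): median 1, interval [0,1]
  s_mix <- summarize_transitions(list(mk1(FALSE), mk1(TRUE), mk1(TRUE)))
  row2 <- s_mix[s_mix$from == "A0" & s_mix$to == "A1", ]
  expect_equal(row2$median, 1)
  expect_equal(row2$lo95, 0, tolerance = 0.1)
  expect_error(summarize_transitions(list()), "at least one")
})

test_that("clade rates divide mean counts by clade branch length", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  lab <- c("A0", "A1")
  part <- assign_clades(tr, data.frame(species = c("A", "B", "C"),
                                       clade = c("X", "X", "Y")))
  ## one A0->A1 event on A's branch (clade X, total length 3)
  segs <- list(list(state = "A0", duration = 1),
               list(state = c("A0", "A1"), duration = c(0.5, 0.5)),
               list(state = "A0", duration = 1),
               list(state = "A0", duration = 2))
  m <- hand_map(tr, lab, segs)
  rates <- clade_empirical_rates(list(m, m), part)
  expect_equal(rates["X", "A0", "A1"], 1 / 3)
  expect_equal(rates["Y", "A0", "A1"], 0)
  ## partition identity: clade counts sum to whole-tree counts
  whole <- count_transitions(m)
  per_clade <- rates["X", , ] * 3 + rates["Y", , ] * 2
  expect_equal(unname(per_clade), unname(whole + 0))
})

test_that("simmap dialect round-trips and validates durations", {
  tr <- simulate_tree(25, seed = 13)
  Q <- default_sim_Q()
  sim <- simulate_discrete(tr, Q, "A0", seed = 14)
  m <- sample_map(tr, sim$tip_states, Q, seed = 15)
  s <- write_simmap(m)
  m2 <- read_simmap(s, tree = tr)
  ## same segments per branch (tree read back in the same orientation)
  expect_equal(length(m2$maps), length(m$maps))
  for (e in seq_along(m$maps)) {
    expect_equal(m2$maps[[e]]$state, m$maps[[e]]$state)
    expect_equal(m2$maps[[e]]$duration, m$maps[[e]]$duration,
                 tolerance = 1e-9)
  }
  ## corrupt a duration: reference-tree validation must fail
  bad <- sub("\\{A0,([0-9.]+)", "{A0,999", s)
  expect_error(read_simmap(bad, tree = tr), "do not sum")
  expect_error(read_simmap("((A:1,B:1):1,C:2);"), "no simmap annotations")
})

test_that("phytools parses our simmap files identically", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(20, seed = 23)
  Q <- default_sim_Q()
  sim <- simulate_discrete(tr, Q, "A0", seed = 24)
  m <- sample_map(tr, sim$tip_states, Q, seed = 25)
  f <- tempfile(fileext = ".simmap")
  write_simmap(m, f)
  pt <- phytools::read.simmap(f, format = "phylip")
  expect_equal(sort(pt$tip.label), sort(tr$tip.label))
  ## total time per state agrees
  ours <- sapply(aquatic_states(), function(s)
    sum(unlist(lapply(m$maps, function(sg)
      sum(sg$duration[sg$state == s])))))
  theirs <- colSums(pt$mapped.edge)[names(ours[ours > 0])]
  expect_equal(unname(theirs), unname(ours[ours > 0]), tolerance = 1e-6)
})

test_that("endpoint-conditioned branch expectations match numerical integration", {
  ## 2-state chain, fixed endpoints: E[N_ij | a, b, t] by integrating
  ## P(a,i,s) q_ij P(j,b,t-s) / P(a,b,t) over jump time s
  r01 <- 0.08; r10 <- 0.03; t <- 8
  lab <- c("0", "1")
  Q <- matrix(c(-r01, r01, r10, -r10), 2, 2, byrow = TRUE,
              dimnames = list(lab, lab))
  Pt <- transition_probs(Q, t)
  exact_expected <- function(a, b, i, j) {
    f <- Vectorize(function(s)
      transition_probs(Q, s)[a, i] * Q[i, j] *
        transition_probs(Q, t - s)[j, b])
    stats::integrate(f, 0, t, rel.tol = 1e-9)$value / Pt[a, b]
  }
  set.seed(41)
  n_samp <- 100000
  for (ab in list(c(1, 1), c(1, 2))) {
    a <- ab[1]; b <- ab[2]
    counts01 <- counts10 <- numeric(n_samp)
    for (k in seq_len(n_samp)) {
      h <- aquaevol:::sample_branch_history(Q, a, b, t, P_t = Pt)
      st <- h$state
      if (length(st) > 1) {
        counts01[k] <- sum(st[-length(st)] == 1 & st[-1] == 2)
        counts10[k] <- sum(st[-length(st)] == 2 & st[-1] == 1)
      }
    }
    e01 <- exact_expected(a, b, 1, 2)
    e10 <- exact_expected(a, b, 2, 1)
    expect_lt(abs(mean(counts01) - e01), 3 * sd(counts01) / sqrt(n_samp))
    expect_lt(abs(mean(counts10) - e10), 3 * sd(counts10) / sqrt(n_samp))
  }
})

test_that("unreachable endpoint pairs raise a sampling error", {
  Q <- assemble_Q(build_structure("IR_102132"), c(0.1, 0.1, 0.1))
  expect_error(aquaevol:::sample_branch_history(Q, 4, 1, 5), "unreachable")
})
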