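# Tree and trait-table input/output, clade partitions, traversal utilities.
#
# Trees are ape "phylo" objects throughout, restricted to rooted, strictly
# bifurcating topologies with finite non-negative branch lengths in Myr.

#' Ordered aquatic-adaptation state space
#'
#' The four ordered levels of aquatic adaptation: `A0` (no aquatic
#' morphological adaptation), `A1` (aquatic adaptations but fully mobile on
#' land), `A2` (limited terrestrial locomotion), `A3` (fully aquatic).
#'
#' @return Character vector of the four state labels, in order.
#' @export
aquatic_states <- function() c("A0", "A1", "A2", "A3")

#' Normalize species names
#'
#' Whitespace runs are replaced by a single underscore so that table names
#' match tree tip labels exactly.
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_species <- function(x) {
  gsub("[[:space:]]+", "_", trimws(as.character(x)))
}

n_tips <- function(tree) length(tree$tip.label)

n_nodes <- function(tree) length(tree$tip.label) + tree$Nnode

root_node <- function(tree) n_tips(tree) + 1L

#' Validate a phylogeny
#'
#' Checks the invariants assumed by every other function in the package:
#' rooted, strictly bifurcating, unique tip labels, finite branch lengths
#' >= 0.
#'
#' @param tree an ape `phylo` object.
#' @return the tree, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (!all(is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0", call. = FALSE)
  ## every internal node must have exactly two children
  tab <- tabulate(tree$edge[, 1], nbins = n_nodes(tree))
  internal <- (n_tips(tree) + 1L):n_nodes(tree)
  bad <- internal[tab[internal] != 2L]
  if (length(bad))
    stop("unsupported topology: polytomy or unbranched node at node(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  invisible(tree)
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unmatched ')' at position ", i,
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of string",
         call. = FALSE)
  if (!grepl(";[[:space:]]*$", text))
    stop("newick parse error: missing terminal ';' at position ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

#' Read a newick tree
#'
#' Parses a newick string (or a file containing one) into a validated
#' phylogeny. Polytomies and missing branch lengths are rejected.
#'
#' @param text a newick string.
#' @param file alternatively, path to a newick file (first tree used).
#' @return a validated `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'text' or 'file'", call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e)
                     stop("newick parse error: ", conditionMessage(e),
                          call. = FALSE))
  if (is.null(tree))
    stop("newick parse error: string could not be parsed", call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  tree$tip.label <- normalize_species(tree$tip.label)
  validate_phylogeny(tree)
  tree
}

#' Write a newick tree
#'
#' @param tree a `phylo` object.
#' @param file optional path; if empty, the newick string is returned.
#' @param digits significant digits for branch lengths (default 10).
#' @return the newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = "", digits = 10) {
  ape::write.tree(tree, file = file, digits = digits)
}

## children[[v]] = child nodes of v; edge index lookup by child node
child_list <- function(tree) {
  kids <- vector("list", n_nodes(tree))
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  kids
}

## edge index whose child is node v (NA for the root)
edge_of_child <- function(tree) {
  idx <- rep(NA_integer_, n_nodes(tree))
  idx[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  idx
}

## internal nodes ordered so children precede parents (tips count as done)
postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1])
}

## tips descending from every node
tips_under <- function(tree) {
  nt <- n_tips(tree)
  below <- vector("list", n_nodes(tree))
  for (i in seq_len(nt)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    a <- po$edge[e, 1]; b <- po$edge[e, 2]
    below[[a]] <- c(below[[a]], below[[b]])
  }
  below
}

#' Assign tips and nodes to clades
#'
#' Builds a clade partition from a tip-to-clade table. A node belongs to a
#' clade iff all its descendant tips belong to that clade; nodes whose
#' descendants span several clades (including the root) fall in the
#' `"background"` partition. A branch belongs to the clade of its child
#' node, so each clade comprises its crown plus its stem branch.
#'
#' @param tree a validated `phylo`.
#' @param table data frame with columns `species` and `clade`.
#' @return an object of class `clade_partition` with elements `tip_clade`
#'   (named by tip label), `node_clade` (length tips + internal nodes) and
#'   `clades` (clade labels, background excluded).
#' @export
assign_clades <- function(tree, table) {
  validate_phylogeny(tree)
  if (!all(c("species", "clade") %in% names(table)))
    stop("clade table needs columns 'species' and 'clade'", call. = FALSE)
  sp <- normalize_species(table$species)
  missing <- setdiff(tree$tip.label, sp)
  if (length(missing))
    stop("clade table incomplete; missing tips: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tip_clade <- as.character(table$clade)[match(tree$tip.label, sp)]
  names(tip_clade) <- tree$tip.label
  nn <- n_nodes(tree)
  nt <- n_tips(tree)
  node_clade <- rep(NA_character_, nn)
  node_clade[seq_len(nt)] <- tip_clade
  kids <- child_list(tree)
  for (v in postorder_nodes(tree)) {
    cl <- unique(node_clade[kids[[v]]])
    node_clade[v] <- if (length(cl) == 1L && !is.na(cl)) cl else "background"
  }
  structure(list(tip_clade = tip_clade,
                 node_clade = node_clade,
                 clades = sort(unique(unname(tip_clade)))),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("Clade partition:", length(x$clades), "clades + background;",
      length(x$tip_clade), "tips\n")
  invisible(x)
}

#' Total branch length of a tree or of one clade
#'
#' For a clade, sums the lengths of all branches whose child node belongs to
#' the clade (crown branches plus the clade's stem). `"background"` selects
#' the branches not assigned to any clade.
#'
#' @param tree a validated `phylo`.
#' @param partition a `clade_partition` (required when `clade` is given).
#' @param clade clade identifier, or `NULL` for the whole tree.
#' @return total branch length in Myr.
#' @export
total_branch_length <- function(tree, partition = NULL, clade = NULL) {
  validate_phylogeny(tree)
  if (is.null(clade)) return(sum(tree$edge.length))
  if (is.null(partition))
    stop("a clade partition is required for clade totals", call. = FALSE)
  if (!clade %in% c(partition$clades, "background"))
    stop("unknown clade: ", clade, call. = FALSE)
  keep <- partition$node_clade[tree$edge[, 2]] == clade
  sum(tree$edge.length[keep])
}

#' Read a tip trait table
#'
#' Tab-separated with header
#' `species\tstate\tlog10_mass\tvert\tinvert\tplant`: aquatic state (A0-A3),
#' log10 body mass in grams, and diet fractions (vertebrate, invertebrate,
#' plant) summing to 1.
#'
#' @param path file path.
#' @param tree optional tree; if given, the table is checked against and
#'   reordered to the tree's tip labels.
#' @return data frame, one row per species.
#' @export
read_tip_table <- function(path, tree = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "state", "log10_mass", "vert", "invert", "plant")
  if (!all(need %in% names(tab)))
    stop("tip table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$species <- normalize_species(tab$species)
  if (!all(tab$state %in% aquatic_states()))
    stop("invalid states: ",
         paste(unique(setdiff(tab$state, aquatic_states())), collapse = ", "),
         call. = FALSE)
  frac <- as.matrix(tab[, c("vert", "invert", "plant")])
  if (any(frac < 0) || any(frac > 1) || any(abs(rowSums(frac) - 1) > 1e-6))
    stop("diet fractions must lie in [0,1] and sum to 1", call. = FALSE)
  if (!is.null(tree)) {
    validate_phylogeny(tree)
    missing <- setdiff(tree$tip.label, tab$species)
    if (length(missing))
      stop("tip table incomplete; missing tips: ",
           paste(missing, collapse = ", "), call. = FALSE)
    tab <- tab[match(tree$tip.label, tab$species), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Read a tip-to-clade table
#'
#' Tab-separated with header `species\tclade`.
#'
#' @param path file path.
#' @return data frame with columns `species`, `clade`.
#' @export
read_clade_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "clade") %in% names(tab)))
    stop("clade table needs columns 'species' and 'clade'", call. = FALSE)
  tab$species <- normalize_species(tab$species)
  tab
}

## named state vector -> integer indices 1..K in 'states' order
state_indices <- function(x, states) {
  xi <- match(as.character(x), states)
  if (anyNA(xi))
    stop("states outside the state space: ",
         paste(unique(as.character(x)[is.na(xi)]), collapse = ", "),
         call. = FALSE)
  names(xi) <- names(x)
  xi
}

## align a named tip-state vector to tree tip order; error on missing tips
align_tip_states <- function(tree, states) {
  if (is.null(names(states)))
    stop("tip states must be named by tip label", call. = FALSE)
  names(states) <- normalize_species(names(states))
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("tip state(s) missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  states[tree$tip.label]
}
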