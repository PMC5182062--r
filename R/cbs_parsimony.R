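# Fitch small parsimony over Cbs variant states on a species tree, for
# counting the minimum number of mutations explaining cross-species
# breakage-site variants.

#' Minimum mutation count for Cbs variants on a species tree
#'
#' Fitch small parsimony over discrete variant states at the tips of a
#' rooted binary tree. Tips with missing data (`NA`, or absent from
#' `tip_variants`) are unconstrained, matching the treatment of unsequenced
#' breakage sites.
#'
#' @param tree an `ape` `phylo` object (or a Newick string). Non-binary
#'   trees are rejected.
#' @param tip_variants named character vector mapping tip labels to variant
#'   labels; `NA` marks missing data.
#' @return integer minimum number of state changes.
#' @examples
#' tree <- ape::read.tree(text = "((a,b),(c,d));")
#' cbs_parsimony(tree, c(a = "canonical", b = "canonical",
#'                       c = "canonical", d = "14C"))
#' @export
cbs_parsimony <- function(tree, tip_variants) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick text")
  if (length(tip_variants) == 0L || all(is.na(tip_variants)))
    stop("no tip variants supplied")
  if (!ape::is.binary(tree)) stop("Fitch parsimony here requires a binary tree")
  ntip <- length(tree$tip.label)
  states <- sort(unique(stats::na.omit(unname(tip_variants))))
  if (length(states) <= 1L) return(0L)
  full <- states
  tipset <- lapply(tree$tip.label, function(tp) {
    v <- tip_variants[[tp]] %||% NA_character_
    if (is.null(v) || is.na(v)) full else v
  })
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  sets[seq_len(ntip)] <- tipset
  changes <- 0L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(po[, 2], po[, 1])[as.character(unique(po[, 1]))]
  parents <- unique(po[, 1])  # postorder: children precede parents
  for (parent in parents) {
    ch <- kids[[as.character(parent)]]
    s <- sets[[ch[1]]]
    for (c2 in ch[-1]) {
      inter <- intersect(s, sets[[c2]])
      if (length(inter)) {
        s <- inter
      } else {
        s <- union(s, sets[[c2]])
        changes <- changes + 1L
      }
    }
    sets[[parent]] <- s
  }
  changes
}

# exhaustive small-parsimony minimum by enumerating all internal labelings;
# exported for use as an independent oracle at tiny tree sizes.
#' Brute-force minimum mutation count (exhaustive internal labelings)
#' @inheritParams cbs_parsimony
#' @return integer minimum number of state changes.
#' @export
cbs_parsimony_bruteforce <- function(tree, tip_variants) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  states <- sort(unique(stats::na.omit(unname(tip_variants))))
  if (length(states) <= 1L) return(0L)
  nnode <- tree$Nnode
  edge <- tree$edge
  tip_state_sets <- lapply(tree$tip.label, function(tp) {
    v <- tip_variants[[tp]] %||% NA_character_
    if (is.null(v) || is.na(v)) states else v
  })
  grids <- c(tip_state_sets, rep(list(states), nnode))
  # enumerate assignments over internal nodes and missing tips
  free <- which(vapply(grids, length, integer(1)) > 1L)
  fixed <- vapply(grids, `[[`, character(1), 1L)
  best <- Inf
  idx <- rep(1L, length(free))
  sizes <- vapply(grids[free], length, integer(1))
  repeat {
    lab <- fixed
    for (j in seq_along(free)) lab[free[j]] <- grids[[free[j]]][idx[j]]
    cost <- sum(lab[edge[, 1]] != lab[edge[, 2]])
    if (cost < best) best <- cost
    k <- 1L
    while (k <= length(free)) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sizes[k]) break
      idx[k] <- 1L
      k <- k + 1L
    }
    if (k > length(free)) break
    if (length(free) == 0L) break
  }
  as.integer(best)
}
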