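## Species-tree input/output and traversal helpers.
##
## A species tree is an ape "phylo" object that has passed
## validate_species_tree(): rooted, strictly binary, unique tip labels,
## non-negative branch lengths on every edge. Node numbering follows ape
## (tips 1..Ntip, internal Ntip+1..; root = Ntip+1).

#' Read a rooted binary species tree from Newick
#'
#' Parses a Newick string or file (optionally gzipped) and validates the tree
#' frame every downstream analysis assumes: rooted, strictly binary, unique
#' leaf labels, and non-negative branch lengths. Polytomies are a hard error
#' naming the offending node rather than being auto-resolved.
#'
#' @param file path to a Newick file (plain or gzip), or a literal Newick
#'   string (detected by the presence of a parenthesis).
#' @return a validated [ape::phylo] tree with node labels filled in
#'   (`N<number>` where the input had none).
#' @export
read_species_tree <- function(file) {
  txt <- if (grepl("(", file, fixed = TRUE)) {
    file
  } else {
    paste(readLines(gzfile(file), warn = FALSE), collapse = "")
  }
  check_newick_syntax(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("Newick parse failed")
  validate_species_tree(tree)
}

check_newick_syntax <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick parse error at character %d: unbalanced ')'", i))
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("Newick parse error at character %d: %d unclosed '('",
                 length(chars), depth))
  }
  invisible(TRUE)
}

#' Validate the species-tree invariants
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly augmented with node labels where missing.
#' @export
validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tab <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  internal <- sort(unique(tree$edge[, 1]))
  bad <- internal[tab[internal] != 2L]
  if (length(bad) > 0L) {
    stop(sprintf("non-binary node: %s has %d children",
                 node_label(tree, bad[1]), tab[bad[1]]))
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    nl <- if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label
    idx <- !nzchar(nl)
    nl[idx] <- paste0("N", (ape::Ntip(tree) + seq_len(tree$Nnode))[idx])
    tree$node.label <- nl
  }
  tree
}

#' Write a species tree to Newick
#'
#' @param tree a validated species tree.
#' @param file output path; `""` returns the Newick string.
#' @export
write_species_tree <- function(tree, file = "") {
  ape::write.tree(tree, file = file, digits = 12)
}

## -- traversal helpers (node ids are ape numbers) ---------------------------

root_node <- function(tree) ape::Ntip(tree) + 1L

n_nodes <- function(tree) ape::Ntip(tree) + tree$Nnode

#' Label of a node (tip label for leaves, node label otherwise)
#' @param tree a species tree
#' @param node node number(s)
#' @export
node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  labs <- c(tree$tip.label,
            if (is.null(tree$node.label)) paste0("N", ntip + seq_len(tree$Nnode))
            else tree$node.label)
  labs[node]
}

#' Node number for a label (inverse of [node_label()])
#' @param tree a species tree
#' @param label tip or node label(s)
#' @export
node_by_label <- function(tree, label) {
  ntip <- ape::Ntip(tree)
  labs <- c(tree$tip.label,
            if (is.null(tree$node.label)) paste0("N", ntip + seq_len(tree$Nnode))
            else tree$node.label)
  idx <- match(label, labs)
  if (anyNA(idx)) stop("unknown node label: ", paste(label[is.na(idx)], collapse = ", "))
  idx
}

children_of <- function(tree) {
  out <- vector("list", n_nodes(tree))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    out[[p]] <- c(out[[p]], tree$edge[e, 2])
  }
  out
}

## tips (numbers) under each node, as a list indexed by node
tips_under <- function(tree) {
  ntip <- ape::Ntip(tree)
  out <- vector("list", n_nodes(tree))
  for (i in seq_len(ntip)) out[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(ord))) {
    out[[ord[e, 1]]] <- c(out[[ord[e, 1]]], out[[ord[e, 2]]])
  }
  out
}

#' Node ages: root-to-node path length
#'
#' The sum of branch lengths from the root to each node, used as a proxy for
#' the evolutionary time at which the node's clade originated (root age 0).
#'
#' @param tree a species tree
#' @return numeric vector over all nodes (tips first, ape numbering)
#' @export
node_ages <- function(tree) {
  ages <- rep(NA_real_, n_nodes(tree))
  ages[root_node(tree)] <- 0
  ## preorder: parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(pre))) {
    ages[pre[e, 2]] <- ages[pre[e, 1]] + lens[e]
  }
  ages
}

## MRCA of a set of tip numbers (the tip itself for a singleton)
mrca_of_tips <- function(tree, tips) {
  if (length(tips) == 1L) return(as.integer(tips))
  ape::getMRCA(tree, as.integer(tips))
}
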