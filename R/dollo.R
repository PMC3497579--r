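## Dollo-parsimony reconstruction of family gains and losses.
##
## Under Dollo parsimony a family is gained exactly once and may only be
## lost afterwards, so the most-parsimonious scenario is fully determined:
## the gain sits at the MRCA of the presence leaves and the losses are the
## maximal subtrees below it that contain no presence leaf. That placement
## provably minimises the number of losses among all single-gain scenarios.

#' Dollo-parsimony gain/loss reconstruction
#'
#' @param presence presence-mode profile matrix whose species set equals
#'   the tree leaf set; families absent everywhere are an error.
#' @param tree a species tree
#' @return a `dollo_reconstruction` data.frame: family_id, gain_node
#'   (label), n_losses, and a list column `loss_edges` of child-node labels
#'   identifying each lost subtree.
#' @export
dollo_reconstruct <- function(presence, tree) {
  tree <- validate_species_tree(tree)
  if (!identical(sort(colnames(presence)), sort(tree$tip.label))) {
    stop("presence matrix species do not match tree leaves")
  }
  if (profile_mode(presence) != "presence") presence <- as_presence(presence)
  kids <- children_of(tree)
  tu <- tips_under(tree)
  n_pres_under <- function(pres_tips) {
    vapply(tu, function(t) sum(t %in% pres_tips), 0L)
  }
  fams <- rownames(presence)
  gain <- character(length(fams)); nloss <- integer(length(fams))
  loss_edges <- vector("list", length(fams))
  for (fi in seq_along(fams)) {
    pres_sp <- colnames(presence)[unclass(presence)[fi, ] > 0]
    if (length(pres_sp) == 0) stop("family ", fams[fi], " present in no species")
    pres_tips <- match(pres_sp, tree$tip.label)
    g <- mrca_of_tips(tree, pres_tips)
    under <- n_pres_under(pres_tips)
    ## maximal empty subtrees below the gain node
    losses <- integer(0)
    stack <- g
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (ch in kids[[v]]) {
        if (under[ch] == 0L) losses <- c(losses, ch) else stack <- c(stack, ch)
      }
    }
    gain[fi] <- node_label(tree, g)
    nloss[fi] <- length(losses)
    loss_edges[[fi]] <- node_label(tree, sort(losses))
  }
  out <- data.frame(family_id = fams, gain_node = gain, n_losses = nloss,
                    stringsAsFactors = FALSE)
  out$loss_edges <- loss_edges
  structure(out, class = c("dollo_reconstruction", "data.frame"))
}

#' Per-node gain statistics
#'
#' For every tree node: its age (root-to-node path length), the number of
#' families gained there, the cumulative gains along the root path, the
#' number of loss edges entering the node, a net gain/loss balance, and —
#' when context/cluster annotation is supplied — the percentage of the
#' families gained at the node that are intronic resp. clustered. A family
#' counts as intronic (clustered) when the majority of its present-day loci
#' are.
#'
#' @param rec a [dollo_reconstruct()] result
#' @param tree the species tree used
#' @param context optional data.frame (locus_id, context) from
#'   [annotate_context()]
#' @param clusters optional data.frame (locus_id, cluster_id) from
#'   [assign_clusters()]
#' @param partition partition mapping loci to the reconstructed families
#'   (required with `context`/`clusters`)
#' @return data.frame, one row per node: node, label, age, n_gains,
#'   cum_gains, n_losses, net_balance, pct_intronic, pct_clustered
#' @export
node_statistics <- function(rec, tree, context = NULL, clusters = NULL,
                            partition = NULL) {
  tree <- validate_species_tree(tree)
  nn <- n_nodes(tree)
  ages <- node_ages(tree)
  gain_nodes <- node_by_label(tree, rec$gain_node)
  n_gains <- tabulate(gain_nodes, nbins = nn)
  n_losses <- tabulate(node_by_label(tree, unlist(rec$loss_edges)), nbins = nn)
  cum <- numeric(nn)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  cum[root_node(tree)] <- n_gains[root_node(tree)]
  for (e in seq_len(nrow(pre))) cum[pre[e, 2]] <- cum[pre[e, 1]] + n_gains[pre[e, 2]]
  fam_flag <- function(ann, col) {
    if (is.null(ann) || is.null(partition)) return(NULL)
    mem <- as_membership(partition)
    fams <- mem[ann$locus_id]
    flag <- if (col == "context") ann$context == "intronic" else !is.na(ann$cluster_id)
    tapply(flag, fams, function(x) mean(x) > 0.5)
  }
  intr <- fam_flag(context, "context")
  clus <- fam_flag(clusters, "cluster")
  pct_at_node <- function(flags) {
    if (is.null(flags)) return(rep(NA_real_, nn))
    vapply(seq_len(nn), function(v) {
      f <- rec$family_id[gain_nodes == v]
      f <- f[f %in% names(flags)]
      if (length(f) == 0) NA_real_ else 100 * mean(flags[f])
    }, 0)
  }
  data.frame(node = seq_len(nn), label = node_label(tree, seq_len(nn)),
             age = ages, n_gains = n_gains, cum_gains = cum,
             n_losses = n_losses, net_balance = n_gains - n_losses,
             pct_intronic = pct_at_node(intr),
             pct_clustered = pct_at_node(clus),
             stringsAsFactors = FALSE)
}

#' Annotated tree figure: branch widths and gain/loss colouring
#'
#' Branch width is proportional to the number of families present among
#' the leaves below the branch; branch colour marks nodes in the top decile
#' of net balance (gain, red) or bottom decile (loss, blue) — a
#' presentation threshold, not an inference. The numeric annotation table is
#' written alongside the SVG.
#'
#' @param presence presence-mode profile matrix
#' @param stats result of [node_statistics()]
#' @param tree the species tree
#' @param svg_file optional SVG output path
#' @param tsv_file optional TSV output path for the per-edge annotations
#' @param quantiles colouring deciles (bottom, top)
#' @return the per-edge annotation data.frame, invisibly
#' @export
annotate_tree_figure <- function(presence, stats, tree, svg_file = NULL,
                                 tsv_file = NULL, quantiles = c(0.1, 0.9)) {
  tree <- validate_species_tree(tree)
  tu <- tips_under(tree)
  pres <- unclass(as_presence(presence))
  sp_cols <- match(tree$tip.label, colnames(pres))
  fam_under <- vapply(seq_len(n_nodes(tree)), function(v) {
    cols <- sp_cols[tu[[v]]]
    sum(rowSums(pres[, cols, drop = FALSE]) > 0)
  }, 0L)
  nb <- stats$net_balance
  qs <- quantile(nb, quantiles)
  colr <- ifelse(nb <= qs[1] & nb < 0, "#2166AC",
                 ifelse(nb >= qs[2] & nb > 0, "#B2182B", "#666666"))
  edges <- data.frame(
    parent = node_label(tree, tree$edge[, 1]),
    child = node_label(tree, tree$edge[, 2]),
    length = tree$edge.length,
    n_families_under = fam_under[tree$edge[, 2]],
    width = 1 + 6 * fam_under[tree$edge[, 2]] / max(1, max(fam_under)),
    colour = colr[tree$edge[, 2]],
    stringsAsFactors = FALSE)
  if (!is.null(tsv_file)) {
    write.table(edges, tsv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(svg_file)) {
    ages <- node_ages(tree)
    ntip <- ape::Ntip(tree)
    y <- rep(NA_real_, n_nodes(tree))
    y[seq_len(ntip)] <- seq_len(ntip)
    post <- ape::reorder.phylo(tree, "postorder")$edge
    kids <- children_of(tree)
    for (e in seq_len(nrow(post))) {
      p <- post[e, 1]
      y[p] <- mean(y[kids[[p]]])
    }
    sx <- function(a) 40 + 500 * a / max(ages)
    sy <- function(v) 20 + 18 * v
    lines <- sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="700" height="%d">',
                     40 + 18 * ntip)
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
      lines <- c(lines, sprintf(
        '<polyline points="%.1f,%.1f %.1f,%.1f %.1f,%.1f" fill="none" stroke="%s" stroke-width="%.2f"/>',
        sx(ages[p]), sy(y[p]), sx(ages[p]), sy(y[c_]), sx(ages[c_]), sy(y[c_]),
        edges$colour[e], edges$width[e]))
    }
    for (i in seq_len(ntip)) {
      lines <- c(lines, sprintf('<text x="%.1f" y="%.1f" font-size="10">%s</text>',
                                sx(ages[i]) + 4, sy(y[i]) + 3, tree$tip.label[i]))
    }
    lines <- c(lines, "</svg>")
    writeLines(lines, svg_file)
  }
  invisible(edges)
}
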