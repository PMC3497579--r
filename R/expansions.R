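## Rapid family expansion / contraction detection under a linear
## birth-death model of family size with equal per-gene birth and death
## rate lambda. The branch transition probability has the closed form
##   P(c | s, t) = sum_j C(s,j) C(s+c-j-1, s-1) alpha^(s+c-2j) (1-2 alpha)^j,
##   alpha = lambda t / (1 + lambda t),
## the likelihood of a family's observed sizes is computed by pruning over
## ancestral sizes, lambda is fitted by bounded 1-D maximisation, and
## per-family p-values come from seeded Monte-Carlo simulation under the
## fitted rate.

#' Birth-death size transition probability
#'
#' @param s parent size (>= 1; extinct lineages cannot regenerate)
#' @param c child size (>= 0)
#' @param t branch length (>= 0)
#' @param lambda per-gene birth(=death) rate (>= 0)
#' @return P(child size = c | parent size = s, t)
#' @export
bd_transition <- function(s, c, t, lambda) {
  if (s < 1) stop("parent size must be >= 1 (extinct lineages cannot regenerate)")
  if (t < 0 || lambda < 0) stop("t and lambda must be non-negative")
  P <- bd_transition_matrix(max(s, c), t, lambda)
  P[s + 1L, c + 1L]
}

#' Full birth-death transition matrix over sizes 0..smax
#'
#' Row/column index i corresponds to size i - 1; row 1 (size 0) is
#' absorbing.
#'
#' @param smax largest size represented
#' @inheritParams bd_transition
#' @return (smax+1) x (smax+1) row-stochastic matrix
#' @export
bd_transition_matrix <- function(smax, t, lambda) {
  ## the closed form alternates in sign once lambda*t > 1 (alpha > 1/2) and
  ## cancels catastrophically for moderate sizes; evaluate at a halved time
  ## where every term is positive and square back up (Chapman-Kolmogorov)
  k <- 0L
  lt <- lambda * t
  while (lt > 0.9) {
    lt <- lt / 2
    k <- k + 1L
  }
  alpha <- lt / (1 + lt)
  P <- bd_trans_matrix_cpp(as.integer(smax), alpha)
  for (i in seq_len(k)) P <- P %*% P
  P
}

#' Families whose Dollo gain sits at the (sub)tree root
#'
#' The birth-death likelihood conditions on presence at the root, so only
#' families whose presence pattern implies a root gain are eligible.
#'
#' @param counts count-mode profile matrix over the tree's leaves
#' @param tree species (sub)tree
#' @return character vector of family ids
#' @export
filter_root_present <- function(counts, tree) {
  tree <- validate_species_tree(tree)
  pres <- as_presence(counts)
  rec <- dollo_reconstruct(pres, tree)
  rec$family_id[rec$gain_node == node_label(tree, root_node(tree))]
}

## per-family log-likelihood of observed sizes, vectorised over families
bd_family_loglik <- function(counts, tree, lambda, max_size = 100L,
                             root_max = NULL) {
  tree <- validate_species_tree(tree)
  m <- unclass(counts)[, tree$tip.label, drop = FALSE]
  if (max(m) > max_size) {
    stop("family size ", max(m), " exceeds max_size = ", max_size)
  }
  smax <- as.integer(max_size)
  nfam <- nrow(m)
  post <- ape::reorder.phylo(tree, "postorder")
  Pcache <- lapply(setNames(nm = unique(post$edge.length)), function(t) {
    bd_transition_matrix(smax, as.numeric(t), lambda)
  })
  part <- vector("list", n_nodes(tree))
  for (v in seq_len(ape::Ntip(tree))) {
    L <- matrix(0, nfam, smax + 1L)
    L[cbind(seq_len(nfam), m[, v] + 1L)] <- 1
    part[[v]] <- L
  }
  scale_log <- numeric(nfam)
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    P <- Pcache[[as.character(post$edge.length[e])]]
    msg <- part[[ch]] %*% t(P)
    part[[p]] <- if (is.null(part[[p]])) msg else part[[p]] * msg
    mx <- apply(part[[p]], 1, max)
    ok <- mx > 0
    part[[p]][ok, ] <- part[[p]][ok, , drop = FALSE] / mx[ok]
    scale_log <- scale_log + ifelse(ok, log(mx), 0)
  }
  if (is.null(root_max)) root_max <- max(max(m), 1L)
  lik <- rowMeans(part[[root_node(tree)]][, 1L + seq_len(root_max), drop = FALSE])
  setNames(log(lik) + scale_log, rownames(m))
}

#' Maximum-likelihood birth-death rate for a family-size matrix
#'
#' The likelihood sums over ancestral sizes by pruning (sizes bounded at
#' `max_size`), with a uniform root-size prior over 1..max observed size;
#' lambda is maximised by bounded one-dimensional optimisation.
#'
#' @param counts count-mode profile matrix, restricted to root-present
#'   families (see [filter_root_present()])
#' @param tree species (sub)tree with branch lengths
#' @param max_size ancestral size bound (default 100)
#' @param upper upper bound of the lambda search interval
#' @param root_max upper end of the uniform root-size prior (default: max
#'   observed size)
#' @return list: lambda (ML estimate), loglik (total), family_loglik
#' @export
fit_lambda <- function(counts, tree, max_size = 100L, upper = 10,
                       root_max = NULL) {
  if (nrow(counts) == 0) stop("empty family set")
  tree <- validate_species_tree(tree)
  if (all(tree$edge.length == 0)) stop("zero-length tree")
  nll <- function(lam) -sum(bd_family_loglik(counts, tree, lam, max_size, root_max))
  opt <- optimize(nll, c(0, upper), tol = 1e-6)
  fl <- bd_family_loglik(counts, tree, opt$minimum, max_size, root_max)
  list(lambda = opt$minimum, loglik = -opt$objective, family_loglik = fl)
}

## most-likely ancestral sizes (max-product), used to flag the branch with
## the largest single-branch likelihood drop
flag_branch <- function(sizes, tree, lambda, max_size = 100L) {
  smax <- as.integer(max_size)
  post <- ape::reorder.phylo(tree, "postorder")
  Pc <- lapply(setNames(nm = unique(post$edge.length)), function(t) {
    log(bd_transition_matrix(smax, as.numeric(t), lambda))
  })
  M <- vector("list", n_nodes(tree))     # max log-lik of subtree given node size
  back <- vector("list", n_nodes(tree))  # per child edge: argmax child size
  for (v in seq_len(ape::Ntip(tree))) {
    M[[v]] <- rep(-Inf, smax + 1L)
    M[[v]][sizes[tree$tip.label[v]] + 1L] <- 0
  }
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    lP <- Pc[[as.character(post$edge.length[e])]]
    sc <- sweep(lP, 2, M[[ch]], "+")        # [s, c] = log P(c|s) + M_ch(c)
    best <- apply(sc, 1, max)
    arg <- apply(sc, 1, which.max)
    M[[p]] <- if (is.null(M[[p]])) best else M[[p]] + best
    back[[ch]] <- arg
  }
  root <- root_node(tree)
  root_size <- which.max(M[[root]][-1]) # root size >= 1
  assign_size <- integer(n_nodes(tree))
  assign_size[root] <- root_size
  pre <- ape::reorder.phylo(tree, "cladewise")
  drop <- setNames(numeric(nrow(pre$edge)), node_label(tree, pre$edge[, 2]))
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
    s <- assign_size[p]
    cches <- back[[ch]][s + 1L]
    assign_size[ch] <- cches - 1L
    lP <- Pc[[as.character(pre$edge.length[e])]]
    drop[e] <- lP[s + 1L, cches]
  }
  names(drop)[which.min(drop)]
}

#' Monte-Carlo expansion p-values under the fitted birth-death rate
#'
#' Simulates `n_sim` null family histories under `lambda` from the uniform
#' root-size prior (explicit event simulation), computes their
#' log-likelihoods, and reports for each observed family the fraction of
#' null histories at least as unlikely (loglik <= observed). The branch
#' with the lowest transition log-probability along the most-likely
#' ancestral size assignment is flagged.
#'
#' @param counts count-mode profile matrix (observed families)
#' @param tree species (sub)tree
#' @param lambda fitted rate (see [fit_lambda()])
#' @param n_sim number of null simulations (> 0)
#' @param seed integer seed
#' @param max_size ancestral size bound
#' @param root_max upper end of the uniform root-size prior shared by the
#'   likelihood and the null simulations (default: max observed size)
#' @return data.frame: family_id, loglik, p_value, flagged_branch
#' @export
expansion_pvalue <- function(counts, tree, lambda, n_sim = 1000L, seed = 1L,
                             max_size = 100L, root_max = NULL) {
  if (n_sim <= 0) stop("n_sim must be positive")
  tree <- validate_species_tree(tree)
  m <- unclass(counts)
  if (is.null(root_max)) root_max <- max(max(m), 1L)
  obs_ll <- bd_family_loglik(counts, tree, lambda, max_size, root_max)
  null_counts <- with_seed(stage_seed(seed, 7L), {
    roots <- sample.int(root_max, n_sim, replace = TRUE)
    simulate_family_sizes(tree, lambda, roots, seed = stage_seed(seed, 8L))
  })
  keep <- unclass(null_counts)
  keep[keep > max_size] <- max_size   # cap pathological null draws
  null_pm <- profile_matrix(keep, "count")
  null_ll <- bd_family_loglik(null_pm, tree, lambda, max_size, root_max)
  p <- vapply(obs_ll, function(x) mean(null_ll <= x), 0)
  flagged <- vapply(seq_len(nrow(m)), function(i) {
    flag_branch(setNames(m[i, ], colnames(m)), tree, lambda, max_size)
  }, "")
  data.frame(family_id = rownames(m), loglik = obs_ll, p_value = p,
             flagged_branch = flagged, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Expansion report for a clade
#'
#' Restricts the count matrix to a clade subtree, keeps root-present
#' families, fits lambda, and computes Monte-Carlo p-values.
#'
#' @param counts count-mode profile matrix over the full tree
#' @param tree full species tree
#' @param clade label of the clade root node (default: tree root)
#' @param n_sim,seed,max_size passed through
#' @param p_threshold significance threshold for the `significant` flag
#' @return list: lambda, report (data.frame sorted by p-value), clade
#' @export
expansion_report <- function(counts, tree, clade = NULL, n_sim = 1000L,
                             seed = 1L, max_size = 100L, p_threshold = 0.01) {
  tree <- validate_species_tree(tree)
  if (!is.null(clade) && clade != node_label(tree, root_node(tree))) {
    node <- node_by_label(tree, clade)
    sub <- ape::extract.clade(tree, node)
    sub <- validate_species_tree(sub)
  } else {
    sub <- tree
  }
  m <- unclass(counts)[, sub$tip.label, drop = FALSE]
  pm <- profile_matrix(m, "count")
  keep <- filter_root_present(pm, sub)
  if (length(keep) == 0) stop("no root-present families in clade")
  pm <- profile_matrix(m[keep, , drop = FALSE], "count")
  fit <- fit_lambda(pm, sub, max_size = max_size)
  rep_ <- expansion_pvalue(pm, sub, fit$lambda, n_sim = n_sim, seed = seed,
                           max_size = max_size)
  rep_$significant <- rep_$p_value < p_threshold
  rep_ <- rep_[order(rep_$p_value, rep_$family_id), ]
  rownames(rep_) <- NULL
  list(lambda = fit$lambda, report = rep_,
       clade = if (is.null(clade)) node_label(tree, root_node(tree)) else clade)
}
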