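## Correlated-evolution testing of binary phylogenetic profiles.
##
## Two binary traits (presence/absence of two families) evolve on the tree
## as a 4-state continuous-time Markov chain over (00, 01, 10, 11). The
## independent model has 4 rates (gain/loss per trait, identical whatever
## the other trait's state); the dependent model frees all 8 single-step
## transitions (simultaneous double transitions are forbidden). The
## dependent model nests the independent one, so
## LR = 2 (lnL_dep - lnL_ind) measures correlated gain/loss.

STATES <- c("00", "01", "10", "11")

#' Build the 4-state rate matrix of the independent or dependent model
#'
#' State order is 00, 01, 10, 11 (trait1 then trait2). Independent rates:
#' `c(a1, b1, a2, b2)` = gain/loss of trait 1, gain/loss of trait 2.
#' Dependent rates: the 8 single-step transitions in the fixed order
#' 00->10, 00->01, 01->11, 01->00, 10->00, 10->11, 11->01, 11->10.
#'
#' @param kind `"independent"` or `"dependent"`
#' @param rates non-negative rate vector (length 4 or 8)
#' @return 4x4 rate matrix with zero row sums
#' @export
ctmc_rate_matrix <- function(kind = c("independent", "dependent"), rates) {
  kind <- match.arg(kind)
  if (any(rates < 0)) stop("rates must be non-negative")
  Q <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  if (kind == "independent") {
    stopifnot(length(rates) == 4)
    a1 <- rates[1]; b1 <- rates[2]; a2 <- rates[3]; b2 <- rates[4]
    Q["00", "10"] <- a1; Q["00", "01"] <- a2
    Q["01", "11"] <- a1; Q["01", "00"] <- b2
    Q["10", "00"] <- b1; Q["10", "11"] <- a2
    Q["11", "01"] <- b1; Q["11", "10"] <- b2
  } else {
    stopifnot(length(rates) == 8)
    Q["00", "10"] <- rates[1]; Q["00", "01"] <- rates[2]
    Q["01", "11"] <- rates[3]; Q["01", "00"] <- rates[4]
    Q["10", "00"] <- rates[5]; Q["10", "11"] <- rates[6]
    Q["11", "01"] <- rates[7]; Q["11", "10"] <- rates[8]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## stationary distribution of a rate matrix (left null vector)
stationary_dist <- function(Q) {
  if (all(Q == 0)) return(rep(0.25, 4))
  ev <- eigen(t(Q))
  i <- which.min(abs(ev$values))
  v <- abs(Re(ev$vectors[, i]))
  v / sum(v)
}

pair_states <- function(x1, x2) 1L + 2L * x1 + x2  # 00,01,10,11 -> 1..4

## precompute the tree- and data-dependent parts of the pruning likelihood
## so optimisers only pay for the C++ kernel per evaluation
prepare_pair_loglik <- function(x1, x2, tree, warn_zero = TRUE) {
  if (!all(tree$tip.label %in% names(x1)) || !all(tree$tip.label %in% names(x2))) {
    stop("profiles must be named by all tree leaves")
  }
  lens <- tree$edge.length
  if (any(lens == 0)) {
    if (warn_zero) warning("zero-length branches collapsed")
    lens[lens == 0] <- 1e-8
  }
  st <- pair_states(x1[tree$tip.label], x2[tree$tip.label])
  nn <- n_nodes(tree)
  leaf_lik <- matrix(0, nn, 4)
  leaf_lik[cbind(seq_len(ape::Ntip(tree)), st)] <- 1
  post <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(post$edge[, 1], post$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  is_leaf <- as.integer(seq_len(nn) <= ape::Ntip(tree))
  root <- root_node(tree)
  function(Q, root_dist) {
    ctmc_loglik_cpp(Q, post$edge, lens[ord], leaf_lik, is_leaf, root, root_dist)
  }
}

#' Felsenstein pruning log-likelihood of a trait pair
#'
#' @param x1,x2 binary vectors named by species (all tree leaves)
#' @param tree species tree; zero-length branches are collapsed (length
#'   replaced by 1e-8) with a warning
#' @param Q 4x4 rate matrix (see [ctmc_rate_matrix()])
#' @param root root state distribution: `"stationary"` (default),
#'   `"uniform"`, or a length-4 probability vector
#' @return log-likelihood
#' @export
pruning_loglik <- function(x1, x2, tree, Q, root = "stationary") {
  tree <- validate_species_tree(tree)
  loglik <- prepare_pair_loglik(x1, x2, tree)
  root_dist <- if (is.numeric(root)) root
  else if (root == "uniform") rep(0.25, 4)
  else stationary_dist(Q)
  loglik(Q, root_dist)
}

#' Fit the independent or dependent model by multi-start ML
#'
#' Rates are optimised on the log scale (bounds 1e-6 to 100) by L-BFGS-B
#' from `restarts` deterministic pseudo-random start points; the best
#' converged fit is returned.
#'
#' @inheritParams pruning_loglik
#' @param kind `"independent"` or `"dependent"`
#' @param restarts number of optimiser starts (default 5)
#' @param seed integer seed for the start points
#' @param root root distribution mode passed to [pruning_loglik()]
#' @return list: kind, rates, loglik, convergence (0 = at least one start
#'   converged), n_converged
#' @export
fit_model <- function(x1, x2, tree, kind = c("independent", "dependent"),
                      restarts = 5L, seed = 1L, root = "stationary") {
  kind <- match.arg(kind)
  npar <- if (kind == "independent") 4L else 8L
  tree <- validate_species_tree(tree)
  loglik <- suppressWarnings(prepare_pair_loglik(x1, x2, tree))
  nll <- function(logr) {
    Q <- ctmc_rate_matrix(kind, exp(logr))
    root_dist <- if (is.numeric(root)) root
    else if (root == "uniform") rep(0.25, 4)
    else stationary_dist(Q)
    ll <- loglik(Q, root_dist)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- with_seed(stage_seed(seed, 11L), {
    lapply(seq_len(restarts), function(i) runif(npar, log(0.05), log(5)))
  })
  best <- NULL; n_conv <- 0L
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, method = "L-BFGS-B",
            lower = log(1e-6), upper = log(100),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed on every start")
  list(kind = kind, rates = exp(best$par), loglik = -best$value,
       convergence = if (n_conv > 0) 0L else 1L, n_converged = n_conv)
}

#' Likelihood-ratio test of correlated evolution for one pair
#'
#' @inheritParams fit_model
#' @return list: lnl_ind, lnl_dep, lr (= 2 * (lnl_dep - lnl_ind)), fits
#' @export
coevolution_test <- function(x1, x2, tree, restarts = 5L, seed = 1L,
                             root = "stationary") {
  fi <- fit_model(x1, x2, tree, "independent", restarts = restarts, seed = seed, root = root)
  fd <- fit_model(x1, x2, tree, "dependent", restarts = restarts, seed = seed, root = root)
  list(lnl_ind = fi$loglik, lnl_dep = fd$loglik,
       lr = 2 * (fd$loglik - fi$loglik), ind = fi, dep = fd)
}

#' Screen trait pairs for correlated evolution
#'
#' Tests all pairs between the rows of `A` and the rows of `B` (or all
#' unordered pairs within `A` when `B` is NULL), after filtering out
#' fixed traits and traits present or absent in fewer than the minimum
#' number of species. Results are sorted by likelihood ratio, significance
#' is judged against a chi-squared(4) quantile (Bonferroni optional), and
#' identical profile pairs are flagged as degenerate.
#'
#' @param A presence-mode profile matrix (rows = traits)
#' @param B optional second presence matrix (e.g. protein families)
#' @param tree species tree
#' @param min_present,min_absent per-trait species-count filters (default 5)
#' @param alpha significance level on the chi-squared(4) LR asymptotics
#' @param bonferroni divide alpha by the number of tested pairs
#' @param restarts,seed optimiser settings per pair
#' @param exclude optional 2-column matrix/data.frame of trait-id pairs to
#'   skip (e.g. pairs from the same synteny block)
#' @param max_pairs hard cap on the number of tested pairs (error above)
#' @return data.frame: trait_a, trait_b, n_present_a, n_present_b,
#'   lnl_ind, lnl_dep, lr, significant, degenerate; filtered traits are
#'   reported in attribute `filtered`.
#' @export
screen_pairs <- function(A, B = NULL, tree, min_present = 5L, min_absent = 5L,
                         alpha = 0.001, bonferroni = FALSE,
                         restarts = 5L, seed = 1L, exclude = NULL,
                         max_pairs = 2000L) {
  tree <- validate_species_tree(tree)
  ok_rows <- function(M) {
    p <- rowSums(unclass(M))
    n <- ncol(M)
    rownames(M)[p >= min_present & (n - p) >= min_absent]
  }
  keep_a <- ok_rows(A)
  pairs <- if (is.null(B)) {
    if (length(keep_a) >= 2) t(utils::combn(keep_a, 2)) else matrix(character(0), 0, 2)
  } else {
    keep_b <- ok_rows(B)
    as.matrix(expand.grid(a = keep_a, b = keep_b, stringsAsFactors = FALSE))
  }
  if (!is.null(exclude) && nrow(pairs) > 0) {
    ex <- paste(exclude[, 1], exclude[, 2])
    keyf <- paste(pairs[, 1], pairs[, 2])
    keyr <- paste(pairs[, 2], pairs[, 1])
    pairs <- pairs[!(keyf %in% ex | keyr %in% ex), , drop = FALSE]
  }
  if (nrow(pairs) > max_pairs) {
    stop(nrow(pairs), " pairs exceed max_pairs = ", max_pairs)
  }
  getB <- if (is.null(B)) function(id) unclass(A)[id, ] else function(id) unclass(B)[id, ]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x1 <- unclass(A)[pairs[i, 1], ]
    x2 <- getB(pairs[i, 2])
    ct <- coevolution_test(x1, x2, tree, restarts = restarts,
                           seed = stage_seed(seed, i))
    data.frame(trait_a = pairs[i, 1], trait_b = pairs[i, 2],
               n_present_a = sum(x1), n_present_b = sum(x2),
               lnl_ind = ct$lnl_ind, lnl_dep = ct$lnl_dep, lr = ct$lr,
               degenerate = identical(unname(x1), unname(x2)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(trait_a = character(0), trait_b = character(0),
               n_present_a = integer(0), n_present_b = integer(0),
               lnl_ind = numeric(0), lnl_dep = numeric(0), lr = numeric(0),
               degenerate = logical(0))
  a_eff <- if (bonferroni && nrow(out) > 0) alpha / nrow(out) else alpha
  out$significant <- out$lr > qchisq(1 - a_eff, df = 4)
  out <- out[order(-out$lr, out$trait_a, out$trait_b), ]
  rownames(out) <- NULL
  attr(out, "filtered") <- setdiff(rownames(A), keep_a)
  out
}

#' Simulate a binary trait pair on the tree
#'
#' Forward simulation of the 4-state chain: the root state is drawn from
#' the stationary distribution and states evolve along each branch with
#' transition matrices exp(Qt). Used for null calibration (independent
#' rates) and power checks (dependent rates).
#'
#' @param tree species tree
#' @param kind,rates model specification (see [ctmc_rate_matrix()])
#' @param seed integer seed
#' @return list of two binary vectors `x1`, `x2` named by species
#' @export
simulate_profile_pair <- function(tree, kind, rates, seed = 1L) {
  tree <- validate_species_tree(tree)
  Q <- ctmc_rate_matrix(kind, rates)
  with_seed(seed, {
    st <- integer(n_nodes(tree))
    st[root_node(tree)] <- sample.int(4, 1, prob = stationary_dist(Q))
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(pre$edge))) {
      P <- as.matrix(Matrix::expm(Q * pre$edge.length[e]))
      st[pre$edge[e, 2]] <- sample.int(4, 1, prob = pmax(P[st[pre$edge[e, 1]], ], 0))
    }
    leaf <- st[seq_len(ape::Ntip(tree))]
    list(x1 = setNames(as.integer(leaf >= 3), tree$tip.label),
         x2 = setNames(as.integer(leaf %% 2 == 0), tree$tip.label))
  })
}
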