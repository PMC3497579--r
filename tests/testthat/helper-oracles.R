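## Independent brute-force oracles used to validate the package's
## implementations on small instances. Each oracle is deliberately written
## from the definition (enumeration / direct formula), not by reusing the
## package's algorithmic path.

## random rooted binary tree with branch lengths, labelled tips
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n))
  validate_species_tree(tr)
}

## -- exhaustive seed-weighted affine alignment -------------------------------
## enumerate every global alignment path (with gap-state bookkeeping) and
## return the best score
oracle_align <- function(a, b, aseed, bseed, sc) {
  n <- length(a); m <- length(b)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      sub <- if (a[i] == b[j] && a[i] != 5L) {
        seeded <- if (sc$seed_mode == "both") aseed[i] && bseed[j]
        else aseed[i] || bseed[j]
        if (seeded) sc$match * sc$seed_mult else sc$match
      } else sc$mismatch
      best <- max(best, sub + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- sc$gap_extend + if (last == "X") 0 else sc$gap_open
      best <- max(best, cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- sc$gap_extend + if (last == "Y") 0 else sc$gap_open
      best <- max(best, cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "S")
}

## -- exhaustive single-gain (Dollo) search -----------------------------------
## enumerate presence/absence states of all internal nodes; keep assignments
## with exactly one 0->1 transition (root = 1 counts as the gain); minimise
## the number of 1->0 transitions
oracle_dollo_losses <- function(tree, presence_tips) {
  ntip <- ape::Ntip(tree)
  internal <- ntip + seq_len(tree$Nnode)
  states <- integer(ntip + tree$Nnode)
  states[presence_tips] <- 1L
  best <- Inf
  for (mask in 0:(2^length(internal) - 1)) {
    states[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    gains <- as.integer(states[ntip + 1L] == 1L)  # root gain
    losses <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- states[tree$edge[e, 1]]; ch <- states[tree$edge[e, 2]]
      if (p == 0L && ch == 1L) gains <- gains + 1L
      if (p == 1L && ch == 0L) losses <- losses + 1L
    }
    if (gains == 1L && losses < best) best <- losses
  }
  best
}

## -- direct split-join formula (loop implementation) -------------------------
oracle_split_join <- function(a, b) {
  a <- split(names(a), unname(a)); b <- split(names(b), unname(b))
  n <- length(unlist(a))
  d1 <- n - sum(vapply(a, function(C) {
    max(vapply(b, function(D) length(intersect(C, D)), 0L))
  }, 0L))
  d2 <- n - sum(vapply(b, function(D) {
    max(vapply(a, function(C) length(intersect(D, C)), 0L))
  }, 0L))
  d1 + d2
}

## -- naive agglomerative single linkage --------------------------------------
oracle_single_linkage <- function(scores, threshold) {
  ids <- rownames(scores)
  comp <- as.list(ids)
  repeat {
    merged <- FALSE
    for (i in seq_along(comp)) {
      for (j in seq_along(comp)) {
        if (j <= i) next
        link <- max(scores[comp[[i]], comp[[j]], drop = FALSE])
        if (link >= threshold) {
          comp[[i]] <- c(comp[[i]], comp[[j]])
          comp <- comp[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  setNames(rep(vapply(comp, min, ""), lengths(comp)), unlist(comp))
}

## -- exhaustive birth-death likelihood on a 3-leaf tree ----------------------
## tree ((A:ta,B:tb):tab,C:tc); root prior uniform over 1..root_max
oracle_bd_loglik_3leaf <- function(sizes, ta, tb, tab, tc, lambda,
                                   max_size, root_max) {
  Pt <- function(t) bd_transition_matrix(max_size, t, lambda)
  Pa <- Pt(ta); Pb <- Pt(tb); Pab <- Pt(tab); Pc <- Pt(tc)
  tot <- 0
  for (r in seq_len(root_max)) {
    for (m in 0:max_size) {
      tot <- tot + (1 / root_max) * Pab[r + 1, m + 1] *
        Pa[m + 1, sizes["A"] + 1] * Pb[m + 1, sizes["B"] + 1] *
        Pc[r + 1, sizes["C"] + 1]
    }
  }
  log(tot)
}

## -- exhaustive 4-state CTMC likelihood --------------------------------------
oracle_ctmc_loglik <- function(x1, x2, tree, Q, root_dist) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  st <- integer(nn)
  st[seq_len(ntip)] <- 1L + 2L * x1[tree$tip.label] + x2[tree$tip.label]
  internal <- ntip + seq_len(tree$Nnode)
  Pedges <- lapply(seq_len(nrow(tree$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  grid <- do.call(expand.grid, rep(list(1:4), length(internal)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st[internal] <- as.integer(grid[g, ])
    p <- root_dist[st[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Pedges[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    tot <- tot + p
  }
  log(tot)
}

## -- brute-force collinear chain extraction for two genomes ------------------
## same semantics and tie-breaking as the detector, but chains are found by
## exhaustive recursive enumeration instead of dynamic programming
oracle_pair_runs <- function(gA, gB, max_gap, mm, min_anchors) {
  all_chains <- function(availA, availB, orient) {
    pairs <- which(outer(gA$family_id, gB$family_id, "==") &
                     outer(availA, availB, "&"), arr.ind = TRUE)
    if (nrow(pairs) == 0) return(list())
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    compat <- function(p, q) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      i2 <- pairs[q, 1]; j2 <- pairs[q, 2]
      if (i2 <= i) return(FALSE)
      if (orient == 1L && j2 <= j) return(FALSE)
      if (orient == -1L && j2 >= j) return(FALSE)
      if (i2 - i - 1L > mm) return(FALSE)
      if (abs(j2 - j) - 1L > mm) return(FALSE)
      if (gA$start[i2] - gA$end[i] - 1L > max_gap) return(FALSE)
      jlo <- min(j, j2); jhi <- max(j, j2)
      if (gB$start[jhi] - gB$end[jlo] - 1L > max_gap) return(FALSE)
      TRUE
    }
    chains <- list()
    extend <- function(chain) {
      chains[[length(chains) + 1L]] <<- chain
      for (q in seq_len(nrow(pairs))) {
        if (compat(chain[length(chain)], q)) extend(c(chain, q))
      }
    }
    for (p in seq_len(nrow(pairs))) extend(p)
    lapply(chains, function(ch) pairs[ch, , drop = FALSE])
  }
  runs <- list()
  availA <- rep(TRUE, nrow(gA)); availB <- rep(TRUE, nrow(gB))
  repeat {
    best <- NULL; best_orient <- NULL
    for (orient in c(1L, -1L)) {
      chains <- all_chains(availA, availB, orient)
      if (length(chains) == 0) next
      lens <- vapply(chains, nrow, 0L)
      cand <- chains[lens == max(lens)]
      ## lexicographically smallest flattened (i1,j1,i2,j2,...) sequence
      keyed <- vapply(cand, function(m) {
        paste(sprintf("%05d%05d", m[, 1], m[, 2]), collapse = "")
      }, "")
      pick <- cand[[order(keyed)[1]]]
      if (is.null(best) || nrow(pick) > nrow(best)) {
        best <- pick; best_orient <- orient
      }
    }
    if (is.null(best) || nrow(best) < min_anchors) break
    runs[[length(runs) + 1L]] <- list(pairs = best, orient = best_orient,
                                      families = gA$family_id[best[, 1]])
    availA[best[, 1]] <- FALSE
    availB[best[, 2]] <- FALSE
  }
  runs
}

## canonical family-run key (forward/reverse symmetric)
canon_run <- function(fams) {
  min(paste(fams, collapse = "|"), paste(rev(fams), collapse = "|"))
}

## build a toy anchor table from per-genome family vectors; anchors are
## 200 bp long and spaced `spacing` bp apart
toy_anchors <- function(genomes, spacing = 800L, kind = "protein") {
  rows <- lapply(names(genomes), function(g) {
    fams <- genomes[[g]]
    start <- 1000L + (seq_along(fams) - 1L) * (spacing + 200L)
    data.frame(species = g, chrom = "chr1", start = start,
               end = start + 199L, strand = "+", family_id = fams,
               locus_id = sprintf("%s_a%d", g, seq_along(fams)),
               kind = kind, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## random partition of n elements into at most k blocks, as membership vector
random_partition <- function(n, k) {
  setNames(paste0("c", sample.int(k, n, replace = TRUE)), paste0("e", seq_len(n)))
}

## misc small helpers shared by test files
mrca_of_tips_test <- function(tree, labels) {
  tips <- match(labels, tree$tip.label)
  if (length(tips) == 1) tips else ape::getMRCA(tree, tips)
}

as_membership_test <- function(p) setNames(p$family_id, p$locus_id)
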