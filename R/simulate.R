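## Synthetic dataset generator with planted ground truth.
##
## Every generator is a pure function of (config, seed): stage seeds are
## derived deterministically from the single global seed so that reruns are
## bit-identical and stages can be re-run in isolation.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' small vertebrate-like study: a 16-species Yule tree, 100 miRNA families
#' gained uniformly over tree nodes, occasional secondary loss, strong seed
#' conservation relative to the rest of the precursor, miRNA loci arranged
#' in genomic clusters, and half of the loci intronic.
#'
#' @param seed integer master seed; all stages derive from it.
#' @param n_species number of species when growing a Yule tree.
#' @param tree optional fixed species tree (Newick string or `phylo`);
#'   overrides `n_species`.
#' @param birth_rate Yule speciation rate (per unit time).
#' @param n_families number of miRNA families to plant.
#' @param gain_root_weight relative weight of the root when drawing each
#'   family's gain node (1 = uniform over all nodes; larger = root-biased).
#' @param loss_prob per-branch probability of secondary loss below the gain.
#' @param sub_prob_offseed per-site, per-branch substitution probability
#'   outside the seed.
#' @param sub_prob_inseed same, inside the seed; must not exceed
#'   `sub_prob_offseed` (seed positions are under stronger constraint).
#' @param dup_rate expected number of extra tandem copies per present
#'   species (Poisson).
#' @param lambda_sim per-gene birth(=death) rate for the family-size
#'   simulator.
#' @param mean_cluster_size mean number of families per planted genomic
#'   cluster (geometric; 1 plants mostly solo loci).
#' @param intra_spacing bp between consecutive loci inside a cluster.
#' @param cluster_threshold bp threshold defining a cluster (annotation-side
#'   default is the same 10 kb).
#' @param frac_intronic fraction of miRNA cluster groups hosted inside a
#'   protein-coding intron.
#' @param intergenic_gap bp between consecutive anchor units on a
#'   chromosome; must exceed `cluster_threshold` so planted clusters stay
#'   separated.
#' @param n_protein_families number of single-copy protein families per
#'   genome (the synteny anchors).
#' @param n_inversions,n_translocations rearrangement operations applied
#'   independently to each species' anchor order.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 16L,
                       tree = NULL,
                       birth_rate = 1,
                       n_families = 100L,
                       gain_root_weight = 1,
                       loss_prob = 0.05,
                       sub_prob_offseed = 0.05,
                       sub_prob_inseed = 0.01,
                       dup_rate = 0.3,
                       lambda_sim = 0.5,
                       mean_cluster_size = 3,
                       intra_spacing = 2000L,
                       cluster_threshold = 10000L,
                       frac_intronic = 0.5,
                       intergenic_gap = 25000L,
                       n_protein_families = 40L,
                       n_inversions = 0L,
                       n_translocations = 0L) {
  cfg <- as.list(environment())
  probs <- c(loss_prob, sub_prob_offseed, sub_prob_inseed, frac_intronic)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (sub_prob_inseed > sub_prob_offseed) {
    stop("in-seed substitution probability must not exceed off-seed")
  }
  if (intra_spacing >= cluster_threshold) {
    stop("intra_spacing must be below cluster_threshold")
  }
  if (intergenic_gap <= cluster_threshold) {
    stop("intergenic_gap must exceed cluster_threshold")
  }
  if (lambda_sim < 0 || dup_rate < 0 || birth_rate <= 0) stop("rates must be non-negative")
  structure(cfg, class = "sim_config")
}

## derive a stage seed from the master seed (kept under 2^31)
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 16807) %% 2147483587
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate the species tree of a configuration
#'
#' Returns the fixed tree when one is configured, otherwise grows a Yule
#' tree with the configured number of species and scales its depth to 1.
#'
#' @param config a [sim_config()]
#' @return a validated species tree
#' @export
simulate_tree <- function(config) {
  if (!is.null(config$tree)) {
    tr <- if (inherits(config$tree, "phylo")) config$tree else read_species_tree(config$tree)
    return(validate_species_tree(tr))
  }
  tr <- with_seed(stage_seed(config$seed, 1L), {
    t <- ape::rphylo(config$n_species, birth = config$birth_rate, death = 0)
    t$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
    t
  })
  tr$edge.length <- tr$edge.length / max(node_ages(validate_species_tree(tr)))
  validate_species_tree(tr)
}

#' Simulate Dollo-consistent family gain/loss histories
#'
#' Each family is gained at a single node (drawn uniformly over all nodes,
#' optionally root-weighted) and then lost independently on branches below
#' the gain with the configured probability; subtrees below a loss stay
#' absent (a family, once lost, is never regained). Families that would go
#' extinct everywhere are re-drawn so every planted family survives in at
#' least one species.
#'
#' @param tree a species tree
#' @param config a [sim_config()]
#' @return list with `presence` (profile matrix), `counts` (profile matrix,
#'   tandem copies per species), and `truth` (per-family gain node label,
#'   loss-edge labels, per-species copy number).
#' @export
simulate_gain_loss <- function(tree, config) {
  tree <- validate_species_tree(tree)
  fam_ids <- sprintf("FAM%04d", seq_len(config$n_families))
  kids <- children_of(tree)
  tu <- tips_under(tree)
  nn <- n_nodes(tree)
  w <- rep(1, nn); w[root_node(tree)] <- config$gain_root_weight
  with_seed(stage_seed(config$seed, 2L), {
    truth <- lapply(fam_ids, function(f) {
      repeat {
        gain <- sample.int(nn, 1L, prob = w)
        loss_edges <- integer(0)
        present <- integer(0)
        ## top-down from the gain node; each edge below may be lost
        stack <- gain
        first <- TRUE
        while (length(stack) > 0) {
          v <- stack[length(stack)]; stack <- stack[-length(stack)]
          if (!first && runif(1) < config$loss_prob) {
            loss_edges <- c(loss_edges, v)
            next
          }
          if (v <= ape::Ntip(tree)) present <- c(present, v)
          ch <- kids[[v]]
          first <- FALSE
          if (length(ch) > 0) stack <- c(stack, ch)
        }
        ## the gain node itself is never lost: re-walk marking gain's
        ## children as losable edges (handled by `first` flag above)
        if (length(present) > 0) {
          counts <- setNames(integer(ape::Ntip(tree)), tree$tip.label)
          counts[present] <- 1L + rpois(length(present), config$dup_rate)
          return(list(gain_node = node_label(tree, gain),
                      loss_edges = node_label(tree, loss_edges),
                      counts = counts))
        }
      }
    })
    names(truth) <- fam_ids
    cnt <- do.call(rbind, lapply(truth, `[[`, "counts"))
    rownames(cnt) <- fam_ids
    counts <- profile_matrix(cnt, "count")
    list(presence = as_presence(counts), counts = counts, truth = truth)
  })
}

.BASES <- c("A", "C", "G", "U")

mutate_seq <- function(chars, seed_mask, p_in, p_off) {
  p <- ifelse(seed_mask, p_in, p_off)
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(.BASES, b), 1L), "")
  }
  chars
}

#' Simulate precursor sequences along the tree
#'
#' One ancestral precursor (length 60-120, uniform ACGU composition) is
#' drawn per family at its gain node and evolved down the tree with
#' independent per-site substitutions at two rates: a low in-seed rate and a
#' higher off-seed rate, reflecting the functional constraint on mature
#' positions 2-8. Tandem copies within a species receive one extra round of
#' substitutions.
#'
#' @param gl result of [simulate_gain_loss()]
#' @param tree the species tree used for `gl`
#' @param config a [sim_config()]
#' @return a data.frame: locus_id, species, family_id, sequence,
#'   mature1_start/end, copy index; plus the ancestral sequences as an
#'   attribute `ancestors`.
#' @export
simulate_sequences <- function(gl, tree, config) {
  tree <- validate_species_tree(tree)
  kids <- children_of(tree)
  with_seed(stage_seed(config$seed, 3L), {
    rows <- list()
    anc <- list()
    for (f in names(gl$truth)) {
      tr <- gl$truth[[f]]
      len <- sample(60:120, 1L)
      mstart <- sample(2:(len - 22L), 1L)
      mend <- mstart + 21L
      seed_pos <- (mstart + 1L):(mstart + 7L)   # mature positions 2-8
      mask <- seq_len(len) %in% seed_pos
      root_seq <- sample(.BASES, len, replace = TRUE)
      anc[[f]] <- paste(root_seq, collapse = "")
      gain <- node_by_label(tree, tr$gain_node)
      lost <- if (length(tr$loss_edges)) node_by_label(tree, tr$loss_edges) else integer(0)
      ## depth-first from the gain node carrying the evolving sequence
      walk <- function(v, sq, first) {
        if (v %in% lost) return(invisible(NULL))
        if (!first) sq <- mutate_seq(sq, mask, config$sub_prob_inseed, config$sub_prob_offseed)
        if (v <= ape::Ntip(tree)) {
          sp <- tree$tip.label[v]
          k <- gl$truth[[f]]$counts[[sp]]
          for (copy in seq_len(k)) {
            cs <- if (copy == 1L) sq else {
              mutate_seq(sq, mask, config$sub_prob_inseed, config$sub_prob_offseed)
            }
            rows[[length(rows) + 1L]] <<- data.frame(
              locus_id = sprintf("%s_%s_c%d", f, sp, copy),
              species = sp, family_id = f,
              sequence = paste(cs, collapse = ""),
              mature1_start = mstart, mature1_end = mend,
              copy = copy, stringsAsFactors = FALSE)
          }
        }
        for (ch in kids[[v]]) walk(ch, sq, FALSE)
      }
      walk(gain, root_seq, TRUE)
    }
    out <- do.call(rbind, rows)
    attr(out, "ancestors") <- anc
    out
  })
}

#' Simulate genomes: anchor order, coordinates, clusters, introns
#'
#' Builds one ancestral chromosome layout (single-copy protein anchors in a
#' fixed order, miRNA cluster groups inserted between them) and realises it
#' in every species: species share the anchor order up to the configured
#' number of inversions/translocations, miRNA loci of one group sit within
#' `intra_spacing` of each other (a planted cluster), and a configured
#' fraction of groups is placed inside a host protein's intron.
#'
#' @param gl result of [simulate_gain_loss()]
#' @param seqs result of [simulate_sequences()]
#' @param tree the species tree
#' @param config a [sim_config()]
#' @return list with `mirna` (validated miRNA locus table), `proteins`
#'   (validated protein locus table), and `truth` (per-locus context and
#'   cluster id, per-species anchor order, planted family runs).
#' @export
simulate_genomes <- function(gl, seqs, tree, config) {
  tree <- validate_species_tree(tree)
  species <- sort(tree$tip.label)
  fam_ids <- names(gl$truth)
  with_seed(stage_seed(config$seed, 4L), {
    ## partition miRNA families into cluster groups
    groups <- list()
    pool <- sample(fam_ids)
    while (length(pool) > 0) {
      k <- min(1L + rpois(1L, max(config$mean_cluster_size - 1, 0)), length(pool))
      groups[[length(groups) + 1L]] <- pool[seq_len(k)]
      pool <- pool[-seq_len(k)]
    }
    group_intronic <- runif(length(groups)) < config$frac_intronic
    prot_fams <- sprintf("PF%03d", seq_len(config$n_protein_families))
    ## ancestral anchor order: units are proteins or miRNA groups; an
    ## intronic group is fused to a host protein unit
    units <- c(lapply(prot_fams, function(p) list(kind = "protein", fam = p, group = NULL)),
               lapply(seq_along(groups), function(gi) {
                 list(kind = "mirna_group", fam = NULL, group = gi)
               }))
    units <- units[sample(length(units))]
    ## attach intronic groups to the nearest protein unit
    host_of <- rep(NA_character_, length(groups))
    prot_positions <- which(vapply(units, function(u) u$kind == "protein", TRUE))
    for (gi in seq_along(groups)) {
      if (group_intronic[gi]) {
        ui <- which(vapply(units, function(u) identical(u$group, gi), TRUE))
        host_of[gi] <- units[[prot_positions[which.min(abs(prot_positions - ui))]]]$fam
      }
    }
    ancestral_units <- units
    mir_rows <- list(); prot_rows <- list(); prot_exons <- list()
    truth_context <- list(); truth_cluster <- list()
    anchor_orders <- list()
    for (sp in species) {
      ord <- seq_along(ancestral_units)
      for (i in seq_len(config$n_inversions)) {
        ij <- sort(sample(length(ord), 2L))
        ord[ij[1]:ij[2]] <- rev(ord[ij[1]:ij[2]])
      }
      for (i in seq_len(config$n_translocations)) {
        ij <- sort(sample(length(ord), 2L))
        seg <- ord[ij[1]:ij[2]]
        rest <- ord[-(ij[1]:ij[2])]
        at <- sample(0:length(rest), 1L)
        ord <- append(rest, seg, after = at)
      }
      pos <- 1L
      fam_run <- character(0)
      for (ui in ord) {
        u <- ancestral_units[[ui]]
        if (u$kind == "protein") {
          pf <- u$fam
          hosted <- which(host_of == pf & group_intronic)
          ## gather hosted miRNA loci present in this species, per group
          hosted_loci <- list()
          for (gi in hosted) {
            sub <- seqs[seqs$family_id %in% groups[[gi]] & seqs$species == sp, , drop = FALSE]
            if (nrow(sub)) hosted_loci[[length(hosted_loci) + 1L]] <- list(gi = gi, sub = sub)
          }
          ## distinct hosted groups stay > intergenic_gap apart within the
          ## intron so planted clusters never merge
          need <- 0L
          for (h in hosted_loci) need <- need + sum(nchar(h$sub$sequence)) +
            config$intra_spacing * nrow(h$sub) + config$intergenic_gap
          intron_len <- max(10000L, need + 2000L)
          e1 <- c(pos, pos + 999L)
          e2 <- c(e1[2] + intron_len + 1L, e1[2] + intron_len + 1000L)
          gid <- sprintf("%s_%s", pf, sp)
          prot_rows[[length(prot_rows) + 1L]] <- data.frame(
            locus_id = gid, species = sp, chrom = "chr1",
            start = e1[1], end = e2[2], strand = "+", family_id = pf,
            stringsAsFactors = FALSE)
          prot_exons[[length(prot_exons) + 1L]] <- rbind(e1, e2)
          fam_run <- c(fam_run, pf)
          ## drop hosted loci into the intron
          ipos <- e1[2] + 1000L
          for (h in hosted_loci) {
            for (r in seq_len(nrow(h$sub))) {
              row <- h$sub[r, ]
              L <- nchar(row$sequence)
              mir_rows[[length(mir_rows) + 1L]] <- data.frame(
                locus_id = row$locus_id, species = sp, chrom = "chr1",
                start = ipos, end = ipos + L - 1L, strand = "+",
                sequence = row$sequence,
                mature1_start = row$mature1_start, mature1_end = row$mature1_end,
                stringsAsFactors = FALSE)
              truth_context[[row$locus_id]] <- "intronic"
              truth_cluster[[row$locus_id]] <- sprintf("G%03d_%s", h$gi, sp)
              fam_run <- c(fam_run, row$family_id)
              ipos <- ipos + L - 1L + config$intra_spacing
            }
            ipos <- ipos - config$intra_spacing + config$intergenic_gap
          }
          pos <- e2[2] + config$intergenic_gap
        } else {
          gi <- u$group
          if (group_intronic[gi]) next  # realised inside its host protein
          first_pos <- pos
          n_placed <- 0L
          for (f in groups[[gi]]) {
            sub <- seqs[seqs$family_id == f & seqs$species == sp, , drop = FALSE]
            for (r in seq_len(nrow(sub))) {
              row <- sub[r, ]
              L <- nchar(row$sequence)
              mir_rows[[length(mir_rows) + 1L]] <- data.frame(
                locus_id = row$locus_id, species = sp, chrom = "chr1",
                start = pos, end = pos + L - 1L, strand = "+",
                sequence = row$sequence,
                mature1_start = row$mature1_start, mature1_end = row$mature1_end,
                stringsAsFactors = FALSE)
              truth_context[[row$locus_id]] <- "intergenic"
              truth_cluster[[row$locus_id]] <- sprintf("G%03d_%s", gi, sp)
              fam_run <- c(fam_run, row$family_id)
              pos <- pos + L - 1L + config$intra_spacing
              n_placed <- n_placed + 1L
            }
          }
          if (n_placed > 0L) pos <- pos - config$intra_spacing + config$intergenic_gap
        }
      }
      anchor_orders[[sp]] <- fam_run
    }
    mirna <- do.call(rbind, mir_rows)
    mirna <- mirna_loci(mirna$locus_id, mirna$species, mirna$chrom, mirna$start,
                        mirna$end, mirna$strand, mirna$sequence,
                        mirna$mature1_start, mirna$mature1_end,
                        family_id = seqs$family_id[match(mirna$locus_id, seqs$locus_id)])
    pr <- do.call(rbind, prot_rows)
    proteins <- protein_loci(pr$locus_id, pr$species, pr$chrom, pr$start, pr$end,
                             pr$strand, pr$family_id, prot_exons)
    ## solo loci (only member of their planted group in a species) are not
    ## clusters; blank their cluster id
    cl <- unlist(truth_cluster)
    tab <- table(cl)
    cl[cl %in% names(tab)[tab < 2]] <- NA_character_
    list(mirna = mirna, proteins = proteins,
         truth = list(context = unlist(truth_context),
                      cluster = cl,
                      anchor_orders = anchor_orders,
                      groups = groups,
                      group_intronic = group_intronic,
                      host_of = host_of))
  })
}

#' Simulate family sizes under the linear birth-death process
#'
#' Explicit event (Gillespie) simulation of a linear birth-death process
#' with equal per-gene birth and death rate `lambda` along every branch,
#' started from the given root size. Serves as the independent generator
#' for testing the expansion module's likelihood machinery.
#'
#' @param tree a species tree
#' @param lambda per-gene birth(=death) rate
#' @param root_sizes integer vector of family sizes at the root (one family
#'   per element; must all be >= 1)
#' @param seed integer seed
#' @return a count-mode profile matrix (families x species), with the full
#'   per-node size history as attribute `node_sizes`.
#' @export
simulate_family_sizes <- function(tree, lambda, root_sizes, seed = 1L) {
  tree <- validate_species_tree(tree)
  if (any(root_sizes < 1)) stop("root sizes must be >= 1")
  if (lambda < 0) stop("lambda must be >= 0")
  nfam <- length(root_sizes)
  fam_ids <- sprintf("FAM%04d", seq_len(nfam))
  with_seed(seed, {
    node_sizes <- matrix(NA_integer_, nfam, n_nodes(tree))
    node_sizes[, root_node(tree)] <- as.integer(root_sizes)
    evolve_branch <- function(n, t) {
      if (lambda == 0 || n == 0) return(n)
      time <- 0
      repeat {
        rate <- 2 * lambda * n
        if (n == 0 || rate == 0) return(n)
        time <- time + rexp(1, rate)
        if (time > t) return(n)
        n <- n + sample(c(1L, -1L), 1L)
      }
    }
    preorder <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (f in seq_len(nfam)) {
      for (e in seq_len(nrow(preorder))) {
        p <- preorder[e, 1]; v <- preorder[e, 2]
        node_sizes[f, v] <- evolve_branch(node_sizes[f, p], lens[e])
      }
    }
    m <- node_sizes[, seq_len(ape::Ntip(tree)), drop = FALSE]
    dimnames(m) <- list(fam_ids, tree$tip.label)
    out <- profile_matrix(m, "count")
    attr(out, "node_sizes") <- node_sizes
    out
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs the tree, gain/loss, sequence and genome generators in order and
#' returns every object plus the planted ground truth.
#'
#' @param config a [sim_config()]
#' @return list: tree, presence, counts, mirna, proteins, sequences, truth,
#'   config.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- simulate_tree(config)
  gl <- simulate_gain_loss(tree, config)
  seqs <- simulate_sequences(gl, tree, config)
  gen <- simulate_genomes(gl, seqs, tree, config)
  truth <- c(gl["truth"], gen["truth"])
  names(truth) <- c("history", "genome")
  list(tree = tree, presence = gl$presence, counts = gl$counts,
       mirna = gen$mirna, proteins = gen$proteins, sequences = seqs,
       truth = truth, config = config)
}

#' Write a synthetic dataset to a directory in standard formats
#'
#' Emits tree.nwk, mirna.gff3 + mirna.fa, proteins.gff3, presence.tsv,
#' counts.tsv and reference_families.tsv (the planted partition, usable as
#' the reference for threshold optimisation).
#'
#' @param ds result of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_species_tree(ds$tree, file.path(dir, "tree.nwk"))
  write_mirna_loci(ds$mirna, file.path(dir, "mirna.gff3"), file.path(dir, "mirna.fa"))
  write_protein_loci(ds$proteins, file.path(dir, "proteins.gff3"))
  write_profile_matrix(ds$presence, file.path(dir, "presence.tsv"))
  write_profile_matrix(ds$counts, file.path(dir, "counts.tsv"))
  ref <- data.frame(locus_id = ds$mirna$locus_id, family_id = ds$mirna$family_id)
  ref <- ref[order(ref$locus_id), ]
  write.table(ref, file.path(dir, "reference_families.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
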