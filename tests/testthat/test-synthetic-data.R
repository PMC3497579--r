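test_that("config validation enforces the seed-conservation constraint", {
  expect_error(sim_config(sub_prob_inseed = 0.2, sub_prob_offseed = 0.1),
               "in-seed")
  expect_error(sim_config(loss_prob = 1.5), "probabilities")
  expect_error(sim_config(intra_spacing = 20000, cluster_threshold = 10000),
               "intra_spacing")
})

test_that("gain/loss histories obey the single-gain structure", {
  tr <- random_tree(8, seed = 11)
  cfg <- sim_config(seed = 5, n_families = 30, tree = tr, loss_prob = 0)
  gl <- simulate_gain_loss(tr, cfg)
  tu <- tips_under(tr)
  for (f in names(gl$truth)) {
    tr_f <- gl$truth[[f]]
    gain <- node_by_label(tr, tr_f$gain_node)
    present <- names(tr_f$counts)[tr_f$counts > 0]
    ## with no losses, presence = exactly the gain clade
    expect_setequal(present, tr$tip.label[tu[[gain]]])
  }
  ## all gained at root with no loss -> all-present matrix
  cfg2 <- sim_config(seed = 5, n_families = 10, tree = tr, loss_prob = 0,
                     gain_root_weight = 1e9)
  gl2 <- simulate_gain_loss(tr, cfg2)
  expect_true(all(unclass(gl2$presence) == 1L))
  ## forced extinction below gains -> only terminal-edge gains survive
  cfg3 <- sim_config(seed = 5, n_families = 20, tree = tr, loss_prob = 1)
  gl3 <- simulate_gain_loss(tr, cfg3)
  expect_true(all(rowSums(unclass(gl3$presence)) == 1))
  ## determinism
  gl_b <- simulate_gain_loss(tr, cfg)
  expect_identical(unclass(gl$counts), unclass(gl_b$counts))
})

test_that("copy-number ground truth matches the presence matrix", {
  cfg <- sim_config(seed = 9, n_species = 10, n_families = 40)
  tr <- simulate_tree(cfg)
  gl <- simulate_gain_loss(tr, cfg)
  expect_identical(unclass(as_presence(gl$counts)), unclass(gl$presence))
})

test_that("sequence simulation respects the two substitution regimes", {
  tr <- random_tree(8, seed = 3)
  cfg0 <- sim_config(seed = 7, tree = tr, n_families = 15,
                     sub_prob_inseed = 0, sub_prob_offseed = 0)
  gl <- simulate_gain_loss(tr, cfg0)
  seqs0 <- simulate_sequences(gl, tr, cfg0)
  ## no substitutions at all -> family members identical
  for (f in unique(seqs0$family_id)) {
    expect_length(unique(seqs0$sequence[seqs0$family_id == f]), 1)
  }
  ## in-seed rate 0 -> seed 7-mers identical within family
  cfg1 <- sim_config(seed = 7, tree = tr, n_families = 15,
                     sub_prob_inseed = 0, sub_prob_offseed = 0.3)
  seqs1 <- simulate_sequences(gl, tr, cfg1)
  for (f in unique(seqs1$family_id)) {
    sub <- seqs1[seqs1$family_id == f, ]
    seeds <- substr(sub$sequence, sub$mature1_start + 1, sub$mature1_start + 7)
    expect_length(unique(seeds), 1)
  }
})

test_that("off-seed divergence from the ancestor tracks the per-branch rate", {
  ## a long chain of branches: identity to the ancestral sequence after k
  ## rounds of per-site substitution at rate p has expectation
  ## 1/4 + 3/4 (1 - 4p/3)^k  (Jukes-Cantor-like per-branch kernel)
  tr <- validate_species_tree(ape::read.tree(
    text = "((((A:1,B:1):1,C:1):1,D:1):1,E:1);"))
  p <- 0.1
  cfg <- sim_config(seed = 21, tree = tr, n_families = 150, loss_prob = 0,
                    gain_root_weight = 1e9, sub_prob_inseed = 0,
                    sub_prob_offseed = p, dup_rate = 0)
  gl <- simulate_gain_loss(tr, cfg)
  seqs <- simulate_sequences(gl, tr, cfg)
  anc <- attr(seqs, "ancestors")
  ident_k <- function(sp, k) {
    sub <- seqs[seqs$species == sp, ]
    obs <- vapply(seq_len(nrow(sub)), function(i) {
      a <- strsplit(anc[[sub$family_id[i]]], "")[[1]]
      b <- strsplit(sub$sequence[i], "")[[1]]
      seed <- (sub$mature1_start[i] + 1):(sub$mature1_start[i] + 7)
      mean((a == b)[-seed])
    }, 0)
    mean(obs)
  }
  for (case in list(c("E", 1), c("D", 2), c("A", 4))) {
    k <- as.numeric(case[2])
    expected <- 0.25 + 0.75 * (1 - 4 * p / 3)^k
    expect_lt(abs(ident_k(case[1], k) - expected), 0.03)
  }
})

test_that("genome simulation plants clusters, introns and shared anchor order", {
  tr <- random_tree(6, seed = 2)
  cfg <- sim_config(seed = 13, tree = tr, n_families = 20, frac_intronic = 1,
                    dup_rate = 0)
  ds_gl <- simulate_gain_loss(tr, cfg)
  seqs <- simulate_sequences(ds_gl, tr, cfg)
  gen <- simulate_genomes(ds_gl, seqs, tr, cfg)
  ## every miRNA locus inside a host intron when frac_intronic = 1
  expect_true(all(gen$truth$context == "intronic"))
  ## no rearrangements -> identical anchor order across species, up to
  ## absence of family members
  ords <- gen$truth$anchor_orders
  shared <- Reduce(intersect, ords)
  for (o in ords) {
    expect_identical(o[o %in% shared], shared[shared %in% o])
  }
  ## planted clusters sit within the threshold, separate groups beyond it
  cl <- assign_clusters(gen$mirna, threshold = cfg$cluster_threshold)
  truth <- gen$truth$cluster[gen$mirna$locus_id]
  expect_identical(is.na(cl$cluster_id), is.na(unname(truth)))
  both <- !is.na(truth)
  expect_equal(split_join(setNames(cl$cluster_id[both], cl$locus_id[both]),
                          setNames(unname(truth[both]), cl$locus_id[both])), 0)
})

test_that("family-size simulation matches birth-death expectations", {
  tr <- read_species_tree("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  ## lambda 0: sizes frozen at the root size
  fz <- simulate_family_sizes(tr, 0, rep(3L, 5), seed = 4)
  expect_true(all(unclass(fz) == 3L))
  ## determinism
  a <- simulate_family_sizes(tr, 0.5, rep(2L, 20), seed = 8)
  b <- simulate_family_sizes(tr, 0.5, rep(2L, 20), seed = 8)
  expect_identical(unclass(a), unclass(b))
  expect_error(simulate_family_sizes(tr, 0.5, c(1L, 0L), seed = 1), ">= 1")
})

test_that("extinction frequency matches the analytic probability", {
  ## P(extinct by time t | size 1) = alpha = lambda t / (1 + lambda t);
  ## a two-leaf star with branch length t gives two dependent observations,
  ## use one leaf only
  tr <- read_species_tree("(A:1.5,B:1.5);")
  lambda <- 1
  alpha <- lambda * 1.5 / (1 + lambda * 1.5)
  n <- 3000
  sz <- simulate_family_sizes(tr, lambda, rep(1L, n), seed = 99)
  phat <- mean(unclass(sz)[, "A"] == 0)
  se <- sqrt(alpha * (1 - alpha) / n)
  expect_lt(abs(phat - alpha), 3.5 * se)
})

test_that("a dataset writes and reads back through the standard formats", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(sim_config(seed = 31, n_species = 6, n_families = 12))
  write_dataset(ds, dir)
  tr <- read_species_tree(file.path(dir, "tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(ds$tree$tip.label))
  mir <- read_mirna_loci(file.path(dir, "mirna.gff3"), file.path(dir, "mirna.fa"))
  expect_setequal(mir$locus_id, ds$mirna$locus_id)
  prot <- read_protein_loci(file.path(dir, "proteins.gff3"))
  expect_equal(nrow(prot), nrow(ds$proteins))
  pm <- read_profile_matrix(file.path(dir, "presence.tsv"))
  expect_identical(unclass(pm), unclass(ds$presence))
})
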