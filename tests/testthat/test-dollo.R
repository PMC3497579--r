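pm_from <- function(tree, present, fam = "F1") {
  m <- matrix(0L, 1, ape::Ntip(tree),
              dimnames = list(fam, tree$tip.label))
  m[1, present] <- 1L
  profile_matrix(m, "presence")
}

test_that("reconstruction places gains at the MRCA and minimal losses", {
  tr <- read_species_tree("((A:1,B:1):1,(C:1,D:1):1);")
  r1 <- dollo_reconstruct(pm_from(tr, c("A", "B")), tr)
  expect_equal(r1$gain_node, node_label(tr, mrca_of_tips_test(tr, c("A", "B"))))
  expect_equal(r1$n_losses, 0L)
  ## scattered presence forces a root gain with two losses
  r2 <- dollo_reconstruct(pm_from(tr, c("A", "C")), tr)
  expect_equal(r2$gain_node, node_label(tr, 5))
  expect_equal(r2$n_losses, 2L)
  expect_setequal(r2$loss_edges[[1]], c("B", "D"))
  ## species-specific family: terminal gain, no losses
  r3 <- dollo_reconstruct(pm_from(tr, "A"), tr)
  expect_equal(r3$gain_node, "A")
  expect_equal(r3$n_losses, 0L)
  ## all-absent families rejected
  expect_error(dollo_reconstruct(pm_from(tr, character(0)), tr), "no species")
  ## species mismatch rejected
  bad <- pm_from(tr, "A")
  colnames(bad) <- c("A", "B", "C", "X")
  expect_error(dollo_reconstruct(bad, tr), "match")
})

test_that("loss counts equal exhaustive single-gain search on random trees", {
  set.seed(19)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    tr <- random_tree(n)
    k <- sample(1:n, 1)
    present <- sample(tr$tip.label, k)
    rec <- dollo_reconstruct(pm_from(tr, present), tr)
    want <- oracle_dollo_losses(tr, match(present, tr$tip.label))
    expect_equal(rec$n_losses, want)
    ## events bounded by leaf count
    expect_lte(1L + rec$n_losses, n)
  }
})

test_that("reconstruction never under-deepens the true gain on synthetic data", {
  cfg <- sim_config(seed = 17, n_species = 12, n_families = 80, loss_prob = 0.15)
  tr <- simulate_tree(cfg)
  gl <- simulate_gain_loss(tr, cfg)
  rec <- dollo_reconstruct(gl$presence, tr)
  tu <- tips_under(tr)
  for (i in seq_len(nrow(rec))) {
    true_gain <- node_by_label(tr, gl$truth[[rec$family_id[i]]]$gain_node)
    est_gain <- node_by_label(tr, rec$gain_node[i])
    ## estimated gain clade contains the true gain node's surviving leaves
    expect_true(all(tu[[est_gain]] %in% tu[[true_gain]]))
  }
  ## and with no losses the gain node is recovered exactly
  cfg0 <- sim_config(seed = 17, n_species = 12, n_families = 80, loss_prob = 0)
  gl0 <- simulate_gain_loss(tr, cfg0)
  rec0 <- dollo_reconstruct(gl0$presence, tr)
  truth0 <- vapply(gl0$truth[rec0$family_id], `[[`, "", "gain_node")
  expect_equal(rec0$gain_node, unname(truth0))
})

test_that("node statistics accumulate gains along root paths", {
  cfg <- sim_config(seed = 23, n_species = 10, n_families = 60)
  ds <- simulate_dataset(cfg)
  rec <- dollo_reconstruct(ds$presence, ds$tree)
  part <- data.frame(locus_id = ds$mirna$locus_id, family_id = ds$mirna$family_id)
  ctx <- data.frame(locus_id = names(ds$truth$genome$context),
                    context = unname(ds$truth$genome$context))
  cl <- data.frame(locus_id = names(ds$truth$genome$cluster),
                   cluster_id = unname(ds$truth$genome$cluster))
  st <- node_statistics(rec, ds$tree, context = ctx, clusters = cl,
                        partition = part)
  expect_equal(st$age[st$node == ape::Ntip(ds$tree) + 1], 0)
  expect_true(all(st$n_gains >= 0))
  expect_equal(sum(st$n_gains), nrow(rec))
  ## per-node gains equal the planted truth (loss_prob default small, but
  ## dollo can only deepen; compare against reconstruction itself)
  expect_equal(st$n_gains[match(rec$gain_node, st$label)] >= 1, rep(TRUE, nrow(rec)))
  ## cumulative gains at each leaf = sum of gains along its root path
  pars <- ds$tree$edge[, 1]
  for (leaf in sample(seq_len(ape::Ntip(ds$tree)), 3)) {
    path <- leaf
    v <- leaf
    while (v != ape::Ntip(ds$tree) + 1) {
      v <- pars[match(v, ds$tree$edge[, 2])]
      path <- c(path, v)
    }
    expect_equal(st$cum_gains[leaf], sum(st$n_gains[path]))
  }
  ## intronic percentages are percentages
  expect_true(all(is.na(st$pct_intronic) |
                    (st$pct_intronic >= 0 & st$pct_intronic <= 100)))
})

test_that("per-node gain counts match the planted history without losses", {
  cfg <- sim_config(seed = 29, n_species = 10, n_families = 70, loss_prob = 0)
  tr <- simulate_tree(cfg)
  gl <- simulate_gain_loss(tr, cfg)
  rec <- dollo_reconstruct(gl$presence, tr)
  st <- node_statistics(rec, tr)
  truth_gains <- table(vapply(gl$truth, `[[`, "", "gain_node"))
  for (lab in names(truth_gains)) {
    expect_equal(st$n_gains[st$label == lab], unname(truth_gains[lab]),
                 ignore_attr = TRUE)
  }
})

test_that("tree figure annotations are consistent and written to TSV", {
  cfg <- sim_config(seed = 31, n_species = 8, n_families = 40)
  ds <- simulate_dataset(cfg)
  rec <- dollo_reconstruct(ds$presence, ds$tree)
  st <- node_statistics(rec, ds$tree)
  svg <- withr::local_tempfile(fileext = ".svg")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  edges <- annotate_tree_figure(ds$presence, st, ds$tree, svg_file = svg,
                                tsv_file = tsv)
  expect_true(file.exists(svg))
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(ds$tree$edge))
  expect_equal(back$n_families_under, edges$n_families_under)
  ## widths scale with family counts
  expect_equal(rank(edges$width), rank(edges$n_families_under))
  ## uniform gains give uniform widths
  tr <- read_species_tree("((A:1,B:1):1,(C:1,D:1):1);")
  m <- profile_matrix(matrix(1L, 2, 4, dimnames = list(c("f1", "f2"),
                                                       tr$tip.label)),
                      "presence")
  rec2 <- dollo_reconstruct(m, tr)
  st2 <- node_statistics(rec2, tr)
  e2 <- annotate_tree_figure(m, st2, tr)
  expect_length(unique(e2$width), 1)
})
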