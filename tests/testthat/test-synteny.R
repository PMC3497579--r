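test_that("anchor building orders and deduplicates records", {
  mir <- mirna_loci(c("m1", "m2"), "sp1", "chr1", c(5000, 30000),
                    c(5069, 30069), "+",
                    rep(paste(rep("ACGUACG", 10), collapse = ""), 2), 5, 26,
                    family_id = c("FM1", "FM2"))
  prot <- protein_loci(c("p1", "p2", "p3"), "sp1", "chr1",
                       c(1000, 10000, 40000), c(2000, 11000, 41000), "+",
                       c("PF1", "PF2", "PF3"),
                       list(cbind(1000, 2000), cbind(10000, 11000),
                            cbind(40000, 41000)))
  a <- build_anchors(mir, prot)
  expect_equal(a$family_id, c("PF1", "FM1", "PF2", "FM2", "PF3"))
  ## duplicate record removed
  prot2 <- rbind(prot, prot[1, ])
  prot2$locus_id[4] <- "p1b"
  expect_equal(nrow(build_anchors(mir, prot2)), 5)
  ## unlabelled locus rejected
  mir2 <- mir; mir2$family_id[1] <- NA
  expect_error(build_anchors(mir2, prot), "unlabelled")
})

test_that("identical, inserted and reversed runs are detected", {
  ## identical 5-anchor order in 2 genomes -> one block, 5 anchors
  g <- list(gA = c("f1", "f2", "f3", "f4", "f5"),
            gB = c("f1", "f2", "f3", "f4", "f5"))
  b <- detect_blocks(toy_anchors(g))
  expect_length(b, 1)
  expect_equal(b[[1]]$families, c("f1", "f2", "f3", "f4", "f5"))
  expect_equal(nrow(b[[1]]$occurrences), 2)
  expect_equal(b[[1]]$occurrences$orientation, c("+", "+"))
  ## one inserted foreign anchor within the gap tolerance
  g2 <- list(gA = c("f1", "f2", "f3", "f4"),
             gB = c("f1", "f2", "x9", "f3", "f4"))
  b2 <- detect_blocks(toy_anchors(g2))
  expect_length(b2, 1)
  expect_equal(b2[[1]]$families, c("f1", "f2", "f3", "f4"))
  ## fully reversed run in the second genome
  g3 <- list(gA = c("f1", "f2", "f3"), gB = c("f3", "f2", "f1"))
  b3 <- detect_blocks(toy_anchors(g3))
  expect_length(b3, 1)
  expect_setequal(b3[[1]]$occurrences$orientation, c("+", "-"))
  ## insertion beyond the physical gap tolerance splits the run
  wide <- toy_anchors(g2, spacing = 6000L)
  b4 <- detect_blocks(wide)
  expect_true(all(vapply(b4, function(b) length(b$families), 0L) < 4))
})

test_that("detector matches brute-force chain enumeration on toy genomes", {
  set.seed(77)
  fams <- paste0("f", 1:6)
  for (i in 1:30) {
    nA <- sample(3:8, 1); nB <- sample(3:8, 1)
    gl <- list(gA = sample(fams, nA, replace = TRUE),
               gB = sample(fams, nB, replace = TRUE))
    if (i %% 3 == 0) gl$gB <- rev(gl$gB)   # exercise reversals
    anch <- toy_anchors(gl)
    got <- detect_blocks(anch, max_mismatch_anchors = 2)
    gs <- mirevol:::genome_sequences(anch)
    want <- oracle_pair_runs(gs[["gA:chr1"]], gs[["gB:chr1"]],
                             max_gap = 10000L, mm = 2L, min_anchors = 2L)
    got_keys <- sort(vapply(got, function(b) canon_run(b$families), ""))
    want_keys <- sort(unique(vapply(want, function(r) canon_run(r$families), "")))
    expect_equal(got_keys, want_keys)
  }
})

test_that("block detection is invariant under genome input order", {
  set.seed(101)
  g <- list(gA = c("f1", "f2", "f3", "f4", "x1"),
            gB = c("x2", "f1", "f2", "f3", "f4"),
            gC = c("f4", "f3", "f2", "f1"))
  a1 <- toy_anchors(g)
  a2 <- toy_anchors(g[c(3, 1, 2)])
  b1 <- detect_blocks(a1); b2 <- detect_blocks(a2)
  key <- function(bs) sort(vapply(bs, function(b) {
    paste(canon_run(b$families),
          paste(sort(paste(b$occurrences$species, b$occurrences$start)),
                collapse = ";"))
  }, ""))
  expect_equal(key(b1), key(b2))
})

test_that("planted blocks are recovered from rearrangement-free genomes", {
  cfg <- sim_config(seed = 71, n_species = 6, n_families = 15, loss_prob = 0,
                    gain_root_weight = 1e9, dup_rate = 0)
  ds <- simulate_dataset(cfg)
  anchors <- build_anchors(ds$mirna, ds$proteins)
  ## gap tolerance must cover the simulated intergenic spacing (25 kb)
  blocks <- detect_blocks(anchors, max_gap_length = 60000L)
  ## all species share the full planted anchor order -> a single block whose
  ## family run equals the planted run, in all 6 genomes
  planted <- ds$truth$genome$anchor_orders[[1]]
  planted <- planted[c(TRUE, planted[-1] != planted[-length(planted)])]
  expect_length(blocks, 1)
  expect_equal(canon_run(blocks[[1]]$families), canon_run(planted))
  expect_equal(nrow(blocks[[1]]$occurrences), 6)
})

test_that("chaining merges adjacent blocks sharing a terminal anchor", {
  ## construct genomes whose shared runs split into two chainable blocks
  g <- list(gA = c("f1", "f2", "f3", "f4"), gB = c("f1", "f2", "f3", "f4"))
  anch <- toy_anchors(g)
  blocks <- detect_blocks(anch)
  ## manually split the block into [f1,f2,f3] and [f3,f4]
  b1 <- blocks[[1]]
  x <- b1; y <- b1
  x$families <- c("f1", "f2", "f3"); x$kinds <- rep("protein", 3)
  y$families <- c("f3", "f4"); y$kinds <- rep("protein", 2)
  for (i in 1:2) {
    x$anchor_starts[[i]] <- b1$anchor_starts[[i]][1:3]
    x$occurrences$end[i] <- x$anchor_starts[[i]][3] + 199L
    y$anchor_starts[[i]] <- b1$anchor_starts[[i]][3:4]
    y$occurrences$start[i] <- y$anchor_starts[[i]][1]
  }
  chained <- chain_blocks(list(x, y))
  expect_length(chained, 1)
  expect_equal(chained[[1]]$families, c("f1", "f2", "f3", "f4"))
  ## idempotence
  again <- chain_blocks(chained)
  expect_equal(again[[1]]$families, chained[[1]]$families)
  expect_length(again, 1)
  ## shared terminal family but different anchor instance: not merged
  y2 <- y
  y2$anchor_starts <- lapply(y2$anchor_starts, function(s) s + 100000L)
  y2$occurrences$start <- y2$occurrences$start + 100000L
  y2$occurrences$end <- y2$occurrences$end + 100000L
  expect_length(chain_blocks(list(x, y2)), 2)
})

test_that("classification and normalised lengths behave", {
  g <- list(gA = c("p1", "p2", "m1", "m2", "p3"),
            gB = c("p1", "p2", "m1", "m2", "p3"))
  anch <- rbind(toy_anchors(lapply(g, function(x) x[1:2]), kind = "protein"),
                toy_anchors(lapply(g, function(x) x[3:4]), kind = "mirna"))
  ## rebuild with coherent coordinates: proteins then mirnas then protein
  anch <- toy_anchors(g)
  anch$kind <- ifelse(grepl("^m", anch$family_id), "mirna", "protein")
  blocks <- detect_blocks(anch)
  expect_equal(blocks[[1]]$class, "mixed")
  sizes <- c(gA = 2e6, gB = 4e6)
  cm <- classify_and_measure(blocks, sizes)
  expect_true(all(cm$measures$norm_length > 0 & cm$measures$norm_length <= 1))
  expect_equal(cm$measures$length[cm$measures$species == "gA"],
               cm$measures$length[cm$measures$species == "gB"])
  expect_equal(cm$measures$norm_length[cm$measures$species == "gA"],
               2 * cm$measures$norm_length[cm$measures$species == "gB"])
  expect_error(classify_and_measure(blocks, c(gA = 0, gB = 1e6)), "zero")
  ## single-kind classes
  m_only <- toy_anchors(list(gA = c("m1", "m2"), gB = c("m1", "m2")),
                        kind = "mirna")
  expect_equal(detect_blocks(m_only)[[1]]$class, "mirna_only")
})

test_that("normalisation aligns compact and expanded genomes", {
  ## same block structure, spacer scaled 3x: unnormalised lengths differ,
  ## normalised lengths coincide when genome size scales the same way
  g <- list(fish = c("f1", "f2", "f3", "f4"))
  compact <- toy_anchors(g, spacing = 800L)
  mammal <- toy_anchors(list(mammal = c("f1", "f2", "f3", "f4")), spacing = 2400L)
  ## place each pair in its own two-genome comparison against a twin
  mk2 <- function(base, nm, spacing) {
    twin <- base; twin$species <- nm
    rbind(base, twin)
  }
  b_fish <- detect_blocks(mk2(compact, "fish2", 800L), max_gap_length = 20000L)
  b_mam <- detect_blocks(mk2(mammal, "mammal2", 2400L), max_gap_length = 20000L)
  len_f <- b_fish[[1]]$occurrences$end[1] - b_fish[[1]]$occurrences$start[1] + 1
  len_m <- b_mam[[1]]$occurrences$end[1] - b_mam[[1]]$occurrences$start[1] + 1
  expect_gt(len_m, len_f)
  gsz_f <- 10 * (800 + 200); gsz_m <- 10 * (2400 + 200)
  cm_f <- classify_and_measure(b_fish, c(fish = gsz_f, fish2 = gsz_f))
  cm_m <- classify_and_measure(b_mam, c(mammal = gsz_m, mammal2 = gsz_m))
  expect_equal(cm_f$measures$norm_length[1], cm_m$measures$norm_length[1],
               tolerance = 0.08)
})

test_that("display alignment handles identical runs, insertions and reversal", {
  g <- list(gA = c("f1", "f2", "f3", "f4"),
            gB = c("f1", "f2", "x9", "f3", "f4"))
  anch <- toy_anchors(g)
  blocks <- detect_blocks(anch)
  al <- align_blocks_for_display(blocks[[1]], anch)
  expect_equal(nrow(al), 2)
  ## the inserted anchor creates exactly one gap column in gA
  expect_equal(sum(is.na(al)), 1)
  expect_equal(ncol(al), 5)
  gB_row <- grep("^gB", rownames(al))
  na_col <- which(is.na(al[-gB_row, ]))
  expect_equal(unname(al[gB_row, na_col]), "x9")
  ## identical occurrences align without gaps
  g2 <- list(gA = c("f1", "f2"), gB = c("f1", "f2"))
  anch2 <- toy_anchors(g2)
  al2 <- align_blocks_for_display(detect_blocks(anch2)[[1]], anch2)
  expect_false(any(is.na(al2)))
  ## deterministic rendering
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_block_svg(al, anch, f1)
  render_block_svg(al, anch, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## single occurrence is an error
  b1 <- blocks[[1]]
  b1$occurrences <- b1$occurrences[1, , drop = FALSE]
  expect_error(align_blocks_for_display(b1, anch), "single")
})
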