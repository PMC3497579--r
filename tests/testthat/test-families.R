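seq_of <- function(s) encode_bases_test(s)
encode_bases_test <- function(s) {
  match(strsplit(s, "")[[1]], c("A", "C", "G", "U", "N"))
}
marked <- function(s, seed_pos = integer(0)) {
  list(bases = seq_of(s), seed = seq_along(seq_of(s)) %in% seed_pos)
}

test_that("seed marking places positions 2-8 of each mature arm", {
  loci <- mirna_loci("m1", "sp", "chr1", 1, 70,
                     "+", paste(rep("ACGUACG", 10), collapse = ""), 5, 26)
  mk <- mark_seed(loci)
  expect_equal(which(mk$m1$seed), 6:12)
  ## two arms give two disjoint 7-position runs
  loci2 <- mirna_loci("m2", "sp", "chr1", 1, 70, "+",
                      paste(rep("ACGUACG", 10), collapse = ""), 5, 26,
                      mature2_start = 40, mature2_end = 61)
  mk2 <- mark_seed(loci2)
  expect_equal(which(mk2$m2$seed), c(6:12, 41:47))
})

test_that("alignment scores hand-computable cases", {
  sc <- scoring_scheme()
  ## perfect 4-mer, no seeds: 4 x 5
  expect_equal(align_score(marked("ACGU"), marked("ACGU"), sc), 20)
  ## positions 2-4 seed on both: 4x5 + 3x10
  a <- marked("ACGUACG", 2:4)
  expect_equal(align_score(a, a, sc), 50)
  ## seed on one side only scores as a plain match under "both" mode
  b <- marked("ACGUACG")
  expect_equal(align_score(a, b, sc), 35)
  ## and doubles under "either" mode
  sc_e <- scoring_scheme(seed_mode = "either")
  expect_equal(align_score(a, b, sc_e), 50)
  ## N never matches
  expect_equal(align_score(marked("NN"), marked("NN"), sc), -8)
  ## symmetry
  x <- marked("ACGGUA", 3:5); y <- marked("AGGUCA", 2:4)
  expect_equal(align_score(x, y, sc), align_score(y, x, sc))
  expect_error(align_score(marked(""), marked("A"), sc))
})

test_that("alignment equals exhaustive enumeration on random short pairs", {
  set.seed(42)
  sc <- scoring_scheme()
  for (i in 1:60) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    a <- sample(1:5, n, replace = TRUE, prob = c(rep(0.23, 4), 0.08))
    b <- sample(1:5, m, replace = TRUE, prob = c(rep(0.23, 4), 0.08))
    as <- runif(n) < 0.4; bs <- runif(m) < 0.4
    got <- align_score(list(bases = a, seed = as), list(bases = b, seed = bs), sc)
    want <- oracle_align(a, b, as, bs, sc)
    expect_equal(got, want)
  }
})

test_that("self-alignment dominates and seed weighting is monotone", {
  set.seed(7)
  sc <- scoring_scheme()
  for (i in 1:20) {
    a <- marked(paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE),
                      collapse = ""), 3:9)
    b <- marked(paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE),
                      collapse = ""), 3:9)
    expect_gte(align_score(a, a, sc), align_score(a, b, sc))
    ## raising the multiplier cannot lower a self score (seeds match)
    sc3 <- scoring_scheme(seed_mult = 3)
    expect_gte(align_score(a, a, sc3), align_score(a, a, sc))
  }
})

test_that("single linkage equals naive agglomeration and is monotone", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    s <- matrix(runif(n * n, 0, 100), n)
    s <- (s + t(s)) / 2
    diag(s) <- 100
    dimnames(s) <- list(paste0("L", 1:n), paste0("L", 1:n))
    t1 <- runif(1, 0, 100)
    p1 <- single_linkage(s, t1)
    want <- oracle_single_linkage(s, t1)
    expect_equal(split_join(p1, want), 0)
    ## refinement: higher threshold partitions refine lower ones
    t2 <- t1 + runif(1, 0, 50)
    p2 <- as_membership_test(single_linkage(s, t2))
    p1m <- as_membership_test(p1)
    for (fam in unique(p2)) {
      members <- names(p2)[p2 == fam]
      expect_length(unique(p1m[members]), 1)
    }
  }
  ## extremes
  s <- matrix(c(100, 10, 10, 100), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_length(unique(single_linkage(s, 1000)$family_id), 2)
  expect_length(unique(single_linkage(s, 0)$family_id), 1)
  s[1, 2] <- NA
  expect_error(single_linkage(s, 5), "missing")
})

test_that("split-join matches the worked value and the direct formula", {
  a <- setNames(c("x", "x", "y", "y"), as.character(1:4))
  b <- setNames(rep("z", 4), as.character(1:4))
  expect_equal(split_join(a, a), 0)
  expect_equal(split_join(a, b), 2)   # (4-4) + (4-2)
  set.seed(13)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    pa <- random_partition(n, 4)
    pb <- setNames(random_partition(n, 4), names(pa))
    expect_equal(split_join(pa, pb), oracle_split_join(pa, pb))
    expect_equal(split_join(pa, pb), split_join(pb, pa))
  }
  expect_error(split_join(a, b[1:3]), "different elements")
})

test_that("threshold optimisation recovers a reference partition", {
  set.seed(5)
  ## three tight groups with high within, low between scores
  ids <- paste0("L", 1:9)
  s <- matrix(runif(81, 0, 20), 9, dimnames = list(ids, ids))
  s <- (s + t(s)) / 2
  grp <- rep(1:3, each = 3)
  for (i in 1:9) for (j in 1:9) {
    if (grp[i] == grp[j] && i <= j) s[i, j] <- s[j, i] <- runif(1, 80, 100)
  }
  ref <- setNames(paste0("g", grp), ids)
  opt <- optimize_threshold(s, ref)
  expect_equal(opt$distance, 0)
  expect_true(opt$threshold %in% as.vector(s))
  ## reference equal to a concrete single-linkage cut -> distance 0
  cut <- single_linkage(s, 50)
  opt2 <- optimize_threshold(s, cut)
  expect_equal(opt2$distance, 0)
})
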