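## miRNA family attribution.
##
## Precursors are compared by global (Needleman-Wunsch) alignment under a
## scoring scheme that doubles the weight of matches inside the seed region
## (mature positions 2-8, marked via an expanded per-position code), and
## families are the connected components of the score graph at a threshold,
## i.e. single-linkage clusters. The threshold is picked by minimising the
## van Dongen split-join distance to a reference partition.

#' Alignment scoring scheme
#'
#' @param match score of an identical-base match (> 0).
#' @param mismatch score of a mismatch (< 0); `N` never matches and always
#'   scores as a mismatch.
#' @param gap_open score charged once per gap, on top of the per-residue
#'   extension (so a gap of length L scores `gap_open + L * gap_extend`).
#' @param gap_extend per-residue gap score.
#' @param seed_mult multiplier applied to `match` for seed-region matches.
#' @param seed_mode `"both"` (default): the multiplier applies only when
#'   both aligned positions are seed-marked; `"either"`: when at least one
#'   is.
#' @return a list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = -10,
                           gap_extend = -2, seed_mult = 2,
                           seed_mode = c("both", "either")) {
  seed_mode <- match.arg(seed_mode)
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    stop("need gap_open <= gap_extend <= 0")
  }
  if (seed_mult < 1) stop("seed_mult must be >= 1")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, seed_mult = seed_mult,
                 seed_mode = seed_mode),
            class = "scoring_scheme")
}

encode_bases <- function(seq) {
  x <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U", "N"))
  if (anyNA(x)) stop("sequence outside ACGUN alphabet")
  as.integer(x)
}

#' Mark seed positions of precursor loci
#'
#' For each annotated mature arm, precursor offsets (arm start + 1) through
#' (arm start + 7) — mature positions 2-8 — are seed-marked; marks of two
#' arms are unioned. The result is the "expanded alphabet" each precursor
#' is aligned under: a base plus a seed/non-seed flag per position.
#'
#' @param loci a validated miRNA locus table
#' @return a named list (by locus id) of objects with integer-encoded
#'   `bases` and a logical `seed` mask.
#' @export
mark_seed <- function(loci) {
  out <- lapply(seq_len(nrow(loci)), function(i) {
    len <- nchar(loci$sequence[i])
    mask <- rep(FALSE, len)
    for (arm in c("mature1", "mature2")) {
      s <- loci[[paste0(arm, "_start")]][i]
      e <- loci[[paste0(arm, "_end")]][i]
      if (is.na(s)) next
      if (e - s + 1L < 8L) stop("locus ", loci$locus_id[i], ": ", arm,
                                " arm shorter than 8 nt")
      mask[(s + 1L):(s + 7L)] <- TRUE
    }
    list(bases = encode_bases(loci$sequence[i]), seed = mask)
  })
  names(out) <- loci$locus_id
  out
}

#' Seed-weighted global alignment score of two marked sequences
#'
#' Optimal global-global alignment score under affine gaps. A match of
#' identical bases scores `match * seed_mult` when the scheme's seed
#' condition holds for the aligned pair, otherwise `match`; mismatches
#' score `mismatch` regardless of seed marks. Symmetric in its arguments.
#'
#' @param a,b elements of a [mark_seed()] list
#' @param scheme a [scoring_scheme()]
#' @return numeric alignment score
#' @export
align_score <- function(a, b, scheme = scoring_scheme()) {
  nw_score_cpp(a$bases, b$bases, a$seed, b$seed,
               scheme$match, scheme$mismatch, scheme$gap_open,
               scheme$gap_extend, scheme$seed_mult,
               scheme$seed_mode == "both")
}

#' All-vs-all seed-weighted alignment score matrix
#'
#' @param marked a [mark_seed()] list
#' @param scheme a [scoring_scheme()]
#' @param max_loci guard against accidental quadratic blow-ups
#' @return symmetric numeric matrix with locus-id dimnames
#' @export
score_matrix <- function(marked, scheme = scoring_scheme(), max_loci = 5000L) {
  if (length(marked) > max_loci) {
    stop(length(marked), " loci exceed max_loci = ", max_loci,
         "; raise the guard explicitly if intended")
  }
  m <- nw_score_matrix_cpp(lapply(marked, `[[`, "bases"),
                           lapply(marked, `[[`, "seed"),
                           scheme$match, scheme$mismatch, scheme$gap_open,
                           scheme$gap_extend, scheme$seed_mult,
                           scheme$seed_mode == "both")
  dimnames(m) <- list(names(marked), names(marked))
  m
}

#' Single-linkage families at a score threshold
#'
#' Families are the connected components of the graph with an edge between
#' two loci whenever their alignment score is >= the threshold. Family ids
#' are deterministic: `F_` plus the lexicographically smallest member id.
#'
#' @param scores symmetric score matrix with locus-id dimnames
#' @param threshold numeric score threshold
#' @return a `family_partition`: data.frame (locus_id, family_id) with the
#'   threshold stored as an attribute
#' @export
single_linkage <- function(scores, threshold) {
  if (is.null(rownames(scores)) || !isTRUE(all.equal(rownames(scores), colnames(scores)))) {
    stop("scores must be a symmetric matrix with matching dimnames")
  }
  if (anyNA(scores)) stop("missing pair entries in score matrix")
  adj <- scores >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ids <- rownames(scores)
  fam <- vapply(split(ids, comp), min, "")
  partition <- data.frame(locus_id = ids,
                          family_id = paste0("F_", fam[as.character(comp)]),
                          stringsAsFactors = FALSE, row.names = NULL)
  partition <- partition[order(partition$locus_id), ]
  rownames(partition) <- NULL
  structure(partition, threshold = threshold, class = c("family_partition", "data.frame"))
}

as_membership <- function(p) {
  if (is.data.frame(p)) setNames(as.character(p$family_id), p$locus_id)
  else if (!is.null(names(p))) setNames(as.character(p), names(p))
  else stop("cannot interpret partition")
}

#' Van Dongen split-join distance between two partitions
#'
#' `d(A,B) = (n - sum_C max_D |C  intersect  D|) + (n - sum_D max_C |D intersect C|)`
#' over clusters C of A and D of B on the same n elements. Zero iff the
#' partitions are identical; symmetric; satisfies the triangle inequality.
#'
#' @param a,b partitions (family_partition data.frames or named membership
#'   vectors) over the same element universe
#' @return non-negative integer distance
#' @export
split_join <- function(a, b) {
  ma <- as_membership(a); mb <- as_membership(b)
  if (!setequal(names(ma), names(mb))) stop("partitions cover different elements")
  mb <- mb[names(ma)]
  tab <- table(ma, mb)
  n <- length(ma)
  (n - sum(apply(tab, 1, max))) + (n - sum(apply(tab, 2, max)))
}

#' Pick the clustering threshold by split-join distance to a reference
#'
#' Evaluates [single_linkage()] on a grid of candidate thresholds (default:
#' every distinct observed score) and returns the threshold minimising the
#' split-join distance to the reference partition; ties break toward the
#' largest threshold, i.e. the most granular partition.
#'
#' @param scores symmetric score matrix
#' @param reference reference partition over the same loci
#' @param thresholds candidate grid (default all distinct scores)
#' @return list: threshold, partition, distance, and the full grid profile
#' @export
optimize_threshold <- function(scores, reference, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- sort(unique(as.vector(scores)))
  if (length(thresholds) == 0) stop("empty threshold grid")
  prof <- lapply(thresholds, function(t) {
    p <- single_linkage(scores, t)
    list(threshold = t, partition = p, distance = split_join(p, reference))
  })
  d <- vapply(prof, `[[`, 0, "distance")
  best <- max(which(d == min(d)))   # ties -> largest threshold
  list(threshold = thresholds[best], partition = prof[[best]]$partition,
       distance = d[best],
       profile = data.frame(threshold = thresholds, distance = d))
}

#' Read / write a family partition TSV (locus_id TAB family_id)
#' @param file TSV path
#' @return a `family_partition` data.frame
#' @export
read_family_partition <- function(file) {
  df <- read.delim(gzfile(file), stringsAsFactors = FALSE)
  if (!all(c("locus_id", "family_id") %in% names(df))) {
    stop("partition file needs locus_id and family_id columns")
  }
  structure(df[order(df$locus_id), c("locus_id", "family_id")],
            class = c("family_partition", "data.frame"))
}

#' @rdname read_family_partition
#' @param partition a `family_partition`
#' @export
write_family_partition <- function(partition, file) {
  write.table(partition[, c("locus_id", "family_id")], file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Full family-attribution step: mark, align, cluster
#'
#' @param loci miRNA locus table
#' @param scheme a [scoring_scheme()]
#' @param threshold fixed score threshold, or NULL to optimise against
#'   `reference`
#' @param reference reference partition (required when `threshold` is NULL)
#' @param max_loci guard passed to [score_matrix()]
#' @return list: partition, threshold, scores, distance (NA for fixed
#'   threshold)
#' @export
cluster_families <- function(loci, scheme = scoring_scheme(), threshold = NULL,
                             reference = NULL, max_loci = 5000L) {
  marked <- mark_seed(loci)
  scores <- score_matrix(marked, scheme, max_loci = max_loci)
  if (is.null(threshold)) {
    if (is.null(reference)) stop("need a reference partition or a fixed threshold")
    opt <- optimize_threshold(scores, reference)
    list(partition = opt$partition, threshold = opt$threshold,
         scores = scores, distance = opt$distance)
  } else {
    list(partition = single_linkage(scores, threshold), threshold = threshold,
         scores = scores, distance = NA_real_)
  }
}
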