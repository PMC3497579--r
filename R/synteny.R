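## Conserved collinear (synteny) block detection from family-labelled
## anchors.
##
## This is a deliberately simple collinear-run detector, not a
## reimplementation of a full synteny graph algorithm: per genome pair it
## repeatedly extracts the longest chain of shared anchor families that is
## collinear (same order, or fully reversed in the second genome), allowing
## up to `max_mismatch_anchors` intervening non-shared anchors and physical
## gaps up to `max_gap_length` bp between consecutive shared anchors; runs
## with identical family sequences are then merged across genome pairs into
## multi-genome blocks. Tie-breaking is fully deterministic (maximum length,
## forward orientation first, then lexicographically smallest match-pair
## sequence), which makes the detector reproducible and directly comparable
## to a brute-force chain enumeration.

#' Build anchor sequences from miRNA and protein loci
#'
#' Combines both locus sets into per-genome (species x chromosome) ordered
#' anchor lists, each anchor identified by its family. Exact duplicate
#' records (same family, species, chromosome and span) are dropped.
#'
#' @param mirna miRNA locus table (family-assigned, or via `partition`)
#' @param proteins protein locus table
#' @param partition optional `family_partition` supplying miRNA family ids
#' @return data.frame of anchors sorted by species, chromosome, start:
#'   species, chrom, start, end, strand, family_id, locus_id, kind
#' @export
build_anchors <- function(mirna, proteins, partition = NULL) {
  fam <- mirna$family_id
  if (!is.null(partition)) fam <- as_membership(partition)[mirna$locus_id]
  if (anyNA(fam)) stop("unlabelled miRNA locus: ",
                       mirna$locus_id[which(is.na(fam))[1]])
  a <- rbind(
    data.frame(species = mirna$species, chrom = mirna$chrom,
               start = mirna$start, end = mirna$end, strand = mirna$strand,
               family_id = fam, locus_id = mirna$locus_id, kind = "mirna",
               stringsAsFactors = FALSE),
    data.frame(species = proteins$species, chrom = proteins$chrom,
               start = proteins$start, end = proteins$end,
               strand = proteins$strand, family_id = proteins$family_id,
               locus_id = proteins$locus_id, kind = "protein",
               stringsAsFactors = FALSE))
  dup <- duplicated(a[, c("species", "chrom", "start", "end", "family_id")])
  a <- a[!dup, ]
  a <- a[order(a$species, a$chrom, a$start, a$end, a$family_id), ]
  rownames(a) <- NULL
  a
}

## split anchors into per-genome lists with tandem same-family runs collapsed
genome_sequences <- function(anchors) {
  key <- paste(anchors$species, anchors$chrom, sep = ":")
  lapply(split(anchors, key), function(g) {
    keep <- c(TRUE, g$family_id[-1] != g$family_id[-nrow(g)])
    g <- g[keep, , drop = FALSE]
    rownames(g) <- NULL
    g
  })
}

## longest collinear chain between two genome data.frames, honouring the
## availability masks; returns NULL or list(pairs = 2-col matrix, orient)
longest_chain <- function(gA, gB, availA, availB, max_gap, mm) {
  fA <- gA$family_id; fB <- gB$family_id
  cand <- NULL
  for (orient in c(1L, -1L)) {
    pairs <- which(outer(fA, fB, "==") &
                     outer(availA, availB, "&"), arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    np <- nrow(pairs)
    compat <- function(p, q) {   # can q follow p in the chain?
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
    ## L[p] = longest chain starting at pair p (forward DP over sorted pairs)
    L <- rep(1L, np)
    for (p in rev(seq_len(np))) {
      for (q in seq_len(np)) {
        if (q != p && compat(p, q) && L[q] + 1L > L[p]) L[p] <- L[q] + 1L
      }
    }
    best_len <- max(L)
    start <- which(L == best_len)[1]   # pairs sorted: first = smallest (i,j)
    chain <- start
    cur <- start
    while (L[cur] > 1L) {
      nxt <- which(vapply(seq_len(np), function(q) {
        q != cur && compat(cur, q) && L[q] == L[cur] - 1L
      }, TRUE))[1]
      chain <- c(chain, nxt)
      cur <- nxt
    }
    res <- list(pairs = pairs[chain, , drop = FALSE], orient = orient,
                len = best_len)
    if (is.null(cand) || res$len > cand$len) cand <- res
  }
  cand
}

#' Detect conserved collinear blocks across genomes
#'
#' @param anchors anchor table from [build_anchors()]
#' @param max_gap_length maximum physical gap (bp) between consecutive
#'   shared anchors, in either genome
#' @param min_regions minimum number of genome occurrences per block
#' @param min_anchors minimum number of shared anchor families per block
#' @param max_mismatch_anchors maximum intervening non-shared anchors
#'   between consecutive shared anchors
#' @return list of `synteny_block` objects: id, families (canonical run),
#'   kinds, class, occurrences (data.frame: species, chrom, start, end,
#'   orientation, n_anchors) with per-occurrence anchor start coordinates
#'   in `anchor_starts`
#' @export
detect_blocks <- function(anchors, max_gap_length = 10000L, min_regions = 2L,
                          min_anchors = 2L, max_mismatch_anchors = 10L) {
  gs <- genome_sequences(anchors)
  keys <- sort(names(gs))
  if (length(keys) < 2) return(list())
  runs <- list()
  for (a in seq_along(keys)) {
    for (b in seq_along(keys)) {
      if (b <= a) next
      gA <- gs[[keys[a]]]; gB <- gs[[keys[b]]]
      availA <- rep(TRUE, nrow(gA)); availB <- rep(TRUE, nrow(gB))
      repeat {
        ch <- longest_chain(gA, gB, availA, availB,
                            max_gap_length, max_mismatch_anchors)
        if (is.null(ch) || ch$len < min_anchors) break
        ia <- ch$pairs[, 1]; ib <- ch$pairs[, 2]
        runs[[length(runs) + 1L]] <- list(
          families = gA$family_id[ia],
          occA = list(key = keys[a], g = gA[ia, , drop = FALSE], orient = 1L),
          occB = list(key = keys[b], g = gB[ib, , drop = FALSE],
                      orient = ch$orient))
        availA[ia] <- FALSE; availB[ib] <- FALSE
      }
    }
  }
  kind_of <- tapply(anchors$kind, anchors$family_id, function(k) k[1])
  merge_runs(runs, kind_of, min_regions)
}

## canonicalise runs (forward vs reversed family sequence) and merge
## occurrences with identical canonical runs into blocks
merge_runs <- function(runs, kind_of, min_regions) {
  if (length(runs) == 0) return(list())
  occs <- list()
  for (r in runs) {
    fam <- r$families
    rev_key <- paste(rev(fam), collapse = "|")
    fwd_key <- paste(fam, collapse = "|")
    canon_fwd <- fwd_key <= rev_key
    canon <- if (canon_fwd) fam else rev(fam)
    key <- min(fwd_key, rev_key)
    for (side in c("occA", "occB")) {
      o <- r[[side]]
      ## orientation of this occurrence relative to the canonical run
      rel <- o$orient * (if (canon_fwd) 1L else -1L)
      occs[[length(occs) + 1L]] <- list(key = key, families = canon,
                                        genome = o$key, g = o$g, orient = rel)
    }
  }
  by_key <- split(occs, vapply(occs, `[[`, "", "key"))
  blocks <- list()
  for (key in sort(names(by_key))) {
    os <- by_key[[key]]
    fam <- os[[1]]$families
    df <- do.call(rbind, lapply(os, function(o) {
      data.frame(species = o$g$species[1], chrom = o$g$chrom[1],
                 start = min(o$g$start), end = max(o$g$end),
                 orientation = if (o$orient == 1L) "+" else "-",
                 n_anchors = nrow(o$g), stringsAsFactors = FALSE)
    }))
    starts <- lapply(os, function(o) sort(o$g$start))  # genomic order
    dup <- duplicated(df[, c("species", "chrom", "start", "end")])
    df <- df[!dup, , drop = FALSE]
    starts <- starts[!dup]
    if (nrow(df) < min_regions) next
    ord <- order(df$species, df$chrom, df$start)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    kinds <- unname(kind_of[fam])
    blocks[[length(blocks) + 1L]] <- structure(
      list(families = fam, kinds = kinds,
           class = block_class(kinds),
           occurrences = df, anchor_starts = starts[ord]),
      class = "synteny_block")
  }
  for (i in seq_along(blocks)) blocks[[i]]$id <- sprintf("SB%04d", i)
  blocks
}

block_class <- function(kinds) {
  if (all(kinds == "protein")) "protein_only"
  else if (all(kinds == "mirna")) "mirna_only"
  else "mixed"
}

#' Chain blocks sharing a terminal anchor
#'
#' Two blocks are chained when the last anchor family of one equals the
#' first of the other (in compatible orientation) and the shared terminal
#' anchor is the same anchor instance (identical start coordinate) in every
#' genome where both blocks occur. The operation is idempotent: after one
#' pass no shared terminal anchor instances remain.
#'
#' @param blocks list of `synteny_block`s from [detect_blocks()]
#' @return chained block list (ids reassigned)
#' @export
chain_blocks <- function(blocks) {
  flip <- function(b) {
    b$families <- rev(b$families); b$kinds <- rev(b$kinds)
    b$occurrences$orientation <- ifelse(b$occurrences$orientation == "+", "-", "+")
    b
  }
  terminal_start <- function(b, i, which) {
    s <- b$anchor_starts[[i]]
    fwd <- b$occurrences$orientation[i] == "+"
    if ((which == "last") == fwd) s[length(s)] else s[1]
  }
  try_merge <- function(x, y) {
    ## x's last anchor == y's first anchor, same instance everywhere shared
    if (x$families[length(x$families)] != y$families[1]) return(NULL)
    gx <- paste(x$occurrences$species, x$occurrences$chrom)
    gy <- paste(y$occurrences$species, y$occurrences$chrom)
    shared <- intersect(gx, gy)
    if (length(shared) == 0) return(NULL)
    for (g in shared) {
      ix <- which(gx == g); iy <- which(gy == g)
      ok <- any(outer(ix, iy, Vectorize(function(i, j) {
        terminal_start(x, i, "last") == terminal_start(y, j, "first")
      })))
      if (!ok) return(NULL)
    }
    merged <- x
    merged$families <- c(x$families, y$families[-1])
    merged$kinds <- c(x$kinds, y$kinds[-1])
    merged$class <- block_class(merged$kinds)
    for (g in shared) {
      ix <- which(gx == g)[1]; iy <- which(gy == g)[1]
      merged$occurrences$start[ix] <- min(x$occurrences$start[ix], y$occurrences$start[iy])
      merged$occurrences$end[ix] <- max(x$occurrences$end[ix], y$occurrences$end[iy])
      merged$occurrences$n_anchors[ix] <-
        x$occurrences$n_anchors[ix] + y$occurrences$n_anchors[iy] - 1L
      merged$anchor_starts[[ix]] <- sort(unique(c(x$anchor_starts[[ix]],
                                                  y$anchor_starts[[iy]])))
    }
    extra <- which(!(gy %in% shared))
    if (length(extra) > 0) {
      merged$occurrences <- rbind(merged$occurrences,
                                  y$occurrences[extra, , drop = FALSE])
      merged$anchor_starts <- c(merged$anchor_starts, y$anchor_starts[extra])
    }
    merged
  }
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(blocks)) {
      for (j in seq_along(blocks)) {
        if (i == j) next
        for (fy in list(identity, flip)) {
          m <- try_merge(blocks[[i]], fy(blocks[[j]]))
          if (!is.null(m)) {
            blocks[[i]] <- m
            blocks <- blocks[-j]
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
      if (changed) break
    }
  }
  for (i in seq_along(blocks)) blocks[[i]]$id <- sprintf("SB%04d", i)
  blocks
}

#' Per-class block length distributions, normalised by genome size
#'
#' @param blocks block list
#' @param genome_sizes named numeric vector of total genome length per
#'   species (all > 0)
#' @return list: `measures` (one row per occurrence: block, class,
#'   species, length, norm_length) and `cumulative` (per species-class
#'   cumulative length distribution tables, both raw and normalised)
#' @export
classify_and_measure <- function(blocks, genome_sizes) {
  if (any(genome_sizes <= 0)) stop("zero genome size")
  rows <- lapply(blocks, function(b) {
    data.frame(block_id = b$id, class = b$class,
               species = b$occurrences$species, chrom = b$occurrences$chrom,
               length = b$occurrences$end - b$occurrences$start + 1L,
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) {
    return(list(measures = data.frame(), cumulative = list()))
  }
  missing <- setdiff(unique(m$species), names(genome_sizes))
  if (length(missing) > 0) stop("no genome size for: ", paste(missing, collapse = ", "))
  m$norm_length <- m$length / genome_sizes[m$species]
  cum <- lapply(split(m, paste(m$species, m$class, sep = ":")), function(d) {
    d <- d[order(d$length), ]
    data.frame(length = d$length, norm_length = d$norm_length,
               cum_fraction = seq_len(nrow(d)) / nrow(d))
  })
  list(measures = m, cumulative = cum)
}

## global alignment of two symbol vectors; returns 2-row index matrix with
## NA for gaps; deterministic traceback preference diag > up > left
nw_symbols <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + if (a[i] == b[j]) match else mismatch
      S[i + 1, j + 1] <- max(d, S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  ai <- integer(0); bi <- integer(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      ai <- c(i, ai); bi <- c(j, bi); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ai <- c(i, ai); bi <- c(NA, bi); i <- i - 1
    } else {
      ai <- c(NA, ai); bi <- c(j, bi); j <- j - 1
    }
  }
  rbind(ai, bi)
}

#' Align a block's occurrences by anchor family for display
#'
#' Extracts the full anchor sequence inside each occurrence span (including
#' anchors not shared by the block), orients reversed occurrences, and
#' aligns every occurrence to the anchor-richest one by symbol-level
#' Needleman-Wunsch (match +1, mismatch -1, gap -1). Genomes are sorted
#' alphabetically by species.
#'
#' @param block a `synteny_block`
#' @param anchors the anchor table the block was detected from
#' @return character matrix (occurrences x alignment columns) of family
#'   ids with NA for gaps; rownames `species:chrom:start-end`
#' @export
align_blocks_for_display <- function(block, anchors) {
  occ <- block$occurrences
  if (nrow(occ) < 2) stop("block has a single occurrence; nothing to align")
  seqs <- lapply(seq_len(nrow(occ)), function(i) {
    g <- anchors[anchors$species == occ$species[i] &
                   anchors$chrom == occ$chrom[i] &
                   anchors$start >= occ$start[i] &
                   anchors$end <= occ$end[i], , drop = FALSE]
    g <- g[order(g$start), ]
    fam <- g$family_id
    keep <- c(TRUE, fam[-1] != fam[-length(fam)])
    fam <- fam[keep]
    if (occ$orientation[i] == "-") fam <- rev(fam)
    fam
  })
  names(seqs) <- sprintf("%s:%s:%d-%d", occ$species, occ$chrom, occ$start, occ$end)
  ord <- order(occ$species, occ$chrom, occ$start)
  seqs <- seqs[ord]
  ref <- which.max(vapply(seqs, length, 0L))
  nref <- length(seqs[[ref]])
  ## columns: one per reference anchor, plus per-occurrence insertion slots
  aligned <- lapply(seqs, function(s) {
    if (identical(s, seqs[[ref]])) {
      list(ref_sym = s, ins = vector("list", nref + 1L))
    } else {
      al <- nw_symbols(seqs[[ref]], s)
      ref_sym <- rep(NA_character_, nref)
      ins <- lapply(seq_len(nref + 1L), function(i) character(0))
      last_ref <- 0L
      for (c_ in seq_len(ncol(al))) {
        ri <- al[1, c_]; si <- al[2, c_]
        if (!is.na(ri)) {
          last_ref <- ri
          if (!is.na(si)) ref_sym[ri] <- s[si]
        } else if (!is.na(si)) {
          ins[[last_ref + 1L]] <- c(ins[[last_ref + 1L]], s[si])
        }
      }
      list(ref_sym = ref_sym, ins = ins)
    }
  })
  n_ins <- vapply(seq_len(nref + 1L), function(i) {
    max(vapply(aligned, function(a) length(a$ins[[i]]), 0L))
  }, 0L)
  ncol_total <- nref + sum(n_ins)
  out <- matrix(NA_character_, length(seqs), ncol_total,
                dimnames = list(names(seqs), NULL))
  for (r in seq_along(aligned)) {
    col <- 1L
    for (i in seq_len(nref + 1L)) {
      ins <- aligned[[r]]$ins[[i]]
      if (length(ins) > 0) out[r, col + seq_along(ins) - 1L] <- ins
      col <- col + n_ins[i]
      if (i <= nref) {
        out[r, col] <- aligned[[r]]$ref_sym[i]
        col <- col + 1L
      }
    }
  }
  out
}

#' Render an aligned block to SVG
#'
#' Cells are coloured by family (stable hash of the family id), protein
#' anchors carry a "P", intronic miRNA anchors an "I"; rows are the
#' occurrences sorted alphabetically with their genomic coordinates.
#'
#' @param alignment matrix from [align_blocks_for_display()]
#' @param anchors anchor table (for anchor kinds)
#' @param file output SVG path
#' @param context optional context annotation (locus-level, via family
#'   majority) marking intronic families
#' @return `file`, invisibly
#' @export
render_block_svg <- function(alignment, anchors, file, context = NULL) {
  kind_of <- tapply(anchors$kind, anchors$family_id, function(k) k[1])
  intronic <- character(0)
  if (!is.null(context)) {
    fam <- anchors$family_id[match(context$locus_id, anchors$locus_id)]
    tab <- tapply(context$context == "intronic", fam, mean)
    intronic <- names(tab)[!is.na(tab) & tab > 0.5]
  }
  fam_col <- function(f) {
    h <- sum(utf8ToInt(f) * seq_along(utf8ToInt(f))) %% 360
    grDevices::hsv(h / 360, 0.55, 0.9)
  }
  cw <- 46; chh <- 22
  w <- 240 + ncol(alignment) * cw
  h <- 20 + nrow(alignment) * (chh + 8)
  lines <- sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', w, h)
  for (r in seq_len(nrow(alignment))) {
    y <- 10 + (r - 1) * (chh + 8)
    lines <- c(lines, sprintf(
      '<text x="4" y="%d" font-size="9">%s</text>', y + 14, rownames(alignment)[r]))
    for (c_ in seq_len(ncol(alignment))) {
      f <- alignment[r, c_]
      if (is.na(f)) next
      mark <- if (!is.na(kind_of[f]) && kind_of[f] == "protein") "P"
      else if (f %in% intronic) "I" else ""
      x <- 236 + (c_ - 1) * cw
      lines <- c(lines, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="#333"/>',
        x, y, cw - 2, chh, fam_col(f)))
      if (nzchar(mark)) {
        lines <- c(lines, sprintf(
          '<text x="%d" y="%d" font-size="11" text-anchor="middle">%s</text>',
          x + (cw - 2) %/% 2, y + 15, mark))
      }
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, file)
  invisible(file)
}

#' Block list to a flat table (one row per occurrence)
#' @param blocks block list
#' @return data.frame: block_id, class, families (|-joined), species,
#'   chrom, start, end, orientation, n_anchors
#' @export
blocks_to_df <- function(blocks) {
  rows <- lapply(blocks, function(b) {
    cbind(data.frame(block_id = b$id, class = b$class,
                     families = paste(b$families, collapse = "|"),
                     stringsAsFactors = FALSE),
          b$occurrences)
  })
  if (length(rows) == 0) {
    return(data.frame(block_id = character(0), class = character(0),
                      families = character(0), species = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      n_anchors = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
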