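## Genomic-context profiles: presence/copy-number matrices, intronic vs
## intergenic annotation, cluster assignment, and the per-family copy-number
## glyph used to eyeball expansions across species.

#' Build presence and copy-number matrices from loci and a partition
#'
#' @param loci miRNA locus table (all loci family-assigned via `partition`)
#' @param partition a `family_partition` covering the loci
#' @param tree species tree; columns are its leaf set (species with no loci
#'   get zero columns), and any locus species outside the tree is an error
#' @return list: `presence` and `counts` profile matrices
#' @export
build_matrices <- function(loci, partition, tree) {
  tree <- validate_species_tree(tree)
  mem <- as_membership(partition)
  if (!all(loci$locus_id %in% names(mem))) stop("partition does not cover all loci")
  fam <- mem[loci$locus_id]
  if (!all(loci$species %in% tree$tip.label)) {
    stop("species not in tree: ",
         paste(setdiff(unique(loci$species), tree$tip.label), collapse = ", "))
  }
  tab <- table(factor(fam, levels = sort(unique(fam))),
               factor(loci$species, levels = sort(tree$tip.label)))
  counts <- profile_matrix(unclass(as.matrix(tab)), "count")
  list(presence = as_presence(counts), counts = counts)
}

#' Annotate intronic vs intergenic context
#'
#' A miRNA locus is intronic iff it is fully contained in a protein locus
#' span and overlaps none of that locus's exons; anything else (outside all
#' genes, straddling a gene boundary, or touching an exon by even 1 bp) is
#' intergenic. When nested host genes both qualify, the shortest wins.
#'
#' @param mirna miRNA locus table
#' @param proteins protein locus table (same species/chromosome space)
#' @param same_strand require the host gene to be on the miRNA's strand
#' @return data.frame: locus_id, context, host_id
#' @export
annotate_context <- function(mirna, proteins, same_strand = FALSE) {
  context <- rep("intergenic", nrow(mirna))
  host <- rep(NA_character_, nrow(mirna))
  for (i in seq_len(nrow(mirna))) {
    cand <- which(proteins$species == mirna$species[i] &
                    proteins$chrom == mirna$chrom[i] &
                    proteins$start <= mirna$start[i] &
                    proteins$end >= mirna$end[i])
    if (same_strand) cand <- cand[proteins$strand[cand] == mirna$strand[i]]
    ok <- cand[vapply(cand, function(j) {
      ex <- proteins$exons[[j]]
      nrow(ex) == 0 ||
        !any(ex[, 1] <= mirna$end[i] & ex[, 2] >= mirna$start[i])
    }, TRUE)]
    if (length(ok) > 0) {
      widths <- proteins$end[ok] - proteins$start[ok]
      context[i] <- "intronic"
      host[i] <- proteins$locus_id[ok[which.min(widths)]]
    }
  }
  data.frame(locus_id = mirna$locus_id, context = context, host_id = host,
             stringsAsFactors = FALSE)
}

#' Assign genomic clusters of miRNA loci
#'
#' Single-linkage chaining along each species-chromosome: consecutive loci
#' whose gap (next start - previous end - 1) is at most the threshold share
#' a cluster. Strand is ignored; input order is internalised by sorting.
#' Size-1 chains are solo loci and get an NA cluster id.
#'
#' @param mirna miRNA locus table
#' @param threshold maximum gap in bp (default 10 kb)
#' @return data.frame: locus_id, cluster_id (NA = solo), cluster_size
#' @export
assign_clusters <- function(mirna, threshold = 10000L) {
  ord <- order(mirna$species, mirna$chrom, mirna$start, mirna$end, mirna$locus_id)
  df <- mirna[ord, ]
  cluster <- rep(NA_character_, nrow(df))
  idx <- 1L
  run_start <- 1L
  flush <- function(run_start, run_end, idx) {
    if (run_end > run_start) {
      cluster[run_start:run_end] <<- sprintf(
        "CL_%s_%s_%04d", df$species[run_start], df$chrom[run_start], idx)
      idx + 1L
    } else idx
  }
  i <- 1L
  while (i < nrow(df)) {
    same <- df$species[i + 1] == df$species[i] && df$chrom[i + 1] == df$chrom[i]
    gap <- df$start[i + 1] - max(df$end[run_start:i]) - 1L
    if (!same || gap > threshold) {
      idx <- flush(run_start, i, idx)
      run_start <- i + 1L
    }
    i <- i + 1L
  }
  if (nrow(df) > 0) idx <- flush(run_start, nrow(df), idx)
  sizes <- table(cluster)
  out <- data.frame(locus_id = df$locus_id, cluster_id = cluster,
                    cluster_size = ifelse(is.na(cluster), 1L,
                                          as.integer(sizes[cluster])),
                    stringsAsFactors = FALSE)
  out[match(mirna$locus_id, out$locus_id), , drop = FALSE]
}

#' Copy-number glyph bins
#'
#' Maps copy numbers to glyph colours: 0 is white (absent), 1-9 a rainbow
#' gradient red through violet, and 10 or more black.
#'
#' @param counts integer vector or matrix of copy numbers
#' @return character colours of the same shape
#' @export
glyph_colors <- function(counts) {
  pal <- grDevices::rainbow(9, end = 0.8)   # red (1) through violet (9)
  col <- ifelse(counts == 0, "#FFFFFF",
                ifelse(counts >= 10, "#000000", pal[pmin(pmax(counts, 1), 9)]))
  if (is.matrix(counts)) dim(col) <- dim(counts)
  col
}

#' Glyph legend table (copy-number bin to colour)
#' @return data.frame: copies, colour
#' @export
glyph_legend <- function() {
  data.frame(copies = c("0", as.character(1:9), ">=10"),
             colour = glyph_colors(c(0:9, 10)), stringsAsFactors = FALSE)
}

#' Render a family-by-species copy-number glyph grid to SVG
#'
#' One square per (family, species) cell, coloured per [glyph_colors()].
#' Output is deterministic for a fixed input.
#'
#' @param counts count-mode profile matrix
#' @param file output SVG path
#' @param families optional subset of families (rows)
#' @param species optional species display order (default: matrix order)
#' @param cell cell size in px
#' @return `file`, invisibly
#' @export
render_family_glyph <- function(counts, file, families = NULL, species = NULL,
                                cell = 12) {
  m <- unclass(counts)
  if (!is.null(families)) m <- m[families, , drop = FALSE]
  if (!is.null(species)) m <- m[, species, drop = FALSE]
  col <- glyph_colors(m)
  w <- (ncol(m) + 14) * cell
  h <- (nrow(m) + 2) * cell
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', w, h))
  for (i in seq_len(nrow(m))) {
    lines <- c(lines, sprintf(
      '<text x="%d" y="%.1f" font-size="%.1f">%s</text>',
      2L, (i + 0.8) * cell, cell * 0.7, rownames(m)[i]))
    for (j in seq_len(ncol(m))) {
      lines <- c(lines, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="#888888"/>',
        (j + 11) * cell, i * cell, cell, cell, col[i, j]))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, file)
  invisible(file)
}
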