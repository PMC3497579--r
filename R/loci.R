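## miRNA and protein locus tables.
##
## Coordinates are 1-based inclusive throughout (GFF3 convention); BED input
## is shifted on read. Mature-arm offsets are positions within the precursor
## in 5'->3' orientation regardless of genomic strand, matching miRBase
## annotation practice.

#' Construct and validate a miRNA locus table
#'
#' @param locus_id,species,chrom,start,end,strand vectors describing each
#'   precursor locus; coordinates 1-based inclusive, strand "+" or "-".
#' @param sequence precursor sequence (RNA alphabet ACGU, N allowed; T is
#'   converted to U). Length must equal `end - start + 1`.
#' @param mature1_start,mature1_end first mature arm, 1-based offsets within
#'   the precursor; arm length must be at least 8 so seed positions 2-8 exist.
#' @param mature2_start,mature2_end optional second arm (NA when absent).
#' @param family_id,context,cluster_id,host_id optional annotation columns
#'   filled by later pipeline stages.
#' @return a `data.frame` with one row per locus.
#' @export
mirna_loci <- function(locus_id, species, chrom, start, end, strand,
                       sequence, mature1_start, mature1_end,
                       mature2_start = NA_integer_, mature2_end = NA_integer_,
                       family_id = NA_character_, context = NA_character_,
                       cluster_id = NA_character_, host_id = NA_character_) {
  df <- data.frame(
    locus_id = as.character(locus_id), species = as.character(species),
    chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand),
    sequence = toupper(chartr("Tt", "Uu", as.character(sequence))),
    mature1_start = as.integer(mature1_start), mature1_end = as.integer(mature1_end),
    mature2_start = as.integer(mature2_start), mature2_end = as.integer(mature2_end),
    family_id = as.character(family_id), context = as.character(context),
    cluster_id = as.character(cluster_id), host_id = as.character(host_id),
    stringsAsFactors = FALSE
  )
  validate_mirna_loci(df)
}

#' Validate miRNA locus invariants
#'
#' Checks coordinate sanity, sequence length against the genomic span, the
#' RNA alphabet, and that every annotated mature arm lies inside the
#' precursor with length >= 8.
#'
#' @param df a miRNA locus table
#' @return `df`, or an error naming the first offending locus
#' @export
validate_mirna_loci <- function(df) {
  if (anyDuplicated(df$locus_id)) stop("duplicate locus id")
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0) stop(sprintf("locus %s: %s", df$locus_id[i[1]], msg))
  }
  bad(df$start > df$end, "start > end")
  bad(!df$strand %in% c("+", "-"), "strand must be + or -")
  len <- nchar(df$sequence)
  bad(df$end - df$start + 1L != len, "precursor length != end - start + 1")
  bad(grepl("[^ACGUN]", df$sequence), "sequence outside ACGUN alphabet")
  check_arm <- function(s, e, which) {
    has <- !is.na(s) | !is.na(e)
    bad(has & (is.na(s) | is.na(e)), paste(which, "arm half-annotated"))
    bad(has & !is.na(s) & !is.na(e) & (s < 1 | e > len), paste(which, "arm outside precursor"))
    bad(has & !is.na(s) & !is.na(e) & (e - s + 1L < 8L), paste(which, "arm shorter than 8 nt"))
  }
  check_arm(df$mature1_start, df$mature1_end, "mature1")
  check_arm(df$mature2_start, df$mature2_end, "mature2")
  bad(is.na(df$mature1_start), "no mature arm annotated")
  df
}

#' Construct and validate a protein locus table
#'
#' Exon intervals are carried in a list column `exons` of two-column
#' matrices (start, end), 1-based inclusive, within the locus span.
#'
#' @param locus_id,species,chrom,start,end,strand,family_id locus fields;
#'   `family_id` is mandatory (loci without family information are not
#'   comparable across species and must be dropped upstream).
#' @param exons list of numeric matrices with columns start, end
#' @return a `data.frame` with one row per locus
#' @export
protein_loci <- function(locus_id, species, chrom, start, end, strand,
                         family_id, exons) {
  df <- data.frame(
    locus_id = as.character(locus_id), species = as.character(species),
    chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), family_id = as.character(family_id),
    stringsAsFactors = FALSE
  )
  df$exons <- exons
  validate_protein_loci(df)
}

#' Validate protein locus invariants
#' @param df a protein locus table
#' @return `df` or an error
#' @export
validate_protein_loci <- function(df) {
  if (anyDuplicated(df$locus_id)) stop("duplicate locus id")
  if (any(is.na(df$family_id) | !nzchar(df$family_id))) {
    stop("protein locus without family id: ",
         df$locus_id[which(is.na(df$family_id) | !nzchar(df$family_id))[1]])
  }
  if (any(df$start > df$end)) stop("start > end")
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0) next
    if (is.unsorted(ex[, 1])) stop("locus ", df$locus_id[i], ": exons not sorted")
    if (any(ex[, 1] > ex[, 2])) stop("locus ", df$locus_id[i], ": exon start > end")
    if (any(ex[, 1] < df$start[i] | ex[, 2] > df$end[i])) {
      stop("locus ", df$locus_id[i], ": exon outside locus span")
    }
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
      stop("locus ", df$locus_id[i], ": overlapping exons")
    }
  }
  df
}

## -- readers ----------------------------------------------------------------

#' Read miRNA loci from GFF3/BED plus a precursor FASTA
#'
#' GFF3 input carries mature-arm offsets and species in attributes
#' (`species`, `mature1_start`, ...); BED input (0-based half-open,
#' converted on read) requires a separate mature-arm table.
#'
#' @param loci_file GFF3 or BED file (plain or gzip)
#' @param fasta_file precursor FASTA; sequence names must match locus ids
#' @param format `"gff3"` or `"bed"`
#' @param mature for BED input, a data.frame or TSV path with columns
#'   locus_id, species, mature1_start, mature1_end (mature2_* optional)
#' @return a validated miRNA locus table
#' @export
read_mirna_loci <- function(loci_file, fasta_file, format = c("gff3", "bed"),
                            mature = NULL) {
  format <- match.arg(format)
  seqs <- Biostrings::readBStringSet(fasta_file)
  seqv <- setNames(as.character(seqs), sub("\\s.*", "", names(seqs)))
  gr <- rtracklayer::import(loci_file, format = format)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  id <- if (format == "bed") mc$name else mc$ID
  if (is.null(id)) stop("locus id column missing")
  missing_seq <- setdiff(id, names(seqv))
  if (length(missing_seq) > 0) {
    stop("missing sequence for locus: ", paste(missing_seq, collapse = ", "))
  }
  if (format == "gff3") {
    getcol <- function(nm) if (nm %in% names(mc)) mc[[nm]] else NA
    df <- mirna_loci(
      locus_id = id, species = getcol("species"),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      sequence = seqv[id],
      mature1_start = as.integer(getcol("mature1_start")),
      mature1_end = as.integer(getcol("mature1_end")),
      mature2_start = suppressWarnings(as.integer(getcol("mature2_start"))),
      mature2_end = suppressWarnings(as.integer(getcol("mature2_end"))),
      family_id = as.character(getcol("family"))
    )
  } else {
    if (is.null(mature)) stop("BED input requires a mature-arm table")
    if (is.character(mature)) mature <- read.delim(mature, stringsAsFactors = FALSE)
    m <- mature[match(id, mature$locus_id), ]
    if (anyNA(m$locus_id)) stop("mature-arm table missing loci")
    df <- mirna_loci(
      locus_id = id, species = m$species,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      sequence = seqv[id],
      mature1_start = m$mature1_start, mature1_end = m$mature1_end,
      mature2_start = if ("mature2_start" %in% names(m)) m$mature2_start else NA,
      mature2_end = if ("mature2_end" %in% names(m)) m$mature2_end else NA
    )
  }
  df
}

#' Read protein loci (with exon structure) from GFF3
#'
#' Expects `gene` records with `ID`, `species` and `family` attributes and
#' `exon` records pointing at their gene via `Parent`.
#'
#' @param gff_file GFF3 path (plain or gzip)
#' @return a validated protein locus table
#' @export
read_protein_loci <- function(gff_file) {
  gr <- rtracklayer::import(gff_file, format = "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr))
  is_gene <- mc$type == "gene"
  genes <- which(is_gene)
  parent <- vapply(mc$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
  exons <- lapply(as.character(mc$ID[genes]), function(gid) {
    ei <- which(!is_gene & !is.na(parent) & parent == gid)
    if (length(ei) == 0) return(matrix(numeric(0), 0, 2))
    m <- cbind(GenomicRanges::start(gr)[ei], GenomicRanges::end(gr)[ei])
    m[order(m[, 1]), , drop = FALSE]
  })
  protein_loci(
    locus_id = as.character(mc$ID[genes]), species = as.character(mc$species[genes]),
    chrom = as.character(GenomicRanges::seqnames(gr))[genes],
    start = GenomicRanges::start(gr)[genes], end = GenomicRanges::end(gr)[genes],
    strand = as.character(GenomicRanges::strand(gr))[genes],
    family_id = as.character(mc$family[genes]),
    exons = exons
  )
}

## -- writers (GFF3 + FASTA), used by the simulator and the pipeline ---------

gff3_escape <- function(x) gsub("([;=,\t])", "%", x)

#' Write miRNA loci to GFF3 (+ optional precursor FASTA)
#' @param df miRNA locus table
#' @param gff_file output GFF3 path
#' @param fasta_file optional FASTA path for precursor sequences
#' @export
write_mirna_loci <- function(df, gff_file, fasta_file = NULL) {
  attr_str <- function(i) {
    a <- c(ID = df$locus_id[i], species = df$species[i],
           mature1_start = df$mature1_start[i], mature1_end = df$mature1_end[i])
    if (!is.na(df$mature2_start[i])) {
      a <- c(a, mature2_start = df$mature2_start[i], mature2_end = df$mature2_end[i])
    }
    if (!is.na(df$family_id[i])) a <- c(a, family = df$family_id[i])
    paste(paste0(names(a), "=", a), collapse = ";")
  }
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(df)), function(i) {
               paste(df$chrom[i], "mirevol", "miRNA", df$start[i], df$end[i], ".",
                     df$strand[i], ".", attr_str(i), sep = "\t")
             }, ""))
  writeLines(lines, gff_file)
  if (!is.null(fasta_file)) {
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(setNames(df$sequence, df$locus_id)), fasta_file)
  }
  invisible(gff_file)
}

#' Write protein loci (genes + exons) to GFF3
#' @param df protein locus table
#' @param gff_file output path
#' @export
write_protein_loci <- function(df, gff_file) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(df))) {
    lines <- c(lines, paste(
      df$chrom[i], "mirevol", "gene", df$start[i], df$end[i], ".",
      df$strand[i], ".",
      sprintf("ID=%s;species=%s;family=%s", df$locus_id[i], df$species[i], df$family_id[i]),
      sep = "\t"))
    ex <- df$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        df$chrom[i], "mirevol", "exon", ex[j, 1], ex[j, 2], ".",
        df$strand[i], ".",
        sprintf("ID=%s.e%d;Parent=%s", df$locus_id[i], j, df$locus_id[i]),
        sep = "\t"))
    }
  }
  writeLines(lines, gff_file)
  invisible(gff_file)
}
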