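## End-to-end pipeline: families -> profiles -> dollo -> expansions ->
## coevolution -> synteny, driven by a single configuration, with a JSON
## run manifest and fixed-seed reproducibility.

#' Pipeline configuration
#'
#' @param tree path to the species tree (Newick)
#' @param mirna_gff3,mirna_fasta miRNA loci + precursor sequences
#' @param proteins_gff3 protein loci with exon structure
#' @param reference optional reference partition TSV (locus_id, family_id)
#'   for threshold optimisation
#' @param outdir output directory
#' @param seed global seed for the stochastic stages
#' @param threshold fixed clustering score threshold (NULL = optimise
#'   against `reference`)
#' @param scheme list of [scoring_scheme()] arguments
#' @param cluster_threshold genomic cluster gap threshold (bp)
#' @param expansion_clade clade label for the expansion scan (NULL = root)
#' @param expansion_n_sim Monte-Carlo replicates per expansion p-value
#' @param coevolution list: min_present, min_absent, restarts, max_pairs
#'   (cap on tested pairs per screen)
#' @param synteny list: max_gap_length, min_regions, min_anchors,
#'   max_mismatch_anchors
#' @return a validated list of class `pipeline_config`
#' @export
pipeline_config <- function(tree, mirna_gff3, mirna_fasta, proteins_gff3,
                            outdir, reference = NULL, seed = 1L,
                            threshold = NULL, scheme = list(),
                            cluster_threshold = 10000L,
                            expansion_clade = NULL, expansion_n_sim = 200L,
                            coevolution = list(), synteny = list()) {
  cfg <- as.list(environment())
  for (p in c("tree", "mirna_gff3", "mirna_fasta", "proteins_gff3")) {
    if (!file.exists(cfg[[p]])) stop("missing input file for '", p, "': ", cfg[[p]])
  }
  if (!is.null(reference) && !file.exists(reference)) {
    stop("missing input file for 'reference': ", reference)
  }
  if (is.null(threshold) && is.null(reference)) {
    stop("either a fixed threshold or a reference partition is required")
  }
  cfg$seed <- as.integer(seed)
  cfg$coevolution <- utils::modifyList(
    list(min_present = 5L, min_absent = 5L, restarts = 2L, max_pairs = 30L),
    coevolution)
  cfg$synteny <- utils::modifyList(
    list(max_gap_length = 10000L, min_regions = 2L, min_anchors = 2L,
         max_mismatch_anchors = 10L), synteny)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param file YAML path with the [pipeline_config()] fields
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages run in order families, profiles, dollo, expansions, coevolution,
#' synteny; every output file is declared in `manifest.json` together with
#' parameters, seed and input checksums. A rerun with the same
#' configuration is byte-identical. A stage failure halts the run with the
#' stage named; outputs of completed stages are kept.
#'
#' @param config a `pipeline_config` (or YAML path)
#' @return list of stage results, invisibly
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  out <- function(name) {
    p <- file.path(config$outdir, name)
    outputs <<- c(outputs, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()
  tree <- stage("input", read_species_tree(config$tree))
  mirna <- stage("input", read_mirna_loci(config$mirna_gff3, config$mirna_fasta))
  proteins <- stage("input", read_protein_loci(config$proteins_gff3))

  res$families <- stage("families", {
    scheme <- do.call(scoring_scheme, config$scheme)
    ref <- if (!is.null(config$reference)) read_family_partition(config$reference)
    cf <- cluster_families(mirna, scheme, threshold = config$threshold,
                           reference = ref)
    write_family_partition(cf$partition, out("families.tsv"))
    jsonlite::write_json(list(threshold = cf$threshold, distance = cf$distance),
                         out("families_threshold.json"), auto_unbox = TRUE,
                         digits = NA)
    cf
  })
  partition <- res$families$partition
  mirna$family_id <- as_membership(partition)[mirna$locus_id]

  res$profiles <- stage("profiles", {
    mats <- build_matrices(mirna, partition, tree)
    ctx <- annotate_context(mirna, proteins)
    cl <- assign_clusters(mirna, threshold = config$cluster_threshold)
    write_profile_matrix(mats$presence, out("presence.tsv"))
    write_profile_matrix(mats$counts, out("counts.tsv"))
    write_tsv(ctx, out("context.tsv"))
    write_tsv(cl, out("clusters.tsv"))
    render_family_glyph(mats$counts, out("glyph.svg"))
    write_tsv(glyph_legend(), out("glyph_legend.tsv"))
    c(mats, list(context = ctx, clusters = cl))
  })

  res$dollo <- stage("dollo", {
    rec <- dollo_reconstruct(res$profiles$presence, tree)
    stats <- node_statistics(rec, tree, context = res$profiles$context,
                             clusters = res$profiles$clusters,
                             partition = partition)
    flat <- rec
    flat$loss_edges <- vapply(rec$loss_edges, paste, "", collapse = ",")
    write_tsv(flat, out("dollo_families.tsv"))
    write_tsv(stats, out("node_statistics.tsv"))
    annotate_tree_figure(res$profiles$presence, stats, tree,
                         svg_file = out("tree.svg"),
                         tsv_file = out("tree_annotation.tsv"))
    list(reconstruction = rec, stats = stats)
  })

  res$expansions <- stage("expansions", {
    er <- expansion_report(res$profiles$counts, tree,
                           clade = config$expansion_clade,
                           n_sim = config$expansion_n_sim, seed = config$seed)
    write_tsv(er$report, out("expansions.tsv"))
    jsonlite::write_json(list(lambda = er$lambda, clade = er$clade),
                         out("expansions_lambda.json"), auto_unbox = TRUE,
                         digits = NA)
    er
  })

  res$coevolution <- stage("coevolution", {
    cc <- config$coevolution
    prot_pres <- protein_presence(proteins, tree)
    sc <- screen_pairs(res$profiles$presence, prot_pres, tree,
                       min_present = cc$min_present, min_absent = cc$min_absent,
                       restarts = cc$restarts, seed = config$seed,
                       max_pairs = cc$max_pairs)
    write_tsv(sc, out("coevolution.tsv"))
    sc
  })

  res$synteny <- stage("synteny", {
    sy <- config$synteny
    anchors <- build_anchors(mirna, proteins)
    blocks <- detect_blocks(anchors, max_gap_length = sy$max_gap_length,
                            min_regions = sy$min_regions,
                            min_anchors = sy$min_anchors,
                            max_mismatch_anchors = sy$max_mismatch_anchors)
    blocks <- chain_blocks(blocks)
    write_tsv(blocks_to_df(blocks), out("synteny_blocks.tsv"))
    sp <- sort(unique(c(mirna$species, proteins$species)))
    gsz <- tapply(mirna$end, mirna$species, max)[sp]
    psz <- tapply(proteins$end, proteins$species, max)[sp]
    genome_sizes <- setNames(pmax(gsz, psz, na.rm = TRUE), sp)
    cm <- classify_and_measure(blocks, genome_sizes)
    write_tsv(cm$measures, out("synteny_lengths.tsv"))
    if (length(blocks) > 0 && nrow(blocks[[1]]$occurrences) >= 2) {
      al <- align_blocks_for_display(blocks[[1]], anchors)
      render_block_svg(al, anchors, out("block1.svg"),
                       context = res$profiles$context)
    }
    list(blocks = blocks, measures = cm)
  })

  manifest <- list(
    package = "mirevol",
    version = as.character(utils::packageVersion("mirevol")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("scheme", "coevolution", "synteny"))],
    scheme = config$scheme, coevolution = config$coevolution,
    synteny = config$synteny,
    inputs = as.list(tools::md5sum(c(config$tree, config$mirna_gff3,
                                     config$mirna_fasta, config$proteins_gff3))),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)), basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Presence matrix of protein families across species
#' @param proteins protein locus table
#' @param tree species tree (columns = leaf set)
#' @return presence-mode profile matrix
#' @export
protein_presence <- function(proteins, tree) {
  tree <- validate_species_tree(tree)
  tab <- table(factor(proteins$family_id),
               factor(proteins$species, levels = sort(tree$tip.label)))
  as_presence(profile_matrix(unclass(as.matrix(tab)), "count"))
}
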