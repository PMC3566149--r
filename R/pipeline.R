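#' Published per-Argonaute PAR-CLIP read counts
#'
#' The input/mapped read counts of the four Ago1-4 HEK293 PAR-CLIP
#' libraries used as the pipeline's reference funnel: 32-nt reads, per-library
#' totals summing to 19,301,715 input reads and 619,208 mapped hits.
#'
#' @return Data.frame with columns `ago_source`, `read_length`,
#'   `total_reads`, `mapped_reads`.
#' @export
parclip_read_counts <- function() {
  data.frame(
    ago_source = c("Ago1", "Ago2", "Ago3", "Ago4"),
    read_length = 32L,
    total_reads = c(4155911L, 4588647L, 4122692L, 6434465L),
    mapped_reads = c(104075L, 197799L, 146122L, 171212L),
    stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects every input path and threshold for an end-to-end run. A YAML
#' file with the same keys can be loaded with [read_pipeline_config()];
#' explicit arguments override file values.
#'
#' @param reads Named list (Ago label -> BED6 path) of mapped-read files.
#' @param gtf Transcript annotation (GTF).
#' @param genome Genome FASTA.
#' @param mirnas Mature miRNA FASTA.
#' @param validated Optional TSV of validated miRNA-mRNA pairs
#'   (columns `mirna_id`, `transcript_id`), or `NULL`.
#' @param out_dir Output directory.
#' @param min_depth Cluster-calling depth threshold.
#' @param score_min,energy_max,site_flank Target-prediction thresholds (see
#'   [scoring_params()]).
#' @param n_bins Positional-profile bin count.
#' @param same_strand Stranded annotation overlap.
#' @param ignore_strand Unstranded cluster calling.
#' @param assume_plus_strand Map unstranded BED records to '+'.
#' @param seed Seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reads, gtf, genome, mirnas, validated = NULL,
                            out_dir = "mrenet_run", min_depth = 5L,
                            score_min = 160, energy_max = -20,
                            site_flank = 15L, n_bins = 10L,
                            same_strand = TRUE, ignore_strand = FALSE,
                            assume_plus_strand = FALSE, seed = 1L) {
  cfg <- list(reads = reads, gtf = gtf, genome = genome, mirnas = mirnas,
              validated = validated, out_dir = out_dir,
              min_depth = as.integer(min_depth), score_min = score_min,
              energy_max = energy_max, site_flank = as.integer(site_flank),
              n_bins = as.integer(n_bins), same_strand = same_strand,
              ignore_strand = ignore_strand,
              assume_plus_strand = assume_plus_strand,
              seed = as.integer(seed))
  assert_that(cfg$min_depth >= 1L, "min_depth must be >= 1")
  assert_that(cfg$n_bins >= 1L, "n_bins must be >= 1")
  for (p in c(unlist(cfg$reads), cfg$gtf, cfg$genome, cfg$mirnas,
              cfg$validated)) {
    assert_that(file.exists(p), sprintf("input file not found: %s", p))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full reconstruction pipeline
#'
#' Executes merge -> cluster calling -> exon annotation -> site extraction
#' and cognate-miRNA prediction -> positional binning -> network assembly,
#' writing `clusters.bed`, a cluster support matrix, `annotations.tsv`,
#' `hits.tsv`, `bins.tsv`, `network.tsv` (plus SIF/GraphML exports),
#' `ago_summary.tsv` and a machine-readable `manifest.json` with the
#' stage-by-stage record funnel, under `config$out_dir`.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with every intermediate object plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  read_sets <- stage("read_bed", lapply(
    stats::setNames(names(config$reads), names(config$reads)),
    function(s) read_bed(config$reads[[s]], s,
                         assume_plus_strand = config$assume_plus_strand)))
  reads <- stage("merge_sources", merge_sources(read_sets))
  transcripts <- stage("read_gtf", read_gtf(config$gtf))
  genome <- stage("read_genome", read_fasta(config$genome, "dna"))
  mirnas <- stage("read_mirnas", read_fasta(config$mirnas, "rna"))
  validated <- if (is.null(config$validated)) {
    data.frame(mirna_id = character(), transcript_id = character())
  } else {
    stage("read_validated",
          utils::read.table(config$validated, sep = "\t", header = TRUE,
                            colClasses = "character"))
  }

  sources <- names(config$reads)
  elements <- stage("call_clusters",
                    call_clusters(reads, min_depth = config$min_depth,
                                  ignore_strand = config$ignore_strand,
                                  sources = sources))
  annotations <- stage("assign_clusters",
                       assign_clusters(elements, transcripts,
                                       same_strand = config$same_strand))
  params <- scoring_params(score_min = config$score_min,
                           energy_max = config$energy_max,
                           site_flank = config$site_flank)
  tx_seqs <- stage("transcript_sequences",
                   transcript_sequences(genome, transcripts))
  sites <- stage("extract_sites",
                 extract_sites(annotations, tx_seqs, params$site_flank))
  hits <- stage("predict_targets", predict_targets(mirnas, sites, params))
  lnc_ann <- annotations[annotations$biotype_class == "lncRNA", , drop = FALSE]
  profile <- stage("bin_elements",
                   bin_elements(lnc_ann, transcripts, config$n_bins))
  net <- stage("build_network",
               build_network(hits[hits$biotype_class == "lncRNA", ],
                             hits[hits$biotype_class == "mRNA", ],
                             validated))
  ago <- stage("summarize_ago_contributions",
               summarize_ago_contributions(elements, annotations, hits,
                                           sources))

  ## exports
  el_bed <- elements
  el_bed$name <- elements$cluster_id
  el_bed$score <- elements$max_depth
  write_bed(el_bed, file.path(out, "clusters.bed"))
  utils::write.table(
    elements[, c("cluster_id", paste0("support_", sources))],
    file.path(out, "cluster_support.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(annotations, file.path(out, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    hits[, setdiff(names(hits), c("mirna_aln", "pair_line", "target_aln"))],
    file.path(out, "hits.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_profile(profile, file.path(out, "bins.tsv"))
  write_network(net, file.path(out, "network.tsv"), "tsv")
  write_network(net, file.path(out, "network.sif"), "sif")
  write_network(net, file.path(out, "network.graphml"), "graphml")
  smry <- ago$summary
  smry$mirnas <- vapply(smry$mirnas, paste, "", collapse = ",")
  utils::write.table(smry, file.path(out, "ago_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cnt <- count_overlaps(annotations)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mrenet")),
    parameters = config[c("min_depth", "score_min", "energy_max",
                          "site_flank", "n_bins", "same_strand",
                          "ignore_strand", "seed")],
    input_md5 = vapply(c(unlist(config$reads), gtf = config$gtf,
                         genome = config$genome, mirnas = config$mirnas),
                       tools::md5sum, ""),
    counts = list(
      reads = nrow(reads),
      clusters = nrow(elements),
      annotated_clusters = length(unique(annotations$cluster_id)),
      lncrna_exons = cnt$n_exons[cnt$biotype_class == "lncRNA"],
      mrna_exons = cnt$n_exons[cnt$biotype_class == "mRNA"],
      hits = nrow(hits),
      edges = nrow(net$edges),
      mirna_nodes = sum(net$nodes$type == "miRNA"),
      lncrna_nodes = sum(net$nodes$type == "lncRNA"),
      mrna_nodes = sum(net$nodes$type == "mRNA")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(reads = reads, elements = elements,
                 annotations = annotations, sites = sites, hits = hits,
                 profile = profile, network = net, ago = ago,
                 manifest = manifest))
}
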