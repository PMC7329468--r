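#' Run the detection pipeline end to end with a reproducibility manifest
#'
#' Orchestrates simulate (optional) -> align -> contamination filter ->
#' merge -> summarise, writing every intermediate as a file plus a JSON
#' manifest holding the configuration snapshot, input checksums, the seed,
#' per-stage record counts and the package version. Re-running with the
#' same config and seed reproduces identical outputs.
#'
#' Config keys (a YAML file path or a nested list):
#' \describe{
#'   \item{nuclear_fasta / organelle_fasta}{paths to real inputs, with
#'     `species`, `assembly_level`, `kind`, `circular`, optional `gff`;}
#'   \item{simulate}{alternatively, parameters for [simulate_organelle()],
#'     [simulate_nuclear()], [insertion_config()] and
#'     `n_contaminants`;}
#'   \item{hits_tsv}{optional pre-computed 12-column hit table, bypassing
#'     the internal aligner;}
#'   \item{scheme / policy / merge_gap}{threshold overrides.}
#' }
#'
#' @param config Config list or YAML path.
#' @param out_dir Output directory (created).
#' @param seed Integer seed for all stochastic stages.
#' @return Invisibly, a list with the `norg_scan` result, the truth table
#'   (when simulated) and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("nuclear_fasta", "organelle_fasta", "species", "assembly_level",
             "kind", "circular", "gff", "simulate", "hits_tsv", "scheme",
             "policy", "merge_gap", "align")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0)
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  scheme <- do.call(scoring_scheme, config$scheme %||% list())
  policy <- do.call(contamination_policy, config$policy %||% list())
  options <- do.call(align_options, config$align %||% list())
  truth <- NULL
  counts <- list()
  checksums <- list()

  if (!is.null(config$nuclear_fasta)) {
    nuc_records <- read_fasta(config$nuclear_fasta)
    assembly <- genome_assembly(nuc_records, config$species %||% "unknown",
                                config$assembly_level %||% "scaffold")
    org_records <- read_fasta(config$organelle_fasta)
    feats <- if (!is.null(config$gff))
      read_gff_features(config$gff, target_id = org_records$id[1],
                        target_length = org_records$length[1]) else NULL
    organelle <- organelle_genome(org_records$id[1], org_records$residues[1],
                                  kind = config$kind %||% "mitochondrion",
                                  circular = config$circular %||% TRUE,
                                  features = feats)
    checksums$nuclear_fasta <- unname(tools::md5sum(config$nuclear_fasta))
    checksums$organelle_fasta <- unname(tools::md5sum(config$organelle_fasta))
  } else {
    sim <- config$simulate %||% list()
    organelle <- do.call(simulate_organelle,
                         c(sim$organelle %||% list(), list(seed = seed)))
    bg <- do.call(simulate_nuclear,
                  c(sim$nuclear %||% list(), list(seed = seed + 1L)))
    icfg <- do.call(insertion_config, sim$insertions %||% list())
    planted <- plant_insertions(bg, organelle, icfg, seed = seed + 2L,
                                species = config$species %||% "synthetic")
    assembly <- planted$assembly
    truth <- planted$truth
    ncontam <- sim$n_contaminants %||% 0
    if (ncontam > 0) {
      crange <- sim$contaminant_length_range %||%
        c(min(2000, floor(organelle$length / 4)),
          min(8000, floor(organelle$length / 2)))
      contam <- make_contaminant_contigs(organelle, ncontam, crange,
                                         seed = seed + 3L)
      assembly <- genome_assembly(bind_rows(assembly$records, contam),
                                  assembly$species, assembly$assembly_level)
    }
    write_fasta(assembly$records, file.path(out_dir, "nuclear.fa"))
    write_fasta(tibble(id = organelle$id, residues = organelle$residues),
                file.path(out_dir, "organelle.fa"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  }
  counts$nuclear_sequences <- nrow(assembly$records)
  counts$nuclear_bp <- assembly$total_length

  hits <- NULL
  if (!is.null(config$hits_tsv)) {
    hits <- read_tabular_hits(config$hits_tsv)
    checksums$hits_tsv <- unname(tools::md5sum(config$hits_tsv))
  }
  scan <- norg_detect(assembly, organelle, scheme = scheme, hits = hits,
                      policy = policy, merge_gap = config$merge_gap %||% 0L,
                      options = options)
  counts$hits_retained <- nrow(scan$hits)
  counts$contaminant_contigs_flagged <- nrow(scan$contamination)
  counts$segments <- nrow(scan$segments)
  counts$total_segment_bp <- sum(scan$segments$length)

  write_tabular_hits(scan$hits, file.path(out_dir, "hits.tsv"))
  write_segments(scan$segments, file.path(out_dir, "segments.bed"), "BED")
  write_segments(scan$segments, file.path(out_dir, "segments.tsv"), "TSV")
  readr::write_tsv(scan$summary, file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(scan$contamination, file.path(out_dir, "contamination.tsv"),
                   progress = FALSE)
  readr::write_tsv(scan$identity_histogram,
                   file.path(out_dir, "identity_histogram.tsv"),
                   progress = FALSE)
  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    version = as.character(utils::packageVersion("norgscan")),
    seed = seed,
    config = config,
    counts = counts,
    input_checksums = checksums,
    output_checksums = as.list(tools::md5sum(
      outputs[!grepl("manifest", outputs)])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scan = scan, truth = truth, manifest = manifest))
}
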