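#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased and any letter outside `{A, C, G, T}` is mapped
#' to `N`. The internal convention throughout the package is 0-based
#' half-open coordinates on the forward strand.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A tibble with columns `id`, `residues`, `length`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgtACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    abort(paste0("duplicate sequence id in ", path, ": ", dup[1]))
  res <- clean_residues(as.character(set))
  tibble(id = unname(ids), residues = unname(res),
         length = unname(nchar(res)))
}

#' Write a sequence table to FASTA
#'
#' @param records Tibble with `id` and `residues` columns.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    seq <- records$residues[i]
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))), con)
  }
  invisible(path)
}

#' Construct a nuclear genome assembly object
#'
#' An assembly bundles a sequence table with the species label and the
#' assembly level reported by the source database. The level is user-supplied
#' metadata, never inferred from sequence.
#'
#' @param records Sequence tibble as returned by [read_fasta()].
#' @param species Species label.
#' @param assembly_level One of `"contig"`, `"scaffold"`, `"chromosome"`,
#'   `"complete"`.
#' @return A `genome_assembly` object (list with `species`, `assembly_level`,
#'   `records`, `total_length`).
#' @export
genome_assembly <- function(records, species,
                            assembly_level = c("contig", "scaffold",
                                               "chromosome", "complete")) {
  assembly_level <- match.arg(assembly_level)
  records <- as_tibble(records)
  stopifnot(all(c("id", "residues") %in% names(records)))
  if (!"length" %in% names(records)) records$length <- nchar(records$residues)
  if (any(records$length != nchar(records$residues)))
    abort("record length field disagrees with residues")
  if (anyDuplicated(records$id))
    abort(paste0("duplicate sequence id in assembly: ",
                 records$id[duplicated(records$id)][1]))
  structure(list(species = species, assembly_level = assembly_level,
                 records = records,
                 total_length = sum(records$length)),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", x$species, " [", x$assembly_level, "]: ",
      nrow(x$records), " sequence(s), ", x$total_length, " bp\n", sep = "")
  invisible(x)
}

#' Construct an organellar genome object
#'
#' @param id Sequence identifier.
#' @param residues Sequence string (A/C/G/T/N after cleaning).
#' @param kind `"mitochondrion"` or `"plastid"`.
#' @param circular Is the molecule circular? Circular queries are searched
#'   across the origin (see [seed_and_extend()]).
#' @param features Optional feature tibble as returned by
#'   [read_gff_features()].
#' @return An `organelle_genome` object.
#' @export
organelle_genome <- function(id, residues, kind = c("mitochondrion", "plastid"),
                             circular = TRUE, features = NULL) {
  kind <- match.arg(kind)
  residues <- clean_residues(residues)
  len <- nchar(residues)
  if (!is.null(features)) {
    features <- as_tibble(features)
    if (nrow(features) > 0 && any(features$start < 0 | features$end > len))
      abort("feature interval outside organellar sequence bounds")
  }
  structure(list(id = id, residues = residues, length = len, kind = kind,
                 circular = isTRUE(circular),
                 features = features %||% empty_features()),
            class = "organelle_genome")
}

#' @export
print.organelle_genome <- function(x, ...) {
  cat("<organelle_genome> ", x$id, " (", x$kind, ", ",
      if (x$circular) "circular" else "linear", "): ", x$length, " bp, ",
      nrow(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

empty_features <- function() {
  tibble(feature_id = character(), klass = character(),
         start = integer(), end = integer(), strand = character())
}

blast12_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         identity_pct = double(), aln_length = integer(),
         mismatches = integer(), gap_opens = integer(),
         q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(),
         strand = character(), evalue = double(), bitscore = double(),
         score = double())
}

#' Read a 12-column tabular local-alignment hit table
#'
#' Reads the de-facto tab-separated format of standard local-alignment
#' searches (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore). Input coordinates are 1-based inclusive;
#' they are converted to the package's 0-based half-open convention, and
#' subject coordinates given in descending order are normalized to ascending
#' with `strand = "-"`.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param dialect Coordinate dialect of the input; only `"blast"` (1-based
#'   inclusive, strand encoded by subject coordinate order) is defined.
#' @return A hit tibble in internal convention.
#' @export
read_tabular_hits <- function(path, dialect = "blast") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) return(empty_hits())
  if (ncol(raw) != 12)
    abort(paste0("expected 12 tab-separated columns, found ", ncol(raw)))
  names(raw) <- blast12_cols
  num_cols <- setdiff(blast12_cols, c("qseqid", "sseqid"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !is.na(raw[[cc]]))
    if (length(bad) > 0 || anyNA(raw[[cc]]))
      abort(paste0("non-numeric value in column '", cc, "' at line ",
                   c(bad, which(is.na(raw[[cc]])))[1]))
    raw[[cc]] <- v
  }
  minus <- raw$sstart > raw$send
  tibble(query_id = raw$qseqid, subject_id = raw$sseqid,
         identity_pct = raw$pident,
         aln_length = as.integer(raw$length),
         mismatches = as.integer(raw$mismatch),
         gap_opens = as.integer(raw$gapopen),
         q_start = as.integer(raw$qstart - 1), q_end = as.integer(raw$qend),
         s_start = as.integer(ifelse(minus, raw$send, raw$sstart) - 1),
         s_end = as.integer(ifelse(minus, raw$sstart, raw$send)),
         strand = ifelse(minus, "-", "+"),
         evalue = raw$evalue, bitscore = raw$bitscore,
         score = NA_real_)
}

#' Write hits in the 12-column tabular format
#'
#' Inverse of [read_tabular_hits()]: coordinates back to 1-based inclusive,
#' minus-strand hits written with descending subject coordinates.
#'
#' @param hits Hit tibble in internal convention.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  minus <- hits$strand == "-"
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = sprintf("%.3f", hits$identity_pct),
    length = hits$aln_length, mismatch = hits$mismatches,
    gapopen = hits$gap_opens,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = ifelse(minus, hits$s_end, hits$s_start + 1L),
    send = ifelse(minus, hits$s_start + 1L, hits$s_end),
    evalue = format(hits$evalue, digits = 6),
    bitscore = format(hits$bitscore, digits = 6))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

gff_klass_map <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA")

#' Read organellar feature annotations from GFF3
#'
#' Rows whose type is CDS, tRNA or rRNA keep their class; every other type is
#' mapped to class `"other"`. Coordinates are converted from GFF3's 1-based
#' inclusive convention to 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @param target_id Optional sequence id to restrict to.
#' @param target_length Optional sequence length used to validate intervals.
#' @return Feature tibble with `feature_id`, `klass`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_features <- function(path, target_id = NULL, target_length = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(empty_features())
  if (!is.null(target_id)) gr <- gr[as.character(GenomicRanges::seqnames(gr)) == target_id]
  if (length(gr) == 0) return(empty_features())
  type <- as.character(gr$type)
  klass <- unname(ifelse(type %in% names(gff_klass_map), type, "other"))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0(type[is.na(ids)], "_", which(is.na(ids)))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (!is.null(target_length) && any(end0 > target_length | start0 < 0))
    abort("feature coordinates outside sequence length")
  std <- as.character(GenomicRanges::strand(gr))
  std[std == "*"] <- "+"
  tibble(feature_id = ids, klass = klass, start = start0, end = end0,
         strand = std)
}

#' Write detected segments to BED or TSV
#'
#' BED output is 0-based half-open with the segment kind and index as the
#' name field. TSV output carries the full segment table (species and
#' organelle kind included when available as attributes).
#'
#' @param segments Segment tibble from [merge_hits()].
#' @param path Output path.
#' @param format `"BED"` or `"TSV"`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, format = c("BED", "TSV")) {
  format <- match.arg(format)
  if (format == "BED") {
    bed <- data.frame(chrom = segments$subject_id,
                      chromStart = segments$start,
                      chromEnd = segments$end,
                      name = paste0(segments$kind, "_", seq_len(nrow(segments))),
                      score = pmin(1000L, as.integer(round(segments$best_identity_pct * 10))),
                      strand = rep(".", nrow(segments)))
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  } else {
    out <- segments
    out$hit_ids <- vapply(out$hit_ids, paste, character(1), collapse = ",")
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Read intervals back from a BED file
#'
#' @param path BED path written by [write_segments()].
#' @return Tibble with `subject_id`, `start`, `end`, `name`, `score`.
#' @export
read_segments_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = "ciicic")
  if (nrow(raw) == 0)
    return(tibble(subject_id = character(), start = integer(),
                  end = integer(), name = character(), score = integer()))
  tibble(subject_id = raw$X1, start = raw$X2, end = raw$X3,
         name = raw$X4, score = raw$X5)
}

#' Read a rooted phylogeny with branch lengths from Newick
#'
#' The comparative layer requires branch lengths on every edge and unique,
#' non-empty tip labels; violations are errors.
#'
#' @param path Newick file with a single tree.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) abort("expected a single tree")
  if (is.null(tr)) abort("could not parse Newick tree")
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    abort("tree must have a branch length on every edge")
  if (any(tr$edge.length < 0)) abort("negative branch length")
  if (anyDuplicated(tr$tip.label)) abort("duplicate tip labels")
  if (any(!nzchar(tr$tip.label))) abort("unlabeled tip")
  invisible(tr)
}
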