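#' Contamination-filter policy
#'
#' Organellar molecules assembled into the nuclear set masquerade as short
#' contigs almost fully covered by organellar hits. A nuclear sequence is
#' flagged when BOTH its length is at most `max_contig_length` AND the
#' fraction of its bases covered by organellar hits is at least
#' `min_covered_fraction`.
#'
#' @param max_contig_length Length ceiling (bp) for a "short" contig.
#' @param min_covered_fraction Coverage floor defining "completely matched".
#' @return A policy list.
#' @export
contamination_policy <- function(max_contig_length = 1e4,
                                 min_covered_fraction = 0.95) {
  stopifnot(max_contig_length > 0,
            min_covered_fraction > 0, min_covered_fraction <= 1)
  list(max_contig_length = max_contig_length,
       min_covered_fraction = min_covered_fraction)
}

# union length of 0-based half-open intervals (single sequence)
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- cummax(end[o])
  new_run <- c(TRUE, start[-1] >= end[-length(end)])
  grp <- cumsum(new_run)
  sum(vapply(split(seq_along(start), grp), function(ix)
    max(end[ix]) - min(start[ix]), numeric(1)))
}

#' Flag contaminant nuclear sequences and drop their hits
#'
#' @param hits Hit tibble (internal convention).
#' @param assembly A [genome_assembly()] or a record tibble with `id` and
#'   `length`.
#' @param policy A [contamination_policy()].
#' @return List with `report` (flagged sequences: `subject_id`, `length`,
#'   `covered_fraction`), `hits` (hits on retained sequences),
#'   `genome_size_bp` (assembly length minus flagged sequences) and the
#'   `policy`.
#' @export
flag_contamination <- function(hits, assembly, policy = contamination_policy()) {
  records <- if (inherits(assembly, "genome_assembly")) assembly$records
  else as_tibble(assembly)
  if (!all(hits$subject_id %in% records$id))
    abort("hits refer to sequences absent from the assembly")
  cov <- dplyr::group_by(hits, .data$subject_id)
  cov <- dplyr::summarise(cov,
    covered = interval_union_length(.data$s_start, .data$s_end),
    .groups = "drop")
  cov <- left_join(cov, records[, c("id", "length")],
                   by = c(subject_id = "id"))
  cov$covered_fraction <- cov$covered / cov$length
  flagged <- cov[cov$length <= policy$max_contig_length &
                   cov$covered_fraction >= policy$min_covered_fraction, ,
                 drop = FALSE]
  report <- tibble(subject_id = flagged$subject_id,
                   length = flagged$length,
                   covered_fraction = flagged$covered_fraction)
  retained <- hits[!hits$subject_id %in% flagged$subject_id, , drop = FALSE]
  list(report = report, hits = retained,
       genome_size_bp = sum(records$length) - sum(flagged$length),
       policy = policy)
}

#' Merge overlapping hits into counted segments
#'
#' The same nuclear region matched by several organellar regions is one
#' insertion and must be counted once: subject intervals of retained hits
#' are grouped per nuclear sequence and every set of intervals overlapping
#' by at least 1 bp (or separated by at most `merge_gap` bp when
#' `merge_gap > 0`) is unioned into a single segment. Abutting but disjoint
#' intervals are not merged at the default `merge_gap = 0`.
#'
#' @param hits Hit tibble, all from one organelle kind.
#' @param merge_gap Maximum separation (bp) still merged; default 0.
#' @param kind Organelle-derived segment kind (`"NUMT"` or `"NUPT"`);
#'   inferred from the hits' `kind` column when present.
#' @return Segment tibble: `subject_id`, `start`, `end`, `length`, `kind`,
#'   `best_identity_pct`, `n_hits`, `hit_ids` (list column), ordered by
#'   subject id then start.
#' @export
merge_hits <- function(hits, merge_gap = 0L, kind = NULL) {
  if (is.null(kind)) {
    kk <- unique(hits$kind[!is.na(hits$kind)])
    if (length(kk) > 1)
      abort("hits span multiple organelle kinds; partition before merging")
    kind <- if (length(kk) == 1) segment_kind(kk) else NA_character_
  }
  if (nrow(hits) == 0) return(empty_segments(kind))
  if (!"hit_id" %in% names(hits))
    hits$hit_id <- sprintf("hit_%05d", seq_len(nrow(hits)))
  out <- lapply(split(hits, hits$subject_id), function(h) {
    o <- order(h$s_start, h$s_end)
    h <- h[o, , drop = FALSE]
    run_end <- cummax(h$s_end)
    gap <- h$s_start[-1] - run_end[-nrow(h)]
    boundary <- if (merge_gap > 0) gap > merge_gap else gap >= 0
    grp <- cumsum(c(TRUE, boundary))
    dplyr::bind_rows(lapply(split(seq_len(nrow(h)), grp), function(ix) {
      tibble(subject_id = h$subject_id[ix[1]],
             start = min(h$s_start[ix]), end = max(h$s_end[ix]),
             best_identity_pct = max(h$identity_pct[ix]),
             n_hits = length(ix), hit_ids = list(h$hit_id[ix]))
    }))
  })
  seg <- dplyr::bind_rows(out)
  seg$length <- seg$end - seg$start
  seg$kind <- kind
  seg <- seg[order(seg$subject_id, seg$start), , drop = FALSE]
  as_tibble(seg[, c("subject_id", "start", "end", "length", "kind",
                    "best_identity_pct", "n_hits", "hit_ids")])
}

segment_kind <- function(kind) {
  switch(kind, mitochondrion = "NUMT", plastid = "NUPT", kind)
}

empty_segments <- function(kind = NA_character_) {
  tibble(subject_id = character(), start = integer(), end = integer(),
         length = integer(), kind = character(),
         best_identity_pct = double(), n_hits = integer(),
         hit_ids = list())
}

#' Summarise segment content for one species and organelle kind
#'
#' @param segments Segment tibble, all of the given kind.
#' @param species Species label.
#' @param kind `"NUMT"` or `"NUPT"`.
#' @param genome_size_bp Nuclear genome size used for per-Mb densities
#'   (assembly length minus flagged contamination).
#' @return One-row tibble: `species`, `kind`, `count`, `total_length_bp`,
#'   `count_per_mb`, `length_per_mb`, `genome_size_bp`.
#' @export
summarize_content <- function(segments, species, kind, genome_size_bp) {
  if (genome_size_bp <= 0) abort("genome_size_bp must be positive")
  count <- nrow(segments)
  total <- if (count) sum(segments$length) else 0L
  mb <- genome_size_bp / 1e6
  tibble(species = species, kind = kind, count = count,
         total_length_bp = as.numeric(total),
         count_per_mb = count / mb, length_per_mb = total / mb,
         genome_size_bp = genome_size_bp)
}

# half-up rounding to integer kilobases, as used in human-readable tables
kb_round <- function(bp) floor(bp / 1000 + 0.5)

#' Attribute segments to organellar feature classes
#'
#' A segment is attributed to class `c` (CDS, tRNA, rRNA, other) when any of
#' its contributing hits' query intervals overlaps a feature of class `c` by
#' at least 1 bp. Segments may carry several classes; segments touching no
#' annotated feature (or when the organelle has no features) carry class
#' `"other"`. Origin-spanning hits on circular queries are unwrapped before
#' the overlap test.
#'
#' @param segments Segment tibble from [merge_hits()].
#' @param hits The hit tibble the segments were built from.
#' @param organelle An [organelle_genome()] (its `features` are used).
#' @param species,genome_size_bp Passed to the per-class summaries.
#' @return List with `segments` (plus a `feature_classes` list column) and
#'   `summary` (per-class content summaries).
#' @export
classify_features <- function(segments, hits, organelle, species = "species",
                              genome_size_bp = NULL) {
  feats <- organelle$features
  L <- organelle$length
  classes_of_hit <- function(q_start, q_end) {
    if (nrow(feats) == 0) return(character())
    pieces <- if (q_end > L) list(c(q_start, L), c(0, q_end - L))
    else list(c(q_start, q_end))
    hit_cl <- character()
    for (p in pieces) {
      ov <- feats$start < p[2] & feats$end > p[1]
      hit_cl <- c(hit_cl, feats$klass[ov])
    }
    unique(hit_cl)
  }
  seg_classes <- lapply(seq_len(nrow(segments)), function(i) {
    ids <- segments$hit_ids[[i]]
    hh <- hits[hits$hit_id %in% ids, , drop = FALSE]
    cl <- unique(unlist(lapply(seq_len(nrow(hh)), function(k)
      classes_of_hit(hh$q_start[k], hh$q_end[k]))))
    if (length(cl) == 0) cl <- "other"
    sort(cl)
  })
  segments$feature_classes <- seg_classes
  if (is.null(genome_size_bp)) genome_size_bp <- 1e6
  kind <- if (nrow(segments)) segments$kind[1] else NA_character_
  all_cl <- c("CDS", "tRNA", "rRNA", "other")
  summ <- dplyr::bind_rows(lapply(all_cl, function(cl) {
    sub <- segments[vapply(seg_classes, function(x) cl %in% x, logical(1)), ,
                    drop = FALSE]
    s <- summarize_content(sub, species, kind, genome_size_bp)
    s$feature_class <- cl
    s
  }))
  list(segments = segments,
       summary = summ[, c("feature_class", setdiff(names(summ), "feature_class"))])
}

#' Histogram of segment identities to their parental organellar sequences
#'
#' Right-closed bins of width `bin_width` percent over `(lo, 100]`. With
#' `lo = NULL` the range starts at the bin containing the lowest observed
#' identity.
#'
#' @param segments Segment tibble.
#' @param bin_width Bin width in percent; must divide 100.
#' @param lo Lower edge of the histogram range, or `NULL` to trim.
#' @return Tibble with `bin_lo`, `bin_hi` (right-closed `(lo, hi]`) and
#'   `count`; counts sum to the number of segments.
#' @export
identity_distribution <- function(segments, bin_width = 5, lo = NULL) {
  if (100 %% bin_width != 0) abort("bin_width must divide 100")
  ident <- segments$best_identity_pct
  edges <- seq(0, 100, by = bin_width)
  idx <- pmax(1L, as.integer(ceiling(ident / bin_width - 1e-9)))
  counts <- tabulate(idx, nbins = length(edges) - 1)
  first <- if (is.null(lo)) {
    if (length(ident) == 0) 1L else min(idx)
  } else match(lo, edges)
  if (is.na(first)) abort("lo must be a multiple of bin_width")
  sel <- first:(length(edges) - 1)
  tibble(bin_lo = edges[sel], bin_hi = edges[sel + 1], count = counts[sel])
}

#' Resolve nuclear regions claimed by both organelles
#'
#' In plants a nuclear interval may be matched by both the mitochondrial and
#' the plastid query (promiscuous organellar DNA). Overlapping NUMT/NUPT
#' segment pairs are resolved by keeping the segment whose contributing hits
#' reach the higher bit score; the other is dropped from its tally.
#'
#' @param segments_numt,segments_nupt Segment tibbles of the two kinds.
#' @param hits_numt,hits_nupt The hit tibbles they were built from.
#' @param report_ambiguous Also return the ambiguous pairs?
#' @return List with resolved `numt` and `nupt` segment tibbles and, when
#'   requested, an `ambiguous` table listing both claims.
#' @export
resolve_promiscuous <- function(segments_numt, segments_nupt,
                                hits_numt, hits_nupt,
                                report_ambiguous = FALSE) {
  best_bs <- function(seg, hits)
    vapply(seg$hit_ids, function(ids)
      max(hits$bitscore[hits$hit_id %in% ids], -Inf), numeric(1))
  bs_mt <- best_bs(segments_numt, hits_numt)
  bs_pt <- best_bs(segments_nupt, hits_nupt)
  drop_mt <- rep(FALSE, nrow(segments_numt))
  drop_pt <- rep(FALSE, nrow(segments_nupt))
  amb <- list()
  for (i in seq_len(nrow(segments_numt))) {
    for (j in seq_len(nrow(segments_nupt))) {
      same <- segments_numt$subject_id[i] == segments_nupt$subject_id[j]
      ov <- same && segments_numt$start[i] < segments_nupt$end[j] &&
        segments_nupt$start[j] < segments_numt$end[i]
      if (!ov) next
      if (bs_mt[i] >= bs_pt[j]) drop_pt[j] <- TRUE else drop_mt[i] <- TRUE
      amb[[length(amb) + 1]] <- tibble(
        subject_id = segments_numt$subject_id[i],
        numt_start = segments_numt$start[i], numt_end = segments_numt$end[i],
        nupt_start = segments_nupt$start[j], nupt_end = segments_nupt$end[j],
        numt_bitscore = bs_mt[i], nupt_bitscore = bs_pt[j],
        assigned = if (bs_mt[i] >= bs_pt[j]) "NUMT" else "NUPT")
    }
  }
  out <- list(numt = segments_numt[!drop_mt, , drop = FALSE],
              nupt = segments_nupt[!drop_pt, , drop = FALSE])
  if (report_ambiguous)
    out$ambiguous <- if (length(amb)) dplyr::bind_rows(amb) else tibble()
  out
}

#' Detect organellar insertions in a nuclear assembly
#'
#' End-to-end detection for one organelle against one assembly: local search
#' (or externally supplied hits), E-value filtering, contamination
#' flagging, hit merging into segments, content summary, feature-class
#' attribution and identity histogram.
#'
#' @param nuclear A [genome_assembly()].
#' @param organelle An [organelle_genome()].
#' @param scheme A [scoring_scheme()].
#' @param hits Optional pre-computed hit tibble (e.g. from
#'   [read_tabular_hits()]); when given, the internal aligner is bypassed.
#' @param policy A [contamination_policy()].
#' @param merge_gap Passed to [merge_hits()].
#' @param options [align_options()] for the internal search.
#' @param params Optional precomputed [karlin_altschul()] parameters.
#' @return A `norg_scan` object: list with `species`, `kind`, `hits`,
#'   `contamination`, `segments`, `summary`, `class_summary`,
#'   `identity_histogram`, `genome_size_bp`.
#' @export
norg_detect <- function(nuclear, organelle, scheme = scoring_scheme(),
                        hits = NULL, policy = contamination_policy(),
                        merge_gap = 0L, options = align_options(),
                        params = NULL) {
  stopifnot(inherits(nuclear, "genome_assembly"),
            inherits(organelle, "organelle_genome"))
  if (is.null(hits))
    hits <- seed_and_extend(organelle, nuclear, scheme = scheme,
                            params = params, options = options)
  if (!"kind" %in% names(hits) || all(is.na(hits$kind)))
    hits$kind <- organelle$kind
  if (!"hit_id" %in% names(hits))
    hits$hit_id <- sprintf("hit_%05d", seq_len(nrow(hits)))
  contam <- flag_contamination(hits, nuclear, policy)
  segments <- merge_hits(contam$hits, merge_gap = merge_gap)
  kind <- segment_kind(organelle$kind)
  cls <- classify_features(segments, contam$hits, organelle,
                           species = nuclear$species,
                           genome_size_bp = contam$genome_size_bp)
  structure(list(
    species = nuclear$species, kind = kind,
    hits = hits, contamination = contam$report,
    segments = cls$segments,
    summary = summarize_content(segments, nuclear$species, kind,
                                contam$genome_size_bp),
    class_summary = cls$summary,
    identity_histogram = identity_distribution(segments),
    genome_size_bp = contam$genome_size_bp),
    class = "norg_scan")
}

#' @export
print.norg_scan <- function(x, ...) {
  cat("<norg_scan> ", x$species, ": ", nrow(x$segments), " ", x$kind,
      " segment(s), total ", sum(x$segments$length), " bp; ",
      nrow(x$contamination), " contaminant contig(s) flagged\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.norg_scan <- function(x, ...) x$segments

#' @export
glance.norg_scan <- function(x, ...) x$summary
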