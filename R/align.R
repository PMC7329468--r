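#' Tuning knobs of the seed-and-extend search
#'
#' @param x_drop Score drop terminating ungapped seed extension.
#' @param gap_trigger Minimum ungapped extension score that admits a seed
#'   chain to the gapped stage. Must exceed `word_size * match` to filter
#'   random seeds; lower it for maximum sensitivity on small problems.
#' @param window_pad Padding (bp) around a seed chain for the gapped
#'   alignment window. Windows grow automatically while the alignment
#'   touches a window edge.
#' @param chain_gap Maximum subject-coordinate gap joining seed chains.
#' @param chain_drift Maximum diagonal drift within a seed chain.
#' @param max_window_cells Cell cap for one gapped window.
#' @param small_full_area Problems at most this many cells additionally get
#'   one exhaustive local-alignment pass, guaranteeing the optimal local
#'   alignment is reported whenever any seed chain passes the trigger.
#' @param dust Low-complexity masking placeholder; only `"off"` is
#'   implemented (a no-op, recorded for configuration completeness).
#' @return List of options.
#' @export
align_options <- function(x_drop = 20L, gap_trigger = 40L, window_pad = 120L,
                          chain_gap = 150L, chain_drift = 24L,
                          max_window_cells = 8e7, small_full_area = 1e6,
                          dust = "off") {
  stopifnot(x_drop > 0, window_pad >= 0, chain_gap >= 0, chain_drift >= 0)
  if (!identical(dust, "off"))
    abort("only dust = 'off' is implemented")
  list(x_drop = as.integer(x_drop), gap_trigger = as.integer(gap_trigger),
       window_pad = as.integer(window_pad), chain_gap = as.integer(chain_gap),
       chain_drift = as.integer(chain_drift),
       max_window_cells = max_window_cells,
       small_full_area = small_full_area, dust = dust)
}

#' Reverse complement of a DNA string
#' @param x A single DNA string (A/C/G/T/N).
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Exact optimal local alignment with affine gaps
#'
#' Full Smith-Waterman dynamic program; quadratic in sequence lengths and
#' capped by `max_cells`. Ties on score are broken deterministically by
#' lowest subject start, then lowest query start. Serves as the exhaustive
#' reference for [seed_and_extend()].
#'
#' @param query,subject DNA strings.
#' @param scheme A [scoring_scheme()].
#' @param max_cells Refuse problems larger than this many DP cells.
#' @return One-row tibble with score, 0-based half-open `q_start`/`q_end`,
#'   `s_start`/`s_end`, `matches`, `aln_length`, `n_gaps`, `gap_opens`,
#'   `identity_pct` and the alignment path as a CIGAR string
#'   (M both, I query-only, D subject-only). Score 0 means no positive-scoring
#'   alignment exists; intervals are then empty.
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           max_cells = 2.5e7) {
  query <- clean_residues(query); subject <- clean_residues(subject)
  r <- sw_full_cpp(query, subject, scheme$match, scheme$mismatch,
                   gap_first_cost(scheme), scheme$gap_extend, max_cells)
  tibble(score = r$score,
         q_start = r$q_start, q_end = r$q_end,
         s_start = r$s_start, s_end = r$s_end,
         matches = r$matches, aln_length = r$aln_length,
         n_gaps = r$n_gaps, gap_opens = r$gap_opens,
         identity_pct = if (r$aln_length > 0) 100 * r$matches / r$aln_length else NA_real_,
         cigar = r$cigar)
}

#' Recompute an alignment score from its stored path
#'
#' Replays a CIGAR path over the two sequences under a scoring scheme;
#' every reported alignment's score must be reproducible this way.
#'
#' @param cigar CIGAR string with ops M/I/D.
#' @param query,subject Full sequences the coordinates refer to.
#' @param q_start,s_start 0-based alignment start positions.
#' @param scheme A [scoring_scheme()].
#' @return List with `score`, `matches`, `aln_length`.
#' @export
rescore_alignment <- function(cigar, query, subject, q_start, s_start,
                              scheme = scoring_scheme()) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
  qi <- q_start; si <- s_start
  score <- 0L; matches <- 0L; aln <- 0L
  gfirst <- gap_first_cost(scheme)
  qv <- strsplit(query, "")[[1]]; sv <- strsplit(subject, "")[[1]]
  for (op in ops) {
    len <- as.integer(sub("[MID]", "", op))
    type <- substr(op, nchar(op), nchar(op))
    if (type == "M") {
      for (k in seq_len(len)) {
        same <- qv[qi + k] == sv[si + k] && qv[qi + k] != "N"
        score <- score + if (same) scheme$match else scheme$mismatch
        if (same) matches <- matches + 1L
      }
      qi <- qi + len; si <- si + len
    } else {
      score <- score - gfirst - scheme$gap_extend * (len - 1L)
      if (type == "D") si <- si + len else qi <- qi + len
    }
    aln <- aln + len
  }
  list(score = score, matches = matches, aln_length = aln)
}

#' Seed-and-extend local-alignment search
#'
#' Exact `word_size`-mer seeds are extended ungapped under an X-drop rule;
#' chains of seeds whose ungapped score reaches `gap_trigger` are aligned
#' with the full affine-gap dynamic program in an adaptively grown window.
#' Both subject strands are searched (the subject is reverse-complemented
#' logically; reported subject intervals are always ascending on the forward
#' strand with a strand flag). Hits with E-value above the scheme's cutoff
#' are discarded. Circular queries are handled by logically doubling the
#' query: hits starting in the second copy are dropped, and a retained hit
#' may have `q_end` greater than the query length, meaning it spans the
#' origin.
#'
#' @param query An [organelle_genome()], or a DNA string.
#' @param subject A [genome_assembly()], a record tibble from
#'   [read_fasta()], or a DNA string.
#' @param scheme A [scoring_scheme()].
#' @param params Karlin-Altschul parameters; computed from `scheme` with a
#'   uniform background when `NULL`.
#' @param options An [align_options()] list.
#' @param both_strands Search the minus strand of the subject too?
#' @param query_id,subject_id Identifiers used when plain strings are given.
#' @return A hit tibble (internal 0-based half-open convention) with
#'   identity, scores, E-values, strand and a `kind` column when the query
#'   is an organellar genome.
#' @export
seed_and_extend <- function(query, subject, scheme = scoring_scheme(),
                            params = NULL, options = align_options(),
                            both_strands = TRUE,
                            query_id = "query", subject_id = "subject") {
  if (is.null(params)) params <- karlin_altschul(scheme)
  kind <- NA_character_
  circular <- FALSE
  if (inherits(query, "organelle_genome")) {
    qseq <- query$residues; qlen_true <- query$length
    query_id <- query$id; kind <- query$kind; circular <- query$circular
  } else {
    qseq <- clean_residues(query); qlen_true <- nchar(qseq)
  }
  qsearch <- if (circular) paste0(qseq, qseq) else qseq

  records <- if (inherits(subject, "genome_assembly")) subject$records
  else if (is.data.frame(subject)) as_tibble(subject)
  else tibble(id = subject_id, residues = clean_residues(subject),
              length = nchar(clean_residues(subject)))

  run_one <- function(sid, sseq) {
    slen <- nchar(sseq)
    per_strand <- function(seq_s, strand) {
      df <- seed_extend_cpp(qsearch, seq_s, scheme$word_size,
                            scheme$match, scheme$mismatch,
                            gap_first_cost(scheme), scheme$gap_extend,
                            options$gap_trigger, options$x_drop,
                            options$window_pad, options$chain_gap,
                            options$chain_drift, options$max_window_cells,
                            options$small_full_area)
      df <- as_tibble(df)
      if (nrow(df) == 0) return(df)
      if (strand == "-") {
        s0 <- slen - df$s_end; s1 <- slen - df$s_start
        df$s_start <- s0; df$s_end <- s1
      }
      df$strand <- strand
      df
    }
    out <- per_strand(sseq, "+")
    if (both_strands)
      out <- bind_rows(out, per_strand(revcomp(sseq), "-"))
    if (nrow(out) == 0) return(out)
    if (circular) {
      out <- out[out$q_start < qlen_true, , drop = FALSE]
      if (nrow(out) == 0) return(out)
      # the doubled query reports the same nuclear locus once per copy;
      # a hit whose subject interval lies inside a better hit's interval on
      # the same strand is that duplicate
      keep <- rep(TRUE, nrow(out))
      for (i in seq_len(nrow(out))) {
        for (j in seq_len(nrow(out))) {
          if (i == j || !keep[i] || !keep[j]) next
          if (out$strand[i] == out$strand[j] &&
              out$s_start[j] >= out$s_start[i] &&
              out$s_end[j] <= out$s_end[i] &&
              (out$score[j] < out$score[i] ||
                 (out$score[j] == out$score[i] && j > i)))
            keep[j] <- FALSE
        }
      }
      out <- out[keep, , drop = FALSE]
    }
    out$subject_id <- sid
    out$evalue <- evalue_of(out$score, qlen_true, slen, params)
    out
  }

  hits <- purrr::map2_dfr(records$id, records$residues, run_one)
  if (nrow(hits) == 0) return(empty_hits_kind(kind))
  hits <- hits[hits$evalue <= scheme$evalue_max, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits_kind(kind))
  hits <- dedupe_hits(hits)
  hits$query_id <- query_id
  hits$identity_pct <- 100 * hits$matches / hits$aln_length
  hits$mismatches <- hits$aln_length - hits$matches - hits$n_gaps
  hits$bitscore <- bitscore_of(hits$score, params)
  hits$kind <- kind
  hits <- hits[order(hits$subject_id, hits$s_start, hits$s_end,
                     hits$q_start, hits$strand), , drop = FALSE]
  hits$hit_id <- sprintf("hit_%05d", seq_len(nrow(hits)))
  as_tibble(hits[, c("hit_id", "query_id", "subject_id", "identity_pct",
                     "aln_length", "mismatches", "gap_opens", "q_start",
                     "q_end", "s_start", "s_end", "strand", "evalue",
                     "bitscore", "score", "matches", "n_gaps", "kind")])
}

empty_hits_kind <- function(kind) {
  h <- empty_hits()
  h$matches <- integer(); h$n_gaps <- integer(); h$kind <- character()
  h$hit_id <- character()
  h[, c("hit_id", names(empty_hits()), "matches", "n_gaps", "kind")]
}

# drop exact duplicates and hits contained in a better hit in both
# coordinates on the same strand
dedupe_hits <- function(hits) {
  key <- paste(hits$subject_id %||% "", hits$strand, hits$q_start, hits$q_end,
               hits$s_start, hits$s_end)
  hits <- hits[!duplicated(key), , drop = FALSE]
  if (nrow(hits) <= 1) return(hits)
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      j <- ord[b]
      if (i == j || !keep[j]) next
      if (hits$subject_id[i] == hits$subject_id[j] &&
          hits$strand[i] == hits$strand[j] &&
          hits$score[j] <= hits$score[i] &&
          hits$q_start[j] >= hits$q_start[i] && hits$q_end[j] <= hits$q_end[i] &&
          hits$s_start[j] >= hits$s_start[i] && hits$s_end[j] <= hits$s_end[i])
        keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}
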