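random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate an organellar genome with annotated features
#'
#' Bases are i.i.d. at the requested GC content. Non-overlapping features of
#' classes CDS, tRNA and rRNA are tiled at random positions with
#' class-typical lengths (CDS 300-1500 bp, tRNA 70-90 bp, rRNA 1000-2500
#' bp).
#'
#' @param length Genome length (bp, >= 1000).
#' @param gc GC fraction.
#' @param circular Circular molecule?
#' @param kind `"mitochondrion"` or `"plastid"`.
#' @param n_features Number of features to place.
#' @param seed Optional RNG seed (full determinism under a fixed seed).
#' @param id Sequence identifier.
#' @return An [organelle_genome()].
#' @export
simulate_organelle <- function(length = 16000, gc = 0.45, circular = TRUE,
                               kind = c("mitochondrion", "plastid"),
                               n_features = 10, seed = NULL, id = "organelle") {
  kind <- match.arg(kind)
  if (length < 1000) abort("organelle length must be >= 1 kb")
  if (!is.null(seed)) set.seed(seed)
  residues <- random_dna(length, gc)
  feats <- empty_features()
  if (n_features > 0) {
    classes <- sample(c("CDS", "tRNA", "rRNA"), n_features, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1))
    lens <- vapply(classes, function(cl) switch(cl,
      CDS = sample(300:1500, 1), tRNA = sample(70:90, 1),
      rRNA = sample(1000:2500, 1)), numeric(1))
    starts <- integer(0); ends <- integer(0)
    for (i in seq_len(n_features)) {
      ok <- FALSE
      for (try in seq_len(500)) {
        st <- sample.int(length - lens[i], 1) - 1L
        en <- st + lens[i]
        if (!any(st < ends & starts < en)) { ok <- TRUE; break }
      }
      if (!ok) abort("infeasible feature packing")
      starts <- c(starts, st); ends <- c(ends, as.integer(en))
    }
    feats <- tibble(feature_id = sprintf("feat_%02d", seq_len(n_features)),
                    klass = classes, start = starts, end = ends,
                    strand = sample(c("+", "-"), n_features, replace = TRUE))
    feats <- feats[order(feats$start), , drop = FALSE]
  }
  organelle_genome(id, residues, kind = kind, circular = circular,
                   features = feats)
}

#' Simulate a random nuclear background sequence set
#'
#' @param length Total length (bp) of each record.
#' @param gc GC fraction.
#' @param n_records Number of sequences.
#' @param seed Optional RNG seed.
#' @param prefix Sequence id prefix.
#' @return A record tibble (`id`, `residues`, `length`).
#' @export
simulate_nuclear <- function(length = 2e6, gc = 0.38, n_records = 1,
                             seed = NULL, prefix = "chr") {
  if (!is.null(seed)) set.seed(seed)
  per <- rep(floor(length / n_records), n_records)
  per[n_records] <- length - sum(per[-n_records])
  tibble(id = paste0(prefix, seq_len(n_records)),
         residues = vapply(per, random_dna, character(1), gc = gc),
         length = as.integer(per))
}

#' Insertion-simulation configuration
#'
#' @param n_insertions Number of fragments to plant.
#' @param length_range Fragment length range (bp).
#' @param identity_range Target identity range (percent) of fragments to
#'   their source; divergence is applied as per-site substitutions at rate
#'   `(100 - identity)/100` with a 2:1 transition:transversion ratio.
#' @param revcomp_fraction Fraction of fragments planted in reverse
#'   complement.
#' @param min_spacing Minimum distance (bp) between planted fragments, so
#'   seed chains cannot bridge distinct insertions.
#' @param indel_rate Per-site probability of a small (1-3 bp) indel inside a
#'   fragment; off by default.
#' @param exact_fraction Share of fragments planted with divergence 0
#'   (identity exactly 100), anchoring exact-boundary checks.
#' @return Config list.
#' @export
insertion_config <- function(n_insertions = 50, length_range = c(200, 2000),
                             identity_range = c(85, 100),
                             revcomp_fraction = 0.5, min_spacing = 200,
                             indel_rate = 0, exact_fraction = 0.2) {
  list(n_insertions = n_insertions, length_range = length_range,
       identity_range = identity_range, revcomp_fraction = revcomp_fraction,
       min_spacing = min_spacing, indel_rate = indel_rate,
       exact_fraction = exact_fraction)
}

transition <- c(A = "G", G = "A", C = "T", T = "C")
transversions <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

mutate_fragment <- function(frag, divergence, indel_rate = 0) {
  v <- strsplit(frag, "")[[1]]
  sub_sites <- which(runif(length(v)) < divergence)
  for (i in sub_sites) {
    b <- v[i]
    v[i] <- if (runif(1) < 2 / 3) transition[[b]] else
      sample(transversions[[b]], 1)
  }
  n_sub <- length(sub_sites)
  if (indel_rate > 0) {
    out <- character(0)
    for (i in seq_along(v)) {
      if (runif(1) < indel_rate) {
        if (runif(1) < 0.5) next  # deletion
        out <- c(out, v[i], strsplit(random_dna(sample(1:3, 1)), "")[[1]])
      } else out <- c(out, v[i])
    }
    v <- out
  }
  list(seq = paste(v, collapse = ""), n_sub = n_sub)
}

# pick a base different from all bases in `avoid`
different_base <- function(avoid) {
  setdiff(c("A", "C", "G", "T"), avoid)[1]
}

#' Plant organellar fragments into a nuclear background
#'
#' Random organellar substrings are copied (optionally reverse-complemented)
#' into random positions of the background, separated by at least
#' `min_spacing` bp. Divergence is applied as independent per-site
#' substitutions (transition:transversion 2:1). The single nuclear base on
#' each side of a planted fragment is set to differ from the adjacent
#' organellar base, so a perfect-identity fragment's optimal local alignment
#' has exactly the planted boundaries and truth-to-segment mapping stays
#' one-to-one.
#'
#' @param background A single background sequence (string) or a one-row
#'   record tibble from [simulate_nuclear()].
#' @param organelle An [organelle_genome()].
#' @param config An [insertion_config()].
#' @param seed Optional RNG seed.
#' @param species,assembly_level Metadata for the returned assembly.
#' @return List with `assembly` (a [genome_assembly()]) and `truth`
#'   (tibble: `subject_id`, `start`, `end`, `kind`, `strand`, `q_start`,
#'   `q_end`, `target_identity_pct`, `realized_identity_pct`).
#' @export
plant_insertions <- function(background, organelle,
                             config = insertion_config(), seed = NULL,
                             species = "synthetic", assembly_level = "scaffold") {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(background)) {
    subject_id <- background$id[1]
    bg <- background$residues[1]
  } else {
    subject_id <- "chr1"
    bg <- background
  }
  B <- nchar(bg)
  n <- config$n_insertions
  # insertion points in background coordinates, pairwise >= min_spacing apart
  pts <- NULL
  for (try in seq_len(500)) {
    cand <- sort(sample.int(B - 1, n))
    if (n == 1 || all(diff(cand) >= config$min_spacing)) { pts <- cand; break }
  }
  if (is.null(pts)) abort("could not place insertions with required spacing")
  O <- organelle$residues; L <- organelle$length
  lens <- sample(seq(config$length_range[1], config$length_range[2]), n,
                 replace = TRUE)
  idents <- runif(n, config$identity_range[1], config$identity_range[2])
  # a controlled share of exact (divergence-0) copies exercises
  # exact-boundary recovery
  idents[runif(n) < config$exact_fraction] <- 100
  rcs <- runif(n) < config$revcomp_fraction
  q_starts <- vapply(lens, function(l) sample.int(L - l, 1) - 1L, numeric(1))

  org_base <- function(pos) {
    # adjacent organellar base, wrapping on circular molecules
    if (pos >= 0 && pos < L) return(substr(O, pos + 1, pos + 1))
    if (!organelle$circular) return(NA_character_)
    p <- ((pos %% L) + L) %% L
    substr(O, p + 1, p + 1)
  }
  comp <- c(A = "T", T = "A", C = "G", G = "C", N = "N")

  bg_v <- strsplit(bg, "")[[1]]
  frags <- character(n); n_subs <- integer(n); frag_lens <- integer(n)
  for (i in seq_len(n)) {
    a <- q_starts[i]; b <- a + lens[i]
    src <- substr(O, a + 1, b)
    if (rcs[i]) src <- revcomp(src)
    div <- (100 - idents[i]) / 100
    mut <- mutate_fragment(src, div, config$indel_rate)
    frags[i] <- mut$seq
    n_subs[i] <- mut$n_sub
    frag_lens[i] <- nchar(mut$seq)
    # junction hardening: a short run of nuclear bases flanking the planted
    # fragment is forced to mismatch the organellar continuation on the
    # planted strand, so the optimal local alignment of an exact fragment
    # ends exactly at the planted boundaries (verified below)
    for (j in seq_len(12)) {
      left_cont <- if (rcs[i]) {
        bb <- org_base(b + j - 1); if (is.na(bb)) NA_character_ else comp[[bb]]
      } else org_base(a - j)
      right_cont <- if (rcs[i]) {
        bb <- org_base(a - j); if (is.na(bb)) NA_character_ else comp[[bb]]
      } else org_base(b + j - 1)
      li <- pts[i] - j + 1
      ri <- pts[i] + j
      if (!is.na(left_cont) && li >= 1 && bg_v[li] == left_cont)
        bg_v[li] <- different_base(left_cont)
      if (!is.na(right_cont) && ri <= B && bg_v[ri] == right_cont)
        bg_v[ri] <- different_base(right_cont)
    }
  }
  # verification: for exact (divergence-0) copies, the optimal local
  # alignment of the organellar neighbourhood against the planted context
  # must be exactly the fragment; rare chance homology at a junction (e.g.
  # via a 1 bp gap) is removed by resampling the flanking bases
  O2 <- if (organelle$circular) paste0(O, O, O) else O
  o_sub <- function(lo, hi) {
    # 0-based half-open window on the organelle, wrapped when circular
    if (organelle$circular) substr(O2, lo + L + 1, hi + L)
    else substr(O, max(0, lo) + 1, min(L, hi))
  }
  for (i in seq_len(n)) {
    if (idents[i] < 100 || n_subs[i] > 0) next
    a <- q_starts[i]; b <- a + lens[i]
    for (attempt in seq_len(60)) {
      left_ix <- seq(max(1, pts[i] - 29), pts[i])
      right_ix <- seq(pts[i] + 1, min(B, pts[i] + 30))
      candidate <- paste0(paste(bg_v[left_ix], collapse = ""), frags[i],
                          paste(bg_v[right_ix], collapse = ""))
      owin <- o_sub(a - 42, b + 42)
      if (rcs[i]) owin <- revcomp(owin)
      r <- smith_waterman(owin, candidate, max_cells = 2e7)
      off <- length(left_ix)
      if (r$score == 2L * lens[i] && r$s_start == off &&
          r$s_end == off + lens[i]) break
      # resample the hardened flanks (still avoiding the direct
      # continuation base)
      for (j in seq_len(12)) {
        li <- pts[i] - j + 1; ri <- pts[i] + j
        if (li >= 1) bg_v[li] <- sample(setdiff(c("A", "C", "G", "T"),
                                                bg_v[li]), 1)
        if (ri <= B) bg_v[ri] <- sample(setdiff(c("A", "C", "G", "T"),
                                                bg_v[ri]), 1)
      }
      left_cont1 <- if (rcs[i]) {
        bb <- org_base(b); if (is.na(bb)) NA_character_ else comp[[bb]]
      } else org_base(a - 1)
      right_cont1 <- if (rcs[i]) {
        bb <- org_base(a - 1); if (is.na(bb)) NA_character_ else comp[[bb]]
      } else org_base(b)
      if (!is.na(left_cont1) && pts[i] >= 1 && bg_v[pts[i]] == left_cont1)
        bg_v[pts[i]] <- different_base(left_cont1)
      if (!is.na(right_cont1) && pts[i] + 1 <= B &&
          bg_v[pts[i] + 1] == right_cont1)
        bg_v[pts[i] + 1] <- different_base(right_cont1)
    }
  }
  # splice fragments in after their insertion points
  pieces <- character(2 * n + 1)
  prev <- 0L
  for (i in seq_len(n)) {
    pieces[2 * i - 1] <- paste(bg_v[(prev + 1):pts[i]], collapse = "")
    pieces[2 * i] <- frags[i]
    prev <- pts[i]
  }
  pieces[2 * n + 1] <- paste(bg_v[(prev + 1):B], collapse = "")
  final <- paste(pieces, collapse = "")
  offsets <- cumsum(c(0, frag_lens))[seq_len(n)]
  starts <- pts + offsets
  truth <- tibble(
    subject_id = subject_id,
    start = as.integer(starts), end = as.integer(starts + frag_lens),
    kind = segment_kind(organelle$kind),
    strand = ifelse(rcs, "-", "+"),
    q_start = as.integer(q_starts), q_end = as.integer(q_starts + lens),
    target_identity_pct = idents,
    realized_identity_pct = if (config$indel_rate == 0)
      100 * (lens - n_subs) / lens else NA_real_)
  records <- tibble(id = subject_id, residues = final,
                    length = nchar(final))
  list(assembly = genome_assembly(records, species, assembly_level),
       truth = truth)
}

#' Generate verbatim organellar contaminant contigs
#'
#' Short contigs that are exact organellar substrings, emulating organellar
#' molecules mistakenly assembled into the nuclear sequence set; these are
#' the targets of [flag_contamination()].
#'
#' @param organelle An [organelle_genome()].
#' @param n Number of contigs.
#' @param length_range Contig length range (bp), below the organelle length.
#' @param seed Optional RNG seed.
#' @param prefix Contig id prefix.
#' @return Record tibble (`id`, `residues`, `length`).
#' @export
make_contaminant_contigs <- function(organelle, n, length_range = c(2000, 8000),
                                     seed = NULL, prefix = "contam") {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(tibble(id = character(), residues = character(), length = integer()))
  if (length_range[2] >= organelle$length)
    abort("contaminant contigs must be shorter than the organelle")
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  starts <- vapply(lens, function(l) sample.int(organelle$length - l, 1),
                   numeric(1))
  tibble(id = paste0(prefix, "_", seq_len(n)),
         residues = substring(organelle$residues, starts, starts + lens - 1),
         length = as.integer(lens))
}

#' Simulate a pure-birth (Yule) tree
#'
#' Exponential waiting times between speciation events at the given birth
#' rate; all branch lengths positive.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional RNG seed.
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  validate_tree(tr)
  tr
}

#' Simulate a trait with lambda-scaled Brownian covariance on a tree
#'
#' `y = intercept + slope * x + e` with
#' `e ~ MVN(0, sigma2 * V(lambda))`, drawn through the Cholesky factor of
#' the lambda-transformed phylogenetic covariance.
#'
#' @param tree `ape::phylo` tree.
#' @param x Predictor values named by tip label, or unnamed in tip order.
#' @param lambda_true Pagel's lambda of the noise covariance.
#' @param slope,intercept Regression coefficients.
#' @param sigma2 Noise scale.
#' @param seed Optional RNG seed.
#' @return Tibble with `species`, `x`, `y`.
#' @export
simulate_traits <- function(tree, x, lambda_true = 1, slope = 0,
                            intercept = 0, sigma2 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tips <- tree$tip.label
  if (!is.null(names(x))) x <- x[tips]
  stopifnot(length(x) == length(tips))
  if (sigma2 == 0) {
    eps <- rep(0, length(tips))
  } else {
    v <- lambda_transform(build_covariance(tree), lambda_true)
    U <- tryCatch(chol(sigma2 * v), error = function(e)
      abort("phylogenetic covariance is not positive definite"))
    eps <- as.numeric(t(U) %*% rnorm(length(tips)))
  }
  tibble(species = tips, x = as.numeric(x),
         y = intercept + slope * as.numeric(x) + eps)
}

#' Simulate a paired tolerant-vs-control design
#'
#' Control values are i.i.d. draws from `noise`; tolerant values are
#' independent draws from the same law shifted by `effect_delta`
#' (`effect_delta = 0` gives a null design).
#'
#' @param n_pairs Number of lineage pairs (>= 5).
#' @param effect_delta Additive shift of the tolerant side.
#' @param noise Function of `n` returning draws; default lognormal
#'   (`meanlog = 3`, `sdlog = 1`), skewed like per-genome insertion counts.
#' @param seed Optional RNG seed.
#' @return Tibble with `pair_id`, `tolerant`, `control`.
#' @export
make_paired_design <- function(n_pairs = 24, effect_delta = 0,
                               noise = function(n) rlnorm(n, 3, 1),
                               seed = NULL) {
  stopifnot(n_pairs >= 5)
  if (!is.null(seed)) set.seed(seed)
  tibble(pair_id = paste0("pair_", seq_len(n_pairs)),
         tolerant = noise(n_pairs) + effect_delta,
         control = noise(n_pairs))
}

#' Score detected segments against planted-insertion truth
#'
#' A truth insertion is recovered when a detected segment of the correct
#' kind covers at least `min_overlap_fraction` of it. Per-base precision is
#' the fraction of detected segment bases lying inside truth intervals;
#' per-base recall is the fraction of truth bases covered by segments.
#'
#' @param segments Segment tibble from [merge_hits()].
#' @param truth Truth tibble from [plant_insertions()].
#' @param min_overlap_fraction Coverage fraction defining recovery.
#' @return List with `summary` (one-row tibble: `n_truth`, `n_recovered`,
#'   `recall`, `precision_bases`, `recall_bases`, `n_exact_boundary`) and
#'   `per_truth` (per-insertion detail).
#' @export
evaluate_recovery <- function(segments, truth, min_overlap_fraction = 0.5) {
  per <- lapply(seq_len(nrow(truth)), function(i) {
    tt <- truth[i, ]
    seg <- segments[segments$subject_id == tt$subject_id &
                      segments$kind == tt$kind, , drop = FALSE]
    ov <- pmax(0, pmin(seg$end, tt$end) - pmax(seg$start, tt$start))
    best <- if (length(ov)) max(ov) else 0
    exact <- any(seg$start == tt$start & seg$end == tt$end)
    tibble(truth_idx = i, length = tt$end - tt$start,
           best_overlap = best,
           recovered = best >= min_overlap_fraction * (tt$end - tt$start),
           exact_boundary = exact)
  })
  per <- dplyr::bind_rows(per)
  total_seg <- sum(segments$length)
  covered_truth <- 0; truth_total <- sum(truth$end - truth$start)
  truth_covered_by_seg <- 0
  for (i in seq_len(nrow(segments))) {
    tt <- truth[truth$subject_id == segments$subject_id[i] &
                  truth$kind == segments$kind[i], , drop = FALSE]
    ov <- pmax(0, pmin(tt$end, segments$end[i]) - pmax(tt$start, segments$start[i]))
    covered_truth <- covered_truth + sum(ov)
  }
  for (i in seq_len(nrow(truth))) {
    seg <- segments[segments$subject_id == truth$subject_id[i] &
                      segments$kind == truth$kind[i], , drop = FALSE]
    ov <- pmax(0, pmin(seg$end, truth$end[i]) - pmax(seg$start, truth$start[i]))
    truth_covered_by_seg <- truth_covered_by_seg + interval_union_length(
      pmax(seg$start, truth$start[i])[ov > 0], pmin(seg$end, truth$end[i])[ov > 0])
  }
  summary <- tibble(
    n_truth = nrow(truth),
    n_recovered = sum(per$recovered),
    recall = if (nrow(truth)) mean(per$recovered) else NA_real_,
    precision_bases = if (total_seg > 0) covered_truth / total_seg else NA_real_,
    recall_bases = if (truth_total > 0) truth_covered_by_seg / truth_total else NA_real_,
    n_exact_boundary = sum(per$exact_boundary))
  list(summary = summary, per_truth = per)
}
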