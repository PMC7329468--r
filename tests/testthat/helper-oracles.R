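# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# per-base boolean-marking oracle for interval union: returns covered base
# count and number of connected runs
mark_oracle <- function(starts, ends, len) {
  v <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) v[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(v)
  list(union = sum(v), n_runs = sum(r$values))
}

# full 2^n sign-assignment enumeration for the Wilcoxon signed-rank test
enum_signrank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  wp_obs <- sum(r[d > 0])
  wm_obs <- sum(r[d < 0])
  w <- min(wp_obs, wm_obs)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wp_all <- as.numeric(signs %*% r)
  tot <- sum(r)
  min(1, mean(wp_all <= w) + mean(wp_all >= tot - w))
}

# all permutations of a vector (small n only)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

# exact two-sided permutation p for Spearman's rho
enum_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  ps <- vapply(all_perms(ry), function(p) abs(cor(rx, p)), numeric(1))
  mean(ps >= obs - 1e-12)
}

# random DNA string
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# point-mutate a DNA string at a given per-site rate (any other base)
mutate_dna <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# does the optimal local alignment contain an exact run of >= word matching
# columns (i.e. a seed the word-hash stage could find)?
has_seed_in_alignment <- function(aln, query, subject, word = 11) {
  if (aln$score <= 0 || nchar(aln$cigar) == 0) return(FALSE)
  ops <- regmatches(aln$cigar, gregexpr("[0-9]+[MID]", aln$cigar))[[1]]
  qi <- aln$q_start; si <- aln$s_start
  run <- 0
  qv <- strsplit(query, "")[[1]]; sv <- strsplit(subject, "")[[1]]
  for (op in ops) {
    len <- as.integer(sub("[MID]", "", op))
    type <- substr(op, nchar(op), nchar(op))
    if (type == "M") {
      for (k in seq_len(len)) {
        same <- qv[qi + k] == sv[si + k] && qv[qi + k] != "N"
        run <- if (same) run + 1 else 0
        if (run >= word) return(TRUE)
      }
      qi <- qi + len; si <- si + len
    } else {
      run <- 0
      if (type == "D") si <- si + len else qi <- qi + len
    }
  }
  FALSE
}

# quick segment tibble with given lengths / identities
mk_segments <- function(lengths = NULL, identity = NULL) {
  n <- max(length(lengths), length(identity))
  if (is.null(lengths)) lengths <- rep(100L, n)
  if (is.null(identity)) identity <- rep(95, n)
  lengths <- rep_len(as.integer(lengths), n)
  identity <- rep_len(identity, n)
  starts <- as.integer(cumsum(c(0L, utils::head(lengths, -1) + 50L)))
  tibble::tibble(subject_id = "chr1", start = starts, end = starts + lengths,
                 length = lengths, kind = "NUMT",
                 best_identity_pct = identity, n_hits = 1L,
                 hit_ids = as.list(sprintf("h%03d", seq_len(n))))
}

# random hit tibble on a handful of subject sequences, for merge testing.
# Abutting pairs (one interval starting exactly where another ends) are
# perturbed away: the per-base marking oracle cannot distinguish abutting
# from overlapping, while the merge rule deliberately keeps abutting
# intervals separate.
random_hits <- function(n, n_subjects = 3, max_pos = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s_start <- sample.int(max_pos - 100, n, replace = TRUE)
  len <- sample(10:200, n, replace = TRUE)
  for (k in 1:20) {
    abut <- s_start %in% (s_start + len)
    if (!any(abut)) break
    s_start[abut] <- s_start[abut] + 1L
  }
  tibble::tibble(
    hit_id = sprintf("h%04d", seq_len(n)),
    query_id = "org",
    subject_id = sample(paste0("chr", seq_len(n_subjects)), n, replace = TRUE),
    identity_pct = runif(n, 80, 100),
    aln_length = len,
    q_start = sample.int(1000, n, replace = TRUE),
    q_end = sample.int(1000, n, replace = TRUE) + 1000L,
    s_start = s_start, s_end = s_start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    evalue = 10^runif(n, -20, -5),
    bitscore = runif(n, 50, 500),
    kind = "mitochondrion")
}
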