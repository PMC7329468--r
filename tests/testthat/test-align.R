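test_that("exhaustive local alignment handles canonical cases", {
  sch <- scoring_scheme()
  L <- 40
  s <- rand_dna(L)
  a <- smith_waterman(s, s, sch)
  expect_equal(a$score, 2L * L)
  expect_equal(a$identity_pct, 100)
  expect_equal(c(a$q_start, a$q_end), c(0L, L))

  # no common letter in register beyond single-base matches
  b <- smith_waterman("ACGT", "TTTT", sch)
  expect_equal(b$score, 2L)
  expect_equal(b$aln_length, 1L)

  # symmetry under swapping query and subject
  set.seed(11)
  for (i in 1:10) {
    q <- rand_dna(sample(20:60, 1)); s <- rand_dna(sample(20:60, 1))
    expect_equal(smith_waterman(q, s, sch)$score,
                 smith_waterman(s, q, sch)$score)
  }
})

test_that("reported scores are reproducible from the stored path", {
  sch <- scoring_scheme()
  set.seed(12)
  for (i in 1:25) {
    q <- rand_dna(80)
    # relate the subject so gapped alignments occur
    s <- paste0(rand_dna(30), mutate_dna(substr(q, 10, 70), 0.1), rand_dna(30))
    a <- smith_waterman(q, s, sch)
    if (a$score == 0) next
    r <- rescore_alignment(a$cigar, q, s, a$q_start, a$s_start, sch)
    expect_equal(r$score, a$score)
    expect_equal(r$matches, a$matches)
    expect_equal(r$aln_length, a$aln_length)
  }
})

test_that("exhaustive aligner agrees with an independent affine-gap implementation", {
  sch <- scoring_scheme()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(13)
  for (i in 1:20) {
    q <- rand_dna(sample(30:90, 1))
    s <- paste0(rand_dna(20), mutate_dna(q, 0.15), rand_dna(20))
    mine <- smith_waterman(q, s, sch)
    ref <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = sch$gap_open,
                                         gapExtension = sch$gap_extend)
    expect_equal(mine$score, Biostrings::score(ref))
  }
})

test_that("alignment cell cap triggers an error", {
  expect_error(smith_waterman(rand_dna(200), rand_dna(200),
                              max_cells = 1e3), "cap")
})

test_that("seed-and-extend finds a perfect planted substring exactly once", {
  set.seed(14)
  sub <- rand_dna(5000)
  frag <- substr(sub, 2001, 2500)
  hits <- seed_and_extend(frag, sub, both_strands = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$s_start, 2000L)
  expect_equal(hits$s_end, 2500L)
  expect_equal(hits$identity_pct, 100)
})

test_that("no shared word means no hits", {
  q <- paste(rep("A", 100), collapse = "")
  s <- paste(rep("C", 300), collapse = "")
  expect_equal(nrow(seed_and_extend(q, s)), 0)
})

test_that("seeded instances reach the exhaustive optimum", {
  sch <- scoring_scheme(evalue_max = 10)
  opts <- align_options(gap_trigger = 22)
  ka <- karlin_altschul(sch)
  set.seed(15)
  n_checked <- 0
  for (i in 1:40) {
    q <- rand_dna(sample(40:100, 1))
    s_len <- sample(150:300, 1)
    core_len <- sample(15:28, 1)
    core_q <- sample.int(nchar(q) - core_len, 1)
    core <- mutate_dna(substr(q, core_q + 1, core_q + core_len), runif(1, 0, 0.15))
    ins <- sample.int(s_len - core_len, 1)
    s <- paste0(rand_dna(ins), core, rand_dna(s_len - ins - core_len))
    best <- smith_waterman(q, s, sch)
    if (!has_seed_in_alignment(best, q, s, sch$word_size)) next
    n_checked <- n_checked + 1
    hits <- seed_and_extend(q, s, sch, params = ka, options = opts,
                            both_strands = FALSE)
    expect_gt(nrow(hits), 0)
    expect_equal(max(hits$score), best$score)
  }
  expect_gte(n_checked, 15)
})

test_that("minus-strand hits mirror hits against the reverse-complemented subject", {
  set.seed(16)
  sub <- rand_dna(4000)
  frag <- revcomp(substr(sub, 1001, 1400))
  hits <- seed_and_extend(frag, sub)
  expect_equal(hits$strand, "-")
  expect_equal(hits$s_start, 1000L)
  expect_equal(hits$s_end, 1400L)

  hits_rc <- seed_and_extend(frag, revcomp(sub), both_strands = FALSE)
  n <- nchar(sub)
  expect_equal(sort(n - hits$s_end), sort(hits_rc$s_start))
  expect_equal(sort(n - hits$s_start), sort(hits_rc$s_end))
  expect_equal(sort(hits$score), sort(hits_rc$score))
})

test_that("circular queries recover origin-spanning insertions once", {
  set.seed(17)
  org_seq <- rand_dna(4000)
  org <- organelle_genome("mt", org_seq, kind = "mitochondrion",
                          circular = TRUE)
  wrap_frag <- paste0(substr(org_seq, 3801, 4000), substr(org_seq, 1, 200))
  # flanks hardened against chance continuation of the alignment
  not_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  left_pad <- paste(vapply(8:1, function(j)
    not_base(substr(org_seq, 3801 - j, 3801 - j)), character(1)),
    collapse = "")
  right_pad <- paste(vapply(1:8, function(j)
    not_base(substr(org_seq, 200 + j, 200 + j)), character(1)),
    collapse = "")
  sub <- paste0(rand_dna(1492), left_pad, wrap_frag, right_pad, rand_dna(1492))
  hits <- seed_and_extend(org, sub)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$q_start, 3800L)
  expect_equal(hits$q_end, 4200L) # q_end > length flags origin wrap
  expect_equal(hits$s_end - hits$s_start, 400L)

  # linear treatment of the same query reports two partial hits instead
  org_lin <- organelle_genome("mt", org_seq, kind = "mitochondrion",
                              circular = FALSE)
  hits_lin <- seed_and_extend(org_lin, sub)
  expect_equal(nrow(hits_lin), 2)
})

test_that("hits below the E-value cutoff are discarded", {
  set.seed(18)
  sub <- rand_dna(50000)
  # a 14 bp exact repeat seeds but cannot reach E <= 1e-4
  frag <- paste0(rand_dna(400), substr(sub, 101, 114))
  hits <- seed_and_extend(frag, sub, scoring_scheme(),
                          options = align_options(gap_trigger = 22))
  expect_true(all(hits$evalue <= 1e-4))
  expect_false(any(hits$aln_length < 25))
})
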