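test_that("simulated organelles meet their composition and feature contracts", {
  org <- simulate_organelle(length = 16000, gc = 0.5, seed = 71)
  gc_obs <- sum(strsplit(org$residues, "")[[1]] %in% c("G", "C")) / org$length
  expect_lt(abs(gc_obs - 0.5), 0.02)

  # determinism under a fixed seed
  org2 <- simulate_organelle(length = 16000, gc = 0.5, seed = 71)
  expect_identical(org$residues, org2$residues)
  expect_identical(org$features, org2$features)

  # features pairwise disjoint and in bounds
  f <- org$features
  if (nrow(f) > 1) {
    o <- order(f$start)
    expect_true(all(f$end[o][-nrow(f)] <= f$start[o][-1]))
  }
  expect_true(all(f$start >= 0 & f$end <= org$length))
  expect_error(simulate_organelle(length = 500), ">= 1 kb")
})

test_that("planted insertions carry exact ground truth", {
  org <- simulate_organelle(seed = 72)
  bg <- simulate_nuclear(3e5, seed = 73)
  cfg <- insertion_config(n_insertions = 30, exact_fraction = 0.3)
  pl <- plant_insertions(bg, org, cfg, seed = 74)
  truth <- pl$truth
  expect_equal(nrow(truth), 30)
  # pairwise disjoint
  o <- order(truth$start)
  expect_true(all(truth$end[o][-30] <= truth$start[o][-1]))

  nuc <- pl$assembly$records$residues[1]
  for (i in seq_len(nrow(truth))) {
    planted <- substr(nuc, truth$start[i] + 1, truth$end[i])
    src <- substr(org$residues, truth$q_start[i] + 1, truth$q_end[i])
    if (truth$strand[i] == "-") src <- revcomp(src)
    # truth-consistency: recomputed identity matches the recorded value
    same <- mapply(function(a, b) a == b,
                   strsplit(planted, "")[[1]], strsplit(src, "")[[1]])
    expect_equal(100 * mean(same), truth$realized_identity_pct[i])
    if (truth$target_identity_pct[i] == 100)
      expect_identical(planted, src)
    # realized within +-3 points of target for fragments >= 200 bp
    if (truth$end[i] - truth$start[i] >= 200)
      expect_lt(abs(truth$realized_identity_pct[i] -
                      truth$target_identity_pct[i]), 3)
  }
})

test_that("contaminant contigs are verbatim organellar substrings", {
  org <- simulate_organelle(seed = 75)
  contam <- make_contaminant_contigs(org, 5, c(2000, 6000), seed = 76)
  expect_equal(nrow(contam), 5)
  for (i in 1:5)
    expect_true(grepl(contam$residues[i], org$residues, fixed = TRUE))
  expect_equal(nrow(make_contaminant_contigs(org, 0)), 0)
})

test_that("pure-birth trees have the requested tips and positive branches", {
  expect_equal(ape::Ntip(simulate_tree(2, seed = 77)), 2)
  tr <- simulate_tree(25, seed = 78)
  expect_equal(ape::Ntip(tr), 25)
  expect_true(all(tr$edge.length > 0))
})

test_that("deeper trees arise from more tips at fixed birth rate", {
  set.seed(79)
  depth <- function(n) {
    mean(replicate(150, max(ape::node.depth.edgelength(
      simulate_tree(n, birth_rate = 1)))))
  }
  expect_lt(depth(5), depth(40))
})

test_that("traits simulated with lambda 0 are uncorrelated across tips", {
  tr <- simulate_tree(15, seed = 80)
  x <- rep(0, 15); names(x) <- tr$tip.label
  set.seed(81)
  ys <- replicate(800, simulate_traits(tr, x, lambda_true = 0, sigma2 = 1)$y)
  emp <- cor(t(ys))
  offdiag <- emp[upper.tri(emp)]
  expect_lt(mean(abs(offdiag)), 0.1)
})

test_that("paired designs follow the requested shift", {
  d0 <- make_paired_design(24, effect_delta = 0, seed = 82)
  expect_equal(nrow(d0), 24)
  d <- make_paired_design(10, effect_delta = 1000, seed = 83)
  expect_true(all(d$tolerant > d$control))
  expect_lt(wilcoxon_signed_rank(d$tolerant, d$control)$p_two_tailed, 0.01)
  expect_error(make_paired_design(3), "n_pairs")
})

test_that("recovery scoring is exact on canonical cases", {
  truth <- tibble::tibble(subject_id = "chr1", start = c(100L, 500L),
                          end = c(300L, 800L), kind = "NUMT",
                          strand = "+", q_start = 0L, q_end = 1L,
                          target_identity_pct = 100,
                          realized_identity_pct = 100)
  exact <- mk_segments()
  exact <- tibble::tibble(subject_id = "chr1", start = truth$start,
                          end = truth$end, length = truth$end - truth$start,
                          kind = "NUMT", best_identity_pct = 100,
                          n_hits = 1L, hit_ids = list("a", "b"))
  r <- evaluate_recovery(exact, truth)
  expect_equal(r$summary$recall, 1)
  expect_equal(r$summary$precision_bases, 1)
  expect_equal(r$summary$n_exact_boundary, 2)

  r0 <- evaluate_recovery(exact[0, ], truth)
  expect_equal(r0$summary$recall, 0)

  # invariant under relabeling of hit ids
  relabeled <- exact
  relabeled$hit_ids <- list("zz", "qq")
  expect_equal(evaluate_recovery(relabeled, truth)$summary, r$summary)
})
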