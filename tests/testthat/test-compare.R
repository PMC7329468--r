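test_that("lineage averaging takes arithmetic means and validates membership", {
  metrics <- tibble::tibble(species = c("Av", "Ar", "Rv"),
                            value = c(22, 4, 53))
  grouping <- tibble::tibble(lineage_id = c("bdelloid_tol", "bdelloid_tol",
                                            "tardigrade"),
                             species = c("Av", "Ar", "Rv"))
  out <- average_lineage(metrics, grouping)
  expect_equal(out$value[out$lineage_id == "bdelloid_tol"], 13)
  expect_equal(out$value[out$lineage_id == "tardigrade"], 53)

  # permutation invariance within a lineage
  out2 <- average_lineage(metrics, grouping[c(2, 1, 3), ])
  expect_equal(dplyr::arrange(out2, lineage_id),
               dplyr::arrange(out, lineage_id))

  expect_error(average_lineage(metrics[-2, ], grouping), "Ar")
  big <- tibble::tibble(lineage_id = "x", species = c("a", "b", "c"))
  expect_error(average_lineage(tibble::tibble(species = c("a", "b", "c"),
                                              value = 1:3), big), "at most 2")
})

test_that("signed-rank p-values are exact by construction on the 5-pair case", {
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(w$w_statistic, 0)
  expect_equal(w$p_two_tailed, 2 / 2^5)
  expect_equal(w$method, "exact")

  z <- wilcoxon_signed_rank(c(3, 3, 3), c(3, 3, 3))
  expect_equal(z$p_two_tailed, 1)
  expect_equal(z$n_effective, 0)

  a <- wilcoxon_signed_rank(c(5, 1, 9, 2), c(2, 8, 4, 7))
  b <- wilcoxon_signed_rank(c(2, 8, 4, 7), c(5, 1, 9, 2))
  expect_equal(a$p_two_tailed, b$p_two_tailed)
})

test_that("exact signed-rank p equals the sign-assignment enumeration oracle", {
  set.seed(41)
  for (n in 3:12) {
    for (rep in 1:3) {
      x <- runif(n) * 10
      y <- runif(n) * 10
      mine <- wilcoxon_signed_rank(x, y)
      expect_equal(mine$method, "exact")
      expect_equal(mine$p_two_tailed, enum_signrank_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("tied and large samples use the corrected normal approximation", {
  set.seed(42)
  x <- sample(1:8, 30, replace = TRUE)
  y <- sample(1:8, 30, replace = TRUE)
  keep <- x != y
  mine <- wilcoxon_signed_rank(x, y)
  expect_equal(mine$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$n_effective, sum(keep))
})

test_that("spearman rho and p behave canonically", {
  x <- c(1, 3, 7, 20, 50, 90)
  expect_equal(spearman_cor(x, x^2)$rho, 1)
  s <- spearman_cor(x, c(5, 1, 4, 2, 6, 3))
  s_rev <- spearman_cor(x, -c(5, 1, 4, 2, 6, 3))
  expect_equal(s$rho, -s_rev$rho)
  expect_equal(s$p_value, s_rev$p_value)
  expect_error(spearman_cor(x, rep(1, 6)), "constant")
})

test_that("small-sample spearman p matches full permutation enumeration", {
  set.seed(43)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    mine <- spearman_cor(x, y)
    expect_equal(mine$method, "exact_permutation")
    expect_equal(mine$p_value, enum_spearman_p(x, y), tolerance = 1e-12)
  }
})

test_that("assembly levels code to the two regression schemes", {
  asm <- tibble::tibble(
    species = c("a", "b", "c", "d"),
    assembly_level = c("contig", "scaffold", "chromosome", "complete"))
  c1 <- code_assembly_levels(asm, "contig_vs_rest")
  expect_equal(c1$code, c(1L, 2L, 2L, 2L))
  c2 <- code_assembly_levels(asm, "scaffold_vs_higher")
  expect_equal(c2$species, c("b", "c", "d"))
  expect_equal(c2$code, c(3L, 4L, 4L))
  asm$assembly_level[1] <- "draft"
  expect_error(code_assembly_levels(asm), "unknown")
})

test_that("paired comparisons run per metric with lineage averaging", {
  summaries <- tibble::tibble(
    species = letters[1:8],
    count = c(10, 20, 5, 8, 30, 31, 2, 2),
    total_length_bp = c(1e4, 2e4, 5e3, 8e3, 3e4, 3e4, 2e3, 2e3),
    genome_size_bp = rep(1e8, 8))
  summaries$count_per_mb <- summaries$count / 100
  summaries$length_per_mb <- summaries$total_length_bp / 100
  design <- tibble::tibble(
    pair_id = rep(c("p1", "p2", "p3"), times = c(4, 2, 2)),
    side = c("tolerant", "tolerant", "control", "control",
             "tolerant", "control", "tolerant", "control"),
    species = letters[1:8])
  res <- run_paired_comparisons(summaries, design)
  expect_equal(sort(unique(res$metric)),
               sort(c("count", "total_length_bp", "count_per_mb",
                      "length_per_mb")))
  expect_equal(unique(res$n_pairs), 3)

  # identical columns give p = 1
  same <- summaries
  same$count <- 7
  res_same <- run_paired_comparisons(same, design, metrics = "count")
  expect_equal(res_same$p_two_tailed, 1)

  # missing species data drops the pair with a warning
  expect_warning(
    res_drop <- run_paired_comparisons(summaries[-1, ], design,
                                       metrics = "count"),
    "p1")
  expect_equal(res_drop$n_pairs, 2)
})

test_that("group and genome-size subsets rerun the test per subset", {
  set.seed(44)
  n <- 12
  summaries <- tibble::tibble(
    species = sprintf("s%02d", 1:(2 * n)),
    count = rlnorm(2 * n, 2, 1),
    genome_size_bp = 10^runif(2 * n, 7, 9))
  design <- tibble::tibble(
    pair_id = rep(sprintf("p%02d", 1:n), each = 2),
    side = rep(c("tolerant", "control"), n),
    species = summaries$species,
    group = rep(c("invertebrate", "plant"), each = n))
  res <- run_paired_comparisons(summaries, design, metrics = "count",
                                subset_by_genome_size = TRUE)
  expect_setequal(res$subset, c("all", "invertebrate", "plant",
                                "small_genomes", "large_genomes"))
})
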