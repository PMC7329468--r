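#' Average per-species metrics into lineage values
#'
#' When one phylogenetic branch of a paired design contains two species, the
#' lineage value is the arithmetic mean of the two; single-species lineages
#' pass through.
#'
#' @param metrics Tibble with `species` and `value`.
#' @param grouping Tibble with `lineage_id` and `species`; each lineage has
#'   1-2 member species.
#' @return Tibble with `lineage_id`, `n_species`, `value`.
#' @export
average_lineage <- function(metrics, grouping) {
  missing <- setdiff(grouping$species, metrics$species)
  if (length(missing) > 0)
    abort(paste0("no metric value for species: ",
                 paste(missing, collapse = ", ")))
  sizes <- table(grouping$lineage_id)
  if (any(sizes > 2)) abort("a lineage may contain at most 2 species")
  g <- left_join(grouping, metrics[, c("species", "value")], by = "species")
  g <- dplyr::group_by(g, .data$lineage_id)
  out <- dplyr::summarise(g, n_species = dplyr::n(),
                          value = mean(.data$value), .groups = "drop")
  out
}

#' Two-tailed Wilcoxon signed-rank test for paired values
#'
#' Zero differences are dropped (the classical treatment); absolute
#' differences are mid-ranked. The statistic is the smaller of the positive
#' and negative rank sums. The p-value is exact by full enumeration of the
#' `2^n` sign assignments when `n_effective <= 25` and there are no tied
#' ranks; otherwise a normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y Paired value vectors (e.g. desiccation-tolerant and control
#'   lineage values).
#' @return A `norg_wilcoxon` object: `w_statistic`, `w_plus`,
#'   `n_effective`, `p_two_tailed`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_wilcoxon(w = 0, w_plus = 0, n = 0L, p = 1, method = "exact"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= 25) {
    # distribution of W+ over all sign assignments (integer ranks 1..n)
    f <- c(1, rep(0, n * (n + 1) / 2))
    for (rr in seq_len(n)) {
      shifted <- c(rep(0, rr), f[seq_len(length(f) - rr)])
      f <- f + shifted
    }
    probs <- f / 2^n
    p <- min(1, 2 * sum(probs[seq_len(w + 1)]))
    return(new_wilcoxon(w, w_plus, as.integer(n), p, "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- w_plus - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  new_wilcoxon(w, w_plus, as.integer(n), p, "normal_approx")
}

new_wilcoxon <- function(w, w_plus, n, p, method) {
  structure(list(w_statistic = w, w_plus = w_plus, n_effective = n,
                 p_two_tailed = p, method = method),
            class = "norg_wilcoxon")
}

#' @export
print.norg_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank (two-tailed, %s): W = %g, n = %d, p = %.4g\n",
    x$method, x$w_statistic, x$n_effective, x$p_two_tailed))
  invisible(x)
}

#' @export
tidy.norg_wilcoxon <- function(x, ...) {
  tibble(w_statistic = x$w_statistic, w_plus = x$w_plus,
         n_effective = x$n_effective, p_two_tailed = x$p_two_tailed,
         method = x$method)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' `rho` is the Pearson correlation of mid-ranked vectors. The two-sided
#' p-value is an exact permutation enumeration for `n <= 9` and a
#' t-distribution approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return A `norg_spearman` object: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    abort("rho undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    p <- spearman_perm_p_cpp(rx, ry)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    method <- "t_approx"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "norg_spearman")
}

#' @export
print.norg_spearman <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, n = %d, p = %.4g (%s)\n",
              x$rho, x$n, x$p_value, x$method))
  invisible(x)
}

#' @export
tidy.norg_spearman <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n = x$n, method = x$method)
}

#' Numeric codes for assembly levels
#'
#' Scheme `"contig_vs_rest"` codes contig-level assemblies 1 and all higher
#' levels 2. Scheme `"scaffold_vs_higher"` codes scaffold 3 and
#' chromosome/complete 4, excluding contig-level species.
#'
#' @param assemblies Tibble with `species` and `assembly_level`.
#' @param scheme Coding scheme.
#' @return Tibble with `species` and integer `code` (excluded species are
#'   absent).
#' @export
code_assembly_levels <- function(assemblies,
                                 scheme = c("contig_vs_rest",
                                            "scaffold_vs_higher")) {
  scheme <- match.arg(scheme)
  lv <- assemblies$assembly_level
  known <- c("contig", "scaffold", "chromosome", "complete")
  if (!all(lv %in% known))
    abort(paste0("unknown assembly level: ",
                 paste(setdiff(lv, known), collapse = ", ")))
  if (scheme == "contig_vs_rest") {
    code <- ifelse(lv == "contig", 1L, 2L)
    out <- tibble(species = assemblies$species, code = code)
  } else {
    keep <- lv != "contig"
    code <- ifelse(lv[keep] == "scaffold", 3L, 4L)
    out <- tibble(species = assemblies$species[keep], code = code)
  }
  attr(out, "scheme") <- scheme
  out
}

#' Paired lineage comparisons across content metrics
#'
#' For each metric, species values are averaged into lineages (two species
#' per branch at most), paired tolerant vs. control, and tested with the
#' two-tailed Wilcoxon signed-rank test. When `design` has a `group` column
#' the tests are rerun within each group; when `subset_by_genome_size` is
#' `TRUE` and genome sizes are available, the pairs are split at the median
#' of the pair-average genome size and rerun in each half.
#'
#' @param summaries Tibble with one row per species (and optionally `kind`)
#'   carrying metric columns and optionally `genome_size_bp`.
#' @param design Long-format paired design: `pair_id`, `side` (`"tolerant"`
#'   or `"control"`), `species`, optional `kind`, optional `group`.
#' @param metrics Metric columns to test.
#' @param subset_by_genome_size Also rerun within genome-size halves?
#' @return Tibble: `metric`, `subset`, `n_pairs`, `w_statistic`,
#'   `p_two_tailed`, `method`.
#' @export
run_paired_comparisons <- function(summaries, design,
                                   metrics = c("count", "total_length_bp",
                                               "count_per_mb",
                                               "length_per_mb"),
                                   subset_by_genome_size = FALSE) {
  stopifnot(all(c("pair_id", "side", "species") %in% names(design)))
  if (!all(design$side %in% c("tolerant", "control")))
    abort("design side must be 'tolerant' or 'control'")
  join_cols <- intersect(c("species", "kind"), names(design))
  join_cols <- intersect(join_cols, names(summaries))

  paired_values <- function(metric, des) {
    cols <- unique(c(join_cols, metric))
    if ("genome_size_bp" %in% names(summaries))
      cols <- c(cols, "genome_size_bp")
    sm <- summaries[, cols, drop = FALSE]
    d <- left_join(des, sm, by = join_cols, relationship = "many-to-one")
    if (anyNA(d[[metric]])) {
      bad_pairs <- unique(d$pair_id[is.na(d[[metric]])])
      warn(paste0("dropping pair(s) with missing data: ",
                  paste(bad_pairs, collapse = ", ")))
      d <- d[!d$pair_id %in% bad_pairs, , drop = FALSE]
    }
    if (nrow(d) == 0) return(NULL)
    g <- dplyr::group_by(d, .data$pair_id, .data$side)
    lv <- dplyr::summarise(g, value = mean(.data[[metric]]),
                           gsize = if ("genome_size_bp" %in% names(d))
                             mean(.data$genome_size_bp) else NA_real_,
                           .groups = "drop")
    wide <- tidyr::pivot_wider(lv, id_cols = "pair_id",
                               names_from = "side",
                               values_from = c("value", "gsize"))
    wide
  }

  one_test <- function(metric, des, label) {
    wide <- paired_values(metric, des)
    if (is.null(wide) || nrow(wide) == 0) return(NULL)
    wt <- wilcoxon_signed_rank(wide$value_tolerant, wide$value_control)
    tibble(metric = metric, subset = label, n_pairs = nrow(wide),
           w_statistic = wt$w_statistic, p_two_tailed = wt$p_two_tailed,
           method = wt$method)
  }

  out <- list()
  for (m in metrics) {
    out[[length(out) + 1]] <- one_test(m, design, "all")
    if ("group" %in% names(design)) {
      for (gg in unique(design$group))
        out[[length(out) + 1]] <-
          one_test(m, design[design$group == gg, , drop = FALSE], gg)
    }
    if (subset_by_genome_size && "genome_size_bp" %in% names(summaries)) {
      wide <- paired_values(m, design)
      if (!is.null(wide) && nrow(wide) >= 4) {
        gs <- rowMeans(wide[, c("gsize_tolerant", "gsize_control")])
        med <- stats::median(gs)
        for (half in c("small_genomes", "large_genomes")) {
          ids <- wide$pair_id[if (half == "small_genomes") gs <= med else gs > med]
          out[[length(out) + 1]] <-
            one_test(m, design[design$pair_id %in% ids, , drop = FALSE], half)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
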