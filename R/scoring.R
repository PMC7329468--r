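#' Scoring scheme for nucleotide local alignment
#'
#' Defaults reproduce the configuration used for organelle-vs-nucleus
#' surveys: match +2, mismatch -3, gap existence 5, gap extension 2, word
#' size 11, E-value cutoff 1e-4.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open Gap existence cost (>= 0).
#' @param gap_extend Gap extension cost per residue (>= 0).
#' @param word_size Exact-match seed length (>= 4).
#' @param evalue_max Hits with E above this are discarded.
#' @param gap_convention How a gap of length g is costed:
#'   `"open-plus-extend"` (the convention of the standard nucleotide search
#'   tool) charges `gap_open + gap_extend * g`; `"open-first"` charges
#'   `gap_open + gap_extend * (g - 1)`.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L, word_size = 11L,
                           evalue_max = 1e-4,
                           gap_convention = c("open-plus-extend", "open-first")) {
  gap_convention <- match.arg(gap_convention)
  if (match <= 0) abort("match reward must be positive")
  if (mismatch >= 0) abort("mismatch penalty must be negative")
  if (gap_open < 0 || gap_extend < 0) abort("gap costs must be non-negative")
  if (word_size < 4) abort("word size must be >= 4")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size),
                 evalue_max = evalue_max,
                 gap_convention = gap_convention),
            class = "scoring_scheme")
}

# cost charged at the first gapped residue
gap_first_cost <- function(scheme) {
  if (scheme$gap_convention == "open-plus-extend")
    scheme$gap_open + scheme$gap_extend
  else scheme$gap_open
}

#' Solve the Karlin-Altschul parameters for a scoring scheme
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`, found numerically to 1e-9.
#' `K` is computed by the classical ungapped series: with sigma the sum over
#' walk lengths i of `(P(S_i >= 0) + Ptilde(S_i < 0)) / i` (Ptilde the
#' exponentially tilted walk), `K = d * lambda * exp(-2 sigma) /
#' (H * (1 - exp(-lambda d)))` where `d` is the score lattice span and `H`
#' the relative entropy. The series is truncated when a term falls below
#' 1e-12 (at most 3000 terms); with two-point match/mismatch steps the
#' i-step walk is binomial, so each term is exact. Gapped searches reuse the
#' ungapped solution for the same substitution scores, a documented
#' approximation.
#'
#' @param scheme A [scoring_scheme()].
#' @param background Base frequencies (A, C, G, T), summing to 1.
#' @return List with `lambda` (nats per score unit), `K`, `H` (nats per
#'   aligned pair) and `background`, class `ka_params`.
#' @export
karlin_altschul <- function(scheme, background = rep(0.25, 4)) {
  if (abs(sum(background) - 1) > 1e-8 || any(background < 0))
    abort("background frequencies must be non-negative and sum to 1")
  p_match <- sum(background^2)
  p_mis <- 1 - p_match
  exp_score <- p_match * scheme$match + p_mis * scheme$mismatch
  if (exp_score >= 0)
    abort("invalid scoring scheme: expected per-residue score must be negative")
  f <- function(l) p_match * exp(l * scheme$match) +
    p_mis * exp(l * scheme$mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-12, hi), tol = 1e-12)$root
  H <- lambda * (scheme$match * p_match * exp(lambda * scheme$match) +
                   scheme$mismatch * p_mis * exp(lambda * scheme$mismatch))
  d <- gcd2(abs(scheme$match), abs(scheme$mismatch))
  sigma <- 0
  for (i in seq_len(3000)) {
    k <- 0:i
    s_vals <- k * scheme$match + (i - k) * scheme$mismatch
    pr <- stats::dbinom(k, i, p_match)
    inner <- sum(pr[s_vals >= 0]) +
      sum(pr[s_vals < 0] * exp(lambda * s_vals[s_vals < 0]))
    sigma <- sigma + inner / i
    if (inner / i < 1e-12) break
  }
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  structure(list(lambda = lambda, K = K, H = H, background = background),
            class = "ka_params")
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' @export
print.ka_params <- function(x, ...) {
  cat(sprintf("<ka_params> lambda = %.6f nats, K = %.4f, H = %.4f\n",
              x$lambda, x$K, x$H))
  invisible(x)
}

#' Karlin-Altschul expectation of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of distinct local
#' alignments scoring at least `S` between random sequences of lengths `m`
#' and `n`. Search-space lengths are raw sequence lengths (no edge-effect
#' correction).
#'
#' @param score Raw alignment score (>= 0).
#' @param m Query search-space length (bp).
#' @param n Subject search-space length (bp).
#' @param params A `ka_params` object from [karlin_altschul()].
#' @return E-value(s).
#' @export
evalue_of <- function(score, m, n, params) {
  if (any(score < 0)) abort("score must be non-negative")
  params$K * m * n * exp(-params$lambda * score)
}

#' Bit score of a raw alignment score
#' @inheritParams evalue_of
#' @return Bit score(s) `(lambda * S - ln K) / ln 2`.
#' @export
bitscore_of <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}
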