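#' Phylogenetic covariance matrix of a set of tips
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j;
#' the diagonal holds root-to-tip depths. Repeated tips (a species
#' contributing both a NUMT and a NUPT observation, the "two samples" rule)
#' are represented as two samples separated by a negligible internal branch:
#' their off-diagonal entry is the tip depth minus `dup_epsilon`, which
#' keeps the matrix non-singular.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param tips Character vector of tip labels, possibly with repeats;
#'   defaults to all tips.
#' @param dup_epsilon Branch length separating duplicated samples.
#' @return A `phylo_covariance` object: list with `v_matrix` (n x n) and
#'   `tips`.
#' @export
build_covariance <- function(tree, tips = NULL, dup_epsilon = 1e-8) {
  validate_tree(tree)
  if (is.null(tips)) tips <- tree$tip.label
  missing <- setdiff(unique(tips), tree$tip.label)
  if (length(missing) > 0)
    abort(paste0("tip(s) absent from tree: ", paste(missing, collapse = ", ")))
  v0 <- ape::vcv.phylo(tree)
  v <- v0[tips, tips, drop = FALSE]
  if (anyDuplicated(tips)) {
    same <- outer(tips, tips, "==")
    diag(same) <- FALSE
    v[same] <- v[same] - dup_epsilon
  }
  rownames(v) <- colnames(v) <- make.unique(tips)
  structure(list(v_matrix = v, tips = tips), class = "phylo_covariance")
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda`; the diagonal is unchanged.
#'
#' @param cov A `phylo_covariance` or a plain covariance matrix.
#' @param lambda Value in \[0, 1\].
#' @return The transformed matrix.
#' @export
lambda_transform <- function(cov, lambda) {
  v <- if (inherits(cov, "phylo_covariance")) cov$v_matrix else cov
  stopifnot(lambda >= 0, lambda <= 1)
  d <- diag(v)
  v <- v * lambda
  diag(v) <- d
  v
}

# GLS fit machinery for a fixed lambda; X is the design matrix
gls_at_lambda <- function(y, X, v, lambda, reml = FALSE) {
  vl <- lambda_transform(v, lambda)
  L <- tryCatch(chol(vl), error = function(e)
    abort("phylogenetic covariance is not positive definite"))
  # transform into iid space: z = L^{-T} is not needed; solve via chol
  zy <- backsolve(L, y, transpose = TRUE)
  zX <- backsolve(L, X, transpose = TRUE)
  colnames(zX) <- colnames(X)
  fit <- stats::lm.fit(zX, zy)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  n <- length(y); p <- ncol(X)
  logdet <- 2 * sum(log(diag(L)))
  if (reml) {
    s2 <- rss / (n - p)
    xtvx <- crossprod(zX)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdet +
                    determinant(xtvx, logarithm = TRUE)$modulus[1] +
                    (n - p))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  }
  list(beta = beta, rss = rss, sigma2 = s2, logLik = as.numeric(ll),
       zy = zy, zX = zX, L = L)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `trait ~ predictor` under error covariance `sigma^2 * V(lambda)`,
#' where V holds shared branch lengths and lambda scales the off-diagonal
#' entries. With `lambda = "ml"` the signal is estimated by maximizing the
#' profile log-likelihood over \[0, 1\] on a 0.01 grid followed by
#' golden-section refinement; a numeric `lambda` fixes it. The slope p-value
#' uses a t distribution with n - 2 degrees of freedom; R-squared is
#' computed in the whitened (V^-1/2-transformed) space against the
#' GLS-weighted mean.
#'
#' @param data Data frame with the trait, predictor and species columns.
#' @param trait,predictor Bare column names.
#' @param tree `ape::phylo` tree covering all species.
#' @param species Bare column name holding tip labels (repeats allowed; see
#'   [build_covariance()]).
#' @param lambda `"ml"` or a fixed value in \[0, 1\].
#' @param method `"ML"` (default) or `"REML"` likelihood for the lambda
#'   profile.
#' @return A `norg_pgls` object.
#' @export
pgls_fit <- function(data, trait, predictor, tree, species = species,
                     lambda = "ml", method = c("ML", "REML")) {
  method <- match.arg(method)
  y <- dplyr::pull(data, {{ trait }})
  x <- dplyr::pull(data, {{ predictor }})
  sp <- as.character(dplyr::pull(data, {{ species }}))
  n <- length(y)
  if (n < 3) abort("PGLS requires at least 3 observations")
  if (sd(x) == 0) abort("singular design: predictor is constant")
  cov <- build_covariance(tree, sp)
  v <- cov$v_matrix
  X <- cbind(`(Intercept)` = 1, slope = x)
  reml <- method == "REML"
  profile <- function(l) gls_at_lambda(y, X, v, l, reml)$logLik
  if (identical(lambda, "ml")) {
    grid <- seq(0, 1, by = 0.01)
    ll <- vapply(grid, profile, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(profile, c(lo, hi), maximum = TRUE,
                    tol = .Machine$double.eps^0.5)
    lambda_hat <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
    profile_tbl <- tibble(lambda = grid, logLik = ll)
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lambda_hat <- lambda
    profile_tbl <- NULL
  }
  fit <- gls_at_lambda(y, X, v, lambda_hat, reml = FALSE)
  # slope inference with the unbiased variance estimate
  s2_unb <- fit$rss / (n - 2)
  xtx_inv <- chol2inv(qr.R(qr(fit$zX)))
  se <- sqrt(diag(xtx_inv) * s2_unb)
  tstat <- fit$beta / se
  p_slope <- 2 * pt(-abs(tstat["slope"]), df = n - 2)
  # R^2 in the whitened space against the GLS mean
  one <- matrix(1, n, 1)
  z1 <- backsolve(fit$L, one, transpose = TRUE)
  zy <- fit$zy
  mu <- sum(z1 * zy) / sum(z1^2)
  tss <- sum((zy - mu * z1)^2)
  r2 <- 1 - fit$rss / tss
  structure(list(
    lambda = lambda_hat, slope = unname(fit$beta["slope"]),
    intercept = unname(fit$beta["(Intercept)"]),
    se_slope = unname(se["slope"]),
    r_squared = r2, p_value = unname(p_slope), n = n,
    sigma2 = fit$sigma2, logLik = fit$logLik,
    method = method, lambda_mode = if (identical(lambda, "ml")) "ml" else "fixed",
    profile = profile_tbl,
    data = tibble(species = sp, x = x, y = y)),
    class = "norg_pgls")
}

#' @export
print.norg_pgls <- function(x, ...) {
  cat(sprintf(
    "PGLS (Pagel's lambda, %s): lambda = %.3f, slope = %.4f, R^2 = %.3f, p = %.4g, n = %d\n",
    x$method, x$lambda, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.norg_pgls <- function(x, ...) {
  tibble(term = c("(Intercept)", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(NA_real_, x$se_slope),
         p.value = c(NA_real_, x$p_value))
}

#' @export
glance.norg_pgls <- function(x, ...) {
  tibble(lambda = x$lambda, r.squared = x$r_squared, slope = x$slope,
         p.value = x$p_value, sigma2 = x$sigma2, logLik = x$logLik,
         n = x$n, method = x$method)
}
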