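# Inter-reader agreement (weighted Cohen's kappa), pathologic response
# categorization, and the response-pathology correlation.

#' Inter-reader confusion matrix
#'
#' Cross-tabulates two readers' response categories over the fixed ordered
#' scale CR/PR/SD/PD.
#'
#' @param ratings_a,ratings_b Equal-length character vectors of categories.
#' @param categories Category order (default [response_categories()]).
#' @return A `confusion_matrix` object: integer matrix with readers A in rows,
#'   B in columns.
#' @export
confusion_matrix <- function(ratings_a, ratings_b,
                             categories = response_categories()) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors differ in length", call. = FALSE)
  }
  bad <- setdiff(c(ratings_a, ratings_b), categories)
  if (length(bad) > 0) {
    stop("invalid category label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fa <- factor(ratings_a, levels = categories)
  fb <- factor(ratings_b, levels = categories)
  m <- table(fa, fb)
  out <- matrix(as.integer(m), nrow = length(categories),
                dimnames = list(reader_a = categories, reader_b = categories))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordered categories, with partial credit for
#' near-miss disagreements: similarity weights `w_ij = 1 - |i - j|/(k - 1)`
#' (linear), `1 - (|i - j|/(k - 1))^2` (quadratic) or identity (none), and
#' `kappa = (po_w - pe_w) / (1 - pe_w)` where `po_w` and `pe_w` are the
#' weighted observed and chance agreement. The confidence interval uses the
#' large-sample (Fleiss-Cohen-Everitt) standard error; by convention the
#' upper bound is not truncated at 1 unless `truncate = TRUE`.
#'
#' When only two categories carry observations, the weighting scheme cancels
#' from both numerator and denominator, so linear, quadratic and unweighted
#' kappa coincide.
#'
#' @param m A `confusion_matrix` (or square count matrix).
#' @param weighting `"linear"` (default), `"quadratic"` or `"none"`.
#' @param conf_level Confidence level (default 0.95).
#' @param truncate Clamp the CI to the interval -1..1 (default `FALSE`).
#' @return A `kappa_result` list: `kappa`, `ci_low`, `ci_high`, `se`,
#'   `weighting`, `percent_agreement` (unweighted trace/total), `n`,
#'   `status` (`"ok"`, or `"undefined"` when chance agreement is exactly 1).
#' @export
weighted_kappa <- function(m, weighting = c("linear", "quadratic", "none"),
                           conf_level = 0.95, truncate = FALSE) {
  weighting <- match.arg(weighting)
  m <- unclass(as.matrix(m))
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(m)
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- switch(weighting, linear = 1 - d, quadratic = 1 - d^2,
              none = (d == 0) * 1)
  p <- m / n
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  po_w <- sum(w * p)
  pe_w <- sum(w * outer(pi_, pj_))
  pa <- sum(diag(p))
  if (1 - pe_w < .Machine$double.eps^0.5) {
    return(structure(list(kappa = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, se = NA_real_,
                          weighting = weighting, percent_agreement = pa,
                          n = n, status = "undefined"),
                     class = "kappa_result"))
  }
  kappa <- (po_w - pe_w) / (1 - pe_w)
  # Fleiss-Cohen-Everitt large-sample variance (non-null)
  wbar_i <- as.vector(w %*% pj_)   # row-wise expected weight
  wbar_j <- as.vector(pi_ %*% w)   # column-wise expected weight
  term <- outer(wbar_i, wbar_j, "+")
  s <- sum(p * (w - term * (1 - kappa))^2)
  var_k <- (s - (kappa - pe_w * (1 - kappa))^2) / (n * (1 - pe_w)^2)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- kappa - z * se
  hi <- kappa + z * se
  if (truncate) {
    lo <- max(lo, -1)
    hi <- min(hi, 1)
  }
  structure(list(kappa = kappa, ci_low = lo, ci_high = hi, se = se,
                 weighting = weighting, percent_agreement = pa, n = n,
                 status = "ok"),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$status != "ok") {
    cat("<kappa_result>", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("<kappa_result> kappa = %.3f (%.3f, %.3f), %s weights, agreement %.1f%% (n = %d)\n",
              x$kappa, x$ci_low, x$ci_high, x$weighting,
              100 * x$percent_agreement, x$n))
  invisible(x)
}

#' Pathologic response category from percent viable tumor
#'
#' Resection-specimen categories: complete response (no residual cancer
#' cells), major response (1% to 49% residual), minor response (>= 50%
#' residual). Fractions strictly between 0 and 1% are categorized as major.
#'
#' @param percent_viable Fraction of residual viable tumor between 0 and 1;
#'   vectorized.
#' @return Character vector among `"complete"`, `"major"`, `"minor"`.
#' @export
pathologic_category <- function(percent_viable) {
  if (any(!is.finite(percent_viable) | percent_viable < 0 |
            percent_viable > 1)) {
    stop("percent_viable must lie in [0, 1]", call. = FALSE)
  }
  ifelse(percent_viable == 0, "complete",
         ifelse(percent_viable < 0.50, "major", "minor"))
}

#' Spearman rank correlation with Fisher-z interval
#'
#' Mid-rank Spearman correlation; for two binary vectors it coincides with
#' the phi coefficient of the 2x2 table. The confidence interval uses the
#' Fisher z transform with standard error `1/sqrt(n - 3)` — an approximation,
#' reported alongside the asymptotic t-based p-value.
#'
#' @param x,y Equal-length numeric/ordinal vectors (length >= 3).
#' @return List with `rho`, `ci_low`, `ci_high`, `p_value`, `n`, `status`
#'   (`"undefined"` when either vector has zero variance).
#' @export
spearman_correlation <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(as.numeric(x)) == 0 || stats::var(as.numeric(y)) == 0) {
    return(list(rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, n = n, status = "undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- 1 / sqrt(n - 3)
  list(rho = rho, ci_low = tanh(z - zc * se), ci_high = tanh(z + zc * se),
       p_value = p, n = n, status = "ok")
}
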