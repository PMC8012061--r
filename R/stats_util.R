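#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by enumeration of the hypergeometric support
#' with fixed margins: all tables whose point probability does not exceed
#' that of the observed table (within a relative tolerance of 1e-7 for
#' floating-point ties) contribute to p. Point probabilities are computed
#' with exact log-factorials (`lgamma`). This is the conventional
#' "sum of small p-values" two-sided definition.
#'
#' Rows are groups, columns outcomes (e.g. delayed-SRP-best vs
#' standard-best cells per genotype).
#'
#' @param tab 2x2 matrix of non-negative integer counts, or the count `a`
#'   when `b`, `c`, `d` are given separately.
#' @param b,c,d optional scalar counts (row-wise: `a`,`b` top row).
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(10, 7, 16, 1), 2, byrow = TRUE)) # 0.0391
fisher_exact_2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) tab <- matrix(c(tab, b, c, d), 2, byrow = TRUE)
  stopifnot(is.matrix(tab), all(dim(tab) == 2))
  counts <- as.vector(t(tab))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty table")
  a <- counts[1]
  r1 <- counts[1] + counts[2]; r2 <- counts[3] + counts[4]
  c1 <- counts[1] + counts[3]
  n <- r1 + r2
  lp <- .hyper_log_pmf(r1, r2, c1)
  p_obs <- exp(lp[as.character(a)])
  p <- sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

# log point probabilities of all admissible tables with the given margins,
# named by the top-left count
.hyper_log_pmf <- function(r1, r2, c1) {
  n <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  lf <- function(x) lgamma(x + 1)
  lp <- lf(r1) + lf(r2) + lf(c1) + lf(n - c1) - lf(n) -
    (lf(k) + lf(r1 - k) + lf(c1 - k) + lf(r2 - c1 + k))
  names(lp) <- as.character(k)
  lp
}

#' Bin burst sizes by prestimulation calcium
#'
#' Cells are pooled into 0.2 uM prestimulation-calcium bins from 0 to
#' 0.8 uM plus a final 0.8–1.2 uM bin (5 bins total). Bins are left-closed,
#' right-open, except the final bin which is closed on both ends; cells
#' above the last edge are excluded and reported.
#'
#' @param pre_ca prestimulation calcium per cell, uM (>= 0).
#' @param burst burst size per cell, fF (secretion within 0.5 s of the
#'   flash).
#' @param edges bin edges, uM.
#' @return Data frame of class `titration_binning` with columns `lower`,
#'   `upper`, `n`, `mean`, `sem`; excluded cell count in
#'   `attr(, "n_excluded")`.
#' @export
bin_titration <- function(pre_ca, burst,
                          edges = c(0, 0.2, 0.4, 0.6, 0.8, 1.2)) {
  stopifnot(length(pre_ca) == length(burst), all(pre_ca >= 0),
            all(diff(edges) > 0))
  nb <- length(edges) - 1
  idx <- findInterval(pre_ca, edges, rightmost.closed = TRUE)
  excluded <- sum(idx == 0 | idx > nb)
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1])
  out$n <- vapply(seq_len(nb), function(j) sum(idx == j), integer(1))
  out$mean <- vapply(seq_len(nb), function(j)
    if (out$n[j] > 0) mean(burst[idx == j]) else NA_real_, numeric(1))
  out$sem <- vapply(seq_len(nb), function(j)
    if (out$n[j] > 1) stats::sd(burst[idx == j]) / sqrt(out$n[j])
    else NA_real_, numeric(1))
  structure(out, n_excluded = excluded,
            class = c("titration_binning", "data.frame"))
}
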