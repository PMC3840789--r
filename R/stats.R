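# Exact statistical primitives shared by the pipeline. These are authored
# in-house so every test in the pipeline can be audited against closed
# forms; the test suite cross-checks them against independent
# implementations and brute-force enumeration.

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value uses
#' the probability-mass convention: the sum of probabilities of all tables
#' (with the same margins) whose point probability does not exceed that of
#' the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled row-wise.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`; sidedness is
#'   with respect to the top-left cell.
#' @return The exact p-value.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.integer(table)
  if (length(x) != 4 || any(x < 0)) stop("need a 2x2 table of counts >= 0")
  if (sum(x) == 0) {
    warning("all-zero table; p = 1 by convention")
    return(1)
  }
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m <- a + b          # row 1 total
  n <- cc + d         # row 2 total
  k <- a + cc         # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  p <- p / sum(p)  # guard rounding
  obs <- p[support == a]
  switch(alternative,
    greater   = sum(p[support >= a]),
    less      = sum(p[support <= a]),
    two.sided = sum(p[p <= obs * (1 + 1e-7)])
  )
}

#' Exact binomial tail probability
#'
#' Tail sum of the binomial distribution, computed term by term from log
#' binomial coefficients; no normal approximation is used.
#'
#' @param k Observed successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param side `"greater"` (P(X >= k)) or `"less"` (P(X <= k)).
#' @return The exact tail probability.
#' @export
binomial_tail <- function(k, n, p0, side = c("greater", "less")) {
  side <- match.arg(side)
  if (k < 0 || k > n || p0 < 0 || p0 > 1) stop("invalid binomial arguments")
  support <- if (side == "greater") k:n else 0:k
  if (p0 == 0) return(if (side == "greater") as.numeric(k == 0) else 1)
  if (p0 == 1) return(if (side == "less") as.numeric(k == n) else 1)
  logp <- lchoose(n, support) + support * log(p0) + (n - support) * log1p(-p0)
  min(1, sum(exp(logp)))
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' @param p Vector of p-values (NAs allowed; they are never rejected and get
#'   NA q-values).
#' @param alpha FDR level, default 0.05.
#' @return A tibble with `p`, `q` (BH-adjusted) and `rejected`, in the input
#'   order.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- sum(!is.na(p))
  q <- rep(NA_real_, length(p))
  rejected <- rep(FALSE, length(p))
  if (m > 0) {
    ok <- which(!is.na(p))
    ord <- ok[order(p[ok])]
    ranked <- p[ord]
    q_sorted <- rev(cummin(rev(ranked * m / seq_len(m))))
    q[ord] <- pmin(1, q_sorted)
    pass <- which(ranked <= seq_len(m) * alpha / m)
    if (length(pass) > 0) rejected[ord[seq_len(max(pass))]] <- TRUE
  }
  tibble(p = p, q = q, rejected = rejected)
}

#' Chi-squared goodness-of-fit test
#'
#' Pearson statistic against expected category proportions, with
#' `length(observed) - 1` degrees of freedom.
#'
#' @param observed Vector of observed counts.
#' @param expected_props Expected proportions (normalised internally).
#' @return A tibble with `statistic`, `dof` and `p`.
#' @export
chi_squared_gof <- function(observed, expected_props) {
  if (length(observed) != length(expected_props)) stop("length mismatch")
  if (any(expected_props <= 0)) stop("expected proportions must be positive")
  e <- expected_props / sum(expected_props) * sum(observed)
  stat <- sum((observed - e)^2 / e)
  dof <- length(observed) - 1L
  tibble(statistic = stat, dof = dof, p = pchisq(stat, dof, lower.tail = FALSE))
}

#' Mann-Whitney rank-sum test
#'
#' The U statistic is computed from midranks. For 20 or fewer combined
#' observations the null distribution of U is obtained by full enumeration
#' of group assignments (exact even under ties); larger samples use the
#' normal approximation with the standard tie correction for the variance.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (with respect
#'   to `x`).
#' @return A tibble with `U`, `p` and `method`.
#' @export
rank_sum <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("need at least one value per group")
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  U <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 20) {
    combos <- combn(n1 + n2, n1)
    us <- apply(combos, 2, u_of)
    p <- switch(alternative,
      greater   = mean(us >= U - 1e-9),
      less      = mean(us <= U + 1e-9),
      two.sided = mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    )
    method <- "exact enumeration"
  } else {
    nt <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- switch(alternative,
      greater   = stats::pnorm(z, lower.tail = FALSE),
      less      = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(-abs(z))
    )
    p <- min(1, p)
    method <- "normal approximation"
  }
  tibble(U = U, p = p, method = method)
}
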