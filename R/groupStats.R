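## Mid-ranks of the pooled sample plus the tie-correction sum  T = sum(t^3 - t)
pooledRanks <- function(values) {
  r <- rank(values, ties.method = "average")
  t <- table(values)
  list(ranks = r, tieSum = sum(t^3 - t))
}

#' Kruskal-Wallis rank test with tie correction
#'
#' H is computed on mid-ranks,
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - (N+1)/2)^2,}
#' then corrected for ties by dividing by
#' \eqn{1 - \sum (t^3 - t) / (N^3 - N)}. The p value comes from the
#' chi-square distribution with k-1 degrees of freedom. When all pooled
#' values are identical the statistic is undefined (reported as \code{NA}
#' with p = 1).
#'
#' @param groups list of >= 2 numeric vectors (each n >= 1, total N >= 3).
#' @return a \linkS4class{GroupTestResult}.
#' @examples
#' testStatistic(kruskalWallis(list(1:3, 4:6, 7:9)))  # H = 7.2
#' @export
kruskalWallis <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- lengths(groups)
  if (any(n < 1L)) stop("each group needs at least 1 value")
  N <- sum(n)
  if (N < 3L) stop("need total N >= 3")
  pooled <- unlist(groups, use.names = FALSE)
  pr <- pooledRanks(pooled)
  gid <- rep(seq_len(k), n)
  meanRanks <- tapply(pr$ranks, gid, mean)
  H <- 12 / (N * (N + 1)) * sum(n * (meanRanks - (N + 1) / 2)^2)
  corr <- 1 - pr$tieSum / (N^3 - N)
  if (corr <= 0) {                      # all values identical
    return(new("GroupTestResult", statistic = NA_real_, pValue = 1,
               method = "Kruskal-Wallis rank test (degenerate: all values tied)",
               groupSizes = as.integer(n), pairwise = data.frame()))
  }
  H <- H / corr
  p <- stats::pchisq(H, df = k - 1L, lower.tail = FALSE)
  new("GroupTestResult", statistic = H, pValue = p,
      method = "Kruskal-Wallis rank test (tie-corrected)",
      groupSizes = as.integer(n), pairwise = data.frame())
}

#' Dunn's multiple-comparison test after Kruskal-Wallis
#'
#' Pairwise z statistics on the pooled mid-ranks,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12}
#'   - \frac{\sum(t^3-t)}{12(N-1)}\right)\left(\frac1{n_i}+\frac1{n_j}\right)}},}
#' with two-sided normal p values adjusted by the chosen correction
#' (default Holm, which dominates Bonferroni and is deterministic).
#'
#' @param groups list of >= 3 numeric vectors (use the rank-sum test for 2).
#' @param correction one of \code{"holm"}, \code{"bonferroni"},
#'   \code{"none"}.
#' @return a \linkS4class{GroupTestResult} whose \code{pairwise} table has
#'   columns group_i, group_j, z, p, p_adj. The statistic/pValue slots carry
#'   the omnibus Kruskal-Wallis result on the same groups.
#' @export
dunnPosthoc <- function(groups, correction = c("holm", "bonferroni", "none")) {
  correction <- match.arg(correction)
  k <- length(groups)
  if (k < 3L) stop("Dunn's test needs >= 3 groups; use wilcoxonRankSum for 2")
  kw <- kruskalWallis(groups)
  n <- lengths(groups)
  N <- sum(n)
  pooled <- unlist(groups, use.names = FALSE)
  pr <- pooledRanks(pooled)
  gid <- rep(seq_len(k), n)
  meanRanks <- tapply(pr$ranks, gid, mean)
  gnames <- if (!is.null(names(groups))) names(groups) else
    paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  varTerm <- N * (N + 1) / 12 - pr$tieSum / (12 * (N - 1))
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    (meanRanks[i] - meanRanks[j]) /
      sqrt(varTerm * (1 / n[i] + 1 / n[j]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(group_i = gnames[pairs[1, ]],
                    group_j = gnames[pairs[2, ]],
                    z = z, p = p,
                    p_adj = stats::p.adjust(p, method = correction))
  new("GroupTestResult", statistic = kw@statistic, pValue = kw@pValue,
      method = sprintf("Dunn's multiple-comparison test (%s)", correction),
      groupSizes = as.integer(n), pairwise = tab)
}

## Exact two-sided rank-sum p: enumerate all C(N, nx) assignments of ranks
## to x and count |U - mu| >= |u_obs - mu|. Only valid without ties.
wilcoxonExactP <- function(ranksX, nx, ny) {
  N <- nx + ny
  u_obs <- sum(ranksX) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  combos <- utils::combn(N, nx)
  U <- colSums(matrix(seq_len(N)[combos], nrow = nx)) - nx * (nx + 1) / 2
  mean(abs(U - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. For \code{min(nx, ny) <= 8} with no ties, the p value is
#' computed from the exact permutation distribution of U (full enumeration
#' of rank assignments). Otherwise the normal approximation is used with
#' tie-corrected variance
#' \eqn{\sigma^2 = \frac{n_x n_y}{12}\left(N + 1 - \frac{\sum(t^3-t)}{N(N-1)}\right)}
#' and a 0.5 continuity correction.
#'
#' @param x,y numeric vectors (each n >= 1).
#' @return a \linkS4class{GroupTestResult}; the statistic is U for x.
#' @examples
#' pValue(wilcoxonRankSum(c(1, 2), c(3, 4)))  # exact: 1/3
#' @export
wilcoxonRankSum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both samples need at least 1 value")
  pooled <- c(x, y)
  pr <- pooledRanks(pooled)
  ranksX <- pr$ranks[seq_len(nx)]
  U <- sum(ranksX) - nx * (nx + 1) / 2
  N <- nx + ny
  noTies <- pr$tieSum == 0
  if (noTies && min(nx, ny) <= 8L) {
    p <- wilcoxonExactP(ranksX, nx, ny)
    method <- "Wilcoxon rank-sum test (exact)"
  } else {
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * (N + 1 - pr$tieSum / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zNum <- max(abs(U - mu) - 0.5, 0)
      p <- min(1, 2 * stats::pnorm(-zNum / sqrt(sigma2)))
    }
    method <- "Wilcoxon rank-sum test (normal approximation, tie-corrected)"
  }
  new("GroupTestResult", statistic = U, pValue = p, method = method,
      groupSizes = c(nx, ny), pairwise = data.frame())
}
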