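new_fp_stat <- function(test, statistic, p_value, n, method,
                        comparisons = NULL, extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    c(list(test = test, statistic = statistic,
           p_value = min(p_value, 1), n = n, method = method,
           comparisons = comparisons), extra),
    class = "fp_stat"
  )
}

#' @export
print.fp_stat <- function(x, ...) {
  cat(sprintf("<fp_stat> %s (%s)\n", x$test, x$method))
  cat(sprintf("  statistic = %.4g, p = %.4g, n = %s\n",
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}

# mid-ranks of |x|
mid_ranks <- function(x) rank(abs(x), ties.method = "average")

#' Two-sided Wilcoxon signed-rank test with exact enumeration
#'
#' Paired two-sample (or one-sample) signed-rank test. Zero differences are
#' dropped (Wilcoxon's rule; `zero_method = "pratt"` keeps them in the
#' ranking). For `n <= exact_limit` (15) remaining pairs the two-sided p
#' value is exact, from full enumeration of all `2^n` sign assignments of
#' the mid-ranked absolute differences; beyond that a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Paired numeric vectors (`y` omitted for a one-sample test
#'   against zero).
#' @param exact_limit Largest n for the exact enumeration.
#' @param zero_method `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @param correct Continuity correction for the normal approximation.
#' @return An `fp_stat` with the signed-rank statistic W (sum of ranks of
#'   positive differences).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 15,
                                 zero_method = c("wilcoxon", "pratt"),
                                 correct = TRUE) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) abort("x and y must have equal length")
    x - y
  }
  d <- d[is.finite(d)]
  nz <- d != 0
  if (!any(nz)) {
    warn("all differences are zero; p = 1")
    return(new_fp_stat("wilcoxon_signed_rank", statistic = 0, p_value = 1,
                       n = 0, method = "degenerate"))
  }
  if (zero_method == "wilcoxon") d <- d[nz]
  if (sum(d != 0) < 3) abort("need at least 3 nonzero differences")
  r <- mid_ranks(d)
  w_obs <- sum(r[d > 0])
  n <- length(d)
  # with Pratt zeros the zero ranks never count toward W under any sign
  r_eff <- r[d != 0]
  w_eff <- w_obs
  if (n <= exact_limit) {
    dist <- signed_rank_distribution(r_eff)
    p <- two_sided_tail(dist, w_eff)
    return(new_fp_stat("wilcoxon_signed_rank", statistic = w_obs,
                       p_value = p, n = n, method = "exact"))
  }
  mu <- sum(r_eff) / 2
  v <- sum(r_eff^2) / 4
  z_num <- w_obs - mu
  if (correct) z_num <- z_num - sign(z_num) * 0.5
  z <- z_num / sqrt(v)
  p <- 2 * pnorm(-abs(z))
  new_fp_stat("wilcoxon_signed_rank", statistic = w_obs, p_value = min(1, p),
              n = n, method = "asymptotic", extra = list(z = z))
}

# all attainable W values (sum of ranks with + sign) over 2^n assignments
signed_rank_distribution <- function(r) {
  w <- 0
  for (ri in r) w <- c(w, w + ri)
  w
}

two_sided_tail <- function(dist, obs) {
  eps <- 1e-9
  lo <- mean(dist <= obs + eps)
  hi <- mean(dist >= obs - eps)
  min(1, 2 * min(lo, hi))
}

#' Two-sided Mann-Whitney U test with exact enumeration
#'
#' Unpaired rank-sum test. For pooled sample sizes up to `exact_limit` (16)
#' the two-sided p value is exact: the U statistic is evaluated over every
#' arrangement of the pooled observed values into the two groups
#' (mid-ranks make this valid under ties as well). Larger samples use the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b Numeric group vectors (both nonempty).
#' @param exact_limit Largest pooled size for the exact enumeration.
#' @param correct Continuity correction for the normal approximation.
#' @return An `fp_stat` with the U statistic of group `a`.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 16, correct = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) abort("both groups must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= exact_limit) {
    combs <- utils::combn(n, na)
    rank_sums <- colSums(matrix(r[combs], nrow = na))
    u_dist <- rank_sums - na * (na + 1) / 2
    p <- two_sided_tail(u_dist, u_obs)
    return(new_fp_stat("mann_whitney_u", statistic = u_obs, p_value = p,
                       n = c(na, nb), method = "exact"))
  }
  mu <- na * nb / 2
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  v <- na * nb / 12 * ((n + 1) - tie_corr)
  z_num <- u_obs - mu
  if (correct) z_num <- z_num - sign(z_num) * 0.5
  z <- z_num / sqrt(v)
  p <- 2 * pnorm(-abs(z))
  new_fp_stat("mann_whitney_u", statistic = u_obs, p_value = min(1, p),
              n = c(na, nb), method = "asymptotic", extra = list(z = z))
}

#' Friedman test for complete randomized blocks
#'
#' Tie-corrected chi-square Friedman statistic (wraps
#' [stats::friedman.test()]). Blocks are rows; each block must be complete.
#'
#' @param blocked A numeric matrix or data frame, `n_blocks x k_treatments`.
#' @return An `fp_stat`.
#' @export
friedman_rank <- function(blocked) {
  m <- as.matrix(blocked)
  if (ncol(m) < 3) abort("need k >= 3 treatments")
  bad <- which(!stats::complete.cases(m))
  if (length(bad) > 0) {
    abort(sprintf("incomplete block(s): %s", paste(bad, collapse = ", ")))
  }
  if (all(apply(m, 1, function(r) diff(range(r)) == 0))) {
    return(new_fp_stat("friedman", statistic = 0, p_value = 1,
                       n = nrow(m), method = "degenerate"))
  }
  ft <- stats::friedman.test(m)
  new_fp_stat("friedman", statistic = unname(ft$statistic),
              p_value = ft$p.value, n = nrow(m), method = "asymptotic")
}

#' Kruskal-Wallis test
#'
#' Tie-corrected chi-square Kruskal-Wallis statistic (wraps
#' [stats::kruskal.test()]).
#'
#' @param groups List of numeric vectors.
#' @return An `fp_stat`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) abort("need at least 2 groups")
  if (diff(range(unlist(groups))) == 0) {
    return(new_fp_stat("kruskal_wallis", statistic = 0, p_value = 1,
                       n = lengths(groups), method = "degenerate"))
  }
  kt <- stats::kruskal.test(groups)
  new_fp_stat("kruskal_wallis", statistic = unname(kt$statistic),
              p_value = kt$p.value, n = lengths(groups),
              method = "asymptotic")
}

# standardized pairwise rank-sum z for two groups (tie-corrected, no cc)
pairwise_ranksum_z <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  r <- rank(c(g1, g2), ties.method = "average")
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  tie_tab <- table(r)
  v <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (v <= 0) return(0)
  (w - mu) / sqrt(v)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For each pair of groups, the Wilcoxon rank-sum statistic of the pair is
#' standardized under the null and `sqrt(2) * |z|` is referred to the
#' studentized-range distribution with `k` groups and infinite degrees of
#' freedom, giving familywise-adjusted p values.
#'
#' @param groups Named list of numeric vectors (k >= 2, each n >= 2).
#' @param alpha Family significance level recorded in the decision column.
#' @return An `fp_stat` whose `comparisons` tibble has one row per pair
#'   (`group1`, `group2`, `z`, `p_adj`, `significant`); the overall
#'   `p_value` is the smallest adjusted p.
#' @export
steel_dwass <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) abort("need at least 2 groups")
  if (any(lengths(groups) < 2)) abort("every group needs n >= 2")
  nms <- names(groups) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  comp <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    z <- pairwise_ranksum_z(groups[[i1]], groups[[i2]])
    p <- ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf, lower.tail = FALSE)
    tibble(group1 = nms[i1], group2 = nms[i2], z = z, p_adj = p)
  })
  comp$significant <- comp$p_adj < alpha
  new_fp_stat("steel_dwass", statistic = max(abs(comp$z)),
              p_value = min(comp$p_adj), n = lengths(groups),
              method = "asymptotic", comparisons = comp)
}

# P(max_j |Z_j| >= q) for m equicorrelated (rho = 0.5) standard normals,
# by 1-D quadrature over the shared component: Z_j = (W + E_j)/sqrt(2)
steel_max_tail <- function(q, m) {
  if (q <= 0) return(1)
  f <- function(w) {
    stats::dnorm(w) *
      (pnorm(q * sqrt(2) - w) - pnorm(-q * sqrt(2) - w))^m
  }
  keep <- integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  1 - keep
}

#' Steel many-to-one nonparametric comparison against a control
#'
#' Each treatment group is compared with the control by a standardized
#' pairwise rank-sum z; the familywise-adjusted p refers `|z|` to the
#' distribution of the maximum absolute value of `k - 1` equicorrelated
#' (`rho = 0.5`) standard normals. That maximum probability reduces to a
#' one-dimensional integral over the shared component, evaluated by
#' adaptive quadrature (deterministic; see the methods vignette).
#'
#' @param groups Named list of numeric vectors.
#' @param control Index or name of the control group.
#' @param alpha Family significance level.
#' @return An `fp_stat` with one comparison row per treatment group.
#' @export
steel_test <- function(groups, control = 1, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) abort("need at least 2 groups")
  if (any(lengths(groups) < 2)) abort("every group needs n >= 2")
  nms <- names(groups) %||% as.character(seq_len(k))
  ci <- if (is.character(control)) match(control, nms) else control
  if (is.na(ci) || ci < 1 || ci > k) abort("invalid control group")
  treats <- setdiff(seq_len(k), ci)
  m <- length(treats)
  comp <- purrr::map_dfr(treats, function(i) {
    z <- pairwise_ranksum_z(groups[[i]], groups[[ci]])
    tibble(group1 = nms[i], group2 = nms[ci], z = z,
           p_adj = steel_max_tail(abs(z), m))
  })
  comp$significant <- comp$p_adj < alpha
  new_fp_stat("steel", statistic = max(abs(comp$z)),
              p_value = min(comp$p_adj), n = lengths(groups),
              method = "quadrature", comparisons = comp)
}

#' Significance markers for a results table
#'
#' @param p Numeric p values.
#' @return Character: `**` below 0.01, `*` below 0.05, empty otherwise.
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", .default = "")
}
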