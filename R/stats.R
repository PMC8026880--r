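# Per-bin two-group nonparametric comparison. The U statistic is reported
# as min(U_A, U_B) with midrank ties; p is exact (full enumeration of group
# labelings) for small tie-free samples, otherwise a normal approximation
# with tie and continuity corrections. Two-sided throughout.

#' Mann-Whitney U test
#'
#' @param a,b numeric samples; NAs are dropped first.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact enumeration;
#'   default: exact when `length(a) + length(b) <= 12` and there are no
#'   ties.
#' @return list: `U` (min of the two one-sided statistics), `p` (two-sided),
#'   `n_a`, `n_b`, `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("both groups need at least one defined value")
  pooled <- c(a, b)
  rk <- rank(pooled)               # midranks
  Ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  U <- min(Ua, Ub)
  ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) exact <- (na + nb <= 12) && !ties
  if (exact && ties)
    warning("ties present; exact enumeration uses midranks")
  if (exact) {
    idx <- combn(na + nb, na)
    rksum <- colSums(matrix(rk[idx], nrow = na))
    Ua_perm <- rksum - na * (na + 1) / 2
    U_perm <- pmin(Ua_perm, na * nb - Ua_perm)
    p <- mean(U_perm <= U + 1e-9)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    nn <- na + nb
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sigma2 <- na * nb / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, n_a = na, n_b = nb,
                                 method = "normal"))
    z <- (U - mu + 0.5) / sqrt(sigma2)   # U <= mu; continuity correction
    p <- min(1, 2 * pnorm(z))
    method <- "normal"
  }
  list(U = U, p = p, n_a = na, n_b = nb, method = method)
}

#' Per-bin group comparison of two binned series
#'
#' Runs a two-sided Mann-Whitney U test on the per-fly values of the two
#' groups in every bin. Bins where either group has no defined values are
#' marked untestable. No multiple-testing correction by default (each bin is
#' reported at its own alpha); Benjamini-Hochberg is available via
#' `p_adjust = "BH"`.
#'
#' @param series_a,series_b data.frames with columns `fly_id`, `bin_start`,
#'   `value` (one row per fly per bin; NA = undefined), for groups A and B.
#'   Bin grids must match.
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return data.frame (class `group_comparison`): bin_start, U, p, n_a,
#'   n_b, significant, testable.
#' @export
compare_bins <- function(series_a, series_b, alpha = 0.05,
                         p_adjust = "none") {
  bins_a <- sort(unique(series_a$bin_start))
  bins_b <- sort(unique(series_b$bin_start))
  if (!isTRUE(all.equal(bins_a, bins_b)))
    stop("bin grids of the two series do not match")
  out <- do.call(rbind, lapply(bins_a, function(b) {
    va <- series_a$value[series_a$bin_start == b]
    vb <- series_b$value[series_b$bin_start == b]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) == 0 || length(vb) == 0)
      return(data.frame(bin_start = b, U = NA_real_, p = NA_real_,
                        n_a = length(va), n_b = length(vb),
                        testable = FALSE))
    mw <- mann_whitney_u(va, vb)
    data.frame(bin_start = b, U = mw$U, p = mw$p,
               n_a = mw$n_a, n_b = mw$n_b, testable = TRUE)
  }))
  if (p_adjust != "none")
    out$p[out$testable] <- p.adjust(out$p[out$testable], method = p_adjust)
  out$significant <- !is.na(out$p) & out$p < alpha
  class(out) <- c("group_comparison", "data.frame")
  attr(out, "alpha") <- alpha
  out
}
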