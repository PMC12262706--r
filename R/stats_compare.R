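# Nonparametric group comparison and effect sizes, with the annotation
# scheme used in the figure legends: star tiers by p value, overridden to
# "ns" when the Cliff's delta effect size is negligible.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (combined n <= 20, or
#' \code{exact = TRUE}) the null distribution of U is enumerated exhaustively
#' over all group assignments of the observed (mid)ranks, which remains valid
#' under ties; otherwise the normal approximation with tie-corrected variance
#' is used, with optional continuity correction. Always satisfies
#' \code{U_x + U_y = n_x * n_y}.
#'
#' @param x,y nonempty numeric samples.
#' @param exact force (TRUE) or forbid (FALSE) exact enumeration; NULL picks
#'   by the n <= 20 rule.
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation (default TRUE).
#' @return list with \code{U} (statistic for x), \code{p_value},
#'   \code{method} ("exact" or "normal"), \code{n_x}, \code{n_y}.
#' @export
mann_whitney <- function(x, y, exact = NULL, continuity = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop_domain("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  use_exact <- exact %||% (nx + ny <= 20L)
  if (use_exact) {
    combs <- utils::combn(nx + ny, nx)
    Uall <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- 2 * min(mean(Uall <= U + 1e-9), mean(Uall >= U - 1e-9))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    nt <- table(r)
    N <- nx + ny
    v <- nx * ny / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- U - mu
      if (continuity) z <- sign(z) * max(abs(z) - 0.5, 0)
      p <- 2 * stats::pnorm(-abs(z) / sqrt(v))
    }
    method <- "normal"
  }
  list(U = U, p_value = min(p, 1), method = method, n_x = nx, n_y = ny)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction and chi-squared p value on
#' k - 1 degrees of freedom (delegated to \code{stats::kruskal.test}). The
#' fully degenerate case (all observations identical) is returned as H = 0,
#' p = 1 with a flag instead of an error.
#'
#' @param groups list of >= 2 nonempty numeric samples.
#' @return list with \code{H}, \code{p_value}, \code{df}, \code{flag}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_domain("groups must be a list of >= 2 samples")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop_domain("all groups must be nonempty")
  allv <- unlist(groups)
  if (length(unique(allv)) == 1L)
    return(list(H = 0, p_value = 1, df = length(groups) - 1L,
                flag = "degenerate_all_tied"))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), flag = NA_character_)
}

#' Cliff's delta effect size
#'
#' \code{delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)}, in [-1, 1].
#' Computed in O((n_x + n_y) log) time via sorted-rank counting. The effect
#' label uses the conventional thresholds: |delta| < 0.147 negligible,
#' < 0.33 small, < 0.474 medium, else large (half-open intervals).
#'
#' @param x,y nonempty numeric samples.
#' @return list with \code{delta} and \code{effect_label}.
#' @export
cliffs_delta <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop_domain("both samples must be nonempty")
  ys <- sort(y)
  lt <- findInterval(x, ys, left.open = TRUE)   # per x_i: #{y_j < x_i}
  leq <- findInterval(x, ys)                    # per x_i: #{y_j <= x_i}
  gt <- length(y) - leq
  delta <- (sum(lt) - sum(gt)) / (length(x) * length(y))
  a <- abs(delta)
  label <- if (a < 0.147) "negligible" else if (a < 0.33) "small"
           else if (a < 0.474) "medium" else "large"
  list(delta = delta, effect_label = label)
}

#' Significance annotation string
#'
#' Figure-legend scheme: \code{"ns"} when 0.05 < p <= 1 \emph{or}
#' |delta| < 0.147 (a negligible effect overrides even tiny p values);
#' otherwise \code{"*"} for 0.01 < p <= 0.05, \code{"**"} for
#' 0.001 < p <= 0.01, \code{"***"} for 0.0001 < p <= 0.001 and
#' \code{"****"} for p <= 0.0001.
#'
#' @param p p value in [0, 1].
#' @param delta Cliff's delta in [-1, 1].
#' @return annotation string.
#' @export
annotate_significance <- function(p, delta) {
  if (!is.finite(p) || p < 0 || p > 1) stop_domain("p must lie in [0, 1]")
  if (p > 0.05 || abs(delta) < 0.147) return("ns")
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**" else "*"
}

#' Full two-group comparison
#'
#' Mann-Whitney U, Cliff's delta and the annotation string in one record,
#' the unit emitted by the comparison tables.
#'
#' @param x,y samples.
#' @param names group names.
#' @param ... passed to \code{\link{mann_whitney}}.
#' @return a one-row data frame (class \code{group_comparison}).
#' @export
compare_groups <- function(x, y, names = c("x", "y"), ...) {
  mw <- mann_whitney(x, y, ...)
  cd <- cliffs_delta(x, y)
  out <- data.frame(group_x = names[1L], group_y = names[2L],
                    test = paste0("Mann-Whitney U (", mw$method, ")"),
                    statistic = mw$U, p_value = mw$p_value,
                    cliffs_delta = cd$delta, effect_label = cd$effect_label,
                    annotation = annotate_significance(mw$p_value, cd$delta),
                    n_x = mw$n_x, n_y = mw$n_y,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}
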