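#' Tie-corrected Kruskal-Wallis test
#'
#' Omnibus nonparametric comparison of k independent groups on pooled
#' ranks: `H = [12 / (N (N + 1)) * sum(n_i * Rbar_i^2)] - 3 (N + 1)`,
#' divided by the tie-correction factor
#' `1 - sum(t_j^3 - t_j) / (N^3 - N)` over tie groups of size `t_j`; the
#' p-value is the chi-square upper tail with `k - 1` degrees of freedom.
#' When every observation is identical the statistic is defined as 0 with
#' p = 1.  The chi-square approximation is standard practice; group sizes
#' of at least 5 are recommended for a trustworthy p-value.
#'
#' @param groups Named list of numeric vectors, one per group (k >= 2,
#'   each non-empty, total N >= 3).
#' @return List with elements `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 1))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  stopifnot(N >= 3)
  k <- length(groups)
  g <- rep(seq_len(k), times = vapply(groups, length, integer(1)))
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- tabulate(g, k)
  H0 <- 12 / (N * (N + 1)) * sum(n_i * rbar^2) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) return(list(H = 0, p = 1, df = k - 1L))  # all values identical
  H <- H0 / C
  list(H = H, p = pchisq(H, df = k - 1, lower.tail = FALSE), df = k - 1L)
}

#' Dunn's post hoc test on preselected pairs
#'
#' Pairwise rank comparisons after a Kruskal-Wallis test.  Ranks are
#' computed once over *all* observations of *all* groups; for a pair
#' (a, b) the statistic is
#' `z = (Rbar_a - Rbar_b) / sqrt[(N (N + 1) / 12 - sum(t^3 - t) / (12 (N - 1))) (1/n_a + 1/n_b)]`
#' with a two-sided normal p-value.  Multiplicity is corrected over the
#' *preselected* pairs only: `p_adjusted = min(1, p_raw x number of pairs)`
#' (Bonferroni over the planned comparisons, not over all k(k-1)/2).
#'
#' @param groups Named list of numeric vectors.
#' @param pairs List of length-2 character vectors naming group pairs.
#' @return Data frame with columns `group_a`, `group_b`, `z`, `p_raw`,
#'   `p_adjusted`, `tier`.
#' @export
dunn_preselected <- function(groups, pairs) {
  stopifnot(is.list(groups), length(groups) >= 2, length(pairs) >= 1)
  labels <- names(groups)
  if (is.null(labels) || any(labels == ""))
    stop("groups must be a fully named list")
  for (p in pairs) {
    if (length(p) != 2 || !all(p %in% labels))
      stop("each pair must name two existing groups; unknown: ",
           paste(setdiff(p, labels), collapse = ", "))
  }
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  g <- rep(labels, times = vapply(groups, length, integer(1)))
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  ties <- table(x)
  var_term <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  m <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(p) {
    se <- sqrt(var_term * (1 / n_i[[p[1]]] + 1 / n_i[[p[2]]]))
    z <- if (se == 0) 0 else (rbar[[p[1]]] - rbar[[p[2]]]) / se
    p_raw <- 2 * pnorm(-abs(z))
    data.frame(group_a = p[1], group_b = p[2], z = z, p_raw = p_raw,
               p_adjusted = min(1, p_raw * m))
  }))
  out$tier <- significance_tier(out$p_adjusted)
  rownames(out) <- NULL
  out
}

#' Significance tier of a p-value
#'
#' Standard star notation: `****` p < 0.0001, `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, otherwise `ns`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp < 1e-4) "****"
    else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Compare one metric across conditions
#'
#' Builds per-condition observation vectors from a long table, runs the
#' tie-corrected Kruskal-Wallis omnibus test and Dunn's post hoc test on
#' the preselected pairs, and attaches significance tiers.  Observations
#' enter individually (per track or per particle), except metrics such as
#' the motile fraction that are inherently per-ROI.
#'
#' @param observations Data frame with columns `condition` and `value`.
#' @param metric Name of the metric (recorded in the result).
#' @param pairs List of length-2 character vectors of condition labels.
#' @return An object of class `"group_comparison"`: list with `metric`,
#'   `groups` (named list), `H`, `p_omnibus`, `pairs` (data frame as from
#'   [dunn_preselected()]).
#' @export
compare_conditions <- function(observations, metric, pairs) {
  stopifnot(all(c("condition", "value") %in% names(observations)))
  obs <- observations[!is.na(observations$value), , drop = FALSE]
  lev <- unique(as.character(observations$condition))
  groups <- split(obs$value, factor(as.character(obs$condition), levels = lev))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0))
    stop("condition(s) with zero observations for metric '", metric, "': ",
         paste(names(groups)[sizes == 0], collapse = ", "))
  kw <- kruskal_wallis(groups)
  dn <- dunn_preselected(groups, pairs)
  structure(list(metric = metric, groups = groups,
                 H = kw$H, p_omnibus = kw$p, df = kw$df, pairs = dn),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison '%s': KW H = %.4g (df = %d), p = %.3g\n",
              x$metric, x$H, x$df, x$p_omnibus))
  print(x$pairs)
  invisible(x)
}

#' Flatten group comparisons into a stats table
#'
#' @param comparisons List of `group_comparison` objects.
#' @return Data frame with columns `metric`, `pair`, `z`, `p_raw`,
#'   `p_adjusted`, `tier`, plus the omnibus `H` and `p_omnibus` repeated
#'   per row.
#' @export
stats_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(cmp) {
    data.frame(metric = cmp$metric,
               pair = paste(cmp$pairs$group_a, "vs", cmp$pairs$group_b),
               z = cmp$pairs$z, p_raw = cmp$pairs$p_raw,
               p_adjusted = cmp$pairs$p_adjusted, tier = cmp$pairs$tier,
               H = cmp$H, p_omnibus = cmp$p_omnibus)
  }))
}
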