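# Community statistics: richness estimators (Chao1, ACE), dominance filters,
# and the Kruskal-Wallis test used for gradient comparisons.

#' Chao1 richness estimator
#'
#' Bias-corrected form (default): S_obs + F1 (F1 - 1) / (2 (F2 + 1)), with F1
#' and F2 the singleton and doubleton counts; defined even when F2 = 0. The
#' classic form S_obs + F1^2 / (2 F2) is available.
#'
#' @param counts integer vector of per-species counts.
#' @param bias_corrected use the bias-corrected form (default TRUE).
#' @return estimated richness; NA with a warning for an empty vector.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- counts[!is.na(counts)]
  if (!length(counts) || all(counts == 0)) {
    return(undefined_value("chao1 undefined: no observations"))
  }
  if (any(counts != floor(counts))) stop("chao1 requires integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) s_obs + f1 * (f1 - 1) / 2 else s_obs + f1^2 / (2 * f2)
  }
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator: species with counts <= `rare_cutoff`
#' (default 10) are "rare"; with sample coverage C = 1 - F1/N_rare and
#' squared coefficient of variation gamma^2,
#' ACE = S_abund + S_rare / C + (F1 / C) gamma^2. When coverage is zero (all
#' rare species are singletons) the estimate falls back to Chao1 with a
#' warning.
#'
#' @param counts integer vector of per-species counts.
#' @param rare_cutoff rare-species abundance cutoff (default 10).
#' @return estimated richness; NA with a warning for an empty vector.
#' @export
ace <- function(counts, rare_cutoff = 10L) {
  counts <- counts[!is.na(counts) & counts > 0]
  if (!length(counts)) {
    return(undefined_value("ace undefined: no observations"))
  }
  if (any(counts != floor(counts))) stop("ace requires integer counts")
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  f1 <- sum(rare == 1)
  n_rare <- sum(rare)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE coverage is zero (all rare species are singletons); ",
            "falling back to Chao1", call. = FALSE)
    return(chao1(counts))
  }
  i <- seq_len(rare_cutoff)
  fi <- vapply(i, function(k) sum(rare == k), 0L)
  gamma2 <- max(0, (s_rare / c_ace) * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Dominance filter on relative abundances
#'
#' Retains features whose relative abundance is strictly greater than
#' `threshold` in at least one sample (e.g. dominant bacterial species at
#' > 0.1%, top viruses at > 1%), optionally capped to the `top_k` features by
#' maximum abundance.
#'
#' @param rel_abund numeric matrix (features x samples) or vector of relative
#'   abundances.
#' @param threshold strict lower threshold (same units as `rel_abund`).
#' @param top_k optional cap on the number of retained features.
#' @return character vector of retained feature names (row names).
#' @export
dominance_filter <- function(rel_abund, threshold, top_k = NULL) {
  stopifnot(threshold >= 0)
  m <- if (is.matrix(rel_abund)) rel_abund else
    matrix(rel_abund, ncol = 1, dimnames = list(names(rel_abund), NULL))
  if (is.null(rownames(m))) stop("features must be named")
  mx <- apply(m, 1, max)
  keep <- mx > threshold
  kept <- rownames(m)[keep]
  if (!is.null(top_k) && length(kept) > top_k) {
    kept <- kept[order(-mx[keep])][seq_len(top_k)]
  }
  kept
}

#' Kruskal-Wallis rank-sum test
#'
#' Nonparametric comparison of >= 2 groups with average-rank tie handling and
#' the chi-square approximation for the p-value (standard convention). The
#' degenerate all-identical case returns H = 0, p = 1.
#'
#' @param groups named or unnamed list of numeric observation vectors, one
#'   per group (each non-empty).
#' @return list with `H` (test statistic), `df` (k - 1) and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need at least 3 observations in total")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    return(list(H = 0, df = nlevels(g) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}
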