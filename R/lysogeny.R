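# Lysogeny indicators: integrase carriage in the free virome, integrase
# relative abundance in the bacterial metagenome, and the mitomycin-C
# prophage-induction assay X = (Vi - Vck) / B.

#' Flag lysogenic viral contigs by integrase carriage
#'
#' A viral contig is counted as a lysogenic phage when at least one of its
#' genes carries a Pfam hit in the integrase list.
#'
#' @param annotations gene table (gene_id, contig_id, pfam_hit, ...).
#' @param contig_ids viral contig identifiers to flag.
#' @param integrase_list [marker_gene_list()] in the pfam namespace.
#' @return named logical vector over `contig_ids`.
#' @export
flag_lysogenic <- function(annotations, contig_ids,
                           integrase_list = default_integrase_list()) {
  stopifnot(inherits(integrase_list, "marker_gene_list"))
  if (integrase_list$namespace != "pfam") {
    stop("integrase detection uses the Pfam namespace")
  }
  hit <- annotations$contig_id[!is.na(annotations$pfam_hit) &
                                 annotations$pfam_hit %in% integrase_list$identifiers]
  stats::setNames(contig_ids %in% hit, contig_ids)
}

#' Relative abundance of lysogenic phages in a sample's virome
#'
#' TPM-weighted (default) share of lysogen-flagged contigs among the viral
#' contigs detected in the sample (TPM > 0). `weighted = FALSE` gives the
#' contig-count ratio over detected contigs.
#'
#' @param flags named logical vector from [flag_lysogenic()].
#' @param tpm named numeric per-contig abundances for the sample.
#' @param weighted abundance-weighted (default) or count-based.
#' @return fraction in \[0,1\]; NA with a warning for an empty virome.
#' @export
virome_lysogen_fraction <- function(flags, tpm, weighted = TRUE) {
  w <- tpm[names(flags)]
  w[is.na(w)] <- 0
  present <- w > 0
  if (!any(present)) {
    return(undefined_value("virome_lysogen_fraction undefined: no viral contigs detected in sample"))
  }
  if (weighted) {
    sum(w[present & flags]) / sum(w[present])
  } else {
    mean(flags[present])
  }
}

#' Relative abundance of phage integrase genes in a bacterial metagenome
#'
#' 100 x (TPM of metagenome genes hitting the integrase list) / (total TPM of
#' all metagenome genes). Scale-invariant in the abundances.
#'
#' @param gene_table data.frame with `gene_id` and `pfam_hit`.
#' @param tpm named numeric per-gene abundances.
#' @param integrase_list Pfam [marker_gene_list()].
#' @return percentage (>= 0); NA with a warning when total TPM is zero.
#' @export
metagenome_integrase_pct <- function(gene_table, tpm,
                                     integrase_list = default_integrase_list()) {
  stopifnot(inherits(integrase_list, "marker_gene_list"))
  w <- tpm[gene_table$gene_id]
  w[is.na(w)] <- 0
  tot <- sum(w)
  if (tot <= 0) {
    return(undefined_value("metagenome_integrase_pct undefined: zero total abundance"))
  }
  is_int <- !is.na(gene_table$pfam_hit) &
    gene_table$pfam_hit %in% integrase_list$identifiers
  100 * sum(w[is_int]) / tot
}

#' Induced phages per bacterial cell
#'
#' Evaluates the prophage-induction assay: X = (Vi - Vck) / B, where Vi and
#' Vck are virus-like-particle counts in the mitomycin-C treatment and the
#' control, and B is bacterial abundance in the same sample. Negative values
#' (treatment below background) are returned unchanged and flagged in the
#' `below_background` attribute rather than floored, so assay noise stays
#' visible.
#'
#' @param Vi,Vck VLP counts per gram, >= 0 (vectorized).
#' @param B bacterial abundance per gram, > 0.
#' @return numeric X (VLP/cell) with logical attribute `below_background`.
#' @export
induced_per_cell <- function(Vi, Vck, B) {
  if (any(B <= 0)) stop("bacterial abundance B must be > 0")
  if (any(Vi < 0) || any(Vck < 0)) stop("VLP counts must be >= 0")
  x <- (Vi - Vck) / B
  attr(x, "below_background") <- x < 0
  x
}

#' Trend of lysogeny indicators along a stress gradient
#'
#' For each indicator column, reports the monotone direction (sign of the
#' Spearman correlation with stress) and a Kruskal-Wallis test across
#' contamination groups.
#'
#' @param profiles data.frame of per-sample indicator values (numeric
#'   columns), one row per sample.
#' @param stress numeric stress level per sample (same order).
#' @param groups factor of contamination groups per sample; by default the
#'   stress range is cut into three equal-width groups
#'   (slight/moderate/high).
#' @return data.frame: indicator, direction (-1/0/1), spearman_rho, H, df, p.
#' @export
gradient_trend <- function(profiles, stress, groups = NULL) {
  stopifnot(is.data.frame(profiles), nrow(profiles) == length(stress))
  if (is.null(groups)) {
    groups <- cut(stress, breaks = 3, labels = c("slight", "moderate", "high"))
  }
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("gradient_trend needs at least 2 contamination groups")
  num <- names(profiles)[vapply(profiles, is.numeric, TRUE)]
  rows <- lapply(num, function(v) {
    x <- profiles[[v]]
    rho <- suppressWarnings(stats::cor(stress, x, method = "spearman",
                                       use = "complete.obs"))
    kw <- kruskal_wallis(split(x, groups))
    data.frame(indicator = v, direction = sign(rho), spearman_rho = rho,
               H = kw$H, df = kw$df, p = kw$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
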