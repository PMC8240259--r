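# TPM normalization, metal-resistance-gene (MRG) screening in viromes,
# attribution of MRGs to lysogenic phages, and eggNOG category profiles.

#' Transcripts-per-million abundance normalization
#'
#' TPM_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j). Features with zero counts
#' get TPM 0; the values sum to 1e6 over the feature universe supplied.
#' Invariant to sequencing depth (scaling all counts).
#'
#' @param counts named numeric vector of read counts (>= 0).
#' @param lengths named numeric vector of feature lengths in nt (> 0),
#'   aligned with or matched by name to `counts`.
#' @return named numeric vector of TPM values; all-NA with a warning when
#'   all counts are zero.
#' @export
compute_tpm <- function(counts, lengths) {
  if (!is.null(names(counts)) && !is.null(names(lengths))) {
    lengths <- lengths[names(counts)]
  }
  stopifnot(length(counts) == length(lengths))
  if (any(is.na(lengths)) || any(lengths <= 0)) stop("feature lengths must be > 0")
  if (any(counts < 0)) stop("read counts must be >= 0")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot <= 0) {
    undefined_value("compute_tpm undefined: all counts are zero")
    return(stats::setNames(rep(NA_real_, length(counts)), names(counts)))
  }
  1e6 * rate / tot
}

viral_gene_table <- function(annotations, viral_contig_ids) {
  annotations[annotations$contig_id %in% viral_contig_ids, , drop = FALSE]
}

#' Screen metal-resistance genes in a sample's virome
#'
#' Relative abundance (percent of total viral-gene TPM) of viral genes whose
#' KO hit falls in the transporter and reductase lists. Denominator is all
#' viral genes in the sample, since the quantities describe shares "in
#' viromes". If an identifier appears in both lists the gene is counted in
#' both classes (with a warning).
#'
#' @param annotations gene table including `ko_hit`.
#' @param viral_contig_ids contigs classified viral.
#' @param gene_tpm named numeric per-gene TPM for the sample.
#' @param transporter_list,reductase_list KO [marker_gene_list()]s.
#' @return one-row data.frame: transporter_pct, reductase_pct.
#' @export
screen_mrg <- function(annotations, viral_contig_ids, gene_tpm,
                       transporter_list = default_transporter_list(),
                       reductase_list = default_reductase_list()) {
  stopifnot(inherits(transporter_list, "marker_gene_list"),
            inherits(reductase_list, "marker_gene_list"))
  if (transporter_list$namespace != "ko" || reductase_list$namespace != "ko") {
    stop("MRG screening uses the KO namespace")
  }
  overlap <- intersect(transporter_list$identifiers, reductase_list$identifiers)
  if (length(overlap)) {
    warning("identifiers in both MRG lists are counted in both classes: ",
            paste(overlap, collapse = ", "), call. = FALSE)
  }
  vg <- viral_gene_table(annotations, viral_contig_ids)
  w <- gene_tpm[vg$gene_id]
  w[is.na(w)] <- 0
  tot <- sum(w)
  if (tot <= 0) {
    undefined_value("screen_mrg undefined: no viral-gene abundance in sample")
    return(data.frame(transporter_pct = NA_real_, reductase_pct = NA_real_))
  }
  in_list <- function(lst) !is.na(vg$ko_hit) & vg$ko_hit %in% lst$identifiers
  data.frame(
    transporter_pct = 100 * sum(w[in_list(transporter_list)]) / tot,
    reductase_pct = 100 * sum(w[in_list(reductase_list)]) / tot
  )
}

#' Fraction of MRGs carried by lysogenic phages
#'
#' Per MRG class, the fraction of MRG genes located on lysogen-flagged viral
#' contigs, out of MRG genes on all viral contigs. Gene-count based by
#' default (the attribution asks where the genes sit, not how abundant they
#' are); a TPM-weighted variant is available.
#'
#' @param annotations gene table including `ko_hit`.
#' @param lysogen_flags named logical vector over viral contigs
#'   (from [flag_lysogenic()]); its names define the viral contig universe.
#' @param transporter_list,reductase_list KO [marker_gene_list()]s.
#' @param gene_tpm optional named per-gene TPM, used when `weighted = TRUE`.
#' @param weighted TPM-weighted instead of gene-count attribution.
#' @return one-row data.frame: on_lysogen_transporter, on_lysogen_reductase,
#'   n_transporter_genes, n_reductase_genes. Fractions are NA (with a
#'   warning) for a class with zero MRG genes.
#' @export
mrg_lysogen_attribution <- function(annotations, lysogen_flags,
                                    transporter_list = default_transporter_list(),
                                    reductase_list = default_reductase_list(),
                                    gene_tpm = NULL, weighted = FALSE) {
  vg <- viral_gene_table(annotations, names(lysogen_flags))
  on_lys <- lysogen_flags[vg$contig_id]
  one_class <- function(lst, label) {
    sel <- !is.na(vg$ko_hit) & vg$ko_hit %in% lst$identifiers
    n <- sum(sel)
    if (n == 0) {
      frac <- undefined_value(paste0("mrg_lysogen_attribution undefined: no ",
                                     label, " genes on viral contigs"))
    } else if (weighted) {
      if (is.null(gene_tpm)) stop("weighted attribution requires gene_tpm")
      w <- gene_tpm[vg$gene_id[sel]]
      w[is.na(w)] <- 0
      frac <- if (sum(w) > 0) sum(w[on_lys[sel]]) / sum(w) else
        undefined_value(paste0("weighted attribution undefined for ", label))
    } else {
      frac <- mean(on_lys[sel])
    }
    list(frac = frac, n = n)
  }
  tr <- one_class(transporter_list, "transporter")
  rd <- one_class(reductase_list, "reductase")
  data.frame(on_lysogen_transporter = tr$frac, on_lysogen_reductase = rd$frac,
             n_transporter_genes = tr$n, n_reductase_genes = rd$n)
}

#' eggNOG (COG) functional category profile of a virome
#'
#' TPM-weighted percentage of viral genes per single-letter COG category;
#' genes without a category form category `"none"`. Percentages sum to 100.
#'
#' @param annotations gene table including `eggnog_cat`.
#' @param viral_contig_ids contigs classified viral.
#' @param gene_tpm named per-gene TPM for the sample.
#' @return data.frame: category, pct (sorted by decreasing pct).
#' @export
eggnog_category_profile <- function(annotations, viral_contig_ids, gene_tpm) {
  vg <- viral_gene_table(annotations, viral_contig_ids)
  w <- gene_tpm[vg$gene_id]
  w[is.na(w)] <- 0
  cat_ <- ifelse(is.na(vg$eggnog_cat) | vg$eggnog_cat == "", "none", vg$eggnog_cat)
  tot <- sum(w)
  if (tot <= 0) {
    undefined_value("eggnog_category_profile undefined: no viral-gene abundance")
    return(data.frame(category = character(), pct = numeric()))
  }
  agg <- tapply(w, cat_, sum)
  out <- data.frame(category = names(agg), pct = 100 * as.numeric(agg) / tot,
                    stringsAsFactors = FALSE)
  out[order(-out$pct), , drop = FALSE]
}
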