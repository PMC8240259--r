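# End-to-end driver: from a community bundle (synthetic or read from disk)
# to per-sample virome profiles.

#' Run the full virome profiling pipeline on a bundle
#'
#' Classifies contigs (length gate, VirSorter rule, annotation criteria),
#' links viral contigs to host genera by exact spacer matching, flags
#' lysogens by integrase carriage, and computes per-sample profiles:
#' lysogen fraction of the free virome, polyvalent fraction, MRG relative
#' abundances and lysogen attribution, metagenome integrase percentage and
#' induced phage per cell.
#'
#' @param bundle a `virome_bundle` (from [generate_community()] or
#'   [read_community_bundle()]).
#' @param integrase_list,transporter_list,reductase_list marker lists;
#'   defaults are the built-in demonstration sets that the synthetic
#'   generator also uses.
#' @param weighted abundance-weighted fractions (default) or count-based.
#' @param min_spacer_len minimum spacer length for host linkage.
#' @param network also build the gene-sharing network and viral clusters
#'   (protein clusters taken as the contigs' VPF tokens).
#' @return object of class `virome_profile`: list with `samples` (per-sample
#'   profile data.frame), `viral_calls`, `host_links`, `host_range`,
#'   `lysogen_flags`, `mrg_attribution`, `eggnog`, `trend`, and optionally
#'   `network`/`clusters`.
#' @export
run_virome_pipeline <- function(bundle,
                                integrase_list = default_integrase_list(),
                                transporter_list = default_transporter_list(),
                                reductase_list = default_reductase_list(),
                                weighted = TRUE,
                                min_spacer_len = 20L,
                                network = FALSE) {
  stopifnot(inherits(bundle, "virome_bundle"))
  cfg <- bundle$config

  counts_tab <- contig_annotation_counts(bundle$contig_info, bundle$annotations,
                                         bundle$virsorter)
  calls <- classify_contigs(counts_tab)
  viral_ids <- calls$contig_id[calls$is_viral]

  links <- NULL
  host_range <- NULL
  if (!is.null(bundle$contigs) && nrow(bundle$spacers)) {
    links <- match_spacers(bundle$contigs[viral_ids], bundle$spacers,
                           min_len = min_spacer_len)
    host_range <- summarize_host_range(links)
  }

  flags <- flag_lysogenic(bundle$annotations, viral_ids, integrase_list)
  x_ind <- induced_per_cell(bundle$induction$Vi, bundle$induction$Vck,
                            bundle$induction$B)

  sample_ids <- names(bundle$counts)
  rows <- lapply(sample_ids, function(sid) {
    ctpm <- contig_tpm(bundle, sid)
    gtpm <- gene_tpm(bundle, sid)
    in_sample <- bundle$contig_info$contig_id[bundle$contig_info$sample_id == sid]
    vflags <- flags[names(flags) %in% in_sample]
    lys <- suppressWarnings(virome_lysogen_fraction(vflags, ctpm, weighted = weighted))
    poly <- if (!is.null(host_range)) {
      hr <- host_range[host_range$contig_id %in% in_sample, , drop = FALSE]
      suppressWarnings(polyvalent_fraction(hr, ctpm, weighted = weighted))
    } else NA_real_
    mrg <- suppressWarnings(screen_mrg(bundle$annotations, intersect(viral_ids, in_sample),
                                       gtpm, transporter_list, reductase_list))
    attr_s <- suppressWarnings(mrg_lysogen_attribution(
      bundle$annotations, vflags, transporter_list, reductase_list))
    meta <- bundle$metagenome[[sid]]
    int_pct <- if (!is.null(meta)) {
      mtpm <- stats::setNames(compute_tpm(meta$read_count, meta$length_nt), meta$gene_id)
      metagenome_integrase_pct(meta, mtpm, integrase_list)
    } else NA_real_
    xi <- x_ind[match(sid, bundle$induction$sample_id)]
    data.frame(sample_id = sid,
               stress = cfg$stress_levels[match(sid, cfg$sample_ids)],
               n_viral = sum(names(flags) %in% in_sample),
               lysogen_fraction = lys,
               polyvalent_fraction = poly,
               transporter_pct = mrg$transporter_pct,
               reductase_pct = mrg$reductase_pct,
               on_lysogen_transporter = attr_s$on_lysogen_transporter,
               on_lysogen_reductase = attr_s$on_lysogen_reductase,
               metagenome_integrase_pct = int_pct,
               induced_per_cell = as.numeric(xi),
               stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, rows)

  mrg_global <- suppressWarnings(mrg_lysogen_attribution(
    bundle$annotations, flags, transporter_list, reductase_list))

  eggnog <- do.call(rbind, lapply(sample_ids, function(sid) {
    prof <- suppressWarnings(eggnog_category_profile(
      bundle$annotations, intersect(viral_ids,
        bundle$contig_info$contig_id[bundle$contig_info$sample_id == sid]),
      gene_tpm(bundle, sid)))
    if (nrow(prof)) cbind(data.frame(sample_id = sid, stringsAsFactors = FALSE), prof)
    else NULL
  }))

  trend <- if (length(unique(samples$stress)) >= 2 && nrow(samples) >= 3) {
    ind <- samples[, c("lysogen_fraction", "polyvalent_fraction",
                       "metagenome_integrase_pct", "induced_per_cell")]
    tryCatch(gradient_trend(ind, samples$stress), error = function(e) NULL)
  } else NULL

  out <- list(samples = samples, viral_calls = calls, host_links = links,
              host_range = host_range, lysogen_flags = flags,
              mrg_attribution = mrg_global, eggnog = eggnog, trend = trend,
              weighted = weighted)

  if (network) {
    assign <- vpf_cluster_assignments(bundle$annotations, viral_ids)
    if (length(assign) >= 2) {
      out$network <- build_network(assign)
      out$clusters <- form_viral_clusters(out$network, names(assign))
    }
  }
  class(out) <- "virome_profile"
  out
}

#' Protein-cluster assignments from VPF tokens
#'
#' In synthetic mode, genes carry viral-protein-family tokens that act as
#' protein-cluster identifiers; each viral contig's cluster set is the set of
#' distinct tokens on its genes. (Clustering real protein sequences is the
#' job of an upstream all-vs-all step whose output table this mirrors.)
#'
#' @param annotations gene table with `vpf_hit`.
#' @param viral_contig_ids contigs to include.
#' @return named list genome_id -> character vector of cluster ids; genomes
#'   without any token are dropped.
#' @export
vpf_cluster_assignments <- function(annotations, viral_contig_ids) {
  va <- annotations[annotations$contig_id %in% viral_contig_ids &
                      !is.na(annotations$vpf_hit), , drop = FALSE]
  lapply(split(va$vpf_hit, va$contig_id), unique)
}

#' @export
print.virome_profile <- function(x, digits = 3, ...) {
  cat("Virome profile (", if (x$weighted) "abundance-weighted" else "count-based",
      " fractions), ", nrow(x$samples), " samples\n\n", sep = "")
  print(format(x$samples, digits = digits), row.names = FALSE)
  if (!is.null(x$trend)) {
    cat("\nGradient trends (Spearman direction, Kruskal-Wallis):\n")
    print(format(x$trend, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
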