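# Viral contig identification: VirSorter category rule plus three
# annotation-based vHMM criteria, behind a strict >5 kb length gate.
#
# All percentage comparisons are carried out on integer counts
# (cross-multiplied rationals), so the 20%/40%/10%/60% boundaries are exact.

#' Length gate for contig identification
#'
#' Retains contigs strictly longer than `min_len` nucleotides (default 5 kb);
#' a contig of exactly `min_len` is removed.
#'
#' @param contigs data.frame with at least columns `contig_id` and `length_nt`.
#' @param min_len integer length threshold in nt (strict `>`).
#' @return The input data.frame restricted to rows with `length_nt > min_len`.
#' @export
apply_length_gate <- function(contigs, min_len = 5000L) {
  stopifnot(is.data.frame(contigs), all(c("contig_id", "length_nt") %in% names(contigs)))
  contigs[contigs$length_nt > min_len, , drop = FALSE]
}

#' VirSorter category acceptance rule
#'
#' A contig is accepted as viral when its VirSorter confidence category is
#' 1, 2, 4 or 5. Categories 3 and 6 (lower-confidence prophage calls) and a
#' missing category are not accepted by this route.
#'
#' @param category integer vector of VirSorter categories (1-6) or NA.
#' @return logical vector.
#' @export
virsorter_rule <- function(category) {
  bad <- !is.na(category) & (category < 1 | category > 6 | category != floor(category))
  if (any(bad)) {
    stop("VirSorter category outside 1..6: ", paste(unique(category[bad]), collapse = ", "))
  }
  !is.na(category) & category %in% c(1L, 2L, 4L, 5L)
}

#' Annotation-based viral criteria (vHMM rules)
#'
#' Evaluates, from per-contig gene-annotation counts, the three criteria used
#' to rescue viral contigs that VirSorter does not call:
#' \itemize{
#'   \item (a) at least 5 genes with viral-protein-family (VPF) hits, KO
#'     coverage < 20% of genes, Pfam coverage <= 40% of genes, and VPF
#'     coverage > 10% of genes;
#'   \item (b) VPF-hit genes at least as numerous as Pfam-hit genes;
#'   \item (c) VPF-hit genes at least 60% of all genes.
#' }
#' "Number of viral protein families" is counted as the number of genes
#' bearing a VPF hit (see [count_vpf_genes()] for the isolated counting rule).
#'
#' @param n_genes,n_vpf,n_ko,n_pfam integer vectors of equal length: total
#'   genes on the contig and genes carrying hits in each namespace.
#' @return data.frame with logical columns `a`, `b`, `c`.
#' @export
vhmm_criteria <- function(n_genes, n_vpf, n_ko, n_pfam) {
  stopifnot(length(n_genes) == length(n_vpf),
            length(n_genes) == length(n_ko),
            length(n_genes) == length(n_pfam))
  if (any(n_genes < 1)) {
    stop("vHMM criteria require at least one gene per contig")
  }
  # exact rational comparisons: x/n < p <=> x * (1/p denominator) < n etc.
  a <- (n_vpf >= 5L) &
    (5L * n_ko < n_genes) &          # n_ko / n_genes < 0.20
    (5L * n_pfam <= 2L * n_genes) &  # n_pfam / n_genes <= 0.40
    (10L * n_vpf > n_genes)          # n_vpf / n_genes > 0.10
  b <- n_vpf >= n_pfam
  cc <- 5L * n_vpf >= 3L * n_genes   # n_vpf >= 0.60 * n_genes
  data.frame(a = a, b = b, c = cc)
}

#' Count genes with a viral-protein-family hit
#'
#' The counting rule behind every "number of viral protein families" quantity
#' in the identification criteria: the number of genes on the contig bearing a
#' VPF hit. The alternative reading (number of distinct VPF identifiers) can
#' be selected with `distinct = TRUE`.
#'
#' @param vpf_hits character vector of per-gene VPF identifiers (NA = no hit).
#' @param distinct count distinct family identifiers instead of hit-bearing
#'   genes.
#' @return integer count.
#' @export
count_vpf_genes <- function(vpf_hits, distinct = FALSE) {
  hits <- vpf_hits[!is.na(vpf_hits) & vpf_hits != ""]
  if (distinct) length(unique(hits)) else length(hits)
}

#' Summarize per-contig annotation counts
#'
#' @param contigs data.frame with `contig_id`, `length_nt` and optionally
#'   `sample_id`.
#' @param annotations gene table with columns `gene_id`, `contig_id`,
#'   `vpf_hit`, `pfam_hit`, `ko_hit` (NA/"" = no hit).
#' @param virsorter optional data.frame `contig_id`, `category`.
#' @return data.frame: contig_id, length_nt, virsorter_category, n_genes,
#'   n_vpf, n_ko, n_pfam.
#' @export
contig_annotation_counts <- function(contigs, annotations, virsorter = NULL) {
  stopifnot(is.data.frame(contigs), is.data.frame(annotations))
  has_hit <- function(x) !is.na(x) & x != ""
  f <- factor(annotations$contig_id, levels = contigs$contig_id)
  out <- data.frame(
    contig_id = contigs$contig_id,
    length_nt = contigs$length_nt,
    n_genes = as.integer(table(f)),
    n_vpf  = as.integer(tapply(has_hit(annotations$vpf_hit), f, sum, default = 0L)),
    n_ko   = as.integer(tapply(has_hit(annotations$ko_hit), f, sum, default = 0L)),
    n_pfam = as.integer(tapply(has_hit(annotations$pfam_hit), f, sum, default = 0L)),
    stringsAsFactors = FALSE
  )
  out$n_vpf[is.na(out$n_vpf)] <- 0L
  out$n_ko[is.na(out$n_ko)] <- 0L
  out$n_pfam[is.na(out$n_pfam)] <- 0L
  if (!is.null(virsorter)) {
    out$virsorter_category <- virsorter$category[match(out$contig_id, virsorter$contig_id)]
  } else {
    out$virsorter_category <- NA_integer_
  }
  out
}

#' Classify contigs as viral or not
#'
#' Applies, in fixed order, the length gate (strict >5 kb), the VirSorter
#' category rule, then the three annotation criteria; the first satisfied
#' rule is recorded as the route. Contigs failing all rules are `rejected`.
#'
#' @param counts per-contig count table from [contig_annotation_counts()], or
#'   a data.frame with columns contig_id, length_nt, virsorter_category,
#'   n_genes, n_vpf, n_ko, n_pfam.
#' @param min_len length-gate threshold (strict `>`), default 5000 nt.
#' @return data.frame `viral_calls`: contig_id, is_viral, route
#'   (one of virsorter, vhmm_a, vhmm_b, vhmm_c, rejected, too_short),
#'   n_genes, n_vpf, n_ko, n_pfam.
#' @export
classify_contigs <- function(counts, min_len = 5000L) {
  need <- c("contig_id", "length_nt", "virsorter_category",
            "n_genes", "n_vpf", "n_ko", "n_pfam")
  stopifnot(is.data.frame(counts), all(need %in% names(counts)))
  n <- nrow(counts)
  route <- rep("rejected", n)
  is_viral <- rep(FALSE, n)

  short <- counts$length_nt <= min_len
  route[short] <- "too_short"

  vs <- virsorter_rule(counts$virsorter_category)
  take_vs <- !short & vs
  route[take_vs] <- "virsorter"
  is_viral[take_vs] <- TRUE

  rest <- which(!short & !vs)
  if (length(rest)) {
    if (any(counts$n_genes[rest] < 1)) {
      stop("contig with zero annotated genes and no accepting VirSorter ",
           "category cannot be classified: ",
           paste(counts$contig_id[rest][counts$n_genes[rest] < 1], collapse = ", "))
    }
    cr <- vhmm_criteria(counts$n_genes[rest], counts$n_vpf[rest],
                        counts$n_ko[rest], counts$n_pfam[rest])
    route[rest][cr$a] <- "vhmm_a"
    route[rest][!cr$a & cr$b] <- "vhmm_b"
    route[rest][!cr$a & !cr$b & cr$c] <- "vhmm_c"
    is_viral[rest] <- cr$a | cr$b | cr$c
  }

  data.frame(contig_id = counts$contig_id, is_viral = is_viral, route = route,
             n_genes = counts$n_genes, n_vpf = counts$n_vpf,
             n_ko = counts$n_ko, n_pfam = counts$n_pfam,
             stringsAsFactors = FALSE)
}
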