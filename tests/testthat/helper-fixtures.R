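# Shared fixtures and independent oracles used across test files.

# Small gene table builder: one contig with given per-namespace hit counts.
make_counts_row <- function(contig_id = "c1", length_nt = 6000L,
                            n_genes = 10L, n_vpf = 0L, n_ko = 0L, n_pfam = 0L,
                            category = NA_integer_) {
  data.frame(contig_id = contig_id, length_nt = length_nt,
             virsorter_category = category,
             n_genes = n_genes, n_vpf = n_vpf, n_ko = n_ko, n_pfam = n_pfam,
             stringsAsFactors = FALSE)
}

# Independent brute-force evaluator of the identification rules, written
# directly from the decision inequalities with floating-point fractions.
oracle_classify <- function(length_nt, category, n_genes, n_vpf, n_ko, n_pfam) {
  if (length_nt <= 5000) return(list(is_viral = FALSE, route = "too_short"))
  if (!is.na(category) && category %in% c(1, 2, 4, 5)) {
    return(list(is_viral = TRUE, route = "virsorter"))
  }
  a <- n_vpf >= 5 && (n_ko / n_genes) < 0.20 && (n_pfam / n_genes) <= 0.40 &&
    (n_vpf / n_genes) > 0.10
  b <- n_vpf >= n_pfam
  cc <- n_vpf >= 0.60 * n_genes
  route <- if (a) "vhmm_a" else if (b) "vhmm_b" else if (cc) "vhmm_c" else "rejected"
  list(is_viral = a || b || cc, route = route)
}

# Base-R reverse complement (independent of Biostrings).
rc_base <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Naive sliding-window comparator: every full-length occurrence of every
# spacer on both strands, by direct substring equality.
oracle_match <- function(contig_seqs, spacers) {
  out <- list()
  for (ci in names(contig_seqs)) {
    seq <- contig_seqs[[ci]]
    L <- nchar(seq)
    for (w in unique(nchar(spacers$sequence))) {
      if (w > L) next
      wins <- substring(seq, 1:(L - w + 1), w:L)
      idx <- which(nchar(spacers$sequence) == w)
      for (i in idx) {
        sp <- spacers$sequence[i]
        rcsp <- rc_base(sp)
        for (p in which(wins == sp)) {
          out[[length(out) + 1L]] <- data.frame(
            contig_id = ci, genus = spacers$genus[i],
            spacer_id = spacers$spacer_id[i], position = p, strand = "+",
            stringsAsFactors = FALSE)
        }
        if (rcsp != sp) {
          for (p in which(wins == rcsp)) {
            out[[length(out) + 1L]] <- data.frame(
              contig_id = ci, genus = spacers$genus[i],
              spacer_id = spacers$spacer_id[i], position = p, strand = "-",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(), genus = character(),
                      spacer_id = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig_id, res$position, res$spacer_id), , drop = FALSE]
}

# Hypergeometric upper tail by explicit enumeration of all draw subsets
# (combinatorial oracle, population n <= 12).
oracle_hyper <- function(a, b, c, n) {
  if (b == 0 || a == 0) return(if (c == 0) 1 else 0)
  draws <- utils::combn(n, b)
  succ <- colSums(draws <= a)   # items 1..a are the "successes"
  mean(succ >= c)
}

# A small annotation-level gradient config for pattern tests.
pattern_config <- function(seed, n = 500L, residency = FALSE) {
  gradient_config(
    stress_levels = c(0.1, 0.4, 0.7, 1.0), sample_ids = paste0("S", 1:4),
    n_viral_contigs = n, n_bacterial_contigs = 0L, n_short_contigs = 0L,
    prophage_residency = residency, emit_sequences = FALSE, seed = seed)
}

# Per-sample count-based lysogeny and integrase-percent indicators computed
# through the package's own functions on an annotation-level bundle.
bundle_indicators <- function(b) {
  cfg <- b$config
  flags <- flag_lysogenic(b$annotations, b$manifest$contigs$contig_id)
  lys <- vapply(cfg$sample_ids, function(sid) {
    ids <- b$contig_info$contig_id[b$contig_info$sample_id == sid]
    suppressWarnings(virome_lysogen_fraction(flags[names(flags) %in% ids],
                                             contig_tpm(b, sid)))
  }, 0)
  lys_count <- vapply(cfg$sample_ids, function(sid) {
    ids <- b$contig_info$contig_id[b$contig_info$sample_id == sid]
    suppressWarnings(virome_lysogen_fraction(flags[names(flags) %in% ids],
                                             contig_tpm(b, sid), weighted = FALSE))
  }, 0)
  intpct <- vapply(cfg$sample_ids, function(sid) {
    m <- b$metagenome[[sid]]
    tpm <- stats::setNames(compute_tpm(m$read_count, m$length_nt), m$gene_id)
    metagenome_integrase_pct(m, tpm)
  }, 0)
  list(lysogen_fraction = lys, lysogen_fraction_count = lys_count,
       integrase_pct = intpct, flags = flags)
}
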