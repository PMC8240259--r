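# CRISPR spacer-protospacer host linkage.
#
# The original workflow aligns host CRISPR spacers against viral contigs with
# BLASTn at E <= 1e-10 and 100% nucleotide identity. For exact matches the
# E-value is a deterministic function of match length and search-space size,
# and typical spacers (25-40 nt) clear 1e-10 comfortably, so the constraint is
# realized as a full-length exact match of at least `min_len` nt (default 20)
# on either strand. spacer_evalue() reports the ungapped Karlin-Altschul
# E-value for a perfect match if the actual number is wanted.

#' Match CRISPR spacers against viral contigs
#'
#' Finds every full-length exact occurrence of each spacer, on either strand
#' of every contig. One link is reported per occurrence; the reported
#' position is the 1-based start of the match on the forward strand, and
#' strand `-` means the contig carries the reverse complement of the spacer.
#'
#' @param contigs named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param spacers data.frame with columns `spacer_id`, `genus`, `sequence`.
#'   Records with non-ACGT characters are skipped with a warning.
#' @param min_len minimum spacer length considered (default 20 nt; shorter
#'   spacers are skipped). At BLAST's default nucleotide scoring an exact
#'   20-mer already has E far below 1e-10 for any desk-scale database.
#' @return data.frame of host links: contig_id, genus, spacer_id, position,
#'   strand, match_len.
#' @export
match_spacers <- function(contigs, spacers, min_len = 20L) {
  stopifnot(is.data.frame(spacers),
            all(c("spacer_id", "genus", "sequence") %in% names(spacers)))
  if (min_len < 1) stop("min_len must be >= 1")
  if (!inherits(contigs, "DNAStringSet")) {
    contigs <- Biostrings::DNAStringSet(unlist(contigs))
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must carry unique names")
  }

  seqs <- toupper(spacers$sequence)
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    warning(sum(bad), " spacer(s) with non-ACGT characters skipped: ",
            paste(utils::head(spacers$spacer_id[bad], 5), collapse = ", "),
            call. = FALSE)
  }
  keep <- which(!bad & nchar(seqs) >= min_len)
  empty <- data.frame(contig_id = character(), genus = character(),
                      spacer_id = character(), position = integer(),
                      strand = character(), match_len = integer(),
                      stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)

  widths <- nchar(seqs[keep])
  out <- if (length(unique(widths)) == 1L) {
    match_spacers_pdict(contigs, spacers[keep, , drop = FALSE], seqs[keep])
  } else {
    match_spacers_scan(contigs, spacers[keep, , drop = FALSE], seqs[keep])
  }
  if (is.null(out) || !nrow(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$contig_id, out$position, out$spacer_id), , drop = FALSE]
}

# Constant-width spacer sets: one Aho-Corasick dictionary per strand,
# scanned once over all contigs concatenated with an N separator (N matches
# nothing under fixed = TRUE, so no hit can span a contig boundary).
# Minus-strand hits are matches of the reverse-complemented spacer at
# forward coordinates.
match_spacers_pdict <- function(contigs, spacers, seqs) {
  ss <- Biostrings::DNAStringSet(seqs)
  rc <- Biostrings::reverseComplement(ss)
  palindromic <- as.character(rc) == seqs
  w <- nchar(seqs[1])
  cn <- names(contigs)
  lens <- Biostrings::width(contigs)
  subject <- Biostrings::DNAString(paste(as.character(contigs), collapse = "N"))
  offset <- cumsum(c(0L, lens[-length(lens)] + 1L))  # global pos of base 1 - 1

  one_strand <- function(dict, strand, drop) {
    st <- Biostrings::startIndex(Biostrings::matchPDict(dict, subject))
    nz <- setdiff(which(lengths(st) > 0), drop)
    if (!length(nz)) return(NULL)
    pos <- unlist(st[nz])
    ci <- findInterval(pos, offset + 1L)
    data.frame(
      contig_id = cn[ci],
      genus = rep(spacers$genus[nz], lengths(st)[nz]),
      spacer_id = rep(spacers$spacer_id[nz], lengths(st)[nz]),
      position = pos - offset[ci],
      strand = strand,
      match_len = w,
      stringsAsFactors = FALSE
    )
  }
  res <- rbind(
    one_strand(Biostrings::PDict(ss), "+", integer()),
    one_strand(Biostrings::PDict(rc), "-", which(palindromic))
  )
  if (is.null(res) || !nrow(res)) NULL else res
}

# General route: one Boyer-Moore scan per spacer and strand.
match_spacers_scan <- function(contigs, spacers, seqs) {
  cn <- names(contigs)
  res <- list()
  one_strand <- function(pattern, strand, i) {
    hits <- Biostrings::vmatchPattern(pattern, contigs, fixed = TRUE)
    starts <- Biostrings::startIndex(hits)
    nz <- which(lengths(starts) > 0)
    if (!length(nz)) return(NULL)
    data.frame(
      contig_id = rep(cn[nz], lengths(starts)[nz]),
      genus = spacers$genus[i], spacer_id = spacers$spacer_id[i],
      position = unlist(starts[nz]), strand = strand,
      match_len = nchar(seqs[i]), stringsAsFactors = FALSE
    )
  }
  for (i in seq_along(seqs)) {
    sq <- seqs[i]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    res[[length(res) + 1L]] <- one_strand(sq, "+", i)
    if (rc != sq) res[[length(res) + 1L]] <- one_strand(rc, "-", i)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) NULL else do.call(rbind, res)
}

#' Karlin-Altschul E-value of a perfect nucleotide match
#'
#' Reporting helper for the expected number of chance ungapped alignments with
#' the score of a full-length exact match, E = K m n exp(-lambda * S), with
#' S = reward * match length. Defaults are the ungapped parameters for
#' match/mismatch scoring +1/-2 used by BLASTn-like searches.
#'
#' @param match_len length of the exact match in nt.
#' @param m query length (spacer length); defaults to `match_len`.
#' @param n search-space size in nt (sum of contig lengths, both strands).
#' @param lambda,K Karlin-Altschul parameters.
#' @return numeric E-value.
#' @export
spacer_evalue <- function(match_len, n, m = match_len,
                          lambda = 1.28, K = 0.46) {
  stopifnot(match_len > 0, n > 0, m > 0)
  K * m * n * exp(-lambda * match_len)
}

#' Summarize host range per viral contig
#'
#' Groups links by contig and reports the number of distinct linked host
#' genera; a contig is polyvalent (broad host range) when it is linked to at
#' least `min_genera` distinct genera. Contigs with no links do not appear.
#'
#' @param links data.frame from [match_spacers()].
#' @param min_genera polyvalence threshold on distinct genera (default 2,
#'   i.e. "links to two or more distinct genera").
#' @return data.frame: contig_id, linked_genera (";"-joined, sorted),
#'   n_genera, polyvalent.
#' @export
summarize_host_range <- function(links, min_genera = 2L) {
  stopifnot(is.data.frame(links))
  if (!nrow(links)) {
    return(data.frame(contig_id = character(), linked_genera = character(),
                      n_genera = integer(), polyvalent = logical(),
                      stringsAsFactors = FALSE))
  }
  by_contig <- split(links$genus, links$contig_id)
  genera <- lapply(by_contig, function(g) sort(unique(g)))
  data.frame(
    contig_id = names(by_contig),
    linked_genera = vapply(genera, paste, "", collapse = ";"),
    n_genera = lengths(genera),
    polyvalent = lengths(genera) >= min_genera,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fraction of polyvalent phages in a sample
#'
#' With `weighted = TRUE` (default) the abundance share: sum of TPM over
#' polyvalent host-linked contigs divided by the sum over all host-linked
#' contigs. With `weighted = FALSE` the contig-count ratio. When `tpm` is
#' supplied, contigs absent from the sample (TPM 0 or missing) are excluded
#' from both numerator and denominator, so the fraction describes the viruses
#' actually detected in the sample.
#'
#' @param summaries data.frame from [summarize_host_range()].
#' @param tpm named numeric vector of per-contig abundances (required when
#'   `weighted = TRUE`).
#' @param weighted abundance-weighted (default) or count-based.
#' @return fraction in \[0,1\], or NA with a warning when no host-linked
#'   contig is present (empty denominator).
#' @export
polyvalent_fraction <- function(summaries, tpm = NULL, weighted = TRUE) {
  stopifnot(is.data.frame(summaries))
  s <- summaries
  if (!is.null(tpm)) {
    w <- tpm[s$contig_id]
    w[is.na(w)] <- 0
    s <- s[w > 0, , drop = FALSE]
    w <- w[w > 0]
  } else if (weighted) {
    stop("weighted polyvalent_fraction requires per-contig TPM")
  }
  if (!nrow(s)) {
    return(undefined_value("polyvalent_fraction undefined: no host-linked contigs in sample"))
  }
  if (weighted) sum(w[s$polyvalent]) / sum(w) else mean(s$polyvalent)
}
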