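# Gene-sharing similarity networks between viral genomes.
#
# Each genome is a set of protein clusters (PCs). For a genome pair sharing c
# PCs, with a and b PCs per genome and n PCs in the whole analysis, the
# chance of sharing at least c clusters is the hypergeometric upper tail
# P(X >= c). The similarity score is -log10(p * T), T = number of genome
# pairs evaluated (a Bonferroni-style correction); pairs with score >= 1 are
# "remarkably similar" and become network edges.

#' Hypergeometric upper-tail probability of shared gene content
#'
#' P(X >= c) for X hypergeometric with population `n`, `a` successes and `b`
#' draws, summed on the log scale for numerical stability.
#'
#' @param a,b protein-cluster counts of the two genomes.
#' @param c shared protein-cluster count.
#' @param n total distinct protein clusters in the analysis.
#' @return probability in (0, 1].
#' @export
hypergeometric_pvalue <- function(a, b, c, n) {
  if (!(c >= 0 && c <= min(a, b) && min(a, b) >= 0 && max(a, b) <= n)) {
    stop("require 0 <= c <= min(a,b) and a,b <= n")
  }
  if (c == 0) return(1)
  k <- c:min(a, b)
  ll <- stats::dhyper(k, m = a, n = n - a, k = b, log = TRUE)
  m <- max(ll)
  min(1, exp(m + log(sum(exp(ll - m)))))
}

#' Build a gene-sharing similarity network
#'
#' Evaluates all unordered genome pairs; the score of a pair sharing `c`
#' protein clusters is -log10(p * T) with p the hypergeometric upper tail and
#' T the number of pairs used in the correction. Edges with score >= the
#' threshold (default 1) are retained. Genomes sharing no clusters never form
#' an edge.
#'
#' @param assignments named list: genome_id -> character vector of
#'   protein-cluster ids (each genome has >= 1).
#' @param threshold minimum retained score (default 1).
#' @param pair_correction `"all"` (default): T = all unordered pairs;
#'   `"nonzero"`: T = pairs sharing at least one cluster.
#' @return data.frame of edges: genome_a, genome_b, shared, pvalue, score;
#'   attributes `n_pairs` (T) and `n_pcs` (population size n).
#' @export
build_network <- function(assignments, threshold = 1,
                          pair_correction = c("all", "nonzero")) {
  pair_correction <- match.arg(pair_correction)
  stopifnot(is.list(assignments), length(assignments) >= 2,
            !is.null(names(assignments)))
  if (any(lengths(assignments) == 0)) stop("every genome needs >= 1 protein cluster")
  sets <- lapply(assignments, unique)
  ids <- names(sets)
  n_pc <- length(unique(unlist(sets, use.names = FALSE)))
  g <- length(sets)
  pr <- utils::combn(g, 2)
  shared <- integer(ncol(pr))
  for (j in seq_len(ncol(pr))) {
    shared[j] <- length(intersect(sets[[pr[1, j]]], sets[[pr[2, j]]]))
  }
  t_pairs <- if (pair_correction == "all") ncol(pr) else sum(shared > 0)
  pv <- rep(1, ncol(pr))
  nz <- which(shared > 0)
  for (j in nz) {
    pv[j] <- hypergeometric_pvalue(length(sets[[pr[1, j]]]),
                                   length(sets[[pr[2, j]]]),
                                   shared[j], n_pc)
  }
  score <- -log10(pv * t_pairs)
  keep <- shared > 0 & score >= threshold
  out <- data.frame(genome_a = ids[pr[1, keep]], genome_b = ids[pr[2, keep]],
                    shared = shared[keep], pvalue = pv[keep],
                    score = score[keep], stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- t_pairs
  attr(out, "n_pcs") <- n_pc
  out
}

#' Form viral clusters from the thresholded network
#'
#' Connected components of the similarity graph; genomes without edges become
#' singleton clusters. Cluster identifiers are deterministic: the
#' lexicographically smallest member's id.
#'
#' @param edges edge data.frame from [build_network()].
#' @param genomes character vector of all genome ids (so singletons appear).
#' @return data.frame: genome_id, cluster_id.
#' @export
form_viral_clusters <- function(edges, genomes) {
  genomes <- as.character(genomes)
  g <- igraph::graph_from_data_frame(
    edges[, c("genome_a", "genome_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = genomes)
  )
  memb <- igraph::components(g)$membership
  cl <- tapply(names(memb), memb, min)
  data.frame(genome_id = genomes,
             cluster_id = unname(cl[as.character(memb[genomes])]),
             stringsAsFactors = FALSE)
}

#' Relate study contigs to reference genomes by network linkage
#'
#' A study contig is "matched" when it has at least one retained edge to any
#' reference genome. Per sample: the matched fraction, and among matched
#' contigs the habitat composition of their reference partners (distinct
#' contig-habitat pairs, normalized to sum to 100%).
#'
#' @param edges edge data.frame from [build_network()] over study + reference
#'   genomes.
#' @param study data.frame: genome_id, sample_id for study contigs.
#' @param reference data.frame: genome_id, habitat for reference genomes.
#' @return list with `matched` (data.frame sample_id, n_contigs, n_matched,
#'   matched_fraction) and `habitats` (data.frame sample_id, habitat, pct).
#' @export
annotate_reference_links <- function(edges, study, reference) {
  stopifnot(all(c("genome_id", "sample_id") %in% names(study)),
            all(c("genome_id", "habitat") %in% names(reference)))
  # orient edges as study -> reference
  a_ref <- edges$genome_a %in% reference$genome_id
  b_ref <- edges$genome_b %in% reference$genome_id
  sr <- rbind(
    data.frame(contig = edges$genome_b[a_ref & !b_ref], ref = edges$genome_a[a_ref & !b_ref]),
    data.frame(contig = edges$genome_a[b_ref & !a_ref], ref = edges$genome_b[b_ref & !a_ref])
  )
  sr <- sr[sr$contig %in% study$genome_id, , drop = FALSE]
  sr$sample_id <- study$sample_id[match(sr$contig, study$genome_id)]
  sr$habitat <- reference$habitat[match(sr$ref, reference$genome_id)]

  samples <- sort(unique(study$sample_id))
  matched <- do.call(rbind, lapply(samples, function(s) {
    ids <- study$genome_id[study$sample_id == s]
    hit <- unique(sr$contig[sr$sample_id == s])
    data.frame(sample_id = s, n_contigs = length(ids), n_matched = length(hit),
               matched_fraction = if (length(ids)) length(hit) / length(ids) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  hab <- if (nrow(sr)) {
    ch <- unique(sr[, c("sample_id", "contig", "habitat")])
    tab <- as.data.frame(table(ch$sample_id, ch$habitat), stringsAsFactors = FALSE)
    names(tab) <- c("sample_id", "habitat", "n")
    tab <- tab[tab$n > 0, , drop = FALSE]
    tot <- tapply(tab$n, tab$sample_id, sum)
    tab$pct <- 100 * tab$n / as.numeric(tot[tab$sample_id])
    tab[order(tab$sample_id, -tab$pct), c("sample_id", "habitat", "pct")]
  } else {
    data.frame(sample_id = character(), habitat = character(), pct = numeric())
  }
  list(matched = matched, habitats = hab)
}
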