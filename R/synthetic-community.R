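# Synthetic community generator.
#
# Emits complete, ground-truthed inputs for the whole pipeline: contigs with
# gene annotations, VirSorter-style categories, CRISPR spacer libraries that
# realize the planted host links, per-sample read counts, a bacterial
# metagenome gene table, and induction-assay triplets -- all structured along
# a configurable environmental stress gradient in which lysogeny,
# polyvalence and MRG carriage increase with stress.
#
# The generator's defaults emulate the ranges reported for chromium-stressed
# soil viromes (lysogen relative abundance from a few percent to ~35%,
# polyvalent fraction ~20-55%, metagenome integrase share 0.1-0.7%,
# induction up to ~22 VLP/cell); see the methods vignette.

#' Configuration for the synthetic stress-gradient community
#'
#' All knobs of [generate_community()], validated. Probabilities are produced
#' from the logit pairs as plogis(intercept + slope * stress), which is
#' naturally clamped to \[0,1\].
#'
#' @param stress_levels numeric stress per sample, each in \[0,1\].
#' @param sample_ids sample names (default L1-L3, Z1-Z4 style tokens when 7
#'   samples, else S01...).
#' @param n_host_genera number of host genera with spacer libraries.
#' @param n_viral_contigs viral contigs generated per sample.
#' @param n_bacterial_contigs bacterial (non-viral) contigs per sample.
#' @param n_short_contigs sub-5 kb decoy contigs per sample (exercise the
#'   length gate).
#' @param contig_length_range min/max viral contig length in nt; the minimum
#'   must exceed 5000 so every viral contig clears the strict >5 kb gate.
#' @param genes_per_kb gene density (genes per kb, > 0).
#' @param lysogeny_logit,polyvalence_logit (intercept, slope) pairs for
#'   P(lysogenic | stress) and P(polyvalent | stress).
#' @param mrg_rate_lytic per-class probability that a lytic contig carries an
#'   MRG gene.
#' @param mrg_lysogen_boost multiplier on that probability for lysogenic
#'   contigs (>= 1); lysogen probability is min(1, rate * boost).
#' @param spacer_length planted protospacer length in nt.
#' @param decoy_spacer_fraction fraction of decoy (unplanted) spacers added
#'   per genus library (at least one).
#' @param abundance_lognormal (meanlog, sdlog) of per-contig abundance
#'   weights.
#' @param library_size per-sample total read count the weights are scaled to.
#' @param virsorter_prob probability a viral contig receives an accepting
#'   VirSorter category (1/2/4/5); the rest rely on the annotation criteria.
#' @param prophage_residency when TRUE, lysogenic phages convert to
#'   integrated prophages (absent from the free virome, visible as metagenome
#'   integrase signal) with probability residency_max * stress^residency_power.
#' @param residency_max,residency_power residency curve parameters.
#' @param n_metagenome_genes ordinary bacterial genes per sample in the
#'   metagenome gene table.
#' @param metagenome_integrase_base,metagenome_integrase_scale baseline and
#'   slope of the metagenome integrase abundance share (share = base +
#'   scale * resident prophage mass fraction).
#' @param x_max induced phage per cell at stress 1 (X = x_max * stress^1.5).
#' @param bacterial_abundance B, bacteria per gram, for the induction assay.
#' @param vck_background control VLP count per gram.
#' @param induction_noise_cv coefficient of variation of the multiplicative
#'   noise on Vi (0 = noiseless).
#' @param genus_names optional real genus names to alias the synthetic host
#'   tokens (purely cosmetic; the pipeline never depends on names).
#' @param emit_sequences generate nucleotide sequences and spacer libraries
#'   (TRUE, default) or stop at the annotation level (cheaper, sufficient
#'   for lysogeny/MRG studies).
#' @param seed RNG seed; a fixed seed makes the whole bundle reproducible.
#' @return validated object of class `gradient_config`.
#' @export
gradient_config <- function(stress_levels = c(0.05, 0.10, 0.40, 0.10, 0.45, 0.75, 1.00),
                            sample_ids = NULL,
                            n_host_genera = 12L,
                            n_viral_contigs = 60L,
                            n_bacterial_contigs = 15L,
                            n_short_contigs = 10L,
                            contig_length_range = c(8000L, 15000L),
                            genes_per_kb = 1.5,
                            lysogeny_logit = c(-2.6, 2.6),
                            polyvalence_logit = c(-1.32, 1.5),
                            mrg_rate_lytic = 0.02,
                            mrg_lysogen_boost = 8,
                            spacer_length = 32L,
                            decoy_spacer_fraction = 0.01,
                            abundance_lognormal = c(1, 0.75),
                            library_size = 1e5,
                            virsorter_prob = 0.7,
                            prophage_residency = FALSE,
                            residency_max = 0.9,
                            residency_power = 3,
                            n_metagenome_genes = 400L,
                            metagenome_integrase_base = 0.001,
                            metagenome_integrase_scale = 0.006,
                            x_max = 22,
                            bacterial_abundance = 1e7,
                            vck_background = 5e6,
                            induction_noise_cv = 0.05,
                            genus_names = NULL,
                            emit_sequences = TRUE,
                            seed = 1L) {
  n_samples <- length(stress_levels)
  if (is.null(sample_ids)) {
    sample_ids <- if (n_samples == 7) c("L1", "L2", "L3", "Z1", "Z2", "Z3", "Z4")
    else sprintf("S%02d", seq_len(n_samples))
  }
  if (length(sample_ids) != n_samples) stop("one sample id per stress level")
  if (any(stress_levels < 0 | stress_levels > 1)) {
    stop("stress levels must lie in [0, 1]")
  }
  if (length(contig_length_range) != 2 || contig_length_range[1] > contig_length_range[2]) {
    stop("contig_length_range must be an increasing pair")
  }
  if (contig_length_range[1] <= 5000) {
    stop("contig_length_range minimum must exceed 5000 nt so viral contigs ",
         "clear the strict >5 kb gate")
  }
  if (genes_per_kb <= 0) stop("genes_per_kb must be > 0")
  if (mrg_rate_lytic < 0 || mrg_rate_lytic > 1) stop("mrg_rate_lytic must be in [0, 1]")
  if (mrg_lysogen_boost < 1) stop("mrg_lysogen_boost must be >= 1")
  if (spacer_length > contig_length_range[1]) {
    stop("spacer_length exceeds the shortest possible contig")
  }
  if (spacer_length < 20) stop("spacer_length must be >= 20 nt")
  if (induction_noise_cv < 0) stop("induction_noise_cv must be >= 0")
  if (virsorter_prob < 0 || virsorter_prob > 1) stop("virsorter_prob must be in [0, 1]")
  if (x_max < 0 || bacterial_abundance <= 0 || vck_background < 0) {
    stop("induction parameters must be non-negative (B strictly positive)")
  }
  if (!is.null(genus_names) && length(genus_names) < n_host_genera) {
    stop("need at least n_host_genera genus names")
  }
  structure(list(
    sample_ids = sample_ids, stress_levels = stress_levels,
    n_samples = n_samples, n_host_genera = as.integer(n_host_genera),
    n_viral_contigs = as.integer(n_viral_contigs),
    n_bacterial_contigs = as.integer(n_bacterial_contigs),
    n_short_contigs = as.integer(n_short_contigs),
    contig_length_range = as.integer(contig_length_range),
    genes_per_kb = genes_per_kb,
    lysogeny_logit = lysogeny_logit, polyvalence_logit = polyvalence_logit,
    mrg_rate_lytic = mrg_rate_lytic, mrg_lysogen_boost = mrg_lysogen_boost,
    spacer_length = as.integer(spacer_length),
    decoy_spacer_fraction = decoy_spacer_fraction,
    abundance_lognormal = abundance_lognormal, library_size = library_size,
    virsorter_prob = virsorter_prob,
    prophage_residency = isTRUE(prophage_residency),
    residency_max = residency_max, residency_power = residency_power,
    n_metagenome_genes = as.integer(n_metagenome_genes),
    metagenome_integrase_base = metagenome_integrase_base,
    metagenome_integrase_scale = metagenome_integrase_scale,
    x_max = x_max, bacterial_abundance = bacterial_abundance,
    vck_background = vck_background, induction_noise_cv = induction_noise_cv,
    genus_names = genus_names, emit_sequences = isTRUE(emit_sequences),
    seed = as.integer(seed)
  ), class = "gradient_config")
}

#' @export
print.gradient_config <- function(x, ...) {
  cat("Synthetic community config: ", x$n_samples, " samples, ",
      x$n_viral_contigs, " viral contigs/sample, ", x$n_host_genera,
      " host genera, seed ", x$seed, "\n", sep = "")
  cat("  stress: ", paste(sprintf("%s=%.2f", x$sample_ids, x$stress_levels),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

random_dna <- function(lengths) {
  tot <- sum(lengths)
  # draw bytes directly (A/C/G/T ASCII codes); much faster than paste()
  big <- rawToChar(as.raw(sample(c(65L, 67L, 71L, 84L), tot, replace = TRUE)))
  ends <- cumsum(lengths)
  substring(big, ends - lengths + 1, ends)
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

# Vectorized gene scaffold for a set of contigs: genes tile each contig
# evenly (gene k of n spans floor((k-1) L / n)+1 .. floor(k L / n)).
tile_genes_vec <- function(contig_ids, lengths_nt, n_genes) {
  ci <- rep(seq_along(contig_ids), n_genes)
  k <- sequence(n_genes)
  L <- lengths_nt[ci]
  n <- n_genes[ci]
  data.frame(
    gene_id = sprintf("%s_g%03d", contig_ids[ci], k),
    contig_id = contig_ids[ci],
    start = as.integer(floor((k - 1) * L / n) + 1),
    end = as.integer(floor(k * L / n)),
    strand = sample(c("+", "-"), length(ci), replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic community bundle
#'
#' Draws, per sample along the configured stress gradient, viral contigs with
#' lifestyles, host sets, MRG cargo and annotation profiles that the
#' pipeline's decision rules invert exactly; bacterial and short decoy
#' contigs; abundances; spacer libraries realizing every planted host link
#' (verbatim protospacer copies, reverse-complemented with probability 0.5,
#' plus ~1% random decoy spacers); a metagenome gene table carrying the
#' integrase signal of integrated prophages; and induction triplets.
#' Deterministic for a fixed seed.
#'
#' @param config a [gradient_config()].
#' @return object of class `virome_bundle`: list with elements `contigs`
#'   (DNAStringSet or NULL), `contig_info`, `annotations`, `virsorter`,
#'   `spacers`, `counts` (per-sample list), `metagenome` (per-sample list),
#'   `induction`, `manifest` (ground truth) and `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "gradient_config"))
  set.seed(config$seed)
  cfg <- config

  genera <- if (!is.null(cfg$genus_names)) cfg$genus_names[seq_len(cfg$n_host_genera)]
  else sprintf("genus%02d", seq_len(cfg$n_host_genera))

  integrase_ids <- default_integrase_list()$identifiers
  transporter_ids <- default_transporter_list()$identifiers
  reductase_ids <- default_reductase_list()$identifiers
  pfam_pool <- sprintf("PF9%04d", 1:60)         # ordinary (non-integrase) families
  ko_pool <- sprintf("K9%04d", 1:80)            # ordinary (non-MRG) KOs
  vpf_pool <- sprintf("VPF%05d", 1:200)
  cog_letters <- c("C", "I", "E", "G", "K", "L", "M", "P", "S")

  info_l <- list(); ann_l <- list(); vs_l <- list(); truth_l <- list()
  mrg_l <- list(); counts <- list(); metagenome <- list()
  spacer_l <- list(); sample_rows <- list()

  lys_p <- plogis(cfg$lysogeny_logit[1] + cfg$lysogeny_logit[2] * cfg$stress_levels)
  poly_p <- plogis(cfg$polyvalence_logit[1] + cfg$polyvalence_logit[2] * cfg$stress_levels)
  res_p <- if (cfg$prophage_residency) {
    cfg$residency_max * cfg$stress_levels^cfg$residency_power
  } else rep(0, cfg$n_samples)

  for (si in seq_len(cfg$n_samples)) {
    sid <- cfg$sample_ids[si]
    z <- cfg$stress_levels[si]

    ## ---- viral contigs -------------------------------------------------
    nv <- cfg$n_viral_contigs
    v_id <- sprintf("%s_vc%04d", sid, seq_len(nv))
    v_len <- sample(cfg$contig_length_range[1]:cfg$contig_length_range[2], nv, replace = TRUE)
    lys <- runif(nv) < lys_p[si]
    resident <- lys & (runif(nv) < res_p[si])
    poly <- runif(nv) < poly_p[si]
    n_hosts <- ifelse(poly, sample(2:3, nv, replace = TRUE), 1L)
    hosts <- lapply(seq_len(nv), function(i) sample(genera, n_hosts[i]))
    vs_cat <- ifelse(runif(nv) < cfg$virsorter_prob,
                     sample(c(1L, 2L, 4L, 5L), nv, replace = TRUE),
                     sample(c(NA_integer_, NA_integer_, 3L, 6L), nv, replace = TRUE))

    v_ng <- pmax(5L, as.integer(round(v_len / 1000 * cfg$genes_per_kb)))
    v_gg <- tile_genes_vec(v_id, v_len, v_ng)
    ntot <- nrow(v_gg)
    offs <- c(0L, cumsum(v_ng))
    vpf_hit <- pfam_hit <- ko_hit <- rep(NA_character_, ntot)
    mrg_contig <- mrg_gene <- mrg_class <- mrg_ko <- character()
    p_mrg_lys <- min(1, cfg$mrg_rate_lytic * cfg$mrg_lysogen_boost)
    for (i in seq_len(nv)) {
      ng <- v_ng[i]
      o <- offs[i]
      # viral annotation profile: VPF coverage >= 70% guarantees criterion (c)
      vpf_idx <- o + sample(ng, ceiling(0.7 * ng))
      vpf_hit[vpf_idx] <- sample(vpf_pool, length(vpf_idx), replace = TRUE)
      if (ng >= 13) {
        ko_idx <- o + sample(ng, floor(0.08 * ng))
        ko_hit[ko_idx] <- sample(ko_pool, length(ko_idx), replace = TRUE)
      }
      pf_idx <- o + sample(ng, floor(0.25 * ng))
      pfam_hit[pf_idx] <- sample(pfam_pool, length(pf_idx), replace = TRUE)
      if (lys[i]) {
        pfam_hit[o + sample(ng, 1)] <- sample(integrase_ids, 1)
      }
      # MRG cargo: one draw per class
      p_mrg <- if (lys[i]) p_mrg_lys else cfg$mrg_rate_lytic
      free <- o + which(is.na(ko_hit[(o + 1):(o + ng)]))
      for (cls in c("transporter", "reductase")) {
        if (length(free) && runif(1) < p_mrg) {
          gi <- if (length(free) == 1L) free else sample(free, 1)
          free <- setdiff(free, gi)
          ko <- if (cls == "transporter") sample(transporter_ids, 1) else sample(reductase_ids, 1)
          ko_hit[gi] <- ko
          mrg_contig <- c(mrg_contig, v_id[i]); mrg_gene <- c(mrg_gene, v_gg$gene_id[gi])
          mrg_class <- c(mrg_class, cls); mrg_ko <- c(mrg_ko, ko)
        }
      }
    }
    v_gg$vpf_hit <- vpf_hit
    v_gg$pfam_hit <- pfam_hit
    v_gg$ko_hit <- ko_hit
    # COG categories: energy metabolism (C) and lipid metabolism (I)
    # upweighted with stress; ~25% of genes uncategorized
    w <- c(1 + z, 1 + z, rep(1, length(cog_letters) - 2))
    v_gg$eggnog_cat <- sample(c(cog_letters, NA), ntot, replace = TRUE,
                              prob = c(w / sum(w) * 0.75, 0.25))
    v_mrg <- if (length(mrg_contig)) {
      data.frame(contig_id = mrg_contig, gene_id = mrg_gene, class = mrg_class,
                 ko_id = mrg_ko, stringsAsFactors = FALSE)
    } else NULL

    ## ---- bacterial contigs ---------------------------------------------
    nb <- cfg$n_bacterial_contigs
    b_id <- if (nb) sprintf("%s_bc%04d", sid, seq_len(nb)) else character()
    b_len <- if (nb) sample(cfg$contig_length_range[1]:cfg$contig_length_range[2], nb, replace = TRUE) else integer()
    b_gg <- NULL
    if (nb) {
      b_ng <- pmax(5L, as.integer(round(b_len / 1000 * cfg$genes_per_kb)))
      b_gg <- tile_genes_vec(b_id, b_len, b_ng)
      nbt <- nrow(b_gg)
      b_offs <- c(0L, cumsum(b_ng))
      bp <- bk <- rep(NA_character_, nbt)
      for (i in seq_len(nb)) {
        ng <- b_ng[i]; o <- b_offs[i]
        pf_idx <- o + sample(ng, max(1L, ceiling(0.6 * ng)))
        bp[pf_idx] <- sample(pfam_pool, length(pf_idx), replace = TRUE)
        ko_idx <- o + sample(ng, ceiling(0.5 * ng))
        bk[ko_idx] <- sample(ko_pool, length(ko_idx), replace = TRUE)
      }
      b_gg$vpf_hit <- NA_character_
      b_gg$pfam_hit <- bp
      b_gg$ko_hit <- bk
      b_gg$eggnog_cat <- sample(c(cog_letters, NA), nbt, replace = TRUE)
    }
    b_cat <- if (nb) sample(c(NA_integer_, 3L, 6L), nb, replace = TRUE) else integer()

    ## ---- short decoy contigs (fail the >5 kb gate) ---------------------
    ns <- cfg$n_short_contigs
    s_id <- if (ns) sprintf("%s_sc%04d", sid, seq_len(ns)) else character()
    s_len <- if (ns) sample(2000:5000, ns, replace = TRUE) else integer()
    s_gg <- NULL
    if (ns) {
      s_gg <- tile_genes_vec(s_id, s_len, rep(3L, ns))
      s_gg$vpf_hit <- as.character(rbind(sample(vpf_pool, ns, replace = TRUE), NA, NA))
      s_gg$pfam_hit <- NA_character_; s_gg$ko_hit <- NA_character_
      s_gg$eggnog_cat <- NA_character_
    }
    s_cat <- if (ns) sample(c(1L, NA_integer_), ns, replace = TRUE) else integer()

    ids <- c(v_id, b_id, s_id)
    lens <- c(v_len, b_len, s_len)
    types <- c(rep("viral", nv), rep("bacterial", nb), rep("short", ns))

    info_l[[si]] <- data.frame(contig_id = ids, sample_id = sid,
                               length_nt = lens, type = types,
                               stringsAsFactors = FALSE)
    ann_l[[si]] <- rbind(v_gg, b_gg, s_gg)
    vs_l[[si]] <- data.frame(contig_id = ids, category = c(vs_cat, b_cat, s_cat),
                             stringsAsFactors = FALSE)
    mrg_l[[si]] <- v_mrg

    ## ---- sequences + planted protospacers ------------------------------
    if (cfg$emit_sequences) {
      seqs <- random_dna(lens)
      names(seqs) <- ids
      sp_rows <- vector("list", nv)
      for (i in seq_len(nv)) {
        hs <- hosts[[i]]
        pos <- sample(v_len[i] - cfg$spacer_length + 1L, length(hs), replace = TRUE)
        proto <- substring(seqs[[v_id[i]]], pos, pos + cfg$spacer_length - 1L)
        flip <- runif(length(hs)) < 0.5
        proto[flip] <- revcomp_chr(proto[flip])
        sp_rows[[i]] <- data.frame(
          spacer_id = sprintf("%s_sp%s", v_id[i], seq_along(hs)),
          genus = hs, sequence = proto, stringsAsFactors = FALSE)
      }
      spacer_l[[si]] <- do.call(rbind, sp_rows)
      info_l[[si]]$sequence <- unname(seqs)
    }

    ## ---- abundances ----------------------------------------------------
    w <- rlnorm(length(ids), cfg$abundance_lognormal[1], cfg$abundance_lognormal[2])
    w_viral <- w[seq_len(nv)]
    resident_mass <- sum(w_viral[resident]) / sum(w_viral)
    w[seq_len(nv)][resident] <- 0      # integrated prophages leave the free virome
    reads <- round(w / sum(w) * cfg$library_size)
    ann_s <- ann_l[[si]]
    glen <- ann_s$end - ann_s$start + 1L
    gene_reads <- round(reads[match(ann_s$contig_id, ids)] * glen / lens[match(ann_s$contig_id, ids)])
    counts[[sid]] <- rbind(
      data.frame(feature_id = ids, feature_type = "contig", read_count = reads,
                 feature_length_nt = lens, stringsAsFactors = FALSE),
      data.frame(feature_id = ann_s$gene_id, feature_type = "gene",
                 read_count = gene_reads, feature_length_nt = glen,
                 stringsAsFactors = FALSE)
    )

    ## ---- bacterial metagenome gene table -------------------------------
    nm <- cfg$n_metagenome_genes
    int_share <- cfg$metagenome_integrase_base +
      cfg$metagenome_integrase_scale * resident_mass
    mw <- rlnorm(nm, cfg$abundance_lognormal[1], cfg$abundance_lognormal[2])
    ordinary <- round(mw / sum(mw) * cfg$library_size * (1 - int_share))
    n_int <- min(3L, length(integrase_ids))
    int_reads <- round(rep(cfg$library_size * int_share / n_int, n_int))
    metagenome[[sid]] <- data.frame(
      gene_id = c(sprintf("%s_mg%04d", sid, seq_len(nm)),
                  sprintf("%s_int%02d", sid, seq_len(n_int))),
      pfam_hit = c(sample(pfam_pool, nm, replace = TRUE), integrase_ids[seq_len(n_int)]),
      read_count = c(ordinary, int_reads),
      length_nt = 1000L,
      stringsAsFactors = FALSE
    )

    truth_l[[si]] <- data.frame(
      contig_id = v_id, sample_id = sid,
      lifestyle = ifelse(lys, "lysogenic", "lytic"),
      resident = resident, polyvalent = poly, n_hosts = n_hosts,
      hosts = vapply(hosts, function(h) paste(sort(h), collapse = ";"), ""),
      stringsAsFactors = FALSE
    )
    sample_rows[[si]] <- data.frame(
      sample_id = sid, stress = z, n_viral = nv,
      p_lysogeny = lys_p[si], p_polyvalence = poly_p[si],
      p_residency = res_p[si], stringsAsFactors = FALSE
    )
  }

  ## ---- spacer decoys ----------------------------------------------------
  spacers <- if (cfg$emit_sequences) {
    sp <- do.call(rbind, spacer_l)
    decoys <- do.call(rbind, lapply(genera, function(g) {
      n_real <- sum(sp$genus == g)
      nd <- max(1L, round(cfg$decoy_spacer_fraction * n_real))
      data.frame(spacer_id = sprintf("%s_decoy%03d", g, seq_len(nd)),
                 genus = g,
                 sequence = random_dna(rep(cfg$spacer_length, nd)),
                 stringsAsFactors = FALSE)
    }))
    rbind(sp, decoys)
  } else {
    data.frame(spacer_id = character(), genus = character(),
               sequence = character(), stringsAsFactors = FALSE)
  }

  ## ---- induction assay --------------------------------------------------
  x_true <- cfg$x_max * cfg$stress_levels^1.5
  induction <- generate_induction_triplets(
    B = cfg$bacterial_abundance, X = x_true,
    noise_cv = cfg$induction_noise_cv, vck = cfg$vck_background)
  induction <- cbind(data.frame(sample_id = cfg$sample_ids,
                                stringsAsFactors = FALSE), induction)

  contig_info <- do.call(rbind, info_l)
  contigs <- NULL
  if (cfg$emit_sequences) {
    contigs <- Biostrings::DNAStringSet(contig_info$sequence)
    names(contigs) <- contig_info$contig_id
    contig_info$sequence <- NULL
  }

  bundle <- structure(list(
    contigs = contigs,
    contig_info = contig_info,
    annotations = do.call(rbind, ann_l),
    virsorter = do.call(rbind, vs_l),
    spacers = spacers,
    counts = counts,
    metagenome = metagenome,
    induction = induction,
    manifest = list(contigs = do.call(rbind, truth_l),
                    mrg = do.call(rbind, mrg_l),
                    samples = do.call(rbind, sample_rows)),
    config = cfg
  ), class = "virome_bundle")
  rownames(bundle$annotations) <- NULL
  rownames(bundle$contig_info) <- NULL

  bundle$manifest$samples <- cbind(bundle$manifest$samples,
                                   manifest_fractions(bundle))
  bundle$manifest$samples$x_true <- x_true
  bundle
}

# Ground-truth per-sample fractions, computed with the same weighting
# functions the pipeline uses (so a noiseless round trip is exact by
# definition of the manifest).
manifest_fractions <- function(bundle) {
  mc <- bundle$manifest$contigs
  rows <- lapply(bundle$config$sample_ids, function(sid) {
    tc <- mc[mc$sample_id == sid, , drop = FALSE]
    tpm <- contig_tpm(bundle, sid)
    flags <- stats::setNames(tc$lifestyle == "lysogenic", tc$contig_id)
    hr <- data.frame(contig_id = tc$contig_id, n_genera = tc$n_hosts,
                     polyvalent = tc$n_hosts >= 2L, stringsAsFactors = FALSE)
    suppressWarnings(data.frame(
      lysogeny_fraction = virome_lysogen_fraction(flags, tpm),
      lysogeny_fraction_count = virome_lysogen_fraction(flags, tpm, weighted = FALSE),
      polyvalence_fraction = polyvalent_fraction(hr, tpm),
      polyvalence_fraction_count = polyvalent_fraction(hr, tpm, weighted = FALSE)
    ))
  })
  do.call(rbind, rows)
}

#' Per-contig TPM for one sample of a bundle
#'
#' @param bundle a `virome_bundle`.
#' @param sample_id sample name.
#' @return named numeric TPM over the sample's contig features.
#' @export
contig_tpm <- function(bundle, sample_id) {
  ct <- bundle$counts[[sample_id]]
  ct <- ct[ct$feature_type == "contig", , drop = FALSE]
  stats::setNames(
    compute_tpm(ct$read_count, ct$feature_length_nt),
    ct$feature_id)
}

#' Per-gene TPM for one sample of a bundle
#'
#' @inheritParams contig_tpm
#' @return named numeric TPM over the sample's gene features.
#' @export
gene_tpm <- function(bundle, sample_id) {
  ct <- bundle$counts[[sample_id]]
  ct <- ct[ct$feature_type == "gene", , drop = FALSE]
  stats::setNames(
    compute_tpm(ct$read_count, ct$feature_length_nt),
    ct$feature_id)
}

#' Generate induction-assay measurement triplets
#'
#' Emits (Vi, Vck, B) with Vi = (Vck + X * B) * eps, where eps is Gaussian
#' multiplicative noise with mean 1 and coefficient of variation `noise_cv`
#' (noiseless arithmetic when `noise_cv = 0`), so the recovered
#' (Vi - Vck) / B is unbiased for X.
#'
#' @param B bacterial abundance per gram (> 0), scalar or per-sample vector.
#' @param X true induced phage per cell (>= 0), recycled against B.
#' @param noise_cv coefficient of variation of the noise on Vi (>= 0).
#' @param vck control (background) VLP count per gram.
#' @param n number of replicate triplets per (B, X) pair.
#' @return data.frame: Vi, Vck, B.
#' @export
generate_induction_triplets <- function(B, X, noise_cv = 0, vck = 5e6, n = 1L) {
  if (any(B <= 0)) stop("bacterial abundance B must be > 0")
  if (any(X < 0)) stop("true induction X must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (any(vck < 0)) stop("background Vck must be >= 0")
  k <- max(length(B), length(X), length(vck)) * n
  B <- rep_len(rep(B, each = n), k)
  X <- rep_len(rep(X, each = n), k)
  vck <- rep_len(rep(vck, each = n), k)
  vi <- (vck + X * B) * (if (noise_cv > 0) rnorm(k, 1, noise_cv) else 1)
  data.frame(Vi = vi, Vck = vck, B = B)
}

#' @export
print.virome_bundle <- function(x, ...) {
  cat("Synthetic virome bundle: ", nrow(x$contig_info), " contigs (",
      sum(x$contig_info$type == "viral"), " viral) across ",
      x$config$n_samples, " samples; ",
      nrow(x$spacers), " spacers in ", x$config$n_host_genera,
      " genus libraries", if (is.null(x$contigs)) " (annotation level, no sequences)",
      "\n", sep = "")
  invisible(x)
}
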