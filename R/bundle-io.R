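# Plain-text serialization of community bundles: FASTA for sequences, TSV
# for tables, JSON for the ground-truth manifest. Round-trips through
# write_community_bundle() / read_community_bundle().

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "", ...)
}

#' Write a community bundle to a directory
#'
#' Emits `contigs.fasta`, `annotations.tsv`, `virsorter.tsv`,
#' `contig_info.tsv`, `spacers/<genus>.fasta`, `counts_<sample>.tsv`,
#' `metagenome_<sample>.tsv`, `induction.tsv` and `manifest.json`.
#'
#' @param bundle a `virome_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "virome_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$contigs)) {
    Biostrings::writeXStringSet(bundle$contigs, file.path(dir, "contigs.fasta"))
  }
  write_tsv(bundle$contig_info, file.path(dir, "contig_info.tsv"))
  write_tsv(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(bundle$virsorter, file.path(dir, "virsorter.tsv"))
  if (nrow(bundle$spacers)) {
    spdir <- file.path(dir, "spacers")
    dir.create(spdir, showWarnings = FALSE)
    for (g in sort(unique(bundle$spacers$genus))) {
      sp <- bundle$spacers[bundle$spacers$genus == g, , drop = FALSE]
      ss <- Biostrings::DNAStringSet(sp$sequence)
      names(ss) <- sp$spacer_id
      Biostrings::writeXStringSet(ss, file.path(spdir, paste0(g, ".fasta")))
    }
  }
  for (sid in names(bundle$counts)) {
    write_tsv(bundle$counts[[sid]], file.path(dir, paste0("counts_", sid, ".tsv")))
  }
  for (sid in names(bundle$metagenome)) {
    write_tsv(bundle$metagenome[[sid]], file.path(dir, paste0("metagenome_", sid, ".tsv")))
  }
  write_tsv(bundle$induction, file.path(dir, "induction.tsv"))
  manifest <- bundle$manifest
  manifest$config <- unclass(bundle$config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' Read a community bundle from a directory
#'
#' Inverse of [write_community_bundle()].
#'
#' @param dir directory written by [write_community_bundle()].
#' @return a `virome_bundle`.
#' @export
read_community_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  manifest$config <- NULL
  config <- do.call(gradient_config, cfg[setdiff(names(cfg),
    c("n_samples"))])

  contigs <- NULL
  fa <- file.path(dir, "contigs.fasta")
  if (file.exists(fa)) contigs <- Biostrings::readDNAStringSet(fa)

  spdir <- file.path(dir, "spacers")
  spacers <- data.frame(spacer_id = character(), genus = character(),
                        sequence = character(), stringsAsFactors = FALSE)
  if (dir.exists(spdir)) {
    spacers <- do.call(rbind, lapply(list.files(spdir, full.names = TRUE), function(f) {
      ss <- Biostrings::readDNAStringSet(f)
      data.frame(spacer_id = names(ss),
                 genus = sub("\\.fasta$", "", basename(f)),
                 sequence = as.character(ss), stringsAsFactors = FALSE)
    }))
    rownames(spacers) <- NULL
  }

  read_sample_tables <- function(prefix) {
    files <- list.files(dir, pattern = paste0("^", prefix, "_.*\\.tsv$"))
    out <- lapply(files, function(f) read_tsv(file.path(dir, f)))
    names(out) <- sub(paste0("^", prefix, "_(.*)\\.tsv$"), "\\1", files)
    out[config$sample_ids[config$sample_ids %in% names(out)]]
  }

  structure(list(
    contigs = contigs,
    contig_info = read_tsv(file.path(dir, "contig_info.tsv")),
    annotations = read_tsv(file.path(dir, "annotations.tsv")),
    virsorter = read_tsv(file.path(dir, "virsorter.tsv")),
    spacers = spacers,
    counts = read_sample_tables("counts"),
    metagenome = read_sample_tables("metagenome"),
    induction = read_tsv(file.path(dir, "induction.tsv")),
    manifest = manifest,
    config = config
  ), class = "virome_bundle")
}
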