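# Curated marker-gene lists: phage integrases (Pfam namespace) and
# metal-resistance genes (KEGG orthology namespace), used for lysogeny
# flagging and MRG screening. The lists shipped under inst/extdata are small
# synthetic defaults for demonstration and testing; real analyses should
# substitute the full curated lists for the system under study.

#' Construct a marker-gene list
#'
#' @param name short label for the list.
#' @param namespace annotation namespace the identifiers live in: `"pfam"`
#'   or `"ko"`.
#' @param identifiers character vector of identifiers; must be non-empty,
#'   duplicates are dropped.
#' @return object of class `marker_gene_list`.
#' @export
marker_gene_list <- function(name, namespace = c("pfam", "ko"), identifiers) {
  namespace <- match.arg(namespace)
  identifiers <- unique(as.character(identifiers))
  identifiers <- identifiers[!is.na(identifiers) & identifiers != ""]
  if (!length(identifiers)) stop("marker gene list '", name, "' is empty")
  structure(list(name = name, namespace = namespace, identifiers = identifiers),
            class = "marker_gene_list")
}

#' @export
print.marker_gene_list <- function(x, ...) {
  cat("Marker gene list '", x$name, "' (", x$namespace, "): ",
      length(x$identifiers), " identifiers\n", sep = "")
  invisible(x)
}

#' Read a marker-gene list from a TSV file
#'
#' Expected columns: `namespace`, `id` (one namespace per file); further
#' columns (e.g. description) are ignored.
#'
#' @param path TSV file path.
#' @param name list label; defaults to the file name.
#' @return `marker_gene_list`.
#' @export
read_marker_list <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("namespace", "id") %in% names(tab)))
  ns <- unique(tab$namespace)
  if (length(ns) != 1) stop("marker list file must use a single namespace")
  marker_gene_list(name, ns, tab$id)
}

marker_file <- function(fname) {
  system.file("extdata", fname, package = "viromegrad", mustWork = TRUE)
}

#' Default marker lists (synthetic demonstration sets)
#'
#' Small built-in lists: phage integrase families (Pfam), heavy-metal
#' membrane transporter genes (KO) and metal reductase genes (KO). They are
#' representative defaults for synthetic-community runs, not the full curated
#' tables a production analysis would use.
#'
#' @return `marker_gene_list`.
#' @export
default_integrase_list <- function() read_marker_list(marker_file("integrase_pfams.tsv"), "integrase")

#' @rdname default_integrase_list
#' @export
default_transporter_list <- function() read_marker_list(marker_file("mrg_transporters.tsv"), "mrg_transporter")

#' @rdname default_integrase_list
#' @export
default_reductase_list <- function() read_marker_list(marker_file("mrg_reductases.tsv"), "mrg_reductase")
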