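# Local biological-knowledge tables: gene info (Entrez id, symbol,
# synonyms, gene type), gene->pathway and gene->disease associations, one
# store per species. Lookups are total: an unknown gene yields an empty
# annotation, never an error. The flat-file schema is:
#   gene_info.tsv    symbol <tab> entrez <tab> synonyms (|-separated) <tab> gene_type
#   gene_pathway.tsv symbol <tab> pathway
#   gene_disease.tsv symbol <tab> disease

ANNOTATION_SPECIES <- c("Homo sapiens", "Rattus norvegicus", "Mus musculus")

read_annotation_tsv <- function(path, n_min, col_names) {
  if (!file.exists(path)) stop("missing annotation file: ", path,
                               call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  rows <- lapply(lines, function(l) stringr::str_split(l, "\t")[[1]])
  ok <- lengths(rows) >= n_min
  if (any(!ok)) {
    warning(sprintf("%s: skipped %d malformed row(s)", basename(path),
                    sum(!ok)), call. = FALSE)
  }
  rows <- rows[ok]
  out <- purrr::map_dfr(rows, function(r) {
    vals <- c(r[seq_len(n_min)], rep(NA_character_,
                                     max(0, length(col_names) - n_min)))
    if (length(r) > n_min) {
      extra <- r[(n_min + 1):min(length(r), length(col_names))]
      vals[(n_min + 1):(n_min + length(extra))] <- extra
    }
    stats::setNames(as.list(stringr::str_trim(vals[seq_along(col_names)])),
                    col_names)
  })
  dplyr::distinct(out)
}

#' Load a species annotation store
#'
#' Builds an in-memory annotation store from three flat tab-separated
#' tables: gene info, gene-to-pathway and gene-to-disease associations.
#' Malformed rows are skipped with a warning; duplicate association rows
#' are stored once (set semantics).
#'
#' @param species One of `"Homo sapiens"`, `"Rattus norvegicus"`,
#'   `"Mus musculus"`.
#' @param gene_info_path TSV: symbol, entrez, synonyms (`|`-separated),
#'   gene_type.
#' @param pathway_path TSV: symbol, pathway.
#' @param disease_path TSV: symbol, disease.
#' @param quiet Suppress the row-count log line.
#' @return An `annotation_store` with tibbles `gene_info`, `gene_pathways`,
#'   `gene_diseases`.
#' @export
load_annotations <- function(species, gene_info_path, pathway_path,
                             disease_path, quiet = TRUE) {
  species <- match.arg(species, ANNOTATION_SPECIES)
  gene_info <- read_annotation_tsv(
    gene_info_path, 2, c("symbol", "entrez", "synonyms", "gene_type"))
  gene_pathways <- read_annotation_tsv(pathway_path, 2,
                                       c("symbol", "pathway"))
  gene_diseases <- if (file.size(disease_path) == 0) {
    tibble::tibble(symbol = character(), disease = character())
  } else {
    read_annotation_tsv(disease_path, 2, c("symbol", "disease"))
  }
  if (!quiet) {
    message(sprintf(
      "annotations [%s]: %d genes, %d gene-pathway, %d gene-disease rows",
      species, nrow(gene_info), nrow(gene_pathways), nrow(gene_diseases)))
  }
  structure(list(species = species, gene_info = gene_info,
                 gene_pathways = gene_pathways,
                 gene_diseases = gene_diseases),
            class = "annotation_store")
}

#' Build an annotation store from in-memory tables
#'
#' @param species Species name.
#' @param gene_info Tibble with columns symbol, entrez, synonyms,
#'   gene_type (missing columns filled with NA).
#' @param gene_pathways Tibble symbol, pathway.
#' @param gene_diseases Tibble symbol, disease.
#' @return An `annotation_store`.
#' @export
annotation_store <- function(species = "Homo sapiens",
                             gene_info = NULL, gene_pathways = NULL,
                             gene_diseases = NULL) {
  species <- match.arg(species, ANNOTATION_SPECIES)
  empty <- function(...) tibble::tibble(...)
  gene_info <- tibble::as_tibble(
    gene_info %||% empty(symbol = character(), entrez = character(),
                         synonyms = character(), gene_type = character()))
  for (col in c("entrez", "synonyms", "gene_type")) {
    if (!col %in% names(gene_info)) gene_info[[col]] <- NA_character_
  }
  gene_pathways <- dplyr::distinct(tibble::as_tibble(
    gene_pathways %||% empty(symbol = character(), pathway = character())))
  gene_diseases <- dplyr::distinct(tibble::as_tibble(
    gene_diseases %||% empty(symbol = character(), disease = character())))
  structure(list(species = species, gene_info = gene_info,
                 gene_pathways = gene_pathways,
                 gene_diseases = gene_diseases),
            class = "annotation_store")
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf(
    "<annotation_store %s> %d genes, %d pathway links, %d disease links\n",
    x$species, nrow(x$gene_info), nrow(x$gene_pathways),
    nrow(x$gene_diseases)))
  invisible(x)
}

#' Biological information for one node
#'
#' The content of the per-node pop-up: Entrez id, symbol, synonyms, gene
#' type, associated pathways and diseases. Unknown nodes return an empty
#' record flagged `annotated = FALSE`.
#'
#' @param store An `annotation_store`.
#' @param node_id Node id (gene symbol).
#' @return A list: `node`, `annotated`, `entrez`, `symbol`, `synonyms`
#'   (character vector), `gene_type`, `pathways` (character vector),
#'   `diseases` (character vector).
#' @export
node_info <- function(store, node_id) {
  stopifnot(inherits(store, "annotation_store"))
  gi <- dplyr::filter(store$gene_info, .data$symbol == node_id)
  pw <- sort(unique(
    store$gene_pathways$pathway[store$gene_pathways$symbol == node_id]))
  ds <- sort(unique(
    store$gene_diseases$disease[store$gene_diseases$symbol == node_id]))
  annotated <- nrow(gi) > 0 || length(pw) > 0 || length(ds) > 0
  syn <- if (nrow(gi) > 0 && !is.na(gi$synonyms[1])) {
    stringr::str_split(gi$synonyms[1], stringr::fixed("|"))[[1]]
  } else character()
  list(
    node = node_id,
    annotated = annotated,
    entrez = if (nrow(gi) > 0) gi$entrez[1] else NA_character_,
    symbol = if (nrow(gi) > 0) gi$symbol[1] else NA_character_,
    synonyms = syn,
    gene_type = if (nrow(gi) > 0) gi$gene_type[1] else NA_character_,
    pathways = pw,
    diseases = ds
  )
}

#' Rank pathways by network gene membership
#'
#' For each pathway annotated to any queried gene, counts the distinct
#' network genes associated with it, sorted by count descending with
#' alphabetical tie-break. The full ranking is returned; the conventional
#' report is its top-10 prefix ([top_pathways()]).
#'
#' @param store An `annotation_store`.
#' @param node_ids Character vector of network node ids (duplicates are
#'   ignored — counting is per distinct gene).
#' @return A `pathway_ranking` tibble: `pathway`, `n_genes`, `genes`
#'   (list-column of member symbols present in the query).
#' @export
rank_pathways <- function(store, node_ids) {
  stopifnot(inherits(store, "annotation_store"))
  if (length(node_ids) == 0) stop("node_ids must be non-empty", call. = FALSE)
  node_ids <- unique(node_ids)
  hits <- dplyr::filter(store$gene_pathways, .data$symbol %in% node_ids)
  ranking <- hits %>%
    dplyr::distinct(.data$symbol, .data$pathway) %>%
    dplyr::group_by(.data$pathway) %>%
    dplyr::summarise(n_genes = dplyr::n_distinct(.data$symbol),
                     genes = list(sort(unique(.data$symbol))),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$pathway)
  structure(ranking, class = c("pathway_ranking", class(ranking)))
}

#' Top-10 pathway table
#'
#' @param ranking A `pathway_ranking` from [rank_pathways()].
#' @param n Number of pathways to keep (default 10; fewer if fewer exist).
#' @return The first `n` rows of the ranking.
#' @export
top_pathways <- function(ranking, n = 10) {
  utils::head(ranking, n)
}

#' Export a pathway ranking as TSV
#'
#' Writes the complete list of pathways and associated network genes
#' (columns: pathway, n_genes, genes `;`-separated).
#'
#' @param ranking A `pathway_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_ranking <- function(ranking, path) {
  flat <- tibble::tibble(
    pathway = ranking$pathway,
    n_genes = ranking$n_genes,
    genes = vapply(ranking$genes, paste, "", collapse = ";")
  )
  readr::write_tsv(flat, path)
  invisible(path)
}
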