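# OrthologMap: cross-namespace gene -> homolog-group relation used to
# compare ranked gene lists between datasets (e.g. Homologene groups
# linking two array platforms or species).

#' Construct an ortholog map
#'
#' An ortholog map is a set of `(gene_id_a, gene_id_b, homolog_group_id)`
#' triples. Homolog groups must partition the mapped genes: a gene id
#' appearing in two different groups (on either side) is rejected. Duplicate
#' identical triples are collapsed. Genes absent from the map are simply
#' unmapped.
#'
#' @param pairs `data.frame` with columns `gene_id_a`, `gene_id_b`,
#'   `homolog_group_id`.
#' @return Object of class `ortholog_map` (a canonically sorted data frame).
#' @export
ortholog_map <- function(pairs) {
  req <- c("gene_id_a", "gene_id_b", "homolog_group_id")
  if (!all(req %in% names(pairs)))
    stop_("ortholog map needs columns: %s", paste(req, collapse = ", "))
  pairs <- unique(as.data.frame(pairs)[, req])
  for (cn in req) pairs[[cn]] <- as.character(pairs[[cn]])
  if (anyNA(pairs)) stop_("ortholog map contains missing values")
  for (side in c("gene_id_a", "gene_id_b")) {
    grp <- unique(pairs[, c(side, "homolog_group_id")])
    bad <- unique(grp[[side]][duplicated(grp[[side]])])
    if (length(bad))
      stop_("gene(s) assigned to more than one homolog group: %s",
            paste(bad, collapse = ", "))
  }
  pairs <- pairs[order(pairs$homolog_group_id, pairs$gene_id_a, pairs$gene_id_b), ]
  rownames(pairs) <- NULL
  structure(pairs, class = c("ortholog_map", "data.frame"))
}

#' Read an ortholog map from a TSV file
#'
#' @param path TSV with columns `gene_id_a`, `gene_id_b`, `homolog_group_id`.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  ortholog_map(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Gene -> homolog-group lookup for one side of the map
#' @noRd
homolog_lookup <- function(map, side = c("a", "b")) {
  side <- match.arg(side)
  col <- paste0("gene_id_", side)
  u <- unique(map[, c(col, "homolog_group_id")])
  stats::setNames(u$homolog_group_id, u[[col]])
}
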