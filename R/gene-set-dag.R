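# GeneSetDAG: gene-set terms with parent edges and true-path propagated
# annotations, supporting conditional over-representation testing.

#' Construct a gene-set DAG
#'
#' Terms form a directed acyclic graph via parent edges; gene annotations are
#' propagated by the true-path rule (a gene annotated to a term is implicitly
#' annotated to every ancestor). A GMT-style flat collection is the special
#' case where every term is parentless.
#'
#' @param terms `data.frame` with columns `term_id`, `name` and `parents`
#'   (semicolon-separated parent term ids, `""` for roots) or a list column
#'   of character vectors.
#' @param annotations `data.frame` with columns `gene_id`, `term_id` giving
#'   direct assignments.
#' @return Object of class `gene_set_dag` with elements `terms` (data frame,
#'   `parents` as a list column), `annotations`, and `propagated` (named list
#'   of gene-id vectors after true-path closure).
#' @export
gene_set_dag <- function(terms, annotations) {
  if (!all(c("term_id", "name") %in% names(terms)))
    stop_("terms need columns term_id, name")
  terms <- as.data.frame(terms)
  terms$term_id <- as.character(terms$term_id)
  terms$name <- as.character(terms$name)
  if (anyDuplicated(terms$term_id))
    stop_("duplicate term id(s): %s",
          paste(unique(terms$term_id[duplicated(terms$term_id)]), collapse = ", "))
  if (is.null(terms$parents)) terms$parents <- ""
  parents <- terms$parents
  if (!is.list(parents)) {
    parents <- lapply(as.character(parents), function(p) {
      p <- trimws(strsplit(p, ";", fixed = TRUE)[[1L]])
      p[nzchar(p)]
    })
  }
  names(parents) <- terms$term_id
  unknown <- setdiff(unique(unlist(parents)), terms$term_id)
  if (length(unknown))
    stop_("parent reference(s) to unknown term(s): %s", paste(unknown, collapse = ", "))

  if (!all(c("gene_id", "term_id") %in% names(annotations)))
    stop_("annotations need columns gene_id, term_id")
  annotations <- unique(as.data.frame(annotations)[, c("gene_id", "term_id")])
  annotations$gene_id <- as.character(annotations$gene_id)
  annotations$term_id <- as.character(annotations$term_id)
  bad <- setdiff(unique(annotations$term_id), terms$term_id)
  if (length(bad))
    stop_("annotation(s) reference unknown term(s): %s", paste(bad, collapse = ", "))

  order_ids <- topo_sort(parents)  # roots first; errors on a cycle

  direct <- split(annotations$gene_id, factor(annotations$term_id, levels = terms$term_id))
  children <- lapply(stats::setNames(vector("list", nrow(terms)), terms$term_id), identity)
  for (tid in terms$term_id)
    for (p in parents[[tid]]) children[[p]] <- c(children[[p]], tid)

  propagated <- stats::setNames(vector("list", nrow(terms)), terms$term_id)
  for (tid in rev(order_ids)) {  # leaves first
    gs <- direct[[tid]]
    for (ch in children[[tid]]) gs <- c(gs, propagated[[ch]])
    propagated[[tid]] <- sort(unique(gs))
  }

  ord <- order(terms$term_id)
  terms <- terms[ord, c("term_id", "name")]
  terms$parents <- lapply(parents[terms$term_id], sort)
  rownames(terms) <- NULL
  annotations <- annotations[order(annotations$term_id, annotations$gene_id), ]
  rownames(annotations) <- NULL
  structure(list(terms = terms, annotations = annotations,
                 propagated = propagated[terms$term_id]),
            class = "gene_set_dag")
}

# Kahn topological sort over the child -> parents relation; returns term ids
# with every parent before its children, alphabetical tie-break. Errors with
# one explicit cycle if the graph is not acyclic.
#' @noRd
topo_sort <- function(parents) {
  ids <- sort(names(parents))
  indeg <- vapply(parents[ids], length, integer(1L))  # unresolved parents
  children <- lapply(stats::setNames(vector("list", length(ids)), ids), identity)
  for (tid in ids) for (p in parents[[tid]]) children[[p]] <- c(children[[p]], tid)
  out <- character(0)
  ready <- ids[indeg == 0L]
  while (length(ready)) {
    ready <- sort(ready)
    nxt <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, nxt)
    for (ch in children[[nxt]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(out) < length(ids)) {
    rem <- setdiff(ids, out)
    cyc <- find_cycle(parents, rem)
    stop_("cycle in term parent graph: %s", paste(cyc, collapse = " -> "))
  }
  out
}

#' @noRd
find_cycle <- function(parents, remaining) {
  cur <- remaining[1L]
  path <- character(0)
  repeat {
    if (cur %in% path) {
      i <- match(cur, path)
      return(c(path[i:length(path)], cur))
    }
    path <- c(path, cur)
    nxt <- intersect(parents[[cur]], remaining)
    cur <- nxt[1L]
  }
}

#' Read gene sets from a GMT file or a two-file DAG dialect
#'
#' GMT: one set per line, tab-separated fields `set_id`, `description`, then
#' gene ids; yields a flat DAG (all terms parentless, propagated == direct).
#' DAG dialect: a term table (`term_id`, `name`, `parents` semicolon-
#' separated) plus an annotation table (`gene_id`, `term_id`); annotations
#' are propagated by the true-path rule.
#'
#' @param gmt_path Path to a GMT file (mutually exclusive with the pair
#'   below).
#' @param terms_path,annotations_path Paths to the term and annotation TSVs.
#' @return A [gene_set_dag()].
#' @export
read_gene_sets <- function(gmt_path = NULL, terms_path = NULL, annotations_path = NULL) {
  if (!is.null(gmt_path)) {
    lines <- readLines(gmt_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(fields, length, integer(1L)) < 3L)
    if (length(short))
      stop_("GMT line %d has fewer than 3 fields", short[1L])
    terms <- data.frame(term_id = vapply(fields, `[[`, "", 1L),
                        name = vapply(fields, `[[`, "", 2L),
                        parents = "", stringsAsFactors = FALSE)
    annotations <- do.call(rbind, lapply(fields, function(f)
      data.frame(gene_id = f[-(1:2)], term_id = f[[1L]], stringsAsFactors = FALSE)))
    return(gene_set_dag(terms, annotations))
  }
  if (is.null(terms_path) || is.null(annotations_path))
    stop_("provide either gmt_path or both terms_path and annotations_path")
  terms <- utils::read.delim(terms_path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character")
  annotations <- utils::read.delim(annotations_path, sep = "\t",
                                   stringsAsFactors = FALSE, colClasses = "character")
  gene_set_dag(terms, annotations)
}

#' Write a gene-set DAG as a GMT file (propagated sets)
#' @noRd
write_gmt <- function(dag, path) {
  lines <- vapply(seq_len(nrow(dag$terms)), function(i) {
    tid <- dag$terms$term_id[i]
    paste(c(tid, dag$terms$name[i], dag$propagated[[tid]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' @export
print.gene_set_dag <- function(x, ...) {
  n_root <- sum(vapply(x$terms$parents, length, integer(1L)) == 0L)
  cat(sprintf("gene_set_dag: %d terms (%d roots), %d direct annotations, %d genes\n",
              nrow(x$terms), n_root, nrow(x$annotations),
              length(unique(x$annotations$gene_id))))
  invisible(x)
}
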