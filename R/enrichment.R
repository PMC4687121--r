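# Conditional hypergeometric over-representation on a gene-set DAG, with
# Count/Global reporting, term-similarity and enrichment-map clustering.

#' Conditional hypergeometric over-representation test
#'
#' Tests each term's propagated gene set for over-representation of the
#' significant genes by the upper-tail hypergeometric probability, walking
#' the DAG children-before-parents: when a term reaches `p <
#' alpha_condition`, its (propagated) genes are removed from every
#' ancestor's gene set before the ancestor is tested, so a parent is only
#' called on signal not already explained by a significant child. Reported
#' `count` (significant genes in the term) and `global` (term size in the
#' universe) reflect the post-conditioning sets. On a flat collection (no
#' parents) this reduces to the plain per-term hypergeometric test.
#'
#' @param dag A [gene_set_dag()].
#' @param sig_genes Character vector of significant gene ids (subset of
#'   `universe`).
#' @param universe Character vector of all tested gene ids.
#' @param alpha_condition Unadjusted-p threshold that triggers conditioning
#'   (default 0.05).
#' @return Object of class `enrichment_result`: `data.frame` with columns
#'   `term_id`, `name`, `p`, `fdr_p`, `count`, `global`, sorted by
#'   ascending p (ties by term id); attribute `n_sig`, `n_universe`.
#' @export
conditional_enrich <- function(dag, sig_genes, universe, alpha_condition = 0.05) {
  stopifnot(inherits(dag, "gene_set_dag"))
  sig_genes <- unique(as.character(sig_genes))
  universe <- unique(as.character(universe))
  extra <- setdiff(sig_genes, universe)
  if (length(extra))
    stop_("significant gene(s) outside the universe: %s",
          paste(utils::head(extra, 5L), collapse = ", "))

  parents <- stats::setNames(dag$terms$parents, dag$terms$term_id)
  order_ids <- topo_sort(parents)          # parents first
  ancestors <- ancestor_closure(parents, order_ids)

  term_genes <- lapply(dag$propagated, intersect, universe)
  removed <- stats::setNames(vector("list", length(term_genes)), names(term_genes))
  n_uni <- length(universe)
  n_sig <- length(sig_genes)

  ids <- rev(order_ids)                    # children before parents
  p <- count <- global <- stats::setNames(numeric(length(ids)), ids)
  for (tid in ids) {
    gs <- setdiff(term_genes[[tid]], removed[[tid]])
    cnt <- length(intersect(gs, sig_genes))
    glob <- length(gs)
    pv <- if (glob == 0L) 1 else
      stats::phyper(cnt - 1L, n_sig, n_uni - n_sig, glob, lower.tail = FALSE)
    p[tid] <- pv; count[tid] <- cnt; global[tid] <- glob
    if (pv < alpha_condition && glob > 0L) {
      for (anc in ancestors[[tid]])
        removed[[anc]] <- union(removed[[anc]], gs)
    }
  }
  res <- data.frame(term_id = ids,
                    name = dag$terms$name[match(ids, dag$terms$term_id)],
                    p = unname(p), count = as.integer(unname(count)),
                    global = as.integer(unname(global)),
                    stringsAsFactors = FALSE)
  res$fdr_p <- bh_adjust(res$p)
  res <- res[order(res$p, res$term_id), c("term_id", "name", "p", "fdr_p", "count", "global")]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"),
            n_sig = n_sig, n_universe = n_uni,
            alpha_condition = alpha_condition)
}

# Full ancestor sets for every term (parents-first order assumed).
#' @noRd
ancestor_closure <- function(parents, order_ids) {
  anc <- stats::setNames(vector("list", length(order_ids)), order_ids)
  for (tid in order_ids) {   # parents come before children
    a <- character(0)
    for (p in parents[[tid]]) a <- c(a, p, anc[[p]])
    anc[[tid]] <- unique(a)
  }
  anc
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat(sprintf("enrichment_result: %d terms, %d significant genes of %d in universe\n",
              nrow(x), attr(x, "n_sig"), attr(x, "n_universe")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' Similarity between two gene sets
#'
#' Jaccard index `|A n B| / |A u B|` (default) or the overlap coefficient
#' `|A n B| / min(|A|, |B|)`; two empty sets have similarity 0.
#'
#' @param a,b Character vectors of gene ids.
#' @param method `"jaccard"` or `"overlap"`.
#' @return Similarity in `[0, 1]`.
#' @export
term_similarity <- function(a, b, method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b)
  i <- length(intersect(a, b))
  denom <- if (method == "jaccard") length(union(a, b)) else min(length(a), length(b))
  if (denom == 0L) 0 else i / denom
}

#' Cluster enriched terms by gene-set similarity
#'
#' Average-linkage agglomerative clustering on one minus the pairwise term
#' similarity, cut at the coarsest grouping (fewest clusters) in which every
#' cluster's mean pairwise member similarity reaches `threshold`
#' (singletons trivially qualify). Each cluster is represented by its most
#' significant term (smallest p; ties broken by larger `global`, then term
#' id).
#'
#' @param result An [conditional_enrich()] result (or any data frame with
#'   `term_id`, `p`, `global`), typically filtered to significant terms.
#' @param dag The [gene_set_dag()] the terms came from.
#' @param universe Gene universe used for the gene sets.
#' @param threshold Required mean within-cluster similarity (e.g. 0.9).
#' @param method Similarity measure, see [term_similarity()].
#' @return `data.frame` with columns `term_id`, `cluster`, `representative`
#'   (logical).
#' @export
cluster_terms <- function(result, dag, universe, threshold = 0.9,
                          method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  ids <- result$term_id
  if (!length(ids)) stop_("no terms to cluster")
  sets <- lapply(dag$propagated[ids], intersect, universe)
  n <- length(ids)
  sim <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      sim[i, j] <- sim[j, i] <- term_similarity(sets[[i]], sets[[j]], method)
    }
  }
  assign_cl <- cut_by_similarity(sim, threshold)
  rep_flag <- logical(n)
  for (cl in unique(assign_cl)) {
    members <- which(assign_cl == cl)
    o <- order(result$p[members], -result$global[members], ids[members])
    rep_flag[members[o[1L]]] <- TRUE
  }
  data.frame(term_id = ids, cluster = assign_cl, representative = rep_flag,
             stringsAsFactors = FALSE)
}

# Coarsest dendrogram cut whose clusters all satisfy the mean-similarity
# threshold (scan k = 1..n over the average-linkage tree).
#' @noRd
cut_by_similarity <- function(sim, threshold) {
  n <- nrow(sim)
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  for (k in seq_len(n)) {
    cl <- stats::cutree(hc, k = k)
    ok <- all(vapply(split(seq_len(n), cl), function(members) {
      if (length(members) < 2L) return(TRUE)
      pairs <- utils::combn(members, 2L)
      mean(sim[cbind(pairs[1L, ], pairs[2L, ])]) >= threshold
    }, logical(1L)))
    if (ok) return(unname(cl))
  }
  seq_len(n)
}

#' Node and edge tables for an enrichment map
#'
#' Emits a node table (one row per term with its statistics) and an edge
#' table (pairwise term similarities above `min_similarity`) suitable for
#' external graph rendering.
#'
#' @inheritParams cluster_terms
#' @param min_similarity Minimum similarity for an edge (default 0, i.e.
#'   any positive overlap).
#' @return List with `nodes` and `edges` data frames.
#' @export
enrichment_map_tables <- function(result, dag, universe, min_similarity = 0,
                                  method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  ids <- result$term_id
  sets <- lapply(dag$propagated[ids], intersect, universe)
  nodes <- as.data.frame(result)[, c("term_id", "name", "p", "fdr_p", "count", "global")]
  edges <- NULL
  n <- length(ids)
  if (n > 1L) {
    pairs <- utils::combn(n, 2L)
    w <- apply(pairs, 2L, function(ij)
      term_similarity(sets[[ij[1L]]], sets[[ij[2L]]], method))
    keep <- w > min_similarity
    edges <- data.frame(term_a = ids[pairs[1L, keep]],
                        term_b = ids[pairs[2L, keep]],
                        similarity = w[keep], stringsAsFactors = FALSE)
  }
  list(nodes = nodes,
       edges = edges %||% data.frame(term_a = character(0), term_b = character(0),
                                     similarity = numeric(0)))
}
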