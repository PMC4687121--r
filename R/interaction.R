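# Genotype x model interaction: genes whose mutant-vs-wild-type expression
# difference differs between two datasets (models), with per-model fold
# changes and their absolute difference.

#' Test for a genotype-by-model interaction per shared gene
#'
#' Matches genes between the two studies through the ortholog map, builds
#' one gene-level expression profile per study (probesets averaged, then
#' median-centred per gene within each study to absorb platform offsets;
#' the centring does not affect the interaction test, which is invariant to
#' per-model shifts), pools all ages, and fits per gene the least-squares
#' model `expression ~ genotype + model + genotype:model`. The reported
#' p-value is the extra-sum-of-squares F-test of the interaction term
#' (equivalent to the squared t-test of the coefficient); `fc_a` and `fc_b`
#' are the within-model MUT - WT contrasts, and `abs_fc_diff = |fc_a -
#' fc_b|`. q-values are Benjamini-Hochberg adjusted.
#'
#' @param study_a,study_b [expression_study()] objects, each with WT and
#'   MUT samples.
#' @param map An [ortholog_map()] linking the two gene namespaces, or
#'   `NULL` when both studies already share gene ids.
#' @return Object of class `interaction_result`: `data.frame` with columns
#'   `id` (homolog group or gene id), `gene_id_a`, `gene_id_b`, `fc_a`,
#'   `fc_b`, `abs_fc_diff`, `p_interaction`, `q`, sorted by ascending
#'   `p_interaction`; attribute `n_unmatched` counts genes present in only
#'   one model.
#' @export
interaction_test <- function(study_a, study_b, map = NULL) {
  stopifnot(inherits(study_a, "expression_study"),
            inherits(study_b, "expression_study"))
  ga <- gene_matrix(study_a)
  gb <- gene_matrix(study_b)
  if (is.null(map)) {
    shared <- intersect(rownames(ga), rownames(gb))
    ids_a <- stats::setNames(shared, shared)
    ids_b <- ids_a
  } else {
    la <- homolog_lookup(map, "a")
    lb <- homolog_lookup(map, "b")
    grp_a <- la[rownames(ga)]
    grp_b <- lb[rownames(gb)]
    shared <- intersect(grp_a[!is.na(grp_a)], grp_b[!is.na(grp_b)])
    # one gene per homolog group and side (first gene id, deterministic)
    pick <- function(grp) {
      ok <- !is.na(grp) & grp %in% shared
      d <- data.frame(gene = names(grp)[ok], grp = unname(grp[ok]))
      d <- d[order(d$grp, d$gene), , drop = FALSE]
      d <- d[!duplicated(d$grp), , drop = FALSE]
      stats::setNames(d$gene, d$grp)
    }
    shared <- sort(shared)
    ids_a <- pick(grp_a)[shared]
    ids_b <- pick(grp_b)[shared]
  }
  if (!length(shared)) stop_("no genes shared between the two studies")
  n_unmatched <- (nrow(ga) - length(shared)) + (nrow(gb) - length(shared))

  ya <- ga[ids_a, , drop = FALSE]
  yb <- gb[ids_b, , drop = FALSE]
  # median-centre per gene within each study
  ya <- ya - apply(ya, 1L, stats::median)
  yb <- yb - apply(yb, 1L, stats::median)

  gt <- factor(c(as.character(study_a$design$genotype),
                 as.character(study_b$design$genotype)), levels = c("WT", "MUT"))
  mdl <- factor(rep(c("A", "B"), c(ncol(ya), ncol(yb))))
  y <- cbind(ya, yb)

  x_full <- stats::model.matrix(~ gt * mdl)
  x_null <- stats::model.matrix(~ gt + mdl)
  rss <- function(x) {
    q <- qr.Q(qr(x))
    rowSums(y^2) - rowSums((y %*% q)^2)
  }
  rss1 <- rss(x_full)
  rss0 <- rss(x_null)
  df_den <- ncol(y) - ncol(x_full)
  if (df_den < 1L) stop_("no residual degrees of freedom")
  f <- pmax(rss0 - rss1, 0) / (rss1 / df_den)
  p <- stats::pf(f, 1L, df_den, lower.tail = FALSE)

  fc_within <- function(ym, design) {
    wt <- design$sample_id[design$genotype == "WT"]
    mut <- design$sample_id[design$genotype == "MUT"]
    rowMeans(ym[, mut, drop = FALSE]) - rowMeans(ym[, wt, drop = FALSE])
  }
  fc_a <- fc_within(ya, study_a$design)
  fc_b <- fc_within(yb, study_b$design)

  res <- data.frame(id = shared,
                    gene_id_a = unname(ids_a), gene_id_b = unname(ids_b),
                    fc_a = unname(fc_a), fc_b = unname(fc_b),
                    abs_fc_diff = abs(unname(fc_a) - unname(fc_b)),
                    p_interaction = unname(p),
                    stringsAsFactors = FALSE)
  res$q <- bh_adjust(res$p_interaction)
  res <- res[order(res$p_interaction, res$id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("interaction_result", "data.frame"),
            n_unmatched = n_unmatched)
}

# One expression row per annotated gene (probesets averaged).
#' @noRd
gene_matrix <- function(study) {
  genes <- probeset_genes(study)
  keep <- !is.na(genes)
  m <- study$matrix[keep, , drop = FALSE]
  g <- genes[keep]
  out <- rowsum(m, group = g) / as.vector(table(g)[sort(unique(g))])
  out[sort(unique(g)), , drop = FALSE]
}

#' @export
print.interaction_result <- function(x, n = 10L, ...) {
  cat(sprintf("interaction_result: %d shared genes (%d unmatched), %d at p < 0.05\n",
              nrow(x), attr(x, "n_unmatched"), sum(x$p_interaction < 0.05)))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' Filter and rank divergent genes
#'
#' Retains genes with a significant interaction (`p_interaction <
#' p_threshold`) whose per-model fold changes differ by strictly more than
#' `min_abs_diff` log2 units, sorted by descending absolute fold-change
#' difference.
#'
#' @param result An [interaction_test()] result.
#' @param p_threshold Interaction p-value threshold (default 0.05).
#' @param min_abs_diff Strict lower bound on `abs_fc_diff` (default 0.20).
#' @return The filtered, re-sorted `interaction_result` rows.
#' @export
rank_divergent <- function(result, p_threshold = 0.05, min_abs_diff = 0.20) {
  keep <- result$p_interaction < p_threshold & result$abs_fc_diff > min_abs_diff
  out <- as.data.frame(result)[keep, , drop = FALSE]
  out <- out[order(-out$abs_fc_diff, out$p_interaction, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
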