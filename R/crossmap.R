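# Cross-dataset comparison: collapsing ranked probeset lists to homolog
# groups, top-N overlap statistics (hypergeometric and permutation), and
# the direction-split rank-bin concordance profile.

#' Collapse a ranked DE result to homolog groups
#'
#' Probesets are first collapsed to unique gene ids keeping, per gene, the
#' entry with smallest p (ties: larger |log2FC|, then probeset id); genes
#' are then mapped to homolog group ids through the ortholog map, and genes
#' of the same homolog group within this dataset are again collapsed by
#' best p. Unmapped genes are recorded and excluded. The output is re-ranked
#' by ascending p with the same deterministic tie-break.
#'
#' @param de A [de_contrast()] result (carries gene annotations).
#' @param map An [ortholog_map()], or `NULL` to stop at gene ids (each gene
#'   becomes its own group, for same-platform comparisons).
#' @param side Which side of the map this dataset's gene ids live on:
#'   `"a"`, `"b"` or `"auto"` (pick the side matching more gene ids).
#' @return Object of class `ranked_gene_list`: `data.frame` with columns
#'   `id` (homolog group), `gene_id`, `probeset_id`, `signed_stat` (log2FC),
#'   `p`, `rank`; attributes `unmapped_genes`, `unmapped_fraction`, `side`.
#' @export
collapse_to_homologs <- function(de, map = NULL, side = c("auto", "a", "b")) {
  side <- match.arg(side)
  stopifnot(inherits(de, "de_result"))
  x <- as.data.frame(de)
  x <- x[!is.na(x$gene_id), , drop = FALSE]
  if (!nrow(x)) stop_("no probesets with gene annotation")
  # best-p collapse to genes (input is already in rank order, which encodes
  # the p / |log2FC| / probeset id tie-break)
  x <- x[order(x$p, -abs(x$log2fc), x$probeset_id), , drop = FALSE]
  x <- x[!duplicated(x$gene_id), , drop = FALSE]

  if (is.null(map)) {
    x$id <- x$gene_id
    unmapped <- character(0)
  } else {
    if (side == "auto") {
      hits_a <- sum(x$gene_id %in% map$gene_id_a)
      hits_b <- sum(x$gene_id %in% map$gene_id_b)
      side <- if (hits_a >= hits_b) "a" else "b"
    }
    lookup <- homolog_lookup(map, side)
    x$id <- unname(lookup[x$gene_id])
    unmapped <- x$gene_id[is.na(x$id)]
    x <- x[!is.na(x$id), , drop = FALSE]
    if (!nrow(x)) stop_("no genes map to homolog groups")
    # within-dataset best-p collapse of multi-gene homolog groups
    x <- x[!duplicated(x$id), , drop = FALSE]
  }
  out <- data.frame(id = x$id, gene_id = x$gene_id, probeset_id = x$probeset_id,
                    signed_stat = x$log2fc, p = x$p,
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  n_genes <- nrow(out) + length(unmapped)
  structure(out, class = c("ranked_gene_list", "data.frame"),
            unmapped_genes = unmapped,
            unmapped_fraction = length(unmapped) / n_genes,
            side = if (is.null(map)) NA_character_ else side,
            label = attr(de, "label"))
}

#' @export
print.ranked_gene_list <- function(x, n = 6L, ...) {
  cat(sprintf("ranked_gene_list '%s': %d homolog groups (%.1f%% of genes unmapped)\n",
              attr(x, "label") %||% "", nrow(x), 100 * attr(x, "unmapped_fraction")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' @noRd
resolve_universe <- function(list_a, list_b, universe = "intersection", fixed_n = NULL) {
  switch(universe,
         intersection = intersect(list_a$id, list_b$id),
         union = union(list_a$id, list_b$id),
         fixed = {
           if (!is_count(fixed_n, min = 1)) stop_("fixed universe needs fixed_n >= 1")
           NULL
         },
         stop_("unknown universe policy '%s'", universe))
}

#' Hypergeometric top-list overlap test
#'
#' Tests whether the top `top_a` entries of one ranked list share more ids
#' with the top `top_b` entries of another than expected by chance, via the
#' upper-tail hypergeometric probability `P[X >= k]` over a stated universe.
#' The universe policy is explicit because it dominates the p-value: the
#' default is the intersection of the two collapsed lists; alternatives are
#' their union or a fixed size (top lists are always restricted to the
#' universe before counting).
#'
#' @param list_a,list_b [collapse_to_homologs()] results on a shared
#'   homolog namespace.
#' @param top_a,top_b Top-list sizes (default 1000).
#' @param universe `"intersection"`, `"union"` or `"fixed"`.
#' @param fixed_n Universe size when `universe = "fixed"`.
#' @return Object of class `overlap_result`: list with `k`, `n1`, `n2`
#'   (top sizes within the universe), `n_universe`, `p_hyper`, `universe`
#'   (policy), `overlap_ids`.
#' @export
overlap_hypergeom <- function(list_a, list_b, top_a = 1000L, top_b = 1000L,
                              universe = c("intersection", "union", "fixed"),
                              fixed_n = NULL) {
  universe <- match.arg(universe)
  if (top_a > nrow(list_a) || top_b > nrow(list_b))
    stop_("top size exceeds list length (%d/%d vs %d/%d)",
          top_a, nrow(list_a), top_b, nrow(list_b))
  uni <- resolve_universe(list_a, list_b, universe, fixed_n)
  n_uni <- if (universe == "fixed") fixed_n else length(uni)
  if (n_uni < max(top_a, top_b))
    stop_("universe size %d smaller than a top-list size", n_uni)
  in_uni <- function(ids) if (universe == "fixed") ids else intersect(ids, uni)
  ta <- in_uni(list_a$id[seq_len(top_a)])
  tb <- in_uni(list_b$id[seq_len(top_b)])
  k <- length(intersect(ta, tb))
  p <- stats::phyper(k - 1L, length(ta), n_uni - length(ta), length(tb),
                     lower.tail = FALSE)
  structure(list(k = k, n1 = length(ta), n2 = length(tb), n_universe = n_uni,
                 p_hyper = p, universe = universe,
                 overlap_ids = sort(intersect(ta, tb))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d/%d vs top %d (universe %d, policy '%s'), p_hyper = %.4g\n",
              x$k, x$n1, x$n2, x$n_universe, x$universe, x$p_hyper))
  if (!is.null(x$p_perm))
    cat(sprintf("permutation p = %.4g (%d resamples)\n", x$p_perm, x$reps))
  invisible(x)
}

#' Permutation p-value for a top-list overlap
#'
#' Resamples the top-A id set uniformly without replacement from the
#' universe and counts resamples whose overlap with the fixed top-B set
#' reaches the observed count; `p = (1 + #exceed) / (reps + 1)`, floored at
#' `1 / (reps + 1)`.
#'
#' @inheritParams overlap_hypergeom
#' @param reps Number of resamples (>= 100; default 10000).
#' @param seed Integer seed (the caller's RNG state is untouched).
#' @return The [overlap_hypergeom()] result augmented with `p_perm`, `reps`.
#' @export
overlap_permutation <- function(list_a, list_b, top_a = 1000L, top_b = 1000L,
                                universe = c("intersection", "union", "fixed"),
                                fixed_n = NULL, reps = 10000L, seed = 1L) {
  universe <- match.arg(universe)
  if (reps < 100L) stop_("reps must be >= 100")
  obs <- overlap_hypergeom(list_a, list_b, top_a, top_b, universe, fixed_n)
  uni <- if (universe == "fixed") {
    # fixed-N universe: ids beyond the two lists are anonymous filler
    c(union(list_a$id, list_b$id),
      sprintf(".filler%d", seq_len(max(0L, fixed_n - length(union(list_a$id, list_b$id))))))
  } else resolve_universe(list_a, list_b, universe, fixed_n)
  tb <- if (universe == "fixed") list_b$id[seq_len(top_b)] else
    intersect(list_b$id[seq_len(top_b)], uni)
  n_draw <- obs$n1
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(reps), function(i) {
      draw <- sample(uni, n_draw)
      length(intersect(draw, tb)) >= obs$k
    }, logical(1L)))
  })
  obs$p_perm <- (1 + exceed) / (reps + 1)
  obs$reps <- as.integer(reps)
  obs
}

#' Direction-split rank-bin concordance profile
#'
#' For each of the top `k` entries of list A, locates its homolog group in
#' the full ranking of list B, assigns it to a consecutive rank bin of
#' `bin_size` entries (the last bin may be short), and splits the bin count
#' by whether the direction of change agrees (concordant) or disagrees
#' (discordant) between the two datasets. Frequencies are fractions of `k`;
#' top-A entries absent from list B contribute to `unmapped_fraction`, so
#' the bin frequencies plus the unmapped fraction sum to one. A
#' concentration of concordant mass in the first bins indicates a shared
#' expression signature.
#'
#' @param list_a,list_b [collapse_to_homologs()] results on a shared
#'   homolog namespace.
#' @param k Top-list size taken from list A (default 200).
#' @param bin_size Rank bin width in list B (default 1000).
#' @return Object of class `concordance_profile`: `data.frame` with columns
#'   `bin`, `concordant_freq`, `discordant_freq`; attributes `k`,
#'   `bin_size`, `unmapped_fraction`, `n_b`.
#' @export
concordance_profile <- function(list_a, list_b, k = 200L, bin_size = 1000L) {
  if (k > nrow(list_a)) stop_("k = %d exceeds list A length %d", k, nrow(list_a))
  if (!is_count(bin_size, min = 1)) stop_("bin_size must be a positive integer")
  n_b <- nrow(list_b)
  n_bins <- max(1L, as.integer(ceiling(n_b / bin_size)))
  top <- list_a[seq_len(k), , drop = FALSE]
  pos <- match(top$id, list_b$id)
  mapped <- !is.na(pos)
  bin <- ceiling(pos[mapped] / bin_size)
  sign_a <- sign(top$signed_stat[mapped])
  sign_b <- sign(list_b$signed_stat[pos[mapped]])
  conc <- sign_a == sign_b
  cf <- tabulate(bin[conc], nbins = n_bins) / k
  df <- tabulate(bin[!conc], nbins = n_bins) / k
  structure(data.frame(bin = seq_len(n_bins), concordant_freq = cf,
                       discordant_freq = df),
            class = c("concordance_profile", "data.frame"),
            k = as.integer(k), bin_size = as.integer(bin_size),
            unmapped_fraction = sum(!mapped) / k, n_b = n_b)
}

#' @export
print.concordance_profile <- function(x, ...) {
  cat(sprintf(
    "concordance_profile: top %d vs %d ranked entries in %d bin(s) of %d (unmapped %.3f)\n",
    attr(x, "k"), attr(x, "n_b"), nrow(x), attr(x, "bin_size"),
    attr(x, "unmapped_fraction")))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Stacked-bar plot of a concordance profile
#'
#' Concordant fractions in green, discordant in red, per rank bin, in the
#' style of a cross-dataset concordance figure.
#'
#' @param x A [concordance_profile()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.concordance_profile <- function(x, ...) {
  h <- t(as.matrix(as.data.frame(x)[, c("concordant_freq", "discordant_freq")]))
  graphics::barplot(h, names.arg = x$bin, col = c("forestgreen", "firebrick"),
                    border = NA, xlab = "rank bin in comparison dataset",
                    ylab = sprintf("fraction of top %d", attr(x, "k")), ...)
  graphics::legend("topright", fill = c("forestgreen", "firebrick"),
                   legend = c("concordant", "discordant"), bty = "n")
  invisible(x)
}
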