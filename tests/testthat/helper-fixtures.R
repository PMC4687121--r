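# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (enumeration, brute force) and never reuse package internals.

# --- fixtures ---------------------------------------------------------------

# Tiny complete study: n_ps probesets, 2 genotypes x n_times x n_reps.
make_study <- function(n_ps = 6, n_times = 3, n_reps = 3, seed = 42,
                       genes = NULL) {
  set.seed(seed)
  design <- expand.grid(rep = seq_len(n_reps), time = seq_len(n_times) * 6,
                        genotype = c("WT", "MUT"), stringsAsFactors = FALSE)
  design$sample_id <- sprintf("s_%s_%d_%d", design$genotype, design$time, design$rep)
  m <- matrix(rnorm(n_ps * nrow(design), mean = 7),
              nrow = n_ps,
              dimnames = list(sprintf("ps%03d", seq_len(n_ps)), design$sample_id))
  genes <- genes %||% sprintf("g%03d", ceiling(seq_len(n_ps) / 2))
  design$model <- "toy"
  expression_study(m,
                   design[, c("sample_id", "genotype", "time", "model")],
                   data.frame(probeset_id = rownames(m), gene_id = genes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-rolled ranked gene list (bypasses collapse) for crossmap unit tests.
make_rgl <- function(ids, stats, p = NULL) {
  p <- p %||% seq_along(ids) / (length(ids) + 1)
  structure(data.frame(id = ids, gene_id = ids, probeset_id = ids,
                       signed_stat = stats, p = p, rank = seq_along(ids),
                       stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"),
            unmapped_fraction = 0, side = "a", label = "fixture")
}

write_study_files <- function(study, dir) {
  mp <- file.path(dir, "matrix.tsv")
  dp <- file.path(dir, "design.tsv")
  ap <- file.path(dir, "annotation.tsv")
  m <- data.frame(probeset_id = rownames(study$matrix), study$matrix,
                  check.names = FALSE)
  write.table(m, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$design, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$annotation, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, design = dp, annotation = ap)
}

# --- oracles ----------------------------------------------------------------

# Step-up BH by direct sort + cumulative minimum from the largest p.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / (m:1)))
  q[order(o)]
}

# Upper-tail hypergeometric P[X >= k] by summing choose() terms.
hyper_tail_oracle <- function(k, n_white, n_black, n_draw) {
  kk <- k:min(n_draw, n_white)
  sum(choose(n_white, kk) * choose(n_black, n_draw - kk)) /
    choose(n_white + n_black, n_draw)
}

# True-path closure by exhaustive ancestor enumeration (repeated expansion).
closure_oracle <- function(terms_parents, annotations) {
  ids <- names(terms_parents)
  anc_or_self <- lapply(ids, function(t0) {
    seen <- t0
    repeat {
      grow <- unique(unlist(terms_parents[seen]))
      new <- setdiff(grow, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    seen
  })
  names(anc_or_self) <- ids
  out <- lapply(ids, function(t0) {
    donors <- ids[vapply(anc_or_self, function(a) t0 %in% a, logical(1))]
    sort(unique(annotations$gene_id[annotations$term_id %in% donors]))
  })
  names(out) <- ids
  out
}

# Best-p collapse by explicit group-by loop.
collapse_oracle <- function(df, key) {
  out <- do.call(rbind, lapply(split(df, df[[key]]), function(g) {
    g <- g[order(g$p, -abs(g$log2fc), g$probeset_id), , drop = FALSE]
    g[1L, , drop = FALSE]
  }))
  out[order(out$p, -abs(out$log2fc), out$probeset_id), , drop = FALSE]
}
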