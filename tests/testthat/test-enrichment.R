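# Conditional over-representation, term similarity and clustering.

flat_dag <- function(sets) {
  terms <- data.frame(term_id = names(sets), name = names(sets), parents = "")
  ann <- data.frame(gene_id = unlist(sets, use.names = FALSE),
                    term_id = rep(names(sets), lengths(sets)))
  gene_set_dag(terms, ann)
}

test_that("flat collections reduce to the plain hypergeometric test", {
  universe <- paste0("g", 1:40)
  sig <- paste0("g", 1:10)
  sets <- list(T1 = paste0("g", 1:8),        # mostly significant
               T2 = paste0("g", 21:35))      # none significant
  res <- conditional_enrich(flat_dag(sets), sig, universe)
  p1 <- hyper_tail_oracle(8, 10, 30, 8)      # all 8 genes significant
  p2 <- hyper_tail_oracle(0, 10, 30, 15)
  expect_equal(res$p[res$term_id == "T1"], p1, tolerance = 1e-12)
  expect_equal(res$p[res$term_id == "T2"], p2, tolerance = 1e-12)
  expect_equal(res$count[res$term_id == "T1"], 8L)
  expect_equal(res$global[res$term_id == "T1"], 8L)
  expect_true(all(res$fdr_p >= res$p))
})

test_that("a significant child conditions its parent away", {
  universe <- paste0("g", 1:60)
  sig <- paste0("g", 1:10)
  # child C holds all the signal; parent P = C plus 20 unremarkable genes
  terms <- data.frame(term_id = c("P", "C"), name = c("parent", "child"),
                      parents = c("", "P"))
  ann <- rbind(data.frame(gene_id = paste0("g", 1:10), term_id = "C"),
               data.frame(gene_id = paste0("g", 31:50), term_id = "P"))
  dag <- gene_set_dag(terms, ann)
  res <- conditional_enrich(dag, sig, universe)
  p_child <- hyper_tail_oracle(10, 10, 50, 10)
  expect_equal(res$p[res$term_id == "C"], p_child, tolerance = 1e-12)
  # conditioned parent: its 30 propagated genes lose the 10 child genes
  p_parent_cond <- hyper_tail_oracle(0, 10, 50, 20)
  p_parent_plain <- hyper_tail_oracle(10, 10, 50, 30)
  expect_equal(res$p[res$term_id == "P"], p_parent_cond, tolerance = 1e-12)
  expect_gt(res$p[res$term_id == "P"], p_parent_plain)
  expect_gt(res$p[res$term_id == "P"], 0.05)
  expect_equal(res$global[res$term_id == "P"], 20L)

  # without conditioning (threshold 0) the parent keeps its full set
  res0 <- conditional_enrich(dag, sig, universe, alpha_condition = 0)
  expect_equal(res0$p[res0$term_id == "P"], p_parent_plain, tolerance = 1e-12)
})

test_that("enrichment rejects significant genes outside the universe", {
  dag <- flat_dag(list(T1 = paste0("g", 1:3)))
  expect_error(conditional_enrich(dag, c("g1", "zz"), paste0("g", 1:10)), "zz")
})

test_that("result is independent of term insertion order", {
  universe <- paste0("g", 1:50)
  sig <- paste0("g", 1:12)
  set.seed(31)
  ids <- sprintf("T%d", 1:6)
  parents <- list(character(0), "T1", "T1", "T2", character(0), c("T2", "T3"))
  ann <- data.frame(gene_id = sample(universe, 60, replace = TRUE),
                    term_id = sample(ids, 60, replace = TRUE))
  mk <- function(ord) {
    terms <- data.frame(term_id = ids, name = ids)[ord, ]
    terms$parents <- lapply(parents[ord], identity)
    conditional_enrich(gene_set_dag(terms, ann), sig, universe)
  }
  r1 <- mk(1:6)
  r2 <- mk(c(4, 2, 6, 1, 3, 5))
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("term similarity implements Jaccard and overlap coefficients", {
  expect_equal(term_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(term_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(term_similarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(term_similarity(character(0), character(0)), 0)
  expect_equal(term_similarity(c("a", "b"), c("a", "b", "c", "d"),
                               method = "overlap"), 1)
})

test_that("term clustering groups identical sets and splits disjoint ones", {
  universe <- paste0("g", 1:30)
  sets <- list(T1 = paste0("g", 1:5), T2 = paste0("g", 1:5),
               T3 = paste0("g", 11:15), T4 = paste0("g", 11:15))
  dag <- flat_dag(sets)
  res <- conditional_enrich(dag, paste0("g", 1:5), universe)
  cl <- cluster_terms(res, dag, universe, threshold = 0.9)
  expect_equal(length(unique(cl$cluster)), 2)
  same <- function(a, b) cl$cluster[cl$term_id == a] == cl$cluster[cl$term_id == b]
  expect_true(same("T1", "T2"))
  expect_true(same("T3", "T4"))
  expect_false(same("T1", "T3"))
  expect_equal(sum(cl$representative), 2)
  # representative is the most significant member
  rep1 <- cl$term_id[cl$representative & cl$term_id %in% c("T1", "T2")]
  expect_equal(rep1, res$term_id[res$term_id %in% c("T1", "T2")][1])

  all_same <- flat_dag(list(A = paste0("g", 1:4), B = paste0("g", 1:4),
                            C = paste0("g", 1:4)))
  res2 <- conditional_enrich(all_same, paste0("g", 1:4), universe)
  cl2 <- cluster_terms(res2, all_same, universe, threshold = 0.9)
  expect_equal(length(unique(cl2$cluster)), 1)
})

test_that("clustering matches the exhaustive dendrogram-cut oracle", {
  set.seed(77)
  universe <- paste0("g", 1:40)
  for (rep in 1:5) {
    n_terms <- sample(4:8, 1)
    sets <- lapply(seq_len(n_terms), function(i) sample(universe, sample(4:12, 1)))
    names(sets) <- sprintf("T%d", seq_len(n_terms))
    dag <- flat_dag(sets)
    res <- conditional_enrich(dag, sample(universe, 10), universe)
    thr <- sample(c(0.3, 0.5, 0.9), 1)
    cl <- cluster_terms(res, dag, universe, threshold = thr)

    # oracle: scan every cutree k over the same average-linkage tree and
    # take the smallest k whose clusters all pass the mean-similarity bar
    ids <- res$term_id
    sim <- outer(seq_along(ids), seq_along(ids), Vectorize(function(i, j)
      term_similarity(sets[[ids[i]]], sets[[ids[j]]])))
    diag(sim) <- 1
    hc <- hclust(as.dist(1 - sim), method = "average")
    best_k <- NA
    for (k in seq_along(ids)) {
      groups <- split(seq_along(ids), cutree(hc, k = k))
      ok <- all(sapply(groups, function(g) {
        if (length(g) < 2) return(TRUE)
        pair <- combn(g, 2)
        mean(sim[cbind(pair[1, ], pair[2, ])]) >= thr
      }))
      if (ok) { best_k <- k; break }
    }
    expect_equal(length(unique(cl$cluster)), best_k)
  }
})

test_that("enrichment-map edge weights equal recomputed similarities", {
  universe <- paste0("g", 1:30)
  sets <- list(T1 = paste0("g", 1:6), T2 = paste0("g", 4:9),
               T3 = paste0("g", 20:25))
  dag <- flat_dag(sets)
  res <- conditional_enrich(dag, paste0("g", 1:6), universe)
  tab <- enrichment_map_tables(res, dag, universe)
  expect_equal(nrow(tab$nodes), 3)
  for (i in seq_len(nrow(tab$edges))) {
    e <- tab$edges[i, ]
    expect_equal(e$similarity,
                 term_similarity(sets[[e$term_a]], sets[[e$term_b]]))
  }
  expect_false(any(tab$edges$similarity == 0))
})
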