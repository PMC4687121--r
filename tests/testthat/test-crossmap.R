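# Ortholog collapsing, top-list overlap statistics, concordance profiles.

make_de_fixture <- function(n_ps = 20, seed = 1, genes = NULL) {
  study <- make_study(n_ps = n_ps, n_times = 2, n_reps = 3, seed = seed,
                      genes = genes)
  de_contrast(study, samples_for(study, genotype = "WT"),
              samples_for(study, genotype = "MUT"))
}

test_that("collapse keeps the best-p probeset per gene and re-ranks", {
  de <- make_de_fixture(n_ps = 20, seed = 2)
  rl <- collapse_to_homologs(de, NULL)
  expect_equal(rl$rank, seq_len(nrow(rl)))
  expect_false(any(duplicated(rl$id)))
  oracle <- collapse_oracle(as.data.frame(de), "gene_id")
  expect_equal(rl$gene_id, oracle$gene_id)
  expect_equal(rl$p, oracle$p)
  expect_equal(rl$probeset_id, oracle$probeset_id)

  # explicit two-probeset case: p = 0.01 (+0.5) and p = 0.2 (-0.1)
  df <- as.data.frame(de)[1:2, ]
  df$gene_id <- "gX"
  df$p <- c(0.01, 0.2); df$log2fc <- c(0.5, -0.1)
  fake <- structure(df, class = c("de_result", "data.frame"), label = "t")
  one <- collapse_to_homologs(fake, NULL)
  expect_equal(nrow(one), 1L)
  expect_equal(one$p, 0.01)
  expect_gt(one$signed_stat, 0)
})

test_that("identity-style map preserves gene order; homolog collapse by best p", {
  genes <- sprintf("g%03d", 1:10)
  de <- make_de_fixture(n_ps = 10, seed = 3, genes = genes)
  map <- ortholog_map(data.frame(gene_id_a = genes, gene_id_b = paste0("x", genes),
                                 homolog_group_id = paste0("h", genes)))
  rl0 <- collapse_to_homologs(de, NULL)
  rl <- collapse_to_homologs(de, map, side = "a")
  expect_equal(rl$gene_id, rl0$gene_id)
  expect_equal(rl$id, paste0("h", rl0$gene_id))

  # two genes in one homolog group: best p wins after gene collapse
  map2 <- ortholog_map(data.frame(gene_id_a = genes,
                                  gene_id_b = paste0("x", genes),
                                  homolog_group_id = c("h1", "h1", paste0("h", 3:10))))
  rl2 <- collapse_to_homologs(de, map2, side = "a")
  expect_equal(nrow(rl2), 9L)
  in_h1 <- rl0[rl0$gene_id %in% genes[1:2], ]
  expect_equal(rl2$p[rl2$id == "h1"], min(in_h1$p))

  # unmapped genes are excluded and reported
  map3 <- ortholog_map(data.frame(gene_id_a = genes[1:4],
                                  gene_id_b = paste0("x", genes[1:4]),
                                  homolog_group_id = paste0("h", 1:4)))
  rl3 <- collapse_to_homologs(de, map3, side = "a")
  expect_equal(nrow(rl3), 4L)
  expect_equal(attr(rl3, "unmapped_fraction"), 0.6)
  expect_setequal(attr(rl3, "unmapped_genes"), genes[5:10])
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  # canonical instance: N = 10, both tops 5, complete overlap
  la <- make_rgl(paste0("g", 1:10), rep(1, 10))
  lb <- make_rgl(paste0("g", 1:10), rep(1, 10))
  ov <- overlap_hypergeom(la, lb, top_a = 5, top_b = 5)
  expect_equal(ov$k, 5)
  expect_equal(ov$p_hyper, 1 / choose(10, 5), tolerance = 1e-12)

  set.seed(9)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    ids <- paste0("g", seq_len(n))
    la <- make_rgl(sample(ids), rnorm(n))
    lb <- make_rgl(sample(ids), rnorm(n))
    ta <- sample(2:(n - 2), 1); tb <- sample(2:(n - 2), 1)
    ov <- overlap_hypergeom(la, lb, ta, tb)
    oracle <- hyper_tail_oracle(ov$k, ta, n - ta, tb)
    expect_equal(ov$p_hyper, oracle, tolerance = 1e-12)
    expect_true(ov$p_hyper > 0 && ov$p_hyper <= 1)
    expect_lte(ov$k, min(ta, tb))
  }
})

test_that("hypergeometric p is monotone non-increasing in k", {
  p_at_k <- sapply(0:5, function(k) hyper_tail_oracle(k, 5, 10, 5))
  expect_true(all(diff(p_at_k) <= 1e-15))
  # same monotonicity via the package on nested constructed overlaps
  ids <- paste0("g", 1:15)
  lb <- make_rgl(ids, rep(1, 15))
  ps <- sapply(1:5, function(k) {
    la <- make_rgl(c(ids[1:k], paste0("u", 1:(15 - k)), ids[(k + 1):15])[1:15],
                   rep(1, 15))
    # universe = intersection; keep it fixed instead
    overlap_hypergeom(la, lb, 5, 5, universe = "fixed", fixed_n = 15)$p_hyper
  })
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("universe policy is explicit and size violations are errors", {
  la <- make_rgl(paste0("g", 1:10), rep(1, 10))
  lb <- make_rgl(paste0("g", 6:15), rep(1, 10))
  inter <- overlap_hypergeom(la, lb, 5, 5, universe = "intersection")
  expect_equal(inter$n_universe, 5)
  uni <- overlap_hypergeom(la, lb, 5, 5, universe = "union")
  expect_equal(uni$n_universe, 15)
  expect_error(overlap_hypergeom(la, lb, 8, 8, universe = "intersection"),
               "universe")
  expect_error(overlap_hypergeom(la, lb, 12, 5), "top size")
})

test_that("permutation p agrees with the hypergeometric null and is seeded", {
  ids <- paste0("g", 1:60)
  set.seed(4)
  la <- make_rgl(sample(ids), rnorm(60))
  lb <- make_rgl(sample(ids), rnorm(60))
  ov <- overlap_permutation(la, lb, 15, 15, reps = 4000, seed = 99)
  se <- sqrt(ov$p_hyper * (1 - ov$p_hyper) / 4000)
  expect_lt(abs(ov$p_perm - ov$p_hyper), 3 * se + 1e-4)
  ov2 <- overlap_permutation(la, lb, 15, 15, reps = 4000, seed = 99)
  expect_identical(ov$p_perm, ov2$p_perm)
  expect_error(overlap_permutation(la, lb, 15, 15, reps = 50), ">= 100")
})

test_that("permutation p floors at 1/(reps+1) for an unreachable overlap", {
  ids <- paste0("g", 1:1000)
  la <- make_rgl(ids, rep(1, 1000))
  lb <- make_rgl(ids, rep(1, 1000))
  ov <- overlap_permutation(la, lb, 5, 5, reps = 10000, seed = 1)
  expect_equal(ov$k, 5)
  expect_equal(ov$p_perm, 1 / 10001, tolerance = 1e-12)
})

test_that("self-comparison concentrates all mass concordantly in bin 1", {
  ids <- paste0("g", 1:1500)
  la <- make_rgl(ids, rep(c(1, -1), 750))
  prof <- concordance_profile(la, la, k = 200, bin_size = 1000)
  expect_equal(prof$concordant_freq[1], 1)
  expect_true(all(prof$discordant_freq == 0))
  expect_equal(attr(prof, "unmapped_fraction"), 0)
})

test_that("toy concordance walk-through matches hand computation", {
  la <- make_rgl(c("g1", "g2"), c(1, -1))
  lb <- make_rgl(c("g1", "gX", "g2"), c(0.5, 1, 0.7))
  prof <- concordance_profile(la, lb, k = 2, bin_size = 2)
  expect_equal(prof$concordant_freq, c(0.5, 0))
  expect_equal(prof$discordant_freq, c(0, 0.5))
})

test_that("concordance conservation and sign-negation invariants hold", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    shared <- paste0("s", seq_len(n))
    extra <- paste0("e", 1:20)
    la <- make_rgl(sample(c(shared, extra)), rnorm(n + 20))
    lb <- make_rgl(sample(shared), rnorm(n))
    k <- sample(10:40, 1)
    prof <- concordance_profile(la, lb, k = k, bin_size = 37)
    total <- sum(prof$concordant_freq) + sum(prof$discordant_freq) +
      attr(prof, "unmapped_fraction")
    expect_equal(total, 1, tolerance = 1e-12)

    lb_neg <- lb
    lb_neg$signed_stat <- -lb_neg$signed_stat
    prof_neg <- concordance_profile(la, lb_neg, k = k, bin_size = 37)
    expect_equal(prof_neg$concordant_freq, prof$discordant_freq)
    expect_equal(prof_neg$discordant_freq, prof$concordant_freq)
  }
  expect_error(concordance_profile(make_rgl("g1", 1), make_rgl("g1", 1), k = 5),
               "exceeds")
})
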