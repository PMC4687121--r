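# Readers, writers and domain-type invariants.

test_that("expression study round-trips through TSV files", {
  study <- make_study(n_ps = 3, n_times = 2, n_reps = 2)
  dir <- withr::local_tempdir()
  paths <- write_study_files(study, dir)
  back <- read_expression_study(paths$matrix, paths$design, paths$annotation)
  expect_equal(back$matrix, study$matrix, tolerance = 1e-12)
  expect_equal(back$design, study$design)
  expect_equal(back$annotation, study$annotation)
})

test_that("reader is independent of row and column order", {
  study <- make_study(n_ps = 5, n_times = 2, n_reps = 2)
  dir <- withr::local_tempdir()
  paths <- write_study_files(study, dir)
  # shuffle matrix rows and columns, and design rows
  m <- read.delim(paths$matrix, check.names = FALSE)
  set.seed(1)
  m <- m[sample(nrow(m)), c(1, 1 + sample(ncol(m) - 1))]
  write.table(m, paths$matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read.delim(paths$design)
  write.table(d[sample(nrow(d)), ], paths$design, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_expression_study(paths$matrix, paths$design, paths$annotation)
  expect_equal(back$matrix, study$matrix, tolerance = 1e-12)
  expect_equal(back$design, study$design)
})

test_that("reader validation: orphans, duplicates, non-numeric cells", {
  study <- make_study(n_ps = 3, n_times = 2, n_reps = 2)
  dir <- withr::local_tempdir()
  paths <- write_study_files(study, dir)

  d <- read.delim(paths$design)
  orphan <- d$sample_id[3]
  write.table(d[-3, ], paths$design, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_study(paths$matrix, paths$design, paths$annotation),
               orphan, fixed = TRUE)
  write.table(d, paths$design, sep = "\t", quote = FALSE, row.names = FALSE)

  m <- read.delim(paths$matrix, check.names = FALSE)
  m2 <- rbind(m, m[1, ])
  write.table(m2, paths$matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_study(paths$matrix, paths$design, paths$annotation),
               "duplicate probeset")

  m3 <- m
  m3[2, 3] <- "oops"
  write.table(m3, paths$matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  err <- expect_error(
    read_expression_study(paths$matrix, paths$design, paths$annotation))
  expect_match(conditionMessage(err), "oops")
  expect_match(conditionMessage(err), m$probeset_id[2])
  expect_match(conditionMessage(err), names(m)[3], fixed = TRUE)
})

test_that("study constructor enforces design-cell replication and genotypes", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  d <- data.frame(sample_id = c("s1", "s2", "s3"),
                  genotype = c("WT", "WT", "MUT"), time = 6, model = "x")
  expect_error(expression_study(m, d), ">= 2 samples")
  d$genotype <- c("WT", "het", "het")
  expect_error(expression_study(m, d), "het")
})

test_that("multi-mapping probesets are dropped from the annotation", {
  study <- make_study(n_ps = 3, n_times = 2, n_reps = 2)
  ann <- rbind(study$annotation,
               data.frame(probeset_id = "ps001", gene_id = "other_gene"))
  expect_message(
    s2 <- expression_study(study$matrix, study$design, ann),
    "multi-mapping")
  expect_true(is.na(s2$annotation$gene_id[s2$annotation$probeset_id == "ps001"]))
  expect_equal(nrow(s2$annotation), nrow(study$annotation))
})

test_that("ortholog map reads, dedupes and rejects partition violations", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "map.tsv")
  pairs <- data.frame(gene_id_a = paste0("a", 1:5), gene_id_b = paste0("b", 1:5),
                      homolog_group_id = paste0("h", 1:5))
  write.table(rbind(pairs, pairs[2, ]), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  map <- read_ortholog_map(path)
  expect_s3_class(map, "ortholog_map")
  expect_equal(nrow(map), 5)
  expect_equal(length(unique(map$homolog_group_id)), 5)

  bad <- rbind(pairs, data.frame(gene_id_a = "a1", gene_id_b = "b9",
                                 homolog_group_id = "h9"))
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ortholog_map(path), "a1")
})

test_that("GMT input yields a flat DAG with propagated == direct", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c("S1\tfirst set\tg1\tg2\tg3", "S2\tsecond set\tg4\tg5\tg6"), path)
  dag <- read_gene_sets(gmt_path = path)
  expect_equal(nrow(dag$terms), 2)
  expect_true(all(lengths(dag$terms$parents) == 0))
  expect_equal(dag$propagated$S1, c("g1", "g2", "g3"))
  expect_equal(dag$propagated$S2, c("g4", "g5", "g6"))
})

test_that("true-path rule propagates annotations up a chain", {
  terms <- data.frame(term_id = c("A", "B", "C"), name = letters[1:3],
                      parents = c("", "A", "B"))
  ann <- data.frame(gene_id = "g", term_id = "C")
  dag <- gene_set_dag(terms, ann)
  expect_equal(dag$propagated$A, "g")
  expect_equal(dag$propagated$B, "g")
  expect_equal(dag$propagated$C, "g")
})

test_that("diamond-DAG propagation matches the brute-force closure oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 8
    ids <- sprintf("T%d", 1:n)
    parents <- lapply(seq_len(n), function(i) {
      if (i == 1) character(0) else
        sample(ids[seq_len(i - 1)], sample(0:min(2, i - 1), 1))
    })
    terms <- data.frame(term_id = ids, name = ids)
    terms$parents <- parents
    ann <- data.frame(gene_id = sample(sprintf("g%d", 1:20), 25, replace = TRUE),
                      term_id = sample(ids, 25, replace = TRUE))
    ann <- unique(ann)
    dag <- gene_set_dag(terms, ann)
    oracle <- closure_oracle(setNames(parents, ids), ann)
    expect_equal(dag$propagated[ids], oracle[ids])
    # parent propagated set contains every child's
    for (i in seq_len(n)) for (p in parents[[i]])
      expect_true(all(dag$propagated[[ids[i]]] %in% dag$propagated[[p]]))
  }
})

test_that("cyclic parent graphs and unknown terms are rejected", {
  terms <- data.frame(term_id = c("A", "B", "C"), name = letters[1:3],
                      parents = c("C", "A", "B"))
  ann <- data.frame(gene_id = "g", term_id = "A")
  expect_error(gene_set_dag(terms, ann), "cycle")
  terms$parents <- c("", "A", "B")
  expect_error(gene_set_dag(terms, data.frame(gene_id = "g", term_id = "Z")),
               "Z")
})

test_that("write_table emits deterministic, round-trippable tables", {
  study <- make_study(n_ps = 12, n_times = 2, n_reps = 3)
  de <- de_contrast(study, samples_for(study, genotype = "WT"),
                    samples_for(study, genotype = "MUT"))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "de.tsv")
  write_table(de, p1)
  back <- read.delim(p1)
  expect_equal(back$probeset_id, de$probeset_id)
  expect_true(all(diff(back$p) >= 0))              # sorted by ascending p
  expect_equal(back$log2FC, as.numeric(sprintf("%.3f", de$log2fc)))
  expect_equal(back$p, signif(de$p, 6), tolerance = 1e-12)

  # empty tabular result -> header-only file
  p2 <- file.path(dir, "empty.tsv")
  write_table(data.frame(a = numeric(0), b = character(0)), p2)
  expect_equal(length(readLines(p2)), 1L)

  # concordance profile round-trip to 6 decimal places
  la <- make_rgl(paste0("g", 1:40), rep(c(1, -1), 20))
  lb <- make_rgl(paste0("g", c(2:30, 1, 31:40)), rep(c(1, -1), 20))
  prof <- concordance_profile(la, lb, k = 10, bin_size = 15)
  p3 <- file.path(dir, "prof.tsv")
  write_table(prof, p3)
  back <- read.delim(p3)
  expect_equal(back$concordant_freq, prof$concordant_freq, tolerance = 1e-6)
  expect_equal(back$discordant_freq, prof$discordant_freq, tolerance = 1e-6)

  expect_error(write_table(de, file.path(dir, "nope", "x.tsv")), "directory")
})
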