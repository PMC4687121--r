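# End-to-end orchestration: simulate (or load) a paired study, run every
# analysis stage, write stage tables, a JSON summary and a MANIFEST, and
# render a plain-text report.

#' Pipeline configuration
#'
#' Thresholds default to the package-wide conventions: significance alpha
#' 0.05 (nominal and FDR), top-200 concordance lists over 1000-gene rank
#' bins, top-1000 overlap tests, trajectory thresholds r >= 0.8 and
#' amplitude >= 0.1 log2 units, and a strict 0.20 log2 bound for divergent
#' genes.
#'
#' @param sim A [simulation_config()] describing the paired study.
#' @param alpha Significance threshold for nominal and FDR calls.
#' @param top_k Concordance top-list size (list A side).
#' @param top_n Overlap-test top-list size.
#' @param bin_size Concordance rank-bin width.
#' @param r_min,min_amp Trajectory classification thresholds.
#' @param min_abs_diff Divergent-gene |fc_a - fc_b| strict lower bound.
#' @param perm_reps Permutation resamples for the overlap test.
#' @param n_terms,planted_terms,odds_ratio Gene-set simulation settings.
#' @param seed Master seed (overrides `sim$seed`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            alpha = 0.05,
                            top_k = 200L, top_n = 1000L, bin_size = 1000L,
                            r_min = 0.8, min_amp = 0.1,
                            min_abs_diff = 0.20,
                            perm_reps = 2000L,
                            n_terms = 40L, planted_terms = 2L, odds_ratio = 8,
                            seed = NULL) {
  stopifnot(inherits(sim, "simulation_config"))
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie in (0, 1)")
  stopifnot(is_count(top_k, 1), is_count(top_n, 1), is_count(bin_size, 1),
            is_count(perm_reps, 100))
  if (min_abs_diff < 0) stop_("min_abs_diff must be >= 0")
  structure(list(sim = sim, alpha = alpha, top_k = as.integer(top_k),
                 top_n = as.integer(top_n), bin_size = as.integer(bin_size),
                 r_min = r_min, min_amp = min_amp, min_abs_diff = min_abs_diff,
                 perm_reps = as.integer(perm_reps),
                 n_terms = as.integer(n_terms),
                 planted_terms = as.integer(planted_terms),
                 odds_ratio = odds_ratio,
                 seed = sim$seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated paired study
#'
#' Stage order: simulate the paired study, genotype differential expression
#' per model, temporal analysis (model A), ortholog collapse + top-list
#' overlap (hypergeometric and permutation) + concordance profile,
#' conditional enrichment on a simulated gene-set DAG, and the
#' genotype-by-model interaction test. Any stage failure aborts with the
#' stage name; when `out_dir` is given, stage tables written so far are
#' retained and the MANIFEST marks the run incomplete.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; stage TSVs, `summary.json`
#'   and a `MANIFEST` (file name + md5 content hash per artifact) are
#'   written there.
#' @param quiet Suppress stage progress messages (written to stderr).
#' @return Object of class `pipeline_report`: list with one element per
#'   stage (`truth`, `de`, `temporal`, `crossmap`, `enrichment`,
#'   `interaction`) plus `summary` (named list of headline numbers) and
#'   `config`.
#' @export
run_full_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet)
    message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0), sprintf(...))
  artifacts <- character(0)
  emit <- function(x, name) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      path <- file.path(out_dir, name)
      write_table(x, path)
      artifacts <<- c(artifacts, path)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) write_manifest(out_dir, artifacts, complete = FALSE)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  say("simulate: paired models (%d genes, seed %d)", config$sim$n_genes, config$seed)
  sim <- stage("simulate", simulate_paired_models(config$sim))

  say("de: genotype contrast per model")
  de <- stage("de", {
    contrast <- function(study, label) {
      de_contrast(study,
                  samples_for(study, genotype = "WT"),
                  samples_for(study, genotype = "MUT"),
                  label = label)
    }
    list(a = contrast(sim$study_a, "genotype MUT-WT, model A"),
         b = contrast(sim$study_b, "genotype MUT-WT, model B"))
  })
  emit(de$a, "de_model_a.tsv"); emit(de$b, "de_model_b.tsv")

  say("temporal: genotype-by-time ANOVA and pattern table (model A)")
  temporal <- stage("temporal",
                    temporal_analysis(sim$study_a, alpha = config$alpha,
                                      r_min = config$r_min, min_amp = config$min_amp))
  emit(temporal$pattern_table, "pattern_table.tsv")

  say("crossmap: collapse, overlap, concordance profile")
  crossmap <- stage("crossmap", {
    if (is.null(sim$map)) {
      la <- collapse_to_homologs(de$a, NULL)
      lb <- collapse_to_homologs(de$b, NULL)
    } else {
      la <- collapse_to_homologs(de$a, sim$map, side = "a")
      lb <- collapse_to_homologs(de$b, sim$map, side = "b")
    }
    top_n <- min(config$top_n, nrow(la), nrow(lb))
    ov <- overlap_permutation(la, lb, top_a = top_n, top_b = top_n,
                              reps = config$perm_reps,
                              seed = substream_seed(config$seed, "overlap-perm"))
    prof <- concordance_profile(la, lb, k = min(config$top_k, nrow(la)),
                                bin_size = config$bin_size)
    list(list_a = la, list_b = lb, overlap = ov, profile = prof)
  })
  emit(crossmap$list_a, "ranked_model_a.tsv")
  emit(crossmap$list_b, "ranked_model_b.tsv")
  emit(crossmap$profile, "concordance_profile.tsv")

  say("enrichment: conditional test on simulated DAG")
  enrichment <- stage("enrichment", {
    dag <- simulate_enrichment(config$sim, n_terms = config$n_terms,
                               planted_terms = config$planted_terms,
                               odds_ratio = config$odds_ratio, truth = sim$truth)
    universe <- unique(stats::na.omit(sim$study_a$annotation$gene_id))
    sig <- unique(stats::na.omit(de$a$gene_id[de$a$p < config$alpha]))
    res <- conditional_enrich(dag, intersect(sig, universe), universe)
    list(dag = dag, result = res)
  })
  emit(enrichment$result, "enrichment.tsv")

  say("interaction: genotype x model test")
  interaction <- stage("interaction", {
    res <- interaction_test(sim$study_a, sim$study_b, sim$map)
    list(result = res,
         divergent = rank_divergent(res, p_threshold = config$alpha,
                                    min_abs_diff = config$min_abs_diff))
  })
  emit(interaction$result, "interaction.tsv")

  first_bin <- crossmap$profile[1L, ]
  summary <- list(
    seed = config$seed,
    n_genes = config$sim$n_genes,
    de_nominal_a = sum(de$a$p < config$alpha),
    de_fdr_a = sum(de$a$q < config$alpha),
    de_nominal_b = sum(de$b$p < config$alpha),
    de_fdr_b = sum(de$b$q < config$alpha),
    temporal_fdr_probesets = sum(temporal$anova$q < config$alpha),
    pattern_table_grand_total = temporal$pattern_table$grand_total,
    pattern_table_mixed_excluded = temporal$pattern_table$n_mixed_pattern,
    overlap_k = crossmap$overlap$k,
    overlap_top_n = crossmap$overlap$n1,
    overlap_universe = crossmap$overlap$n_universe,
    overlap_p_hyper = crossmap$overlap$p_hyper,
    overlap_p_perm = crossmap$overlap$p_perm,
    first_bin_concordant_freq = first_bin$concordant_freq,
    first_bin_discordant_freq = first_bin$discordant_freq,
    unmapped_fraction = attr(crossmap$profile, "unmapped_fraction"),
    enrichment_top_term = enrichment$result$term_id[1L],
    enrichment_top_p = enrichment$result$p[1L],
    enrichment_sig_terms = sum(enrichment$result$p < config$alpha),
    interaction_sig = sum(interaction$result$p_interaction < config$alpha),
    divergent_genes = nrow(interaction$divergent))

  report <- structure(list(truth = sim$truth, de = de, temporal = temporal,
                           crossmap = crossmap, enrichment = enrichment,
                           interaction = interaction, summary = summary,
                           config = config),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    json_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = 10)
    artifacts <- c(artifacts, json_path)
    write_manifest(out_dir, artifacts, complete = TRUE)
  }
  say("done")
  report
}

#' @noRd
write_manifest <- function(out_dir, artifacts, complete) {
  lines <- c(sprintf("status\t%s", if (complete) "complete" else "INCOMPLETE"),
             sprintf("%s\t%s", basename(artifacts),
                     unname(tools::md5sum(artifacts))))
  writeLines(lines, file.path(out_dir, "MANIFEST"))
}

#' Render a plain-text summary report
#'
#' One section per pipeline stage with its headline numbers, at fixed
#' precision; deterministic for a given report bundle. An incomplete bundle
#' (missing stage) is an error naming the missing stage.
#'
#' @param report A [run_full_pipeline()] result.
#' @return Character vector of report lines (invisibly printed with
#'   `cat()` when at top level via `print`).
#' @export
render_summary <- function(report) {
  req <- c("de", "temporal", "crossmap", "enrichment", "interaction", "summary")
  miss <- req[!vapply(req, function(nm) !is.null(report[[nm]]), logical(1L))]
  if (length(miss)) stop_("report bundle is missing stage(s): %s",
                          paste(miss, collapse = ", "))
  s <- report$summary
  c(sprintf("pipeline summary (seed %d, %d genes)", s$seed, s$n_genes),
    "",
    "## differential expression (genotype MUT-WT)",
    sprintf("model A: %d nominal, %d FDR-significant probesets",
            s$de_nominal_a, s$de_fdr_a),
    sprintf("model B: %d nominal, %d FDR-significant probesets",
            s$de_nominal_b, s$de_fdr_b),
    "",
    "## temporal",
    sprintf("%d probesets FDR-significant in the genotype-by-time screen",
            s$temporal_fdr_probesets),
    sprintf("pattern table grand total: %d genes (%d mixed-pattern excluded)",
            s$pattern_table_grand_total, s$pattern_table_mixed_excluded),
    "",
    "## crossmap",
    sprintf("top-%d overlap: %d/%d in universe %d (p_hyper = %.3g, p_perm = %.3g)",
            s$overlap_top_n, s$overlap_k, s$overlap_top_n, s$overlap_universe,
            s$overlap_p_hyper, s$overlap_p_perm),
    sprintf("first-bin concordant %.3f vs discordant %.3f (unmapped %.3f)",
            s$first_bin_concordant_freq, s$first_bin_discordant_freq,
            s$unmapped_fraction),
    "",
    "## enrichment",
    sprintf("%d terms at p < 0.05; top term %s (p = %.3g)",
            s$enrichment_sig_terms, s$enrichment_top_term, s$enrichment_top_p),
    "",
    "## interaction",
    sprintf("%d genes with significant genotype x model interaction; %d divergent",
            s$interaction_sig, s$divergent_genes))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
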