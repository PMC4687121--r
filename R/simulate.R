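# Synthetic paired two-model study generator. Emulates the design of a
# replicated two-genotype (WT vs MUT), three-age striatal time course run
# in two mouse models on distinct array platforms linked by an ortholog
# map, with planted genotype effects (shared / discordant between models),
# planted temporal trajectories, gene-wise variances drawn from a scaled
# inverse-chi-square prior, and planted gene-set enrichment, so that every
# downstream analysis stage has ground truth.

#' Simulation configuration
#'
#' Defaults describe the emulated study: 5000 genes, 2 genotypes x 3 ages
#' (6/12/18 months) x 5 replicates per cell, log2 expression around a
#' baseline of 7, gene-wise variances from a scaled inverse-chi-square with
#' `d0_true = 4` prior df and `s0_sq_true = 0.05` (log2 units squared),
#' 8% of genes differentially expressed by genotype with |log2FC| ~
#' N(0.4, 0.15^2) truncated at 0.05, of which 70% share the signature in
#' both models (same sign), 5% are planted discordant (opposite sign) and
#' the rest are model-specific; temporal trajectories up/flat/down with
#' probabilities 0.15/0.70/0.15 and slope 0.25 log2 per time step; 85% of
#' genes mappable across models.
#'
#' @param n_genes Number of genes.
#' @param probesets_per_gene Named probability vector over probeset counts
#'   per gene (names "1", "2", ...).
#' @param replicates_per_cell Replicates per (genotype, time) cell (>= 2).
#' @param times Ordered time points in months.
#' @param baseline_mean Baseline log2 expression.
#' @param effect_mean,effect_sd Mean and sd of the planted |log2FC| of DE
#'   genes (`effect_sd = 0` gives a point mass).
#' @param de_fraction Fraction of genes DE by genotype.
#' @param shared_fraction,discordant_fraction Fractions of DE genes planted
#'   in both models with the same / opposite sign (the remainder is
#'   model-specific, split evenly).
#' @param trajectory_mix Probabilities over `c(up, flat, down)` trajectories.
#' @param trajectory_slope Log2 change per unit time index for up/down
#'   trajectories.
#' @param d0_true,s0_sq_true Scaled inverse-chi-square variance prior.
#' @param mappable_fraction Fraction of genes linked by the ortholog map.
#' @param seed Integer seed; all generators derive named substreams from it.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 5000L,
                              probesets_per_gene = c("1" = 0.7, "2" = 0.25, "3" = 0.05),
                              replicates_per_cell = 5L,
                              times = c(6, 12, 18),
                              baseline_mean = 7,
                              effect_mean = 0.4,
                              effect_sd = 0.15,
                              de_fraction = 0.08,
                              shared_fraction = 0.7,
                              discordant_fraction = 0.05,
                              trajectory_mix = c(up = 0.15, flat = 0.7, down = 0.15),
                              trajectory_slope = 0.25,
                              d0_true = 4,
                              s0_sq_true = 0.05,
                              mappable_fraction = 0.85,
                              seed = 1L) {
  stopifnot(is_count(n_genes, min = 1), is_count(replicates_per_cell, min = 0))
  if (replicates_per_cell < 2L) stop_("replicates_per_cell must be >= 2")
  if (de_fraction < 0 || de_fraction > 1) stop_("de_fraction must lie in [0, 1]")
  if (shared_fraction < 0 || discordant_fraction < 0 ||
      shared_fraction + discordant_fraction > 1)
    stop_("shared_fraction + discordant_fraction must lie in [0, 1]")
  if (abs(sum(probesets_per_gene) - 1) > 1e-8)
    stop_("probesets_per_gene probabilities must sum to 1")
  if (length(trajectory_mix) != 3L || abs(sum(trajectory_mix) - 1) > 1e-8)
    stop_("trajectory_mix must be 3 probabilities summing to 1")
  if (d0_true <= 0 || s0_sq_true <= 0) stop_("variance prior must be positive")
  if (mappable_fraction < 0 || mappable_fraction > 1)
    stop_("mappable_fraction must lie in [0, 1]")
  structure(list(n_genes = as.integer(n_genes),
                 probesets_per_gene = probesets_per_gene,
                 replicates_per_cell = as.integer(replicates_per_cell),
                 times = as.numeric(times),
                 baseline_mean = baseline_mean,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 de_fraction = de_fraction,
                 shared_fraction = shared_fraction,
                 discordant_fraction = discordant_fraction,
                 trajectory_mix = stats::setNames(as.numeric(trajectory_mix),
                                                  c("up", "flat", "down")),
                 trajectory_slope = trajectory_slope,
                 d0_true = d0_true, s0_sq_true = s0_sq_true,
                 mappable_fraction = mappable_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw the ground truth for a paired two-model simulation
#'
#' Assigns per-gene DE status and signs for both models (shared /
#' discordant / model-specific per the configured fractions), per-genotype
#' temporal trajectories, effect sizes, and the true gene-wise variances
#' `sigma^2_g ~ d0_true * s0_sq_true / chisq(d0_true)`.
#'
#' @param config A [simulation_config()].
#' @return Object of class `simulated_truth`: `data.frame` with one row per
#'   gene (`gene`, `is_de_a`, `is_de_b`, `sign_a`, `sign_b`, `effect`,
#'   `trajectory_wt`, `trajectory_mut`, `sigma_sq`, `mappable`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  with_seed(substream_seed(config$seed, "truth"), {
    n_de <- round(config$de_fraction * n)
    de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    n_shared <- round(config$shared_fraction * n_de)
    n_disc <- round(config$discordant_fraction * n_de)
    kind <- rep("none", n)
    if (n_de > 0) {
      labels <- c(rep("shared", n_shared), rep("discordant", n_disc),
                  rep(c("a_only", "b_only"), length.out = n_de - n_shared - n_disc))
      kind[de_idx] <- labels
    }
    sgn <- sample(c(-1L, 1L), n, replace = TRUE)
    is_de_a <- kind %in% c("shared", "discordant", "a_only")
    is_de_b <- kind %in% c("shared", "discordant", "b_only")
    sign_a <- ifelse(is_de_a, sgn, 0L)
    sign_b <- ifelse(is_de_b, ifelse(kind == "discordant", -sgn, sgn), 0L)
    effect <- pmax(stats::rnorm(n, config$effect_mean, config$effect_sd), 0.05)
    if (config$effect_sd == 0) effect <- rep(config$effect_mean, n)
    traj_wt <- sample(c("up", "flat", "down"), n, replace = TRUE,
                      prob = config$trajectory_mix)
    # MUT follows WT except for DE-in-A genes, whose MUT trajectory is
    # redrawn so genotype x time interactions exist in the data
    traj_mut <- traj_wt
    redraw <- is_de_a | is_de_b
    traj_mut[redraw] <- sample(c("up", "flat", "down"), sum(redraw), replace = TRUE,
                               prob = config$trajectory_mix)
    sigma_sq <- config$d0_true * config$s0_sq_true /
      stats::rchisq(n, df = config$d0_true)
    mappable <- stats::runif(n) < config$mappable_fraction
    structure(data.frame(gene = seq_len(n),
                         is_de_a = is_de_a, is_de_b = is_de_b,
                         sign_a = sign_a, sign_b = sign_b,
                         effect = effect,
                         trajectory_wt = traj_wt, trajectory_mut = traj_mut,
                         sigma_sq = sigma_sq, mappable = mappable,
                         stringsAsFactors = FALSE),
              class = c("simulated_truth", "data.frame"))
  })
}

#' @noRd
trajectory_slopes <- function(traj, slope) {
  ifelse(traj == "up", slope, ifelse(traj == "down", -slope, 0))
}

#' Simulate one expression study
#'
#' Generates `y = mu_g + beta_g I(MUT) + gamma_g(genotype) t + eps` with
#' `eps ~ N(0, sigma^2_g)`, where `t` is the 0-based ordered time index
#' (trajectory templates are rank-based, so month spacing is irrelevant),
#' `beta_g` is the planted genotype effect (sign per truth, magnitude from
#' the effect-size distribution) and the per-genotype slopes `gamma_g`
#' encode the planted trajectories. Probeset counts per gene follow the
#' configured distribution; probesets of a gene share its signal and gene
#' variance but have independent noise and their own baseline offset.
#' Fully reproducible from the configuration seed via a named substream per
#' model label.
#'
#' @param config A [simulation_config()].
#' @param model_label Label for this study (also the probeset namespace
#'   prefix).
#' @param truth A [simulate_truth()] result consistent with `config`.
#' @param side Which truth columns drive the genotype effect: `"a"` or
#'   `"b"`.
#' @return An [expression_study()].
#' @export
simulate_study <- function(config, model_label, truth, side = c("a", "b")) {
  side <- match.arg(side)
  stopifnot(inherits(config, "simulation_config"), inherits(truth, "simulated_truth"))
  if (nrow(truth) != config$n_genes) stop_("truth does not match config (n_genes)")
  if (config$replicates_per_cell < 2L) stop_("replicates_per_cell must be >= 2")
  n <- config$n_genes
  sgn <- if (side == "a") truth$sign_a else truth$sign_b
  beta <- sgn * truth$effect
  slope_wt <- trajectory_slopes(truth$trajectory_wt, config$trajectory_slope)
  slope_mut <- trajectory_slopes(truth$trajectory_mut, config$trajectory_slope)

  times <- sort(config$times)
  reps <- config$replicates_per_cell
  design <- expand.grid(rep = seq_len(reps), time = times,
                        genotype = c("WT", "MUT"), stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_t%02d_r%d", model_label, design$genotype,
                              match(design$time, times) - 1L, design$rep)
  design <- data.frame(sample_id = design$sample_id, genotype = design$genotype,
                       time = design$time, model = model_label,
                       stringsAsFactors = FALSE)
  t_idx <- match(design$time, times) - 1L
  is_mut <- design$genotype == "MUT"

  with_seed(substream_seed(config$seed, paste0("study:", model_label)), {
    k <- as.integer(names(config$probesets_per_gene))
    n_ps <- sample(k, n, replace = TRUE, prob = config$probesets_per_gene)
    gene_of_ps <- rep(seq_len(n), n_ps)
    ps_ids <- sprintf("%s_ps%05d_%d", model_label, gene_of_ps,
                      sequence(n_ps))
    gene_ids <- sprintf("g%s%05d", model_label, seq_len(n))

    mu_gene <- stats::rnorm(n, config$baseline_mean, 1)
    ps_offset <- stats::rnorm(length(ps_ids), 0, 0.25)
    # per-sample expected value for each gene
    slope <- outer(slope_wt, rep(1, nrow(design)))
    slope[, is_mut] <- slope_mut
    eta_gene <- outer(beta, as.numeric(is_mut)) + slope * rep(t_idx, each = n)
    eta <- eta_gene[gene_of_ps, , drop = FALSE] + mu_gene[gene_of_ps] + ps_offset
    noise <- matrix(stats::rnorm(length(ps_ids) * nrow(design),
                                 sd = rep(sqrt(truth$sigma_sq[gene_of_ps]),
                                          nrow(design))),
                    nrow = length(ps_ids))
    m <- eta + noise
    dimnames(m) <- list(ps_ids, design$sample_id)
    annotation <- data.frame(probeset_id = ps_ids,
                             gene_id = gene_ids[gene_of_ps],
                             stringsAsFactors = FALSE)
    expression_study(m, design, annotation)
  })
}

#' Simulate a paired two-model study
#'
#' Generates two studies on disjoint probeset and gene namespaces from one
#' shared truth (shared-signature genes DE in both with concordant sign,
#' discordant-fraction genes with opposite sign), plus the ortholog map
#' linking the configured mappable fraction of genes.
#'
#' @param config A [simulation_config()].
#' @param labels Length-2 character vector of model labels.
#' @return List with elements `study_a`, `study_b`, `map`
#'   ([ortholog_map()] or `NULL` when no gene is mappable), and `truth`.
#' @export
simulate_paired_models <- function(config, labels = c("A", "B")) {
  stopifnot(inherits(config, "simulation_config"), length(labels) == 2L)
  truth <- simulate_truth(config)
  study_a <- simulate_study(config, labels[1L], truth, side = "a")
  study_b <- simulate_study(config, labels[2L], truth, side = "b")
  mp <- which(truth$mappable)
  map <- NULL
  if (length(mp)) {
    map <- ortholog_map(data.frame(
      gene_id_a = sprintf("g%s%05d", labels[1L], mp),
      gene_id_b = sprintf("g%s%05d", labels[2L], mp),
      homolog_group_id = sprintf("hg%05d", mp),
      stringsAsFactors = FALSE))
  }
  list(study_a = study_a, study_b = study_b, map = map, truth = truth)
}

#' Simulate a gene-set DAG with planted enrichment
#'
#' Builds a random rooted DAG of `n_terms` terms over the model-A gene
#' universe (each non-root term gets 1-2 parents among earlier terms) and
#' draws each term's direct annotations uniformly; in `planted_terms`
#' randomly chosen terms, genes that are DE in model A are favoured at the
#' stated odds ratio, planting true enrichment signal. Deterministic given
#' the configuration seed.
#'
#' @param config A [simulation_config()].
#' @param n_terms Number of terms (default 40).
#' @param planted_terms Number of terms with planted signal (<= `n_terms`).
#' @param odds_ratio Sampling odds favouring DE genes in planted terms
#'   (default 8; `Inf` draws DE genes only).
#' @param truth A [simulate_truth()] result (defaults to re-deriving it
#'   from `config`).
#' @param label Model label whose gene namespace the terms annotate.
#' @param term_size_range Range of direct annotation counts per term.
#' @return A [gene_set_dag()] with attribute `planted` (term ids carrying
#'   planted signal).
#' @export
simulate_enrichment <- function(config, n_terms = 40L, planted_terms = 2L,
                                odds_ratio = 8, truth = NULL, label = "A",
                                term_size_range = c(10L, 60L)) {
  stopifnot(inherits(config, "simulation_config"))
  if (planted_terms > n_terms) stop_("planted_terms must be <= n_terms")
  truth <- truth %||% simulate_truth(config)
  genes <- sprintf("g%s%05d", label, truth$gene)
  is_de <- if (label == "A" || label == "a") truth$is_de_a else truth$is_de_b
  with_seed(substream_seed(config$seed, "enrichment"), {
    term_ids <- sprintf("T%04d", seq_len(n_terms))
    parents <- vector("list", n_terms)
    if (n_terms > 1L) {
      for (i in 2:n_terms) {
        n_par <- sample(0:2, 1L, prob = c(0.3, 0.5, 0.2))
        n_par <- min(n_par, i - 1L)
        parents[[i]] <- if (n_par > 0) sort(sample(term_ids[seq_len(i - 1L)], n_par))
        else character(0)
      }
    }
    planted <- if (planted_terms > 0) sort(sample(term_ids, planted_terms)) else character(0)
    sizes <- sample(term_size_range[1L]:term_size_range[2L], n_terms, replace = TRUE)
    ann <- lapply(seq_len(n_terms), function(i) {
      sz <- min(sizes[i], length(genes))
      if (term_ids[i] %in% planted) {
        w <- ifelse(is_de, if (is.infinite(odds_ratio)) 1 else odds_ratio,
                    if (is.infinite(odds_ratio)) 0 else 1)
        if (sum(w > 0) < sz) sz <- sum(w > 0)
        sample(genes, sz, prob = w)
      } else {
        sample(genes, sz)
      }
    })
    annotations <- data.frame(
      gene_id = unlist(ann),
      term_id = rep(term_ids, vapply(ann, length, integer(1L))),
      stringsAsFactors = FALSE)
    terms <- data.frame(term_id = term_ids,
                        name = sprintf("synthetic term %d", seq_len(n_terms)),
                        stringsAsFactors = FALSE)
    terms$parents <- parents
    dag <- gene_set_dag(terms, annotations)
    attr(dag, "planted") <- planted
    dag
  })
}
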