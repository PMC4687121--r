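# Genotype-dependent change over the time course: per-probeset two-way
# ANOVA screen, trajectory classification against monotone templates, and
# the (WT pattern x MUT pattern) count table with direction tallies.

#' Genotype-associated time-course ANOVA
#'
#' Per-probeset two-way fixed-effects ANOVA with genotype and time (both
#' categorical) and their interaction. The reported p-value is the
#' extra-sum-of-squares F-test of all genotype-containing terms (genotype
#' main effect + genotype:time interaction) against the time-only model,
#' i.e. a screen for any genotype-dependent expression over the time course.
#' q-values are Benjamini-Hochberg adjusted.
#'
#' @param study An [expression_study()] with >= 2 genotypes, >= 2 times and
#'   >= 2 replicates in every design cell.
#' @return `data.frame` with columns `probeset_id`, `gene_id`, `F`, `p`, `q`.
#' @export
genotype_time_anova <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  d <- study$design
  if (nlevels(droplevels(d$genotype)) < 2L) stop_("need both genotypes")
  if (length(unique(d$time)) < 2L) stop_("need >= 2 time points")
  cell <- table(d$genotype, d$time)
  if (any(cell < 2L)) stop_("empty or singleton (genotype, time) design cell")

  gt <- droplevels(d$genotype)
  tm <- factor(d$time)
  x_full <- stats::model.matrix(~ gt * tm)
  x_null <- stats::model.matrix(~ tm)
  y <- study$matrix  # probesets x samples

  rss <- function(x) {
    q <- qr.Q(qr(x))
    tss <- rowSums(y^2)
    fit <- y %*% q
    tss - rowSums(fit^2)
  }
  rss1 <- rss(x_full)
  rss0 <- rss(x_null)
  df_num <- ncol(x_full) - ncol(x_null)
  df_den <- ncol(y) - ncol(x_full)
  if (df_den < 1L) stop_("no residual degrees of freedom")
  f <- pmax(rss0 - rss1, 0) / df_num / (rss1 / df_den)
  p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  genes <- probeset_genes(study)
  data.frame(probeset_id = rownames(y),
             gene_id = unname(genes[rownames(y)]),
             F = f, p = p, q = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a temporal trajectory as up / no-change / down
#'
#' Correlates the per-time means against the standardized monotone "up"
#' template over the ordered time index (the "down" template is its
#' negation) and calls the winner by the larger |r|; the call is no-change
#' (`"NC"`) when the amplitude (max - min of the means, log2 units) falls
#' below `min_amp` or the winning |r| falls below `r_min`. Constant input
#' (zero variance, correlation undefined) is treated as r = 0, hence NC.
#' The reported `r` is the correlation against the *up* template, so a clean
#' downward trajectory has r near -1.
#'
#' @param means Numeric vector of per-time means over >= 3 ordered times.
#' @param r_min Minimum winning |Pearson r| (default 0.8).
#' @param min_amp Minimum amplitude in log2 units (default 0.1).
#' @return List with elements `pattern` (`"up"`, `"NC"` or `"down"`), `r`
#'   and `amplitude`.
#' @export
classify_trajectory <- function(means, r_min = 0.8, min_amp = 0.1) {
  if (length(means) < 3L) stop_("need >= 3 time points")
  template <- seq(-1, 1, length.out = length(means))
  amp <- max(means) - min(means)
  r <- if (stats::sd(means) == 0) 0 else stats::cor(means, template)
  pattern <- if (amp < min_amp || abs(r) < r_min) "NC" else if (r > 0) "up" else "down"
  list(pattern = pattern, r = r, amplitude = amp)
}

#' Per-probeset trajectory calls for both genotypes
#'
#' For each selected probeset, computes per-time means within each genotype,
#' classifies each genotype's trajectory with [classify_trajectory()], and
#' records the genotype direction: the sign of the average MUT - WT
#' difference across times (`"down"` = lower in MUT).
#'
#' @param study An [expression_study()].
#' @param probesets Probeset ids to call (default all); typically the
#'   FDR-significant set from [genotype_time_anova()].
#' @param r_min,min_amp Thresholds passed to [classify_trajectory()].
#' @return `data.frame` with columns `probeset_id`, `gene_id`, `pattern_wt`,
#'   `pattern_mut`, `r_wt`, `r_mut`, `amp_wt`, `amp_mut`, `direction`
#'   (`"up"`/`"down"`).
#' @export
trajectory_calls <- function(study, probesets = NULL, r_min = 0.8, min_amp = 0.1) {
  stopifnot(inherits(study, "expression_study"))
  d <- study$design
  times <- sort(unique(d$time))
  if (length(times) < 3L) stop_("need >= 3 time points")
  probesets <- probesets %||% rownames(study$matrix)
  missing <- setdiff(probesets, rownames(study$matrix))
  if (length(missing)) stop_("unknown probeset id(s): %s", paste(missing, collapse = ", "))
  m <- study$matrix[probesets, , drop = FALSE]

  time_means <- function(genotype) {
    sapply(times, function(tt)
      rowMeans(m[, d$sample_id[d$genotype == genotype & d$time == tt], drop = FALSE]))
  }
  mu_wt <- time_means("WT")
  mu_mut <- time_means("MUT")
  if (length(probesets) == 1L) {
    mu_wt <- matrix(mu_wt, nrow = 1L)
    mu_mut <- matrix(mu_mut, nrow = 1L)
  }

  call_one <- function(mu) {
    calls <- apply(mu, 1L, classify_trajectory, r_min = r_min, min_amp = min_amp)
    list(pattern = vapply(calls, `[[`, "", "pattern"),
         r = vapply(calls, `[[`, 0, "r"),
         amp = vapply(calls, `[[`, 0, "amplitude"))
  }
  cw <- call_one(mu_wt)
  cm <- call_one(mu_mut)
  genes <- probeset_genes(study)
  data.frame(probeset_id = probesets,
             gene_id = unname(genes[probesets]),
             pattern_wt = cw$pattern, pattern_mut = cm$pattern,
             r_wt = cw$r, r_mut = cm$r,
             amp_wt = cw$amp, amp_mut = cm$amp,
             direction = ifelse(rowMeans(mu_mut) - rowMeans(mu_wt) >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate probeset trajectory calls to genes
#'
#' A gene inherits its probesets' pattern when all of them agree (per
#' genotype); disagreement yields `"mixed"`. Likewise for the genotype
#' direction. Probesets without a gene annotation are dropped.
#'
#' @param calls Output of [trajectory_calls()].
#' @return `data.frame` with columns `gene_id`, `pattern_wt`, `pattern_mut`,
#'   `direction` (values include `"mixed"`).
#' @export
gene_trajectory_calls <- function(calls) {
  calls <- calls[!is.na(calls$gene_id), , drop = FALSE]
  agg <- function(v) if (length(unique(v)) == 1L) v[[1L]] else "mixed"
  sp <- split(calls, calls$gene_id)
  out <- data.frame(gene_id = names(sp),
                    pattern_wt = vapply(sp, function(x) agg(x$pattern_wt), ""),
                    pattern_mut = vapply(sp, function(x) agg(x$pattern_mut), ""),
                    direction = vapply(sp, function(x) agg(x$direction), ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Build the (WT pattern x MUT pattern) count table
#'
#' Cross-tabulates gene-level trajectory calls into a 3 x 3 table (MUT
#' pattern in rows, WT pattern in columns, each up/NC/down), recording
#' within each cell the number of genes whose expression is lower
#' (`"down"`) or higher (`"up"`) in MUT. Genes with a mixed pattern in
#' either genotype cannot be placed in a cell and are excluded (their count
#' is recorded); genes with an unambiguous pattern but a mixed direction
#' stay in their cell and are excluded only from the down/up tallies, so
#' down + up <= cell count.
#'
#' @param gene_calls Output of [gene_trajectory_calls()] (or any data frame
#'   with columns `gene_id`, `pattern_wt`, `pattern_mut`, `direction`).
#' @return Object of class `pattern_table`: list with 3 x 3 matrices
#'   `counts`, `n_down`, `n_up` (rows = MUT pattern, cols = WT pattern),
#'   `row_totals`, `col_totals`, `grand_total`, and `n_mixed_pattern`.
#' @export
build_pattern_table <- function(gene_calls) {
  req <- c("gene_id", "pattern_wt", "pattern_mut", "direction")
  stopifnot(all(req %in% names(gene_calls)))
  levs <- c("up", "NC", "down")
  mixed <- gene_calls$pattern_wt == "mixed" | gene_calls$pattern_mut == "mixed"
  gc <- gene_calls[!mixed, , drop = FALSE]
  bad <- setdiff(unique(c(gc$pattern_wt, gc$pattern_mut)), levs)
  if (length(bad)) stop_("unknown pattern value(s): %s", paste(bad, collapse = ", "))
  fw <- factor(gc$pattern_wt, levels = levs)
  fm <- factor(gc$pattern_mut, levels = levs)
  counts <- table(fm, fw)
  n_down <- table(fm[gc$direction == "down"], fw[gc$direction == "down"])
  n_up <- table(fm[gc$direction == "up"], fw[gc$direction == "up"])
  as_m <- function(tb) {
    m <- matrix(0L, 3L, 3L, dimnames = list(MUT = levs, WT = levs))
    m[rownames(tb), colnames(tb)] <- as.integer(tb)
    m
  }
  counts <- as_m(counts); n_down <- as_m(n_down); n_up <- as_m(n_up)
  structure(list(counts = counts, n_down = n_down, n_up = n_up,
                 row_totals = rowSums(counts), col_totals = colSums(counts),
                 grand_total = sum(counts),
                 n_mixed_pattern = sum(mixed)),
            class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  levs <- c("up", "NC", "down")
  cell <- function(i, j) sprintf("%d (%dv,%d^)", x$counts[i, j], x$n_down[i, j], x$n_up[i, j])
  cat("pattern table (rows = MUT trajectory, cols = WT trajectory):\n")
  header <- sprintf("%-6s %-14s %-14s %-14s %s", "", "WT up", "WT NC", "WT down", "Total")
  cat(header, "\n")
  for (i in levs) {
    tot <- sprintf("%d (%dv,%d^)", x$row_totals[i], sum(x$n_down[i, ]), sum(x$n_up[i, ]))
    cat(sprintf("%-6s %-14s %-14s %-14s %s\n", i, cell(i, "up"), cell(i, "NC"),
                cell(i, "down"), tot))
  }
  cat(sprintf("%-6s %-14d %-14d %-14d %d\n", "Total", x$col_totals["up"],
              x$col_totals["NC"], x$col_totals["down"], x$grand_total))
  if (x$n_mixed_pattern > 0)
    cat(sprintf("(%d mixed-pattern gene(s) excluded)\n", x$n_mixed_pattern))
  invisible(x)
}

#' Full temporal analysis
#'
#' Runs the genotype-by-time ANOVA screen, selects probesets at
#' `q < alpha`, classifies their trajectories per genotype, aggregates to
#' genes and builds the pattern table.
#'
#' @param study An [expression_study()].
#' @param alpha FDR threshold for the ANOVA screen (default 0.05).
#' @param r_min,min_amp Trajectory thresholds (see [classify_trajectory()]).
#' @return List with elements `anova` (per-probeset screen), `calls`
#'   (significant probeset calls), `gene_calls`, `pattern_table`.
#' @export
temporal_analysis <- function(study, alpha = 0.05, r_min = 0.8, min_amp = 0.1) {
  an <- genotype_time_anova(study)
  sig <- an$probeset_id[an$q < alpha]
  if (!length(sig)) {
    empty <- data.frame(gene_id = character(0), pattern_wt = character(0),
                        pattern_mut = character(0), direction = character(0))
    return(list(anova = an,
                calls = NULL, gene_calls = empty,
                pattern_table = build_pattern_table(empty)))
  }
  calls <- trajectory_calls(study, sig, r_min = r_min, min_amp = min_amp)
  gcalls <- gene_trajectory_calls(calls)
  list(anova = an, calls = calls, gene_calls = gcalls,
       pattern_table = build_pattern_table(gcalls))
}
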