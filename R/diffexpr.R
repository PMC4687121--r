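# Two-group differential expression with empirical-Bayes variance
# moderation (moderated t), BH-FDR, fold-change conventions and ranking.

#' Per-probeset two-group summary statistics
#'
#' Computes, for each probeset, the log2 fold change `mean(group2) -
#' mean(group1)` and the pooled within-group variance with `n1 + n2 - 2`
#' residual degrees of freedom. The contrast orientation convention
#' throughout the package is MUT - WT (genotype) and later - earlier (age),
#' i.e. `group1` is the reference.
#'
#' @param study An [expression_study()].
#' @param group1,group2 Character vectors of sample ids (each of length >= 2).
#' @return `data.frame` with columns `probeset_id`, `log2fc`, `s2`, `df`.
#' @export
group_stats <- function(study, group1, group2) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$matrix
  for (g in list(group1, group2)) {
    missing <- setdiff(g, colnames(m))
    if (length(missing)) stop_("unknown sample id(s): %s", paste(missing, collapse = ", "))
  }
  if (length(intersect(group1, group2)))
    stop_("groups overlap: %s", paste(intersect(group1, group2), collapse = ", "))
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop_("each group needs >= 2 samples (got %d and %d)", n1, n2)
  x1 <- m[, group1, drop = FALSE]
  x2 <- m[, group2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  data.frame(probeset_id = rownames(m),
             log2fc = m2 - m1,
             s2 = (ss1 + ss2) / df,
             df = df,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate the variance-moderation hyper-prior
#'
#' Method-of-moments fit of the scaled inverse-chi-square prior
#' `sigma^2_g ~ d0 * s0^2 / chisq(d0)` on the log observed variances:
#' `trigamma(d0/2) = var(log s2) - mean(trigamma(df/2))`, solved by monotone
#' root finding on `d0` in `[0.1, 1e6]`; `s0^2` follows from the mean of
#' `log s2` with the digamma bias correction. When the observed dispersion
#' of `log s2` is no larger than its expected sampling dispersion the prior
#' is degenerate: `d0 = Inf` and `s0^2` is the bias-corrected geometric mean.
#' Zero variances are excluded from the moment fit.
#'
#' @param s2 Per-probeset residual variances.
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List with elements `d0` and `s0_sq`.
#' @export
estimate_prior <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  stopifnot(length(df) == length(s2))
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop_("all variances are zero; cannot estimate a variance prior")
  if (sum(ok) < 10L) stop_("need >= 10 probesets with positive variance")
  z <- log(s2[ok])
  dg <- df[ok]
  # E log s2 = log s0^2 + [digamma(dg/2) - log(dg/2)] - [digamma(d0/2) - log(d0/2)]
  # Var log s2 = trigamma(dg/2) + trigamma(d0/2)
  target <- stats::var(z) - mean(trigamma(dg / 2))
  mean_adj <- mean(z) - mean(digamma(dg / 2) - log(dg / 2))
  lo <- 0.1; hi <- 1e6
  if (!is.finite(target) || target <= trigamma(hi / 2)) {
    return(list(d0 = Inf, s0_sq = exp(mean_adj)))
  }
  if (target >= trigamma(lo / 2)) {
    d0 <- lo
  } else {
    d0 <- stats::uniroot(function(d) trigamma(d / 2) - target,
                         lower = lo, upper = hi, tol = 1e-10)$root
  }
  list(d0 = d0, s0_sq = exp(mean_adj + digamma(d0 / 2) - log(d0 / 2)))
}

#' Moderated t statistic and two-sided p-value
#'
#' Shrinks each probeset variance toward the prior,
#' `s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df)`, and refers
#' `t = log2fc / sqrt(s2_tilde * (1/n1 + 1/n2))` to a t distribution with
#' `d0 + df` degrees of freedom. `d0 = 0` recovers the classical pooled
#' two-sample t; `d0 = Inf` uses `s0_sq` for every probeset and a normal
#' reference.
#'
#' @param log2fc,s2,df Per-probeset contrast estimates from [group_stats()].
#' @param d0,s0_sq Prior degrees of freedom and variance from
#'   [estimate_prior()].
#' @param n1,n2 Group sizes.
#' @return `data.frame` with columns `t`, `p`.
#' @export
moderated_t <- function(log2fc, s2, df, d0, s0_sq, n1, n2) {
  stopifnot(n1 >= 2L, n2 >= 2L, d0 >= 0)
  s2_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t <- log2fc / se
  zero <- se == 0
  if (any(zero)) {
    warning(sprintf("%d probeset(s) with zero moderated variance; p set to 0", sum(zero)))
    t[zero] <- sign(log2fc[zero]) * Inf
    t[zero & log2fc == 0] <- 0
  }
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t)) else
    2 * stats::pt(-abs(t), df = d0 + df)
  p[zero] <- ifelse(log2fc[zero] == 0, 1, 0)
  data.frame(t = t, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1 and
#' mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values (q-values).
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_("p must be numeric")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Absolute fold change from a log2 fold change
#'
#' `abs_fc = 2^|log2fc|`: the linear-scale magnitude of change regardless of
#' direction, always >= 1.
#'
#' @param log2fc Finite log2 fold change(s).
#' @return Absolute fold change(s).
#' @examples
#' abs_fold_change(-0.645) # 1.564 to three decimals
#' @export
abs_fold_change <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop_("log2fc must be finite")
  2^abs(log2fc)
}

#' Two-group differential expression contrast
#'
#' Full moderated-t pipeline for one two-group contrast: per-probeset
#' statistics, empirical-Bayes prior, moderated t and p, BH-FDR q, absolute
#' fold change, and a deterministic 1-based rank (ascending p, ties broken
#' by descending |log2FC| then probeset id).
#'
#' @inheritParams group_stats
#' @param label Free-text contrast label stored in the result.
#' @return Object of class `de_result`: a `data.frame` with columns
#'   `probeset_id`, `gene_id`, `log2fc`, `abs_fc`, `t`, `p`, `q`, `rank`
#'   (rows in rank order) and attributes `d0`, `s0_sq`, `n1`, `n2`, `label`.
#' @export
de_contrast <- function(study, group1, group2, label = "group2-group1") {
  gs <- group_stats(study, group1, group2)
  prior <- estimate_prior(gs$s2, gs$df)
  tp <- moderated_t(gs$log2fc, gs$s2, gs$df, prior$d0, prior$s0_sq,
                    length(group1), length(group2))
  genes <- probeset_genes(study)
  res <- data.frame(probeset_id = gs$probeset_id,
                    gene_id = unname(genes[gs$probeset_id]),
                    log2fc = gs$log2fc,
                    abs_fc = abs_fold_change(gs$log2fc),
                    t = tp$t, p = tp$p,
                    q = bh_adjust(tp$p),
                    stringsAsFactors = FALSE)
  ord <- order(res$p, -abs(res$log2fc), res$probeset_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(res, class = c("de_result", "data.frame"),
            d0 = prior$d0, s0_sq = prior$s0_sq,
            n1 = length(group1), n2 = length(group2), label = label)
}

#' @export
print.de_result <- function(x, n = 10L, ...) {
  cat(sprintf("de_result '%s': %d probesets (n1 = %d, n2 = %d)\n",
              attr(x, "label"), nrow(x), attr(x, "n1"), attr(x, "n2")))
  cat(sprintf("prior: d0 = %s, s0_sq = %.4g\n",
              format(attr(x, "d0"), digits = 4), attr(x, "s0_sq")))
  cat(sprintf("significant: %d at nominal p < 0.05, %d at FDR q < 0.05\n",
              sum(x$p < 0.05), sum(x$q < 0.05)))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' @export
summary.de_result <- function(object, alpha = 0.05, ...) {
  sig_p <- object$p < alpha
  sig_q <- object$q < alpha
  out <- list(label = attr(object, "label"),
              n = nrow(object),
              d0 = attr(object, "d0"), s0_sq = attr(object, "s0_sq"),
              alpha = alpha,
              n_nominal = sum(sig_p),
              n_nominal_up = sum(sig_p & object$log2fc > 0),
              n_nominal_down = sum(sig_p & object$log2fc < 0),
              n_fdr = sum(sig_q),
              n_fdr_up = sum(sig_q & object$log2fc > 0),
              n_fdr_down = sum(sig_q & object$log2fc < 0))
  class(out) <- "summary.de_result"
  out
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("contrast '%s' over %d probesets (prior d0 = %s)\n",
              x$label, x$n, format(x$d0, digits = 4)))
  cat(sprintf("nominal p < %g: %d (%d up, %d down)\n",
              x$alpha, x$n_nominal, x$n_nominal_up, x$n_nominal_down))
  cat(sprintf("FDR q < %g: %d (%d up, %d down)\n",
              x$alpha, x$n_fdr, x$n_fdr_up, x$n_fdr_down))
  invisible(x)
}
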