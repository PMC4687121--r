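# Deterministic TSV serialization for every result type. UTF-8,
# tab-separated, '.' decimal separator; statistics carry 6 significant
# digits, log2FC/AbsFC columns 3 decimal places, frequencies 6 decimals.

#' Write an analysis result as a TSV file
#'
#' Each result type has a stated column order and row sort key, so output
#' files are byte-deterministic given the same input.
#'
#' @param x A result object (`de_result`, `ranked_gene_list`,
#'   `concordance_profile`, `pattern_table`, `enrichment_result`,
#'   `interaction_result`, or a plain data frame).
#' @param path Output file path.
#' @param ... Unused.
#' @return Invisibly, the path.
#' @export
write_table <- function(x, path, ...) UseMethod("write_table")

#' @noRd
write_tsv_ <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_("cannot write '%s': directory does not exist", path)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop_("cannot write '%s': %s", path, conditionMessage(e)))
  invisible(path)
}

#' @noRd
sig6 <- function(x) as.character(signif(x, 6))

#' @noRd
dp3 <- function(x) sprintf("%.3f", x)

#' @export
write_table.de_result <- function(x, path, ...) {
  df <- data.frame(probeset_id = x$probeset_id, gene_id = x$gene_id,
                   log2FC = dp3(x$log2fc), AbsFC = dp3(x$abs_fc),
                   t = sig6(x$t), p = sig6(x$p), q = sig6(x$q),
                   rank = x$rank, stringsAsFactors = FALSE)
  write_tsv_(df[order(x$rank), , drop = FALSE], path)
}

#' @export
write_table.ranked_gene_list <- function(x, path, ...) {
  df <- data.frame(id = x$id, gene_id = x$gene_id, probeset_id = x$probeset_id,
                   signed_stat = dp3(x$signed_stat), p = sig6(x$p),
                   rank = x$rank, stringsAsFactors = FALSE)
  write_tsv_(df[order(x$rank), , drop = FALSE], path)
}

#' @export
write_table.concordance_profile <- function(x, path, ...) {
  df <- data.frame(bin_index = x$bin,
                   concordant_freq = sprintf("%.6f", x$concordant_freq),
                   discordant_freq = sprintf("%.6f", x$discordant_freq),
                   stringsAsFactors = FALSE)
  write_tsv_(df, path)
}

#' @export
write_table.pattern_table <- function(x, path, ...) {
  levs <- c("up", "NC", "down")
  grid <- expand.grid(mut_pattern = levs, wt_pattern = levs,
                      stringsAsFactors = FALSE)
  df <- data.frame(grid,
                   count = mapply(function(i, j) x$counts[i, j],
                                  grid$mut_pattern, grid$wt_pattern),
                   n_down = mapply(function(i, j) x$n_down[i, j],
                                   grid$mut_pattern, grid$wt_pattern),
                   n_up = mapply(function(i, j) x$n_up[i, j],
                                 grid$mut_pattern, grid$wt_pattern))
  write_tsv_(df, path)
}

#' @export
write_table.enrichment_result <- function(x, path, ...) {
  df <- data.frame(term_id = x$term_id, name = x$name,
                   p = sig6(x$p), fdr_p = sig6(x$fdr_p),
                   count = x$count, global = x$global, stringsAsFactors = FALSE)
  write_tsv_(df, path)
}

#' @export
write_table.interaction_result <- function(x, path, ...) {
  df <- data.frame(id = x$id, gene_id_a = x$gene_id_a, gene_id_b = x$gene_id_b,
                   fc_a = dp3(x$fc_a), fc_b = dp3(x$fc_b),
                   abs_fc_diff = dp3(x$abs_fc_diff),
                   p_interaction = sig6(x$p_interaction), q = sig6(x$q),
                   stringsAsFactors = FALSE)
  write_tsv_(df, path)
}

#' @export
write_table.data.frame <- function(x, path, ...) {
  num <- vapply(x, is.numeric, logical(1L))
  df <- x
  df[num] <- lapply(df[num], function(v) if (all(v == round(v), na.rm = TRUE)) v else sig6(v))
  write_tsv_(df, path)
}
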