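# ExpressionStudy container: log2 expression matrix + sample design +
# probeset-to-gene annotation. All downstream analyses consume this type.

#' Construct an expression study
#'
#' Bundles a complete log2 expression matrix (probesets x samples) with its
#' per-sample design (genotype, time, model label) and a probeset-to-gene
#' annotation. The constructor canonicalizes ordering (probesets and samples
#' sorted by identifier) so that a study built from row- or column-shuffled
#' inputs is identical to one built from sorted inputs.
#'
#' Invariants enforced: unique probeset ids; every sample has a complete
#' design record and vice versa; no missing or non-numeric expression values;
#' at least 2 samples in every (genotype, time) design cell so that
#' within-cell variances are estimable. Probesets annotated to more than one
#' gene are dropped from the annotation (with a message); many probesets per
#' gene are allowed.
#'
#' @param matrix Numeric matrix of log2 intensities with probeset row names
#'   and sample column names.
#' @param design `data.frame` with columns `sample_id`, `genotype` (values
#'   `"WT"`/`"MUT"`), `time` (ordered numeric, e.g. months) and `model`
#'   (dataset label).
#' @param annotation `data.frame` with columns `probeset_id`, `gene_id`;
#'   may omit probesets (these carry an `NA` gene).
#' @return An object of class `expression_study` with elements `matrix`,
#'   `design`, `annotation`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("ps", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample_id = paste0("s", 1:4),
#'                 genotype = rep(c("WT", "MUT"), each = 2),
#'                 time = 6, model = "demo")
#' a <- data.frame(probeset_id = paste0("ps", 1:3),
#'                 gene_id = c("g1", "g1", "g2"))
#' study <- expression_study(m, d, a)
#' @export
expression_study <- function(matrix, design, annotation = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop_("expression matrix must be a numeric matrix")
  ps <- rownames(matrix)
  if (is.null(ps) || is.null(colnames(matrix)))
    stop_("expression matrix must have probeset row names and sample column names")
  dup <- ps[duplicated(ps)]
  if (length(dup))
    stop_("duplicate probeset id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(matrix)) {
    idx <- which(is.na(matrix), arr.ind = TRUE)[1L, ]
    stop_("missing expression value at probeset '%s', sample '%s'",
          ps[idx[1L]], colnames(matrix)[idx[2L]])
  }

  req <- c("sample_id", "genotype", "time", "model")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop_("design is missing column(s): %s", paste(miss, collapse = ", "))
  design <- as.data.frame(design)[, req]
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop_("duplicate sample id(s) in design: %s",
          paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
  if (anyNA(design)) stop_("design contains missing values")
  bad_gt <- setdiff(unique(design$genotype), c("WT", "MUT"))
  if (length(bad_gt))
    stop_("genotype values must be 'WT' or 'MUT'; found: %s", paste(bad_gt, collapse = ", "))

  orphan_m <- setdiff(colnames(matrix), design$sample_id)
  if (length(orphan_m))
    stop_("sample(s) in matrix absent from design: %s", paste(orphan_m, collapse = ", "))
  orphan_d <- setdiff(design$sample_id, colnames(matrix))
  if (length(orphan_d))
    stop_("sample(s) in design absent from matrix: %s", paste(orphan_d, collapse = ", "))

  # canonical order: probesets and samples sorted by id
  ord_ps <- order(ps)
  ord_s <- order(design$sample_id)
  design <- design[ord_s, , drop = FALSE]
  rownames(design) <- NULL
  matrix <- matrix[ord_ps, design$sample_id, drop = FALSE]
  design$genotype <- factor(design$genotype, levels = c("WT", "MUT"))
  design$time <- as.numeric(design$time)
  design$model <- as.character(design$model)

  cell <- table(design$genotype, design$time)
  if (any(cell > 0 & cell < 2))
    stop_("each (genotype, time) design cell needs >= 2 samples for variance estimation")

  if (is.null(annotation)) {
    annotation <- data.frame(probeset_id = rownames(matrix),
                             gene_id = NA_character_,
                             stringsAsFactors = FALSE)
  } else {
    if (!all(c("probeset_id", "gene_id") %in% names(annotation)))
      stop_("annotation needs columns probeset_id, gene_id")
    annotation <- unique(as.data.frame(annotation)[, c("probeset_id", "gene_id")])
    annotation$probeset_id <- as.character(annotation$probeset_id)
    annotation$gene_id <- as.character(annotation$gene_id)
    multi <- unique(annotation$probeset_id[duplicated(annotation$probeset_id)])
    if (length(multi)) {
      message(sprintf("dropping %d multi-mapping probeset(s) from annotation", length(multi)))
      annotation <- annotation[!annotation$probeset_id %in% multi, , drop = FALSE]
    }
    annotation <- annotation[annotation$probeset_id %in% rownames(matrix), , drop = FALSE]
    missing_ps <- setdiff(rownames(matrix), annotation$probeset_id)
    if (length(missing_ps))
      annotation <- rbind(annotation,
                          data.frame(probeset_id = missing_ps, gene_id = NA_character_))
    annotation <- annotation[order(annotation$probeset_id), , drop = FALSE]
    rownames(annotation) <- NULL
  }

  structure(list(matrix = matrix, design = design, annotation = annotation),
            class = "expression_study")
}

#' Read an expression study from TSV files
#'
#' The matrix file has a header row of sample ids and a first column of
#' probeset ids; the design file has columns `sample_id`, `genotype`, `time`,
#' `model`; the annotation file has columns `probeset_id`, `gene_id`. Samples
#' are reconciled by id, never by position, and the result is independent of
#' the row/column order of the input files.
#'
#' @param matrix_path,design_path,annotation_path Paths to TSV files
#'   (UTF-8, tab-separated, '.' decimal separator). `annotation_path` may be
#'   `NULL`.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(matrix_path, design_path, annotation_path = NULL) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop_("matrix file '%s' has no sample columns", matrix_path)
  ps <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals), dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals) & nzchar(trimws(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("non-numeric value '%s' at probeset '%s', sample '%s' in %s",
          vals[bad[1L, 1L], bad[1L, 2L]], ps[bad[1L, 1L]],
          colnames(vals)[bad[1L, 2L]], matrix_path)
  }
  rownames(num) <- ps
  design <- utils::read.delim(design_path, sep = "\t", stringsAsFactors = FALSE)
  annotation <- if (!is.null(annotation_path))
    utils::read.delim(annotation_path, sep = "\t", stringsAsFactors = FALSE)
  expression_study(num, design, annotation)
}

#' Select sample ids by design attributes
#'
#' @param study An [expression_study()].
#' @param genotype,time,model Optional filters; `NULL` means no restriction.
#' @return Character vector of sample ids.
#' @export
samples_for <- function(study, genotype = NULL, time = NULL, model = NULL) {
  stopifnot(inherits(study, "expression_study"))
  d <- study$design
  keep <- rep(TRUE, nrow(d))
  if (!is.null(genotype)) keep <- keep & d$genotype %in% genotype
  if (!is.null(time)) keep <- keep & d$time %in% time
  if (!is.null(model)) keep <- keep & d$model %in% model
  d$sample_id[keep]
}

#' @export
print.expression_study <- function(x, ...) {
  d <- x$design
  cat(sprintf("expression_study: %d probesets x %d samples (model: %s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(unique(d$model), collapse = ", ")))
  cat("design cells (genotype x time):\n")
  print(table(d$genotype, d$time))
  n_genes <- length(unique(stats::na.omit(x$annotation$gene_id)))
  cat(sprintf("annotation: %d probesets mapped to %d genes\n",
              sum(!is.na(x$annotation$gene_id)), n_genes))
  invisible(x)
}

#' Gene ids aligned to the probeset rows of a study
#' @noRd
probeset_genes <- function(study) {
  stats::setNames(study$annotation$gene_id, study$annotation$probeset_id)[rownames(study$matrix)]
}
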