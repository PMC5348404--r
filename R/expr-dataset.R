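# Expression dataset container: a genes x samples value table plus per-sample
# stage/group annotations. Values are RPKM-like (non-negative) until
# log2-transformed.

#' Construct an expression dataset
#'
#' Bundles an expression value table with its sample annotations. Values are
#' expected on the raw (RPKM-like, non-negative) scale; use
#' [log2_transform()] before running stage statistics on the log scale.
#'
#' @param values Data frame with a `gene_id` column followed by one numeric
#'   column per sample.
#' @param meta Data frame with columns `sample_id`, `stage`, `group`; one row
#'   per sample column of `values`.
#' @param transform Either `"none"` (raw scale) or `"log2"`.
#' @return An `expr_dataset` object (list with tibbles `values` and `meta`).
#' @export
expr_dataset <- function(values, meta, transform = "none") {
  values <- as_tibble(values)
  meta <- as_tibble(meta)
  if (!"gene_id" %in% names(values)) abort("`values` needs a `gene_id` column")
  if (anyDuplicated(values$gene_id)) abort("gene_ids must be unique")
  needed <- c("sample_id", "stage", "group")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) {
    abort(paste0("`meta` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  sample_cols <- setdiff(names(values), "gene_id")
  if (!setequal(sample_cols, meta$sample_id)) {
    abort("sample columns of `values` must match `meta$sample_id`")
  }
  if (anyNA(meta$stage) || anyNA(meta$group)) abort("every sample needs a stage and a group")
  mat <- as.matrix(values[sample_cols])
  if (!is.numeric(mat)) abort("expression values must be numeric")
  if (transform == "none" && any(mat < 0)) abort("raw expression values must be non-negative")
  transform <- match.arg(transform, c("none", "log2"))
  structure(
    list(values = values, meta = meta, transform = transform),
    class = "expr_dataset"
  )
}

#' @method print expr_dataset
#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %d genes x %d samples (%s scale)\n",
    nrow(x$values), nrow(x$meta),
    if (x$transform == "none") "raw" else "log2"
  ))
  cat("  stages: ", paste(levels(factor(x$meta$stage)), collapse = ", "), "\n", sep = "")
  cat("  groups: ", paste(levels(factor(x$meta$group)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Long-format view of an expression dataset
#'
#' @param x An `expr_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`, `stage`,
#'   `group`.
#' @method tidy expr_dataset
#' @export
tidy.expr_dataset <- function(x, ...) {
  x$values |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "value") |>
    left_join(x$meta, by = "sample_id")
}

#' Log2-transform an expression dataset
#'
#' Replaces every value x by `log2(x + pseudocount)`. Transforming an already
#' transformed dataset is an error; stage statistics conventionally run on
#' this log2(RPKM + 1)-style scale.
#'
#' @param dataset An `expr_dataset` on the raw scale.
#' @param pseudocount Positive offset added before taking logs (default 1, so
#'   a zero stays a zero).
#' @return The transformed `expr_dataset`.
#' @export
log2_transform <- function(dataset, pseudocount = 1) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (dataset$transform != "none") abort("dataset is already log2-transformed")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number")
  }
  dataset$values <- dataset$values |>
    mutate(across(-"gene_id", ~ log2(.x + pseudocount)))
  dataset$transform <- "log2"
  dataset$pseudocount <- pseudocount
  dataset
}

# Pull one gene's values (optionally restricted to one group) together with
# its stage labels. Internal workhorse for the stage statistics.
gene_vector <- function(dataset, gene, group = NULL) {
  row <- dataset$values[dataset$values$gene_id == gene, , drop = FALSE]
  if (nrow(row) == 0) {
    abort(paste0(
      "unknown gene `", gene, "`; available genes include: ",
      paste(head(dataset$values$gene_id, 5), collapse = ", "),
      if (nrow(dataset$values) > 5) ", ..." else ""
    ))
  }
  meta <- dataset$meta
  if (!is.null(group)) {
    if (!group %in% meta$group) {
      abort(paste0(
        "unknown group `", group, "`; available: ",
        paste(unique(meta$group), collapse = ", ")
      ))
    }
    meta <- meta[meta$group == group, , drop = FALSE]
  }
  x <- as.numeric(row[1, meta$sample_id])
  list(x = x, stage = factor(meta$stage))
}

#' Write / read the expression TSV pair
#'
#' The on-disk format is two TSVs: an expression matrix whose first column is
#' `gene_id` with one column per sample, and a metadata table with columns
#' `sample_id`, `stage`, `group`.
#'
#' @param dataset An `expr_dataset`.
#' @param matrix_path,meta_path File paths.
#' @return `write_expression()` returns the dataset invisibly;
#'   `read_expression()` returns an `expr_dataset`.
#' @export
write_expression <- function(dataset, matrix_path, meta_path) {
  stopifnot(inherits(dataset, "expr_dataset"))
  readr::write_tsv(dataset$values, matrix_path)
  readr::write_tsv(dataset$meta, meta_path)
  invisible(dataset)
}

#' @rdname write_expression
#' @param transform Scale flag recorded on the dataset being read.
#' @export
read_expression <- function(matrix_path, meta_path, transform = "none") {
  values <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  expr_dataset(values, meta, transform = transform)
}
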