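#' Construct a log-scale expression matrix with condition labels
#'
#' The central data container of the package: a genes x samples matrix of
#' log2-scale abundances (e.g. VST-transformed microarray values, or
#' Ct-derived log2 quantities) together with a condition label for every
#' sample. All downstream steps (stability ranking, filtering,
#' normalization factors) operate on this container.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Must
#'   carry unique, non-empty rownames (gene ids) and colnames (sample ids).
#' @param conditions named character vector mapping every sample id to a
#'   condition label, or an unnamed vector of length `ncol(values)` taken
#'   in column order.
#' @param scale_tag either `"log2"` (values increase with abundance) or
#'   `"ct"` (values derived from quantification cycles via
#'   [ct_to_expression_matrix()]; still log2 quantities, the tag records
#'   provenance so normalization factors know their source scale).
#' @param na_action what to do with rows containing missing values:
#'   `"error"` (default) or `"drop"` (drop with a message reporting the
#'   count).
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix), `condition_of` (named character), and
#'   `scale_tag`.
#' @export
expression_matrix <- function(values, conditions, scale_tag = c("log2", "ct"),
                              na_action = c("error", "drop")) {
  scale_tag <- match.arg(scale_tag)
  na_action <- match.arg(na_action)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))

  bad <- !stats::complete.cases(values) | apply(values, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    if (na_action == "error")
      stop(sum(bad), " gene row(s) contain missing or non-finite values; ",
           "first offender: ", rownames(values)[which(bad)[1]])
    message("dropping ", sum(bad), " gene row(s) with missing values")
    values <- values[!bad, , drop = FALSE]
  }

  samples <- colnames(values)
  if (is.null(names(conditions))) {
    if (length(conditions) != length(samples))
      stop("unnamed `conditions` must have one entry per sample")
    names(conditions) <- samples
  }
  missing_lab <- setdiff(samples, names(conditions))
  if (length(missing_lab))
    stop("sample(s) without condition label: ", paste(missing_lab, collapse = ", "))
  condition_of <- as.character(conditions[samples])
  names(condition_of) <- samples

  structure(list(values = values,
                 condition_of = condition_of,
                 scale_tag = scale_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  tab <- table(x$condition_of)
  cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Restrict an expression matrix to a subset of genes and/or samples
#'
#' @param x an `expression_matrix`.
#' @param genes,samples character vectors of ids to keep (default: all).
#'   Order of the result follows the order given here.
#' @return an `expression_matrix`.
#' @export
subset_matrix <- function(x, genes = gene_ids(x), samples = sample_ids(x)) {
  missing_g <- setdiff(genes, gene_ids(x))
  if (length(missing_g))
    stop("gene(s) not in matrix: ", paste(missing_g, collapse = ", "))
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_s))
    stop("sample(s) not in matrix: ", paste(missing_s, collapse = ", "))
  expression_matrix(x$values[genes, samples, drop = FALSE],
                    x$condition_of[samples], x$scale_tag)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample names and gene identifiers in the first
#' column. Condition labels come from a sample sheet (CSV with columns
#' `sample_id`, `condition`) or directly via `conditions`.
#'
#' @param path path to the matrix file.
#' @param sample_sheet optional path to the sample-sheet CSV.
#' @param conditions optional named character vector (overrides
#'   `sample_sheet`).
#' @param sep field delimiter; `NULL` (default) auto-detects from the file
#'   extension (`.csv` = comma, `.tsv`/`.txt` = tab).
#' @param scale_tag see [expression_matrix()].
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, sample_sheet = NULL, conditions = NULL,
                                   sep = NULL, scale_tag = "log2") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("expected gene-id column plus at least one sample column")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated gene id(s) in ", path, ": ",
                        paste(dup, collapse = ", "))
  num <- df[-1]
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(num[[j]]))) &
                         !is.na(num[[j]]))[1]
      stop("non-numeric value in column '", names(num)[j], "', row ",
           if (is.na(bad_row)) "?" else ids[bad_row])
    }
  }
  m <- as.matrix(num)
  rownames(m) <- ids

  if (is.null(conditions)) {
    if (is.null(sample_sheet))
      stop("supply either `sample_sheet` or `conditions`")
    ss <- utils::read.csv(sample_sheet, stringsAsFactors = FALSE)
    req <- c("sample_id", "condition")
    if (!all(req %in% names(ss)))
      stop("sample sheet must have columns: ", paste(req, collapse = ", "))
    conditions <- stats::setNames(as.character(ss$condition),
                                  as.character(ss$sample_id))
  }
  expression_matrix(m, conditions, scale_tag = scale_tag)
}

#' Write an expression matrix (and its sample sheet) to delimited text
#'
#' @param x an `expression_matrix`.
#' @param path output path for the matrix; delimiter from extension.
#' @param sample_sheet optional path for the sample-sheet CSV.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sample_sheet = NULL) {
  sep <- detect_sep(path)
  df <- data.frame(gene = gene_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(sample_sheet)) {
    utils::write.csv(data.frame(sample_id = sample_ids(x),
                                condition = unname(x$condition_of)),
                     sample_sheet, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
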