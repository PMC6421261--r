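#' Construct a long-format table of qPCR quantification cycles
#'
#' Holds raw Ct measurements with their technical-replicate structure.
#' Measurements above the limit of detection (LOD) are retained but
#' flagged censored; censoring is strict (`ct > lod`), so a reading at
#' exactly the LOD counts as detected.
#'
#' @param records data.frame with columns `gene`, `sample`, `condition`,
#'   `replicate` (technical replicate index), `ct` (cycles, > 0).
#' @param lod limit of detection in cycles (default 35).
#' @return An object of class `ct_table`: list with `records` (the
#'   data.frame, plus a logical `censored` column) and `lod`.
#' @export
ct_table <- function(records, lod = 35) {
  req <- c("gene", "sample", "condition", "replicate", "ct")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  records <- as.data.frame(records)[req]
  if (nrow(records) == 0) {
    warning("empty Ct table")
    records$censored <- logical(0)
    return(structure(list(records = records, lod = lod), class = "ct_table"))
  }
  records$gene <- as.character(records$gene)
  records$sample <- as.character(records$sample)
  records$condition <- as.character(records$condition)
  records$replicate <- as.integer(records$replicate)
  records$ct <- as.numeric(records$ct)
  if (any(!is.finite(records$ct)) || any(records$ct <= 0))
    stop("all Ct values must be finite and > 0")
  key <- paste(records$gene, records$sample, records$replicate, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("duplicated (gene, sample, replicate) triple(s): ",
         paste(gsub("\r", "/", dup), collapse = "; "))
  records$censored <- records$ct > lod
  structure(list(records = records, lod = lod), class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("<ct_table> %d records, %d genes, %d samples, LOD %g cycles (%d censored)\n",
              nrow(x$records), length(unique(x$records$gene)),
              length(unique(x$records$sample)), x$lod, sum(x$records$censored)))
  invisible(x)
}

#' Read a long-format Ct table from CSV
#'
#' @param path CSV with columns `gene`, `sample`, `condition`, `replicate`,
#'   `ct`.
#' @param lod limit of detection in cycles (default 35).
#' @return a `ct_table`.
#' @export
read_ct_table <- function(path, lod = 35) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(gene = character(0), sample = character(0),
                     condition = character(0), replicate = integer(0),
                     ct = numeric(0))
  }
  ct_table(df, lod = lod)
}

#' Write a Ct table to CSV
#'
#' The derived `censored` column is not written; it is recomputed from the
#' LOD on read.
#'
#' @param x a `ct_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  cols <- c("gene", "sample", "condition", "replicate", "ct")
  utils::write.csv(x$records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
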