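#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are collapsed; duplicate set names across lines are an
#' error.
#'
#' @param path path to the GMT file.
#' @return An object of class `gene_set_collection`: list with `sets`
#'   (named list of character vectors) and `description` (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    nm <- fields[1]
    if (nm %in% names(sets)) stop("duplicated set name: ", nm)
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " (", nm, ") has no members")
    sets[[nm]] <- members
    desc[nm] <- fields[2]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection in memory
#'
#' @param sets named list of character vectors (set name to member genes).
#' @param description optional named character vector of set descriptions.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a non-empty named list")
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(vapply(sets, length, 1L) == 0)) stop("every set must be non-empty")
  if (is.null(description)) description <- stats::setNames(rep("", length(sets)),
                                                           names(sets))
  structure(list(sets = sets, description = description[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %s\n", length(x$sets),
              paste(range(vapply(x$sets, length, 1L)), collapse = "-")))
  invisible(x)
}
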