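# TSV dialect: UTF-8, tab separated, no quoting, header row of sample IDs
# with first header cell "feature_id", "NA" for missing (rejected in
# matrices), dot decimal separator regardless of locale.

#' Read a features-by-samples matrix from TSV
#'
#' @param path Path to a TSV file whose header row holds sample IDs and
#'   whose first column holds feature IDs.
#' @param layer_tag Layer tag to assign (see [omics_matrix()]).
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, layer_tag) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("matrix file '", path, "' is empty or has no sample columns",
         call. = FALSE)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature IDs in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric or missing cell in '%s' at feature '%s', sample '%s' (value '%s')",
      path, ids[bad[1L, 1L]], colnames(raw)[-1L][bad[1L, 2L]],
      body[bad[1L, , drop = FALSE]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(raw)[-1L])
  omics_matrix(num, layer_tag)
}

#' Write a features-by-samples matrix to TSV
#'
#' Values are formatted with 17 significant digits so that
#' `read_omics_matrix(write_omics_matrix(x))` round-trips bit-exactly.
#'
#' @param x An [omics_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  body <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  lines <- paste(rownames(x), apply(body, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with a header; must contain a `sample_id` column.
#' @return A data frame (character/numeric columns as parsed).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_table(meta)
  meta
}

#' Write sample metadata to TSV
#' @param meta Data frame of per-sample metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within one line are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_library()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("GMT file '", path, "' is empty; returning an empty library",
            call. = FALSE)
    return(pathway_library(stats::setNames(list(), character())))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need set name, description and >= 1 member",
                   i, length(fields)), call. = FALSE)
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s' (line %d) has duplicate members; deduplicated",
                      fields[1L], i), call. = FALSE)
      members <- unique(members)
    }
    sets[[fields[1L]]] <- members
  }
  pathway_library(sets)
}

#' Write a pathway library to GMT
#' @param lib A [pathway_library()].
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path, descriptions = NULL) {
  stopifnot(inherits(lib, "pathway_library"))
  lines <- vapply(names(lib$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, lib$sets[[nm]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a pair-results table to TSV
#' @param results Data frame of pair results (see [run_all_pairs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pair-results table from TSV
#' @param path Path written by [write_pair_results()].
#' @return Data frame of pair results.
#' @export
read_pair_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
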