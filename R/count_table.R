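#' ZOTU count tables
#'
#' A count table is the universal input of the workflow: a non-negative
#' integer matrix of read counts with ZOTUs as rows and samples as columns
#' (the common amplicon orientation). `count_table()` validates a matrix and
#' stamps it with the `"count_table"` class; all downstream functions accept
#' either a validated table or a plain matrix with dimnames.
#'
#' @param counts integer matrix, ZOTUs x samples, with unique rownames
#'   (ZOTU ids) and unique colnames (sample ids).
#' @return An integer matrix of class `count_table`.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop_("counts must be numeric")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_("counts must carry ZOTU ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop_("duplicate ZOTU id(s): %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_("duplicate sample id(s): %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop_("count table needs at least 1 ZOTU and 1 sample")
  if (anyNA(counts)) stop_("count table contains missing values")
  if (any(counts < 0)) stop_("negative count(s) present")
  if (max(abs(counts - round(counts))) > 1e-9) {
    bad <- which(abs(counts - round(counts)) > 1e-9, arr.ind = TRUE)[1L, ]
    stop_("non-integer count at ZOTU '%s', sample '%s'",
          rownames(counts)[bad[1L]], colnames(counts)[bad[2L]])
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(matrix()))
  counts
}

as_count_matrix <- function(x) {
  if (inherits(x, "count_table")) return(unclass(x))
  unclass(count_table(x))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d ZOTUs x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.double(x)), big.mark = ",")))
  invisible(x)
}

#' Read a ZOTU count table from TSV
#'
#' Expects a header row of sample ids, a first column of ZOTU ids (header
#' `#ZOTU_ID` by convention) and integer cells.
#'
#' @param path path to a tab-separated file.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_("no data rows in '%s'", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples))
    stop_("duplicate sample id(s) in header of '%s': %s", path,
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- cells[-1L]
  if (any(lengths(body) != length(header)))
    stop_("ragged rows in '%s'", path)
  zotus <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(zotus))
    stop_("duplicate ZOTU id(s) in '%s': %s", path,
          paste(unique(zotus[duplicated(zotus)]), collapse = ", "))
  raw <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                nrow = length(body), byrow = TRUE)
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_("non-numeric count at ZOTU '%s', sample '%s' in '%s'",
          zotus[bad[1L]], samples[bad[2L]], path)
  }
  if (max(abs(num - round(num))) > 1e-9) {
    bad <- which(abs(num - round(num)) > 1e-9, arr.ind = TRUE)[1L, ]
    stop_("non-integer count at ZOTU '%s', sample '%s' in '%s'",
          zotus[bad[1L]], samples[bad[2L]], path)
  }
  dimnames(num) <- list(zotus, samples)
  count_table(num)
}

#' Write a ZOTU count table to TSV
#'
#' Emits the same orientation the reader expects (`#ZOTU_ID` header, one
#' column per sample), UTF-8 with LF line endings, so that a read/write
#' round-trip is bit-exact.
#'
#' @param table a [count_table()] (or coercible matrix).
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  m <- as_count_matrix(table)
  header <- paste(c("#ZOTU_ID", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], m[i, ]), collapse = "\t")
  }, character(1))
  write_tsv_lines(c(header, body), path)
}
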