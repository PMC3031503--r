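#' Read a labeled matrix from tab-separated text
#'
#' Reads the package's labeled-matrix dialect: first row holds the column
#' identifiers after a leading corner field (whose content is ignored), the first
#' field of every following row is the row identifier, fields are
#' tab-separated, decimal point, UTF-8. Empty cells and the literal
#' \code{NA} are treated as missing: rejected by default, or replaced by
#' the row mean of the observed cells when \code{imputeMissing = TRUE}.
#'
#' @param path path to a TSV file.
#' @param imputeMissing replace missing cells by the row mean instead of
#'   failing. A row with no observed value is always an error.
#' @return a numeric matrix with row and column names.
#' @seealso \code{\link{writeLabeledMatrix}}
#' @export
readLabeledMatrix <- function(path, imputeMissing = FALSE) {
  if (!file.exists(path)) .ioError("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2L)
    .formatError("%s: need a header row and at least one data row", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # trailing empty field from a line ending in \t must be kept by strsplit;
  # R drops it, so re-pad from the raw line
  nsep <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE)))
  fields <- mapply(function(f, k) c(f, rep("", k + 1L - length(f))),
                   fields, nsep, SIMPLIFY = FALSE)
  header <- fields[[1L]]
  body <- fields[-1L]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L)
    .formatError("%s: ragged rows (field counts %s)", path,
                 paste(sort(unique(widths)), collapse = ", "))
  w <- widths[1L]
  if (length(header) != w)
    .formatError("%s: header has %d fields but data rows have %d (corner field required)",
                 path, length(header), w)
  colIds <- header[-1L]
  rowIds <- vapply(body, `[`, character(1L), 1L)
  if (any(rowIds == "") || any(colIds == ""))
    .validationError("%s: empty identifiers", path)
  if (anyDuplicated(rowIds) || anyDuplicated(colIds))
    .validationError("%s: duplicated identifiers", path)
  cells <- t(vapply(body, function(f) f[-1L], character(w - 1L)))
  if (w == 2L) cells <- matrix(cells, ncol = 1L)  # vapply folds 1-col case
  miss <- cells == "" | cells == "NA"
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (any(is.na(vals) & !miss))
    .formatError("%s: non-numeric cell(s), e.g. '%s'", path,
                 cells[is.na(vals) & !miss][1L])
  if (any(miss)) {
    if (!imputeMissing)
      .validationError("%s: %d missing cell(s); set imputeMissing = TRUE to row-mean impute",
                       path, sum(miss))
    for (i in which(rowSums(miss) > 0L)) {
      obs <- vals[i, !miss[i, ]]
      if (length(obs) == 0L)
        .validationError("%s: row '%s' has no observed values to impute from",
                         path, rowIds[i])
      vals[i, miss[i, ]] <- mean(obs)
    }
  }
  dimnames(vals) <- list(rowIds, colIds)
  .checkLabeledMatrix(vals, path)
  vals
}

#' Write a labeled matrix as tab-separated text
#'
#' Emits the dialect read by \code{\link{readLabeledMatrix}} with full
#' double precision (17 significant digits), so a write/read round trip is
#' bit-exact.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeLabeledMatrix <- function(mat, path) {
  .checkLabeledMatrix(mat, "matrix")
  ids <- c(rownames(mat), colnames(mat))
  if (any(grepl("\t", ids, fixed = TRUE)))
    .validationError("identifiers must not contain tab characters")
  rows <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t"),
    character(1L))
  out <- c(paste(c("", colnames(mat)), collapse = "\t"), rows)
  status <- try(writeLines(out, path), silent = TRUE)
  if (inherits(status, "try-error"))
    .ioError("cannot write %s: %s", path, attr(status, "condition")$message)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Reads DNA sequences (e.g. upstream promoter regions) with
#' \code{Biostrings::readDNAStringSet}. The sequence identifier is the
#' first whitespace-delimited token of the header; sequences are
#' upper-cased; duplicated identifiers are an error. An empty file yields
#' an empty set.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}.
#' @export
readPromoters <- function(path) {
  if (!file.exists(path)) .ioError("file not found: %s", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) .formatError("%s: %s", path,
                                                    conditionMessage(e)))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(seqs) && (anyNA(names(seqs)) || any(names(seqs) == "")))
    .formatError("%s: record with empty identifier", path)
  if (anyDuplicated(names(seqs)))
    .validationError("%s: duplicated sequence identifiers", path)
  seqs
}

#' Read gene-to-term annotation pairs
#'
#' Reads a two-column tab-separated file of (gene, term) annotation pairs,
#' e.g. gene-to-GO-term assignments. Duplicated pairs are collapsed.
#'
#' @param path path to a two-column TSV file without a header.
#' @return a data.frame with columns \code{gene} and \code{term}.
#' @export
readAnnotationPairs <- function(path) {
  if (!file.exists(path)) .ioError("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[lines != ""]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L))
    .formatError("%s: every line must have exactly 2 tab-separated fields", path)
  gene <- vapply(fields, `[`, character(1L), 1L)
  term <- vapply(fields, `[`, character(1L), 2L)
  if (any(gene == "") || any(term == ""))
    .validationError("%s: empty identifiers", path)
  unique(data.frame(gene = gene, term = term))
}
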