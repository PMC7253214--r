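## ---------------------------------------------------------------------------
## Expression container
## ---------------------------------------------------------------------------

#' Build the expression container used throughout the pipeline
#'
#' Expression data are carried as a `SummarizedExperiment` with one assay
#' (`"exprs"`), probe annotation in `rowData()` (`probe_id`, `gene_id`,
#' `is_negative_control`) and the sample table in `colData()`. The
#' processing scale is recorded in `metadata()$scale_tag`, one of
#' `raw`, `background_corrected`, `normalized`, `log2`, `batch_adjusted`.
#'
#' @param values numeric probes x samples matrix with rownames (probe ids)
#'   and colnames (sample ids).
#' @param probeData data.frame with columns `probe_id`, `gene_id`,
#'   `is_negative_control` (missing columns are filled with defaults).
#' @param sampleData data.frame keyed by `sample_id`.
#' @param scaleTag character processing-scale tag.
#' @return a `SummarizedExperiment`.
#' @export
makeCoexExperiment <- function(values, probeData = NULL, sampleData = NULL,
                               scaleTag = "raw") {
  validateExpressionValues(values)
  if (is.null(probeData))
    probeData <- data.frame(probe_id = rownames(values),
                            gene_id = rownames(values),
                            is_negative_control = FALSE)
  if (is.null(probeData$gene_id)) probeData$gene_id <- probeData$probe_id
  if (is.null(probeData$is_negative_control))
    probeData$is_negative_control <- FALSE
  stopifnot(identical(probeData$probe_id, rownames(values)))
  if (any(probeData$is_negative_control & nzchar(probeData$gene_id)))
    stop("negative-control probes must have empty gene_id", call. = FALSE)
  if (is.null(sampleData))
    sampleData <- data.frame(sample_id = colnames(values))
  stopifnot(identical(sampleData$sample_id, colnames(values)))
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    rowData = DataFrame(probeData, row.names = rownames(values)),
    colData = DataFrame(sampleData, row.names = colnames(values)))
  metadata(se)$scale_tag <- scaleTag
  se
}

validateExpressionValues <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry probe and sample ids", call. = FALSE)
  dupP <- rownames(values)[duplicated(rownames(values))]
  if (length(dupP))
    stop("duplicated probe id(s): ", paste(unique(dupP), collapse = ", "),
         call. = FALSE)
  dupS <- colnames(values)[duplicated(colnames(values))]
  if (length(dupS))
    stop("duplicated sample id(s): ", paste(unique(dupS), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

#' Processing-scale tag of an expression container
#' @param se a `SummarizedExperiment` built by [makeCoexExperiment()].
#' @return character tag.
#' @export
scaleTag <- function(se) metadata(se)$scale_tag

## ---------------------------------------------------------------------------
## TSV expression matrices
## ---------------------------------------------------------------------------

#' Read / write probe x sample expression matrices as TSV
#'
#' The dialect is a tab-separated table whose first column holds probe ids
#' and whose header row holds sample ids. Values are written at full double
#' precision (17 significant digits) so that a write/read round trip is the
#' identity.
#'
#' @param path TSV file path.
#' @param backgroundPath optional path of a paired background-intensity
#'   matrix; it must have identical probe and sample ids.
#' @return `readExpressionTSV`: a numeric matrix with dimnames (with the
#'   background matrix in `attr(, "background")` when requested);
#'   `writeExpressionTSV`: `path`, invisibly.
#' @export
readExpressionTSV <- function(path, backgroundPath = NULL) {
  m <- .readMatrixTSV(path)
  if (!is.null(backgroundPath)) {
    b <- .readMatrixTSV(backgroundPath)
    if (!identical(dim(m), dim(b)) ||
        !identical(dimnames(m), dimnames(b)))
      stop("background matrix shape or identifiers differ from foreground",
           call. = FALSE)
    attr(m, "background") <- b
  }
  m
}

.readMatrixTSV <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression TSV needs a probe-id column plus >=1 sample column",
         call. = FALSE)
  probes <- df[[1L]]
  dup <- probes[duplicated(probes)]
  if (length(dup))
    stop("duplicated probe id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  samples <- colnames(df)[-1L]
  dupS <- samples[duplicated(samples)]
  if (length(dupS))
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(dupS), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row %d (probe %s), column %d (sample %s)",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 probes[bad[1L, 1L]], bad[1L, 2L], samples[bad[1L, 2L]]),
         call. = FALSE)
  dimnames(num) <- list(probes, samples)
  num
}

#' @rdname readExpressionTSV
#' @param values numeric matrix with probe rownames and sample colnames.
#' @param idColumn name for the probe-id column in the written header.
#' @export
writeExpressionTSV <- function(values, path, idColumn = "probe_id") {
  stopifnot(is.matrix(values))
  df <- data.frame(id = rownames(values), check.names = FALSE)
  names(df) <- idColumn
  for (j in seq_len(ncol(values))) df[[colnames(values)[j]]] <-
      .fmtNum(values[, j])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample phenotype table
#'
#' Expects a TSV with at least `sample_id`, `population`, `batch`,
#' `body_weight`, `testis_weight`, `sperm_count`; optional motility traits
#' (VCL, VAP, VSL, ALH, BCF) are kept if present. Basic sanity bounds are
#' enforced (positive body weight, non-negative testis weight / sperm count).
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
readSampleTable <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   comment.char = "#")
  need <- c("sample_id", "population", "batch", "body_weight",
            "testis_weight", "sperm_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$body_weight <= 0, na.rm = TRUE))
    stop("body_weight must be > 0", call. = FALSE)
  if (any(df$testis_weight < 0, na.rm = TRUE) ||
      any(df$sperm_count < 0, na.rm = TRUE))
    stop("testis_weight and sperm_count must be >= 0", call. = FALSE)
  df
}

## ---------------------------------------------------------------------------
## GMT gene sets
## ---------------------------------------------------------------------------

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then tab-separated gene ids.
#' Duplicate gene ids within a line are removed; a duplicated set name or a
#' line with fewer than three fields is an error.
#'
#' @param path GMT path.
#' @return `readGMT`: named list of character vectors, with the description
#'   line in `attr(, "description")`.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >=1 gene",
                   i, length(f)), call. = FALSE)
    if (f[1L] %in% names(sets))
      stop("duplicated gene-set name: '", f[1L], "'", call. = FALSE)
    sets[[f[1L]]] <- unique(f[-(1:2)])
    desc[f[1L]] <- f[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' @rdname readGMT
#' @param sets named list of character gene-id vectors.
#' @param descriptions optional named character descriptions.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## BED intervals (0-based half-open)
## ---------------------------------------------------------------------------

#' Read / write BED3+ interval files
#'
#' Coordinates are 0-based half-open throughout the package. Intervals are
#' returned as a `GRanges` (1-based internally, as GRanges requires) with the
#' original BED coordinates kept in `mcols()$bedStart` / `bedEnd`; a fourth
#' column, when present, becomes `names()`. `start >= end` is a format error
#' reporting the offending line.
#'
#' @param path BED path.
#' @return `readBED`: a `GRanges`.
#' @export
readBED <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(GRanges())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 3L))
    stop("BED line ", lineNo[which(nf < 3L)[1L]], " has fewer than 3 fields",
         call. = FALSE)
  chrom <- vapply(f, `[`, character(1L), 1L)
  s <- as.numeric(vapply(f, `[`, character(1L), 2L))
  e <- as.numeric(vapply(f, `[`, character(1L), 3L))
  if (any(is.na(s)) || any(is.na(e)))
    stop("non-numeric BED coordinate at line ",
         lineNo[which(is.na(s) | is.na(e))[1L]], call. = FALSE)
  bad <- which(s >= e)
  if (length(bad))
    stop(sprintf("BED line %d: start (%d) must be < end (%d)",
                 lineNo[bad[1L]], as.integer(s[bad[1L]]),
                 as.integer(e[bad[1L]])), call. = FALSE)
  gr <- GRanges(chrom, IRanges(as.integer(s) + 1L, as.integer(e)))
  gr$bedStart <- as.integer(s)
  gr$bedEnd <- as.integer(e)
  if (all(nf >= 4L)) names(gr) <- vapply(f, `[`, character(1L), 4L)
  gr
}

#' @rdname readBED
#' @param gr a `GRanges` (names, if set, are written as the 4th column).
#' @export
writeBED <- function(gr, path) {
  s <- if (!is.null(gr$bedStart)) gr$bedStart else start(gr) - 1L
  e <- if (!is.null(gr$bedEnd)) gr$bedEnd else end(gr)
  cols <- list(as.character(seqnames(gr)), s, e)
  if (!is.null(names(gr)) && all(nzchar(names(gr))))
    cols <- c(cols, list(names(gr)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}
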