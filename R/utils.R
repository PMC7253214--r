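#' @import methods
#' @importFrom stats cor median quantile sd mad var rnorm runif prcomp
#'   p.adjust phyper pnorm pt setNames as.dist hclust cutree ks.test dhyper
#' @importFrom utils read.delim write.table head modifyList
NULL

.timestamp <- function() format(Sys.time(), "%Y-%m-%d %H:%M:%S")

#' Log a pipeline message to standard error
#'
#' All pipeline stages log through this helper so that runs can be followed
#' (and redirected) uniformly. Messages go to stderr with a timestamp.
#'
#' @param ... character fragments pasted together.
#' @param verbose logical; if `FALSE` nothing is emitted.
#' @return invisibly, the formatted message.
#' @keywords internal
coexLog <- function(..., verbose = TRUE) {
  msg <- paste0("[", .timestamp(), "] ", paste0(..., collapse = ""))
  if (isTRUE(verbose)) message(msg)
  invisible(msg)
}

#' Derive a deterministic per-stage seed from a root seed
#'
#' Every randomized stage seeds its own RNG with a value derived from the
#' single root seed and the stage name, so stages can be re-run in isolation
#' and still reproduce a full pipeline run. The derived seed is kept inside
#' the 32-bit integer range.
#'
#' @param rootSeed integer root seed for the whole run.
#' @param stage character stage name (e.g. `"network"`).
#' @return a single integer seed.
#' @export
#' @examples
#' stageSeed(1L, "network")
stageSeed <- function(rootSeed, stage) {
  stopifnot(is.numeric(rootSeed), length(rootSeed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(rootSeed)) * 1000003 + h) %% 2147483629 + 1)
}

## run code with a locally-set RNG state, restoring the caller's state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' = %s is outside [%s, %s]", name, format(x),
                 format(lower), format(upper)), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(TRUE)
}

## lower-triangle (i < j) values of a square matrix
.lowerTri <- function(m) m[lower.tri(m)]

## Pearson correlation that tolerates zero-variance columns (returns 0 there)
.safeCor <- function(x, y = NULL) {
  suppressWarnings(r <- cor(x, y))
  r[!is.finite(r)] <- 0
  r
}

## format numbers for TSV output at full double precision
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
  out
}

## write a data.frame as TSV with a '#'-prefixed provenance header
writeResultTSV <- function(df, path, headerLines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in headerLines) writeLines(paste0("# ", h), con)
  num <- vapply(df, is.double, logical(1L))
  out <- df
  for (j in which(num)) out[[j]] <- .fmtNum(df[[j]])
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
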