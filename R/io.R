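# Readers and writers for the interchange formats: BED-like interval
# tables and commented TSV. All genomic coordinates are 0-based half-open.

#' Read a BED-like interval table
#'
#' Expects at least `chrom`, `start`, `end` as the first three columns,
#' tab-separated, 0-based half-open. Lines starting with `#` are metadata
#' and skipped. Extra columns are preserved and named from
#' `extra_names` where provided.
#'
#' @param path File path.
#' @param extra_names Optional names for columns beyond the first three.
#' @return Data frame with `chrom` (character), `start`, `end` (integer)
#'   plus any extra columns.
#' @export
read_bed <- function(path, extra_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  if (length(lineno) == 0) stop("no interval records in ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3))
    stop("malformed BED line ", lineno[which(ncols < 3)[1]], " in ", path,
         ": fewer than 3 fields")
  ncol_use <- max(ncols)
  m <- t(vapply(parts, function(p) c(p, rep(NA_character_, ncol_use - length(p))),
                character(ncol_use)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end <= start)
  if (length(bad) > 0)
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         ": need 0 <= start < end")
  df <- data.frame(chrom = m[, 1], start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (ncol_use > 3) {
    extra <- as.data.frame(m[, -(1:3), drop = FALSE], stringsAsFactors = FALSE)
    # numeric conversion where it round-trips cleanly
    extra[] <- lapply(extra, function(v) {
      nv <- suppressWarnings(as.numeric(v))
      if (all(is.na(v) | !is.na(nv))) nv else v
    })
    names(extra) <- if (!is.null(extra_names))
      extra_names[seq_len(ncol(extra))] else paste0("V", 3 + seq_len(ncol(extra)))
    df <- cbind(df, extra)
  }
  df
}

#' Write a BED-like interval table
#'
#' @param df Data frame whose first three columns are `chrom`, `start`,
#'   `end`; extra columns are appended.
#' @param path Output path.
#' @param metadata Optional named character vector written as `#key=value`
#'   header lines (a `cfcin_version` stamp is always included).
#' @export
write_bed <- function(df, path, metadata = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)[1:3]))
  hdr <- c(cfcin_version = as.character(utils::packageVersion("cfcin")), metadata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", names(hdr), "=", hdr), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a TSV with commented metadata header
#'
#' @inheritParams write_bed
#' @export
write_tsv <- function(df, path, metadata = NULL) {
  hdr <- c(cfcin_version = as.character(utils::packageVersion("cfcin")), metadata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", names(hdr), "=", hdr), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' Skips `#` metadata lines; first remaining line is the header.
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
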