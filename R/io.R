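# Plain-text I/O: SMILES record files and key=value sidecars.

#' Read a SMILES record file
#'
#' One record per line: `<id>TAB<smiles>[TAB<extra>]`, where the optional
#' third column is a binding energy or a provenance tag.  Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @return data.frame with columns `id`, `smiles`, `extra` (NA when absent).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    return(data.frame(id = character(0), smiles = character(0),
                      extra = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) {
    stop("malformed SMILES record at line ", bad[1], " of ", path, call. = FALSE)
  }
  data.frame(
    id = vapply(parts, `[`, character(1), 1L),
    smiles = vapply(parts, `[`, character(1), 2L),
    extra = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                   character(1)),
    stringsAsFactors = FALSE)
}

#' Write a SMILES record file
#'
#' @param df data.frame with columns `id`, `smiles` and optionally more;
#'   extra columns are appended tab-separated.
#' @param path Output path.
#' @param comment Optional `#` header line content.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(df, path, comment = NULL) {
  stopifnot(all(c("id", "smiles") %in% names(df)))
  body <- apply(df, 1L, function(r) paste(r[!is.na(r)], collapse = "\t"))
  writeLines(c(if (!is.null(comment)) paste0("# ", comment), body), path)
  invisible(path)
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- trimws(p[2])
    suppressWarnings(n <- as.numeric(v))
    if (is.na(n)) v else n
  })
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}
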