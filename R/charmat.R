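# Binary morphological character matrices (taxa x characters), TSV and
# NEXUS characters-block I/O. States 0/1 (absence/presence), '?' missing.
# Character classes (megasclere/microsclere) ride in the TSV header as
# "name:class" and in attr(m, "classes").

#' Read a morphological character matrix
#'
#' TSV format: first column `taxon`, then one column per character with
#' values `0`, `1` or `?`. A column header of the form `name:class` assigns
#' the character class (e.g. `sterraster:microsclere`); a bare `name` gets
#' class `"unknown"`. NEXUS input uses \pkg{ape}'s characters/data block
#' reader (classes all `"unknown"`).
#'
#' @param path input file.
#' @param format `"tsv"` or `"nexus"`.
#' @return an integer matrix (taxa x characters, `NA` for missing) with
#'   character names as colnames and a `classes` attribute.
#' @export
read_character_matrix <- function(path, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    if (names(df)[1L] != "taxon") stop("first TSV column must be 'taxon'")
    taxa <- df[[1L]]
    raw <- as.matrix(df[-1L])
    hdr <- colnames(raw)
    has_class <- grepl(":", hdr, fixed = TRUE)
    cls <- ifelse(has_class, sub("^[^:]*:", "", hdr), "unknown")
    nm <- sub(":.*$", "", hdr)
  } else {
    lst <- ape::read.nexus.data(path)
    taxa <- names(lst)
    raw <- do.call(rbind, lst)
    nm <- paste0("char", seq_len(ncol(raw)))
    cls <- rep("unknown", ncol(raw))
  }
  if (any(duplicated(taxa))) stop("duplicate taxa in character matrix")
  raw[raw %in% c("?", "-", "")] <- NA
  bad <- setdiff(unique(raw[!is.na(raw)]), c("0", "1"))
  if (length(bad))
    stop("non-binary state(s) in character matrix: ",
         paste(bad, collapse = " "))
  m <- matrix(as.integer(raw), nrow = length(taxa),
              dimnames = list(taxa, nm))
  attr(m, "classes") <- stats::setNames(cls, nm)
  m
}

#' Write a morphological character matrix as TSV
#'
#' @param m integer matrix as from [read_character_matrix()]; a `classes`
#'   attribute, when present, is encoded into the header as `name:class`.
#' @param file output path.
#' @export
write_character_matrix <- function(m, file) {
  cls <- attr(m, "classes")
  hdr <- colnames(m)
  if (!is.null(cls)) hdr <- paste(hdr, cls[colnames(m)], sep = ":")
  body <- m
  mode(body) <- "character"
  body[is.na(body)] <- "?"
  df <- data.frame(taxon = rownames(m), body, check.names = FALSE)
  names(df) <- c("taxon", hdr)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' One character column from a matrix
#'
#' @param m character matrix.
#' @param character column name or index.
#' @return a named integer vector over the taxa.
#' @export
character_column <- function(m, character) {
  stats::setNames(m[, character], rownames(m))
}
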