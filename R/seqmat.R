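# Aligned nucleotide matrices: I/O, site classification, concatenation, K2P.
#
# An alignment is a plain character matrix, taxa in rows (unique rownames),
# sites in columns, symbols in {A,C,G,T, IUPAC ambiguity, '-', '?'}; the
# partition name travels in attr(m, "partition").

IUPAC_SYMBOLS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-", "?")

.as_aln <- function(seqs, name = NULL, source = "alignment") {
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    stop("ragged alignment in ", source, ": taxon '", bad, "' has length ",
         lens[names(seqs) == bad][1L], ", expected ", lens[1L])
  }
  m <- do.call(rbind, lapply(seqs, toupper))
  rownames(m) <- names(seqs)
  if (any(duplicated(rownames(m))))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  bad <- setdiff(unique(as.vector(m)), IUPAC_SYMBOLS)
  if (length(bad))
    stop("unknown symbol(s) in ", source, ": ", paste(bad, collapse = " "))
  if (ncol(m) < 1L) stop("alignment has width 0")
  attr(m, "partition") <- name
  m
}

#' Read an aligned nucleotide matrix
#'
#' Reads a FASTA file or the data/characters block of a NEXUS file into a
#' character matrix (taxa x sites). Sequences must be equal length; lowercase
#' is normalised to uppercase; symbols outside the IUPAC nucleotide alphabet
#' (plus `-` and `?`) are rejected.
#'
#' @param path input file.
#' @param format `"fasta"` or `"nexus"`.
#' @param name optional partition name stored in `attr(, "partition")`.
#' @return a character matrix with taxon rownames.
#' @export
read_alignment <- function(path, format = c("fasta", "nexus"), name = NULL) {
  format <- match.arg(format)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  seqs <- switch(format,
    fasta = {
      x <- ape::read.FASTA(path)
      lapply(as.character(x), function(s) unname(s))
    },
    nexus = ape::read.nexus.data(path))
  .as_aln(seqs, name = name, source = path)
}

#' Write an alignment to FASTA or a NEXUS data block
#'
#' @param m alignment matrix as returned by [read_alignment()].
#' @param file output path.
#' @param format `"fasta"` or `"nexus"` (non-interleaved data block).
#' @export
write_alignment <- function(m, file, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  taxa <- rownames(m)
  seqs <- apply(m, 1L, paste, collapse = "")
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", taxa), seqs)), file)
  } else {
    pad <- formatC(gsub(" ", "_", taxa), width = max(nchar(taxa)) + 2L,
                   flag = "-")
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
                 "  FORMAT DATATYPE=DNA MISSING=? GAP=-;", "  MATRIX",
                 paste0("    ", pad, seqs), "  ;", "END;"), file)
  }
  invisible(file)
}

#' Classify alignment sites by parsimony informativeness
#'
#' A site is parsimony-informative when at least two distinct unambiguous
#' nucleotides each occur in at least two taxa; constant when at most one
#' distinct unambiguous nucleotide occurs; otherwise variable-uninformative.
#' Gaps, `?` and IUPAC ambiguity codes are treated as missing data, following
#' the usual PAUP*-style convention for these counts.
#'
#' @param m alignment matrix.
#' @return an object of class `site_classification`: list with `labels`
#'   (factor, one per site), `counts` (named totals) and `width`.
#' @export
classify_sites <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 taxa")
  lv <- c("constant", "variable-uninformative", "parsimony-informative")
  lab <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (length(tab) <= 1L) lab[j] <- lv[1L]
    else if (sum(tab >= 2L) >= 2L) lab[j] <- lv[3L]
    else lab[j] <- lv[2L]
  }
  labels <- factor(lab, levels = lv)
  out <- list(labels = labels, counts = table(labels), width = ncol(m))
  class(out) <- "site_classification"
  out
}

#' @export
print.site_classification <- function(x, ...) {
  cat("Site classification over", x$width, "sites:\n")
  print(x$counts)
  invisible(x)
}

#' Export a site classification as TSV
#'
#' @param x a `site_classification`.
#' @param file output path.
#' @export
write_site_classification <- function(x, file) {
  df <- data.frame(site = seq_len(x$width), class = as.character(x$labels))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Concatenate alignment partitions into a supermatrix
#'
#' Builds one matrix whose rows are species and whose width is the sum of the
#' partition widths. `key` maps specimen labels to species labels, so markers
#' sequenced from different specimens of the same species are merged onto one
#' row; labels absent from `key` map to themselves. A species missing from a
#' partition is filled with `missing_symbol` across that partition's span.
#' Partition boundaries are recorded in `attr(, "partitions")`.
#'
#' @param partitions a list of alignment matrices (named, or partition names
#'   are taken from their `partition` attributes).
#' @param key named character vector, specimen label -> species label.
#' @param missing_symbol fill symbol for absent species (default `"?"`).
#' @return the concatenated matrix, with a `partitions` attribute
#'   (data.frame: name, start, end).
#' @export
concatenate_partitions <- function(partitions, key = NULL,
                                   missing_symbol = "?") {
  stopifnot(length(partitions) >= 1L)
  pnames <- names(partitions)
  if (is.null(pnames))
    pnames <- vapply(seq_along(partitions), function(i) {
      p <- attr(partitions[[i]], "partition")
      if (is.null(p)) paste0("partition", i) else p
    }, character(1))
  map <- function(labs) {
    out <- labs
    hit <- labs %in% names(key)
    out[hit] <- unname(key[labs[hit]])
    out
  }
  species_by_part <- lapply(partitions, function(p) map(rownames(p)))
  for (i in seq_along(partitions)) {
    sp <- species_by_part[[i]]
    if (any(duplicated(sp)))
      stop("partition '", pnames[i], "': several specimens map to species ",
           paste(unique(sp[duplicated(sp)]), collapse = ", "),
           "; pre-select one specimen per species")
  }
  species <- unique(unlist(species_by_part))
  widths <- vapply(partitions, ncol, integer(1))
  out <- matrix(missing_symbol, nrow = length(species), ncol = sum(widths),
                dimnames = list(species, NULL))
  at <- 0L
  for (i in seq_along(partitions)) {
    idx <- at + seq_len(widths[i])
    out[species_by_part[[i]], idx] <- partitions[[i]]
    at <- at + widths[i]
  }
  ends <- cumsum(widths)
  attr(out, "partitions") <- data.frame(name = pnames,
                                        start = ends - widths + 1L,
                                        end = ends)
  attr(out, "partition") <- "concatenated"
  out
}

#' Write partition boundaries as a NEXUS sets block
#'
#' @param m a concatenated matrix from [concatenate_partitions()].
#' @param file output path.
#' @export
write_partition_sets <- function(m, file) {
  parts <- attr(m, "partitions")
  if (is.null(parts)) stop("matrix has no 'partitions' attribute")
  writeLines(c("#NEXUS", "BEGIN SETS;",
               sprintf("  CHARSET %s = %d-%d;", parts$name, parts$start,
                       parts$end),
               "END;"), file)
  invisible(file)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either symbol is not an unambiguous nucleotide are removed
#' first (pairwise deletion). With `P` the proportion of transitions and `Q`
#' the proportion of transversions over the retained sites,
#' `d = -log(1 - 2P - Q)/2 - log(1 - 2Q)/4`, in expected substitutions per
#' site.
#'
#' @param s1,s2 character vectors (or single strings) of equal length.
#' @return the K2P distance.
#' @export
k2p_distance <- function(s1, s2) {
  expand <- function(s) {
    if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "")[[1L]]
    toupper(s)
  }
  s1 <- expand(s1); s2 <- expand(s2)
  if (length(s1) != length(s2))
    stop("sequences have different lengths (", length(s1), " vs ",
         length(s2), ")")
  ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
  s1 <- s1[ok]; s2 <- s2[ok]
  n <- length(s1)
  if (n == 0L) stop("no sites retained after pairwise deletion")
  purine <- function(x) x %in% c("A", "G")
  diffs <- s1 != s2
  ts <- diffs & (purine(s1) == purine(s2))
  P <- sum(ts) / n
  Q <- sum(diffs & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturation): 1-2P-Q = ", signif(w1, 6),
         ", 1-2Q = ", signif(w2, 6))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix
#'
#' @param m alignment matrix.
#' @return a symmetric numeric matrix of K2P distances (pairwise deletion).
#' @export
k2p_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- k2p_distance(m[i, ], m[j, ])
  d
}

#' Mean between-group K2P distance
#'
#' The arithmetic mean of all cross-group pairwise K2P distances, the
#' convention used here for a single between-group divergence (e.g. between
#' two geographic haplotype groups of one species).
#'
#' @param m alignment matrix.
#' @param groups named vector (names = taxa) with exactly two group labels.
#' @return the mean cross-group K2P distance.
#' @export
between_group_k2p <- function(m, groups) {
  groups <- groups[rownames(m)]
  g <- unique(groups)
  if (length(g) != 2L) stop("need exactly two groups, found ", length(g))
  a <- which(groups == g[1L]); b <- which(groups == g[2L])
  d <- outer(a, b, Vectorize(function(i, j) k2p_distance(m[i, ], m[j, ])))
  mean(d)
}
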