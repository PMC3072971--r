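#' @importFrom ape read.tree write.tree keep.tip unroot Ntip
#' @importFrom stats optimize setNames
#' @importFrom utils read.delim write.table
NULL

#' Read a phylogeny from newick
#'
#' Parses a single newick tree from a file or a string and validates it as a
#' phylogeny usable by the reconstruction machinery: unique non-empty tip
#' labels, finite non-negative branch lengths. Missing branch lengths are set
#' to 0 with a warning. Lines starting with `#` are treated as comments and
#' ignored. Internal node labels, if present, are kept as support annotations
#' (never treated as taxon names).
#'
#' @param file path to a newick file (one tree), or `NULL` when `text` given.
#' @param text a newick string, used instead of `file`.
#' @return an object of class `phylo` (see \pkg{ape}), rooted as written.
#' @seealso [write_newick()], [prune_to_taxa()]
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either 'file' or 'text' must be given")
    lines <- readLines(file, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines)]
    text <- paste(lines, collapse = "")
  }
  .check_newick_tokens(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("newick parse error: no tree could be read")
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected exactly one tree, found ", length(tree))
    tree <- tree[[1L]]
  }
  validate_phylo(tree)
}

# Pre-check bracket balance so malformed input fails with a position,
# which ape's parser does not report.
.check_newick_tokens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unmatched ')' at position ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("newick parse error: missing terminating ';'", call. = FALSE)
  invisible(TRUE)
}

#' Validate a phylogeny
#'
#' Enforces the invariants assumed throughout the package: tip labels unique
#' and non-empty, branch lengths finite and non-negative. Trees without any
#' branch lengths get all lengths 0, with a warning; individual `NA` lengths
#' are likewise zeroed with a warning.
#'
#' @param tree a `phylo` object.
#' @return the validated (possibly repaired) `phylo` object, invisibly usable.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tl <- tree$tip.label
  if (any(!nzchar(tl))) stop("empty tip label(s) found")
  dup <- unique(tl[duplicated(tl)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning(sum(is.na(tree$edge.length)),
            " missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length)))
    stop("non-finite branch length(s)")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s)")
  tree
}

#' Write a phylogeny to newick
#'
#' @param tree a `phylo` object.
#' @param file optional output path; when `NULL` the newick string is returned.
#' @param digits number of significant digits for branch lengths.
#' @return the newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Non-trivial bipartitions of a tree
#'
#' Computes the set of splits of the tip-label set induced by the internal
#' edges of the unrooted version of the tree. Trivial splits (one tip versus
#' the rest) are excluded, and each split is put in a canonical,
#' orientation-independent form: the block not containing the alphabetically
#' first tip label, sorted, joined with `"|"`. Trees with fewer than 4 tips
#' have no non-trivial splits.
#'
#' @param tree a `phylo` object.
#' @return a character vector of canonical split keys (possibly empty).
#' @export
tree_bipartitions <- function(tree) {
  tree <- validate_phylo(tree)
  n <- ape::Ntip(tree)
  if (n < 4L) return(character(0))
  utree <- ape::unroot(tree)
  ntipu <- ape::Ntip(utree)
  labels <- utree$tip.label
  anchor <- min(labels)
  edge <- utree$edge
  root <- ntipu + 1L
  internal_children <- unique(edge[edge[, 2L] > ntipu, 2L])
  # tips below each node, built bottom-up over a postorder edge ordering
  po <- ape::reorder.phylo(utree, "postorder")$edge
  below <- vector("list", ntipu + utree$Nnode)
  for (i in seq_len(ntipu)) below[[i]] <- labels[i]
  for (e in seq_len(nrow(po)))
    below[[po[e, 1L]]] <- c(below[[po[e, 1L]]], below[[po[e, 2L]]])
  keys <- character(0)
  for (v in internal_children) {
    blk <- below[[v]]
    if (length(blk) <= 1L || length(blk) >= ntipu - 1L) next
    if (anchor %in% blk) blk <- setdiff(labels, blk)
    keys <- c(keys, paste(sort(blk), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference distance of Robinson and Foulds: the number of
#' non-trivial bipartitions found in one tree but not the other, computed on
#' the unrooted topologies. Zero exactly when the two unrooted topologies
#' agree; at most `2(n-3)` for binary trees with `n` tips.
#'
#' @param t1,t2 `phylo` objects over the same tip-label set.
#' @return a non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("tip sets differ; only in first: [",
         paste(only1, collapse = ", "), "]; only in second: [",
         paste(only2, collapse = ", "), "]")
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Prune a tree to a subset of taxa
#'
#' Returns the subtree induced by `keep`: other tips are removed and the
#' resulting degree-2 internal nodes are suppressed, with branch lengths
#' summed, so path lengths between retained tips are preserved.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  tree <- validate_phylo(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, keep)
}
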