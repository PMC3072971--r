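# End-to-end orchestration: reconstruct all characters, build the homoplasy
# report, and summarise alignment partitions. These functions are the
# programmatic interface; inst/cli/spicule-pipeline.R is a thin shell
# wrapper over them.

.log_msg <- function(..., logfile = NULL) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

.check_taxa <- function(tree, m) {
  extra_tree <- setdiff(tree$tip.label, rownames(m))
  extra_mat <- setdiff(rownames(m), tree$tip.label)
  if (length(extra_tree) || length(extra_mat))
    stop("tree and character matrix taxa differ; only in tree: [",
         paste(extra_tree, collapse = ", "), "]; only in matrix: [",
         paste(extra_mat, collapse = ", "), "]")
  invisible(TRUE)
}

#' Reconstruct every character of a matrix on a tree
#'
#' Fits a per-character Mk rate and computes marginal ancestral-state
#' posteriors for each column of the character matrix. Tree and matrix must
#' cover the same taxa; use [prune_to_taxa()] first to reduce the tree.
#' When `out_dir` is given, one reconstruction table per character plus a
#' rates summary are written as TSV, and a run log records the seedless,
#' deterministic configuration.
#'
#' @param tree a `phylo` object, or a path to a newick file.
#' @param characters a character matrix (see [read_character_matrix()]) or a
#'   path to its TSV.
#' @param out_dir optional output directory.
#' @param rate optional fixed Mk rate; default `NULL` fits one rate per
#'   character by maximum likelihood. A fixed small rate is appropriate when
#'   characters are known to change rarely (e.g. scoring planted loss
#'   scenarios at their generating rarity scale).
#' @return a named list of `mk_asr` objects (invisibly when writing).
#' @export
run_asr <- function(tree, characters, out_dir = NULL, rate = NULL) {
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(characters))
    characters <- read_character_matrix(characters)
  tree <- validate_phylo(tree)
  .check_taxa(tree, characters)
  logfile <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    logfile <- file.path(out_dir, "run.log")
    .log_msg("run_asr: ", ncol(characters), " characters, ",
             ape::Ntip(tree), " tips; spiculevol ",
             as.character(utils::packageVersion("spiculevol")), " on ",
             R.version.string, logfile = logfile)
  }
  recons <- list()
  for (ch in colnames(characters)) {
    recons[[ch]] <- if (is.null(rate))
      reconstruct_character(tree, character_column(characters, ch))
    else marginal_asr(tree, character_column(characters, ch),
                      mk_model(2L, rate))
    if (!is.null(out_dir)) {
      df <- data.frame(node = seq_len(nrow(recons[[ch]]$prob)),
                       label = rownames(recons[[ch]]$prob),
                       recons[[ch]]$prob,
                       rate = recons[[ch]]$model$rate,
                       loglik = recons[[ch]]$loglik)
      utils::write.table(df, file.path(out_dir, paste0("asr_", ch, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    rates <- data.frame(
      character = names(recons),
      rate = vapply(recons, function(r) r$model$rate, numeric(1)),
      loglik = vapply(recons, function(r) r$loglik, numeric(1)),
      constant = vapply(recons, function(r) isTRUE(r$constant), logical(1)))
    utils::write.table(rates, file.path(out_dir, "rates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .log_msg("run_asr: wrote ", length(recons), " reconstruction tables",
             logfile = logfile)
    return(invisible(recons))
  }
  recons
}

#' Run the full homoplasy report
#'
#' Reconstructs all characters ([run_asr()]), calls two-tier confidence
#' states, counts loss/gain events, stratifies them by depth habit, and
#' writes the report tables.
#'
#' @inheritParams run_asr
#' @param meta depth metadata (data.frame or path to TSV with columns
#'   `taxon`, `habit`).
#' @param moderate,high calling thresholds (defaults 0.65 and 0.95).
#' @param rate optional fixed Mk rate passed to [run_asr()].
#' @return a `homoplasy_report` (invisibly when writing).
#' @export
run_report <- function(tree, characters, meta, out_dir = NULL,
                       moderate = 0.65, high = 0.95, rate = NULL) {
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(characters))
    characters <- read_character_matrix(characters)
  if (is.character(meta)) meta <- utils::read.delim(meta)
  classes <- attr(characters, "classes")
  recons <- run_asr(tree, characters, out_dir = out_dir, rate = rate)
  rep <- homoplasy_report(recons, tree, meta = meta, classes = classes,
                          moderate = moderate, high = high)
  if (!is.null(out_dir)) {
    write_homoplasy_report(rep, out_dir, tree)
    .log_msg("run_report: ", nrow(rep$events), " event edges over ",
             nrow(rep$table), " characters",
             logfile = file.path(out_dir, "run.log"))
    return(invisible(rep))
  }
  rep
}

#' Site statistics and concatenation summary for alignment partitions
#'
#' Classifies the sites of each partition (constant /
#' variable-uninformative / parsimony-informative), concatenates the
#' partitions into a supermatrix (merging specimens onto species via `key`),
#' and classifies the concatenation.
#'
#' @param alignments named list of alignment matrices, or a named character
#'   vector of FASTA paths.
#' @param key optional specimen-to-species merge map (named character
#'   vector).
#' @param out_dir optional output directory for TSV summaries.
#' @return a list: `per_partition` (site classifications), `concatenated`
#'   (matrix), `concat_classification`, `summary` (data.frame).
#' @export
run_sitestats <- function(alignments, key = NULL, out_dir = NULL) {
  if (is.character(alignments)) {
    paths <- alignments
    alignments <- lapply(paths, read_alignment)
    if (!is.null(names(paths))) names(alignments) <- names(paths)
  }
  per <- lapply(alignments, classify_sites)
  concat <- concatenate_partitions(alignments, key = key)
  cc <- classify_sites(concat)
  counts <- function(x) as.integer(x$counts)
  summary <- data.frame(
    partition = c(names(per), "concatenated"),
    width = c(vapply(per, function(x) x$width, integer(1)), cc$width),
    n_taxa = c(vapply(alignments, nrow, integer(1)), nrow(concat)),
    do.call(rbind, c(lapply(per, counts), list(counts(cc)))))
  names(summary)[4:6] <- c("constant", "variable_uninformative",
                           "parsimony_informative")
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary, file.path(out_dir, "site_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_partition_sets(concat, file.path(out_dir, "charsets.nex"))
  }
  list(per_partition = per, concatenated = concat,
       concat_classification = cc, summary = summary)
}
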