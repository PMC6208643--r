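#' Read and write the package's plain-text interchange formats
#'
#' Trees travel as Newick (via ape); trait tables, community tables and
#' distance matrices as tab-separated text. All round trips are loss-free up
#' to numeric printing precision.
#'
#' @param tree A phylo object.
#' @param file Path to read from or write to.
#' @name phylosym-io
NULL

#' @rdname phylosym-io
#' @export
write_tree_newick <- function(tree, file) {
  check_phylo(tree)
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' @rdname phylosym-io
#' @export
read_tree_newick <- function(file) {
  ape::read.tree(file)
}

#' @rdname phylosym-io
#' @param traits Tips x traits numeric matrix with rownames.
#' @export
write_traits <- function(traits, file) {
  df <- data.frame(label = rownames(traits), as.data.frame(traits),
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname phylosym-io
#' @export
read_traits <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname phylosym-io
#' @param table Hosts x microbes integer abundance matrix with dimnames.
#' @export
write_community <- function(table, file) {
  df <- data.frame(host = rownames(table), as.data.frame(table),
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname phylosym-io
#' @export
read_community <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname phylosym-io
#' @param d Symmetric distance matrix with dimnames.
#' @export
write_distance <- function(d, file) {
  d <- as.matrix(d)
  df <- data.frame(label = rownames(d), as.data.frame(d),
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname phylosym-io
#' @export
read_distance <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
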