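# Plain-text I/O: FASTA sequences/alignments and Newick trees carrying
# bootstrap supports as internal node labels and a `#1` token marking
# foreground branches.

#' Read a FASTA file of in-frame sequences as a codon alignment
#'
#' @param path FASTA file of equal-length, in-frame nucleotide sequences.
#' @param allow_stops Tolerate in-frame stop codons (pseudogene data).
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, allow_stops = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  v <- stats::setNames(as.character(seqs), names(seqs))
  codon_alignment(.as_codon_matrix(v), allow_stops = allow_stops)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences, or a [codon_alignment()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "codon_alignment"))
    seqs <- apply(seqs$codons, 1L, paste, collapse = "")
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Newick tree with supports and foreground marks
#'
#' Internal node labels are read as bootstrap supports (percent); a `#1`
#' token appended to any tip or internal node label marks the branch leading
#' to that node as foreground for the branch-site analysis.
#'
#' @param path File containing one Newick tree (or the Newick text itself
#'   via `text`).
#' @param text Newick string, as in [ape::read.tree()].
#' @return An [ape::phylo] with numeric-string `node.label` supports and an
#'   extra element `foreground`: a logical vector over edge rows.
#' @export
read_labeled_tree <- function(path = NULL, text = NULL) {
  tree <- ape::read.tree(file = path, text = text)
  ntip <- length(tree$tip.label)
  marked <- logical(ntip + tree$Nnode)
  strip <- function(labels, offset) {
    has <- grepl("#1$", labels)
    marked[offset + which(has)] <<- TRUE
    sub("#1$", "", labels)
  }
  tree$tip.label <- strip(tree$tip.label, 0L)
  if (!is.null(tree$node.label))
    tree$node.label <- strip(tree$node.label, ntip)
  tree$foreground <- marked[tree$edge[, 2]]
  tree
}

#' Write a Newick tree with supports and foreground marks
#'
#' @param tree An [ape::phylo]; `tree$foreground` (logical over edge rows)
#'   or `foreground` marks branches with the `#1` token.
#' @param path Output file; when `NULL` the Newick string is returned.
#' @param foreground Optional logical vector over edge rows overriding
#'   `tree$foreground`.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_labeled_tree <- function(tree, path = NULL, foreground = NULL) {
  fg <- foreground %||% tree$foreground
  out <- tree
  out$foreground <- NULL
  if (!is.null(fg) && any(fg)) {
    ntip <- length(tree$tip.label)
    marked_nodes <- tree$edge[fg, 2]
    tips <- marked_nodes[marked_nodes <= ntip]
    ints <- marked_nodes[marked_nodes > ntip]
    if (length(tips))
      out$tip.label[tips] <- paste0(out$tip.label[tips], "#1")
    if (length(ints)) {
      if (is.null(out$node.label)) out$node.label <- rep("", tree$Nnode)
      out$node.label[ints - ntip] <- paste0(out$node.label[ints - ntip], "#1")
    }
  }
  nwk <- ape::write.tree(out)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Human-readable branch identifiers
#'
#' Names each edge of a tree by its child node: the tip label for terminal
#' branches, the node label (or `node<k>`) for internal ones.
#'
#' @param tree An [ape::phylo].
#' @return Character vector, one id per edge row.
#' @export
branch_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  ids <- character(length(child))
  tipc <- child <= ntip
  ids[tipc] <- tree$tip.label[child[tipc]]
  lab <- tree$node.label
  for (i in which(!tipc)) {
    k <- child[i] - ntip
    ids[i] <- if (!is.null(lab) && !is.na(lab[k]) && nzchar(lab[k]))
      lab[k] else paste0("node", child[i])
  }
  ids
}

`%||%` <- function(a, b) if (is.null(a)) b else a
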