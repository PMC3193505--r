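# Codon alignment container and sanitation: back-translation of protein
# alignments onto codons, gap-fraction column trimming with an auditable
# mask, and collapsing of weakly supported tree branches.

#' Construct a codon alignment
#'
#' A codon alignment stores, per taxon, a row of 3-letter codon cells
#' (`"---"` for gaps) together with a `source_map` giving, for every
#' alignment column, the 1-based codon index in that taxon's original CDS
#' (NA at gaps).
#'
#' @param codons Character matrix (taxa x codon columns) of codon cells.
#' @param source_map Optional integer matrix of the same shape mapping
#'   alignment columns to source-CDS codon indices; computed from the gap
#'   pattern when missing.
#' @param allow_stops Keep rows containing in-frame stop codons (needed for
#'   pseudogene fixtures). By default in-frame stops are an error.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(codons, source_map = NULL, allow_stops = FALSE) {
  .build_code_tables()
  if (!is.matrix(codons) || !is.character(codons))
    stop("codons must be a character matrix", call. = FALSE)
  if (is.null(rownames(codons)))
    stop("codons must have taxa as rownames", call. = FALSE)
  bad <- !(codons == "---" | nchar(codons) == 3L)
  if (any(bad)) stop("every cell must be a codon triplet or '---'", call. = FALSE)
  stops <- matrix(codons %in% .stop_codons(), nrow(codons))
  if (any(stops) && !allow_stops) {
    w <- which(stops, arr.ind = TRUE)[1, ]
    stop("in-frame stop codon in taxon '", rownames(codons)[w[1]],
         "' at codon column ", w[2],
         " (use allow_stops = TRUE for pseudogene data)", call. = FALSE)
  }
  if (is.null(source_map)) {
    source_map <- t(apply(codons != "---", 1L, function(g) {
      idx <- rep(NA_integer_, length(g)); idx[g] <- seq_len(sum(g)); idx
    }))
    dimnames(source_map) <- dimnames(codons)
  }
  structure(list(taxa = rownames(codons), codons = codons,
                 source_map = source_map),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$taxa), " taxa x ", ncol(x$codons),
      " codon columns\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.codon_alignment <- function(x, ...) x$codons

# Accept a codon_alignment, a codon character matrix, or a named character
# vector of equal-length in-frame nucleotide strings.
.as_codon_matrix <- function(x) {
  if (inherits(x, "codon_alignment")) return(x$codons)
  if (is.matrix(x) && is.character(x)) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    lens <- unique(nchar(x))
    if (length(lens) != 1L) stop("sequences must have equal length", call. = FALSE)
    return(do.call(rbind, lapply(x, function(s) {
      cs <- .split_codons(toupper(s))
      cs[cs == "---"] <- "---"
      cs
    })))
  }
  stop("cannot interpret input as a codon alignment", call. = FALSE)
}

#' Back-translate a protein alignment onto codons
#'
#' Maps an aligned set of amino-acid sequences back onto the codons of the
#' unaligned coding sequences they were translated from. Every amino-acid
#' column becomes the corresponding source codon; gaps become `"---"`.
#'
#' @param protein_alignment Named character vector of aligned amino-acid
#'   strings (equal lengths, `-` for gaps).
#' @param cds_by_taxon Named character vector of unaligned coding sequences;
#'   each must translate exactly (standard code) to its ungapped protein row.
#'   A trailing stop codon on the CDS is tolerated and dropped.
#' @return A [codon_alignment()].
#' @export
backtranslate_alignment <- function(protein_alignment, cds_by_taxon) {
  if (is.null(names(protein_alignment)) || is.null(names(cds_by_taxon)))
    stop("both inputs must be named by taxon", call. = FALSE)
  taxa <- names(protein_alignment)
  missing_cds <- setdiff(taxa, names(cds_by_taxon))
  if (length(missing_cds))
    stop("no CDS for taxa: ", paste(missing_cds, collapse = ", "), call. = FALSE)
  widths <- unique(nchar(protein_alignment))
  if (length(widths) != 1L)
    stop("protein alignment rows differ in length", call. = FALSE)
  ncol_aln <- widths
  codons <- matrix("---", length(taxa), ncol_aln, dimnames = list(taxa, NULL))
  source_map <- matrix(NA_integer_, length(taxa), ncol_aln,
                       dimnames = list(taxa, NULL))
  for (tx in taxa) {
    aa_aln <- strsplit(toupper(protein_alignment[[tx]]), "")[[1]]
    cds <- toupper(cds_by_taxon[[tx]])
    cd <- .split_codons(cds)
    # drop a trailing stop codon if present
    if (length(cd) && cd[length(cd)] %in% .stop_codons())
      cd <- cd[-length(cd)]
    aa_cds <- .codon_to_aa(cd)
    resid <- which(aa_aln != "-")
    if (length(resid) != length(cd))
      stop("taxon '", tx, "': protein row has ", length(resid),
           " residues but CDS has ", length(cd), " codons", call. = FALSE)
    mism <- which(aa_aln[resid] != aa_cds)
    if (length(mism))
      stop("taxon '", tx, "': CDS translation differs from protein row at ",
           "alignment column ", resid[mism[1]], " (", aa_cds[mism[1]], " vs ",
           aa_aln[resid[mism[1]]], ")", call. = FALSE)
    codons[tx, resid] <- cd
    source_map[tx, resid] <- seq_along(cd)
  }
  codon_alignment(codons, source_map, allow_stops = TRUE)
}

#' Remove gapped codon columns
#'
#' Simple gap-fraction column filter at codon granularity: a codon column is
#' removed when its fraction of gap cells exceeds `max_gap_fraction`
#' (default 0: any gap removes the column). The returned mask maps window
#' coordinates on the trimmed alignment back to the original columns.
#'
#' @param alignment A [codon_alignment()] (or coercible input).
#' @param max_gap_fraction Highest tolerated gap fraction per column.
#' @return A list with `alignment` (trimmed [codon_alignment()]) and `mask`
#'   (a tibble with `column`, `gap_fraction`, `kept`).
#' @export
trim_gapped_columns <- function(alignment, max_gap_fraction = 0) {
  codons <- .as_codon_matrix(alignment)
  src <- if (inherits(alignment, "codon_alignment")) alignment$source_map else NULL
  gap_frac <- colMeans(codons == "---")
  kept <- gap_frac <= max_gap_fraction
  mask <- tibble::tibble(column = seq_along(gap_frac),
                         gap_fraction = unname(gap_frac),
                         kept = unname(kept))
  trimmed <- codons[, kept, drop = FALSE]
  src_trimmed <- if (!is.null(src)) src[, kept, drop = FALSE] else NULL
  list(alignment = codon_alignment(trimmed, src_trimmed, allow_stops = TRUE),
       mask = mask)
}

#' Collapse weakly supported branches into polytomies
#'
#' Contracts every internal edge whose bootstrap support (stored in
#' `node.label` of the child node, as a percentage) is below `threshold`.
#' The contracted edge's length is added to each child edge of the new
#' polytomy, so root-to-tip path lengths are preserved.
#'
#' @param tree An [ape::phylo] with numeric internal node labels as support.
#' @param threshold Support threshold; edges with support `< threshold` are
#'   collapsed, edges at or above it are retained.
#' @return The collapsed `phylo`.
#' @export
collapse_low_support <- function(tree, threshold = 70) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label))
    stop("tree has no node labels to read support values from", call. = FALSE)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  support <- suppressWarnings(as.numeric(tree$node.label))
  if (any(!is.na(support) & (support < 0 | support > 100)))
    stop("support values must lie in [0, 100]", call. = FALSE)
  child <- tree$edge[, 2]
  internal_edge <- child > ntip
  child_support <- rep(NA_real_, length(child))
  child_support[internal_edge] <- support[child[internal_edge] - ntip]
  drop <- internal_edge & !is.na(child_support) & child_support < threshold
  if (!any(drop)) return(tree)
  .contract_edges(tree, which(drop))
}

# Contract the given edge rows (children must be internal, non-root nodes);
# each contracted edge's length is pushed onto the edges below it.
.contract_edges <- function(tree, edge_rows) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  dropped_child <- edge[edge_rows, 2]
  parent_of <- integer(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  add_len <- numeric(max(edge))
  add_len[edge[, 2]] <- if (is.null(len)) 0 else len
  # resolve each surviving edge's parent upward past dropped nodes,
  # accumulating the contracted lengths
  keep <- setdiff(seq_len(nrow(edge)), edge_rows)
  new_parent <- edge[keep, 1]
  new_child <- edge[keep, 2]
  new_len <- if (is.null(len)) NULL else len[keep]
  for (i in seq_along(new_parent)) {
    p <- new_parent[i]
    while (p %in% dropped_child) {
      if (!is.null(new_len)) new_len[i] <- new_len[i] + add_len[p]
      p <- parent_of[p]
    }
    new_parent[i] <- p
  }
  # renumber: tips keep 1..ntip; surviving internals renumbered in old order
  old_internal <- sort(unique(new_parent))
  map <- integer(max(edge))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[old_internal] <- ntip + seq_along(old_internal)
  out <- list(edge = cbind(map[new_parent], map[new_child]),
              tip.label = tree$tip.label,
              Nnode = length(old_internal))
  if (!is.null(new_len)) out$edge.length <- new_len
  if (!is.null(tree$node.label))
    out$node.label <- tree$node.label[old_internal - ntip]
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}
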