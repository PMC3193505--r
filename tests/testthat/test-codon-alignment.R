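test_that("back-translation expands gaps and maps codons", {
  aln <- backtranslate_alignment(c(a = "MK"), c(a = "ATGAAA"))
  expect_equal(unname(aln$codons["a", ]), c("ATG", "AAA"))
  aln2 <- backtranslate_alignment(c(a = "M-K"), c(a = "ATGAAA"))
  expect_equal(unname(aln2$codons["a", ]), c("ATG", "---", "AAA"))
  expect_equal(unname(aln2$source_map["a", ]), c(1L, NA, 2L))
  # trailing stop on the CDS is tolerated
  aln3 <- backtranslate_alignment(c(a = "MK"), c(a = "ATGAAATAA"))
  expect_equal(ncol(aln3$codons), 2L)
  expect_error(backtranslate_alignment(c(a = "MW"), c(a = "ATGAAA")),
               "translation differs")
})

test_that("back-translation round-trips a seeded multi-taxon alignment", {
  set.seed(21)
  taxa <- paste0("t", 1:5)
  n_aa <- 30
  prot <- list(); cds <- list()
  for (tx in taxa) {
    codons <- sample(setdiff(sense_codons(), "ATG"), n_aa, replace = TRUE)
    aa <- strsplit(translate_cds(paste(codons, collapse = "")), "")[[1]]
    # sprinkle alignment gaps
    gaps <- sort(sample(n_aa + 5, 5))
    row <- rep("-", n_aa + 5)
    row[setdiff(seq_len(n_aa + 5), gaps)] <- aa
    prot[[tx]] <- paste(row, collapse = "")
    cds[[tx]] <- paste(codons, collapse = "")
  }
  aln <- backtranslate_alignment(unlist(prot), unlist(cds))
  # translating each codon row back gives the protein alignment
  for (tx in taxa) {
    back <- translate_cds(paste(aln$codons[tx, ], collapse = ""))
    expect_equal(back, prot[[tx]], info = tx)
  }
})

test_that("gap-fraction trimming matches a per-column scan", {
  m <- rbind(a = c("ATG", "AAA", "CCC", "GGG"),
             b = c("ATG", "---", "CCC", "GGG"),
             c = c("ATG", "AAA", "---", "GGG"),
             d = c("ATG", "AAA", "CCC", "GGG"))
  tr0 <- trim_gapped_columns(codon_alignment(m))
  expect_equal(tr0$mask$kept, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(ncol(tr0$alignment$codons), 2L)
  # threshold 0.25 keeps columns with at most one gap in four
  tr25 <- trim_gapped_columns(codon_alignment(m), max_gap_fraction = 0.25)
  expect_equal(tr25$mask$kept, rep(TRUE, 4))
  # no gaps anywhere: identity
  m2 <- m; m2[m2 == "---"] <- "AAA"
  trid <- trim_gapped_columns(codon_alignment(m2))
  expect_true(all(trid$mask$kept))
  # seeded case against brute force
  set.seed(22)
  big <- matrix(sample(c(sense_codons(), "---"), 8 * 50, replace = TRUE,
                       prob = c(rep(1, 61), 8)), nrow = 8,
                dimnames = list(paste0("s", 1:8), NULL))
  res <- trim_gapped_columns(codon_alignment(big, allow_stops = TRUE))
  expect_equal(res$mask$kept, colSums(big == "---") == 0)
})

test_that("trimming commutes with trimming the protein alignment", {
  prot <- c(a = "MKL-F", b = "MK-AF", c = "MKLAF")
  cds <- c(a = "ATGAAACTGTTT", b = "ATGAAAGCGTTT", c = "ATGAAACTGGCATTT")
  full <- backtranslate_alignment(prot, cds)
  trimmed <- trim_gapped_columns(full)
  kept <- trimmed$mask$kept
  # translating each trimmed codon row reproduces the protein alignment
  # restricted to the kept columns
  for (tx in names(prot)) {
    aa_kept <- paste(strsplit(prot[[tx]], "")[[1]][kept], collapse = "")
    expect_equal(translate_cds(paste(trimmed$alignment$codons[tx, ],
                                     collapse = "")), aa_kept, info = tx)
  }
})

test_that("in-frame stops are rejected unless allowed", {
  m <- rbind(a = c("ATG", "TAA"), b = c("ATG", "AAA"))
  expect_error(codon_alignment(m), "stop codon")
  expect_silent(codon_alignment(m, allow_stops = TRUE))
})

test_that("low-support branches collapse exactly below the threshold", {
  nwk <- "((a:1,b:1)95:1,((c:1,d:1)69:1,(e:1,f:1)70:1)80:1);"
  tree <- read_labeled_tree(text = nwk)
  col <- collapse_low_support(tree, threshold = 70)
  expect_setequal(col$tip.label, tree$tip.label)
  # one internal edge (support 69) contracted
  expect_equal(col$Nnode, tree$Nnode - 1L)
  # the 70-support clade survives
  labs <- col$node.label
  expect_true("70" %in% labs)
  expect_false("69" %in% labs)
  # support 100 everywhere: unchanged
  nwk2 <- "((a:1,b:1)100:1,(c:1,d:1)100:1);"
  t2 <- read_labeled_tree(text = nwk2)
  expect_equal(collapse_low_support(t2)$Nnode, t2$Nnode)
})

test_that("collapsing preserves root-to-tip path lengths and bipartitions", {
  set.seed(23)
  for (rep in 1:4) {
    tree <- ape::rtree(8)
    tree$node.label <- c("", as.character(sample(50:100, tree$Nnode - 1L,
                                                 replace = TRUE)))
    depths_before <- ape::node.depth.edgelength(tree)[1:8]
    col <- collapse_low_support(tree, threshold = 70)
    depths_after <- ape::node.depth.edgelength(col)[1:8]
    expect_equal(depths_after[order(col$tip.label)],
                 depths_before[order(tree$tip.label)], tolerance = 1e-12)
    # surviving clades = input clades with support >= 70 (plus the root)
    clade_set <- function(tr) {
      pp <- ape::prop.part(tr)
      sort(vapply(pp, function(idx)
        paste(sort(attr(pp, "labels")[idx]), collapse = ","), character(1)))
    }
    ntip <- 8
    keep <- c(TRUE, suppressWarnings(
      as.numeric(tree$node.label[-1])) >= 70)
    expected <- sort(unique(c(
      paste(sort(tree$tip.label), collapse = ","),
      vapply(which(keep), function(k) {
        cl <- ape::extract.clade(tree, ntip + k)
        paste(sort(cl$tip.label), collapse = ",")
      }, character(1)))))
    expect_equal(clade_set(col), expected, info = rep)
  }
})

test_that("newick round trip preserves supports and foreground marks", {
  nwk <- "((a:1,b:1)95#1:0.5,(c:1,d#1:1)80:0.5);"
  tree <- read_labeled_tree(text = nwk)
  expect_equal(sum(tree$foreground), 2L)
  marked_children <- tree$edge[tree$foreground, 2]
  expect_true(which(tree$tip.label == "d") %in% marked_children)
  expect_equal(sort(tree$node.label), c("", "80", "95"))
  out <- write_labeled_tree(tree)
  again <- read_labeled_tree(text = out)
  expect_equal(sum(again$foreground), 2L)
  expect_equal(sort(again$node.label), sort(tree$node.label))
})
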