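#' Read and write species trees with a CODEML-style foreground mark
#'
#' \code{readSpeciesTree} parses a Newick string or file. A label suffixed
#' with \code{#1} (e.g. \code{vlangalii#1}) marks the branch above that node
#' as the foreground branch for branch-site fits. \code{writeSpeciesTree}
#' emits Newick with the \code{#1} mark restored.
#'
#' @param x Newick text (containing \code{"("} and \code{";"}) or a file path.
#' @param foreground optional label overriding any \code{#1} mark.
#' @return a \linkS4class{SpeciesTree}.
#' @export
readSpeciesTree <- function(x, foreground = NULL) {
  txt <- if (grepl("\\(", x[1]) && grepl(";", x[1])) x[1] else
    paste(readLines(x, warn = FALSE), collapse = "")
  fg <- NA_character_
  m <- regmatches(txt, regexec("([A-Za-z0-9_.|+-]+)[ ]*#[ ]*1", txt))[[1]]
  if (length(m) == 2L) {
    fg <- m[2]
    txt <- sub("#[ ]*1", "", txt)
  }
  if (!is.null(foreground)) fg <- foreground
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse Newick tree")
  if (is.null(phy$edge.length))
    phy$edge.length <- rep(0.1, nrow(phy$edge))
  SpeciesTree(phy, fg)
}

#' @rdname readSpeciesTree
#' @param tree a \linkS4class{SpeciesTree}.
#' @param file optional output path; when missing, the Newick string is
#'   returned.
#' @export
writeSpeciesTree <- function(tree, file = NULL) {
  phy <- tree@tree
  fg <- tree@foreground
  if (!is.na(fg)) {
    i <- match(fg, phy$tip.label)
    if (!is.na(i)) phy$tip.label[i] <- paste0(fg, "#1")
    else {
      j <- match(fg, phy$node.label)
      if (!is.na(j)) phy$node.label[j] <- paste0(fg, "#1")
    }
  }
  txt <- ape::write.tree(phy)
  txt <- gsub("'", "", txt, fixed = TRUE)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' The default five-taxon study tree
#'
#' The unrooted topology \code{(((vlangalii, przewalskii), anolis), gallus,
#' pelodiscus)} relating the two agamid lizards to the green anole, chicken
#' and Chinese softshell turtle, with the high-elevation \code{vlangalii}
#' terminal branch flagged as foreground. Branch lengths are in expected
#' substitutions per codon and are configuration choices (no published
#' lengths exist for this tree); the defaults put the two focal terminals
#' at 0.1 and the deeper amniote branches at 0.1--0.5.
#'
#' @param branchLengths optional numeric vector of 7 edge lengths in
#'   \code{ape} edge order, replacing the defaults.
#' @param foreground foreground tip label.
#' @return a \linkS4class{SpeciesTree}.
#' @export
defaultSpeciesTree <- function(branchLengths = NULL,
                               foreground = "vlangalii") {
  txt <- paste0("(((vlangalii:0.1,przewalskii:0.1):0.15,anolis:0.45):0.1,",
                "gallus:0.5,pelodiscus:0.45);")
  st <- readSpeciesTree(txt, foreground = foreground)
  if (!is.null(branchLengths)) {
    stopifnot(length(branchLengths) == nrow(st@tree$edge))
    st@tree$edge.length <- branchLengths
    methods::validObject(st)
  }
  st
}

.phyloOf <- function(tree) {
  if (methods::is(tree, "SpeciesTree")) tree@tree else tree
}

# Node id of the foreground label (tip or internal node label).
.foregroundNode <- function(stree) {
  fg <- stree@foreground
  if (is.na(fg)) stop("tree has no foreground branch flagged")
  phy <- stree@tree
  i <- match(fg, phy$tip.label)
  if (!is.na(i)) return(i)
  j <- match(fg, phy$node.label)
  if (is.na(j)) stop(sprintf("foreground label '%s' not in tree", fg))
  length(phy$tip.label) + j
}

# Directed postorder traversal of the (possibly unrooted) tree from a
# chosen root node. Returns the edge list (parent, child) ordered so that
# every subtree precedes the edge above it, together with branch lengths
# and the row index of each edge in phy$edge (stable identity for
# reporting regardless of the rooting used).
.treeEngine <- function(phy, root = NULL) {
  E <- phy$edge
  len <- phy$edge.length
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  if (is.null(root)) root <- ntip + 1L
  adj <- vector("list", nnode)
  for (k in seq_len(nrow(E))) {
    a <- E[k, 1]; b <- E[k, 2]
    adj[[a]] <- c(adj[[a]], b, k)
    adj[[b]] <- c(adj[[b]], a, k)
  }
  ne <- nrow(E)
  edge <- matrix(0L, ne, 2)
  elen <- numeric(ne)
  orig <- integer(ne)
  cnt <- 0L
  rec <- function(node, parent) {
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (r in seq(1, length(nb), by = 2)) {
      ch <- nb[r]; k <- nb[r + 1]
      if (ch == parent) next
      rec(ch, node)
      cnt <<- cnt + 1L
      edge[cnt, ] <<- c(node, ch)
      elen[cnt] <<- len[k]
      orig[cnt] <<- k
    }
    invisible()
  }
  rec(root, 0L)
  list(edge = edge, len = elen, orig = orig, nnodes = nnode, ntaxa = ntip,
       root = as.integer(root), tips = phy$tip.label)
}

# Human-readable label per row of phy$edge: tip label for terminal edges,
# the sorted tips of the smaller bipartition side joined by '+' otherwise.
.edgeLabels <- function(phy) {
  ntip <- length(phy$tip.label)
  labs <- character(nrow(phy$edge))
  for (k in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[k, 2]
    if (ch <= ntip) {
      labs[k] <- phy$tip.label[ch]
    } else {
      below <- sort(phy$tip.label[.tipsBelow(phy, ch)])
      above <- sort(setdiff(phy$tip.label, below))
      side <- if (length(above) < length(below)) above else below
      labs[k] <- paste(side, collapse = "+")
    }
  }
  labs
}

.tipsBelow <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, .tipsBelow, phy = phy))
}

# Row index in phy$edge of the edge above the foreground node.
.foregroundEdgeRow <- function(stree) {
  node <- .foregroundNode(stree)
  phy <- stree@tree
  k <- which(phy$edge[, 2] == node)
  if (length(k) != 1L) stop("foreground node has no unique parent edge")
  k
}
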