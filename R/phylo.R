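#' @importFrom ape nj read.tree write.tree
NULL

#' Pairwise distance matrix from sequences
#'
#' Distances are p-distances on the optimal global alignment:
#' \code{1 - identity}, where identity counts equal residues over all
#' alignment columns. Monotone with divergence at the scales this
#' package simulates; no rate correction is applied.
#'
#' @param seqs named character vector or XStringSet of >= 2 sequences.
#' @param scheme [ScoringScheme-class]; default protein (BLOSUM62).
#' @return symmetric numeric matrix with zero diagonal and entries in
#'   [0, 1], labelled by sequence names.
#' @export
distanceMatrix <- function(seqs, scheme = scoringScheme("protein")) {
    if (!is.character(seqs)) seqs <- as.character(seqs)
    n <- length(seqs)
    if (n < 2L) stop("need at least 2 sequences")
    if (any(nchar(seqs) == 0L)) stop("empty sequence in input")
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            aln <- globalAlign(seqs[[i]], seqs[[j]], scheme)
            d[i, j] <- d[j, i] <- 1 - aln@identity
        }
    }
    d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining on a symmetric distance matrix; negative
#' estimated branch lengths are clamped to zero. NJ recovers the exact
#' topology and branch lengths from any additive distance matrix.
#'
#' @param d symmetric numeric matrix with zero diagonal (labelled).
#' @return an [ape::phylo] tree (unrooted for n >= 3).
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' njTree(d)$edge.length   # pendant branches 1, 1, 2
#' @export
njTree <- function(d) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8))
        stop("distance matrix must be symmetric")
    if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
    n <- nrow(d)
    if (n < 2L) stop("need at least 2 taxa")
    if (n == 2L) {
        lab <- rownames(d)
        return(read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        lab[1L], d[1L, 2L] / 2,
                                        lab[2L], d[1L, 2L] / 2)))
    }
    tr <- nj(d)
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] tree.
#' @param path optional file path; when NULL the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
    txt <- write.tree(tree, digits = 12L)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Read a tree from Newick text or a file
#'
#' Malformed input (unbalanced parentheses, missing terminator) raises
#' a parse error reporting the offending character position.
#'
#' @param text Newick string, or NULL when \code{path} is given.
#' @param path optional file to read from.
#' @return an [ape::phylo] tree.
#' @export
readNewick <- function(text = NULL, path = NULL) {
    if (is.null(text)) text <- paste(readLines(path), collapse = "")
    chars <- strsplit(text, "")[[1L]]
    depth <- 0L
    for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        if (chars[i] == ")") depth <- depth - 1L
        if (depth < 0L)
            stop("Newick parse error: unmatched ')' at position ", i)
    }
    if (depth != 0L)
        stop("Newick parse error: ", depth,
             " unclosed '(' at end of input (position ", length(chars), ")")
    if (!grepl(";\\s*$", text))
        stop("Newick parse error: missing ';' terminator at position ",
             length(chars))
    tr <- read.tree(text = text)
    if (is.null(tr)) stop("Newick parse error: unparsable input")
    tr
}

#' Test whether a set of tips is monophyletic in an unrooted tree
#'
#' A tip set is a clade of an unrooted tree when some edge splits the
#' tips exactly into the set and its complement.
#'
#' @param tree an [ape::phylo] tree.
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
isClade <- function(tree, tips) {
    tips <- unique(tips)
    n <- length(tree$tip.label)
    if (length(tips) <= 1L || length(tips) >= n - 1L) return(TRUE)
    if (!all(tips %in% tree$tip.label)) return(FALSE)
    # bipartitions: tips below each internal edge
    below <- function(node, edge) {
        kids <- edge[edge[, 1L] == node, 2L]
        if (!length(kids)) return(node)
        unlist(lapply(kids, below, edge = edge))
    }
    target <- sort(match(tips, tree$tip.label))
    for (nd in unique(tree$edge[, 2L])) {
        if (nd <= n) next
        grp <- sort(below(nd, tree$edge))
        if (identical(grp, target) ||
            identical(sort(setdiff(seq_len(n), grp)), target))
            return(TRUE)
    }
    FALSE
}
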