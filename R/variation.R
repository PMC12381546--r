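#' @importFrom stats prcomp
NULL

.kmersOf <- function(seq, k) {
    L <- nchar(seq)
    if (L < k) return(character(0))
    km <- substring(seq, seq_len(L - k + 1L), k:L)
    km[!grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), km)]
}

#' Genotype-level k-mer frequency matrix
#'
#' Overlapping peptide k-mers are counted per genotype across all of
#' that genotype's family proteins; k-mers containing non-standard
#' residues (X, *) are skipped. Each row is normalized by the
#' genotype's total k-mer count, so partial deletions, PAV and CNV all
#' translate into frequency shifts rather than raw-count artifacts.
#'
#' @param seqs character vector of protein sequences.
#' @param genotypes genotype of each sequence (same length as
#'   \code{seqs}); factor levels define the row set, so genotypes with
#'   no sequences keep an all-zero (flagged) row.
#' @param k k-mer length; default 3.
#' @return genotype x k-mer matrix of frequencies; rows with any k-mer
#'   sum to 1. Attribute \code{"flaggedEmpty"} names all-zero rows.
#' @export
kmerProfile <- function(seqs, genotypes, k = 3L) {
    stopifnot(k >= 1L, length(seqs) == length(genotypes))
    genotypes <- if (is.factor(genotypes)) genotypes else
        factor(genotypes, levels = unique(genotypes))
    counts <- lapply(split(seqs, genotypes), function(ss) {
        km <- unlist(lapply(ss, .kmersOf, k = k), use.names = FALSE)
        if (!length(km)) return(integer(0))
        table(km)
    })
    cols <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
    mat <- matrix(0, length(counts), length(cols),
                  dimnames = list(names(counts), cols))
    for (g in names(counts)) {
        tab <- counts[[g]]
        if (!length(tab)) next
        mat[g, names(tab)] <- as.numeric(tab) / sum(tab)
    }
    empty <- rownames(mat)[rowSums(mat) == 0]
    attr(mat, "flaggedEmpty") <- empty
    mat
}

#' PCA of a k-mer frequency matrix
#'
#' Eigen-decomposition of the row-centered (optionally
#' column-standardized) matrix. Explained variance per dimension is the
#' eigenvalue share in percent. cos2 of genotype i on dimension d is
#' \code{coords[i, d]^2 / sum_d coords[i, d]^2}, i.e. the share of the
#' genotype's squared distance from the centroid that the dimension
#' carries; it sums to 1 over all dimensions for any genotype off the
#' centroid. Zero-variance columns are dropped before scaling. Rows are
#' centered by default but not scaled: the rows are already normalized
#' frequencies, and near-constant k-mer columns make unit-variance
#' scaling unstable.
#'
#' @param mat matrix from [kmerProfile()] (>= 2 rows).
#' @param center,scale passed to the decomposition; defaults TRUE,
#'   FALSE.
#' @return A [PCAResult-class]. When all rows are identical the result
#'   is flagged degenerate with zero coordinates and cos2.
#' @export
kmerPCA <- function(mat, center = TRUE, scale = FALSE) {
    if (nrow(mat) < 2L) stop("need at least 2 genotypes")
    keep <- apply(mat, 2L, function(x) var(x) > 0)
    m <- mat[, keep, drop = FALSE]
    if (ncol(m) == 0L) {
        nd <- 1L
        coords <- matrix(0, nrow(mat), nd,
                         dimnames = list(rownames(mat), "Dim1"))
        return(new("PCAResult", coords = coords,
                   explainedVariance = 0, cos2 = coords,
                   cos2Plane = setNames(rep(0, nrow(mat)), rownames(mat)),
                   degenerate = TRUE, excludedFamily = NA_character_))
    }
    pc <- prcomp(m, center = center, scale. = scale)
    coords <- pc$x
    colnames(coords) <- paste0("Dim", seq_len(ncol(coords)))
    ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
    ev <- ev[seq_len(ncol(coords))]
    ss <- rowSums(coords^2)
    cos2 <- coords^2 / ifelse(ss > 0, ss, 1)
    cos2[ss == 0, ] <- 0
    plane <- rowSums(cos2[, seq_len(min(2L, ncol(cos2))), drop = FALSE])
    new("PCAResult", coords = coords, explainedVariance = as.numeric(ev),
        cos2 = cos2, cos2Plane = plane, degenerate = FALSE,
        excludedFamily = NA_character_)
}

#' @rdname PCAResult-class
#' @param x a [PCAResult-class].
#' @export
pcaCoords <- function(x) x@coords

#' @rdname PCAResult-class
#' @export
explainedVariance <- function(x) x@explainedVariance

#' @rdname PCAResult-class
#' @export
cos2Values <- function(x) x@cos2

#' Repeat the k-mer PCA with one family excluded
#'
#' Rebuilds the k-mer matrix from all proteins except the named
#' family's and reruns the PCA, keeping the full genotype set as rows.
#' Used to test whether an apparent separation is driven by a single
#' family's presence/absence or divergence.
#'
#' @param seqs,genotypes,k as in [kmerProfile()].
#' @param families family of each sequence.
#' @param family the family to exclude.
#' @param center,scale as in [kmerPCA()].
#' @return A [PCAResult-class] tagged with the excluded family.
#' @export
leaveFamilyOut <- function(seqs, genotypes, families, family, k = 3L,
                           center = TRUE, scale = FALSE) {
    stopifnot(length(seqs) == length(families))
    keep <- families != family
    if (!any(keep)) stop("excluding '", family, "' removes all sequences")
    genotypes <- if (is.factor(genotypes)) genotypes else
        factor(genotypes, levels = unique(genotypes))
    mat <- kmerProfile(seqs[keep], factor(genotypes[keep],
                                          levels = levels(genotypes)), k)
    res <- kmerPCA(mat, center = center, scale = scale)
    res@excludedFamily <- family
    res
}

#' Rank families by between-group k-mer divergence
#'
#' For each family, genotype k-mer profiles are computed from that
#' family's sequences only and averaged within each group; the family's
#' divergence is the Euclidean distance between the two group
#' centroids. Families are ranked by descending divergence (ties broken
#' alphabetically) -- a formalized replacement for manually building a
#' phylogeny of contrasting genotypes to spot the gene driving a PCA
#' separation.
#'
#' @param seqs,genotypes,families,k as in [leaveFamilyOut()].
#' @param groupA,groupB disjoint genotype sets, each non-empty.
#' @return data.frame with \code{family}, \code{divergence},
#'   \code{flagged} (TRUE when the family is absent from an entire
#'   group, in which case the centroid is the zero profile).
#' @export
rankDriverGenes <- function(seqs, genotypes, families, groupA, groupB,
                            k = 3L) {
    if (length(intersect(groupA, groupB)))
        stop("groups must be disjoint")
    if (!length(groupA) || !length(groupB))
        stop("both groups must be non-empty")
    genotypes <- as.character(genotypes)
    out <- lapply(sort(unique(families)), function(fam) {
        sel <- families == fam & genotypes %in% c(groupA, groupB)
        gts <- factor(genotypes[sel], levels = c(groupA, groupB))
        mat <- kmerProfile(seqs[sel], gts, k)
        inA <- rownames(mat) %in% groupA
        cA <- colMeans(mat[inA, , drop = FALSE])
        cB <- colMeans(mat[!inA, , drop = FALSE])
        absentA <- all(rowSums(mat[inA, , drop = FALSE]) == 0)
        absentB <- all(rowSums(mat[!inA, , drop = FALSE]) == 0)
        data.frame(family = fam,
                   divergence = sqrt(sum((cA - cB)^2)),
                   flagged = absentA || absentB,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    res <- res[order(-res$divergence, res$family), , drop = FALSE]
    rownames(res) <- NULL
    res
}
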