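#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom S4Vectors DataFrame
NULL

#' Validate a gene against pangenome assemblies
#'
#' Runs the seed-and-extend genomic search for one gene's genomic
#' sequence against every genotype assembly and merges hits into loci;
#' the merged locus count per genotype is the validated copy count.
#'
#' @param query gene genomic sequence (character scalar).
#' @param assemblies named list of per-genotype replicon sets
#'   ([Biostrings::DNAStringSet] or named character vectors).
#' @param kSeed,minIdentity,minCoverage see [seedExtendSearch()].
#' @param maxGap locus merge gap, see [mergeHits()].
#' @param queryId id copied into hit tables.
#' @param sourceGenotype optional genotype the gene model came from; a
#'   consistency error is raised if the gene is not recovered there.
#' @param indices optional named list of prebuilt [kmerIndex()] objects
#'   per genotype (reused when validating many genes).
#' @return list with \code{loci} (per-genotype locus data.frames) and
#'   \code{counts} (named integer copy counts).
#' @export
validateGene <- function(query, assemblies, kSeed = 15L,
                         minIdentity = 0.9, minCoverage = 0.8,
                         maxGap = 2000L, queryId = "gene",
                         sourceGenotype = NULL, indices = NULL) {
    loci <- list()
    counts <- setNames(integer(length(assemblies)), names(assemblies))
    for (gt in names(assemblies)) {
        hits <- seedExtendSearch(query, assemblies[[gt]], kSeed = kSeed,
                                 minIdentity = minIdentity,
                                 minCoverage = minCoverage,
                                 queryId = queryId,
                                 index = indices[[gt]])
        l <- mergeHits(hits, maxGap = maxGap)
        l$genotype <- rep(gt, nrow(l))
        loci[[gt]] <- l
        counts[gt] <- nrow(l)
    }
    if (!is.null(sourceGenotype) && counts[sourceGenotype] == 0L)
        stop("gene ", queryId, " not recovered from its source assembly ",
             sourceGenotype)
    list(loci = loci, counts = counts)
}

#' Build a gene-by-genotype presence matrix
#'
#' @param counts integer matrix of copy counts, genes in rows and
#'   genotypes in columns.
#' @return A [PresenceMatrix-class]; rows are classified core when
#'   present (count >= 1) in every genotype, dispensable otherwise. The
#'   presence-count histogram is stored in the object metadata.
#' @export
buildPresenceMatrix <- function(counts) {
    if (is.null(colnames(counts)))
        stop("counts must have genotype column names")
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    pc <- as.integer(rowSums(counts >= 1L))
    cls <- ifelse(pc == ncol(counts), "core", "dispensable")
    se <- SummarizedExperiment(
        assays = list(copies = counts),
        rowData = DataFrame(presenceCount = pc, class = cls))
    obj <- new("PresenceMatrix", se)
    S4Vectors::metadata(obj)$presenceHistogram <-
        table(factor(pc, levels = 0:ncol(counts)))
    obj
}

#' @rdname PresenceMatrix-class
#' @param x a [PresenceMatrix-class].
#' @export
copyCounts <- function(x) assay(x, "copies")

#' @rdname PresenceMatrix-class
#' @export
geneClass <- function(x) setNames(rowData(x)$class, rownames(x))

#' @rdname PresenceMatrix-class
#' @export
presenceCount <- function(x) setNames(rowData(x)$presenceCount, rownames(x))

#' @rdname PresenceMatrix-class
#' @export
presenceHistogram <- function(x) S4Vectors::metadata(x)$presenceHistogram

# pattern-global / subject-local alignment (anchor a full exon in a locus)
.globalLocalAlign <- function(a, b, scheme) {
    pa <- pairwiseAlignment(a, b, type = "global-local",
        substitutionMatrix = scheme@matrix,
        gapOpening = -scheme@gapOpen, gapExtension = -scheme@gapExtend)
    .asPairAlignment(pa, a, b, "local")
}

# signed indels from a pair of aligned rows (a = reference)
.alignmentIndels <- function(alnA, alnB, refOffset = 0L) {
    ca <- strsplit(alnA, "")[[1L]]
    cb <- strsplit(alnB, "")[[1L]]
    indels <- list()
    refPos <- refOffset
    i <- 1L
    n <- length(ca)
    while (i <= n) {
        if (ca[i] == "-") {
            j <- i
            while (j < n && ca[j + 1L] == "-") j <- j + 1L
            indels[[length(indels) + 1L]] <-
                data.frame(refPos = refPos, len = j - i + 1L,
                           bases = paste(cb[i:j], collapse = ""))
            i <- j + 1L
        } else if (cb[i] == "-") {
            j <- i
            while (j < n && cb[j + 1L] == "-") j <- j + 1L
            indels[[length(indels) + 1L]] <-
                data.frame(refPos = refPos, len = -(j - i + 1L),
                           bases = paste(ca[i:j], collapse = ""))
            refPos <- refPos + (j - i + 1L)
            i <- j + 1L
        } else {
            refPos <- refPos + 1L
            i <- i + 1L
        }
    }
    if (!length(indels))
        return(data.frame(refPos = integer(), len = integer(),
                          bases = character()))
    do.call(rbind, indels)
}

# canonicalize 1-bp indel positions: shift left through equal-base runs
# (bounded by the exon start), matching the convention the simulator's
# truth table records
.normalizeIndels <- function(indels, cds, exonStartsCds) {
    if (!nrow(indels)) return(indels)
    for (r in seq_len(nrow(indels))) {
        if (abs(indels$len[r]) != 1L) next
        p <- indels$refPos[r]
        exStart <- exonStartsCds[findInterval(p, exonStartsCds)]
        if (indels$len[r] == -1L) {
            while (p > exStart + 1L &&
                   substr(cds, p, p) == substr(cds, p + 1L, p + 1L))
                p <- p - 1L
        } else {
            b <- indels$bases[r]
            while (p > exStart + 1L && substr(cds, p, p) == b)
                p <- p - 1L
        }
        indels$refPos[r] <- p
    }
    indels[order(indels$refPos), , drop = FALSE]
}

#' Exon-aware alignment of a reference CDS to a genomic locus
#'
#' Each reference exon is first anchored in the locus by local
#' alignment, then aligned end-to-end (exon-global, locus-local) inside
#' its anchor window; the per-exon alignments are concatenated in exon
#' order. Exons that fail to anchor are reported as missing intervals.
#'
#' @param cds reference coding sequence (spliced, including the stop
#'   codon).
#' @param exonLens integer vector of exon lengths (sums to
#'   \code{nchar(cds)}).
#' @param locus genomic locus sequence recovered by [validateGene()].
#' @param scheme DNA [ScoringScheme-class].
#' @param anchorIdentity,anchorCoverage minimum local identity/exon
#'   coverage for an exon to count as anchored.
#' @return An \code{ExonAlignment}: list with \code{indels} (signed,
#'   positions 0-based on the reference CDS), \code{missingExons},
#'   \code{anchored}, \code{variantCds} (locus bases under the anchored
#'   exons, in exon order), \code{refCds}, \code{identity},
#'   \code{coverage} (fraction of reference CDS anchored).
#' @export
exonAwareAlignCds <- function(cds, exonLens, locus,
                              scheme = scoringScheme("dna"),
                              anchorIdentity = 0.75,
                              anchorCoverage = 0.5) {
    stopifnot(sum(exonLens) == nchar(cds))
    cum <- c(0L, cumsum(exonLens))
    nex <- length(exonLens)
    anchored <- logical(nex)
    segs <- character(nex)
    indels <- list()
    alns <- vector("list", nex)
    matchCols <- 0; totalCols <- 0
    searchFrom <- 0L
    for (i in seq_len(nex)) {
        exonSeq <- substring(cds, cum[i] + 1L, cum[i + 1L])
        loc <- localAlign(exonSeq, locus, scheme)
        exCov <- (loc@querySpan[2L] - loc@querySpan[1L]) / nchar(exonSeq)
        if (loc@score <= 0 || loc@identity < anchorIdentity ||
            exCov < anchorCoverage || loc@subjectSpan[1L] < searchFrom) {
            anchored[i] <- FALSE
            next
        }
        pad <- loc@querySpan[1L] + 10L
        padR <- (nchar(exonSeq) - loc@querySpan[2L]) + 10L
        winA <- max(1L, loc@subjectSpan[1L] + 1L - pad)
        winB <- min(nchar(locus), loc@subjectSpan[2L] + padR)
        gl <- .globalLocalAlign(exonSeq, substring(locus, winA, winB),
                                scheme)
        anchored[i] <- TRUE
        alns[[i]] <- gl
        segs[i] <- gsub("-", "", gl@alignedB, fixed = TRUE)
        ind <- .alignmentIndels(gl@alignedA, gl@alignedB,
                                refOffset = cum[i])
        if (nrow(ind)) indels[[length(indels) + 1L]] <- ind
        matchCols <- matchCols + gl@identity * nchar(gl@alignedA)
        totalCols <- totalCols + nchar(gl@alignedA)
        searchFrom <- winA - 1L + gl@subjectSpan[2L] -
            (nchar(exonSeq) - 1L)  # next exon must not jump backwards
    }
    if (!any(anchored))
        stop("no exon of the reference model anchors in the locus")
    indels <- if (length(indels)) do.call(rbind, indels) else
        data.frame(refPos = integer(), len = integer(),
                   bases = character())
    indels <- .normalizeIndels(indels, cds, cum[-length(cum)])
    rownames(indels) <- NULL
    structure(list(
        indels = indels, anchored = anchored,
        missingExons = which(!anchored),
        variantCds = paste(segs[anchored], collapse = ""),
        refCds = cds, exonLens = exonLens,
        identity = if (totalCols) matchCols / totalCols else 0,
        coverage = sum(exonLens[anchored]) / sum(exonLens),
        exonAlignments = alns), class = "ExonAlignment")
}

#' Detect frameshifts from an exon-aware alignment
#'
#' The net reading-frame shift is the signed indel sum modulo 3; a
#' frameshift is called when it is nonzero. A premature stop is the
#' first stop codon, translating the variant CDS, that falls before
#' 90\% of the reference protein length.
#'
#' @param exonAln an \code{ExonAlignment} from [exonAwareAlignCds()].
#' @param prematureFrac fraction of the reference protein length before
#'   which a stop counts as premature; default 0.9.
#' @return A \code{FrameshiftReport}: list with \code{indels},
#'   \code{netShift} (0, 1 or 2), \code{frameshift}, \code{prematureStop}
#'   (1-based residue index or NA), \code{variantCds}, and empty rescue
#'   fields (\code{altStart}, \code{rescuedProtein},
#'   \code{retainedDomains}).
#' @export
detectFrameshift <- function(exonAln, prematureFrac = 0.9) {
    netShift <- sum(exonAln$indels$len) %% 3L
    refProtLen <- nchar(exonAln$refCds) %/% 3L - 1L
    pep <- translateDNA(exonAln$variantCds)
    stops <- which(strsplit(pep, "")[[1L]] == "*")
    premature <- stops[stops < prematureFrac * refProtLen]
    structure(list(
        indels = exonAln$indels, netShift = netShift,
        frameshift = netShift != 0L,
        prematureStop = if (length(premature)) premature[1L] else NA_integer_,
        variantCds = exonAln$variantCds,
        altStart = NA_integer_, rescuedProtein = NA_character_,
        retainedDomains = character(0)), class = "FrameshiftReport")
}

#' Rescue a frameshift variant via an alternative translation start
#'
#' Scans for ATG codons downstream of the last frame-disrupting indel
#' that are in the reading frame of the reference stop codon (anchored
#' at the 3' end of the variant CDS). The 5'-most ATG whose downstream
#' translation reaches the original stop without interruption is
#' selected; the rescued protein is translated and re-scanned for
#' domains.
#'
#' @param report a \code{FrameshiftReport} with \code{frameshift = TRUE}.
#' @param pssms list of [PSSM-class] models used to re-scan the rescued
#'   protein.
#' @param thresholds,calibrations passed to [scanDomainSet()].
#' @return the updated \code{FrameshiftReport}; \code{altStart} stays NA
#'   when no qualifying ATG exists.
#' @export
rescueAlternativeStart <- function(report, pssms, thresholds = NULL,
                                   calibrations = NULL) {
    stopifnot(inherits(report, "FrameshiftReport"))
    v <- report$variantCds
    L <- nchar(v)
    ind <- report$indels
    shifting <- ind[ind$len %% 3L != 0L, , drop = FALSE]
    if (!nrow(shifting)) return(report)
    last <- shifting[nrow(shifting), ]
    # variant-coordinate position of the last disrupting indel
    shiftBefore <- sum(ind$len[ind$refPos < last$refPos])
    varPos <- last$refPos + shiftBefore + max(0L, last$len)
    cand <- varPos:(L - 6L)
    cand <- cand[(L - cand) %% 3L == 0L]
    for (p in cand) {
        if (substring(v, p + 1L, p + 3L) != "ATG") next
        pep <- translateDNA(substring(v, p + 1L, L))
        body <- substr(pep, 1L, nchar(pep) - 1L)
        if (grepl("*", body, fixed = TRUE)) next
        report$altStart <- p
        report$rescuedProtein <- body
        if (!is.null(pssms)) {
            hits <- scanDomainSet(pssms, body, thresholds = thresholds,
                                  calibrations = calibrations)
            report$retainedDomains <- unique(hits$label)
        }
        return(report)
    }
    report
}

#' Reconcile genome-level and annotation-level evidence for a gene
#'
#' Decision table assigning one status per (gene, genotype):
#' \itemize{
#'   \item no locus in the assembly: \code{TRUE_DELETION};
#'   \item net reading-frame shift at the genomic locus:
#'     \code{NATURAL_VARIANT};
#'   \item reference domains absent from the locus (or reference
#'     coverage below threshold): \code{PARTIAL_DOMAIN_LOSS};
#'   \item premature stop or identity below threshold:
#'     \code{NATURAL_VARIANT};
#'   \item locus intact and the annotated protein carries all reference
#'     domains: \code{CONSISTENT};
#'   \item locus intact but the annotation is missing or domain
#'     truncated: \code{MISANNOTATION_CANDIDATE}.
#' }
#'
#' @param locusFound logical, any locus recovered.
#' @param frameshift logical, net frame shift at the locus.
#' @param prematureStop logical, premature stop at the locus.
#' @param identity,coverage alignment identity / reference CDS coverage.
#' @param refDomains domain labels of the reference protein.
#' @param variantDomains domain labels found in the locus translation.
#' @param annotatedDomains domain labels of the annotated protein, or
#'   NULL when the gene is unannotated in this genotype.
#' @param identityThr,coverageThr intactness thresholds (defaults 0.9,
#'   0.8).
#' @return character scalar, one of CONSISTENT, MISANNOTATION_CANDIDATE,
#'   NATURAL_VARIANT, PARTIAL_DOMAIN_LOSS, TRUE_DELETION.
#' @export
geneStatus <- function(locusFound, frameshift, prematureStop,
                       identity, coverage, refDomains, variantDomains,
                       annotatedDomains = NULL,
                       identityThr = 0.9, coverageThr = 0.8) {
    if (!locusFound) return("TRUE_DELETION")
    if (frameshift) return("NATURAL_VARIANT")
    # domain loss before the premature-stop rule: an in-frame deletion
    # shortens the protein and would otherwise masquerade as a stop variant
    if (coverage < coverageThr || !all(refDomains %in% variantDomains))
        return("PARTIAL_DOMAIN_LOSS")
    if (prematureStop || identity < identityThr) return("NATURAL_VARIANT")
    if (!is.null(annotatedDomains) &&
        all(refDomains %in% annotatedDomains)) return("CONSISTENT")
    "MISANNOTATION_CANDIDATE"
}

#' Label loci by their nearest reference copy
#'
#' Each locus is assigned the reference with the highest
#' global-alignment identity; when the best and second-best identities
#' differ by less than \code{margin} the label is AMBIGUOUS.
#'
#' @param loci named character vector of locus sequences.
#' @param references named character vector of >= 2 reference sequences.
#' @param scheme [ScoringScheme-class]; default DNA.
#' @param margin minimum identity lead (absolute fraction) for an
#'   unambiguous call; default 0.005 (0.5 percentage points).
#' @return data.frame with \code{locus}, \code{label},
#'   \code{bestIdentity}, \code{secondIdentity}.
#' @export
classifyCopiesByReference <- function(loci, references,
                                      scheme = scoringScheme("dna"),
                                      margin = 0.005) {
    if (length(references) < 2L) stop("need at least 2 references")
    out <- lapply(names(loci), function(id) {
        ident <- vapply(references, function(r)
            globalAlign(loci[[id]], r, scheme)@identity, numeric(1))
        ord <- order(-ident)
        best <- ident[ord[1L]]; second <- ident[ord[2L]]
        lab <- if (best - second < margin) "AMBIGUOUS"
               else names(references)[ord[1L]]
        data.frame(locus = id, label = lab, bestIdentity = best,
                   secondIdentity = second, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Cross-tabulate gene presence against a phenotype label
#'
#' @param pm a [PresenceMatrix-class].
#' @param labels named character vector mapping every genotype to a
#'   phenotype (use \code{"unknown"} where uncharacterized).
#' @param gene gene (row) to tabulate.
#' @return contingency table with rows \code{present}/\code{absent} and
#'   one column per phenotype; marginals sum to the genotype count.
#' @export
crosstabPresencePhenotype <- function(pm, labels, gene) {
    cc <- copyCounts(pm)
    if (!gene %in% rownames(cc)) stop("unknown gene: ", gene)
    gts <- colnames(cc)
    if (!all(gts %in% names(labels)))
        stop("phenotype label missing for: ",
             paste(setdiff(gts, names(labels)), collapse = ", "))
    presence <- factor(ifelse(cc[gene, gts] >= 1L, "present", "absent"),
                       levels = c("present", "absent"))
    phen <- factor(labels[gts])
    table(presence = presence, phenotype = phen)
}
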