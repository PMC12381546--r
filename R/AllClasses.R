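#' @import methods
#' @importFrom S4Vectors metadata
NULL

#' Scoring scheme for pairwise alignment
#'
#' Container for an affine-gap scoring scheme. A gap of length \code{L}
#' costs \code{gapOpen + L * gapExtend} (both penalties are non-positive).
#' The substitution matrix is symmetric and indexed by residue letters.
#'
#' @slot alphabet either \code{"dna"} or \code{"protein"}.
#' @slot matrix symmetric substitution matrix with residue dimnames.
#' @slot gapOpen gap opening penalty (<= 0), charged once per gap.
#' @slot gapExtend gap extension penalty (<= 0), charged per gapped column.
#'
#' @seealso [scoringScheme()], [globalAlign()], [localAlign()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
    representation(
        alphabet  = "character",
        matrix    = "matrix",
        gapOpen   = "numeric",
        gapExtend = "numeric"
    )
)

setValidity("ScoringScheme", function(object) {
    msg <- character()
    if (!object@alphabet %in% c("dna", "protein"))
        msg <- c(msg, "alphabet must be 'dna' or 'protein'")
    if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0))
        msg <- c(msg, "penalties must satisfy gapOpen <= gapExtend <= 0")
    m <- object@matrix
    if (is.null(dimnames(m)) || !identical(rownames(m), colnames(m)))
        msg <- c(msg, "substitution matrix must have matching dimnames")
    else if (!isSymmetric(unname(m)))
        msg <- c(msg, "substitution matrix must be symmetric")
    if (length(msg)) msg else TRUE
})

#' Pairwise alignment result
#'
#' Gapped alignment of two sequences. Removing the gap characters from
#' \code{alignedA}/\code{alignedB} reproduces the aligned subsequences of
#' the inputs; spans are 0-based half-open on the original sequences.
#' Identity is the fraction of alignment columns (including gap columns)
#' whose residues are equal.
#'
#' @slot alignedA,alignedB gapped sequence strings (gap = \code{"-"}).
#' @slot score alignment score in scheme units.
#' @slot identity fraction of equal columns, in [0, 1].
#' @slot querySpan,subjectSpan integer (start, end), 0-based half-open.
#'
#' @exportClass PairAlignment
setClass("PairAlignment",
    representation(
        alignedA    = "character",
        alignedB    = "character",
        score       = "numeric",
        identity    = "numeric",
        querySpan   = "integer",
        subjectSpan = "integer"
    )
)

setValidity("PairAlignment", function(object) {
    msg <- character()
    if (nchar(object@alignedA) != nchar(object@alignedB))
        msg <- c(msg, "aligned rows must have equal length")
    if (object@identity < 0 || object@identity > 1)
        msg <- c(msg, "identity must lie in [0, 1]")
    if (length(object@querySpan) != 2L || length(object@subjectSpan) != 2L)
        msg <- c(msg, "spans must be length-2 integer vectors")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PairAlignment", function(object) {
    cat(sprintf("PairAlignment: score %.1f, identity %.3f, %d columns\n",
        object@score, object@identity, nchar(object@alignedA)))
    if (nchar(object@alignedA) > 0 && nchar(object@alignedA) <= 80) {
        cat(" ", object@alignedA, "\n ", object@alignedB, "\n", sep = "")
    }
})

#' Simulation configuration for the synthetic pangenome generator
#'
#' Defines the study conditions under which a synthetic pangenome is
#' generated: population and family sizes, genome length, gene structure,
#' neutral divergence, and per-gene-per-genotype probabilities for each
#' planted event kind.
#'
#' @slot nGenotypes number of genotypes (>= 2).
#' @slot nFamilies number of gene families.
#' @slot genomeLength bp of assembly per genotype.
#' @slot exonsPerGene integer (min, max) exon count per gene.
#' @slot substitutionRate per-site neutral substitution probability;
#'   applied to intergenic and intronic sites, and as a per-codon
#'   synonymous substitution probability inside coding sequence.
#' @slot eventRates named probabilities for \code{deletion},
#'   \code{tandem_duplication}, \code{dispersed_duplication},
#'   \code{indel_1bp}, \code{domain_deletion}, \code{annotation_truncation}.
#' @slot duplicateDivergence per-site divergence applied to new copies.
#' @slot seed master RNG seed; one stream per genotype is derived from it.
#'
#' @seealso [simConfig()], [simulatePangenome()]
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        nGenotypes          = "integer",
        nFamilies           = "integer",
        genomeLength        = "integer",
        exonsPerGene        = "integer",
        substitutionRate    = "numeric",
        eventRates          = "numeric",
        duplicateDivergence = "numeric",
        seed                = "integer"
    )
)

.EVENT_KINDS <- c("deletion", "tandem_duplication", "dispersed_duplication",
                  "indel_1bp", "domain_deletion", "annotation_truncation")

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nGenotypes < 2L)
        msg <- c(msg, "nGenotypes must be >= 2")
    if (object@nFamilies < 1L)
        msg <- c(msg, "nFamilies must be >= 1")
    if (length(object@exonsPerGene) != 2L || object@exonsPerGene[1L] < 1L ||
        object@exonsPerGene[2L] < object@exonsPerGene[1L])
        msg <- c(msg, "exonsPerGene must be (min, max) with min >= 1")
    rates <- c(object@substitutionRate, object@eventRates,
               object@duplicateDivergence)
    if (any(rates < 0 | rates > 1))
        msg <- c(msg, "all rates must lie in [0, 1]")
    if (!all(.EVENT_KINDS %in% names(object@eventRates)))
        msg <- c(msg, paste("eventRates must name:",
                            paste(.EVENT_KINDS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenotypes, "genotypes x", object@nFamilies,
        "families,", object@genomeLength, "bp, seed", object@seed, "\n")
    cat("  substitutionRate", object@substitutionRate,
        " duplicateDivergence", object@duplicateDivergence, "\n")
    cat("  eventRates:", paste(names(object@eventRates),
        format(object@eventRates), sep = "=", collapse = " "), "\n")
})

#' Synthetic pangenome with ground truth
#'
#' In-memory representation of a simulated multi-genotype pangenome:
#' per-genotype assemblies, gene annotations, annotated proteins, the
#' founder gene set they all derive from, and a truth table recording
#' every planted event with its coordinates on the genotype assembly
#' (0-based half-open).
#'
#' @slot assemblies named list of [Biostrings::DNAStringSet], one per genotype.
#' @slot annotations named list (per genotype) of gene models; each gene
#'   model is a list with elements \code{geneId}, \code{familyId},
#'   \code{chrom}, \code{strand}, \code{exons} (matrix of 0-based half-open
#'   genomic intervals in transcription order) and \code{phases}.
#' @slot proteins named list of [Biostrings::AAStringSet], the annotated
#'   proteins per genotype (translation of the annotated, spliced CDS).
#' @slot truth data.frame with columns \code{family_id}, \code{genotype},
#'   \code{event}, \code{chrom}, \code{start}, \code{end}, \code{detail}.
#' @slot founder founder gene set as returned by [buildFounderGenes()].
#' @slot config the [SimConfig-class] used.
#'
#' @exportClass SyntheticPangenome
setClass("SyntheticPangenome",
    representation(
        assemblies  = "list",
        annotations = "list",
        proteins    = "list",
        truth       = "data.frame",
        founder     = "list",
        config      = "SimConfig"
    )
)

setValidity("SyntheticPangenome", function(object) {
    msg <- character()
    gt <- names(object@assemblies)
    if (!identical(gt, names(object@annotations)) ||
        !identical(gt, names(object@proteins)))
        msg <- c(msg, "assembly/annotation/protein genotype names must agree")
    need <- c("family_id", "genotype", "event", "chrom", "start", "end",
              "detail")
    if (!all(need %in% names(object@truth)))
        msg <- c(msg, "truth table lacks required columns")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticPangenome", function(object) {
    cat("SyntheticPangenome:", length(object@assemblies), "genotypes,",
        length(object@founder$genes), "families,",
        nrow(object@truth), "planted events\n")
    if (nrow(object@truth)) {
        tab <- table(object@truth$event)
        cat("  events:", paste(names(tab), tab, sep = "=", collapse = " "),
            "\n")
    }
})

#' Position-specific scoring matrix for domain scanning
#'
#' Ungapped log-odds model of a fixed-length protein domain. Column
#' scores are \code{log2((count + pseudocount * background) /
#' ((n + pseudocount) * background))} per residue. Non-standard residues
#' score 0 in every column.
#'
#' @slot label domain label (e.g. \code{"CCT"}).
#' @slot logOdds residue x column matrix of bit scores.
#' @slot background residue background frequencies (sums to 1).
#'
#' @seealso [buildPSSM()], [scanDomains()], [calibrateNull()]
#' @exportClass PSSM
setClass("PSSM",
    representation(
        label      = "character",
        logOdds    = "matrix",
        background = "numeric"
    )
)

setValidity("PSSM", function(object) {
    msg <- character()
    if (abs(sum(object@background) - 1) > 1e-6)
        msg <- c(msg, "background frequencies must sum to 1")
    if (any(is.na(object@logOdds)))
        msg <- c(msg, "log-odds must not contain NA")
    if (!identical(rownames(object@logOdds), names(object@background)))
        msg <- c(msg, "logOdds rownames must match background names")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PSSM", function(object) {
    cat(sprintf("PSSM '%s': %d columns, max attainable score %.1f bits\n",
        object@label, ncol(object@logOdds),
        sum(apply(object@logOdds, 2L, max))))
})

#' Gene-by-genotype presence matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' \code{copies} holds validated copy counts per gene (rows) and genotype
#' (columns). Row metadata carries the presence count (number of genotypes
#' with at least one copy) and the core/dispensable class: a gene is
#' \emph{core} iff it is present in every genotype.
#'
#' @seealso [buildPresenceMatrix()], [copyCounts()], [geneClass()],
#'   [presenceCount()]
#' @exportClass PresenceMatrix
setClass("PresenceMatrix", contains = "SummarizedExperiment")

setValidity("PresenceMatrix", function(object) {
    msg <- character()
    if (!"copies" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'copies' is required")
    else {
        cc <- SummarizedExperiment::assay(object, "copies")
        if (any(cc < 0) || any(cc != round(cc)))
            msg <- c(msg, "copy counts must be non-negative integers")
        rd <- SummarizedExperiment::rowData(object)
        if (!all(c("presenceCount", "class") %in% names(rd)))
            msg <- c(msg, "rowData must carry presenceCount and class")
        else {
            pc <- rowSums(cc >= 1L)
            if (!all(rd$presenceCount == pc))
                msg <- c(msg, "presenceCount inconsistent with counts")
            if (!all((rd$class == "core") == (pc == ncol(cc))))
                msg <- c(msg, "core class must equal presence in all genotypes")
        }
    }
    if (length(msg)) msg else TRUE
})

#' k-mer PCA result
#'
#' Principal component analysis of a genotype x k-mer frequency matrix.
#' \code{cos2[i, d] = coords[i, d]^2 / sum_d' coords[i, d']^2} measures how
#' much of genotype i's squared distance from the centroid dimension d
#' explains; \code{cos2Plane} sums dimensions 1-2 (the plotted plane).
#'
#' @slot coords genotype x dimension coordinate matrix.
#' @slot explainedVariance percentage of variance per dimension,
#'   non-increasing, summing to <= 100.
#' @slot cos2 genotype x dimension squared-cosine matrix.
#' @slot cos2Plane per-genotype cos2 summed over dimensions 1-2.
#' @slot degenerate TRUE when all rows were identical (all eigenvalues 0).
#' @slot excludedFamily family excluded before the analysis, or NA.
#'
#' @seealso [kmerPCA()], [leaveFamilyOut()]
#' @exportClass PCAResult
setClass("PCAResult",
    representation(
        coords            = "matrix",
        explainedVariance = "numeric",
        cos2              = "matrix",
        cos2Plane         = "numeric",
        degenerate        = "logical",
        excludedFamily    = "character"
    )
)

setValidity("PCAResult", function(object) {
    msg <- character()
    ev <- object@explainedVariance
    if (length(ev) && (any(diff(ev) > 1e-8) || sum(ev) > 100 + 1e-6))
        msg <- c(msg, "explainedVariance must be non-increasing, sum <= 100")
    if (length(object@cos2) && (any(object@cos2 < -1e-9) ||
                                any(object@cos2 > 1 + 1e-9)))
        msg <- c(msg, "cos2 values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PCAResult", function(object) {
    cat("PCAResult:", nrow(object@coords), "genotypes,",
        ncol(object@coords), "dimensions")
    if (!is.na(object@excludedFamily))
        cat(" (excluding family ", object@excludedFamily, ")", sep = "")
    cat("\n")
    if (object@degenerate) {
        cat("  degenerate: all genotype profiles identical\n")
    } else {
        ev <- object@explainedVariance
        cat(sprintf("  Dim1 %.1f%%  Dim2 %.1f%%\n", ev[1L],
                    if (length(ev) > 1L) ev[2L] else 0))
    }
})
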