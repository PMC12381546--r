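#' @importFrom utils head tail
NULL

# map a CDS coordinate (0-based) to a within-gene genomic offset
.cdsToGeneOffset <- function(cdsPos, exonLens, exonStarts) {
    cum <- c(0L, cumsum(exonLens))
    i <- findInterval(cdsPos, cum, rightmost.closed = FALSE,
                      left.open = FALSE)
    i <- min(max(i, 1L), length(exonLens))
    exonStarts[i] + (cdsPos - cum[i])
}

# evolve one gene for one genotype; returns the mutated gene state
.evolveGene <- function(g, config, events) {
    state <- list(deleted = FALSE, truncated = FALSE,
                  indel = NULL, domdel = NULL, gene = g)
    if ("deletion" %in% events) {
        state$deleted <- TRUE
        return(state)
    }
    cds <- .synonymousSubstitute(g$cds, config@substitutionRate)
    intronSeqs <- vapply(g$intronSeqs, .substituteDNA,
                         character(1), rate = config@substitutionRate,
                         USE.NAMES = FALSE)
    exonLens <- g$exonLens
    mod <- intersect(c("indel_1bp", "domain_deletion",
                       "annotation_truncation"), events)[1]
    if (!is.na(mod) && mod == "domain_deletion") {
        aaLen <- (g$cctNtEnd - g$cctNtStart) %/% 3L
        delAa <- max(3L, as.integer(floor(0.6 * aaLen)))
        delLen <- 3L * delAa
        delStart <- g$cctNtStart                     # codon-aligned
        cds <- paste0(substr(cds, 1L, delStart),
                      substring(cds, delStart + delLen + 1L))
        ex <- findInterval(delStart, c(0L, cumsum(exonLens)))
        exonLens[ex] <- exonLens[ex] - delLen
        state$domdel <- list(cdsStart = delStart, len = delLen)
    } else if (!is.na(mod) && mod == "indel_1bp") {
        # interior coding positions only: an indel at or near an exon
        # boundary acts as a splice-site mutation, not the coding-indel
        # phenomenon planted here
        cand <- 30:(nchar(cds) - 33L)
        bnd <- c(0L, cumsum(exonLens))
        near <- unlist(lapply(bnd, function(b) (b - 12L):(b + 12L)))
        p <- .pick(setdiff(cand, near))              # 0-based CDS position
        sign <- .pick(c(-1L, 1L))
        exStart <- bnd[findInterval(p, bnd)]
        if (sign < 0L) {
            # left-normalize within the homopolymer run (and exon) so the
            # recorded position is the canonical one an aligner reports
            while (p > exStart + 1L &&
                   substr(cds, p, p) == substr(cds, p + 1L, p + 1L))
                p <- p - 1L
            cds <- paste0(substr(cds, 1L, p), substring(cds, p + 2L))
        } else {
            b <- .pick(.DNA_BASES)
            while (p > exStart + 1L && substr(cds, p, p) == b)
                p <- p - 1L
            cds <- paste0(substr(cds, 1L, p), b, substring(cds, p + 1L))
        }
        ex <- findInterval(p, c(0L, cumsum(exonLens)))
        exonLens[ex] <- exonLens[ex] + sign
        state$indel <- list(cdsPos = p, sign = sign,
                            upstreamOfCct = p < g$cctNtStart)
    } else if (!is.na(mod)) {
        state$truncated <- TRUE
    }
    gm <- g
    gm$cds <- cds
    gm$exonLens <- exonLens
    gm$intronSeqs <- intronSeqs
    gm$geneSeq <- .assembleGeneSeq(gm)
    state$gene <- gm
    state
}

# annotated protein for a (possibly truncated/frameshifted) gene state
.annotatedProtein <- function(state) {
    g <- state$gene
    cds <- g$cds
    if (state$truncated) {
        nex <- length(g$exonLens)
        if (nex <= 2L) return(NULL)           # annotation lost entirely
        cum <- c(0L, cumsum(g$exonLens))
        retained <- substring(cds, cum[2L] + 1L, cum[nex])
        phase <- (3L - cum[2L] %% 3L) %% 3L
        pep <- translateDNA(retained, frame = phase)
    } else {
        pep <- translateDNA(cds)
    }
    stop_at <- regexpr("*", pep, fixed = TRUE)
    if (stop_at > 0L) pep <- substr(pep, 1L, stop_at - 1L)
    if (nchar(pep) == 0L) NULL else pep
}

# annotation (exon intervals on the genotype assembly) for a gene state
.annotationFor <- function(state, geneStart, chrom) {
    if (state$deleted) return(NULL)
    g <- state$gene
    nex <- length(g$exonLens)
    keep <- seq_len(nex)
    if (state$truncated) {
        if (nex <= 2L) return(NULL)
        keep <- 2:(nex - 1L)
    }
    exonStarts <- .exonGeneStarts(g$exonLens, g$intronSeqs)
    cum <- as.integer(c(0L, cumsum(g$exonLens)))
    exons <- cbind(start = geneStart + exonStarts[keep],
                   end = geneStart + exonStarts[keep] + g$exonLens[keep])
    phases <- vapply(keep, function(i) (3L - cum[i] %% 3L) %% 3L,
                     integer(1))
    list(geneId = g$geneId, familyId = g$familyId, chrom = chrom,
         strand = "+", exons = exons, phases = phases)
}

#' Evolve one genotype from the founder set
#'
#' Draws planted events independently per gene from the configured
#' rates, applies them together with neutral divergence (intergenic and
#' intronic per-site substitutions; synonymous codon substitutions in
#' CDS), and assembles the genotype. A gene deletion suppresses all
#' other events on that gene; of the mutually exclusive coding events at
#' most one is applied per gene (priority: 1-bp indel, then domain
#' deletion, then annotation truncation). Tandem duplicates are inserted
#' 200-2000 bp downstream of the source gene; dispersed duplicates at
#' least 50 kb away. Duplicated copies derive from the founder sequence
#' diverged at \code{duplicateDivergence} per site, and are deliberately
#' left out of the annotation (novel copies are discoverable only from
#' the assembly). An annotation truncation leaves the genomic sequence
#' intact but removes the first and last exon from the annotation and
#' the protein output.
#'
#' @param founder FounderSet from [buildFounderGenes()].
#' @param config a [SimConfig-class].
#' @param genotypeId genotype name.
#' @param streamSeed integer seed for this genotype's RNG stream.
#' @return list with \code{assembly} (named character), \code{annotations}
#'   (list of gene models), \code{proteins} (named character),
#'   \code{truth} (data.frame of planted-event rows).
#' @export
evolveGenotype <- function(founder, config, genotypeId, streamSeed) {
    set.seed(streamSeed)
    genes <- founder$genes
    n <- length(genes)
    chrom <- founder$chrom

    # draw events per gene
    eventList <- lapply(genes, function(g) {
        draws <- runif(length(.EVENT_KINDS)) < config@eventRates
        kinds <- .EVENT_KINDS[draws]
        if ("deletion" %in% kinds) kinds <- "deletion"
        kinds
    })
    states <- lapply(seq_len(n), function(i)
        .evolveGene(genes[[i]], config, eventList[[i]]))

    # duplicate copies: (source gene, mode, target intergenic, offset)
    dups <- list()
    igLens <- nchar(founder$intergenic)
    geneLens <- vapply(genes, function(g) nchar(g$geneSeq), numeric(1))
    segStart <- numeric(n + 1L)   # founder-coordinate start of intergenic i
    pos <- 0
    for (i in seq_len(n + 1L)) {
        segStart[i] <- pos
        pos <- pos + igLens[i] + if (i <= n) geneLens[i] else 0
    }
    for (i in seq_len(n)) {
        kinds <- eventList[[i]]
        for (mode in intersect(c("tandem_duplication",
                                 "dispersed_duplication"), kinds)) {
            copySeq <- .substituteDNA(genes[[i]]$geneSeq,
                                      config@duplicateDivergence)
            if (mode == "tandem_duplication") {
                tgt <- i + 1L                      # intergenic after gene i
                off <- min(.pick(200:2000), igLens[tgt] - 1L)
            } else {
                geneAt <- segStart[i] + igLens[i]
                dist <- abs(segStart - geneAt)
                ok <- which(dist >= 50000 & igLens > 200L)
                tgt <- if (length(ok)) .pick(ok) else which.max(dist)
                off <- .pick(100:max(100L, igLens[tgt] - 100L))
                off <- min(off, igLens[tgt] - 1L)
            }
            dups[[length(dups) + 1L]] <- list(src = i, mode = mode,
                                              tgt = tgt, offset = off,
                                              seq = copySeq)
        }
    }

    # assemble the chromosome left to right
    pieces <- character(0)
    truth <- list()
    annotations <- list()
    proteins <- character(0)
    addTruth <- function(fam, ev, s, e, detail)
        truth[[length(truth) + 1L]] <<- data.frame(
            family_id = fam, genotype = genotypeId, event = ev,
            chrom = chrom, start = s, end = e, detail = detail,
            stringsAsFactors = FALSE)
    pos <- 0L
    copyTally <- setNames(integer(n), names(genes))
    for (i in seq_len(n + 1L)) {
        ig <- .substituteDNA(founder$intergenic[i],
                             config@substitutionRate)
        myDups <- Filter(function(d) d$tgt == i, dups)
        if (length(myDups)) {
            myDups <- myDups[order(vapply(myDups, `[[`, numeric(1),
                                          "offset"))]
            igPieces <- character(0)
            cursor <- 0L
            walk <- pos
            for (d in myDups) {
                igPieces <- c(igPieces,
                              substring(ig, cursor + 1L, d$offset))
                walk <- walk + (d$offset - cursor)
                fam <- genes[[d$src]]$familyId
                copyTally[fam] <- copyTally[fam] + 1L
                addTruth(fam, d$mode, walk, walk + nchar(d$seq),
                         sprintf("copy_index=%d;mode=%s",
                                 copyTally[fam], d$mode))
                igPieces <- c(igPieces, d$seq)
                walk <- walk + nchar(d$seq)
                cursor <- d$offset
            }
            igPieces <- c(igPieces, substring(ig, cursor + 1L))
            ig <- paste(igPieces, collapse = "")
        }
        pieces <- c(pieces, ig)
        pos <- pos + nchar(ig)
        if (i <= n) {
            st <- states[[i]]
            g <- st$gene
            fam <- g$familyId
            if (st$deleted) {
                addTruth(fam, "deletion", pos, pos,
                         sprintf("founder_len=%d", nchar(genes[[i]]$geneSeq)))
                next
            }
            geneStart <- pos
            ann <- .annotationFor(st, geneStart, chrom)
            if (!is.null(ann))
                annotations[[g$geneId]] <- ann
            pep <- .annotatedProtein(st)
            if (!is.null(ann) && !is.null(pep))
                proteins[g$geneId] <- pep
            if (!is.null(st$indel)) {
                exonStarts <- .exonGeneStarts(g$exonLens, g$intronSeqs)
                gpos <- geneStart +
                    .cdsToGeneOffset(st$indel$cdsPos, g$exonLens,
                                     exonStarts)
                addTruth(fam, "indel_1bp", gpos,
                         gpos + max(0L, -st$indel$sign),
                         sprintf("cds_pos=%d;sign=%+d;upstream_of_cct=%d",
                                 st$indel$cdsPos, st$indel$sign,
                                 as.integer(st$indel$upstreamOfCct)))
            }
            if (!is.null(st$domdel)) {
                exonStarts <- .exonGeneStarts(g$exonLens, g$intronSeqs)
                gpos <- geneStart +
                    .cdsToGeneOffset(st$domdel$cdsStart, g$exonLens,
                                     exonStarts)
                addTruth(fam, "domain_deletion", gpos, gpos,
                         sprintf("cds_start=%d;len=%d",
                                 st$domdel$cdsStart, st$domdel$len))
            }
            if (st$truncated) {
                addTruth(fam, "annotation_truncation", geneStart,
                         geneStart + nchar(g$geneSeq),
                         "exons_removed=first,last")
            }
            pieces <- c(pieces, g$geneSeq)
            pos <- pos + nchar(g$geneSeq)
        }
    }

    truthDf <- if (length(truth)) do.call(rbind, truth) else
        data.frame(family_id = character(), genotype = character(),
                   event = character(), chrom = character(),
                   start = integer(), end = integer(), detail = character(),
                   stringsAsFactors = FALSE)
    assembly <- setNames(paste(pieces, collapse = ""), chrom)
    list(assembly = assembly, annotations = annotations,
         proteins = proteins, truth = truthDf)
}

#' Simulate a synthetic pangenome with ground truth
#'
#' Generates founders once from the master seed and evolves each
#' genotype on an independent RNG stream derived from it, so any
#' genotype is reproducible in isolation and identical configurations
#' yield byte-identical output.
#'
#' @param config a [SimConfig-class] (see [simConfig()]).
#' @param templates domain templates; default [domainLibrary()].
#' @return A [SyntheticPangenome-class].
#' @examples
#' pg <- simulatePangenome(simConfig(nGenotypes = 3, nFamilies = 3,
#'     genomeLength = 60000L, seed = 7))
#' pg
#' @export
simulatePangenome <- function(config, templates = domainLibrary()) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config@seed)
    founder <- buildFounderGenes(templates, config)
    streamSeeds <- sample.int(99999999L, config@nGenotypes)
    gt <- sprintf("G%02d", seq_len(config@nGenotypes))
    assemblies <- list(); annotations <- list(); proteins <- list()
    truth <- list()
    for (i in seq_len(config@nGenotypes)) {
        ev <- evolveGenotype(founder, config, gt[i], streamSeeds[i])
        assemblies[[gt[i]]] <- Biostrings::DNAStringSet(ev$assembly)
        annotations[[gt[i]]] <- ev$annotations
        proteins[[gt[i]]] <- if (length(ev$proteins))
            Biostrings::AAStringSet(ev$proteins) else
            Biostrings::AAStringSet()
        truth[[i]] <- ev$truth
    }
    truthDf <- do.call(rbind, truth)
    rownames(truthDf) <- NULL
    new("SyntheticPangenome", assemblies = assemblies,
        annotations = annotations, proteins = proteins, truth = truthDf,
        founder = founder, config = config)
}

#' @describeIn SyntheticPangenome-class genotype names
#' @param pg a [SyntheticPangenome-class].
#' @export
genotypeNames <- function(pg) names(pg@assemblies)

#' @describeIn SyntheticPangenome-class per-genotype assemblies
#' @export
assemblies <- function(pg) pg@assemblies

#' @describeIn SyntheticPangenome-class per-genotype gene models
#' @export
annotations <- function(pg) pg@annotations

#' @describeIn SyntheticPangenome-class annotated proteins per genotype
#' @export
annotatedProteins <- function(pg) pg@proteins

#' @describeIn SyntheticPangenome-class truth table of planted events
#' @export
truthTable <- function(pg) pg@truth

#' @describeIn SyntheticPangenome-class founder gene models
#' @export
founderGenes <- function(pg) pg@founder$genes
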