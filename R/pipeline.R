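#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
#' @importFrom stats var
NULL

#' Build the PSSM library for a set of domain templates
#'
#' Samples aligned domain instances from each template (consensus plus
#' per-position tolerated substitutions) and builds one PSSM per
#' domain.
#'
#' @param templates from [domainLibrary()].
#' @param nInstances instances sampled per template.
#' @param pseudocount passed to [buildPSSM()].
#' @param seed RNG seed for instance sampling.
#' @return named list of [PSSM-class] objects.
#' @export
pssmLibrary <- function(templates = domainLibrary(), nInstances = 10L,
                        pseudocount = 1, seed = 1L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    lapply(templates, function(tpl) {
        inst <- vapply(seq_len(nInstances),
                       function(i) .instantiateDomain(tpl), character(1))
        buildPSSM(inst, pseudocount = pseudocount, label = tpl$label)
    })
}

#' Calibrate null thresholds for a PSSM library
#'
#' @param pssms from [pssmLibrary()].
#' @param querySetWindows windows in the real query set (rescaling
#'   target of the expected false-hit count).
#' @param decoyLengthTotal,nSamples,seed passed to [calibrateNull()].
#' @return named list of \code{NullCalibration} objects.
#' @export
calibratePssmLibrary <- function(pssms, querySetWindows = 1e4,
                                 decoyLengthTotal = 6e4, nSamples = 150L,
                                 seed = 1L) {
    lapply(pssms, function(p)
        calibrateNull(p, decoyLengthTotal = decoyLengthTotal,
                      nSamples = nSamples, seed = seed,
                      querySetWindows = querySetWindows))
}

#' Validate and check pipeline parameters
#'
#' @param identity minimum search identity to call presence (0, 1].
#' @param coverage minimum query coverage to call presence (0, 1].
#' @param maxGap locus merge gap in bp.
#' @param kSeed seed length for the genomic search.
#' @param k peptide k-mer length for the PCA stage.
#' @param pseudocount PSSM pseudocount weight.
#' @param nInstances PSSM instances per domain template.
#' @param ... rejected; unknown parameters are an error.
#' @return validated parameter list.
#' @export
pipelineParams <- function(identity = 0.9, coverage = 0.8, maxGap = 2000L,
                           kSeed = 15L, k = 3L, pseudocount = 1,
                           nInstances = 10L, ...) {
    extra <- list(...)
    if (length(extra))
        stop("unknown pipeline parameters: ",
             paste(names(extra), collapse = ", "))
    if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
    if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
    if (maxGap < 0) stop("maxGap must be >= 0")
    if (kSeed < 8) stop("kSeed must be >= 8")
    if (k < 1) stop("k must be >= 1")
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    list(identity = identity, coverage = coverage,
         maxGap = as.integer(maxGap), kSeed = as.integer(kSeed),
         k = as.integer(k), pseudocount = pseudocount,
         nInstances = as.integer(nInstances))
}

#' Genomic validation, frameshift and status analysis of gene families
#'
#' For every reference gene model, searches all genotype assemblies,
#' counts merged loci (copies), aligns the reference CDS exon-by-exon
#' to the best locus, detects frameshifts, attempts alternative-start
#' rescue, and reconciles genome-level evidence with the annotated
#' proteins into one status per (gene, genotype).
#'
#' @param refGenes list of reference gene models with fields
#'   \code{geneId}, \code{geneSeq}, \code{cds}, \code{exonLens},
#'   \code{protein} (e.g. [founderGenes()] output, or models built from
#'   a reference genotype).
#' @param assemblies named list of per-genotype
#'   [Biostrings::DNAStringSet].
#' @param annotatedProteins named list of per-genotype
#'   [Biostrings::AAStringSet] keyed by gene id.
#' @param pssms PSSM library from [pssmLibrary()].
#' @param params from [pipelineParams()].
#' @param calibrations optional calibrations from
#'   [calibratePssmLibrary()].
#' @param annotations optional per-genotype gene-model lists; when a
#'   gene is annotated in a genotype, the locus overlapping the
#'   annotated position (rather than the best-scoring locus, which may
#'   be an intact duplicate copy) is the one aligned and
#'   status-checked.
#' @return list with \code{counts} (gene x genotype copy matrix),
#'   \code{status} (long data.frame), \code{frameshifts} (long
#'   data.frame), \code{reports} (nested FrameshiftReport objects),
#'   \code{loci} (per gene), \code{refDomains} (per gene).
#' @export
analyzeFamilies <- function(refGenes, assemblies, annotatedProteins,
                            pssms, params = pipelineParams(),
                            calibrations = NULL, annotations = NULL) {
    gts <- names(assemblies)
    genes <- vapply(refGenes, `[[`, character(1), "geneId")
    counts <- matrix(0L, length(genes), length(gts),
                     dimnames = list(genes, gts))
    statusRows <- list(); fsRows <- list(); lociAll <- list()
    reports <- list(); refDomainsList <- list()
    annDomains <- function(gt, id) {     # hits for the annotated protein
        prots <- annotatedProteins[[gt]]
        if (is.null(prots) || !id %in% names(prots)) return(NULL)
        scanDomainSet(pssms, as.character(prots[[id]]),
                      calibrations = calibrations)
    }
    indices <- lapply(assemblies, kmerIndex, k = params$kSeed)
    # a domain counts as retained only when its hit scores at least this
    # fraction of the reference protein's hit: a majority-deleted domain
    # remnant can still be a statistically significant (E < 1) match
    retainFrac <- 0.7
    retained <- function(hits, refScores) {
        if (!nrow(hits)) return(character(0))
        top <- vapply(split(hits$bitScore, hits$label), max, numeric(1))
        shared <- intersect(names(top), names(refScores))
        names(top)[names(top) %in%
            shared[top[shared] >= retainFrac * refScores[shared]]]
    }
    for (g in refGenes) {
        id <- g$geneId
        refHits <- scanDomainSet(pssms, g$protein,
                                 calibrations = calibrations)
        refDomains <- unique(refHits$label)
        refScores <- vapply(split(refHits$bitScore, refHits$label), max,
                            numeric(1))
        refDomainsList[[id]] <- refDomains
        val <- validateGene(g$geneSeq, assemblies, kSeed = params$kSeed,
                            minIdentity = params$identity,
                            minCoverage = params$coverage,
                            maxGap = params$maxGap, queryId = id,
                            indices = indices)
        counts[id, ] <- val$counts[gts]
        lociAll[[id]] <- do.call(rbind, val$loci)
        for (gt in gts) {
            loci <- val$loci[[gt]]
            if (!nrow(loci)) {
                statusRows[[length(statusRows) + 1L]] <- data.frame(
                    gene = id, genotype = gt, status = "TRUE_DELETION",
                    stringsAsFactors = FALSE)
                next
            }
            best <- loci[which.max(loci$score), ]
            ann <- if (!is.null(annotations)) annotations[[gt]][[id]]
                   else NULL
            if (!is.null(ann)) {
                annA <- min(ann$exons[, "start"])
                annB <- max(ann$exons[, "end"])
                ov <- pmin(loci$end, annB) - pmax(loci$start, annA)
                ov[loci$replicon != ann$chrom] <- -Inf
                if (max(ov) > 0) best <- loci[which.max(ov), ]
            }
            asm <- as.character(assemblies[[gt]][[best$replicon]])
            a <- max(1L, best$start + 1L - 50L)
            b <- min(nchar(asm), best$end + 50L)
            locusSeq <- substr(asm, a, b)
            if (best$strand == "-") locusSeq <- revComp(locusSeq)
            aln <- tryCatch(
                exonAwareAlignCds(g$cds, g$exonLens, locusSeq),
                error = function(e) NULL)
            if (is.null(aln)) {
                statusRows[[length(statusRows) + 1L]] <- data.frame(
                    gene = id, genotype = gt, status = "TRUE_DELETION",
                    stringsAsFactors = FALSE)
                next
            }
            fs <- detectFrameshift(aln)
            if (fs$frameshift)
                fs <- rescueAlternativeStart(fs, pssms,
                                             calibrations = calibrations)
            variantPep <- translateDNA(aln$variantCds)
            vHits <- scanDomainSet(pssms, variantPep,
                                   calibrations = calibrations)
            annHits <- annDomains(gt, id)
            st <- geneStatus(
                locusFound = TRUE, frameshift = fs$frameshift,
                prematureStop = !is.na(fs$prematureStop),
                identity = aln$identity, coverage = aln$coverage,
                refDomains = refDomains,
                variantDomains = retained(vHits, refScores),
                annotatedDomains = if (is.null(annHits)) NULL else
                    retained(annHits, refScores),
                identityThr = params$identity,
                coverageThr = params$coverage)
            statusRows[[length(statusRows) + 1L]] <- data.frame(
                gene = id, genotype = gt, status = st,
                stringsAsFactors = FALSE)
            reports[[id]][[gt]] <- fs
            fsRows[[length(fsRows) + 1L]] <- data.frame(
                gene = id, genotype = gt, nIndels = nrow(fs$indels),
                netShift = fs$netShift, frameshift = fs$frameshift,
                prematureStop = fs$prematureStop,
                altStart = fs$altStart,
                retainedDomains = paste(fs$retainedDomains,
                                        collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    list(counts = counts,
         status = do.call(rbind, statusRows),
         frameshifts = do.call(rbind, fsRows),
         reports = reports, loci = lociAll,
         refDomains = refDomainsList)
}

#' Run the full pipeline on a simulated pangenome
#'
#' Chains the stages in identification-pipeline order: simulate, domain
#' scan and family classification of annotated proteins, genomic
#' validation (presence matrix), frameshift/rescue/status, phylogeny
#' (frameshift variants excluded), and genotype k-mer PCA. Each stage's
#' outputs are written before the next starts; a manifest with the
#' configuration, input checksums and per-stage record counts is
#' written last.
#'
#' @param config a [SimConfig-class] driving the simulation (its seed
#'   drives every stage).
#' @param outDir output directory.
#' @param params from [pipelineParams()].
#' @param verbose emit per-stage progress messages.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config = simConfig(), outDir,
                        params = pipelineParams(), verbose = TRUE) {
    say <- function(...) if (verbose) message("[panfam] ", ...)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stageCounts <- list()

    say("stage 1/6: simulate pangenome (", config@nGenotypes,
        " genotypes, ", config@nFamilies, " families)")
    pg <- simulatePangenome(config)
    simDir <- file.path(outDir, "simulated")
    files <- writePangenome(pg, simDir)
    stageCounts$simulate <- c(genotypes = config@nGenotypes,
                              plantedEvents = nrow(truthTable(pg)))

    say("stage 2/6: domain scan + family classification")
    pssms <- pssmLibrary(seed = config@seed,
                         pseudocount = params$pseudocount,
                         nInstances = params$nInstances)
    allProt <- unlist(lapply(annotatedProteins(pg), length))
    cals <- calibratePssmLibrary(pssms,
        querySetWindows = max(1, sum(allProt)) * 200,
        seed = config@seed)
    classRows <- list()
    for (gt in genotypeNames(pg)) {
        prots <- annotatedProteins(pg)[[gt]]
        for (id in names(prots)) {
            hits <- scanDomainSet(pssms, as.character(prots[[id]]),
                                  calibrations = cals)
            cl <- classifyFamily(hits)
            classRows[[length(classRows) + 1L]] <- data.frame(
                genotype = gt, gene = id, class = cl$class,
                flagged = cl$flagged, nDomains = nrow(hits),
                stringsAsFactors = FALSE)
        }
    }
    classification <- do.call(rbind, classRows)
    write.table(classification, file.path(outDir, "classification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stageCounts$classify <- c(proteins = nrow(classification))
    say("  classified ", nrow(classification), " proteins: ",
        paste(names(table(classification$class)),
              table(classification$class), sep = "=", collapse = " "))

    say("stage 3/6: genomic validation + presence matrix")
    ana <- analyzeFamilies(founderGenes(pg), assemblies(pg),
                           annotatedProteins(pg), pssms, params,
                           calibrations = cals,
                           annotations = annotations(pg))
    pm <- buildPresenceMatrix(ana$counts)
    write.table(data.frame(gene = rownames(copyCounts(pm)),
                           copyCounts(pm), check.names = FALSE),
                file.path(outDir, "presence_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    loci <- do.call(rbind, ana$loci)
    write.table(loci, file.path(outDir, "loci.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stageCounts$validate <- c(
        loci = nrow(loci),
        core = sum(geneClass(pm) == "core"),
        dispensable = sum(geneClass(pm) == "dispensable"))
    say("  ", stageCounts$validate[["core"]], " core / ",
        stageCounts$validate[["dispensable"]], " dispensable genes")

    say("stage 4/6: frameshift detection + status assignment")
    write.table(ana$frameshifts, file.path(outDir, "frameshift.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ana$status, file.path(outDir, "status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stageCounts$status <- table(ana$status$status)
    say("  statuses: ", paste(names(stageCounts$status),
        stageCounts$status, sep = "=", collapse = " "))

    say("stage 5/6: phylogeny of non-frameshift proteins")
    shifted <- ana$status$status == "NATURAL_VARIANT"
    bad <- paste(ana$status$genotype[shifted], ana$status$gene[shifted])
    seqs <- character(0)
    for (gt in genotypeNames(pg)) {
        prots <- annotatedProteins(pg)[[gt]]
        for (id in names(prots)) {
            if (paste(gt, id) %in% bad) next
            seqs[paste(gt, id, sep = "|")] <- as.character(prots[[id]])
        }
    }
    tree <- NULL
    if (length(seqs) >= 3L) {
        dm <- distanceMatrix(seqs)
        tree <- njTree(dm)
        writeNewick(tree, file.path(outDir, "tree.nwk"))
    }
    stageCounts$phylo <- c(tips = length(seqs))

    say("stage 6/6: genotype k-mer PCA (k = ", params$k, ")")
    seqAll <- character(0); gtAll <- character(0); famAll <- character(0)
    for (gt in genotypeNames(pg)) {
        prots <- annotatedProteins(pg)[[gt]]
        for (id in names(prots)) {
            seqAll <- c(seqAll, as.character(prots[[id]]))
            gtAll <- c(gtAll, gt)
            famAll <- c(famAll, id)
        }
    }
    km <- kmerProfile(seqAll, factor(gtAll, levels = genotypeNames(pg)),
                      k = params$k)
    pca <- kmerPCA(km)
    write.table(data.frame(genotype = rownames(pcaCoords(pca)),
                           pcaCoords(pca), cos2_12 = pca@cos2Plane,
                           check.names = FALSE),
                file.path(outDir, "pca_coords.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(dimension = seq_along(explainedVariance(pca)),
                           explained_variance = explainedVariance(pca)),
                file.path(outDir, "pca_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stageCounts$pca <- c(dimensions = ncol(pcaCoords(pca)))
    say("  Dim1 ", round(explainedVariance(pca)[1], 1), "% / Dim2 ",
        round(explainedVariance(pca)[2], 1), "%")

    manifest <- list(
        tool = "panfam",
        version = as.character(utils::packageVersion("panfam")),
        timestamp = format(Sys.time(), tz = "UTC"),
        config = list(
            nGenotypes = config@nGenotypes, nFamilies = config@nFamilies,
            genomeLength = config@genomeLength,
            substitutionRate = config@substitutionRate,
            eventRates = as.list(config@eventRates),
            duplicateDivergence = config@duplicateDivergence,
            seed = config@seed),
        params = params,
        inputChecksums = as.list(md5sum(sort(files))),
        stageCounts = lapply(stageCounts, as.list))
    write_json(manifest, file.path(outDir, "manifest.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(pangenome = pg, classification = classification,
                   presence = pm, analysis = ana, tree = tree,
                   pca = pca, manifest = manifest))
}
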