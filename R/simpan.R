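#' @importFrom stats runif
NULL

# ---- small sequence helpers (internal) --------------------------------------

# sample one element of a vector (safe for length-1 vectors)
.pick <- function(v) v[sample.int(length(v), 1L)]

.randDNA <- function(n) {
    if (n <= 0L) return("")
    paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
}

.randPeptide <- function(n) {
    if (n <= 0L) return("")
    paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

# substitute each site with probability `rate` to a different base
.substituteDNA <- function(seq, rate) {
    n <- nchar(seq)
    if (n == 0L || rate <= 0) return(seq)
    idx <- which(runif(n) < rate)
    if (!length(idx)) return(seq)
    chars <- strsplit(seq, "")[[1L]]
    chars[idx] <- vapply(chars[idx], function(b)
        sample(setdiff(.DNA_BASES, b), 1L), character(1))
    paste(chars, collapse = "")
}

.SYN_CODONS <- local({
    gc <- Biostrings::GENETIC_CODE
    split(names(gc), unname(gc))
})

.backTranslate <- function(protein) {
    aa <- strsplit(protein, "")[[1L]]
    paste(vapply(aa, function(a) {
        cods <- .SYN_CODONS[[a]]
        cods[sample.int(length(cods), 1L)]
    }, character(1)), collapse = "")
}

# synonymous substitutions: with prob `rate` per codon, swap to a random
# synonymous codon (single-codon amino acids are left untouched)
.synonymousSubstitute <- function(cds, rate) {
    n <- nchar(cds) %/% 3L
    if (n == 0L || rate <= 0) return(cds)
    codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    idx <- which(runif(n) < rate)
    idx <- setdiff(idx, 1L)                 # keep the ATG
    for (i in idx) {
        aa <- Biostrings::GENETIC_CODE[[codons[i]]]
        alt <- setdiff(.SYN_CODONS[[aa]], codons[i])
        if (length(alt)) codons[i] <- alt[sample.int(length(alt), 1L)]
    }
    paste(codons, collapse = "")
}

# ---- domain template library ------------------------------------------------

.DOMAIN_CONSENSI <- c(
    CCT  = "REARVLRYREKRKTRKFDKTIRYASRKAYAE",
    BBOX = "CELCGGAAAVHCAADSAFLCRECDAKVHGANF",
    PRR  = "VLIVDDSSVDRTVISGLLRKSSYEVTAVDSGK",
    ZF   = "GKGGWQCEKCDKHNVKYPFCNRCGAPKSGH",
    GATA = "CSHCGTTKTPQWRSGPAGPKSLCNACGIRYRK"
)

#' Library of protein domain templates
#'
#' Returns the five domain templates used by the synthetic pangenome:
#' CCT (the conserved C-terminal DNA-binding domain that defines the
#' family), B-box, PRR receiver, zinc finger and GATA. Consensus
#' peptides are fixed, mutually dissimilar (pairwise global-alignment
#' identity below 40\%) and carry a per-position substitution tolerance:
#' structurally anchoring residues (cysteines and the first three
#' positions) never vary, the remaining columns vary with probability
#' 0.08 when a domain instance is planted in a founder protein.
#'
#' @param seed accepted for interface stability; the library is a fixed
#'   deterministic set.
#' @return named list of \code{DomainTemplate} objects (lists with
#'   \code{label}, \code{consensus}, \code{variability}).
#' @export
domainLibrary <- function(seed = 1L) {
    lapply(setNames(names(.DOMAIN_CONSENSI), names(.DOMAIN_CONSENSI)),
           function(lab) {
        cons <- .DOMAIN_CONSENSI[[lab]]
        chars <- strsplit(cons, "")[[1L]]
        var <- rep(0.08, length(chars))
        var[chars == "C"] <- 0
        var[1:3] <- 0
        structure(list(label = lab, consensus = cons, variability = var),
                  class = "DomainTemplate")
    })
}

# instantiate a domain: per-column substitution with prob = variability
.instantiateDomain <- function(template) {
    chars <- strsplit(template$consensus, "")[[1L]]
    hit <- runif(length(chars)) < template$variability
    chars[hit] <- vapply(chars[hit], function(a)
        sample(setdiff(.AA20, a), 1L), character(1))
    paste(chars, collapse = "")
}

.ARCH_COMPANION <- c(CMF = NA, CO = "BBOX", PRR = "PRR", GATA = "GATA",
                     ZCCT = "ZF")

# ---- founder construction ---------------------------------------------------

#' Construct founder genes for a synthetic pangenome
#'
#' Builds one founder gene per family on a shared neutral background
#' chromosome. Family architectures cycle through CMF (CCT only), CO
#' (CCT + B-box), PRR (CCT + receiver), GATA (CCT + GATA) and ZCCT
#' (CCT + zinc finger), so any configuration with at least three
#' families contains a CCT-only, a CCT+B-box and a CCT+PRR family. Each
#' founder has an exon/intron model whose CDS starts with ATG and ends
#' with a stop codon; the CCT domain is encoded entirely within the last
#' exon, companion domains within interior exons (so that removing the
#' terminal exons from the annotation mimics a CCT-truncating
#' misannotation), and an in-frame methionine sits a few residues
#' upstream of the CCT domain as a natural alternative-start candidate.
#' Genes are placed non-overlapping with at least 2 kb spacing.
#'
#' @param templates domain template list from [domainLibrary()].
#' @param config a [SimConfig-class]. The RNG state is taken as-is; call
#'   via [simulatePangenome()] for seeded generation.
#' @return FounderSet: list with \code{genes} (per-family gene models),
#'   \code{intergenic} (background segment sequences), \code{chrom}.
#' @export
buildFounderGenes <- function(templates, config) {
    if (!length(templates)) stop("templates must be nonempty")
    archs <- rep(names(.ARCH_COMPANION),
                 length.out = config@nFamilies)
    ids <- character(config@nFamilies)
    tally <- setNames(integer(length(.ARCH_COMPANION)),
                      names(.ARCH_COMPANION))
    for (i in seq_len(config@nFamilies)) {
        a <- archs[i]
        tally[a] <- tally[a] + 1L
        ids[i] <- paste0(a, tally[a])
    }
    nex_range <- config@exonsPerGene
    genes <- vector("list", config@nFamilies)
    for (i in seq_len(config@nFamilies)) {
        genes[[i]] <- .buildFounderGene(ids[i], archs[i], templates,
                                        nex_range)
    }
    names(genes) <- ids
    geneLens <- vapply(genes, function(g) nchar(g$geneSeq), numeric(1))
    spare <- config@genomeLength - sum(geneLens) -
        2000 * (config@nFamilies + 1L)
    if (spare < 0)
        stop("genome too short for ", config@nFamilies, " genes: need >= ",
             sum(geneLens) + 2000 * (config@nFamilies + 1L), " bp")
    w <- runif(config@nFamilies + 1L)
    extra <- floor(spare * w / sum(w))
    extra[1L] <- extra[1L] + (spare - sum(extra))
    igLens <- 2000L + as.integer(extra)
    intergenic <- vapply(igLens, .randDNA, character(1))
    list(genes = genes, intergenic = intergenic, chrom = "chr1")
}

.buildFounderGene <- function(id, arch, templates, nex_range) {
    Laa <- sample(170:230, 1L)
    comp <- .ARCH_COMPANION[[arch]]
    compStart <- if (!is.na(comp)) sample(12:18, 1L) else NA_integer_
    compSeq <- if (!is.na(comp)) .instantiateDomain(templates[[comp]])
               else NULL
    compEnd <- if (!is.na(comp)) compStart + nchar(compSeq) - 1L
               else NA_integer_
    cctSeq <- .instantiateDomain(templates[["CCT"]])
    cctEnd <- Laa - sample(5:10, 1L)
    cctStart <- cctEnd - nchar(cctSeq) + 1L
    anchorAa <- cctStart - sample(4:8, 1L)

    chars <- strsplit(.randPeptide(Laa), "")[[1L]]
    chars[1L] <- "M"
    if (!is.na(comp))
        chars[compStart:compEnd] <- strsplit(compSeq, "")[[1L]]
    chars[anchorAa] <- "M"
    chars[cctStart:cctEnd] <- strsplit(cctSeq, "")[[1L]]
    protein <- paste(chars, collapse = "")

    cds <- paste0(.backTranslate(protein),
                  sample(c("TAA", "TGA", "TAG"), 1L))
    cdsLen <- nchar(cds)
    cctNtStart <- 3L * (cctStart - 1L)           # 0-based on CDS
    cctNtEnd <- 3L * cctEnd
    compNtStart <- if (!is.na(comp)) 3L * (compStart - 1L) else NA_integer_
    compNtEnd <- if (!is.na(comp)) 3L * compEnd else NA_integer_

    nex <- .pick(seq(nex_range[1L], nex_range[2L]))
    lowMid <- if (!is.na(comp)) compNtEnd + 6L else 60L
    highMid <- cctNtStart - 12L
    boundaries <- integer(0)
    if (nex >= 2L) {
        if (nex >= 3L) {
            b1hi <- if (!is.na(comp)) compNtStart - 3L else 45L
            boundaries <- .pick(24:max(24L, b1hi))
            nmid <- nex - 2L
            if (nmid > 0L) {
                cand <- seq(lowMid, highMid, by = 21L)
                boundaries <- c(boundaries,
                                sort(sample(cand, nmid)))
            }
        } else {
            boundaries <- .pick(seq(lowMid, highMid, by = 21L))
        }
    }
    exonLens <- as.integer(diff(c(0L, boundaries, cdsLen)))
    intronLens <- if (nex > 1L) sample(80:300, nex - 1L, replace = TRUE)
                  else integer(0)
    intronSeqs <- vapply(intronLens, function(n)
        paste0("GT", .randDNA(n - 4L), "AG"), character(1))

    g <- list(geneId = id, familyId = id, arch = arch, protein = protein,
              cds = cds, exonLens = exonLens, intronSeqs = intronSeqs,
              anchorAa = anchorAa,
              cctNtStart = cctNtStart, cctNtEnd = cctNtEnd,
              cctAaStart = cctStart, cctAaEnd = cctEnd,
              compLabel = comp, compNtStart = compNtStart,
              compNtEnd = compNtEnd)
    g$geneSeq <- .assembleGeneSeq(g)
    g
}

# splice model -> genomic gene sequence, and exon starts within the gene
.assembleGeneSeq <- function(g) {
    ends <- cumsum(g$exonLens)
    starts <- c(0L, utils::head(ends, -1L))
    exonSeqs <- substring(g$cds, starts + 1L, ends)
    pieces <- character(0)
    for (i in seq_along(exonSeqs)) {
        pieces <- c(pieces, exonSeqs[i])
        if (i < length(exonSeqs)) pieces <- c(pieces, g$intronSeqs[i])
    }
    paste(pieces, collapse = "")
}

.exonGeneStarts <- function(exonLens, intronSeqs) {
    intronLens <- nchar(intronSeqs)
    starts <- integer(length(exonLens))
    pos <- 0L
    for (i in seq_along(exonLens)) {
        starts[i] <- pos
        pos <- pos + exonLens[i] +
            if (i < length(exonLens)) intronLens[i] else 0L
    }
    starts
}

.cdsPhases <- function(exonLens) {
    cum <- c(0L, cumsum(exonLens))
    vapply(seq_along(exonLens), function(i)
        (3L - cum[i] %% 3L) %% 3L, integer(1))
}

#' Construct a simulation configuration
#'
#' Defaults describe the reference desk-scale study condition: 12
#' genotypes, 8 families, 0.5 Mb per genotype, 3-4 exons per gene,
#' 2\% neutral divergence, and per-gene-per-genotype event
#' probabilities of 5\% for deletions, tandem duplications, 1-bp coding
#' indels and annotation truncations, and 3\% for dispersed duplications
#' and partial domain deletions.
#'
#' @param nGenotypes,nFamilies,genomeLength,exonsPerGene,substitutionRate
#'   see [SimConfig-class].
#' @param eventRates named per-gene-per-genotype probabilities.
#' @param duplicateDivergence,seed see [SimConfig-class].
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nGenotypes = 12L, nFamilies = 8L,
                      genomeLength = 500000L, exonsPerGene = c(3L, 4L),
                      substitutionRate = 0.02,
                      eventRates = c(deletion = 0.05,
                                     tandem_duplication = 0.05,
                                     dispersed_duplication = 0.03,
                                     indel_1bp = 0.05,
                                     domain_deletion = 0.03,
                                     annotation_truncation = 0.05),
                      duplicateDivergence = 0.02, seed = 1L) {
    new("SimConfig", nGenotypes = as.integer(nGenotypes),
        nFamilies = as.integer(nFamilies),
        genomeLength = as.integer(genomeLength),
        exonsPerGene = as.integer(exonsPerGene),
        substitutionRate = substitutionRate,
        eventRates = eventRates[.EVENT_KINDS],
        duplicateDivergence = duplicateDivergence,
        seed = as.integer(seed))
}
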