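test_that("presence matrix classifies core and dispensable genes", {
    counts <- matrix(c(1L, 1L, 1L,   # core
                       2L, 1L, 3L,   # core with CNV
                       1L, 0L, 1L,   # absent in exactly one
                       0L, 0L, 0L),  # fully absent
                     nrow = 4, byrow = TRUE,
                     dimnames = list(paste0("g", 1:4), paste0("G", 1:3)))
    pm <- buildPresenceMatrix(counts)
    expect_s4_class(pm, "PresenceMatrix")
    expect_equal(unname(geneClass(pm)),
                 c("core", "core", "dispensable", "dispensable"))
    expect_equal(unname(presenceCount(pm)), c(3L, 3L, 2L, 0L))
    # core + dispensable partition the gene set
    expect_equal(sum(geneClass(pm) == "core") +
                 sum(geneClass(pm) == "dispensable"), nrow(counts))
    hist <- presenceHistogram(pm)
    expect_equal(as.integer(hist[c("0", "2", "3")]), c(1L, 1L, 2L))
    expect_error(buildPresenceMatrix(unname(counts)), "column names")
})

test_that("a gene missing from its own source assembly is a consistency error", {
    set.seed(800)
    gene <- random_dna(400)
    asm <- list(G1 = c(chr = random_dna(20000)),
                G2 = c(chr = paste0(random_dna(500), gene,
                                    random_dna(500))))
    expect_error(validateGene(gene, asm, queryId = "g",
                              sourceGenotype = "G1"),
                 "not recovered from its source")
    val <- validateGene(gene, asm, queryId = "g", sourceGenotype = "G2")
    expect_equal(unname(val$counts), c(0L, 1L))
})

test_that("exon-aware alignment is exact on an identical locus", {
    pg <- small_sim()
    g <- founderGenes(pg)[[1]]
    aln <- exonAwareAlignCds(g$cds, g$exonLens, g$geneSeq)
    expect_equal(nrow(aln$indels), 0L)
    expect_equal(length(aln$missingExons), 0L)
    expect_equal(aln$identity, 1)
    expect_equal(aln$coverage, 1)
    expect_equal(aln$variantCds, g$cds)
})

test_that("planted 1-bp and 3-bp indels are read off the alignment", {
    pg <- small_sim()
    g <- founderGenes(pg)[[2]]
    p <- 120L
    locus <- plant_indel(g, p, -1L)
    aln <- exonAwareAlignCds(g$cds, g$exonLens, locus)
    expect_equal(nrow(aln$indels), 1L)
    expect_equal(aln$indels$len, -1L)
    expect_lte(abs(aln$indels$refPos - p), 1L)
    fs <- detectFrameshift(aln)
    expect_true(fs$frameshift)
    expect_equal(fs$netShift, 2L)      # (-1) mod 3
    # in-frame 3-bp deletion: single -3 indel, no frameshift
    locus3 <- plant_indel(g, 120L, -3L)
    aln3 <- exonAwareAlignCds(g$cds, g$exonLens, locus3)
    expect_equal(aln3$indels$len, -3L)
    fs3 <- detectFrameshift(aln3)
    expect_false(fs3$frameshift)
    expect_equal(fs3$netShift, 0L)
})

test_that("compensating indels cancel the net shift but are both listed", {
    set.seed(803)
    cds <- paste0("ATG", random_dna(300), "TAA")
    # apply the downstream deletion first so coordinates stay simple
    locus <- paste0(substr(cds, 1, 200), substring(cds, 202))
    locus <- paste0(substr(locus, 1, 90), "C", substring(locus, 91))
    aln <- exonAwareAlignCds(cds, nchar(cds), locus)
    expect_equal(nrow(aln$indels), 2L)
    expect_setequal(aln$indels$len, c(1L, -1L))
    fs <- detectFrameshift(aln)
    expect_equal(fs$netShift, 0L)
    expect_false(fs$frameshift)
})

test_that("alignment failure on a foreign locus raises an error", {
    set.seed(801)
    pg <- small_sim()
    g <- founderGenes(pg)[[1]]
    expect_error(exonAwareAlignCds(g$cds, g$exonLens, random_dna(2000)),
                 "no exon")
})

test_that("alternative-start rescue requires a qualifying downstream ATG", {
    # frameshift followed by a CDS stripped of every downstream ATG:
    # rescue must return none
    cds <- paste0("ATG", paste(rep("GCT", 60), collapse = ""), "TAA")
    var <- paste0("ATGG", substring(cds, 4))   # +1 insertion after ATG
    report <- structure(list(
        indels = data.frame(refPos = 3L, len = 1L, bases = "G"),
        netShift = 1L, frameshift = TRUE, prematureStop = NA_integer_,
        variantCds = var, altStart = NA_integer_,
        rescuedProtein = NA_character_, retainedDomains = character(0)),
        class = "FrameshiftReport")
    out <- rescueAlternativeStart(report, pssms = NULL)
    expect_true(is.na(out$altStart))
})

test_that("copy labels follow the nearest-reference rule with a margin", {
    set.seed(802)
    refs <- c(Ha = random_dna(900), Hb = random_dna(900),
              Hc = random_dna(900))
    # identical locus maps to its reference with identity 1
    res <- classifyCopiesByReference(c(x = refs[["Ha"]]), refs)
    expect_equal(res$label, "Ha")
    expect_equal(res$bestIdentity, 1)
    # simulated queries <= 10% diverged from their source: all correct
    for (i in 1:10) {
        src <- sample(names(refs), 1)
        q <- mutate_dna(refs[[src]], runif(1, 0.02, 0.10))
        res <- classifyCopiesByReference(setNames(q, "q"), refs)
        expect_equal(res$label, src)
    }
    # an exact tie returns AMBIGUOUS
    a <- paste0("AAAA", random_dna(200))
    b <- paste0("TTTT", substring(a, 5))
    q <- paste0("AATT", substring(a, 5))    # 2 mismatches to each
    res <- classifyCopiesByReference(c(q = q), c(A = a, B = b))
    expect_equal(res$label, "AMBIGUOUS")
    expect_error(classifyCopiesByReference(c(q = q), c(A = a)),
                 "at least 2")
})

test_that("status assignment is a total single-valued function", {
    statuses <- c("CONSISTENT", "MISANNOTATION_CANDIDATE",
                  "NATURAL_VARIANT", "PARTIAL_DOMAIN_LOSS",
                  "TRUE_DELETION")
    for (locus in c(TRUE, FALSE)) for (fsh in c(TRUE, FALSE))
        for (stp in c(TRUE, FALSE)) for (idn in c(0.5, 0.95))
            for (cov in c(0.5, 0.95))
                for (annotated in list(NULL, "CCT", c("CCT", "BBOX"))) {
        st <- geneStatus(locus, fsh, stp, idn, cov,
                         refDomains = c("CCT", "BBOX"),
                         variantDomains = c("CCT", "BBOX"),
                         annotatedDomains = annotated)
        expect_length(st, 1L)
        expect_true(st %in% statuses)
    }
    # spot checks of the decision table
    expect_equal(geneStatus(FALSE, FALSE, FALSE, 1, 1, "CCT", "CCT"),
                 "TRUE_DELETION")
    expect_equal(geneStatus(TRUE, TRUE, FALSE, 1, 1, "CCT", "CCT", "CCT"),
                 "NATURAL_VARIANT")
    expect_equal(geneStatus(TRUE, FALSE, FALSE, 1, 1, "CCT",
                            character(0), "CCT"), "PARTIAL_DOMAIN_LOSS")
    expect_equal(geneStatus(TRUE, FALSE, FALSE, 1, 1, "CCT", "CCT", "CCT"),
                 "CONSISTENT")
    expect_equal(geneStatus(TRUE, FALSE, FALSE, 1, 1, "CCT", "CCT", NULL),
                 "MISANNOTATION_CANDIDATE")
})

test_that("presence-phenotype crosstab conserves marginals", {
    counts <- matrix(c(rep(1L, 10), 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L,
                       1L),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("gene1", "vrn2like"),
                                     paste0("G", 1:10)))
    labels <- setNames(c(rep("spring", 6), rep("winter", 3), "unknown"),
                       paste0("G", 1:10))
    tab <- crosstabPresencePhenotype(buildPresenceMatrix(counts),
                                     labels, "vrn2like")
    expect_equal(sum(tab), 10)
    # the VRN2-like gene was deleted in exactly the 6 spring genotypes
    expect_equal(tab["absent", "spring"], 6L)
    expect_equal(tab["present", "winter"], 3L)
    tabAll <- crosstabPresencePhenotype(buildPresenceMatrix(counts),
                                        labels, "gene1")
    expect_true(all(tabAll["absent", ] == 0L))
    expect_error(crosstabPresencePhenotype(buildPresenceMatrix(counts),
                                           labels[1:5], "gene1"),
                 "label missing")
})
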