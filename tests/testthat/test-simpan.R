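test_that("domain template library is fixed, labelled and dissimilar", {
    lib <- domainLibrary(seed = 1)
    expect_setequal(names(lib), c("CCT", "BBOX", "PRR", "ZF", "GATA"))
    lib2 <- domainLibrary(seed = 1)
    expect_identical(lapply(lib, `[[`, "consensus"),
                     lapply(lib2, `[[`, "consensus"))
    expect_true(all(vapply(lib, function(t) nchar(t$consensus), 1) >= 10))
    sch <- scoringScheme("protein")
    labs <- names(lib)
    for (i in 1:4) for (j in (i + 1):5) {
        id <- globalAlign(lib[[i]]$consensus, lib[[j]]$consensus,
                          sch)@identity
        expect_lt(id, 0.4)
    }
})

test_that("founder genes satisfy their structural contract", {
    pg <- small_sim()
    genes <- founderGenes(pg)
    archs <- vapply(genes, `[[`, "", "arch")
    expect_true(all(c("CMF", "CO", "PRR") %in% archs))
    for (g in genes) {
        expect_equal(nchar(g$cds) %% 3, 0)
        expect_equal(substr(g$cds, 1, 3), "ATG")
        expect_true(substr(g$cds, nchar(g$cds) - 2, nchar(g$cds)) %in%
                        c("TAA", "TGA", "TAG"))
        expect_equal(sum(g$exonLens), nchar(g$cds))
        expect_equal(translateDNA(g$cds), paste0(g$protein, "*"))
        # an in-frame methionine precedes the CCT domain (rescue anchor)
        expect_equal(substr(g$protein, g$anchorAa, g$anchorAa), "M")
        expect_lt(g$anchorAa, g$cctAaStart)
    }
    # planted domains are recoverable from the founder proteins by scan
    pssms <- pssmLibrary(seed = 9)
    comp <- c(CMF = NA, CO = "BBOX", PRR = "PRR", GATA = "GATA",
              ZCCT = "ZF")
    for (g in genes) {
        labs <- unique(scanDomainSet(pssms, g$protein,
                                     thresholds = list(CCT = 40, BBOX = 40,
                                                       PRR = 40, ZF = 40,
                                                       GATA = 40))$label)
        expect_true("CCT" %in% labs)
        if (!is.na(comp[g$arch])) expect_true(comp[[g$arch]] %in% labs)
    }
})

test_that("single-exon configuration forces single-exon founders", {
    cfg <- simConfig(nGenotypes = 2, nFamilies = 3,
                     genomeLength = 40000L, exonsPerGene = c(1, 1),
                     seed = 3)
    pg <- simulatePangenome(cfg)
    for (g in founderGenes(pg)) {
        expect_equal(length(g$exonLens), 1L)
        expect_equal(g$geneSeq, g$cds)
    }
})

test_that("infeasible genome size raises a sizing error", {
    expect_error(simulatePangenome(
        simConfig(nGenotypes = 2, nFamilies = 5, genomeLength = 10000L)),
        "genome too short")
})

test_that("simulation is deterministic in the seed", {
    cfg <- simConfig(nGenotypes = 3, nFamilies = 3,
                     genomeLength = 60000L, seed = 5L)
    pg1 <- small_sim()
    pg2 <- simulatePangenome(cfg)
    expect_identical(lapply(assemblies(pg1), as.character),
                     lapply(assemblies(pg2), as.character))
    expect_identical(truthTable(pg1), truthTable(pg2))
    expect_identical(lapply(annotatedProteins(pg1), as.character),
                     lapply(annotatedProteins(pg2), as.character))
    # byte-identical files on disk
    d1 <- tempfile(); d2 <- tempfile()
    writePangenome(pg1, d1); writePangenome(pg2, d2)
    f1 <- list.files(d1, full.names = TRUE)
    f2 <- list.files(d2, full.names = TRUE)
    expect_equal(basename(f1), basename(f2))
    expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("a zero-rate configuration evolves nothing", {
    cfg <- simConfig(nGenotypes = 3, nFamilies = 3,
                     genomeLength = 60000L, substitutionRate = 0,
                     eventRates = c(deletion = 0, tandem_duplication = 0,
                                    dispersed_duplication = 0,
                                    indel_1bp = 0, domain_deletion = 0,
                                    annotation_truncation = 0),
                     duplicateDivergence = 0, seed = 8)
    pg <- simulatePangenome(cfg)
    expect_equal(nrow(truthTable(pg)), 0L)
    asm <- lapply(assemblies(pg), as.character)
    expect_identical(asm[[1]], asm[[2]])
    expect_identical(asm[[1]], asm[[3]])
})

test_that("deletion rate 1 removes every gene and records every event", {
    cfg <- simConfig(nGenotypes = 2, nFamilies = 3,
                     genomeLength = 60000L,
                     eventRates = c(deletion = 1, tandem_duplication = 0,
                                    dispersed_duplication = 0,
                                    indel_1bp = 0, domain_deletion = 0,
                                    annotation_truncation = 0),
                     seed = 9)
    pg <- simulatePangenome(cfg)
    tr <- truthTable(pg)
    expect_equal(nrow(tr), 6L)     # 3 families x 2 genotypes
    expect_true(all(tr$event == "deletion"))
    expect_true(all(vapply(annotations(pg), length, 1L) == 0L))
})

test_that("gene counts per genotype follow exact event arithmetic", {
    fx <- full_sim()
    pg <- fx$pg
    tr <- truthTable(pg)
    nFounders <- length(founderGenes(pg))
    for (gt in genotypeNames(pg)) {
        del <- sum(tr$event == "deletion" & tr$genotype == gt)
        # truncation keeps the gene (>= 3 exons by default config)
        expect_equal(length(annotations(pg)[[gt]]), nFounders - del)
    }
    # every truth coordinate lies inside its genotype assembly
    for (i in seq_len(nrow(tr))) {
        r <- tr[i, ]
        expect_lte(r$end,
                   nchar(as.character(assemblies(pg)[[r$genotype]][[r$chrom]])))
        expect_gte(r$start, 0)
    }
})

test_that("annotation truncation removes terminal exons but not sequence", {
    fx <- full_sim()
    pg <- fx$pg
    tr <- truthTable(pg)
    rows <- tr[tr$event == "annotation_truncation", ]
    for (i in seq_len(nrow(rows))) {
        r <- rows[i, ]
        founder <- founderGenes(pg)[[r$family_id]]
        ann <- annotations(pg)[[r$genotype]][[r$family_id]]
        expect_equal(nrow(ann$exons), length(founder$exonLens) - 2L)
        # the genomic span of the gene is structurally intact: same
        # length, and the full reference CDS aligns without indels
        asm <- as.character(assemblies(pg)[[r$genotype]][[r$chrom]])
        expect_equal(r$end - r$start, nchar(founder$geneSeq))
        aln <- exonAwareAlignCds(founder$cds, founder$exonLens,
                                 substr(asm, r$start + 1, r$end))
        expect_equal(nrow(aln$indels), 0L)
        expect_equal(length(aln$missingExons), 0L)
        # annotated protein keeps the companion but has lost the CCT end
        prot <- as.character(annotatedProteins(pg)[[r$genotype]][[r$family_id]])
        expect_false(grepl(substr(founder$protein, founder$cctAaStart,
                                  founder$cctAaEnd), prot, fixed = TRUE))
    }
})
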