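# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

# reference desk-scale study condition: 12 genotypes x 8 families,
# 0.5 Mb per genotype, divergence <= 5%
full_sim <- function() {
    if (is.null(.fixture_cache$full)) {
        cfg <- simConfig(seed = 101L)
        pg <- simulatePangenome(cfg)
        pssms <- pssmLibrary(seed = 101L)
        cals <- calibratePssmLibrary(pssms, querySetWindows = 2e4,
                                     seed = 101L)
        ana <- analyzeFamilies(founderGenes(pg), assemblies(pg),
                               annotatedProteins(pg), pssms,
                               pipelineParams(), calibrations = cals,
                               annotations = annotations(pg))
        .fixture_cache$full <- list(cfg = cfg, pg = pg, pssms = pssms,
                                    cals = cals, ana = ana)
    }
    .fixture_cache$full
}

# tiny pangenome for structural / I/O tests
small_sim <- function() {
    if (is.null(.fixture_cache$small)) {
        cfg <- simConfig(nGenotypes = 3, nFamilies = 3,
                         genomeLength = 60000L, seed = 5L)
        .fixture_cache$small <- simulatePangenome(cfg)
    }
    .fixture_cache$small
}

# copy counts implied by the truth table (1 per founder, minus
# deletions, plus duplications)
truth_counts <- function(pg) {
    tr <- truthTable(pg)
    gts <- genotypeNames(pg)
    fams <- names(founderGenes(pg))
    expected <- matrix(1L, length(fams), length(gts),
                       dimnames = list(fams, gts))
    for (i in seq_len(nrow(tr))) {
        r <- tr[i, ]
        if (r$event == "deletion")
            expected[r$family_id, r$genotype] <- 0L
        if (grepl("duplication", r$event))
            expected[r$family_id, r$genotype] <-
                expected[r$family_id, r$genotype] + 1L
    }
    expected
}

# plant an indel at CDS position p (0-based) into a founder gene's
# genomic sequence, independent of the simulator's own event machinery
plant_indel <- function(g, p, len, base = "G") {
    cum <- c(0L, cumsum(g$exonLens))
    ex <- findInterval(p, cum)
    starts <- panfam:::.exonGeneStarts(g$exonLens, g$intronSeqs)
    gpos <- starts[ex] + (p - cum[ex])
    seq <- g$geneSeq
    if (len < 0)
        paste0(substr(seq, 1, gpos), substring(seq, gpos + 1 - len))
    else
        paste0(substr(seq, 1, gpos),
               paste(rep(base, len), collapse = ""),
               substring(seq, gpos + 1))
}

truth_field <- function(detail, key) {
    as.integer(sub(paste0(".*", key, "=(-?[0-9+]+).*"), "\\1",
                   detail))
}
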