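test_that("k-mer profiles count overlapping peptide k-mers per genotype", {
    m <- kmerProfile("AAAA", "G1", k = 3)
    expect_equal(unname(m["G1", "AAA"]), 1)
    # proteins shorter than k contribute nothing
    m2 <- kmerProfile(c("AK", "AKC"), c("G1", "G1"), k = 3)
    expect_equal(unname(m2["G1", "AKC"]), 1)
    # genotypes with identical protein sets have identical rows
    m3 <- kmerProfile(c("MKVLW", "AKCDE", "MKVLW", "AKCDE"),
                      c("G1", "G1", "G2", "G2"), k = 3)
    expect_equal(unname(m3["G1", ]), unname(m3["G2", ]))
    # nonempty rows are normalized
    expect_equal(unname(rowSums(m3)), c(1, 1))
    # k-mers containing non-standard residues are skipped
    m4 <- kmerProfile("MKXLW", "G1", k = 3)
    expect_false(any(grepl("X", colnames(m4))))
    # empty genotypes keep a flagged all-zero row
    m5 <- kmerProfile("MKVLW", factor("G1", levels = c("G1", "G2")), k = 3)
    expect_equal(attr(m5, "flaggedEmpty"), "G2")
})

test_that("PCA satisfies its variance and cos2 invariants", {
    set.seed(1001)
    seqs <- vapply(1:8, function(i) mutate_protein(
        paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = ""), 0.2), "")
    m <- kmerProfile(seqs, paste0("G", 1:8), k = 3)
    res <- kmerPCA(m)
    ev <- explainedVariance(res)
    expect_true(all(diff(ev) <= 1e-8))
    expect_lte(sum(ev), 100 + 1e-6)
    cs <- rowSums(cos2Values(res))
    expect_equal(unname(cs), rep(1, 8), tolerance = 1e-9)
    expect_true(all(res@cos2Plane >= 0 & res@cos2Plane <= 1 + 1e-9))
    # two distinct genotypes: one dimension carries all variance
    res2 <- kmerPCA(kmerProfile(c("MKVLWCDE", "AAAPQRST"),
                                c("G1", "G2"), k = 3))
    expect_equal(explainedVariance(res2)[1], 100)
    # identical rows: flagged degenerate
    res3 <- kmerPCA(kmerProfile(c("MKVLW", "MKVLW"), c("G1", "G2"), k = 3))
    expect_true(res3@degenerate)
    expect_true(all(pcaCoords(res3) == 0))
})

test_that("PCA is equivariant under genotype permutation", {
    set.seed(1002)
    seqs <- vapply(1:6, function(i) mutate_protein(
        paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = ""), 0.2), "")
    gts <- paste0("G", 1:6)
    m <- kmerProfile(seqs, gts, k = 3)
    perm <- c(4, 2, 6, 1, 3, 5)
    m2 <- m[perm, ]
    r1 <- kmerPCA(m)
    r2 <- kmerPCA(m2)
    expect_equal(explainedVariance(r1), explainedVariance(r2))
    # coordinates match up to a per-dimension sign flip
    for (d in 1:2) {
        x1 <- pcaCoords(r1)[rownames(m2), d]
        x2 <- pcaCoords(r2)[, d]
        expect_true(isTRUE(all.equal(x1, x2, tolerance = 1e-8)) ||
                    isTRUE(all.equal(x1, -x2, tolerance = 1e-8)))
    }
})

test_that("leave-family-out only changes results when the family had sequences", {
    set.seed(1003)
    base <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = "")
    seqs <- c(vapply(1:6, function(i) mutate_protein(base, 0.2), ""))
    gts <- paste0("G", 1:6)
    fams <- rep("famA", 6)
    full <- kmerPCA(kmerProfile(seqs, gts, k = 3))
    # excluding a family absent from every genotype changes nothing
    out <- leaveFamilyOut(seqs, gts, fams, family = "ghost", k = 3)
    expect_equal(pcaCoords(out), pcaCoords(full))
    expect_equal(out@excludedFamily, "ghost")
    # excluding one of two identical families leaves coordinates
    # unchanged up to sign
    seqs2 <- c(seqs, seqs)
    fams2 <- c(rep("famA", 6), rep("famB", 6))
    gts2 <- c(gts, gts)
    r <- leaveFamilyOut(seqs2, gts2, fams2, family = "famB", k = 3)
    for (d in seq_len(ncol(pcaCoords(full)))) {
        x1 <- pcaCoords(full)[, d]; x2 <- pcaCoords(r)[, d]
        expect_true(isTRUE(all.equal(x1, x2, tolerance = 1e-6)) ||
                    isTRUE(all.equal(x1, -x2, tolerance = 1e-6)))
    }
    expect_error(leaveFamilyOut(seqs, gts, fams, family = "famA"),
                 "removes all")
})

test_that("driver ranking orders families by between-group divergence", {
    set.seed(1004)
    base <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = "")
    gts <- paste0("G", 1:8)
    groupA <- gts[1:4]; groupB <- gts[5:8]
    fams <- paste0("fam", 1:4)
    seqs <- character(0); gvec <- character(0); fvec <- character(0)
    driverAllele <- mutate_protein(base, 0.15)
    for (g in gts) for (f in fams) {
        s <- if (f == "fam2" && g %in% groupB) driverAllele else base
        seqs <- c(seqs, s); gvec <- c(gvec, g); fvec <- c(fvec, f)
    }
    rk <- rankDriverGenes(seqs, gvec, fvec, groupA, groupB)
    expect_equal(rk$family[1], "fam2")
    expect_true(all(rk$divergence[-1] == 0))
    # swapping the groups leaves the ranking unchanged
    rk2 <- rankDriverGenes(seqs, gvec, fvec, groupB, groupA)
    expect_equal(rk, rk2)
    # all-identical families all have zero divergence, ties alphabetical
    grid <- expand.grid(g = gts[1:2], f = fams,
                        stringsAsFactors = FALSE)
    rk0 <- rankDriverGenes(rep(base, nrow(grid)), grid$g, grid$f,
                           gts[1], gts[2])
    expect_true(all(rk0$divergence == 0))
    expect_equal(rk0$family, sort(fams))
    expect_error(rankDriverGenes(seqs, gvec, fvec, gts[1:4], gts[4:8]),
                 "disjoint")
})
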