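test_that("PSSM log-odds follow the pseudocount formula", {
    # invariant column, no pseudocount: log2(1 / bg) = log2(20)
    p <- buildPSSM(c("KA", "KA", "KA"), pseudocount = 0)
    expect_equal(unname(p@logOdds["K", 1]), log2(20))
    # counts proportional to background: log-odds 0 in every cell
    inst <- vapply(1:20, function(i)
        paste(rep(rownames(p@logOdds)[i], 2), collapse = ""), "")
    p2 <- buildPSSM(inst, pseudocount = 0)
    expect_true(all(abs(p2@logOdds) < 1e-12))
    # pseudocount -> infinity drives all log-odds to 0
    p3 <- buildPSSM(c("KA", "KA", "KA"), pseudocount = 1e9)
    expect_true(all(abs(p3@logOdds) < 1e-6))
    expect_error(buildPSSM(c("KA", "KAA")), "equal length")
    expect_error(buildPSSM("KA"), "at least 2")
})

test_that("scanning finds the consensus at its maximum score", {
    set.seed(601)
    tpl <- domainLibrary()[["CCT"]]
    pssms <- pssmLibrary(nInstances = 8, seed = 601)
    p <- pssms[["CCT"]]
    hits <- scanDomains(p, tpl$consensus, threshold = 0)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$start, 0L)
    # the consensus maximizes every column sum
    expect_lte(hits$bitScore, sum(apply(p@logOdds, 2, max)) + 1e-9)
    # protein shorter than the model yields nothing
    expect_equal(nrow(scanDomains(p, "MKV", threshold = -1e6)), 0L)
    # consensus planted inside a decoy is located exactly
    for (i in 1:5) {
        pos <- sample(0:160, 1)
        decoy <- mutate_protein(paste(rep("A", 200), collapse = ""), 0.9)
        prot <- paste0(substr(decoy, 1, pos), tpl$consensus,
                       substring(decoy, pos + 1))
        h <- scanDomains(p, prot, threshold = 40)
        expect_equal(h$start, pos)
    }
})

test_that("scan hits are non-overlapping, sorted, and monotone in threshold", {
    set.seed(602)
    pssms <- pssmLibrary(nInstances = 8, seed = 602)
    p <- pssms[["BBOX"]]
    cons <- domainLibrary()[["BBOX"]]$consensus
    prot <- paste0(cons, mutate_protein(cons, 0.2), cons)
    hits <- scanDomains(p, prot, threshold = -1e6)
    if (nrow(hits) > 1) {
        expect_true(all(diff(hits$start) >= pssmWidth(p)))
        expect_true(!is.unsorted(hits$start))
    }
    n_prev <- Inf
    for (thr in c(-1e6, 0, 20, 50, 1e6)) {
        n <- nrow(scanDomains(p, prot, threshold = thr))
        expect_lte(n, n_prev)
        n_prev <- n
    }
})

test_that("null calibration matches its own expectation on fresh decoys", {
    set.seed(603)
    pssms <- pssmLibrary(nInstances = 8, seed = 603)
    p <- pssms[["CCT"]]
    cal <- calibrateNull(p, decoyLengthTotal = 4e4, nSamples = 120,
                         seed = 10, querySetWindows = 4e4)
    # decoy windows score at most 0 bits on average (log-odds vs own null)
    expect_lte(mean(cal$nullScores), 0)
    # scanning a fresh decoy set of the calibrated query size yields a
    # false-hit count within 2x of the expectation of 1
    set.seed(11)
    decoy <- paste(sample(names(p@background), 4e4 + pssmWidth(p),
                          replace = TRUE, prob = p@background),
                   collapse = "")
    nFalse <- nrow(scanDomains(p, decoy, threshold = cal$threshold))
    expect_lte(nFalse, 2)
    # doubling the decoy sample moves the threshold by < 0.5 bits when
    # the threshold sits at an interior tail quantile (decoy windows
    # well in excess of the query-set size)
    calA <- calibrateNull(p, decoyLengthTotal = 1e5, nSamples = 120,
                          seed = 12, querySetWindows = 2e3)
    calB <- calibrateNull(p, decoyLengthTotal = 2e5, nSamples = 240,
                          seed = 13, querySetWindows = 2e3)
    expect_lt(abs(calA$threshold - calB$threshold), 0.5)
    expect_error(calibrateNull(p, nSamples = 10), ">= 100")
})

test_that("family classification implements the overlap rule table", {
    expect_equal(classifyFamily("CCT")$class, "CMF")
    expect_equal(classifyFamily(c("CCT", "BBOX"))$class, "CO")
    expect_equal(classifyFamily(c("CCT", "PRR"))$class, "PRR")
    expect_equal(classifyFamily(c("CCT", "GATA"))$class, "GATA")
    expect_equal(classifyFamily(c("CCT", "ZF"))$class, "ZCCT")
    # companion precedence with multiple companions present
    expect_equal(classifyFamily(c("CCT", "BBOX", "PRR"))$class, "PRR")
    expect_equal(classifyFamily(c("CCT", "ZF", "GATA"))$class, "ZCCT")
    # companion without CCT: flagged as potential CCT-domain deletion
    bb <- classifyFamily("BBOX")
    expect_equal(bb$class, "BBOX_ONLY")
    expect_true(bb$flagged)
    pr <- classifyFamily("PRR")
    expect_equal(pr$class, "PRR_ONLY")
    expect_true(pr$flagged)
    expect_equal(classifyFamily(character(0))$class, "NONE")
    expect_false(classifyFamily(character(0))$flagged)
    # accepts a hit data.frame as produced by the scanner
    expect_equal(classifyFamily(data.frame(label = c("CCT", "BBOX")))$class,
                 "CO")
})
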