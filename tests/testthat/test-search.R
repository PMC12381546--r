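test_that("planted exact copies are found with full identity and coverage", {
    set.seed(501)
    query <- random_dna(300)
    bg <- random_dna(10000)
    subject <- c(chrA = paste0(substr(bg, 1, 5000), query,
                               substring(bg, 5001)))
    hits <- seedExtendSearch(query, subject, queryId = "q")
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$identity, 1)
    expect_equal(hits$coverage, 1)
    expect_equal(hits$strand, "+")
    expect_equal(c(hits$start, hits$end), c(5000L, 5300L))

    # reverse-complement planting reports strand "-" on forward coords
    subject2 <- c(chrA = paste0(substr(bg, 1, 5000), revComp(query),
                                substring(bg, 5001)))
    hits2 <- seedExtendSearch(query, subject2, queryId = "q")
    expect_equal(nrow(hits2), 1L)
    expect_equal(hits2$strand, "-")
    expect_equal(c(hits2$start, hits2$end), c(5000L, 5300L))
})

test_that("no hit is reported without any shared seed k-mer", {
    set.seed(502)
    repeat {
        query <- random_dna(300)
        subject <- random_dna(10000)
        qk <- substring(query, 1:(300 - 14), 15:300)
        qk <- c(qk, substring(revComp(query), 1:(300 - 14), 15:300))
        sk <- substring(subject, 1:(10000 - 14), 15:10000)
        if (!length(intersect(qk, sk))) break
    }
    hits <- seedExtendSearch(query, c(chr = subject))
    expect_equal(nrow(hits), 0L)
})

test_that("search input contracts are enforced", {
    expect_error(seedExtendSearch(random_dna(10), c(chr = random_dna(100))),
                 "shorter than kSeed")
    expect_error(seedExtendSearch(random_dna(100), c(chr = random_dna(200)),
                                  kSeed = 4), ">= 8")
})

test_that("diverged planted copies >= 200 bp are recovered", {
    # recall property at the study conditions: <= 5% per-site divergence,
    # k = 15, identity >= 0.9, coverage >= 0.8
    set.seed(503)
    for (i in 1:15) {
        len <- sample(200:1200, 1)
        query <- random_dna(len)
        copy <- mutate_dna(query, runif(1, 0, 0.05))
        pos <- sample(1000:4000, 1)
        bg <- random_dna(8000)
        subject <- c(chr = paste0(substr(bg, 1, pos), copy,
                                  substring(bg, pos + 1)))
        hits <- seedExtendSearch(query, subject)
        expect_gte(nrow(hits), 1L)
        expect_gte(hits$identity[1], 0.9)
        expect_gte(hits$coverage[1], 0.8)
    }
})

make_hits <- function(starts, ends, qstarts = NULL, qends = NULL,
                      strand = "+") {
    n <- length(starts)
    df <- data.frame(query = "q", replicon = "chr", start = starts,
                     end = ends, strand = strand, identity = 0.95,
                     coverage = 0.9, score = ends - starts,
                     stringsAsFactors = FALSE)
    if (!is.null(qstarts)) { df$qstart <- qstarts; df$qend <- qends }
    df
}

test_that("hit merging bridges gaps up to maxGap", {
    expect_equal(nrow(mergeHits(make_hits(c(100, 300), c(400, 600)))), 1L)
    m <- mergeHits(make_hits(c(100, 300), c(400, 600)))
    expect_equal(c(m$start, m$end), c(100, 600))
    expect_equal(nrow(mergeHits(make_hits(c(0, 10000), c(300, 10300)),
                                maxGap = 2000)), 2L)
    expect_equal(nrow(mergeHits(make_hits(c(0, 400), c(300, 700)),
                                maxGap = 2000)), 1L)
})

test_that("merging keeps full-coverage nearby copies separate", {
    # two copies each covering the whole query must not fuse into one
    # locus even when closer than maxGap; complementary fragments must
    h <- make_hits(c(0, 1500), c(1000, 2500),
                   qstarts = c(0, 0), qends = c(1000, 1000))
    expect_equal(nrow(mergeHits(h, maxGap = 2000)), 2L)
    frag <- make_hits(c(0, 1100), c(1000, 2100),
                      qstarts = c(0, 1000), qends = c(1000, 2000))
    expect_equal(nrow(mergeHits(frag, maxGap = 2000)), 1L)
})

test_that("hit merging is idempotent and order-independent", {
    set.seed(504)
    for (i in 1:10) {
        n <- sample(3:8, 1)
        starts <- sort(sample(0:20000, n))
        h <- make_hits(starts, starts + sample(200:800, n, replace = TRUE))
        m1 <- mergeHits(h)
        m2 <- mergeHits(h[sample(n), ])
        expect_equal(m1, m2)
        m3 <- mergeHits(m1)
        expect_equal(m1[, c("start", "end")], m3[, c("start", "end")])
    }
})
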