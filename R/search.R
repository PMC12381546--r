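# encode all k-mers of a sequence as base-4 numeric codes (A=0..T=3);
# k-mers containing non-ACGT letters encode as NA. k <= 15 keeps codes
# exactly representable (4^15 < 2^31).
.encodeKmers <- function(seq, k) {
    x <- match(strsplit(seq, "")[[1L]], .DNA_BASES) - 1L
    n <- length(x) - k + 1L
    if (n < 1L) return(numeric(0))
    K <- numeric(n)
    valid <- rep(TRUE, n)
    for (j in 0:(k - 1L)) {
        xi <- x[(1L + j):(n + j)]
        valid <- valid & !is.na(xi)
        xi[is.na(xi)] <- 0L
        K <- K * 4 + xi
    }
    K[!valid] <- NA_real_
    K
}

#' Build an exact k-mer index of replicon sequences
#'
#' Sorted numeric-code index of every k-mer position per replicon; used
#' as the seed stage of [seedExtendSearch()]. Building the index once
#' per genotype and passing it to repeated searches avoids re-indexing
#' the same assembly for every gene.
#'
#' @param subject named character vector or [Biostrings::DNAStringSet].
#' @param k seed length (8-15).
#' @return an object of class \code{KmerIndex}.
#' @export
kmerIndex <- function(subject, k = 15L) {
    if (k < 8L || k > 15L) stop("k must be in 8..15")
    if (is(subject, "DNAStringSet")) subject <- as.character(subject)
    if (is.null(names(subject)))
        names(subject) <- paste0("replicon", seq_along(subject))
    idx <- lapply(subject, function(s) {
        K <- .encodeKmers(s, k)
        keep <- which(!is.na(K))
        Kk <- K[keep]
        ord <- order(Kk)
        list(codes = Kk[ord], pos = keep[ord], length = nchar(s))
    })
    structure(list(k = k, replicons = idx, sequences = subject),
              class = "KmerIndex")
}

# seed positions of query k-mer codes in one replicon index:
# returns list(qpos, spos) of matching (query, subject) 1-based starts
.lookupSeeds <- function(repIdx, qcodes, maxHitsPerKmer = 50L) {
    qpos <- which(!is.na(qcodes))
    if (!length(qpos)) return(list(qpos = integer(0), spos = integer(0)))
    qc <- qcodes[qpos]
    hi <- findInterval(qc, repIdx$codes)
    lo <- findInterval(qc - 0.5, repIdx$codes)
    counts <- hi - lo
    sel <- counts > 0L & counts <= maxHitsPerKmer
    if (!any(sel)) return(list(qpos = integer(0), spos = integer(0)))
    reps <- counts[sel]
    sidx <- rep(lo[sel], reps) + sequence(reps)
    list(qpos = rep(qpos[sel], reps), spos = repIdx$pos[sidx])
}

#' Seed-and-extend genomic search
#'
#' In-repo nucleotide homology search: exact k-mer seed matching over
#' both strands (via the reverse complement of the query), chaining of
#' seeds into candidate loci by diagonal bands, and a local-alignment
#' extension of the query against each candidate window. Hits are
#' reported when alignment identity and query coverage pass their
#' thresholds. The diagonal band half-width is
#' \code{20 + 0.05 * query length}, wide enough to tolerate planted
#' indels without aligning the full subject.
#'
#' @param query character scalar, DNA query (length >= \code{kSeed}).
#' @param subject named character vector or [Biostrings::DNAStringSet]
#'   of replicon sequences; ignored when \code{index} is supplied.
#' @param kSeed seed length (>= 8); default 15.
#' @param scheme DNA [ScoringScheme-class] used in the extension stage.
#' @param minIdentity minimum alignment identity to report a hit.
#' @param minCoverage minimum fraction of the query aligned.
#' @param queryId identifier copied into the \code{query} column.
#' @param index optional prebuilt [kmerIndex()] of the subject.
#' @return data.frame of hits with columns \code{query}, \code{replicon},
#'   \code{start}, \code{end} (0-based half-open on the forward strand),
#'   \code{strand}, \code{identity}, \code{coverage}, \code{score},
#'   \code{qstart}, \code{qend}; sorted by score descending. Strand
#'   \code{"-"} means the reverse complement of the subject interval
#'   aligns to the query.
#' @seealso [mergeHits()], [validateGene()]
#' @export
seedExtendSearch <- function(query, subject = NULL, kSeed = 15L,
                             scheme = scoringScheme("dna"),
                             minIdentity = 0.9, minCoverage = 0.8,
                             queryId = "query", index = NULL) {
    query <- toupper(as.character(query))
    if (kSeed < 8L) stop("kSeed must be >= 8")
    L <- nchar(query)
    if (L < kSeed) stop("query shorter than kSeed")
    if (is.null(index)) {
        if (is.null(subject)) stop("either subject or index is required")
        index <- kmerIndex(subject, kSeed)
    } else if (index$k != kSeed) {
        stop("index was built with k = ", index$k)
    }
    band <- ceiling(20 + 0.05 * L)
    pad <- band + 30L
    qcodesF <- .encodeKmers(query, kSeed)
    qcodesR <- .encodeKmers(revComp(query), kSeed)

    hits <- list()
    for (rep_id in names(index$replicons)) {
        repIdx <- index$replicons[[rep_id]]
        subj <- index$sequences[[rep_id]]
        slen <- repIdx$length
        for (strand in c("+", "-")) {
            qseq <- if (strand == "+") query else revComp(query)
            seeds <- .lookupSeeds(repIdx,
                                  if (strand == "+") qcodesF else qcodesR)
            if (!length(seeds$qpos)) next
            diag <- seeds$spos - seeds$qpos
            ord <- order(diag, seeds$spos)
            diag <- diag[ord]; ss <- seeds$spos[ord]
            grp <- cumsum(c(1L, diff(diag) > band))
            for (g in unique(grp)) {
                sel <- grp == g
                smin <- min(ss[sel]); smax <- max(ss[sel]) + kSeed - 1L
                winA <- max(1L, smin - pad)
                winB <- min(slen, smax + pad)
                win <- substr(subj, winA, winB)
                aln <- localAlign(qseq, win, scheme)
                qs <- aln@querySpan
                cov <- (qs[2L] - qs[1L]) / L
                if (aln@identity < minIdentity || cov < minCoverage) next
                s0 <- (winA - 1L) + aln@subjectSpan[1L]
                e0 <- (winA - 1L) + aln@subjectSpan[2L]
                if (strand == "-") qs <- c(L - qs[2L], L - qs[1L])
                hits[[length(hits) + 1L]] <- data.frame(
                    query = queryId, replicon = rep_id, start = s0, end = e0,
                    strand = strand, identity = aln@identity, coverage = cov,
                    score = aln@score, qstart = qs[1L], qend = qs[2L],
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(hits)) return(.emptyHits())
    res <- do.call(rbind, hits)
    res <- res[!duplicated(res[, c("replicon", "strand", "start", "end")]), ,
               drop = FALSE]
    res <- res[order(-res$score), , drop = FALSE]
    rownames(res) <- NULL
    res
}

.emptyHits <- function() {
    data.frame(query = character(), replicon = character(),
               start = integer(), end = integer(), strand = character(),
               identity = numeric(), coverage = numeric(), score = numeric(),
               qstart = integer(), qend = integer(), stringsAsFactors = FALSE)
}

#' Merge genomic hits into loci
#'
#' Hits on the same replicon and strand whose subject intervals overlap
#' or lie within \code{maxGap} merge into one locus, provided their query
#' spans are complementary (overlap of the query spans below half the
#' shorter span). The guard keeps fragments of one fragmented alignment
#' together while leaving distinct nearby copies -- which each cover the
#' same query region -- as separate loci, so the locus count is the copy
#' count. The merged locus keeps the best identity, coverage and score of
#' its members. Merging is idempotent and independent of input order.
#'
#' @param hits data.frame as returned by [seedExtendSearch()].
#' @param maxGap maximum gap (bp) bridged when merging; default 2000.
#' @return data.frame of loci with columns \code{query}, \code{replicon},
#'   \code{strand}, \code{start}, \code{end}, \code{identity},
#'   \code{coverage}, \code{score}, \code{nHits}.
#' @export
mergeHits <- function(hits, maxGap = 2000L) {
    if (!nrow(hits)) {
        out <- .emptyHits()
        out$nHits <- integer()
        return(out[, c("query", "replicon", "strand", "start", "end",
                       "identity", "coverage", "score", "nHits")])
    }
    hasQ <- all(c("qstart", "qend") %in% names(hits))
    out <- list()
    for (key in unique(paste(hits$replicon, hits$strand))) {
        h <- hits[paste(hits$replicon, hits$strand) == key, , drop = FALSE]
        h <- h[order(h$start, h$end), , drop = FALSE]
        cur <- h[1L, , drop = FALSE]
        cur$nHits <- 1L
        flush <- function(x) out[[length(out) + 1L]] <<- x
        for (i in seq_len(nrow(h))[-1L]) {
            nxt <- h[i, , drop = FALSE]
            gap_ok <- nxt$start - cur$end <= maxGap
            comp_ok <- TRUE
            if (hasQ) {
                ov <- min(cur$qend, nxt$qend) - max(cur$qstart, nxt$qstart)
                shorter <- min(cur$qend - cur$qstart, nxt$qend - nxt$qstart)
                comp_ok <- ov < 0.5 * shorter
            }
            if (gap_ok && comp_ok) {
                cur$end <- max(cur$end, nxt$end)
                cur$start <- min(cur$start, nxt$start)
                cur$identity <- max(cur$identity, nxt$identity)
                cur$coverage <- max(cur$coverage, nxt$coverage)
                cur$score <- max(cur$score, nxt$score)
                if (hasQ) {
                    cur$qstart <- min(cur$qstart, nxt$qstart)
                    cur$qend <- max(cur$qend, nxt$qend)
                }
                cur$nHits <- cur$nHits + 1L
            } else {
                flush(cur)
                cur <- nxt
                cur$nHits <- 1L
            }
        }
        flush(cur)
    }
    res <- do.call(rbind, out)
    res <- res[order(res$replicon, res$start), , drop = FALSE]
    rownames(res) <- NULL
    res[, c("query", "replicon", "strand", "start", "end", "identity",
            "coverage", "score", "nHits")]
}
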