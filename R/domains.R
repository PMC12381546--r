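#' @importFrom stats setNames
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.uniformBackground <- function() setNames(rep(1 / 20, 20L), .AA20)

#' Build a position-specific scoring matrix from aligned instances
#'
#' Column log-odds are \code{log2((count[r, c] + pseudocount * bg[r]) /
#' ((n + pseudocount) * bg[r]))}, i.e. observed residue frequencies with
#' a background-proportional pseudocount, in bits against the background.
#'
#' @param instances character vector of >= 2 gap-free peptides of equal
#'   length.
#' @param pseudocount non-negative pseudocount weight; default 1.
#' @param background residue background frequencies (named, sums to 1);
#'   default uniform over the 20 standard amino acids.
#' @param label domain label stored in the model.
#' @return A [PSSM-class].
#' @examples
#' buildPSSM(c("KR", "KR", "KK"), pseudocount = 1, label = "toy")
#' @export
buildPSSM <- function(instances, pseudocount = 1,
                      background = .uniformBackground(), label = "domain") {
    if (length(instances) < 2L) stop("need at least 2 instances")
    w <- unique(nchar(instances))
    if (length(w) != 1L) stop("instances must have equal length")
    if (any(grepl("-", instances, fixed = TRUE)))
        stop("instances must be gap-free")
    n <- length(instances)
    chars <- do.call(rbind, strsplit(instances, ""))
    lo <- matrix(0, 20L, w, dimnames = list(.AA20, NULL))
    for (c_ in seq_len(w)) {
        counts <- table(factor(chars[, c_], levels = .AA20))
        lo[, c_] <- log2((as.numeric(counts) + pseudocount * background) /
                         ((n + pseudocount) * background))
    }
    new("PSSM", label = label, logOdds = lo,
        background = background[.AA20])
}

#' Width (number of columns) of a PSSM
#' @param pssm a [PSSM-class].
#' @return integer column count.
#' @export
pssmWidth <- function(pssm) ncol(pssm@logOdds)

.windowScores <- function(pssm, protein) {
    w <- pssmWidth(pssm)
    chars <- strsplit(protein, "")[[1L]]
    L <- length(chars)
    if (L < w) return(numeric(0))
    idx <- match(chars, rownames(pssm@logOdds))
    n <- L - w + 1L
    acc <- numeric(n)
    for (c_ in seq_len(w)) {
        s <- unname(pssm@logOdds[, c_])[idx[c_:(c_ + n - 1L)]]
        s[is.na(s)] <- 0          # non-standard residues score 0
        acc <- acc + s
    }
    acc
}

#' Calibrate a score threshold on background decoys
#'
#' Monte-Carlo calibration of the PSSM null: decoy sequences are drawn
#' from the background residue distribution and all window scores are
#' recorded. The returned threshold \code{s*} is the score at which the
#' expected number of decoy hits, rescaled to the size of the real query
#' set, equals 1 -- the analogue of excluding candidate hits with an
#' expected false-positive count (E-value) above 1.
#'
#' @param pssm a [PSSM-class].
#' @param decoyLengthTotal total decoy residues to simulate.
#' @param nSamples number of decoy sequences (>= 100).
#' @param seed RNG seed for the decoy draw.
#' @param querySetWindows number of windows in the real query set that
#'   the expected-hit count is rescaled to.
#' @return An object of class \code{NullCalibration}: a list with
#'   \code{threshold}, sorted \code{nullScores}, \code{nullWindows} and
#'   \code{querySetWindows}.
#' @export
calibrateNull <- function(pssm, decoyLengthTotal = 2e5, nSamples = 200L,
                          seed = 1L, querySetWindows = 1e4) {
    if (nSamples < 100L) stop("nSamples must be >= 100")
    rng <- apply(pssm@logOdds, 2L, function(x) diff(range(x)))
    if (all(rng == 0)) stop("degenerate PSSM: all columns constant")
    len <- max(pssmWidth(pssm), ceiling(decoyLengthTotal / nSamples))
    scores <- local({
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old))
        set.seed(seed)
        unlist(lapply(seq_len(nSamples), function(i) {
            decoy <- paste(sample(names(pssm@background), len, replace = TRUE,
                                  prob = pssm@background), collapse = "")
            .windowScores(pssm, decoy)
        }))
    })
    nullWindows <- length(scores)
    sorted <- sort(scores, decreasing = TRUE)
    # expected decoy hits at >= s, rescaled: E(s) = qw * (# null >= s) / nw
    m <- max(1L, round(nullWindows / querySetWindows))
    threshold <- if (m <= nullWindows) sorted[m] else sorted[nullWindows]
    structure(list(threshold = threshold, nullScores = sorted,
                   nullWindows = nullWindows,
                   querySetWindows = querySetWindows),
              class = "NullCalibration")
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Expected false-hit count for a score under a calibrated null
#'
#' @param calibration a \code{NullCalibration} from [calibrateNull()].
#' @param score bit score(s).
#' @return expected number of false hits at or above \code{score} in a
#'   query set of the calibrated size.
#' @export
expectLike <- function(calibration, score) {
    vapply(score, function(s)
        calibration$querySetWindows *
            sum(calibration$nullScores >= s) / calibration$nullWindows,
        numeric(1))
}

#' Scan a protein with a PSSM
#'
#' Sliding-window scoring with greedy selection of non-overlapping
#' windows by descending score (ties to the leftmost start). Windows
#' scoring below \code{threshold} are excluded; when a calibration is
#' supplied, hits with an expected false-hit count above 1 are also
#' excluded.
#'
#' @param pssm a [PSSM-class].
#' @param protein peptide string (length >= 1).
#' @param threshold minimum bit score; default from \code{calibration},
#'   else \code{-Inf}.
#' @param calibration optional \code{NullCalibration} from
#'   [calibrateNull()].
#' @return data.frame of hits: \code{label}, \code{start}, \code{end}
#'   (0-based half-open on the protein), \code{bitScore},
#'   \code{expectLike}; sorted by start, mutually non-overlapping.
#' @export
scanDomains <- function(pssm, protein, threshold = NULL,
                        calibration = NULL) {
    if (nchar(protein) < 1L) stop("protein must have length >= 1")
    if (is.null(threshold))
        threshold <- if (!is.null(calibration)) calibration$threshold
                     else -Inf
    w <- pssmWidth(pssm)
    empty <- data.frame(label = character(), start = integer(),
                        end = integer(), bitScore = numeric(),
                        expectLike = numeric(), stringsAsFactors = FALSE)
    scores <- .windowScores(pssm, protein)
    if (!length(scores)) return(empty)
    cand <- which(scores >= threshold)
    if (!length(cand)) return(empty)
    cand <- cand[order(-scores[cand], cand)]
    chosen <- integer(0)
    for (p in cand) {
        if (!any(abs(chosen - p) < w)) chosen <- c(chosen, p)
    }
    chosen <- sort(chosen)
    el <- if (!is.null(calibration)) expectLike(calibration, scores[chosen])
          else rep(NA_real_, length(chosen))
    res <- data.frame(label = pssm@label, start = chosen - 1L,
                      end = chosen - 1L + w, bitScore = scores[chosen],
                      expectLike = el, stringsAsFactors = FALSE)
    if (!is.null(calibration)) res <- res[res$expectLike <= 1, , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Scan a protein with a set of PSSMs
#'
#' @param pssms list of [PSSM-class] objects.
#' @param protein peptide string.
#' @param thresholds named numeric thresholds per label (optional).
#' @param calibrations named list of \code{NullCalibration}s (optional).
#' @return combined hit data.frame as from [scanDomains()].
#' @export
scanDomainSet <- function(pssms, protein, thresholds = NULL,
                          calibrations = NULL) {
    out <- lapply(pssms, function(p) {
        thr <- if (!is.null(thresholds)) thresholds[[p@label]] else NULL
        cal <- if (!is.null(calibrations)) calibrations[[p@label]] else NULL
        scanDomains(p, protein, threshold = thr, calibration = cal)
    })
    res <- do.call(rbind, out)
    res <- res[order(res$start), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Classify a protein's family from its domain hits
#'
#' Overlap rule for CCT-family membership: CCT alone gives CMF; CCT with
#' a companion gives CO (B-box), PRR (pseudo-response regulator
#' receiver), ZCCT (zinc finger) or GATA. When several companions are
#' present the precedence is PRR > BBOX > ZF > GATA. Without a CCT hit,
#' a retained B-box or PRR domain is reported as BBOX_ONLY or PRR_ONLY
#' and flagged as a potential CCT-domain deletion; anything else is NONE.
#'
#' @param hits data.frame of domain hits (needs a \code{label} column),
#'   or a character vector of domain labels.
#' @return list with elements \code{class} (one of CMF, CO, PRR, GATA,
#'   ZCCT, BBOX_ONLY, PRR_ONLY, NONE) and \code{flagged} (TRUE for
#'   potential CCT-domain deletions).
#' @examples
#' classifyFamily(c("CCT", "BBOX"))$class   # "CO"
#' classifyFamily(c("BBOX"))$flagged        # TRUE
#' @export
classifyFamily <- function(hits) {
    labels <- if (is.data.frame(hits)) hits$label else hits
    s <- unique(labels)
    if ("CCT" %in% s) {
        cls <- if ("PRR" %in% s) "PRR"
               else if ("BBOX" %in% s) "CO"
               else if ("ZF" %in% s) "ZCCT"
               else if ("GATA" %in% s) "GATA"
               else "CMF"
        return(list(class = cls, flagged = FALSE))
    }
    if ("PRR" %in% s) return(list(class = "PRR_ONLY", flagged = TRUE))
    if ("BBOX" %in% s) return(list(class = "BBOX_ONLY", flagged = TRUE))
    list(class = "NONE", flagged = FALSE)
}
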