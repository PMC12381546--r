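#' @importFrom Biostrings pairwiseAlignment DNAString DNAStringSet AAString
#'   reverseComplement GENETIC_CODE pattern subject score PDict matchPDict
#' @importFrom utils data
NULL

.DNA_BASES <- c("A", "C", "G", "T")

.dnaSubMatrix <- function(match, mismatch) {
    letters <- c(.DNA_BASES, "N")
    m <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
    diag(m) <- match
    m["N", ] <- 0
    m[, "N"] <- 0
    m
}

.blosum62 <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            e <- new.env()
            data("BLOSUM62", package = "Biostrings", envir = e)
            cache <<- e$BLOSUM62
        }
        cache
    }
})

#' Construct an affine-gap scoring scheme
#'
#' Defaults follow common BLAST-like practice: DNA match/mismatch +1/-1
#' with gap open -5 and extend -1; protein BLOSUM62 with gap open -11 and
#' extend -1. A gap of length L costs \code{gapOpen + L * gapExtend}.
#'
#' @param alphabet \code{"dna"} or \code{"protein"}.
#' @param match,mismatch DNA match/mismatch scores (ignored for protein).
#' @param gapOpen,gapExtend non-positive gap penalties.
#' @param matrix optional substitution matrix overriding the default.
#' @return A [ScoringScheme-class] object.
#' @examples
#' scoringScheme("dna")
#' scoringScheme("protein", gapOpen = -10)
#' @export
scoringScheme <- function(alphabet = c("dna", "protein"), match = 1,
                          mismatch = -1, gapOpen = if (alphabet == "dna") -5
                          else -11, gapExtend = -1, matrix = NULL) {
    alphabet <- match.arg(alphabet)
    if (is.null(matrix)) {
        matrix <- if (alphabet == "dna") .dnaSubMatrix(match, mismatch)
                  else .blosum62()
    }
    new("ScoringScheme", alphabet = alphabet, matrix = matrix,
        gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend))
}

.checkAlphabet <- function(x, scheme) {
    ok <- if (scheme@alphabet == "dna") "ACGTN" else
        paste(rownames(scheme@matrix), collapse = "")
    bad <- setdiff(strsplit(x, "")[[1L]], strsplit(ok, "")[[1L]])
    if (length(bad))
        stop("sequence contains letters outside the scheme alphabet: ",
             paste(unique(bad), collapse = ", "))
    invisible(TRUE)
}

.columnIdentity <- function(a, b) {
    n <- nchar(a)
    if (n == 0L) return(0)
    ca <- strsplit(a, "")[[1L]]
    cb <- strsplit(b, "")[[1L]]
    sum(ca == cb & ca != "-") / n
}

.asPairAlignment <- function(pa, a, b, type) {
    alnA <- as.character(pattern(pa))
    alnB <- as.character(subject(pa))
    if (type == "global") {
        qs <- c(0L, nchar(a))
        ss <- c(0L, nchar(b))
    } else {
        if (nchar(alnA) == 0L) {
            qs <- ss <- c(0L, 0L)
        } else {
            qs <- c(Biostrings::start(pattern(pa)) - 1L,
                    Biostrings::end(pattern(pa)))
            ss <- c(Biostrings::start(subject(pa)) - 1L,
                    Biostrings::end(subject(pa)))
        }
    }
    new("PairAlignment", alignedA = alnA, alignedB = alnB,
        score = score(pa), identity = .columnIdentity(alnA, alnB),
        querySpan = as.integer(qs), subjectSpan = as.integer(ss))
}

.pairAlign <- function(a, b, scheme, type) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    .checkAlphabet(a, scheme); .checkAlphabet(b, scheme)
    if (nchar(a) == 0L && nchar(b) == 0L)
        return(new("PairAlignment", alignedA = "", alignedB = "", score = 0,
                   identity = 0, querySpan = c(0L, 0L),
                   subjectSpan = c(0L, 0L)))
    pa <- pairwiseAlignment(a, b, type = type,
        substitutionMatrix = scheme@matrix,
        gapOpening = -scheme@gapOpen, gapExtension = -scheme@gapExtend)
    res <- .asPairAlignment(pa, a, b, type)
    if (type == "local" && res@score <= 0)
        res <- new("PairAlignment", alignedA = "", alignedB = "", score = 0,
                   identity = 0, querySpan = c(0L, 0L),
                   subjectSpan = c(0L, 0L))
    res
}

#' Optimal global (Needleman-Wunsch) alignment with affine gaps
#'
#' @param a,b sequences (character scalars) over the scheme alphabet.
#' @param scheme a [ScoringScheme-class]; default DNA scheme.
#' @return A [PairAlignment-class].
#' @examples
#' globalAlign("ACGT", "AGT",
#'     scoringScheme("dna", gapOpen = -2, gapExtend = -1))
#' @export
globalAlign <- function(a, b, scheme = scoringScheme("dna")) {
    .pairAlign(a, b, scheme, "global")
}

#' Optimal local (Smith-Waterman) alignment with affine gaps
#'
#' The empty alignment with score 0 is returned when no positively
#' scoring local alignment exists.
#'
#' @inheritParams globalAlign
#' @return A [PairAlignment-class].
#' @export
localAlign <- function(a, b, scheme = scoringScheme("dna")) {
    .pairAlign(a, b, scheme, "local")
}

#' Reverse complement of a DNA string
#'
#' @param dna character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revComp <- function(dna) {
    as.character(reverseComplement(DNAString(dna)))
}

#' Translate DNA in a given frame and strand
#'
#' Standard genetic code; stop codons render as \code{"*"}, codons
#' containing N (or any non-ACGT letter) as \code{"X"}; a trailing partial
#' codon is ignored. On the minus strand the sequence is
#' reverse-complemented before the frame offset is applied, so
#' \code{translateDNA(revComp(x), f, "+") == translateDNA(x, f, "-")}.
#'
#' @param dna character scalar over A/C/G/T/N.
#' @param frame 0, 1 or 2.
#' @param strand \code{"+"} or \code{"-"}.
#' @return peptide string.
#' @examples
#' translateDNA("ATGAAATAG")      # "MK*"
#' translateDNA("CAT", strand = "-")  # "M"
#' @export
translateDNA <- function(dna, frame = 0, strand = "+") {
    stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
    dna <- toupper(as.character(dna))
    if (strand == "-") dna <- revComp(dna)
    if (frame > 0) dna <- substring(dna, frame + 1L)
    n <- nchar(dna) %/% 3L
    if (n == 0L) return("")
    codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

#' Find open reading frames in all six frames
#'
#' Reports every ATG paired with its nearest in-frame downstream stop
#' codon whose encoded peptide (stop excluded) has at least \code{minAa}
#' residues. Coordinates are 0-based half-open on the forward strand and
#' include the stop codon.
#'
#' @param dna character scalar over A/C/G/T/N.
#' @param minAa minimum peptide length (>= 1).
#' @return data.frame with columns \code{frame}, \code{strand},
#'   \code{start}, \code{end}, \code{peptide}, sorted by peptide length
#'   descending.
#' @examples
#' findOrfs("ATGAAATAG", minAa = 2)
#' @export
findOrfs <- function(dna, minAa = 50L) {
    stopifnot(minAa >= 1L)
    dna <- toupper(as.character(dna))
    n <- nchar(dna)
    out <- list()
    for (strand in c("+", "-")) {
        s <- if (strand == "+") dna else revComp(dna)
        for (frame in 0:2) {
            pep <- translateDNA(s, frame, "+")
            chars <- strsplit(pep, "")[[1L]]
            stops <- which(chars == "*")
            starts <- which(chars == "M")
            if (!length(stops) || !length(starts)) next
            for (i in starts) {
                j <- stops[stops > i]
                if (!length(j)) next
                j <- j[1L]
                peptide <- substr(pep, i, j - 1L)
                if (nchar(peptide) < minAa) next
                a <- frame + 3L * (i - 1L)      # 0-based on s
                b <- frame + 3L * j
                if (strand == "-") { tmp <- a; a <- n - b; b <- n - tmp }
                out[[length(out) + 1L]] <- data.frame(
                    frame = frame, strand = strand, start = a, end = b,
                    peptide = peptide, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(frame = integer(), strand = character(),
                          start = integer(), end = integer(),
                          peptide = character(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res[order(-nchar(res$peptide), res$start), , drop = FALSE]
}
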