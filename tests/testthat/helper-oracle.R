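# Independent alignment oracles, written against the stated gap model
# (a gap of length L costs open + L * ext) and never sharing code with
# the package's alignment path.

# exhaustive enumeration of every global alignment of a and b (tiny n):
# recursion over aligned column strings, scored by parsing gap runs
enum_global_score <- function(a, b, match = 1, mismatch = -1,
                              open = -5, ext = -1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    score_cols <- function(ca, cb) {
        s <- 0
        run <- ""   # current gap row: "", "A", or "B"
        for (k in seq_along(ca)) {
            if (ca[k] == "-" || cb[k] == "-") {
                row <- if (ca[k] == "-") "A" else "B"
                if (row != run) s <- s + open
                s <- s + ext
                run <- row
            } else {
                run <- ""
                s <- s + if (ca[k] == cb[k]) match else mismatch
            }
        }
        s
    }
    best <- -Inf
    rec <- function(i, j, ca, cb) {
        if (i > length(A) && j > length(B)) {
            best <<- max(best, score_cols(ca, cb))
            return(invisible())
        }
        if (i <= length(A) && j <= length(B))
            rec(i + 1, j + 1, c(ca, A[i]), c(cb, B[j]))
        if (i <= length(A)) rec(i + 1, j, c(ca, A[i]), c(cb, "-"))
        if (j <= length(B)) rec(i, j + 1, c(ca, "-"), c(cb, B[j]))
    }
    rec(1, 1, character(0), character(0))
    best
}

# affine-gap global alignment score by Gotoh three-state DP (pure R)
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                open = -5, ext = -1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    if (n == 0 && m == 0) return(0)
    if (n == 0) return(open + m * ext)
    if (m == 0) return(open + n * ext)
    NEG <- -1e15
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)   # gap in b (A consumed)
    Y <- matrix(NEG, n + 1, m + 1)   # gap in a (B consumed)
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- open + i * ext
    for (j in seq_len(m)) Y[1, j + 1] <- open + j * ext
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (A[i] == B[j]) match else mismatch
            M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
            X[i + 1, j + 1] <- max(M[i, j + 1] + open + ext,
                                   X[i, j + 1] + ext,
                                   Y[i, j + 1] + open + ext)
            Y[i + 1, j + 1] <- max(M[i + 1, j] + open + ext,
                                   Y[i + 1, j] + ext,
                                   X[i + 1, j] + open + ext)
        }
    }
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# affine-gap local (Smith-Waterman) score; empty alignment scores 0
oracle_local_score <- function(a, b, match = 1, mismatch = -1,
                               open = -5, ext = -1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    if (n == 0 || m == 0) return(0)
    NEG <- -1e15
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)
    Y <- matrix(NEG, n + 1, m + 1)
    M[1, ] <- 0; M[, 1] <- 0
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (A[i] == B[j]) match else mismatch
            M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + s)
            X[i + 1, j + 1] <- max(M[i, j + 1] + open + ext,
                                   X[i, j + 1] + ext,
                                   Y[i, j + 1] + open + ext)
            Y[i + 1, j + 1] <- max(M[i + 1, j] + open + ext,
                                   Y[i + 1, j] + ext,
                                   X[i + 1, j] + open + ext)
            best <- max(best, M[i + 1, j + 1])
        }
    }
    best
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-site substitution to a different base; independent of the
# package's internal mutation code
mutate_dna <- function(seq, rate) {
    chars <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(chars)) < rate)
    for (i in hit)
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    paste(chars, collapse = "")
}

mutate_protein <- function(seq, rate) {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    chars <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(chars)) < rate)
    for (i in hit) chars[i] <- sample(setdiff(aa, chars[i]), 1)
    paste(chars, collapse = "")
}
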