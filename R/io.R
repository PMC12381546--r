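#' @importFrom Biostrings readBStringSet writeXStringSet AAStringSet
#' @importFrom utils read.delim write.table
NULL

#' Read a FASTA file
#'
#' Record ids must be unique; lowercase residues are normalized to
#' uppercase with a warning. An empty file yields an empty record set.
#'
#' @param path file path.
#' @param type \code{"dna"} or \code{"protein"}.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @export
readFasta <- function(path, type = c("dna", "protein")) {
    type <- match.arg(type)
    if (file.size(path) == 0L)
        return(if (type == "dna") Biostrings::DNAStringSet()
               else Biostrings::AAStringSet())
    x <- readBStringSet(path)
    ids <- names(x)
    if (anyDuplicated(ids))
        stop("duplicate FASTA ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    chr <- as.character(x)
    if (any(grepl("[a-z]", chr))) {
        warning("lowercase residues normalized to uppercase")
        chr <- toupper(chr)
    }
    names(chr) <- ids
    if (type == "dna") Biostrings::DNAStringSet(chr)
    else Biostrings::AAStringSet(chr)
}

#' Write a FASTA file (wrapped at 60 columns)
#'
#' @param records an XStringSet or named character vector.
#' @param path output path.
#' @param type \code{"dna"} or \code{"protein"} (used for character input).
#' @export
writeFasta <- function(records, path, type = c("dna", "protein")) {
    type <- match.arg(type)
    if (is.character(records))
        records <- if (type == "dna") Biostrings::DNAStringSet(records)
                   else Biostrings::AAStringSet(records)
    writeXStringSet(records, path, width = 60L)
    invisible(path)
}

# ---- GFF3 -------------------------------------------------------------------

#' Write gene models to GFF3
#'
#' Emits a gene/mRNA/exon/CDS hierarchy with 1-based inclusive
#' coordinates (converted from the internal 0-based half-open exon
#' intervals) and CDS phases.
#'
#' @param models list of gene models (see
#'   [SyntheticPangenome-class] for the fields).
#' @param path output path.
#' @export
writeGff3 <- function(models, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (m in models) {
        gs <- min(m$exons[, "start"]) + 1L
        ge <- max(m$exons[, "end"])
        rid <- paste0(m$geneId, ".t1")
        lines <- c(
            sprintf("%s\tpanfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s;family_id=%s",
                    m$chrom, gs, ge, m$strand, m$geneId, m$familyId),
            sprintf("%s\tpanfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                    m$chrom, gs, ge, m$strand, rid, m$geneId))
        for (i in seq_len(nrow(m$exons))) {
            s1 <- m$exons[i, "start"] + 1L
            e1 <- m$exons[i, "end"]
            lines <- c(lines,
                sprintf("%s\tpanfam\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                        m$chrom, s1, e1, m$strand, rid, i, rid),
                sprintf("%s\tpanfam\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
                        m$chrom, s1, e1, m$strand, m$phases[i], rid, i, rid))
        }
        writeLines(lines, con)
    }
    invisible(path)
}

.gffAttr <- function(attr, key) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]*"), attr)
    out <- rep(NA_character_, length(attr))
    hit <- m > 0L
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(attr, m))
    out
}

#' Read gene models from GFF3
#'
#' Parses a gene/mRNA/exon/CDS hierarchy, converting 1-based inclusive
#' coordinates to internal 0-based half-open intervals. Structural
#' checks: \code{end >= start} for every feature, children inside their
#' parent's span, and CDS phases consistent with cumulative exon frames.
#'
#' @param path file path.
#' @return list of gene models (one per gene), each with \code{geneId},
#'   \code{familyId}, \code{chrom}, \code{strand}, \code{exons},
#'   \code{phases}.
#' @export
readGff3 <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(lines)) return(list())
    f <- read.delim(text = lines, header = FALSE, sep = "\t",
                    quote = "", stringsAsFactors = FALSE,
                    col.names = c("chrom", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attr"))
    if (any(f$end < f$start)) {
        bad <- which(f$end < f$start)[1L]
        stop("feature with end < start: ", f$attr[bad])
    }
    f$ID <- .gffAttr(f$attr, "ID")
    f$Parent <- .gffAttr(f$attr, "Parent")
    genesDf <- f[f$type == "gene", , drop = FALSE]
    models <- vector("list", nrow(genesDf))
    for (i in seq_len(nrow(genesDf))) {
        g <- genesDf[i, ]
        mr <- f[f$type == "mRNA" & f$Parent == g$ID, , drop = FALSE]
        if (nrow(mr) != 1L)
            stop("gene ", g$ID, " must have exactly one mRNA")
        cds <- f[f$type == "CDS" & f$Parent == mr$ID, , drop = FALSE]
        ex <- f[f$type == "exon" & f$Parent == mr$ID, , drop = FALSE]
        kids <- rbind(cds, ex, mr)
        out_of_span <- kids$start < g$start | kids$end > g$end
        if (any(out_of_span))
            stop("feature outside parent span of gene ", g$ID, ": ",
                 kids$ID[which(out_of_span)[1L]])
        cds <- cds[order(cds$start), , drop = FALSE]
        exons <- cbind(start = cds$start - 1L, end = cds$end)
        lens <- exons[, "end"] - exons[, "start"]
        got <- as.integer(cds$phase)
        # a nonzero first phase marks a CDS that starts mid-codon (e.g.
        # a truncated annotation); later phases must follow the frame
        # recurrence from there
        expect <- vapply(seq_along(lens), function(i) {
            before <- sum(lens[seq_len(i - 1L)]) - got[1L]
            as.integer((3L - (before %% 3L)) %% 3L)
        }, integer(1))
        if (!all(got == expect))
            warning("CDS phases of ", g$ID,
                    " inconsistent with cumulative exon frames")
        models[[i]] <- list(geneId = g$ID,
                            familyId = .gffAttr(g$attr, "family_id"),
                            chrom = g$chrom, strand = g$strand,
                            exons = exons, phases = got)
    }
    names(models) <- vapply(models, `[[`, character(1), "geneId")
    models
}

# ---- pangenome round-trip ---------------------------------------------------

#' Write a synthetic pangenome to disk
#'
#' Emits, per genotype, an assembly FASTA, a GFF3 annotation and a
#' protein FASTA, plus a single truth TSV for the whole pangenome.
#'
#' @param pg a [SyntheticPangenome-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @seealso [readPangenome()]
#' @export
writePangenome <- function(pg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (gt in genotypeNames(pg)) {
        fa <- file.path(dir, paste0(gt, ".assembly.fa"))
        writeFasta(pg@assemblies[[gt]], fa)
        gff <- file.path(dir, paste0(gt, ".genes.gff3"))
        writeGff3(pg@annotations[[gt]], gff)
        pfa <- file.path(dir, paste0(gt, ".proteins.fa"))
        writeFasta(pg@proteins[[gt]], pfa, type = "protein")
        files <- c(files, fa, gff, pfa)
    }
    tsv <- file.path(dir, "truth.tsv")
    write.table(pg@truth, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(files, tsv))
}

#' Read a pangenome directory written by [writePangenome()]
#'
#' @param dir directory path.
#' @return list with \code{assemblies}, \code{annotations},
#'   \code{proteins} (named per genotype) and \code{truth}.
#' @export
readPangenome <- function(dir) {
    fas <- sort(list.files(dir, pattern = "\\.assembly\\.fa$"))
    gts <- sub("\\.assembly\\.fa$", "", fas)
    assemblies <- list(); annotations <- list(); proteins <- list()
    for (gt in gts) {
        assemblies[[gt]] <- readFasta(
            file.path(dir, paste0(gt, ".assembly.fa")))
        annotations[[gt]] <- readGff3(
            file.path(dir, paste0(gt, ".genes.gff3")))
        proteins[[gt]] <- readFasta(
            file.path(dir, paste0(gt, ".proteins.fa")), type = "protein")
    }
    truth <- read.delim(file.path(dir, "truth.tsv"), sep = "\t",
                        stringsAsFactors = FALSE)
    list(assemblies = assemblies, annotations = annotations,
         proteins = proteins, truth = truth)
}
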