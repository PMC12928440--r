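# Similarity-hit filtering and reciprocal-best-hit extraction.

.blast6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Columns are taken positionally in the standard outfmt-6 order
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore); extra trailing columns are ignored.
#'
#' @param path Path to a tab-separated hit table without header.
#' @return data.frame with the twelve standard columns.
#' @export
readBlastTab <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#")
    if (ncol(df) < 12) {
        stop("expected at least 12 outfmt-6 columns, got ", ncol(df))
    }
    df <- df[, 1:12]
    names(df) <- .blast6_cols
    df
}

#' Soft-masked (repeat) fraction of a CDS
#'
#' Fraction of lowercase bases, the operational measure of repetitive
#' content in a soft-masked CDS.
#'
#' @param seq A character scalar or \code{BString}; must be non-empty.
#' @return Numeric in [0, 1].
#' @examples
#' repeatFraction("ACGTacgt")  # 0.5
#' @export
repeatFraction <- function(seq) {
    s <- as.character(seq)
    if (nchar(s) == 0) {
        stop("empty sequence")
    }
    chars <- strsplit(s, "")[[1]]
    sum(chars %in% letters) / length(chars)
}

#' Filter similarity hits by the pipeline thresholds
#'
#' Applies, per hit: e-value strictly below \code{max_evalue}, percent
#' identity at least \code{min_identity}, alignment length at least
#' \code{min_length} bp; and, per gene, removal of every hit touching a CDS
#' whose soft-masked fraction strictly exceeds \code{max_repeat_fraction}.
#' Defaults are the standard permissive-RBH settings (1e-5, 70, 60, 0.25).
#'
#' @param hits data.frame of outfmt-6 hits (see \code{\link{readBlastTab}}).
#' @param max_evalue,min_identity,min_length,max_repeat_fraction Thresholds.
#' @param masked_cds Named character vector or \code{BStringSet} of
#'   soft-masked CDS covering every gene id in \code{hits}.
#' @return The surviving rows of \code{hits}.
#' @export
filterHits <- function(hits, max_evalue = 1e-5, min_identity = 70,
                       min_length = 60, max_repeat_fraction = 0.25,
                       masked_cds = NULL) {
    if (nrow(hits) == 0) {
        return(hits)
    }
    keep <- hits$evalue < max_evalue &
        hits$pident >= min_identity &
        hits$length >= min_length
    if (!is.null(masked_cds)) {
        seqs <- .seqChar(masked_cds)
        ids <- unique(c(hits$qseqid, hits$sseqid))
        absent <- setdiff(ids, names(seqs))
        if (length(absent)) {
            stop("masked CDS missing for gene(s): ",
                 paste(utils::head(absent, 5), collapse = ", "))
        }
        frac <- vapply(seqs[ids], repeatFraction, numeric(1))
        bad <- ids[frac > max_repeat_fraction]
        keep <- keep & !(hits$qseqid %in% bad) & !(hits$sseqid %in% bad)
    }
    hits[keep, , drop = FALSE]
}

# Collapse multiple HSPs between the same (query, subject) pair to the
# single best HSP: max bitscore, ties by lower e-value then higher identity.
.collapseHSPs <- function(hits) {
    if (nrow(hits) == 0) {
        return(hits)
    }
    ord <- order(hits$qseqid, hits$sseqid, -hits$bitscore, hits$evalue,
                 -hits$pident)
    hits <- hits[ord, , drop = FALSE]
    key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
    hits[!duplicated(key), , drop = FALSE]
}

# Best subject per query: max bitscore, ties by lower e-value, higher
# identity, then lexicographically smallest subject id.
.bestHits <- function(hits) {
    if (nrow(hits) == 0) {
        return(hits)
    }
    ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, -hits$pident,
                 hits$sseqid)
    hits <- hits[ord, , drop = FALSE]
    hits[!duplicated(hits$qseqid), , drop = FALSE]
}

#' Reciprocal best hits between two gene sets
#'
#' A pair (a, b) is retained iff b is a's best surviving hit in the second
#' gene set and a is b's best hit in the first, best meaning maximal
#' bitscore (ties broken by lower e-value, higher identity, then subject
#' id). Multiple HSPs per gene pair are collapsed to the best HSP first.
#' Inputs are assumed already filtered (\code{\link{filterHits}}).
#'
#' @param hits_ab,hits_ba outfmt-6 data.frames for the two directions.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{bitscore} (max of the two directions), \code{score_ab},
#'   \code{score_ba}.
#' @export
reciprocalBestHits <- function(hits_ab, hits_ba) {
    empty <- data.frame(gene_a = character(0), gene_b = character(0),
                        bitscore = numeric(0), score_ab = numeric(0),
                        score_ba = numeric(0))
    if (nrow(hits_ab) == 0 || nrow(hits_ba) == 0) {
        return(empty)
    }
    best_ab <- .bestHits(.collapseHSPs(hits_ab))
    best_ba <- .bestHits(.collapseHSPs(hits_ba))
    fwd <- paste(best_ab$qseqid, best_ab$sseqid, sep = "\r")
    rev <- paste(best_ba$sseqid, best_ba$qseqid, sep = "\r")
    keep <- best_ab[fwd %in% rev, , drop = FALSE]
    if (nrow(keep) == 0) {
        return(empty)
    }
    back <- best_ba[match(paste(keep$qseqid, keep$sseqid, sep = "\r"),
                          paste(best_ba$sseqid, best_ba$qseqid, sep = "\r")),
                    , drop = FALSE]
    out <- data.frame(
        gene_a = keep$qseqid, gene_b = keep$sseqid,
        bitscore = pmax(keep$bitscore, back$bitscore),
        score_ab = keep$bitscore, score_ba = back$bitscore,
        stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
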