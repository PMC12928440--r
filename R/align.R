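#' Protein-guided codon alignment of two coding sequences
#'
#' Aligns two CDS at the protein level (global Needleman-Wunsch with
#' BLOSUM62 and affine gaps) and threads the nucleotide codons back through
#' the protein alignment, so every aligned column is a full codon. This
#' plays the role a codon-aware aligner plays in divergence pipelines:
#' indels are constrained to whole-codon units and frame is preserved.
#'
#' Trailing partial codons are trimmed with a warning. Internal stop codons
#' are tolerated (they translate to \code{*}, which BLOSUM62 scores) and
#' flagged in the result; downstream site counting excludes stop columns.
#'
#' @param cds_a,cds_b Character scalars or \code{DNAString}s; coding
#'   sequences, length at least one codon.
#' @param gapOpening,gapExtension Affine gap penalties passed to the
#'   protein-level aligner.
#' @return An object of class \code{"CodonAlignment"}: a list with
#'   \code{a}, \code{b} (aligned codon vectors, \code{"---"} for gaps),
#'   \code{score} (protein alignment score), and per-column logical flags
#'   \code{gap} and \code{stop}.
#' @examples
#' aln <- alignCodons("ATGGCTGCT", "ATGGCT")
#' aln$b  # one codon gap
#' @export
alignCodons <- function(cds_a, cds_b, gapOpening = 10, gapExtension = 0.5) {
    a <- as.character(cds_a)
    b <- as.character(cds_b)
    if (nchar(a) < 3 || nchar(b) < 3) {
        stop("both sequences must contain at least one full codon")
    }
    if (nchar(a) %% 3 != 0 || nchar(b) %% 3 != 0) {
        warning("trailing partial codon trimmed")
    }
    cod_a <- .splitCodons(a)
    cod_b <- .splitCodons(b)
    prot_a <- paste(.translateCodons(cod_a), collapse = "")
    prot_b <- paste(.translateCodons(cod_b), collapse = "")

    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
        substitutionMatrix = data_env$BLOSUM62,
        gapOpening = gapOpening, gapExtension = gapExtension,
        type = "global"
    )
    pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]

    ia <- 0L
    ib <- 0L
    out_a <- character(length(pat))
    out_b <- character(length(pat))
    for (k in seq_along(pat)) {
        if (pat[k] == "-") {
            out_a[k] <- "---"
        } else {
            ia <- ia + 1L
            out_a[k] <- cod_a[ia]
        }
        if (sub[k] == "-") {
            out_b[k] <- "---"
        } else {
            ib <- ib + 1L
            out_b[k] <- cod_b[ib]
        }
    }
    gap <- out_a == "---" | out_b == "---"
    aa_a <- .translateCodons(out_a)
    aa_b <- .translateCodons(out_b)
    stop_col <- (!gap) & (aa_a == "*" | aa_b == "*")
    structure(
        list(a = out_a, b = out_b, score = Biostrings::score(pa),
             gap = gap, stop = stop_col),
        class = "CodonAlignment"
    )
}

#' @export
print.CodonAlignment <- function(x, ...) {
    cat("CodonAlignment: ", length(x$a), " columns, ",
        sum(x$gap), " gap, ", sum(x$stop), " stop\n", sep = "")
    invisible(x)
}
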