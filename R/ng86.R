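#' Nei-Gojobori (1986) synonymous and nonsynonymous divergence
#'
#' Counting-based Ks/Ka estimation on a codon alignment. Synonymous site
#' counts per codon are the fraction of the nine single-nucleotide changes
#' that preserve the amino acid (changes creating a stop count as
#' nonsynonymous, so S + N equals three times the number of compared
#' codons); sites are averaged between the two sequences. For codon pairs
#' differing at several positions, synonymous/nonsynonymous differences are
#' averaged over all orderings of single-nucleotide steps, excluding
#' orderings that pass through a stop codon. Proportions are corrected for
#' multiple hits with the Jukes-Cantor formula
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3}p)}.
#'
#' Only columns that are gap-free, stop-free and composed of unambiguous
#' A/C/G/T bases in both sequences are compared.
#'
#' @param alignment A \code{CodonAlignment} from \code{\link{alignCodons}},
#'   or a list with codon vectors \code{a} and \code{b} of equal length.
#' @return A list of class \code{"NG86Result"}: \code{S}, \code{N}
#'   (site counts), \code{Sd}, \code{Nd} (pathway-averaged differences),
#'   \code{ps}, \code{pn}, \code{Ks}, \code{Ka} (NA when saturated),
#'   \code{codons} (columns compared), and logical flags
#'   \code{saturated_s}, \code{saturated_n}.
#' @examples
#' ng86(alignCodons("ATGGCTAAA", "ATGGCCAAA"))$Ks > 0
#' @export
ng86 <- function(alignment) {
    cod_a <- toupper(alignment$a)
    cod_b <- toupper(alignment$b)
    if (length(cod_a) != length(cod_b)) {
        stop("aligned codon vectors differ in length")
    }
    codons <- .codons()
    ia <- match(cod_a, codons)
    ib <- match(cod_b, codons)
    sites <- .ng86Sites()
    ok <- !is.na(ia) & !is.na(ib) &
        !is.na(sites[ia]) & !is.na(sites[ib])
    if (!any(ok)) {
        stop("no comparable (ungapped, stop-free, unambiguous) codon columns")
    }
    ia <- ia[ok]
    ib <- ib[ok]
    tabs <- .ng86PairTables()
    Sd <- sum(tabs$sd[cbind(ia, ib)])
    Nd <- sum(tabs$nd[cbind(ia, ib)])
    S <- (sum(sites[ia]) + sum(sites[ib])) / 2
    n_codons <- length(ia)
    N <- 3 * n_codons - S
    ps <- if (S > 0) Sd / S else 0
    pn <- if (N > 0) Nd / N else 0
    jc <- function(p) {
        if (p >= 3 / 4) {
            NA_real_
        } else if (p <= 0) {
            0
        } else {
            -3 / 4 * log(1 - 4 * p / 3)
        }
    }
    res <- list(
        S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
        Ks = jc(ps), Ka = jc(pn),
        saturated_s = ps >= 3 / 4, saturated_n = pn >= 3 / 4,
        codons = n_codons
    )
    class(res) <- "NG86Result"
    res
}

#' @export
print.NG86Result <- function(x, ...) {
    cat(sprintf(
        "NG86Result: %d codons | S=%.2f N=%.2f Sd=%.2f Nd=%.2f | Ks=%s Ka=%s\n",
        x$codons, x$S, x$N, x$Sd, x$Nd,
        if (is.na(x$Ks)) "saturated" else sprintf("%.4f", x$Ks),
        if (is.na(x$Ka)) "saturated" else sprintf("%.4f", x$Ka)
    ))
    invisible(x)
}

#' Ks/Ka for a table of homolog pairs
#'
#' Convenience driver: for each pair of gene identifiers, aligns the two
#' CDS (skipping the protein-alignment step when both sequences have equal
#' length, where codons pair off directly) and applies \code{\link{ng86}}.
#'
#' @param pairs A data.frame with columns \code{gene_a}, \code{gene_b}.
#' @param cds Named character vector (or \code{DNAStringSet}) of CDS
#'   covering every gene in \code{pairs}.
#' @param align \code{"auto"} aligns only unequal-length pairs through the
#'   protein guide; \code{"protein"} always aligns; \code{"none"} requires
#'   equal lengths.
#' @return \code{pairs} with columns \code{Ks}, \code{Ka}, \code{S},
#'   \code{N}, \code{Sd}, \code{Nd}, \code{saturated} appended.
#' @export
ng86Pairs <- function(pairs, cds, align = c("auto", "protein", "none")) {
    align <- match.arg(align)
    cds <- .seqChar(cds)
    missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
    if (length(missing)) {
        stop("CDS missing for: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    n <- nrow(pairs)
    out <- data.frame(
        Ks = rep(NA_real_, n), Ka = NA_real_, S = NA_real_, N = NA_real_,
        Sd = NA_real_, Nd = NA_real_, saturated = FALSE
    )
    for (i in seq_len(n)) {
        sa <- cds[[pairs$gene_a[i]]]
        sb <- cds[[pairs$gene_b[i]]]
        if (align == "protein" || (align == "auto" && nchar(sa) != nchar(sb))) {
            aln <- alignCodons(sa, sb)
        } else {
            if (nchar(sa) != nchar(sb)) {
                stop("align = 'none' requires equal-length sequences")
            }
            aln <- list(a = .splitCodons(sa), b = .splitCodons(sb))
        }
        r <- ng86(aln)
        out$Ks[i] <- r$Ks
        out$Ka[i] <- r$Ka
        out$S[i] <- r$S
        out$N[i] <- r$N
        out$Sd[i] <- r$Sd
        out$Nd[i] <- r$Nd
        out$saturated[i] <- r$saturated_s
    }
    cbind(pairs, out)
}

#' Filter homolog pairs by their Ks estimate
#'
#' Retains pairs with \eqn{0.01 \le Ks < 3}: values below 0.01 are treated
#' as highly similar copies (allelic noise, tandem duplicates), values at or
#' above 3 as saturated divergence. Saturation-flagged pairs (no numeric
#' Ks) are removed. The operation is idempotent.
#'
#' @param pairs A data.frame with a \code{Ks} column (NA = saturated).
#' @param ks_min,ks_max Inclusive lower / exclusive upper bound.
#' @return The retained rows of \code{pairs}.
#' @export
filterKs <- function(pairs, ks_min = 0.01, ks_max = 3) {
    keep <- !is.na(pairs$Ks) & pairs$Ks >= ks_min & pairs$Ks < ks_max
    pairs[keep, , drop = FALSE]
}
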