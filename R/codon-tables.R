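# Internal codon machinery shared by the NG86 estimator and the sequence
# simulator. All tables are built once per session and cached.

.wgdpaint_cache <- new.env(parent = emptyenv())

.codons <- function() {
    names(Biostrings::GENETIC_CODE)
}

.codonAA <- function() {
    unname(Biostrings::GENETIC_CODE)
}

.isStopCodon <- function(codon) {
    Biostrings::GENETIC_CODE[codon] == "*"
}

#' @noRd
.translateCodons <- function(codons) {
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    unname(aa)
}

# Synonymous site count per codon: for each of the nine single-nucleotide
# changes, a change is synonymous iff it preserves the amino acid and does
# not create a stop. Changes to stop codons count as nonsynonymous so that
# S + N = 3 per codon. Stop codons themselves get NA (excluded upstream).
.ng86Sites <- function() {
    if (!is.null(.wgdpaint_cache$sites)) {
        return(.wgdpaint_cache$sites)
    }
    code <- Biostrings::GENETIC_CODE
    codons <- names(code)
    nts <- c("A", "C", "G", "T")
    s <- vapply(codons, function(cod) {
        if (code[[cod]] == "*") {
            return(NA_real_)
        }
        bases <- strsplit(cod, "")[[1]]
        syn <- 0
        for (pos in 1:3) {
            for (nt in setdiff(nts, bases[pos])) {
                alt <- bases
                alt[pos] <- nt
                altc <- paste(alt, collapse = "")
                if (code[[altc]] != "*" && code[[altc]] == code[[cod]]) {
                    syn <- syn + 1
                }
            }
        }
        syn / 3
    }, numeric(1))
    .wgdpaint_cache$sites <- s
    s
}

# Pathway-averaged synonymous/nonsynonymous difference counts per codon
# pair. For codons differing at d positions, all d! orderings of single
# steps are enumerated; orderings passing through a stop codon are dropped
# (if every ordering is blocked, all are used). Entries for pairs involving
# stop codons are NA.
.ng86PairTables <- function() {
    if (!is.null(.wgdpaint_cache$pair_sd)) {
        return(list(sd = .wgdpaint_cache$pair_sd, nd = .wgdpaint_cache$pair_nd))
    }
    code <- Biostrings::GENETIC_CODE
    codons <- names(code)
    n <- length(codons)
    sdM <- matrix(0, n, n, dimnames = list(codons, codons))
    ndM <- matrix(0, n, n, dimnames = list(codons, codons))

    step_counts <- function(from, to) {
        # one ordering: returns c(syn, nonsyn) or NULL if a stop intermediate
        bases_from <- strsplit(from, "")[[1]]
        bases_to <- strsplit(to, "")[[1]]
        diffs <- which(bases_from != bases_to)
        orders <- if (length(diffs) <= 1) list(diffs) else .permutations(diffs)
        paths <- list()
        for (ord in orders) {
            cur <- bases_from
            syn <- 0
            nonsyn <- 0
            ok <- TRUE
            for (pos in ord) {
                prev <- paste(cur, collapse = "")
                cur[pos] <- bases_to[pos]
                nxt <- paste(cur, collapse = "")
                if (code[[nxt]] == "*") {
                    ok <- FALSE
                    break
                }
                if (code[[nxt]] == code[[prev]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
            }
            if (ok) paths[[length(paths) + 1]] <- c(syn, nonsyn)
        }
        if (length(paths) == 0) {
            # all orderings blocked by a stop intermediate: fall back to
            # counting through them (classifying the stop steps too)
            for (ord in orders) {
                cur <- bases_from
                syn <- 0
                nonsyn <- 0
                for (pos in ord) {
                    prev <- paste(cur, collapse = "")
                    cur[pos] <- bases_to[pos]
                    nxt <- paste(cur, collapse = "")
                    if (code[[nxt]] == code[[prev]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
                }
                paths[[length(paths) + 1]] <- c(syn, nonsyn)
            }
        }
        m <- do.call(rbind, paths)
        colMeans(m)
    }

    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (code[[codons[i]]] == "*" || code[[codons[j]]] == "*") {
                sdM[i, j] <- NA_real_
                ndM[i, j] <- NA_real_
            } else if (i != j) {
                if (j > i) {
                    cnt <- step_counts(codons[i], codons[j])
                    sdM[i, j] <- cnt[1]
                    ndM[i, j] <- cnt[2]
                } else {
                    sdM[i, j] <- sdM[j, i]
                    ndM[i, j] <- ndM[j, i]
                }
            }
        }
    }
    .wgdpaint_cache$pair_sd <- sdM
    .wgdpaint_cache$pair_nd <- ndM
    list(sd = sdM, nd = ndM)
}

.permutations <- function(x) {
    if (length(x) == 1) {
        return(list(x))
    }
    out <- list()
    for (i in seq_along(x)) {
        for (rest in .permutations(x[-i])) {
            out[[length(out) + 1]] <- c(x[i], rest)
        }
    }
    out
}

# Split a nucleotide string into codons, dropping a trailing partial codon.
.splitCodons <- function(seq) {
    seq <- toupper(seq)
    n <- nchar(seq) %/% 3
    if (n == 0) {
        return(character(0))
    }
    substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# Synonymous alternatives per codon (same amino acid, excluding itself);
# used by the sequence simulator.
.synonymousAlternatives <- function() {
    if (!is.null(.wgdpaint_cache$syn_alt)) {
        return(.wgdpaint_cache$syn_alt)
    }
    code <- Biostrings::GENETIC_CODE
    alt <- lapply(names(code), function(cod) {
        if (code[[cod]] == "*") {
            return(character(0))
        }
        setdiff(names(code)[code == code[[cod]]], cod)
    })
    names(alt) <- names(code)
    .wgdpaint_cache$syn_alt <- alt
    alt
}

# Single-step nonsynonymous (non-stop) neighbours per codon.
.nonsynNeighbours <- function() {
    if (!is.null(.wgdpaint_cache$nonsyn_nb)) {
        return(.wgdpaint_cache$nonsyn_nb)
    }
    code <- Biostrings::GENETIC_CODE
    nts <- c("A", "C", "G", "T")
    nb <- lapply(names(code), function(cod) {
        if (code[[cod]] == "*") {
            return(character(0))
        }
        bases <- strsplit(cod, "")[[1]]
        out <- character(0)
        for (pos in 1:3) {
            for (nt in setdiff(nts, bases[pos])) {
                alt <- bases
                alt[pos] <- nt
                altc <- paste(alt, collapse = "")
                if (code[[altc]] != "*" && code[[altc]] != code[[cod]]) {
                    out <- c(out, altc)
                }
            }
        }
        out
    })
    names(nb) <- names(code)
    .wgdpaint_cache$nonsyn_nb <- nb
    nb
}

# Name-preserving coercion of a sequence container (XStringSet or named
# character vector) to a named character vector.
.seqChar <- function(x) {
    s <- as.character(x)
    if (is.null(names(s))) {
        names(s) <- names(x)
    }
    s
}
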