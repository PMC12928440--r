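# Independent oracles used across the suite. Each is written as direct,
# naive code so it shares no machinery with the implementation it checks.

GC <- Biostrings::GENETIC_CODE
NTS <- c("A", "C", "G", "T")

oracle_split_codons <- function(s) {
    s <- toupper(s)
    n <- nchar(s) %/% 3
    vapply(seq_len(n), function(i) substr(s, 3 * i - 2, 3 * i), character(1))
}

# --- NG86 pathway-enumeration oracle ---------------------------------------

oracle_syn_sites <- function(codon) {
    aa <- GC[[codon]]
    bases <- strsplit(codon, "")[[1]]
    syn <- 0
    for (pos in 1:3) {
        for (nt in NTS[NTS != bases[pos]]) {
            alt <- bases
            alt[pos] <- nt
            alt_aa <- GC[[paste(alt, collapse = "")]]
            if (alt_aa != "*" && alt_aa == aa) syn <- syn + 1
        }
    }
    syn / 3
}

oracle_all_orderings <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
        for (tail in oracle_all_orderings(v[-i])) {
            out[[length(out) + 1]] <- c(v[i], tail)
        }
    }
    out
}

oracle_pair_diffs <- function(c1, c2) {
    b1 <- strsplit(c1, "")[[1]]
    b2 <- strsplit(c2, "")[[1]]
    pos <- which(b1 != b2)
    if (length(pos) == 0) return(c(0, 0))
    walk <- function(ord, allow_stop) {
        cur <- b1
        sy <- 0
        ns <- 0
        for (p in ord) {
            before <- GC[[paste(cur, collapse = "")]]
            cur[p] <- b2[p]
            after <- GC[[paste(cur, collapse = "")]]
            if (after == "*" && !allow_stop) return(NULL)
            if (after == before) sy <- sy + 1 else ns <- ns + 1
        }
        c(sy, ns)
    }
    res <- Filter(Negate(is.null),
                  lapply(oracle_all_orderings(pos), walk, allow_stop = FALSE))
    if (length(res) == 0) {
        res <- lapply(oracle_all_orderings(pos), walk, allow_stop = TRUE)
    }
    colMeans(do.call(rbind, res))
}

# Full NG86 on two aligned stop-free codon vectors.
oracle_ng86 <- function(cod_a, cod_b) {
    keep <- !(GC[cod_a] == "*" | GC[cod_b] == "*" |
                  is.na(GC[cod_a]) | is.na(GC[cod_b]))
    cod_a <- cod_a[keep]
    cod_b <- cod_b[keep]
    S <- (sum(vapply(cod_a, oracle_syn_sites, numeric(1))) +
              sum(vapply(cod_b, oracle_syn_sites, numeric(1)))) / 2
    N <- 3 * length(cod_a) - S
    d <- rowSums(vapply(seq_along(cod_a), function(i)
        oracle_pair_diffs(cod_a[i], cod_b[i]), numeric(2)))
    ps <- d[1] / S
    pn <- d[2] / N
    jc <- function(p) if (p >= 0.75) NA_real_ else if (p <= 0) 0 else
        -0.75 * log(1 - 4 * p / 3)
    list(S = S, N = N, Sd = d[1], Nd = d[2], ps = ps, pn = pn,
         Ks = jc(ps), Ka = jc(pn))
}

# --- Protein Needleman-Wunsch (Gotoh affine) oracle ------------------------

oracle_blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})

oracle_nw_score <- function(p1, p2, go = 10, ge = 0.5) {
    a <- strsplit(p1, "")[[1]]
    b <- strsplit(p2, "")[[1]]
    n <- length(a)
    m <- length(b)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
    Y <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
    M[1, 1] <- 0
    for (i in 2:(n + 1)) X[i, 1] <- -(go + ge * (i - 1))
    for (j in 2:(m + 1)) Y[1, j] <- -(go + ge * (j - 1))
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            s <- oracle_blosum62[a[i - 1], b[j - 1]]
            M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                           Y[i - 1, j - 1]) + s
            X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
            Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
        }
    }
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- Brute-force RBH oracle -------------------------------------------------

oracle_rbh <- function(hits_ab, hits_ba) {
    best_of <- function(h, q) {
        hh <- h[h$qseqid == q, , drop = FALSE]
        if (nrow(hh) == 0) return(NA_character_)
        # collapse HSPs to best per subject first
        subs <- unique(hh$sseqid)
        per <- lapply(subs, function(s) {
            d <- hh[hh$sseqid == s, , drop = FALSE]
            d <- d[order(-d$bitscore, d$evalue, -d$pident), , drop = FALSE]
            d[1, ]
        })
        d <- do.call(rbind, per)
        d <- d[order(-d$bitscore, d$evalue, -d$pident, d$sseqid), ,
               drop = FALSE]
        d$sseqid[1]
    }
    pairs <- character(0)
    for (q in unique(hits_ab$qseqid)) {
        s <- best_of(hits_ab, q)
        if (is.na(s)) next
        back <- best_of(hits_ba, s)
        if (identical(back, q)) {
            pairs <- c(pairs, paste(q, s, sep = "\r"))
        }
    }
    sort(pairs)
}

# --- Brute-force chaining oracle -------------------------------------------

# Same definition as the implementation (longest chain, ascending
# preferred, lexicographically smallest, iterated extraction) written as
# plain nested loops over explicit candidate lists.
oracle_chain_blocks <- function(ra, rb, min_pairs, max_gap) {
    # ladder of gap allowances: every level at which some pair-to-pair
    # link first becomes legal, computed over the full instance
    lvls <- 0
    for (i in seq_along(ra)) {
        for (j in seq_along(ra)) {
            if (j <= i) next
            g <- max(abs(ra[i] - ra[j]), abs(rb[i] - rb[j])) - 1
            if (g <= max_gap) lvls <- c(lvls, g)
        }
    }
    lvls <- sort(unique(lvls))
    chains <- list()
    alive <- order(ra, rb)
    for (gap_allow in lvls) {
        chains <- oracle_extract_at(ra, rb, alive, min_pairs, gap_allow,
                                    chains)
        alive <- setdiff(alive, unlist(chains))
        if (length(alive) < min_pairs) break
    }
    chains
}

oracle_extract_at <- function(ra, rb, alive, min_pairs, max_gap, chains) {
    repeat {
        if (length(alive) < min_pairs) break
        sra <- ra[alive]
        srb <- rb[alive]
        n <- length(alive)
        best_len <- 0
        best_chain <- NULL
        for (desc in c(FALSE, TRUE)) {
            f <- integer(n)
            for (i in n:1) {
                mx <- 0
                for (j in seq_len(n)) {
                    if (j > i) {
                        oka <- sra[j] > sra[i] && sra[j] - sra[i] - 1 <= max_gap
                        d <- if (desc) srb[i] - srb[j] else srb[j] - srb[i]
                        if (oka && d > 0 && d - 1 <= max_gap && f[j] > mx) {
                            mx <- f[j]
                        }
                    }
                }
                f[i] <- mx + 1
            }
            if (max(f) > best_len) {
                best_len <- max(f)
                # greedy lexicographic reconstruction
                ch <- integer(0)
                need <- best_len
                prev <- 0
                while (need > 0) {
                    for (i in seq_len(n)) {
                        if (f[i] != need) next
                        if (prev > 0) {
                            if (i <= prev) next
                            oka <- sra[i] > sra[prev] &&
                                sra[i] - sra[prev] - 1 <= max_gap
                            d <- if (desc) srb[prev] - srb[i] else
                                srb[i] - srb[prev]
                            if (!(oka && d > 0 && d - 1 <= max_gap)) next
                        }
                        ch <- c(ch, i)
                        prev <- i
                        break
                    }
                    need <- need - 1
                }
                best_chain <- ch
            }
        }
        if (best_len < min_pairs) break
        chains[[length(chains) + 1]] <- alive[best_chain]
        alive <- alive[-best_chain]
    }
    chains
}

# --- Exact multinomial majority probabilities ------------------------------

# Support of each origin: probability that it holds the (possibly tied)
# maximum count among m draws, ties contributing 1/#tied.
oracle_majority_support <- function(probs, m) {
    k <- length(probs)
    support <- stats::setNames(numeric(k), names(probs))
    counts <- function(left, vec) {
        if (length(vec) == k - 1) {
            full <- c(vec, left)
            p <- stats::dmultinom(full, prob = probs)
            mx <- max(full)
            tied <- which(full == mx)
            support[tied] <<- support[tied] + p / length(tied)
            return(invisible(NULL))
        }
        for (x in 0:left) counts(left - x, c(vec, x))
    }
    counts(m, integer(0))
    support
}
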