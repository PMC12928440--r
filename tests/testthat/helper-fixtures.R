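# In-code fixtures shared across tests (all generated deterministically).

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]

random_cds <- function(codons, seed) {
    set.seed(seed)
    paste(c("ATG", sample(SENSE_CODONS, codons - 1, replace = TRUE)),
          collapse = "")
}

# Codon-pair fixtures for the NG86 oracle-equivalence checks: crafted
# edge cases (multi-position differences, serine-island jumps,
# stop-adjacent codons) plus seeded random pairs of up to 15 codons.
ng86_fixture_pairs <- function() {
    crafted <- list(
        list(a = c("ATG", "AAA", "CCC"), b = c("ATG", "AAA", "CCC")),
        list(a = c("AAA", "GGG"), b = c("AAG", "GGA")),            # syn only
        list(a = c("TTT", "GAT"), b = c("TTA", "GAA")),            # mixed
        list(a = c("AGT", "TGG"), b = c("TCT", "CGG")),            # 3-diff ser
        list(a = c("TGT", "TAT"), b = c("TGG", "TAC")),            # stop-adj
        list(a = c("ATG", "CGA", "GGG"), b = c("ATG", "AGG", "GGC"))
    )
    set.seed(42)
    random <- lapply(1:30, function(i) {
        n <- sample(2:15, 1)
        a <- sample(SENSE_CODONS, n, replace = TRUE)
        b <- a
        # mutate a few positions of b, sometimes multiple bases per codon
        for (j in seq_len(n)) {
            if (runif(1) < 0.6) {
                bb <- strsplit(b[j], "")[[1]]
                for (pos in sample(1:3, sample(1:3, 1))) {
                    bb[pos] <- sample(c("A", "C", "G", "T"), 1)
                }
                cand <- paste(bb, collapse = "")
                if (Biostrings::GENETIC_CODE[[cand]] != "*") b[j] <- cand
            }
        }
        list(a = a, b = b)
    })
    c(crafted, random)
}

# Random outfmt-6-style hit tables between two gene sets.
random_hit_table <- function(n_a, n_b, n_hits, seed) {
    set.seed(seed)
    data.frame(
        qseqid = sprintf("a%02d", sample(n_a, n_hits, replace = TRUE)),
        sseqid = sprintf("b%02d", sample(n_b, n_hits, replace = TRUE)),
        pident = round(runif(n_hits, 70, 100), 2),
        length = sample(60:500, n_hits, replace = TRUE),
        mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
        sstart = 1L, send = 1L,
        evalue = 10^-runif(n_hits, 6, 50),
        bitscore = round(runif(n_hits, 50, 900), 1),
        stringsAsFactors = FALSE
    )
}

# A random collinearity instance emulating a filtered homolog table on one
# chromosome pair: a few collinear runs (some inverted, with rank jitter)
# plus sparse background noise pairs.
random_chain_instance <- function(n_genes, seed) {
    set.seed(seed)
    used_a <- logical(n_genes)
    used_b <- logical(n_genes)
    ra <- integer(0)
    rb <- integer(0)
    n_runs <- sample(1:4, 1)
    for (r in seq_len(n_runs)) {
        len <- sample(4:20, 1)
        step_a <- 1 + rpois(len - 1, 0.8)
        step_b <- 1 + rpois(len - 1, 0.8)
        start_a <- sample(n_genes, 1)
        start_b <- sample(n_genes, 1)
        pos_a <- start_a + c(0, cumsum(step_a))
        pos_b <- start_b + c(0, cumsum(step_b))
        if (runif(1) < 0.3) pos_b <- rev(pos_b)
        ok <- pos_a <= n_genes & pos_b <= n_genes
        pos_a <- pos_a[ok]
        pos_b <- pos_b[ok]
        free <- !used_a[pos_a] & !used_b[pos_b]
        pos_a <- pos_a[free]
        pos_b <- pos_b[free]
        used_a[pos_a] <- TRUE
        used_b[pos_b] <- TRUE
        ra <- c(ra, pos_a)
        rb <- c(rb, pos_b)
    }
    n_noise <- rpois(1, max(2, length(ra) * 0.12))
    for (i in seq_len(n_noise)) {
        fa <- which(!used_a)
        fb <- which(!used_b)
        if (!length(fa) || !length(fb)) break
        a <- fa[sample(length(fa), 1)]
        b <- fb[sample(length(fb), 1)]
        used_a[a] <- TRUE
        used_b[b] <- TRUE
        ra <- c(ra, a)
        rb <- c(rb, b)
    }
    ord <- order(ra)
    list(ra = ra[ord], rb = rb[ord])
}

chain_setup <- function(ra, rb) {
    pos_a <- positions_from_ranks("a", "chrA", seq_len(max(ra)))
    pos_b <- positions_from_ranks("b", "chrB", seq_len(max(rb)))
    pairs <- data.frame(gene_a = sprintf("a%03d", ra),
                        gene_b = sprintf("b%03d", rb),
                        stringsAsFactors = FALSE)
    list(pairs = pairs, pos_a = pos_a, pos_b = pos_b)
}

positions_from_ranks <- function(prefix, chrom, ranks) {
    data.frame(
        gene_id = sprintf("%s%03d", prefix, ranks), chrom = chrom,
        rank = as.integer(ranks), strand = "+", stringsAsFactors = FALSE
    )
}

# Small cached replay shared by simulator/pipeline/karyotype tests (the
# acceptance test runs its own full-size replay).
small_replay <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cache <<- runSpartinaReplay(genes_per_chrom = 30,
                                        mask_rate = 0, seed = 7,
                                        n_bootstrap = 300)
        }
        cache
    }
})
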