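test_that("five collinear pairs form one block and four form none", {
    s <- chain_setup(1:5, 11:15)
    out <- chainBlocks(s$pairs, s$pos_a, s$pos_b)
    expect_equal(nrow(out$blocks), 1)
    expect_equal(out$blocks$n_pairs, 5)
    expect_equal(out$blocks$orientation, "same")
    s4 <- chain_setup(1:4, 11:14)
    expect_equal(nrow(chainBlocks(s4$pairs, s4$pos_a, s4$pos_b)$blocks), 0)
})

test_that("inverted collinearity is chained as a distinct orientation", {
    s <- chain_setup(1:6, 16:11)
    out <- chainBlocks(s$pairs, s$pos_a, s$pos_b)
    expect_equal(out$blocks$orientation, "inverted")
    expect_equal(out$blocks$n_pairs, 6)
})

test_that("gap constraint applies to both genomes", {
    # gap of 3 intervening genes on genome B exceeds max_gap = 2, so the
    # two tight runs chain separately; a run needing the larger allowance
    # only chains when max_gap admits it
    s <- chain_setup(1:6, c(1, 2, 3, 7, 8, 9))
    out <- chainBlocks(s$pairs, s$pos_a, s$pos_b, min_pairs = 3, max_gap = 2)
    expect_equal(nrow(out$blocks), 2)
    expect_equal(sort(out$blocks$n_pairs), c(3, 3))
    wide <- chain_setup(1:6, c(1, 2, 6, 11, 16, 21))
    expect_equal(nrow(chainBlocks(wide$pairs, wide$pos_a, wide$pos_b,
                                  min_pairs = 5, max_gap = 2)$blocks), 0)
    out_loose <- chainBlocks(wide$pairs, wide$pos_a, wide$pos_b,
                             min_pairs = 5, max_gap = 5)
    expect_equal(nrow(out_loose$blocks), 1)
    expect_equal(out_loose$blocks$n_pairs, 6)
})

test_that("chaining equals the brute-force DP oracle on random instances", {
    for (seed in 1:40) {
        inst <- random_chain_instance(sample(40:200, 1), seed = seed)
        s <- chain_setup(inst$ra, inst$rb)
        for (gap in c(20, 100)) {
            out <- chainBlocks(s$pairs, s$pos_a, s$pos_b, min_pairs = 3,
                               max_gap = gap)
            oracle <- oracle_chain_blocks(inst$ra, inst$rb, min_pairs = 3,
                                          max_gap = gap)
            got <- if (nrow(out$members)) {
                lapply(split(out$members, out$members$block_id), function(m)
                    sort(paste(m$rank_a, m$rank_b)))
            } else list()
            want <- lapply(oracle, function(idx)
                sort(paste(inst$ra[idx], inst$rb[idx])))
            expect_equal(unname(got[order(vapply(got, paste, character(1),
                                                 collapse = ";"))]),
                         unname(want[order(vapply(want, paste, character(1),
                                                  collapse = ";"))]))
        }
    }
})

test_that("chained-pair totals are monotone in the gap threshold", {
    for (seed in 41:70) {
        inst <- random_chain_instance(sample(60:200, 1), seed = seed)
        s <- chain_setup(inst$ra, inst$rb)
        tot <- vapply(c(100, 60, 20), function(gap) {
            sum(chainBlocks(s$pairs, s$pos_a, s$pos_b, min_pairs = 5,
                            max_gap = gap)$blocks$n_pairs)
        }, numeric(1))
        expect_true(all(diff(tot) <= 0))
    }
})

test_that("same-chromosome multicopy genes are excluded, cross-chromosome kept", {
    pos_a <- positions_from_ranks("a", "chrA", 1:3)
    pos_b <- rbind(positions_from_ranks("b", "chr1", 1:4),
                   positions_from_ranks("c", "chr2", 1:2))
    pairs <- data.frame(
        gene_a = c("a001", "a001", "a002", "a002", "a003"),
        gene_b = c("b001", "b002", "b003", "c001", "c002"),
        stringsAsFactors = FALSE
    )
    out <- dropSameChromosomeMulticopy(pairs, pos_a, pos_b)
    # a001 has two homologs on chr1 -> both removed; a002 split across
    # chromosomes -> kept
    expect_setequal(out$gene_a, c("a002", "a003"))
    expect_error(
        dropSameChromosomeMulticopy(
            data.frame(gene_a = "zzz", gene_b = "b001"), pos_a, pos_b),
        "zzz")
})

test_that("multicopy filter equals a per-(gene, chromosome) count oracle", {
    set.seed(12)
    for (rep in 1:5) {
        pos_a <- positions_from_ranks("a", "chrA", 1:30)
        pos_b <- rbind(positions_from_ranks("b", "chr1", 1:30),
                       positions_from_ranks("c", "chr2", 1:30))
        pairs <- unique(data.frame(
            gene_a = sprintf("a%03d", sample(30, 60, TRUE)),
            gene_b = sample(c(sprintf("b%03d", 1:30),
                              sprintf("c%03d", 1:30)), 60, TRUE),
            stringsAsFactors = FALSE
        ))
        out <- dropSameChromosomeMulticopy(pairs, pos_a, pos_b)
        chrom_of <- function(g) ifelse(grepl("^b", g), "chr1", "chr2")
        keep <- logical(nrow(pairs))
        for (i in seq_len(nrow(pairs))) {
            cb <- chrom_of(pairs$gene_b[i])
            n_same <- sum(pairs$gene_a == pairs$gene_a[i] &
                              chrom_of(pairs$gene_b) == cb)
            n_back <- sum(pairs$gene_b == pairs$gene_b[i])
            keep[i] <- n_same < 2 && n_back < 2
        }
        expect_setequal(paste(out$gene_a, out$gene_b),
                        paste(pairs$gene_a, pairs$gene_b)[keep])
    }
})

test_that("syntenic depth counts distinct partners and reports the mode", {
    blocks <- data.frame(
        chr_a = c("r1", "r1", "r1", "r1", "r2", "r2", "r3", "r3"),
        chr_b = c("s1", "s2", "s3", "s4", "s5", "s6", "s7", "s7"),
        n_pairs = 10
    )
    d <- syntenicDepth(blocks, reference_chroms = c("r1", "r2", "r3", "r4"))
    expect_equal(unname(d$depth), c(4L, 2L, 1L, 0L))
    blocks_self <- data.frame(chr_a = c("c1", "c2"), chr_b = c("c1", "c2"),
                              n_pairs = 5)
    expect_equal(
        syntenicDepth(blocks_self, exclude_self = TRUE)$modal_depth, 0L)
    expect_equal(syntenicDepth(blocks_self)$modal_depth, 1L)
})

test_that("scaffolds are grouped into pseudochromosomes by plurality", {
    blocks <- data.frame(
        chr_a = c("sc1", "sc1", "sc2", "sc3", "sc3"),
        chr_b = c("chr3", "chr5", "chr3", "chr2", "chr7"),
        n_pairs = c(40, 10, 12, 6, 6)
    )
    out <- assemblePseudochromosomes(blocks,
                                     scaffolds = c("sc1", "sc2", "sc3",
                                                   "sc4"))
    m <- out$map
    expect_equal(m$pseudochromosome[m$scaffold == "sc1"], "chr3")
    expect_equal(m$pseudochromosome[m$scaffold == "sc2"], "chr3")
    # 50/50 tie resolved toward the lower-numbered chromosome and flagged
    expect_equal(m$pseudochromosome[m$scaffold == "sc3"], "chr2")
    expect_true(m$tie[m$scaffold == "sc3"])
    expect_equal(out$unplaced, "sc4")
})

test_that("dotplot export labels Ks bands as closed-open intervals", {
    pos_a <- positions_from_ranks("a", "chrA", 1:5)
    pos_b <- positions_from_ranks("b", "chrB", 1:5)
    pairs <- data.frame(
        gene_a = sprintf("a%03d", 1:5), gene_b = sprintf("b%03d", 1:5),
        Ks = c(0.5, 0.478, 0.786, 0.1, NA)
    )
    bands <- data.frame(lower = 0.478, upper = 0.786, label = "wgd")
    out <- exportDotplotTable(pairs, pos_a, pos_b, bands)
    expect_equal(out$band, c("wgd", "wgd", "other", "other", "other"))
    set.seed(8)
    ks <- runif(50, 0, 1)
    pairs2 <- data.frame(gene_a = rep("a001", 50), gene_b = rep("b001", 50),
                         Ks = ks)
    bands2 <- data.frame(lower = c(0, 0.3), upper = c(0.3, 0.6),
                         label = c("lo", "mid"))
    out2 <- exportDotplotTable(pairs2, pos_a, pos_b, bands2)
    want <- ifelse(ks < 0.3, "lo", ifelse(ks < 0.6, "mid", "other"))
    expect_equal(out2$band, want)
    empty <- exportDotplotTable(pairs[0, ], pos_a, pos_b, bands)
    expect_equal(nrow(empty), 0)
})
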