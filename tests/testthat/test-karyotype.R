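published_map <- readHomologyMap(
    system.file("extdata", "ancestral_homology_map.tsv",
                package = "WGDpaint"))

test_that("published homology map resolves known single and multi origins", {
    # all hits on rice chromosome 1 imply A1 with probability 1
    hits <- data.frame(species = "O_sativa", chromosome = "1",
                       bitscore = c(200, 350))
    v <- mapHitsToAncestral(hits, published_map)
    expect_equal(unname(v["A1"]), 1)
    # one sorghum chromosome-2 hit shares its mass among A6, A7 and A9
    hits2 <- data.frame(species = "S_bicolor", chromosome = "2",
                        bitscore = 300)
    v2 <- mapHitsToAncestral(hits2, published_map)
    expect_setequal(names(v2), c("A6", "A7", "A9"))
    expect_equal(as.numeric(v2), rep(1 / 3, 3))
    expect_equal(sum(v2), 1, tolerance = 1e-9)
    expect_error(mapHitsToAncestral(hits[0, ], published_map), "no comp")
    expect_error(
        mapHitsToAncestral(data.frame(species = "O_sativa",
                                      chromosome = "99", bitscore = 1),
                           published_map),
        "99")
})

test_that("origin probabilities are bitscore-weighted before normalization", {
    map <- data.frame(species = "sp",
                      chrom = c("c1", "c2"),
                      origin = c("A1", "A2"))
    hits <- data.frame(species = "sp", chromosome = c("c1", "c2"),
                       bitscore = c(300, 100))
    v <- mapHitsToAncestral(hits, map)
    expect_equal(unname(v[c("A1", "A2")]), c(0.75, 0.25))
})

test_that("bootstrap support matches exact multinomial majority probabilities", {
    cases <- list(
        list(p = c(A = 0.6, B = 0.3, C = 0.1), m = 5),
        list(p = c(A = 0.5, B = 0.5), m = 4),
        list(p = c(A = 0.45, B = 0.35, C = 0.2), m = 6),
        list(p = c(A = 0.8, B = 0.2), m = 3),
        list(p = c(A = 1 / 3, B = 1 / 3, C = 1 / 3), m = 6)
    )
    for (cs in cases) {
        exact <- oracle_majority_support(cs$p, cs$m)
        got <- bootstrapAssign(cs$p, m = cs$m, n_bootstrap = 1000,
                               seed = 99)$support_table
        for (o in names(cs$p)) {
            expect_lt(abs(got[o] - exact[o]), 0.02)
        }
    }
})

test_that("certain and symmetric cases assign as expected", {
    sure <- bootstrapAssign(c(A3 = 1), m = 4, seed = 1)
    expect_equal(sure$status, "unique")
    expect_equal(sure$origin, "A3")
    expect_equal(sure$support, 1)
    split <- bootstrapAssign(c(A1 = 0.5, A2 = 0.5), m = 4,
                             n_bootstrap = 2000, seed = 1)
    expect_equal(split$status, "ambiguous")
    expect_lt(split$margin, 0.05)
})

test_that("stricter support or margin thresholds never create uniqueness", {
    set.seed(30)
    for (rep in 1:20) {
        p <- runif(3)
        p <- sort(p / sum(p), decreasing = TRUE)
        names(p) <- c("A1", "A2", "A3")
        loose <- bootstrapAssign(p, m = 5, n_bootstrap = 500, seed = rep)
        strict <- bootstrapAssign(p, m = 5, n_bootstrap = 500, seed = rep,
                                  support_min = 0.7, margin_min = 0.2)
        if (loose$status == "ambiguous") {
            expect_equal(strict$status, "ambiguous")
        }
    }
})

make_members <- function(genes, chrom = "c1", block = 1L) {
    data.frame(block_id = block, gene_a = genes, gene_b = paste0(genes, "_p"),
               chr_a = chrom, chr_b = "p1", rank_a = seq_along(genes),
               rank_b = seq_along(genes), Ks = 0.1,
               stringsAsFactors = FALSE)
}

test_that("ambiguous members inherit a compatible block origin", {
    genes <- sprintf("g%02d", 1:10)
    assignments <- data.frame(
        gene_id = genes,
        origin = c(rep("A5", 4), NA, NA, rep("A5", 4)),
        support = 0.9, margin = 0.5,
        status = c(rep("unique", 4), "ambiguous", "ambiguous",
                   rep("unique", 4)),
        candidates = c(rep("A5", 4), "A5,A3", "A2,A4", rep("A5", 4)),
        m = 3, stringsAsFactors = FALSE
    )
    painted <- paintBlocks(assignments, make_members(genes))
    expect_equal(painted$origin[painted$gene_id == "g05"], "A5")
    expect_equal(painted$status[painted$gene_id == "g05"], "inherited")
    # the A5-incompatible ambiguous gene stays ambiguous
    expect_true(is.na(painted$origin[painted$gene_id == "g06"]))
})

test_that("blocks split where unambiguous members disagree", {
    genes <- sprintf("g%02d", 1:10)
    assignments <- data.frame(
        gene_id = genes,
        origin = c(rep("A5", 5), rep("A3", 5)),
        support = 0.9, margin = 0.5, status = "unique",
        candidates = c(rep("A5", 5), rep("A3", 5)),
        m = 3, stringsAsFactors = FALSE
    )
    painted <- paintBlocks(assignments, make_members(genes))
    expect_equal(length(unique(painted$sub_block)), 2)
    expect_equal(unique(painted$origin[1:5]), "A5")
    expect_equal(unique(painted$origin[6:10]), "A3")
})

test_that("high-ambiguity windows are excised as transition zones", {
    genes <- sprintf("g%02d", 1:30)
    status <- rep("unique", 30)
    status[11:20] <- "ambiguous"
    painted <- data.frame(
        gene_id = genes, chrom = "c1", rank = 1:30, block_id = 1L,
        sub_block = 1L,
        origin = ifelse(status == "unique", "A1", NA),
        status = status, stringsAsFactors = FALSE
    )
    out <- terminateTransitionZones(painted, window = 10, threshold = 0.5)
    zones <- attr(out, "zones")
    expect_equal(nrow(zones), 1)
    expect_true(all(out$status[11:20] == "transition"))
    # a clean block is untouched
    clean <- painted
    clean$status <- "unique"
    clean$origin <- "A1"
    out2 <- terminateTransitionZones(clean, window = 10, threshold = 0.5)
    expect_equal(nrow(attr(out2, "zones")), 0)
    expect_identical(out2$status, clean$status)
})

seg <- function(chrom, origins, n = 10) {
    data.frame(chrom = chrom, start_rank = seq_along(origins),
               end_rank = seq_along(origins), origin = origins,
               n_genes = n, stringsAsFactors = FALSE)
}

test_that("painted patterns yield NCI calls, nested ones innermost-first", {
    ev <- callRearrangements(seg("c1", c("A6", "A9", "A6")))
    expect_equal(ev$type, "NCI")
    expect_equal(ev$inserted, "A9")
    expect_equal(ev$outer, "A6")
    nested <- callRearrangements(
        seg("c2", c("A2", "A10", "A12", "A10", "A2")))
    expect_equal(nested$type, c("NCI", "NCI"))
    expect_equal(nested$inserted, c("A12", "A10"))
    expect_equal(nested$outer, c("A10", "A2"))
    expect_equal(nested$depth, c(1L, 2L))
    none <- callRearrangements(seg("c3", "A4"))
    expect_equal(nrow(none), 0)
})

test_that("reciprocal junctions are translocations, one-sided ones are not", {
    segs <- rbind(seg("c1", c("A6", "A1")), seg("c2", c("A1", "A6")))
    ev <- callRearrangements(segs)
    expect_true(all(ev$type == "translocation"))
    lone <- callRearrangements(rbind(seg("c1", c("A6", "A1")),
                                     seg("c2", "A3")))
    expect_equal(lone$type, "end_fusion")
    expect_false(lone$unresolved)
    # partner truncated elsewhere without reciprocity -> unresolved
    half <- callRearrangements(rbind(seg("c1", c("A6", "A1")),
                                     seg("c2", c("A1", "A3"))))
    expect_true(any(half$unresolved))
    short <- callRearrangements(seg("c1", c("A6", "A9", "A6"), n = 3),
                                min_segment = 5)
    expect_equal(nrow(short), 0)
})
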