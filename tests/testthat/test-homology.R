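make_hit <- function(q = "a1", s = "b1", pident = 90, len = 200,
                     evalue = 1e-20, bitscore = 300) {
    data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
               sstart = 1L, send = len, evalue = evalue,
               bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("threshold boundaries follow the strict/inclusive rules", {
    hits <- rbind(
        make_hit("a1", "b1", pident = 69.9),          # identity below 70
        make_hit("a2", "b2", pident = 70),            # identity at 70: kept
        make_hit("a3", "b3", evalue = 1e-5),          # e-value not strictly <
        make_hit("a4", "b4", len = 59),               # too short
        make_hit("a5", "b5", len = 60)                # exactly 60: kept
    )
    out <- filterHits(hits)
    expect_setequal(out$qseqid, c("a2", "a5"))
})

test_that("repeat-rich CDS removes every hit touching the gene", {
    seqs <- c(
        a1 = paste(rep("ACGT", 30), collapse = ""),
        b1 = paste0(tolower(paste(rep("acgt", 8), collapse = "")),
                    paste(rep("ACGT", 22), collapse = "")),  # 26.7% masked
        b2 = paste(rep("ACGT", 30), collapse = "")
    )
    hits <- rbind(make_hit("a1", "b1"), make_hit("a1", "b2"))
    out <- filterHits(hits, masked_cds = seqs)
    expect_equal(out$sseqid, "b2")
    expect_error(filterHits(make_hit("a1", "zz"), masked_cds = seqs),
                 "missing")
})

test_that("repeat fraction is an exact lowercase count", {
    expect_equal(repeatFraction("ACGTACGT"), 0)
    s25 <- paste0(strrep("a", 30), strrep("A", 90))
    expect_equal(repeatFraction(s25), 0.25)
    # a CDS at exactly 25% is kept (rule is strictly greater)
    hits <- make_hit("a1", "b1")
    seqs <- c(a1 = s25, b1 = "ACGT")
    expect_equal(nrow(filterHits(hits, masked_cds = seqs)), 1)
    expect_error(repeatFraction(""), "empty")
    set.seed(3)
    chars <- sample(c(letters[1:4], LETTERS[1:4]), 200, replace = TRUE)
    s <- paste(chars, collapse = "")
    expect_equal(repeatFraction(s), mean(chars %in% letters))
})

test_that("mutual best hits are kept and one-sided bests are not", {
    ab <- rbind(make_hit("a1", "b1", bitscore = 500),
                make_hit("a1", "b2", bitscore = 300),
                make_hit("a2", "b2", bitscore = 400))
    ba <- rbind(make_hit("b1", "a1", bitscore = 500),
                make_hit("b2", "a1", bitscore = 450),  # b2 prefers a1
                make_hit("b2", "a2", bitscore = 400))
    out <- reciprocalBestHits(ab, ba)
    expect_equal(nrow(out), 1)
    expect_equal(out$gene_a, "a1")
    expect_equal(out$gene_b, "b1")
    expect_equal(out$bitscore, 500)
})

test_that("RBH equals a brute-force oracle on random tables", {
    for (seed in 1:10) {
        ab <- random_hit_table(20, 20, 80, seed = seed)
        ba <- random_hit_table(20, 20, 80, seed = seed + 100)
        names(ba)[1:2] <- c("qseqid", "sseqid")
        ba$qseqid <- sub("^a", "b", ba$qseqid)
        ba$sseqid <- sub("^b", "a", ba$sseqid)
        out <- reciprocalBestHits(ab, ba)
        got <- sort(paste(out$gene_a, out$gene_b, sep = "\r"))
        expect_identical(got, oracle_rbh(ab, ba))
        # symmetry: swapping directions yields the same unordered pairs
        swapped <- reciprocalBestHits(ba, ab)
        expect_identical(sort(paste(swapped$gene_b, swapped$gene_a,
                                    sep = "\r")), got)
        expect_lte(nrow(out), min(length(unique(ab$qseqid)),
                                  length(unique(ba$qseqid))))
    }
})

test_that("relaxing any filter threshold never removes a surviving hit", {
    hits <- random_hit_table(15, 15, 120, seed = 4)
    hits$pident <- round(runif(120, 50, 100), 1)
    hits$evalue <- 10^-runif(120, 2, 40)
    hits$length <- sample(30:300, 120, replace = TRUE)
    base <- filterHits(hits)
    relaxed <- list(
        filterHits(hits, max_evalue = 1e-3),
        filterHits(hits, min_identity = 50),
        filterHits(hits, min_length = 30)
    )
    key <- function(d) paste(d$qseqid, d$sseqid, d$bitscore)
    for (r in relaxed) {
        expect_true(all(key(base) %in% key(r)))
    }
})

test_that("outfmt-6 tables round-trip through the reader", {
    hits <- random_hit_table(5, 5, 12, seed = 9)
    path <- withr::local_tempfile(fileext = ".tsv")
    write.table(cbind(hits, extra = "x"), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    back <- readBlastTab(path)
    expect_equal(back$bitscore, hits$bitscore)
    expect_equal(ncol(back), 12)
    expect_equal(nrow(reciprocalBestHits(hits[0, ], hits[0, ])), 0)
})
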