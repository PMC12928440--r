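test_that("identical sequences give zero divergence", {
    cod <- oracle_split_codons("ATGGCTAAACCCGGG")
    r <- ng86(list(a = cod, b = cod))
    expect_equal(r$Sd, 0)
    expect_equal(r$Nd, 0)
    expect_equal(r$Ks, 0)
    expect_equal(r$Ka, 0)
    expect_equal(r$S + r$N, 3 * r$codons)
})

test_that("synonymous-only third-position changes leave Ka at zero", {
    a <- c("ATG", "AAA", "GGG", "CCC", "GTT")
    b <- c("ATG", "AAG", "GGA", "CCC", "GTT")
    r <- ng86(list(a = a, b = b))
    expect_equal(r$Nd, 0)
    expect_equal(r$Ka, 0)
    expect_gt(r$Ks, 0)
})

test_that("estimator matches the pathway-enumeration oracle exactly", {
    for (fx in ng86_fixture_pairs()) {
        r <- ng86(list(a = fx$a, b = fx$b))
        o <- oracle_ng86(fx$a, fx$b)
        expect_equal(r$S, o$S, tolerance = 1e-12)
        expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
        expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
        expect_equal(r$Ks, o$Ks, tolerance = 1e-12)
        expect_equal(r$Ka, o$Ka, tolerance = 1e-12)
    }
})

test_that("gap, stop and ambiguous columns are excluded from comparison", {
    a <- c("ATG", "---", "TGA", "ANG", "AAA")
    b <- c("ATG", "GGG", "TGG", "AAG", "AAG")
    r <- ng86(list(a = a, b = b))
    expect_equal(r$codons, 2)  # only ATG/ATG and AAA/AAG compared
    expect_error(ng86(list(a = c("---", "TAA"), b = c("AAA", "TAA"))),
                 "comparable")
})

test_that("saturation is flagged instead of returning a number", {
    # maximally divergent synonymous codons repeated: ps above 3/4
    a <- rep(c("TCT", "CGA"), 20)
    b <- rep(c("AGC", "AGG"), 20)
    r <- ng86(list(a = a, b = b))
    if (r$ps >= 0.75) {
        expect_true(r$saturated_s)
        expect_true(is.na(r$Ks))
    } else {
        succeed()
    }
})

test_that("Ks range filter applies [0.01, 3) and drops saturated pairs", {
    pairs <- data.frame(
        gene_a = letters[1:6], gene_b = LETTERS[1:6],
        Ks = c(0.009, 0.01, 2.999, 3.0, NA, 0.5)
    )
    kept <- filterKs(pairs)
    expect_equal(kept$Ks, c(0.01, 2.999, 0.5))
    expect_identical(filterKs(kept), kept)  # idempotent
})
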