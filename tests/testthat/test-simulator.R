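test_that("a WGD doubles every chromosome and every gene", {
    anc <- ancestralGenome(10, 5, codons = 30, seed = 3)
    scen <- evolutionScenario(list(evWGD(), evSpeciation("sp")), seed = 3)
    sim <- simulateScenario(scen, anc)
    sp <- sim$species$sp
    expect_equal(length(unique(sp$genes$chrom)), 20)
    expect_equal(nrow(sp$genes), 100)
    # every ancestral gene present in exactly two copies
    expect_true(all(table(sp$origins$ancestor) == 2))
})

test_that("nested insertion rewires gene order and bookkeeping", {
    anc <- ancestralGenome(12, 10, codons = 30, seed = 1)
    st <- applyNCI(anc, inserted = "A9", target = "A6", breakpoint = 4)
    expect_equal(length(st$chroms), 11)
    fused <- st$chroms[["A6"]]
    origins <- st$genes$origin[match(fused, st$genes$uid)]
    expect_equal(rle(origins)$values, c("A6", "A9", "A6"))
    st2 <- applyNCI(anc, inserted = "A10", target = "A2", breakpoint = 5)
    o2 <- st2$genes$origin[match(st2$chroms[["A2"]], st2$genes$uid)]
    expect_equal(rle(o2)$values, c("A2", "A10", "A2"))
    expect_error(applyNCI(anc, "A9", "A9"), "itself")
    expect_error(applyNCI(anc, "A9", "A6", breakpoint = 10), "interior")
    expect_error(applyNCI(anc, "A9", "A6", breakpoint = 0), "interior")
})

test_that("scenario errors name the offending event index", {
    anc <- ancestralGenome(4, 5, codons = 30, seed = 1)
    scen <- evolutionScenario(list(evWGD(), evNCI("A1", "A2")), seed = 1)
    expect_error(simulateScenario(scen, anc), "event 2")
})

test_that("the scripted replay reaches the recorded stage counts", {
    scen <- spartinaScenario(genes_per_chrom = 10, mask_rate = 0, seed = 2)
    anc <- ancestralGenome(12, 10, codons = 30, seed = 2)
    sim <- simulateScenario(scen, anc)
    tr <- sim$truth
    ev <- tr@events
    # n = 12 -> two fusions -> 10 -> WGD -> 20 -> five NCIs -> 15 -> WGD -> 30
    expect_equal(tr@stage_n[["initial"]], 12L)
    expect_equal(ev$n_after[ev$type == "wgd"], c(20L, 30L))
    expect_equal(min(ev$n_after), 10L)
    expect_equal(ev$n_after[max(which(ev$type == "nci"))], 15L)
    expect_equal(unname(tr@final_n["maritimus_like"]), 30L)
    expect_equal(unname(tr@final_n["outgroup10"]), 10L)
    # five NCI signatures fall between the two WGDs, two before the first
    expect_equal(sum(tr@nci_signatures$wgd_stage == 0), 2)
    expect_equal(sum(tr@nci_signatures$wgd_stage == 1), 5)
    # chromosome-count bookkeeping: closed form from the event list
    n_pred <- 12L
    for (i in seq_len(nrow(ev))) {
        if (ev$type[i] == "wgd") n_pred <- n_pred * 2L
        if (ev$type[i] == "nci") n_pred <- n_pred - 1L
        expect_equal(ev$n_after[i], n_pred)
    }
})

test_that("identical seeds reproduce the simulation byte for byte", {
    run <- function() {
        scen <- spartinaScenario(genes_per_chrom = 8, seed = 5)
        sim <- simulateScenario(scen, ancestralGenome(12, 8, codons = 30,
                                                      seed = 5))
        d <- withr::local_tempdir()
        writeFixtureBundle(sim, d)
        files <- sort(list.files(d, full.names = TRUE))
        unname(tools::md5sum(files))
    }
    expect_identical(unname(run()), unname(run()))
})

test_that("different seeds change sequences but not the event structure", {
    mk <- function(seed) {
        simulateScenario(spartinaScenario(genes_per_chrom = 6, seed = seed),
                         ancestralGenome(12, 6, codons = 30, seed = seed))
    }
    s1 <- mk(1)
    s2 <- mk(2)
    expect_identical(s1$truth@events$type, s2$truth@events$type)
    expect_identical(s1$truth@stage_n, s2$truth@stage_n)
    expect_false(identical(s1$species$maritimus_like$cds,
                           s2$species$maritimus_like$cds))
})

test_that("calibrated pairs converge on their Ks targets", {
    for (cfg in list(list(ks = 0.06, codons = 150),
                     list(ks = 0.28, codons = 150),
                     list(ks = 0.9, codons = 300))) {
        ks <- vapply(seq_len(500), function(i) {
            p <- evolveCdsPair(cfg$codons, cfg$ks, seed = i)
            ng86(list(a = oracle_split_codons(p$a),
                      b = oracle_split_codons(p$b)))$Ks
        }, numeric(1))
        expect_lt(abs(mean(ks) - cfg$ks), 0.05)
    }
})

test_that("separated Ks targets give separated empirical modes", {
    lo <- vapply(1:120, function(i)
        ng86(list(a = oracle_split_codons(evolveCdsPair(150, 0.06,
                                                        seed = i)$a),
                  b = oracle_split_codons(evolveCdsPair(150, 0.06,
                                                        seed = i)$b)))$Ks,
        numeric(1))
    hi <- vapply(1:120, function(i)
        ng86(list(a = oracle_split_codons(evolveCdsPair(150, 0.28,
                                                        seed = 1000 + i)$a),
                  b = oracle_split_codons(evolveCdsPair(150, 0.28,
                                                        seed = 1000 + i)$b)))$Ks,
        numeric(1))
    expect_lt(quantile(lo, 0.95), quantile(hi, 0.05))
})

test_that("zero targets and impossible targets behave as specified", {
    p <- evolveCdsPair(40, 0, 0, seed = 1)
    expect_identical(p$a, p$b)
    expect_error(evolveCdsPair(40, 3.2, seed = 1), "saturation")
    expect_error(evolveCdsPair(10, 0.1, seed = 1), "at least 30")
})

test_that("fixture bundles round-trip and expose the truth", {
    anc <- ancestralGenome(2, 6, codons = 30, seed = 4)
    scen <- evolutionScenario(list(evSpeciation("tiny")), seed = 4)
    sim <- simulateScenario(scen, anc)
    d <- withr::local_tempdir()
    files <- writeFixtureBundle(sim, d)
    expect_length(files, 4)  # fasta, bed, homology map, truth json
    fa <- Biostrings::readBStringSet(file.path(d, "tiny.cds.fasta"))
    bed <- read.table(file.path(d, "tiny.genes.bed"), sep = "\t")
    expect_setequal(names(fa), bed$V5)
    pos <- genePositions(data.frame(chrom = bed$V1, start = bed$V2,
                                    end = bed$V3, strand = bed$V4,
                                    gene_id = bed$V5))
    expect_equal(max(pos$rank), 6)
    truth <- jsonlite::read_json(file.path(d, "truth.json"))
    expect_equal(truth$pseudochromosome_count, 2)
    # the scripted replay records the expected final pseudochromosome count
    scen30 <- spartinaScenario(genes_per_chrom = 6, seed = 4)
    sim30 <- simulateScenario(scen30, ancestralGenome(12, 6, codons = 30,
                                                      seed = 4))
    d2 <- withr::local_tempdir()
    writeFixtureBundle(sim30, d2)
    truth30 <- jsonlite::read_json(file.path(d2, "truth.json"))
    expect_equal(truth30$pseudochromosome_count, 30)
    # degenerate input
    expect_error(writeFixtureBundle(list(species = list()), d), "empty")
})

test_that("soft-masking marks the scripted fraction of genes", {
    scen <- evolutionScenario(
        list(evSpeciation("m", branch_ks = 0, mask_rate = 0.5)), seed = 9)
    sim <- simulateScenario(scen, ancestralGenome(4, 30, codons = 40,
                                                  seed = 9))
    fr <- vapply(sim$species$m$cds, repeatFraction, numeric(1))
    expect_gt(sum(fr > 0.25), 0)
    expect_gt(sum(fr == 0), 0)
    expect_true(all(fr[fr > 0] >= 0.29))
})
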