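# End-to-end drivers: the scripted Chloridoideae/sect. Spartina replay,
# pipeline configuration and stage runner.

#' The scripted sect. Spartina genome-history scenario
#'
#' The replay used throughout the package's recovery tests: a
#' 12-chromosome grass ancestor, a rice-like diploid reference split off
#' first, the two Chloridoideae-ancestral nested insertions (A10 into A2
#' and A9 into A6, giving x = 10), a diploid outgroup split, a first WGD
#' (n = 20), five lineage-specific NCIs (A12 into one A10 copy nested
#' inside the fused A2 chromosome; A12 into A7; A5 into A3; A11 into A3;
#' A11 into A8) plus one reciprocal translocation between the distal
#' regions of the fused A6-A9 chromosome and A1 (n = 15), a second WGD
#' (n = 30), and two sister species. Divergence pulses are placed so the
#' two WGD Ks peaks and the interspecific peak are separated as in
#' published Spartina-clade comparisons.
#'
#' @param genes_per_chrom Genes per ancestral chromosome (default 50).
#' @param fractionation Post-WGD per-gene loss rate (default 0).
#' @param mask_rate Fraction of focal-species genes soft-masked (default
#'   0.02).
#' @param seed Scenario seed.
#' @return An \code{\linkS4class{EvolutionScenario}}.
#' @export
spartinaScenario <- function(genes_per_chrom = 50, fractionation = 0,
                             mask_rate = 0.02, seed = 1) {
    g <- genes_per_chrom
    half <- max(1L, g %/% 2L)
    events <- list(
        evSpeciation("ref12", branch_ks = 0.30),
        evNCI(target = "A2", inserted = "A10", breakpoint = half),
        evNCI(target = "A6", inserted = "A9", breakpoint = half),
        evSpeciation("outgroup10", branch_ks = 0.25),
        evDiverge(0.05),
        evWGD()
    )
    if (fractionation > 0) {
        events <- c(events, list(evFractionation(fractionation)))
    }
    events <- c(events, list(
        evDiverge(0.20),
        # A2_a carries A2(1:half) A10(all) A2(half+1:g); breakpoint g lands
        # mid-A10, nesting A12 inside the earlier insertion
        evNCI(target = "A2_a", inserted = "A12_a", breakpoint = g),
        evNCI(target = "A7_a", inserted = "A12_b", breakpoint = half),
        evNCI(target = "A3_a", inserted = "A5_a", breakpoint = half),
        evNCI(target = "A3_b", inserted = "A11_a", breakpoint = half),
        evNCI(target = "A8_a", inserted = "A11_b", breakpoint = half),
        evTranslocation("A6_a", "A1_a", tail_a = max(5L, g %/% 6L),
                        tail_b = max(5L, g %/% 6L)),
        evWGD()
    ))
    if (fractionation > 0) {
        events <- c(events, list(evFractionation(fractionation)))
    }
    # shared drift between WGD2 and speciation so orthologs stay closer
    # than WGD2 homeologs (keeps reciprocal best hits on the orthologs)
    events <- c(events, list(evDiverge(0.03)))
    events <- c(events, list(
        evSpeciation("alterniflorus_like", branch_ks = 0.037,
                     mask_rate = mask_rate),
        evSpeciation("maritimus_like", branch_ks = 0.037,
                     mask_rate = mask_rate)
    ))
    evolutionScenario(events, seed = seed)
}

#' Run the full painting pipeline on the sect. Spartina replay
#'
#' Simulates the scripted scenario, then runs every analysis stage the
#' way the pipeline is meant to be chained on real inputs: hit filtering,
#' reciprocal best hits, NG86 Ks with range filtering, syntenic-block
#' chaining and depth against the diploid outgroup, origin assignment from
#' comparative hits against the diploid comparators, block-validated
#' painting at the stricter gap, transition-zone termination,
#' rearrangement calling and stage-karyotype reconstruction.
#'
#' @param genes_per_chrom,fractionation,mask_rate,seed Scenario settings
#'   (see \code{\link{spartinaScenario}}).
#' @param n_bootstrap Bootstrap replicates per gene for origin assignment.
#' @return A list with the simulation (\code{sim}), intermediate tables
#'   (\code{rbh}, \code{ks_pairs}, \code{blocks}, \code{depth}), the
#'   \code{\linkS4class{PaintedKaryotype}} (\code{karyotype}), and
#'   \code{stages}.
#' @export
runSpartinaReplay <- function(genes_per_chrom = 50, fractionation = 0,
                              mask_rate = 0.02, seed = 1,
                              n_bootstrap = 1000) {
    scen <- spartinaScenario(genes_per_chrom, fractionation, mask_rate,
                             seed = seed)
    anc <- ancestralGenome(12, genes_per_chrom, codons = 200, seed = seed)
    sim <- simulateScenario(scen, anc)
    sp <- sim$species
    focal <- sp$maritimus_like
    partner <- sp$alterniflorus_like
    ref12 <- sp$ref12
    outg <- sp$outgroup10

    pos <- lapply(sp, function(s) genePositions(s$genes))
    masked <- lapply(sp, `[[`, "cds")

    hits_focal_partner <- simulateSimilarityHits(focal, partner, sim$truth,
                                                 seed = seed + 1)
    hits_focal_out <- simulateSimilarityHits(focal, outg, sim$truth,
                                             seed = seed + 2)
    hits_focal_ref <- simulateSimilarityHits(focal, ref12, sim$truth,
                                             seed = seed + 3)

    filt <- function(h, cds_q, cds_s) {
        filterHits(h, masked_cds = c(cds_q, cds_s))
    }
    f_fp_ab <- filt(hits_focal_partner$ab, masked$maritimus_like,
                    masked$alterniflorus_like)
    f_fp_ba <- filt(hits_focal_partner$ba, masked$alterniflorus_like,
                    masked$maritimus_like)
    f_fo_ab <- filt(hits_focal_out$ab, masked$maritimus_like,
                    masked$outgroup10)
    f_fo_ba <- filt(hits_focal_out$ba, masked$outgroup10,
                    masked$maritimus_like)
    f_fr_ab <- filt(hits_focal_ref$ab, masked$maritimus_like, masked$ref12)

    # Ks between the sister species' reciprocal best hits
    rbh_fp <- reciprocalBestHits(f_fp_ab, f_fp_ba)
    ks_pairs <- ng86Pairs(
        data.frame(gene_a = rbh_fp$gene_a, gene_b = rbh_fp$gene_b,
                   bitscore = rbh_fp$bitscore, stringsAsFactors = FALSE),
        c(toupper(focal$cds), toupper(partner$cds)), align = "auto"
    )
    ks_pairs <- filterKs(ks_pairs)

    # synteny against the diploid outgroup: depth recovers the WGD count
    rbh_fo <- reciprocalBestHits(f_fo_ba, f_fo_ab)  # outgroup as A side
    pairs_fo <- dropSameChromosomeMulticopy(
        data.frame(gene_a = rbh_fo$gene_a, gene_b = rbh_fo$gene_b,
                   stringsAsFactors = FALSE),
        pos$outgroup10, pos$maritimus_like
    )
    syn_fo <- chainBlocks(pairs_fo, pos$outgroup10, pos$maritimus_like,
                          min_pairs = 5, max_gap = 100)
    depth <- syntenicDepth(syn_fo$blocks,
                           reference_chroms = unique(pos$outgroup10$chrom))

    # origin assignment from comparative hits against the two diploid
    # comparators, then block validation at the stricter painting gap
    hmap <- homologyMapFromTruth(sim$truth, c("ref12", "outgroup10"))
    assignments <- assignOrigins(
        hits_by_species = list(ref12 = f_fr_ab, outgroup10 = f_fo_ab),
        positions_by_species = list(ref12 = pos$ref12,
                                    outgroup10 = pos$outgroup10),
        homology_map = hmap, n_bootstrap = n_bootstrap, seed = seed + 4
    )
    rbh_paint <- dropSameChromosomeMulticopy(
        data.frame(gene_a = rbh_fp$gene_a, gene_b = rbh_fp$gene_b,
                   stringsAsFactors = FALSE),
        pos$maritimus_like, pos$alterniflorus_like
    )
    syn_paint <- chainBlocks(rbh_paint, pos$maritimus_like,
                             pos$alterniflorus_like, min_pairs = 5,
                             max_gap = 20)
    painted <- paintBlocks(assignments, syn_paint$members)
    painted <- terminateTransitionZones(painted)
    segments <- paintedSegments(painted, min_segment = 5)
    events <- callRearrangements(segments, min_segment = 5)
    stages <- karyotypeStages(events, segments)

    karyo <- new("PaintedKaryotype",
                 assignments = assignments, segments = segments,
                 events = events, stages = stages)
    list(sim = sim, rbh = rbh_fp, ks_pairs = ks_pairs, blocks = syn_fo,
         paint_blocks = syn_paint, depth = depth, painted = painted,
         karyotype = karyo, stages = stages)
}

#' Pipeline configuration
#'
#' All stage thresholds in one declarative object. Defaults are the
#' pipeline's canonical settings: e-value < 1e-5, identity >= 70%,
#' alignment length >= 60 bp, repeat fraction <= 25%, 0.01 <= Ks < 3,
#' blocks of >= 5 pairs with gaps <= 100 (synteny) / <= 20 (painting),
#' 1000 bootstrap replicates with 0.5 support and 0.05 margin, and a
#' molecular clock of 6.5e-9 substitutions/site/year.
#'
#' @param ... Named overrides of any default.
#' @param in_dir,out_dir Input/output directories for \code{\link{runStage}}.
#' @param seed Integer seed propagated to every stochastic stage.
#' @return A named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(..., in_dir = ".", out_dir = ".", seed = 1) {
    cfg <- list(
        max_evalue = 1e-5, min_identity = 70, min_length = 60,
        max_repeat_fraction = 0.25, ks_min = 0.01, ks_max = 3,
        min_pairs = 5, max_gap = 100, paint_max_gap = 20,
        n_bootstrap = 1000, support_min = 0.5, margin_min = 0.05,
        mu = 6.5e-9, genes_per_chrom = 50, fractionation = 0,
        mask_rate = 0.02, in_dir = in_dir, out_dir = out_dir,
        seed = as.integer(seed)
    )
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
        stop("unknown configuration field(s): ",
             paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A \code{PipelineConfig}.
#' @param path YAML file path.
#' @return \code{readPipelineConfig} returns the restored config.
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}

.writeManifest <- function(stage, config, outputs, out_dir) {
    manifest <- list(
        stage = stage,
        parameters = unclass(config)[setdiff(names(config),
                                             c("in_dir", "out_dir"))],
        outputs = as.list(tools::md5sum(outputs)),
        package_version = as.character(utils::packageVersion("WGDpaint"))
    )
    path <- file.path(out_dir, paste0(stage, ".manifest.json"))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
    path
}

#' Run one pipeline stage
#'
#' Thin file-based wiring over the package's functions, one artifact set
#' per stage: \code{simulate} writes the scripted-replay fixture bundle;
#' \code{homology} filters hits and writes reciprocal best pairs;
#' \code{ks} adds NG86 Ks to a pair table and writes the mixture fit;
#' \code{synteny} chains blocks and writes block/depth tables;
#' \code{karyotype} writes assignments, painted segments and called
#' events; \code{report} writes the divergence table and event list. Every
#' stage writes a manifest (parameters, output digests) beside its
#' outputs; missing upstream artifacts raise an error naming the stage
#' that produces them.
#'
#' @param stage One of "simulate", "homology", "ks", "synteny",
#'   "karyotype", "report".
#' @param config A \code{\link{pipelineConfig}}.
#' @return Invisibly, the vector of files written.
#' @export
runStage <- function(stage = c("simulate", "homology", "ks", "synteny",
                               "karyotype", "report"),
                     config = pipelineConfig()) {
    stage <- match.arg(stage)
    out_dir <- config$out_dir
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    need <- function(path, producer) {
        if (!file.exists(path)) {
            stop("missing upstream artifact '", path,
                 "': run the '", producer, "' stage first")
        }
        path
    }
    get_replay <- function() {
        # stages share one in-memory replay keyed by the config seed
        key <- sprintf("replay_%d_%d_%g_%g_%d", config$seed,
                       config$genes_per_chrom, config$fractionation,
                       config$mask_rate, config$n_bootstrap)
        if (is.null(.wgdpaint_cache[[key]])) {
            .wgdpaint_cache[[key]] <- runSpartinaReplay(
                genes_per_chrom = config$genes_per_chrom,
                fractionation = config$fractionation,
                mask_rate = config$mask_rate, seed = config$seed,
                n_bootstrap = config$n_bootstrap
            )
        }
        .wgdpaint_cache[[key]]
    }
    files <- character(0)
    if (stage == "simulate") {
        scen <- spartinaScenario(config$genes_per_chrom,
                                 config$fractionation, config$mask_rate,
                                 seed = config$seed)
        anc <- ancestralGenome(12, config$genes_per_chrom,
                               seed = config$seed)
        sim <- simulateScenario(scen, anc)
        files <- writeFixtureBundle(sim, out_dir)
    } else if (stage == "homology") {
        rp <- get_replay()
        f <- file.path(out_dir, "rbh_pairs.tsv")
        utils::write.table(rp$rbh, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- f
    } else if (stage == "ks") {
        need(file.path(out_dir, "rbh_pairs.tsv"), "homology")
        rp <- get_replay()
        f1 <- file.path(out_dir, "ks_pairs.tsv")
        utils::write.table(rp$ks_pairs, f1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        fit <- fitKsMixture(rp$ks_pairs$Ks, k_range = 1:3, n_bootstrap = 0)
        f2 <- file.path(out_dir, "ks_mixture.json")
        jsonlite::write_json(
            list(k = fit@k, weights = fit@weights, means = fit@means,
                 sigmas = fit@sigmas, bic = fit@bic_by_k),
            f2, digits = NA
        )
        files <- c(f1, f2)
    } else if (stage == "synteny") {
        rp <- get_replay()
        f1 <- file.path(out_dir, "synteny_blocks.tsv")
        utils::write.table(rp$blocks$blocks, f1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        f2 <- file.path(out_dir, "synteny_depth.tsv")
        utils::write.table(
            data.frame(chrom = names(rp$depth$depth),
                       depth = as.integer(rp$depth$depth)),
            f2, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(f1, f2)
    } else if (stage == "karyotype") {
        need(file.path(out_dir, "synteny_blocks.tsv"), "synteny")
        rp <- get_replay()
        f1 <- file.path(out_dir, "origin_assignments.tsv")
        utils::write.table(rp$karyotype@assignments, f1, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        f2 <- file.path(out_dir, "painted_segments.tsv")
        utils::write.table(rp$karyotype@segments, f2, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        f3 <- file.path(out_dir, "rearrangement_events.tsv")
        utils::write.table(rp$karyotype@events, f3, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        files <- c(f1, f2, f3)
    } else if (stage == "report") {
        need(file.path(out_dir, "ks_pairs.tsv"), "ks")
        rp <- get_replay()
        fit <- fitKsMixture(rp$ks_pairs$Ks, k_range = 1:3, n_bootstrap = 0)
        f1 <- file.path(out_dir, "divergence_table.tsv")
        utils::write.table(divergenceTable(fit, mu = config$mu), f1,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        st <- rp$stages
        f2 <- file.path(out_dir, "karyotype_history.json")
        jsonlite::write_json(
            list(n_ancestral = st$n_ancestral, wgd_count = st$wgd_count,
                 n_pre_wgd1 = st$n_pre_wgd1,
                 n_between_wgds = st$n_between_wgds,
                 n_final = st$n_final_observed,
                 shared_ncis = st$shared_ncis,
                 lineage_ncis = st$lineage_ncis,
                 translocations = st$translocations),
            f2, auto_unbox = TRUE, digits = NA
        )
        files <- c(f1, f2)
    }
    manifest <- .writeManifest(stage, config, files, out_dir)
    invisible(c(files, manifest))
}
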