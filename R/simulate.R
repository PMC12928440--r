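# Genome-history simulator: multi-species gene complements descending from
# a 12-chromosome grass ancestor through scripted karyotype events
# (whole-genome duplications, nested chromosome insertions, reciprocal
# translocations, fractionation) and calibrated sequence divergence.

#' Build an ancestral genome
#'
#' The starting point of every simulation: \code{n_chrom} chromosomes
#' (named A1, A2, ...) each carrying \code{genes_per_chrom} genes in a
#' total, gap-free order. Every gene carries exactly one
#' ancestral-chromosome label and a random stop-free CDS beginning with
#' ATG.
#'
#' @param n_chrom Number of ancestral chromosomes (default 12, the grass
#'   ancestor).
#' @param genes_per_chrom Genes per chromosome (default 50, enough for
#'   desk-scale painting).
#' @param codons CDS length in codons (including the start codon).
#' @param seed Integer seed.
#' @return A genome state (list with \code{chroms}, \code{genes},
#'   \code{seqs}), consumed by \code{\link{simulateScenario}}.
#' @export
ancestralGenome <- function(n_chrom = 12, genes_per_chrom = 50,
                            codons = 200, seed = 1) {
    stopifnot(n_chrom >= 1, genes_per_chrom >= 1, codons >= 30)
    set.seed(seed)
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    sense <- setdiff(sense, "ATG")
    chrom_names <- paste0("A", seq_len(n_chrom))
    genes <- list()
    chroms <- list()
    seqs <- character(0)
    for (ch in chrom_names) {
        ids <- sprintf("%s_g%03d", ch, seq_len(genes_per_chrom))
        chroms[[ch]] <- ids
        genes[[ch]] <- data.frame(
            uid = ids, ancestor = ids, origin = ch, stringsAsFactors = FALSE
        )
        for (id in ids) {
            body <- sample(sense, codons - 1, replace = TRUE)
            seqs[[id]] <- paste(c("ATG", body), collapse = "")
        }
    }
    list(
        chroms = chroms,
        genes = do.call(rbind, genes),
        seqs = seqs,
        codons = codons
    )
}

# ---- Event constructors ----------------------------------------------------

#' Scenario event constructors
#'
#' Build the event records of an \code{\linkS4class{EvolutionScenario}}.
#' \code{evWGD} doubles every chromosome (copies get \code{_a}/\code{_b}
#' suffixes). \code{evNCI} inserts one whole chromosome between the arms of
#' another at an intra-arm breakpoint (strictly interior; drawn uniformly
#' when NULL); the fused chromosome keeps the target's name.
#' \code{evTranslocation} reciprocally exchanges the distal \code{tail_a} /
#' \code{tail_b} genes of two chromosomes. \code{evFractionation} removes
#' each gene with probability \code{rate}. \code{evDiverge} applies a
#' synonymous-divergence pulse: lineages separated before the pulse gain
#' approximately \code{ks} pairwise Ks (each current sequence receives
#' \code{ks/2}). \code{evSpeciation} snapshots the current genome as a
#' species whose sequences then diverge by the per-branch \code{branch_ks}
#' (single-lineage, in Ks units).
#'
#' @param target,inserted,chrom_a,chrom_b Chromosome names in the state at
#'   the point of application.
#' @param breakpoint Number of target genes before the insertion point
#'   (1 to length-1).
#' @param tail_a,tail_b Distal gene counts exchanged.
#' @param rate Per-gene loss probability.
#' @param ks Pairwise synonymous divergence of the pulse.
#' @param label Species label.
#' @param branch_ks Per-branch synonymous divergence of the species.
#' @param mask_rate Fraction of the species' genes soft-masked over >25%
#'   of their length (simulated repeat content).
#' @return An event record (list) for \code{\link{evolutionScenario}}.
#' @name scenario-events
NULL

#' @rdname scenario-events
#' @export
evWGD <- function() {
    list(type = "wgd")
}

#' @rdname scenario-events
#' @export
evNCI <- function(target, inserted, breakpoint = NULL) {
    if (target == inserted) {
        stop("a chromosome cannot be inserted into itself")
    }
    list(type = "nci", target = target, inserted = inserted,
         breakpoint = breakpoint)
}

#' @rdname scenario-events
#' @export
evTranslocation <- function(chrom_a, chrom_b, tail_a, tail_b) {
    list(type = "translocation", chrom_a = chrom_a, chrom_b = chrom_b,
         tail_a = as.integer(tail_a), tail_b = as.integer(tail_b))
}

#' @rdname scenario-events
#' @export
evFractionation <- function(rate) {
    stopifnot(rate >= 0, rate < 1)
    list(type = "fractionation", rate = rate)
}

#' @rdname scenario-events
#' @export
evDiverge <- function(ks) {
    stopifnot(ks >= 0)
    list(type = "diverge", ks = ks)
}

#' @rdname scenario-events
#' @export
evSpeciation <- function(label, branch_ks = 0, mask_rate = 0) {
    stopifnot(branch_ks >= 0, mask_rate >= 0, mask_rate <= 1)
    list(type = "speciation", label = label, branch_ks = branch_ks,
         mask_rate = mask_rate)
}

#' Construct an evolution scenario
#'
#' @param events List of event records (see \link{scenario-events}),
#'   applied in order.
#' @param seed Integer seed governing every stochastic choice of the
#'   simulation.
#' @return An \code{\linkS4class{EvolutionScenario}}.
#' @export
evolutionScenario <- function(events, seed = 1) {
    new("EvolutionScenario", events = events, seed = as.integer(seed))
}

setMethod("show", "EvolutionScenario", function(object) {
    cat("EvolutionScenario:", length(object@events), "events, seed",
        object@seed, "\n")
    types <- vapply(object@events, `[[`, character(1), "type")
    cat(" ", paste(types, collapse = " -> "), "\n")
    invisible(NULL)
})

# ---- Sequence evolution ----------------------------------------------------

# Replace each codon with a random synonymous alternative with probability
# q (codons without alternatives are left untouched).
.mutateSynCodons <- function(codvec, q) {
    if (q <= 0) {
        return(codvec)
    }
    alts <- .synonymousAlternatives()
    hit <- which(stats::runif(length(codvec)) < q)
    for (i in hit) {
        a <- alts[[codvec[i]]]
        if (length(a)) {
            codvec[i] <- if (length(a) == 1) a else sample(a, 1)
        }
    }
    codvec
}

# Replace each codon with a random single-step nonsynonymous neighbour
# with probability q.
.mutateNonsynCodons <- function(codvec, q) {
    if (q <= 0) {
        return(codvec)
    }
    nb <- .nonsynNeighbours()
    hit <- which(stats::runif(length(codvec)) < q)
    for (i in hit) {
        a <- nb[[codvec[i]]]
        if (length(a)) {
            codvec[i] <- if (length(a) == 1) a else sample(a, 1)
        }
    }
    codvec
}

.mutateSeq <- function(seq, q_syn, q_nonsyn = 0) {
    cod <- .splitCodons(seq)
    body <- cod[-1]  # preserve the start codon
    body <- .mutateSynCodons(body, q_syn)
    if (q_nonsyn > 0) {
        body <- .mutateNonsynCodons(body, q_nonsyn)
    }
    paste(c(cod[1], body), collapse = "")
}

# Mean NG86 Ks/Ka between once-mutated copies (pairwise = both copies
# mutated, as in evolveCdsPair) or between an original and its mutated
# copy (single-lineage, as in divergence pulses); the calibration pre-run.
.measureDivergence <- function(q_syn, q_nonsyn, codons, n_genes = 40,
                               pairwise = FALSE) {
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    ks <- numeric(n_genes)
    ka <- numeric(n_genes)
    for (g in seq_len(n_genes)) {
        cod <- c("ATG", sample(sense, codons - 1, replace = TRUE))
        root <- paste(cod, collapse = "")
        seq_a <- if (pairwise) .mutateSeq(root, q_syn, q_nonsyn) else root
        seq_b <- .mutateSeq(root, q_syn, q_nonsyn)
        r <- ng86(list(a = .splitCodons(seq_a), b = .splitCodons(seq_b)))
        ks[g] <- if (is.na(r$Ks)) 3 else r$Ks
        ka[g] <- if (is.na(r$Ka)) 3 else r$Ka
    }
    c(ks = mean(ks), ka = mean(ka))
}

# Calibrate the per-codon synonymous replacement probability that yields a
# given single-lineage Ks (measured by the package's own NG86 estimator).
# Bisection over q in [0, 1]; cached per (target, codons).
.calibrateSynQ <- function(target_ks, codons, pairwise = FALSE) {
    if (target_ks <= 0) {
        return(0)
    }
    key <- sprintf("synq_%.6f_%d_%d", target_ks, codons, pairwise)
    if (!is.null(.wgdpaint_cache[[key]])) {
        return(.wgdpaint_cache[[key]])
    }
    if (!exists(".Random.seed", envir = globalenv())) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(20260926)
    lo <- 0
    hi <- 1
    f_hi <- .measureDivergence(1, 0, codons, pairwise = pairwise)["ks"]
    if (f_hi < target_ks) {
        stop("requested Ks ", target_ks,
             " exceeds the attainable synonymous divergence (", round(f_hi, 2),
             ")")
    }
    for (it in 1:12) {
        mid <- (lo + hi) / 2
        f <- .measureDivergence(mid, 0, codons, pairwise = pairwise)["ks"]
        if (f < target_ks) lo <- mid else hi <- mid
    }
    q <- (lo + hi) / 2
    .wgdpaint_cache[[key]] <- q
    q
}

.calibrateNonsynQ <- function(target_ka, codons, pairwise = FALSE) {
    if (target_ka <= 0) {
        return(0)
    }
    key <- sprintf("nonsynq_%.6f_%d_%d", target_ka, codons, pairwise)
    if (!is.null(.wgdpaint_cache[[key]])) {
        return(.wgdpaint_cache[[key]])
    }
    if (!exists(".Random.seed", envir = globalenv())) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(20260927)
    lo <- 0
    hi <- 1
    f_hi <- .measureDivergence(0, 1, codons, pairwise = pairwise)["ka"]
    if (f_hi < target_ka) {
        stop("requested Ka ", target_ka, " is not attainable")
    }
    for (it in 1:12) {
        mid <- (lo + hi) / 2
        f <- .measureDivergence(0, mid, codons, pairwise = pairwise)["ka"]
        if (f < target_ka) lo <- mid else hi <- mid
    }
    q <- (lo + hi) / 2
    .wgdpaint_cache[[key]] <- q
    q
}

#' Simulate a calibrated pair of diverged coding sequences
#'
#' Generates a random stop-free CDS and two descendant copies whose
#' expected Nei-Gojobori divergence matches the requested targets. The
#' synonymous and nonsynonymous per-codon substitution probabilities are
#' tuned by a short calibration pre-run against the package's own NG86
#' estimator (each copy receives half the pairwise target).
#'
#' @param length_codons CDS length (at least 30 codons).
#' @param target_ks,target_ka Pairwise divergence targets; Ks above the
#'   saturation bound 3 is rejected.
#' @param seed Integer seed.
#' @return A list with character CDS \code{a} and \code{b}.
#' @export
evolveCdsPair <- function(length_codons, target_ks, target_ka = 0,
                          seed = 1) {
    if (length_codons < 30) {
        stop("length_codons must be at least 30")
    }
    if (target_ks < 0 || target_ka < 0) {
        stop("divergence targets must be non-negative")
    }
    if (target_ks >= 3) {
        stop("target_ks >= 3 is beyond the saturation bound of the ",
             "Jukes-Cantor-corrected estimator")
    }
    q_syn <- .calibrateSynQ(target_ks, length_codons, pairwise = TRUE)
    q_nonsyn <- .calibrateNonsynQ(target_ka, length_codons, pairwise = TRUE)
    set.seed(seed)
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    root <- paste(c("ATG", sample(sense, length_codons - 1, replace = TRUE)),
                  collapse = "")
    a <- .mutateSeq(root, q_syn, q_nonsyn)
    b <- .mutateSeq(root, q_syn, q_nonsyn)
    list(a = a, b = b)
}

# ---- Event application -----------------------------------------------------

.requireChrom <- function(state, name, idx) {
    if (!name %in% names(state$chroms)) {
        stop("event ", idx, ": chromosome '", name,
             "' does not exist at this point of the scenario ",
             "(present: ", paste(names(state$chroms), collapse = ", "), ")")
    }
}

#' Apply a nested chromosome insertion to a genome state
#'
#' Inserts the whole \code{inserted} chromosome between the arms of
#' \code{target} at \code{breakpoint} (counted in genes from the target's
#' start; strictly interior, so both flanking arms are non-empty -- a
#' breakpoint at a chromosome end would be an end-to-end fusion, not an
#' NCI). The chromosome count decreases by one and the fused chromosome
#' keeps the target's name.
#'
#' @param state A genome state (\code{\link{ancestralGenome}} or mid-
#'   scenario).
#' @param inserted,target Chromosome names; must differ.
#' @param breakpoint Integer in 1..(length(target) - 1), or NULL to draw
#'   uniformly from the interior.
#' @return The modified state; attribute \code{"signature"} records the
#'   (outer origin, inserted origin) pair at the insertion point.
#' @export
applyNCI <- function(state, inserted, target, breakpoint = NULL) {
    if (inserted == target) {
        stop("a chromosome cannot be inserted into itself")
    }
    .requireChrom(state, inserted, NA)
    .requireChrom(state, target, NA)
    tgt <- state$chroms[[target]]
    ins <- state$chroms[[inserted]]
    if (is.null(breakpoint)) {
        breakpoint <- sample(seq_len(length(tgt) - 1), 1)
    }
    if (breakpoint < 1 || breakpoint > length(tgt) - 1) {
        stop("breakpoint must be strictly interior to the target ",
             "chromosome (an end breakpoint would be an end-to-end fusion)")
    }
    fused <- c(tgt[seq_len(breakpoint)], ins,
               tgt[(breakpoint + 1):length(tgt)])
    origin_of <- function(uids) {
        state$genes$origin[match(uids, state$genes$uid)]
    }
    sig <- data.frame(
        outer_chrom = target, inserted_chrom = inserted,
        outer_origin = origin_of(tgt[breakpoint]),
        inserted_origin = names(sort(table(origin_of(ins)),
                                     decreasing = TRUE))[1],
        stringsAsFactors = FALSE
    )
    state$chroms[[target]] <- fused
    state$chroms[[inserted]] <- NULL
    attr(state, "signature") <- sig
    state
}

.applyWGD <- function(state) {
    new_chroms <- list()
    genes <- state$genes
    add_genes <- list()
    for (ch in names(state$chroms)) {
        uids <- state$chroms[[ch]]
        for (suf in c("a", "b")) {
            new_uids <- paste0(uids, ".", suf)
            new_chroms[[paste0(ch, "_", suf)]] <- new_uids
            g <- genes[match(uids, genes$uid), , drop = FALSE]
            g$uid <- new_uids
            add_genes[[length(add_genes) + 1]] <- g
            ns <- state$seqs[uids]
            names(ns) <- new_uids
            state$seqs <- c(state$seqs, ns)
        }
        state$seqs <- state$seqs[setdiff(names(state$seqs), uids)]
    }
    state$chroms <- new_chroms
    state$genes <- do.call(rbind, add_genes)
    state
}

.applyTranslocation <- function(state, ev, idx) {
    .requireChrom(state, ev$chrom_a, idx)
    .requireChrom(state, ev$chrom_b, idx)
    a <- state$chroms[[ev$chrom_a]]
    b <- state$chroms[[ev$chrom_b]]
    if (ev$tail_a >= length(a) || ev$tail_b >= length(b) ||
        ev$tail_a < 1 || ev$tail_b < 1) {
        stop("event ", idx, ": translocated tails must be shorter than ",
             "their chromosomes and non-empty")
    }
    keep_a <- a[seq_len(length(a) - ev$tail_a)]
    tail_a <- a[(length(a) - ev$tail_a + 1):length(a)]
    keep_b <- b[seq_len(length(b) - ev$tail_b)]
    tail_b <- b[(length(b) - ev$tail_b + 1):length(b)]
    state$chroms[[ev$chrom_a]] <- c(keep_a, tail_b)
    state$chroms[[ev$chrom_b]] <- c(keep_b, tail_a)
    state
}

.applyFractionation <- function(state, rate) {
    for (ch in names(state$chroms)) {
        uids <- state$chroms[[ch]]
        drop <- stats::runif(length(uids)) < rate
        gone <- uids[drop]
        state$chroms[[ch]] <- uids[!drop]
        if (length(gone)) {
            state$seqs <- state$seqs[setdiff(names(state$seqs), gone)]
            state$genes <- state$genes[!state$genes$uid %in% gone, ,
                                       drop = FALSE]
        }
    }
    state
}

.applyDiverge <- function(state, ks, codons) {
    q <- .calibrateSynQ(ks / 2, codons)
    for (uid in names(state$seqs)) {
        state$seqs[[uid]] <- .mutateSeq(state$seqs[[uid]], q)
    }
    state
}

# Snapshot the state as a species: anonymised gene ids, renamed
# chromosomes, branch divergence and soft-masking applied.
.makeSpecies <- function(state, label, branch_ks, mask_rate, codons) {
    n_genes <- sum(lengths(state$chroms))
    if (n_genes == 0) {
        stop("cannot emit species '", label, "': the genome has no genes")
    }
    q <- .calibrateSynQ(branch_ks, codons)
    chrom_names <- sprintf("%s_chr%02d", label, seq_along(state$chroms))
    bed <- list()
    origins <- list()
    cds <- character(0)
    counter <- 0L
    gene_len <- 3L * codons
    for (ci in seq_along(state$chroms)) {
        uids <- state$chroms[[ci]]
        ids <- sprintf("%s_g%05d", label, counter + seq_along(uids))
        counter <- counter + length(uids)
        starts <- (seq_along(uids) - 1L) * (gene_len + 500L)
        bed[[ci]] <- data.frame(
            chrom = chrom_names[ci], start = starts, end = starts + gene_len,
            strand = "+", gene_id = ids, stringsAsFactors = FALSE
        )
        gidx <- match(uids, state$genes$uid)
        origins[[ci]] <- data.frame(
            species = label, gene_id = ids,
            origin = state$genes$origin[gidx],
            ancestor = state$genes$ancestor[gidx],
            chrom = chrom_names[ci], stringsAsFactors = FALSE
        )
        sq <- state$seqs[uids]
        if (branch_ks > 0) {
            sq <- vapply(sq, .mutateSeq, character(1), q_syn = q)
        }
        if (mask_rate > 0) {
            masked <- stats::runif(length(sq)) < mask_rate
            sq[masked] <- vapply(sq[masked], function(s) {
                n <- nchar(s)
                span <- max(1L, ceiling(0.3 * n))
                at <- sample(seq_len(n - span + 1L), 1)
                paste0(substr(s, 1, at - 1),
                       tolower(substr(s, at, at + span - 1)),
                       substr(s, at + span, n))
            }, character(1))
        }
        names(sq) <- ids
        cds <- c(cds, sq)
    }
    list(
        genes = do.call(rbind, bed),
        cds = cds,
        origins = do.call(rbind, origins)
    )
}

#' Run a scripted genome-history simulation
#'
#' Applies the scenario's events in order to the ancestral genome,
#' emitting one species (gene table, CDS set, truth origins) per
#' speciation event, and a \code{\linkS4class{TruthRecord}} with the event
#' log, stage chromosome counts and NCI signatures. Identical seeds give
#' identical output.
#'
#' @param scenario An \code{\linkS4class{EvolutionScenario}}.
#' @param ancestor A genome state from \code{\link{ancestralGenome}}.
#' @return A list with \code{species} (named list of speciation snapshots)
#'   and \code{truth}.
#' @export
simulateScenario <- function(scenario, ancestor) {
    stopifnot(is(scenario, "EvolutionScenario"))
    set.seed(scenario@seed)
    state <- ancestor
    codons <- ancestor$codons
    species <- list()
    ev_rows <- list()
    sigs <- list()
    wgd_count <- 0L
    n0 <- length(state$chroms)
    for (i in seq_along(scenario@events)) {
        ev <- scenario@events[[i]]
        detail <- ""
        if (ev$type == "wgd") {
            state <- .applyWGD(state)
            wgd_count <- wgd_count + 1L
        } else if (ev$type == "nci") {
            .requireChrom(state, ev$target, i)
            .requireChrom(state, ev$inserted, i)
            state <- applyNCI(state, ev$inserted, ev$target, ev$breakpoint)
            sig <- attr(state, "signature")
            sig$wgd_stage <- wgd_count
            sigs[[length(sigs) + 1]] <- sig
            detail <- paste0(ev$inserted, " into ", ev$target)
        } else if (ev$type == "translocation") {
            state <- .applyTranslocation(state, ev, i)
            detail <- paste0(ev$chrom_a, " <-> ", ev$chrom_b)
        } else if (ev$type == "fractionation") {
            state <- .applyFractionation(state, ev$rate)
            detail <- paste0("rate ", ev$rate)
        } else if (ev$type == "diverge") {
            state <- .applyDiverge(state, ev$ks, codons)
            detail <- paste0("ks ", ev$ks)
        } else if (ev$type == "speciation") {
            species[[ev$label]] <- .makeSpecies(state, ev$label,
                                                ev$branch_ks, ev$mask_rate,
                                                codons)
            detail <- ev$label
        }
        ev_rows[[i]] <- data.frame(
            index = i, type = ev$type, detail = detail,
            n_after = length(state$chroms), wgd_so_far = wgd_count,
            stringsAsFactors = FALSE
        )
    }
    events_df <- do.call(rbind, ev_rows)
    stage_n <- c(initial = n0, stats::setNames(events_df$n_after,
                                               paste0("event", events_df$index)))
    origins <- do.call(rbind, lapply(species, `[[`, "origins"))
    rownames(origins) <- NULL
    final_n <- vapply(species, function(sp) {
        length(unique(sp$genes$chrom))
    }, integer(1))
    truth <- new("TruthRecord",
        gene_origins = origins, events = events_df,
        final_n = final_n, stage_n = as.integer(stage_n),
        nci_signatures = if (length(sigs)) do.call(rbind, sigs) else
            data.frame()
    )
    names(truth@stage_n) <- names(stage_n)
    list(species = species, truth = truth)
}

setMethod("show", "TruthRecord", function(object) {
    cat("TruthRecord:", nrow(object@events), "events,",
        nrow(object@nci_signatures), "NCIs\n")
    cat("  final n:",
        paste(names(object@final_n), object@final_n, sep = "=",
              collapse = ", "), "\n")
    invisible(NULL)
})

#' Simulated all-vs-all similarity hits between two species
#'
#' Emits an outfmt-6-dialect hit table for every gene pair descending from
#' the same ancestral gene (the simulator's genes carry no indels, so
#' identity is a direct per-base comparison; bitscore is proportional to
#' the number of matching bases). Optional noise hits between unrelated
#' genes fall below the standard identity threshold. Both directions are
#' returned.
#'
#' @param sp_a,sp_b Species entries from \code{\link{simulateScenario}}.
#' @param truth The simulation's \code{TruthRecord}.
#' @param noise_rate Expected noise hits per gene of species A.
#' @param seed Integer seed for the noise.
#' @return A list with data.frames \code{ab} and \code{ba}.
#' @export
simulateSimilarityHits <- function(sp_a, sp_b, truth, noise_rate = 0.02,
                                   seed = 1) {
    set.seed(seed)
    org <- truth@gene_origins
    oa <- org[org$species == sp_a$origins$species[1], , drop = FALSE]
    ob <- org[org$species == sp_b$origins$species[1], , drop = FALSE]
    bidx <- split(seq_len(nrow(ob)), ob$ancestor)
    rows <- list()
    seq_a <- toupper(sp_a$cds)
    seq_b <- toupper(sp_b$cds)
    for (i in seq_len(nrow(oa))) {
        js <- bidx[[oa$ancestor[i]]]
        if (is.null(js)) next
        ga <- oa$gene_id[i]
        sa <- strsplit(seq_a[[ga]], "")[[1]]
        for (j in js) {
            gb <- ob$gene_id[j]
            sb <- strsplit(seq_b[[gb]], "")[[1]]
            len <- min(length(sa), length(sb))
            matches <- sum(sa[seq_len(len)] == sb[seq_len(len)])
            rows[[length(rows) + 1]] <- data.frame(
                qseqid = ga, sseqid = gb,
                pident = round(100 * matches / len, 2), length = len,
                mismatch = len - matches, gapopen = 0L,
                qstart = 1L, qend = len, sstart = 1L, send = len,
                evalue = 1e-180, bitscore = round(1.9 * matches, 1),
                stringsAsFactors = FALSE
            )
        }
    }
    n_noise <- stats::rpois(1, noise_rate * nrow(oa))
    if (n_noise > 0 && nrow(ob) > 1) {
        for (k in seq_len(n_noise)) {
            i <- sample(nrow(oa), 1)
            j <- sample(nrow(ob), 1)
            if (identical(ob$ancestor[j], oa$ancestor[i])) next
            len <- nchar(seq_a[[oa$gene_id[i]]])
            pid <- stats::runif(1, 45, 65)
            rows[[length(rows) + 1]] <- data.frame(
                qseqid = oa$gene_id[i], sseqid = ob$gene_id[j],
                pident = round(pid, 2), length = len,
                mismatch = as.integer(len * (1 - pid / 100)), gapopen = 0L,
                qstart = 1L, qend = len, sstart = 1L, send = len,
                evalue = 1e-6, bitscore = round(0.9 * len * pid / 100, 1),
                stringsAsFactors = FALSE
            )
        }
    }
    ab <- do.call(rbind, rows)
    ba <- ab
    names(ba)[names(ba) == "qseqid"] <- ".tmp"
    names(ba)[names(ba) == "sseqid"] <- "qseqid"
    names(ba)[names(ba) == ".tmp"] <- "sseqid"
    ba <- ba[, names(ab)]
    list(ab = ab, ba = ba)
}

#' Chromosome-to-ancestral homology map implied by a simulation
#'
#' For each comparator species, maps every chromosome to the set of
#' ancestral chromosomes whose genes it carries -- the simulated
#' counterpart of a published chromosome homology table.
#'
#' @param truth A \code{TruthRecord}.
#' @param species Character vector of comparator species labels.
#' @return data.frame with columns \code{species}, \code{chrom},
#'   \code{origin} (long form; one row per mapping).
#' @export
homologyMapFromTruth <- function(truth, species) {
    org <- truth@gene_origins
    org <- org[org$species %in% species, , drop = FALSE]
    out <- unique(org[, c("species", "chrom", "origin")])
    rownames(out) <- NULL
    out[order(out$species, out$chrom, out$origin), , drop = FALSE]
}

#' Write a simulation as pipeline-ready fixture files
#'
#' Emits, per species, a (soft-maskable) CDS FASTA and a BED-like gene
#' position table; plus a homology-map TSV (one row per ancestral
#' chromosome, one column per species with comma-separated chromosome
#' lists) and the truth record as JSON.
#'
#' @param sim Result of \code{\link{simulateScenario}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeFixtureBundle <- function(sim, out_dir) {
    if (length(sim$species) == 0) {
        stop("empty simulation: no species to write")
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (label in names(sim$species)) {
        sp <- sim$species[[label]]
        if (nrow(sp$genes) == 0) {
            stop("species '", label, "' has an empty gene set")
        }
        if (!setequal(names(sp$cds), sp$genes$gene_id)) {
            off <- c(setdiff(names(sp$cds), sp$genes$gene_id),
                     setdiff(sp$genes$gene_id, names(sp$cds)))
            stop("FASTA/table id mismatch for '", label, "': ",
                 paste(utils::head(off, 5), collapse = ", "))
        }
        fa <- file.path(out_dir, paste0(label, ".cds.fasta"))
        writeLines(paste0(">", names(sp$cds), "\n", unname(sp$cds)), fa)
        bed <- file.path(out_dir, paste0(label, ".genes.bed"))
        utils::write.table(sp$genes, bed, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        files <- c(files, fa, bed)
    }
    map_long <- homologyMapFromTruth(sim$truth, names(sim$species))
    origins <- sort(unique(map_long$origin))
    map_wide <- data.frame(ancestral_chromosome = origins,
                           stringsAsFactors = FALSE)
    for (sp in unique(map_long$species)) {
        map_wide[[sp]] <- vapply(origins, function(o) {
            paste(sort(map_long$chrom[map_long$species == sp &
                                          map_long$origin == o]),
                  collapse = ", ")
        }, character(1))
    }
    map_path <- file.path(out_dir, "homology_map.tsv")
    utils::write.table(map_wide, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_path <- file.path(out_dir, "truth.json")
    tr <- sim$truth
    jsonlite::write_json(
        list(
            gene_origins = tr@gene_origins, events = tr@events,
            final_n = as.list(tr@final_n),
            stage_n = as.list(tr@stage_n),
            nci_signatures = tr@nci_signatures,
            pseudochromosome_count = unname(max(tr@final_n))
        ),
        truth_path, auto_unbox = TRUE, digits = NA
    )
    files <- c(files, map_path, truth_path)
    invisible(files)
}
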