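# Ancestral-karyotype painting: bitscore-weighted origin probabilities,
# bootstrap assignment, block-level validation, transition zones and
# rearrangement calling.

#' Read a chromosome-to-ancestral homology map
#'
#' Parses a wide TSV whose first column lists ancestral chromosomes
#' (A1..A12) and whose remaining columns hold, per comparator species,
#' comma-separated lists of that species' chromosomes homologous to the
#' ancestral chromosome. Returns the long form used by
#' \code{\link{mapHitsToAncestral}}.
#'
#' A packaged map with published grass chromosome homologies ships as
#' \code{system.file("extdata", "ancestral_homology_map.tsv",
#' package = "WGDpaint")}.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{species}, \code{chrom},
#'   \code{origin}.
#' @export
readHomologyMap <- function(path) {
    wide <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE,
                              quote = "")
    origins <- wide[[1]]
    out <- list()
    for (sp in names(wide)[-1]) {
        for (i in seq_along(origins)) {
            cell <- trimws(wide[[sp]][i])
            if (cell == "" || is.na(cell)) next
            chroms <- trimws(strsplit(cell, ",")[[1]])
            out[[length(out) + 1]] <- data.frame(
                species = sp, chrom = chroms, origin = origins[i],
                stringsAsFactors = FALSE
            )
        }
    }
    long <- do.call(rbind, out)
    missing <- by(long, long$species, function(d) {
        setdiff(origins, unique(d$origin))
    })
    bad <- names(missing)[vapply(missing, length, integer(1)) > 0]
    if (length(bad)) {
        warning("species without a full ancestral complement: ",
                paste(bad, collapse = ", "))
    }
    rownames(long) <- NULL
    long
}

#' Ancestral-origin probability vector for one gene
#'
#' Translates each comparative hit's chromosome into the ancestral
#' chromosome(s) it implies under the homology map, splitting the hit's
#' bitscore equally across implied origins, and normalizes by the total
#' bitscore: the empirical probability of each candidate origin.
#'
#' @param gene_hits data.frame with columns \code{species},
#'   \code{chromosome}, \code{bitscore} -- the filtered comparative hits of
#'   one focal gene.
#' @param homology_map Long-form map (\code{\link{readHomologyMap}}).
#' @return Named numeric vector of origin probabilities (summing to 1),
#'   with attribute \code{m} = number of contributing hits.
#' @export
mapHitsToAncestral <- function(gene_hits, homology_map) {
    if (is.null(gene_hits) || nrow(gene_hits) == 0) {
        stop("no comparative hits: cannot form an origin vector")
    }
    mass <- list()
    for (i in seq_len(nrow(gene_hits))) {
        sp <- gene_hits$species[i]
        ch <- gene_hits$chromosome[i]
        origins <- homology_map$origin[homology_map$species == sp &
                                           homology_map$chrom == ch]
        if (length(origins) == 0) {
            stop("chromosome '", ch, "' of species '", sp,
                 "' is absent from the homology map")
        }
        share <- gene_hits$bitscore[i] / length(origins)
        for (o in origins) {
            mass[[o]] <- (if (is.null(mass[[o]])) 0 else mass[[o]]) + share
        }
    }
    v <- unlist(mass)
    v <- v / sum(gene_hits$bitscore)
    v <- sort(v, decreasing = TRUE)
    stopifnot(abs(sum(v) - 1) < 1e-9)
    attr(v, "m") <- nrow(gene_hits)
    v
}

#' Bootstrap assignment of an ancestral origin
#'
#' Draws \code{n_bootstrap} replicates of \code{m} origin labels from the
#' empirical probabilities; an origin's support is the fraction of
#' replicates in which it is the majority label (ties split equally among
#' the tied origins). Replicates are drawn as a balanced bootstrap (the
#' pooled labels match the empirical frequencies exactly and are permuted
#' into replicates), which keeps each replicate an m-label resample while
#' reducing Monte-Carlo noise in the support estimates. The assignment is unique iff the best origin's
#' support is at least \code{support_min} and exceeds the runner-up's by
#' at least \code{margin_min}; otherwise the gene is ambiguous and all
#' origins within \code{margin_min} of the best support are retained as
#' candidates.
#'
#' @param probs Named probability vector (\code{\link{mapHitsToAncestral}}).
#' @param m Labels per replicate; defaults to the vector's hit count.
#' @param n_bootstrap,support_min,margin_min Bootstrap parameters
#'   (defaults 1000, 0.5, 0.05).
#' @param seed Optional integer seed.
#' @return list with \code{origin}, \code{support}, \code{margin},
#'   \code{status} ("unique"/"ambiguous"), \code{candidates},
#'   \code{support_table}.
#' @export
bootstrapAssign <- function(probs, m = NULL, n_bootstrap = 1000,
                            support_min = 0.5, margin_min = 0.05,
                            seed = NULL) {
    if (!is.null(seed)) {
        set.seed(seed)
    }
    if (is.null(m)) {
        m <- attr(probs, "m")
        if (is.null(m)) m <- length(probs)
    }
    k <- length(probs)
    support <- stats::setNames(numeric(k), names(probs))
    if (k == 1) {
        support[1] <- 1
    } else {
        # balanced bootstrap: the pooled n_bootstrap x m label draws carry
        # the empirical frequencies exactly (largest-remainder rounding)
        # and are permuted into replicates, reducing Monte-Carlo noise
        # relative to independent multinomial replicates
        total <- n_bootstrap * m
        base <- floor(probs * total)
        rem <- total - sum(base)
        if (rem > 0) {
            frac <- probs * total - base
            base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
                base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
        }
        pool <- sample(rep.int(seq_len(k), base))
        cnt <- vapply(seq_len(k), function(j) {
            tabulate(((which(pool == j) - 1L) %/% m) + 1L, n_bootstrap)
        }, integer(n_bootstrap))
        cnt <- t(matrix(cnt, nrow = n_bootstrap))
        mx <- apply(cnt, 2, max)
        is_top <- sweep(cnt, 2, mx, "==")
        n_top <- colSums(is_top)
        support <- rowSums(sweep(is_top, 2, n_top, "/")) / n_bootstrap
        names(support) <- names(probs)
    }
    support <- sort(support, decreasing = TRUE)
    best <- support[1]
    runner <- if (k > 1) support[2] else 0
    unique_hit <- best >= support_min && (best - runner) >= margin_min
    candidates <- names(support)[support >= best - margin_min]
    list(
        origin = if (unique_hit) names(support)[1] else candidates,
        support = unname(best), margin = unname(best - runner),
        status = if (unique_hit) "unique" else "ambiguous",
        candidates = candidates, support_table = support
    )
}

#' Assign ancestral origins to every gene of a focal genome
#'
#' Batch driver over \code{\link{mapHitsToAncestral}} and
#' \code{\link{bootstrapAssign}}. Evidence rows are filtered comparative
#' hits of the focal genome against the comparator species, with the
#' comparator chromosome looked up from its position table.
#'
#' @param hits_by_species Named list (species -> outfmt-6 data.frame of
#'   focal-vs-comparator hits, focal gene as \code{qseqid}).
#' @param positions_by_species Named list of comparator position tables
#'   (\code{\link{genePositions}}).
#' @param homology_map Long-form homology map.
#' @param n_bootstrap,support_min,margin_min,seed See
#'   \code{\link{bootstrapAssign}}.
#' @return data.frame: gene_id, origin (best or NA when ambiguous),
#'   support, margin, status, candidates (comma-joined), m.
#' @export
assignOrigins <- function(hits_by_species, positions_by_species,
                          homology_map, n_bootstrap = 1000,
                          support_min = 0.5, margin_min = 0.05, seed = 1) {
    ev <- list()
    for (sp in names(hits_by_species)) {
        h <- hits_by_species[[sp]]
        if (nrow(h) == 0) next
        pos <- positions_by_species[[sp]]
        idx <- match(h$sseqid, pos$gene_id)
        if (anyNA(idx)) {
            stop("comparator gene(s) of '", sp, "' missing positions: ",
                 paste(utils::head(h$sseqid[is.na(idx)], 3), collapse = ", "))
        }
        ev[[sp]] <- data.frame(
            gene_id = h$qseqid, species = sp, chromosome = pos$chrom[idx],
            bitscore = h$bitscore, stringsAsFactors = FALSE
        )
    }
    evidence <- do.call(rbind, ev)
    set.seed(seed)
    genes <- sort(unique(evidence$gene_id))
    by_gene <- split(evidence, evidence$gene_id)
    rows <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
        g <- genes[gi]
        probs <- mapHitsToAncestral(by_gene[[g]], homology_map)
        asg <- bootstrapAssign(probs, n_bootstrap = n_bootstrap,
                               support_min = support_min,
                               margin_min = margin_min)
        rows[[gi]] <- data.frame(
            gene_id = g,
            origin = if (asg$status == "unique") asg$origin else NA_character_,
            support = asg$support, margin = asg$margin, status = asg$status,
            candidates = paste(asg$candidates, collapse = ","),
            m = attr(probs, "m"), stringsAsFactors = FALSE
        )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Validate origins along syntenic blocks
#'
#' Cross-validates per-gene assignments with synteny: within a block
#' (built at the stricter painting gap), the origin shared by the
#' unambiguous members becomes the block origin; ambiguous members inherit
#' it when it is among their candidates. Where unambiguous members
#' disagree, the block is split at each disagreement point and the
#' fragments are painted separately.
#'
#' @param assignments Output of \code{\link{assignOrigins}} for the focal
#'   genome's genes.
#' @param members Block membership table (\code{$members} of
#'   \code{\link{chainBlocks}}, focal genes on the A side).
#' @return data.frame of painted focal genes: gene_id, chrom, rank,
#'   block_id, sub_block, origin, status
#'   ("unique"/"inherited"/"ambiguous").
#' @export
paintBlocks <- function(assignments, members) {
    aidx <- match(members$gene_a, assignments$gene_id)
    tab <- data.frame(
        gene_id = members$gene_a, chrom = members$chr_a,
        rank = members$rank_a, block_id = members$block_id,
        origin = assignments$origin[aidx],
        status = assignments$status[aidx],
        candidates = assignments$candidates[aidx],
        stringsAsFactors = FALSE
    )
    tab <- tab[!is.na(tab$status), , drop = FALSE]
    out <- list()
    for (blk in split(tab, tab$block_id)) {
        blk <- blk[order(blk$rank), , drop = FALSE]
        # split at points where consecutive unambiguous origins disagree
        uo <- ifelse(blk$status == "unique", blk$origin, NA_character_)
        sub <- integer(nrow(blk))
        cur <- 1L
        last <- NA_character_
        for (i in seq_len(nrow(blk))) {
            if (!is.na(uo[i])) {
                if (!is.na(last) && uo[i] != last) {
                    cur <- cur + 1L
                }
                last <- uo[i]
            }
            sub[i] <- cur
        }
        blk$sub_block <- sub
        for (sb in split(blk, blk$sub_block)) {
            uniq <- sb$origin[sb$status == "unique"]
            block_origin <- if (length(uniq)) uniq[1] else NA_character_
            painted_status <- sb$status
            painted_origin <- sb$origin
            if (!is.na(block_origin)) {
                amb <- sb$status == "ambiguous"
                inheritable <- amb & vapply(
                    strsplit(sb$candidates, ","),
                    function(cc) block_origin %in% cc, logical(1)
                )
                painted_origin[inheritable] <- block_origin
                painted_status[inheritable] <- "inherited"
            }
            out[[length(out) + 1]] <- data.frame(
                gene_id = sb$gene_id, chrom = sb$chrom, rank = sb$rank,
                block_id = sb$block_id, sub_block = sb$sub_block,
                origin = painted_origin, status = painted_status,
                stringsAsFactors = FALSE
            )
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$chrom, res$rank), , drop = FALSE]
}

#' Terminate blocks at transition zones
#'
#' Slides a window along each painted block; where the fraction of
#' still-ambiguous genes exceeds the threshold, the window's genes are
#' excised from the block and flagged as a transition zone (regions where
#' rearrangement obscures a single ancestral origin).
#'
#' @param painted Output of \code{\link{paintBlocks}}.
#' @param window Window size in genes (default 10).
#' @param threshold Ambiguous fraction above which a window is terminated
#'   (default 0.5).
#' @return \code{painted} with transition genes set to status
#'   \code{"transition"} (origin NA); attribute \code{"zones"} lists the
#'   excised windows (chrom, start_rank, end_rank).
#' @export
terminateTransitionZones <- function(painted, window = 10, threshold = 0.5) {
    zones <- list()
    for (key in unique(painted$block_id)) {
        idx <- which(painted$block_id == key)
        idx <- idx[order(painted$rank[idx])]
        n <- length(idx)
        if (n == 0) next
        amb <- painted$status[idx] == "ambiguous"
        w <- min(window, n)
        kill <- logical(n)
        for (s in seq_len(n - w + 1)) {
            win <- s:(s + w - 1)
            if (mean(amb[win]) > threshold) {
                kill[win] <- TRUE
            }
        }
        if (any(kill)) {
            painted$status[idx[kill]] <- "transition"
            painted$origin[idx[kill]] <- NA_character_
            zones[[length(zones) + 1]] <- data.frame(
                chrom = painted$chrom[idx[1]],
                start_rank = min(painted$rank[idx[kill]]),
                end_rank = max(painted$rank[idx[kill]]),
                block_id = key, stringsAsFactors = FALSE
            )
        }
    }
    attr(painted, "zones") <- if (length(zones)) do.call(rbind, zones) else
        data.frame(chrom = character(0), start_rank = integer(0),
                   end_rank = integer(0), block_id = integer(0))
    painted
}

#' Collapse painted genes into ordered chromosome segments
#'
#' Orders each chromosome's resolved genes by rank, drops origin runs
#' shorter than \code{min_segment} as noise, and merges adjacent runs of
#' equal origin.
#'
#' @param painted Painted gene table (origin resolved or NA).
#' @param min_segment Minimum genes per painted segment (default 5).
#' @return data.frame: chrom, start_rank, end_rank, origin, n_genes.
#' @export
paintedSegments <- function(painted, min_segment = 5) {
    painted <- painted[!is.na(painted$origin), , drop = FALSE]
    segs <- list()
    for (ch in sort(unique(painted$chrom))) {
        d <- painted[painted$chrom == ch, , drop = FALSE]
        d <- d[order(d$rank), , drop = FALSE]
        r <- rle(d$origin)
        keep <- r$lengths >= min_segment
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        vals <- r$values[keep]
        st <- starts[keep]
        en <- ends[keep]
        if (length(vals) == 0) next
        # merge adjacent equal origins after noise removal
        merged <- list()
        for (i in seq_along(vals)) {
            last <- if (length(merged)) merged[[length(merged)]] else NULL
            if (!is.null(last) && last$origin == vals[i]) {
                last$end <- en[i]
                last$n <- last$n + (en[i] - st[i] + 1)
                merged[[length(merged)]] <- last
            } else {
                merged[[length(merged) + 1]] <-
                    list(origin = vals[i], start = st[i], end = en[i],
                         n = en[i] - st[i] + 1)
            }
        }
        for (mseg in merged) {
            segs[[length(segs) + 1]] <- data.frame(
                chrom = ch, start_rank = d$rank[mseg$start],
                end_rank = d$rank[mseg$end], origin = mseg$origin,
                n_genes = mseg$n, stringsAsFactors = FALSE
            )
        }
    }
    out <- do.call(rbind, segs)
    if (is.null(out)) {
        out <- data.frame(chrom = character(0), start_rank = integer(0),
                          end_rank = integer(0), origin = character(0),
                          n_genes = integer(0))
    }
    rownames(out) <- NULL
    out
}

#' Call rearrangement events from painted chromosome structure
#'
#' Per chromosome, repeatedly reduces innermost outer-inner-outer painted
#' patterns to nested chromosome insertion (NCI) calls (reported
#' innermost-first with a nesting depth), then classifies leftover
#' multi-origin junctions: a junction (X, Y) mirrored by a reciprocal
#' (Y, X) junction on another chromosome is a translocation; a partner
#' origin seen truncated elsewhere without a reciprocal junction is
#' flagged unresolved; anything else is an end-to-end fusion.
#'
#' @param segments Painted segment table (\code{\link{paintedSegments}}).
#' @param min_segment Segments below this many genes are ignored as noise.
#' @return data.frame of events: type ("NCI"/"translocation"/
#'   "end_fusion"), chrom, outer, inserted (NCI) or partner origins,
#'   depth, unresolved flag.
#' @export
callRearrangements <- function(segments, min_segment = 5) {
    segments <- segments[segments$n_genes >= min_segment, , drop = FALSE]
    events <- list()
    leftovers <- list()
    for (ch in unique(segments$chrom)) {
        s <- segments[segments$chrom == ch, , drop = FALSE]
        s <- s[order(s$start_rank), , drop = FALSE]
        seqo <- s$origin
        # merge adjacent duplicates defensively
        seqo <- rle(seqo)$values
        depth <- 0L
        repeat {
            found <- FALSE
            if (length(seqo) >= 3) {
                for (i in 2:(length(seqo) - 1)) {
                    if (seqo[i - 1] == seqo[i + 1] && seqo[i] != seqo[i - 1]) {
                        depth <- depth + 1L
                        events[[length(events) + 1]] <- data.frame(
                            type = "NCI", chrom = ch, outer = seqo[i - 1],
                            inserted = seqo[i], partner = NA_character_,
                            depth = depth, unresolved = FALSE,
                            stringsAsFactors = FALSE
                        )
                        seqo <- seqo[-c(i, i + 1)]
                        seqo <- rle(seqo)$values
                        found <- TRUE
                        break
                    }
                }
            }
            if (!found) break
        }
        leftovers[[ch]] <- seqo
    }
    # classify residual junctions across chromosomes
    junctions <- list()
    for (ch in names(leftovers)) {
        seqo <- leftovers[[ch]]
        if (length(seqo) < 2) next
        for (i in seq_len(length(seqo) - 1)) {
            junctions[[length(junctions) + 1]] <-
                list(chrom = ch, x = seqo[i], y = seqo[i + 1])
        }
    }
    jkey <- vapply(junctions, function(j) paste(j$x, j$y, sep = ">"),
                   character(1))
    for (j in junctions) {
        reciprocal <- paste(j$y, j$x, sep = ">")
        has_recip <- any(jkey == reciprocal)
        partner_elsewhere <- any(vapply(junctions, function(o) {
            o$chrom != j$chrom && (o$x == j$y || o$y == j$y)
        }, logical(1)))
        type <- if (has_recip) "translocation" else "end_fusion"
        events[[length(events) + 1]] <- data.frame(
            type = type, chrom = j$chrom, outer = j$x, inserted = NA_character_,
            partner = j$y, depth = 0L,
            unresolved = !has_recip && partner_elsewhere,
            stringsAsFactors = FALSE
        )
    }
    out <- if (length(events)) do.call(rbind, events) else
        data.frame(type = character(0), chrom = character(0),
                   outer = character(0), inserted = character(0),
                   partner = character(0), depth = integer(0),
                   unresolved = logical(0))
    rownames(out) <- NULL
    out
}

#' Reconstruct stage karyotypes from called events
#'
#' Classifies each distinct rearrangement by the number of final
#' chromosome copies exhibiting it: events present in all
#' \eqn{2^w} copies (w = number of WGDs, inferred from the modal number of
#' chromosomes carrying each ancestral origin) predate the first WGD;
#' events in half the copies fall between the two WGDs. Chromosome counts
#' are then reconstructed stage by stage: ancestral count, count after the
#' shared fusions (pre-WGD1), count after WGD1 plus the lineage-specific
#' fusions (pre-WGD2), and the doubled final count.
#'
#' @param events Called events (\code{\link{callRearrangements}}).
#' @param segments Painted segments (for copy counting).
#' @return list: \code{n_ancestral}, \code{wgd_count},
#'   \code{n_pre_wgd1}, \code{n_between_wgds}, \code{n_final_expected},
#'   \code{n_final_observed}, plus data.frames \code{shared_ncis},
#'   \code{lineage_ncis}, \code{translocations}.
#' @export
karyotypeStages <- function(events, segments) {
    origins <- unique(segments$origin)
    n_anc <- length(origins)
    copies <- vapply(origins, function(o) {
        length(unique(segments$chrom[segments$origin == o]))
    }, integer(1))
    modal_copies <- as.integer(names(sort(table(copies),
                                          decreasing = TRUE))[1])
    w <- max(0L, as.integer(round(log2(modal_copies))))
    full <- 2^w

    ncis <- events[events$type == "NCI", , drop = FALSE]
    sig <- paste(ncis$inserted, ncis$outer, sep = ">")
    sig_chroms <- lapply(split(ncis$chrom, sig), unique)
    counts <- vapply(sig_chroms, length, integer(1))
    shared_sig <- names(counts)[counts > full / 2]
    lineage_sig <- names(counts)[counts <= full / 2 & counts > full / 4]

    split_sig <- function(sigs) {
        if (length(sigs) == 0) {
            return(data.frame(inserted = character(0), outer = character(0),
                              copies = integer(0)))
        }
        parts <- strsplit(sigs, ">")
        data.frame(
            inserted = vapply(parts, `[`, character(1), 1),
            outer = vapply(parts, `[`, character(1), 2),
            copies = as.integer(counts[sigs]), stringsAsFactors = FALSE
        )
    }

    # unresolved junctions carry translocation-like evidence (the partner
    # is truncated elsewhere) and are not counted as chromosome-reducing
    fus <- events[events$type == "end_fusion" & !events$unresolved, ,
                  drop = FALSE]
    fkey <- apply(cbind(fus$outer, fus$partner), 1, function(x)
        paste(sort(x), collapse = "|"))
    f_counts <- vapply(split(fus$chrom, fkey), function(x)
        length(unique(x)), integer(1))
    shared_fus <- names(f_counts)[f_counts > full / 2]
    lineage_fus <- names(f_counts)[f_counts <= full / 2 &
                                       f_counts > full / 4]

    tra <- events[events$type == "translocation", , drop = FALSE]
    tkey <- apply(cbind(tra$outer, tra$partner), 1, function(x)
        paste(sort(x), collapse = "|"))
    tra_unique <- unique(data.frame(pair = tkey,
                                    stringsAsFactors = FALSE))

    n_pre1 <- n_anc - length(shared_sig) - length(shared_fus)
    n_between <- 2L * n_pre1 - length(lineage_sig) - length(lineage_fus)
    list(
        n_ancestral = n_anc, wgd_count = w,
        n_pre_wgd1 = n_pre1, n_between_wgds = n_between,
        n_final_expected = 2L * n_between,
        n_final_observed = length(unique(segments$chrom)),
        shared_ncis = split_sig(shared_sig),
        lineage_ncis = split_sig(lineage_sig),
        translocations = tra_unique
    )
}

setMethod("show", "PaintedKaryotype", function(object) {
    cat("PaintedKaryotype:", nrow(object@assignments), "genes painted,",
        nrow(object@segments), "segments,",
        nrow(object@events), "events\n")
    if (length(object@stages)) {
        st <- object@stages
        cat(sprintf("  stages: n=%d -> %d (pre-WGD1) -> %d (pre-WGD2) -> %d\n",
                    st$n_ancestral, st$n_pre_wgd1, st$n_between_wgds,
                    st$n_final_observed))
    }
    invisible(NULL)
})
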