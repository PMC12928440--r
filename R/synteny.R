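# Collinearity: chaining homolog pairs into syntenic blocks, syntenic
# depth ratios, pseudochromosome assembly and dotplot export.

#' Gene ranks from a BED-like position table
#'
#' Converts 0-based half-open gene coordinates into ordinal ranks along
#' each chromosome/scaffold (rank space is the gap metric used by the
#' chaining criterion "no more than N intervening genes").
#'
#' @param bed data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{gene_id}.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{rank}, \code{strand}.
#' @export
genePositions <- function(bed) {
    stopifnot(all(c("chrom", "start", "gene_id") %in% names(bed)))
    bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
    rank <- stats::ave(bed$start, bed$chrom, FUN = seq_along)
    data.frame(
        gene_id = bed$gene_id, chrom = bed$chrom, rank = as.integer(rank),
        strand = if ("strand" %in% names(bed)) bed$strand else "+",
        stringsAsFactors = FALSE
    )
}

.lookupPositions <- function(genes, positions, genome) {
    idx <- match(genes, positions$gene_id)
    if (anyNA(idx)) {
        stop("missing position (genome ", genome, ") for gene(s): ",
             paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
    }
    positions[idx, , drop = FALSE]
}

#' Remove genes with multiple homologs on one partner chromosome
#'
#' Local (tandem-like) duplications blur collinearity: any gene whose
#' homologs in the partner genome include two or more copies on a single
#' partner chromosome has those pairs removed (pairs to chromosomes where
#' the gene has a unique homolog are kept). The rule is applied to both
#' sides of the pair table on the original input.
#'
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b}.
#' @param positions_a,positions_b Position tables
#'   (\code{\link{genePositions}}) for the two genomes.
#' @return The retained rows of \code{pairs}.
#' @export
dropSameChromosomeMulticopy <- function(pairs, positions_a, positions_b) {
    if (nrow(pairs) == 0) {
        return(pairs)
    }
    pa <- .lookupPositions(pairs$gene_a, positions_a, "A")
    pb <- .lookupPositions(pairs$gene_b, positions_b, "B")
    key_a <- paste(pairs$gene_a, pb$chrom, sep = "\r")
    key_b <- paste(pairs$gene_b, pa$chrom, sep = "\r")
    multi_a <- names(which(table(key_a) >= 2))
    multi_b <- names(which(table(key_b) >= 2))
    keep <- !(key_a %in% multi_a) & !(key_b %in% multi_b)
    pairs[keep, , drop = FALSE]
}

# Longest chain starting at each index under the gap/monotonicity rules.
# ranks_a strictly increasing across the chain; ranks_b strictly
# increasing (asc) or decreasing (desc); at most max_gap intervening gene
# ranks on both genomes between consecutive pairs.
.chainForwardDP <- function(ra, rb, max_gap, descending) {
    n <- length(ra)
    f <- integer(n)
    for (i in rev(seq_len(n))) {
        best <- 0L
        for (j in seq_len(n)) {
            if (j <= i) next
            if (ra[j] <= ra[i]) next
            if (ra[j] - ra[i] - 1L > max_gap) next
            db <- if (descending) rb[i] - rb[j] else rb[j] - rb[i]
            if (db <= 0L || db - 1L > max_gap) next
            if (f[j] > best) best <- f[j]
        }
        f[i] <- 1L + best
    }
    f
}

# Gap levels at which new links between pairs become legal: the sorted
# unique values of max(gap_a, gap_b) over monotone pair combinations, up
# to the cap (extraction between consecutive levels cannot change).
.linkLevels <- function(ra, rb, max_gap) {
    n <- length(ra)
    if (n < 2) {
        return(0L)
    }
    ga <- abs(outer(ra, ra, "-")) - 1L
    gb <- abs(outer(rb, rb, "-")) - 1L
    lev <- pmax(ga, gb)[upper.tri(ga)]
    sort(unique(c(0L, lev[lev >= 0L & lev <= max_gap])))
}

# Lexicographically-smallest maximum-length chain (vector of indices into
# the pool, which is sorted by (rank_a, rank_b)).
.extractBestChain <- function(ra, rb, max_gap) {
    f_asc <- .chainForwardDP(ra, rb, max_gap, descending = FALSE)
    f_desc <- .chainForwardDP(ra, rb, max_gap, descending = TRUE)
    use_desc <- max(f_desc) > max(f_asc)
    f <- if (use_desc) f_desc else f_asc
    lmax <- max(f)
    chain <- integer(0)
    need <- lmax
    prev <- 0L
    for (step in seq_len(lmax)) {
        for (i in seq_along(f)) {
            if (f[i] != need) next
            if (prev > 0L) {
                if (i <= prev || ra[i] <= ra[prev]) next
                if (ra[i] - ra[prev] - 1L > max_gap) next
                db <- if (use_desc) rb[prev] - rb[i] else rb[i] - rb[prev]
                if (db <= 0L || db - 1L > max_gap) next
            }
            chain <- c(chain, i)
            prev <- i
            break
        }
        need <- need - 1L
    }
    list(chain = chain, orientation = if (use_desc) "inverted" else "same")
}

#' Chain collinear homolog pairs into syntenic blocks
#'
#' Within each (chromosome A, chromosome B) combination, chains pairs with
#' monotone rank progression (ascending and descending orientations
#' chained separately) and at most \code{max_gap} intervening genes
#' between consecutive pairs on \emph{both} genomes, by progressive gap
#' relaxation: the longest chains are repeatedly extracted first under a
#' gap allowance of 0, then the allowance is raised one legal level at a
#' time up to \code{max_gap}, re-extracting at each level; chains below
#' \code{min_pairs} pairs are never extracted. Ties are resolved
#' deterministically (ascending orientation first, then the
#' lexicographically smallest chain in (rank A, rank B) order).
#'
#' Tightest-first extraction prefers coherent collinear runs over chains
#' that bridge distant runs, and makes the chained-pair total monotone in
#' \code{max_gap} by construction: the extraction schedule under a
#' smaller cap is a prefix of the schedule under a larger one.
#'
#' @param pairs data.frame with \code{gene_a}, \code{gene_b} and
#'   optionally \code{Ks}.
#' @param positions_a,positions_b Position tables for the two genomes.
#' @param min_pairs Minimum pairs per retained block (default 5).
#' @param max_gap Maximum intervening gene ranks (default 100).
#' @return A list with \code{blocks} (block_id, chr_a, chr_b, orientation,
#'   n_pairs, ks_median, start/end ranks) and \code{members} (per-pair
#'   rows with block_id and both ranks).
#' @export
chainBlocks <- function(pairs, positions_a, positions_b, min_pairs = 5,
                        max_gap = 100) {
    empty <- list(
        blocks = data.frame(
            block_id = integer(0), chr_a = character(0), chr_b = character(0),
            orientation = character(0), n_pairs = integer(0),
            ks_median = numeric(0), start_a = integer(0), end_a = integer(0),
            start_b = integer(0), end_b = integer(0)
        ),
        members = data.frame(
            block_id = integer(0), gene_a = character(0),
            gene_b = character(0), chr_a = character(0), chr_b = character(0),
            rank_a = integer(0), rank_b = integer(0), Ks = numeric(0)
        )
    )
    if (nrow(pairs) == 0) {
        return(empty)
    }
    pa <- .lookupPositions(pairs$gene_a, positions_a, "A")
    pb <- .lookupPositions(pairs$gene_b, positions_b, "B")
    tab <- data.frame(
        gene_a = pairs$gene_a, gene_b = pairs$gene_b,
        chr_a = pa$chrom, chr_b = pb$chrom,
        rank_a = pa$rank, rank_b = pb$rank,
        Ks = if ("Ks" %in% names(pairs)) pairs$Ks else NA_real_,
        stringsAsFactors = FALSE
    )
    blocks <- list()
    members <- list()
    bid <- 0L
    for (grp in split(tab, list(tab$chr_a, tab$chr_b), drop = TRUE)) {
        grp <- grp[order(grp$rank_a, grp$rank_b), , drop = FALSE]
        pool <- grp
        # gap levels at which some pairwise link first becomes legal;
        # computed from the full group so the ladder is cap-independent
        levels <- .linkLevels(grp$rank_a, grp$rank_b, max_gap)
        for (lev in levels) {
            repeat {
                if (nrow(pool) < min_pairs) break
                res <- .extractBestChain(pool$rank_a, pool$rank_b, lev)
                if (length(res$chain) < min_pairs) break
                bid <- bid + 1L
                mem <- pool[res$chain, , drop = FALSE]
                members[[bid]] <- cbind(block_id = bid, mem)
                blocks[[bid]] <- data.frame(
                    block_id = bid, chr_a = mem$chr_a[1],
                    chr_b = mem$chr_b[1],
                    orientation = res$orientation, n_pairs = nrow(mem),
                    ks_median = stats::median(mem$Ks),
                    start_a = min(mem$rank_a), end_a = max(mem$rank_a),
                    start_b = min(mem$rank_b), end_b = max(mem$rank_b),
                    stringsAsFactors = FALSE
                )
                pool <- pool[-res$chain, , drop = FALSE]
            }
            if (nrow(pool) < min_pairs) break
        }
    }
    if (length(blocks) == 0) {
        return(empty)
    }
    out_blocks <- do.call(rbind, blocks)
    out_members <- do.call(rbind, members)
    rownames(out_blocks) <- rownames(out_members) <- NULL
    list(blocks = out_blocks, members = out_members)
}

#' Syntenic depth profile of a reference genome
#'
#' For each reference chromosome (the A side of the blocks), counts the
#' distinct partner chromosomes/scaffolds covered by at least one syntenic
#' block, and reports the modal depth. Depth reflects cumulative ploidy
#' difference: a diploid reference against a genome with two additional
#' WGDs shows modal depth 4.
#'
#' @param blocks Block table from \code{\link{chainBlocks}} (the
#'   \code{$blocks} element).
#' @param reference_chroms Optional character vector of all reference
#'   chromosomes (so chromosomes without blocks count depth 0).
#' @param exclude_self Drop blocks whose two chromosomes share one name
#'   (for within-genome comparisons).
#' @return A list with \code{depth} (named integer per reference
#'   chromosome) and \code{modal_depth}.
#' @export
syntenicDepth <- function(blocks, reference_chroms = NULL,
                          exclude_self = FALSE) {
    if (is.null(reference_chroms)) {
        reference_chroms <- sort(unique(blocks$chr_a))
    }
    if (exclude_self) {
        blocks <- blocks[blocks$chr_a != blocks$chr_b, , drop = FALSE]
    }
    depth <- vapply(reference_chroms, function(ch) {
        length(unique(blocks$chr_b[blocks$chr_a == ch]))
    }, integer(1))
    names(depth) <- reference_chroms
    if (length(depth) == 0) {
        return(list(depth = depth, modal_depth = NA_integer_))
    }
    tt <- table(depth)
    modal <- as.integer(names(tt)[which.max(tt)])
    list(depth = depth, modal_depth = modal)
}

#' Assign scaffolds to pseudochromosomes by majority synteny
#'
#' Each scaffold (A side of the blocks) is assigned to the reference
#' chromosome (B side) carrying the plurality of its chained pairs;
#' pseudochromosomes take the reference numbering. Ties are broken toward
#' the lower-numbered reference chromosome and flagged. Scaffolds with no
#' blocks are listed as unplaced.
#'
#' @param blocks Block table (\code{$blocks} from \code{\link{chainBlocks}}
#'   of scaffolds vs the reference).
#' @param scaffolds Optional character vector of all scaffolds (to report
#'   unplaced ones).
#' @return A list with \code{map} (scaffold, pseudochromosome, pairs,
#'   tie flag) and \code{unplaced}.
#' @export
assemblePseudochromosomes <- function(blocks, scaffolds = NULL) {
    if (is.null(scaffolds)) {
        scaffolds <- sort(unique(blocks$chr_a))
    }
    chrom_order <- function(x) {
        num <- suppressWarnings(as.numeric(gsub("\\D", "", x)))
        order(ifelse(is.na(num), Inf, num), x)
    }
    rows <- list()
    unplaced <- character(0)
    for (sc in scaffolds) {
        b <- blocks[blocks$chr_a == sc, , drop = FALSE]
        if (nrow(b) == 0) {
            unplaced <- c(unplaced, sc)
            next
        }
        votes <- tapply(b$n_pairs, b$chr_b, sum)
        best <- max(votes)
        winners <- names(votes)[votes == best]
        winner <- winners[chrom_order(winners)[1]]
        rows[[length(rows) + 1]] <- data.frame(
            scaffold = sc, pseudochromosome = winner, pairs = best,
            tie = length(winners) > 1, stringsAsFactors = FALSE
        )
    }
    map <- if (length(rows)) do.call(rbind, rows) else
        data.frame(scaffold = character(0), pseudochromosome = character(0),
                   pairs = numeric(0), tie = logical(0))
    list(map = map, unplaced = unplaced)
}

#' Export dotplot data with Ks band labels
#'
#' One row per homolog pair with both genome coordinates and a Ks-band
#' label; bands are closed-open intervals \code{[lower, upper)}. Pairs not
#' covered by any band are labelled \code{"other"}.
#'
#' @param pairs data.frame with \code{gene_a}, \code{gene_b}, \code{Ks}.
#' @param positions_a,positions_b Position tables.
#' @param bands data.frame with \code{lower}, \code{upper}, \code{label}.
#' @param path Optional TSV output path.
#' @return data.frame (invisibly when \code{path} given).
#' @export
exportDotplotTable <- function(pairs, positions_a, positions_b,
                               bands = NULL, path = NULL) {
    if (nrow(pairs) > 0) {
        pa <- .lookupPositions(pairs$gene_a, positions_a, "A")
        pb <- .lookupPositions(pairs$gene_b, positions_b, "B")
        out <- data.frame(
            gene_a = pairs$gene_a, gene_b = pairs$gene_b,
            chr_a = pa$chrom, rank_a = pa$rank,
            chr_b = pb$chrom, rank_b = pb$rank,
            Ks = if ("Ks" %in% names(pairs)) pairs$Ks else NA_real_,
            band = "other", stringsAsFactors = FALSE
        )
        if (!is.null(bands)) {
            for (i in seq_len(nrow(bands))) {
                hit <- !is.na(out$Ks) & out$Ks >= bands$lower[i] &
                    out$Ks < bands$upper[i]
                out$band[hit] <- bands$label[i]
            }
        }
    } else {
        out <- data.frame(
            gene_a = character(0), gene_b = character(0),
            chr_a = character(0), rank_a = integer(0),
            chr_b = character(0), rank_b = integer(0),
            Ks = numeric(0), band = character(0)
        )
    }
    if (!is.null(path)) {
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(out))
    }
    out
}
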