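# Molecular-clock conversion of synonymous divergence to time.

.roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

#' Convert a Ks value to million years
#'
#' Applies the molecular clock \eqn{T = Ks / (2\mu)} with a synonymous
#' substitution rate \eqn{\mu} (default the monocot rate
#' \eqn{6.5\times10^{-9}} substitutions/site/year), returning million years
#' rounded half-up to one decimal as conventionally tabulated.
#'
#' @param ks Numeric vector of Ks values (non-negative).
#' @param mu Substitution rate in substitutions per site per year.
#' @param digits Decimal places of the returned Mya values.
#' @return Numeric vector of divergence times in Mya.
#' @examples
#' ksToMya(0.914)  # 70.3
#' @export
ksToMya <- function(ks, mu = 6.5e-9, digits = 1) {
    if (any(ks < 0)) {
        stop("ks must be non-negative")
    }
    if (mu <= 0) {
        stop("mu must be positive")
    }
    .roundHalfUp(ks / (2 * mu) / 1e6, digits)
}

#' Divergence-time window of a Ks mixture component
#'
#' Converts a fitted mixture component (mean, stdev) to a
#' (min, mode, max) divergence window in Mya: the interval
#' (mean - stdev, mean, mean + stdev) passed through \code{\link{ksToMya}}.
#' A lower bound below zero is floored at Ks = 0 and flagged.
#'
#' @param mean,stdev Component mean and standard deviation on the Ks scale.
#' @param mu Substitution rate, as in \code{\link{ksToMya}}.
#' @return A list with \code{min_mya}, \code{mode_mya}, \code{max_mya}
#'   (one decimal) and logical \code{floored}.
#' @examples
#' peakInterval(0.914, 0.335)  # 44.5 / 70.3 / 96.1
#' @export
peakInterval <- function(mean, stdev, mu = 6.5e-9) {
    if (stdev < 0) {
        stop("stdev must be non-negative")
    }
    lo <- mean - stdev
    floored <- lo < 0
    if (floored) {
        lo <- 0
    }
    out <- list(
        min_mya = ksToMya(lo, mu),
        mode_mya = ksToMya(mean, mu),
        max_mya = ksToMya(mean + stdev, mu),
        floored = floored
    )
    stopifnot(out$min_mya <= out$mode_mya, out$mode_mya <= out$max_mya)
    out
}

#' Divergence table for a fitted mixture
#'
#' One row per mixture component with Ks mode, stdev and the clock-converted
#' (min, mode, max) window, mirroring the layout of published divergence
#' tables.
#'
#' @param fit A \code{\link{KsMixtureFit}}.
#' @param mu Substitution rate.
#' @return data.frame with columns component, weight, ks_mode, ks_sd,
#'   min_mya, mode_mya, max_mya.
#' @export
divergenceTable <- function(fit, mu = 6.5e-9) {
    rows <- lapply(seq_len(fit@k), function(i) {
        pi <- peakInterval(fit@means[i], fit@sigmas[i], mu)
        data.frame(
            component = i, weight = fit@weights[i],
            ks_mode = fit@means[i], ks_sd = fit@sigmas[i],
            min_mya = pi$min_mya, mode_mya = pi$mode_mya,
            max_mya = pi$max_mya
        )
    })
    do.call(rbind, rows)
}
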