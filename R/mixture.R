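#' Fit a Gaussian mixture to a Ks distribution by EM
#'
#' Expectation-maximization fitting of a univariate Gaussian mixture with
#' unequal variances, iterated until the log-likelihood improves by less
#' than \code{tol} (default 0.001, the conventional setting for Ks-peak
#' modelling). The number of components is chosen by BIC over
#' \code{k_range}. Peaks in the resulting fit are candidate whole-genome
#' duplication events; component means are the reported Ks modes.
#'
#' Initialisation is deterministic (quantile-spaced means), so the selected
#' fit does not depend on the seed; the seed governs the bootstrap, which
#' resamples the Ks vector with replacement and refits with k fixed to the
#' selected value, reporting the standard deviation of each component mean.
#'
#' @param ks Numeric vector of Ks values (length at least 50).
#' @param k_range Candidate component counts, a subset of 1..5.
#' @param tol Absolute log-likelihood change at which EM stops.
#' @param max_iter Maximum EM iterations (non-convergence is flagged,
#'   not an error).
#' @param n_bootstrap Bootstrap replicates (0 disables).
#' @param seed Integer seed for the bootstrap.
#' @return A \code{\link{KsMixtureFit}}.
#' @examples
#' set.seed(1)
#' fit <- fitKsMixture(c(rnorm(300, 0.1, 0.02), rnorm(300, 0.5, 0.1)),
#'                     k_range = 1:3, n_bootstrap = 0)
#' ksMeans(fit)
#' @export
fitKsMixture <- function(ks, k_range = 1:4, tol = 0.001, max_iter = 1000,
                         n_bootstrap = 1000, seed = NULL) {
    ks <- as.numeric(ks[!is.na(ks)])
    if (length(ks) < 50) {
        stop("at least 50 Ks values are required")
    }
    if (!all(k_range %in% 1:5)) {
        stop("k_range must be a subset of 1..5")
    }
    n <- length(ks)
    fits <- lapply(k_range, function(k) .emFit(ks, k, tol, max_iter))
    bic <- vapply(fits, function(f) f$bic, numeric(1))
    names(bic) <- as.character(k_range)
    best <- fits[[which.min(bic)]]

    boot <- data.frame()
    if (n_bootstrap > 0) {
        if (!is.null(seed)) {
            set.seed(seed)
        }
        bm <- matrix(NA_real_, n_bootstrap, best$k)
        for (b in seq_len(n_bootstrap)) {
            xb <- sample(ks, n, replace = TRUE)
            fb <- .emFit(xb, best$k, tol, max_iter,
                         init = list(w = best$weights, m = best$means,
                                     s = best$sigmas))
            bm[b, ] <- fb$means
        }
        boot <- data.frame(
            component = seq_len(best$k),
            mean_sd = apply(bm, 2, stats::sd)
        )
    }
    new("KsMixtureFit",
        k = as.integer(best$k), weights = best$weights, means = best$means,
        sigmas = best$sigmas, loglik = best$loglik, bic = best$bic,
        converged = best$converged, n = as.integer(n), bootstrap = boot,
        bic_by_k = bic)
}

# Deterministic univariate EM. Components returned sorted by mean.
.emFit <- function(x, k, tol, max_iter, init = NULL) {
    n <- length(x)
    if (is.null(init)) {
        qs <- stats::quantile(x, probs = seq(0, 1, length.out = k + 2))
        m <- as.numeric(qs[2:(k + 1)])
        s <- rep(max(stats::sd(x) / max(k, 1), 1e-4), k)
        w <- rep(1 / k, k)
    } else {
        w <- init$w
        m <- init$m
        s <- init$s
    }
    # guard against identical initial means (heavily tied data)
    if (anyDuplicated(m)) {
        m <- m + seq_len(k) * 1e-6
    }
    loglik <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
        dens <- vapply(seq_len(k), function(j) {
            w[j] * stats::dnorm(x, m[j], s[j])
        }, numeric(n))
        dens <- matrix(dens, nrow = n)
        rs <- rowSums(dens)
        rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
        ll <- sum(log(rs))
        resp <- dens / rs
        wsum <- colSums(resp)
        wsum[wsum < 1e-12] <- 1e-12
        w <- wsum / n
        m <- colSums(resp * x) / wsum
        s <- sqrt(vapply(seq_len(k), function(j) {
            sum(resp[, j] * (x - m[j])^2) / wsum[j]
        }, numeric(1)))
        s[s < 1e-6] <- 1e-6
        if (is.finite(loglik) && abs(ll - loglik) < tol) {
            loglik <- ll
            converged <- TRUE
            break
        }
        loglik <- ll
    }
    ord <- order(m)
    list(
        k = k, weights = w[ord] / sum(w), means = m[ord], sigmas = s[ord],
        loglik = loglik, bic = -2 * loglik + (3 * k - 1) * log(n),
        converged = converged
    )
}

#' @describeIn fitKsMixture Component means (Ks modes) of a fit.
#' @param fit A \code{KsMixtureFit}.
#' @export
ksMeans <- function(fit) {
    fit@means
}

#' @describeIn fitKsMixture Component weights of a fit.
#' @export
ksWeights <- function(fit) {
    fit@weights
}

#' @describeIn fitKsMixture Component standard deviations of a fit.
#' @export
ksSigmas <- function(fit) {
    fit@sigmas
}

setMethod("show", "KsMixtureFit", function(object) {
    cat("KsMixtureFit with", object@k, "component(s) over", object@n,
        "Ks values\n")
    cat(sprintf("  logLik %.2f  BIC %.2f  converged: %s\n",
                object@loglik, object@bic, object@converged))
    for (i in seq_len(object@k)) {
        cat(sprintf("  [%d] weight %.3f  mean %.4f  sd %.4f\n",
                    i, object@weights[i], object@means[i], object@sigmas[i]))
    }
    invisible(NULL)
})
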