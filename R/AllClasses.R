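#' @import methods
NULL

#' Fitted Gaussian mixture over a Ks distribution
#'
#' Container for an expectation-maximization fit of a univariate Gaussian
#' mixture to a vector of synonymous-divergence (Ks) values. Components are
#' candidate whole-genome-duplication peaks and are stored sorted by mean.
#'
#' @slot k Integer; number of components.
#' @slot weights,means,sigmas Numeric vectors of length \code{k}.
#' @slot loglik,bic Numeric scalars for the selected fit.
#' @slot converged Logical; EM reached the log-likelihood tolerance.
#' @slot n Integer; number of Ks values fitted.
#' @slot bootstrap A data.frame of bootstrap standard errors per component
#'   (possibly zero rows when no bootstrap was run).
#' @slot bic_by_k Numeric; BIC for each candidate k (named).
#' @export
setClass("KsMixtureFit",
    representation(
        k = "integer", weights = "numeric", means = "numeric",
        sigmas = "numeric", loglik = "numeric", bic = "numeric",
        converged = "logical", n = "integer", bootstrap = "data.frame",
        bic_by_k = "numeric"
    )
)

setValidity("KsMixtureFit", function(object) {
    msg <- character(0)
    if (length(object@weights) != object@k ||
        length(object@means) != object@k ||
        length(object@sigmas) != object@k) {
        msg <- c(msg, "weights/means/sigmas must have length k")
    }
    if (abs(sum(object@weights) - 1) > 1e-9) {
        msg <- c(msg, "weights must sum to 1")
    }
    if (any(object@sigmas <= 0)) {
        msg <- c(msg, "sigmas must be positive")
    }
    if (is.unsorted(object@means)) {
        msg <- c(msg, "components must be sorted by mean")
    }
    if (length(msg)) msg else TRUE
})

#' Scripted genome evolution scenario
#'
#' An ordered list of karyotype and divergence events applied to an
#' ancestral genome: whole-genome duplications, nested chromosome
#' insertions, reciprocal translocations, gene fractionation, sequence
#' divergence pulses and speciation snapshots. Events are applied in list
#' order.
#'
#' @slot events A list of event records (see \code{\link{evWGD}} and
#'   friends).
#' @slot seed Integer seed controlling all stochastic choices.
#' @export
setClass("EvolutionScenario",
    representation(events = "list", seed = "integer")
)

setValidity("EvolutionScenario", function(object) {
    ok <- vapply(object@events, function(e) {
        is.list(e) && !is.null(e$type) &&
            e$type %in% c("wgd", "nci", "translocation", "fractionation",
                          "speciation", "diverge")
    }, logical(1))
    if (all(ok)) TRUE else paste("malformed event at index", which(!ok)[1])
})

#' Ground truth of a simulated genome history
#'
#' Machine-readable record emitted alongside simulated species: per-gene
#' ancestral origins, the event log with branch placement, final monoploid
#' chromosome numbers, chromosome counts at each named stage, and the
#' signatures (outer, inserted) of every nested chromosome insertion.
#'
#' @slot gene_origins data.frame: gene_id, species, ancestral origin.
#' @slot events data.frame: event log in application order.
#' @slot final_n Named integer: monoploid chromosome number per species.
#' @slot stage_n Named integer: chromosome count after each event.
#' @slot nci_signatures data.frame: outer origin, inserted origin, stage.
#' @export
setClass("TruthRecord",
    representation(
        gene_origins = "data.frame", events = "data.frame",
        final_n = "integer", stage_n = "integer",
        nci_signatures = "data.frame"
    )
)

#' Painted karyotype of a focal genome
#'
#' Result container for ancestral-chromosome painting: per-gene origin
#' assignments with bootstrap support, painted chromosome segments,
#' called rearrangement events and reconstructed stage karyotypes.
#'
#' @slot assignments data.frame: gene, origin, support, margin, status.
#' @slot segments data.frame: chromosome, start/end rank, origin.
#' @slot events data.frame: called NCI / fusion / translocation events.
#' @slot stages list: reconstructed chromosome counts per history stage.
#' @export
setClass("PaintedKaryotype",
    representation(
        assignments = "data.frame", segments = "data.frame",
        events = "data.frame", stages = "list"
    )
)
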