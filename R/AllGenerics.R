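#' @title Accessors for SummaryMR classes
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
#' @param x an object of the documented class
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("indexSnps", function(x) standardGeneric("indexSnps"))

#' @rdname accessors
#' @export
setGeneric("fStats", function(x) standardGeneric("fStats"))

#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname accessors
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' @rdname accessors
#' @export
setGeneric("mrCI", function(x) standardGeneric("mrCI"))

#' @rdname accessors
#' @export
setGeneric("mrPval", function(x) standardGeneric("mrPval"))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname accessors
#' @export
setGeneric("oddsRatioCI", function(x) standardGeneric("oddsRatioCI"))

#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname accessors
#' @export
setGeneric("mrExtra", function(x) standardGeneric("mrExtra"))

#' @rdname accessors
#' @export
setGeneric("globalP", function(x) standardGeneric("globalP"))

#' @rdname accessors
#' @export
setGeneric("outlierP", function(x) standardGeneric("outlierP"))

#' @rdname accessors
#' @export
setGeneric("flaggedSnps", function(x) standardGeneric("flaggedSnps"))

#' @rdname accessors
#' @export
setGeneric("trueTheta", function(x) standardGeneric("trueTheta"))

#' @rdname accessors
setMethod("variantIds", "SumStats", function(x) x$variant_id)

#' @rdname accessors
setMethod("variantIds", "HarmonizedInstruments", function(x) x$variant_id)

#' @rdname accessors
setMethod("indexSnps", "InstrumentSet", function(x) x@index_snps)

#' @rdname accessors
setMethod("fStats", "InstrumentSet",
          function(x) stats::setNames(x@f_stats, x@index_snps))

#' @rdname accessors
setMethod("mrBeta", "MREstimate", function(x) x@beta)

#' @rdname accessors
setMethod("mrSE", "MREstimate", function(x) x@se)

#' @rdname accessors
setMethod("mrCI", "MREstimate", function(x) c(x@ci_low, x@ci_high))

#' @rdname accessors
setMethod("mrPval", "MREstimate", function(x) x@pval)

#' @rdname accessors
setMethod("nSnps", "MREstimate", function(x) x@n_snps)

#' @rdname accessors
setMethod("nSnps", "HarmonizedInstruments", function(x) nrow(x))

#' @rdname accessors
setMethod("nSnps", "InstrumentSet", function(x) length(x@index_snps))

#' @rdname accessors
setMethod("oddsRatio", "MREstimate", function(x) exp(x@beta))

#' @rdname accessors
setMethod("oddsRatioCI", "MREstimate", function(x) exp(c(x@ci_low, x@ci_high)))

#' @rdname accessors
setMethod("mrMethod", "MREstimate", function(x) x@method)

#' @rdname accessors
setMethod("mrExtra", "MREstimate", function(x) x@extra)

#' @rdname accessors
setMethod("globalP", "PressoResult", function(x) x@global_p)

#' @rdname accessors
setMethod("outlierP", "PressoResult", function(x) x@outlier_p)

#' @rdname accessors
setMethod("flaggedSnps", "PressoResult", function(x) x@flagged)

#' @rdname accessors
setMethod("trueTheta", "SimTruth", function(x) x@theta)

#' Provenance of a harmonization run
#'
#' @param x a \linkS4class{HarmonizedInstruments} object
#' @return A list with counts \code{kept}, \code{flipped}, \code{dropped}
#'   and the dropped variant ids.
#' @export
harmonizationProvenance <- function(x) {
    stopifnot(is(x, "HarmonizedInstruments"))
    metadata(x)$provenance
}

setMethod("show", "MREstimate", function(object) {
    ci <- sprintf("[%.4g, %.4g]", object@ci_low, object@ci_high)
    orci <- sprintf("[%.4g, %.4g]", exp(object@ci_low), exp(object@ci_high))
    cat(sprintf("MREstimate: %s (%d SNPs)\n", object@method, object@n_snps))
    cat(sprintf("  beta = %.4g (se %.4g), 95%% CI %s, p = %.3g\n",
                object@beta, object@se, ci, object@pval))
    cat(sprintf("  OR   = %.4g, 95%% CI %s\n", exp(object@beta), orci))
    if (length(object@extra)) {
        lab <- vapply(names(object@extra),
                      function(k) sprintf("%s = %.4g", k,
                                          as.numeric(object@extra[[k]])[1]),
                      character(1))
        cat("  extra:", paste(lab, collapse = ", "), "\n")
    }
})

setMethod("show", "InstrumentSet", function(object) {
    cat(sprintf("InstrumentSet: %d index SNPs", length(object@index_snps)))
    if (length(object@params))
        cat(sprintf(" (window %d kb, p1 %.3g, r2 %.3g)",
                    object@params$window_kb, object@params$p1,
                    object@params$r2_max))
    cat("\n")
    if (length(object@index_snps)) {
        k <- min(5L, length(object@index_snps))
        cat("  head:", paste(object@index_snps[seq_len(k)], collapse = ", "),
            if (length(object@index_snps) > k) "..." else "", "\n")
    }
})

setMethod("show", "PressoResult", function(object) {
    cat(sprintf("PressoResult: RSS_obs = %.4g, global p = %.4g (%d simulations, seed %d)\n",
                object@rss_obs, object@global_p, object@n_sim, object@seed))
    if (length(object@outlier_p) && !all(is.na(object@outlier_p)))
        cat(sprintf("  outlier test: %d flagged of %d (uncorrected p < 0.05)\n",
                    length(object@flagged), length(object@outlier_p)))
    else
        cat("  outlier test: not run\n")
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport:\n")
    cat(sprintf("  input:                 %d\n", object@n_input))
    cat(sprintf("  removed (MAF):         %d\n", object@n_removed_maf))
    cat(sprintf("  removed (nonbiallelic):%d\n", object@n_removed_nonbiallelic))
    cat(sprintf("  removed (ambiguous):   %d\n", object@n_removed_ambiguous))
    cat(sprintf("  removed (INFO):        %d\n", object@n_removed_info))
    cat(sprintf("  output:                %d\n", object@n_output))
})

setMethod("show", "SimTruth", function(object) {
    n_instr <- sum(object@gamma != 0)
    cat(sprintf("SimTruth: %d variants, %d instruments, theta = %.4g, seed %d\n",
                length(object@gamma), n_instr, object@theta, object@seed))
    cat(sprintf("  pleiotropy: %s, prop_invalid = %.2f; n_exp = %g, n_out = %g (case fraction %.2f)\n",
                object@pleiotropy_mode, object@prop_invalid, object@n_exp,
                object@n_out, object@case_frac))
})

setMethod("show", "LeaveOneOutResult", function(object) {
    cat(sprintf("LeaveOneOutResult: %d exclusions\n", length(object@estimates)))
    cat("  overall: "); show(object@overall)
})
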