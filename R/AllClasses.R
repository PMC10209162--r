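#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.VALID_ALLELES <- c("A", "C", "G", "T")

.SUMSTATS_REQUIRED <- c("variant_id", "chrom", "pos", "effect_allele",
                        "other_allele", "eaf", "beta", "se", "pval")

#' GWAS summary-statistics table
#'
#' A \linkS4class{DataFrame} subclass holding one GWAS's per-variant
#' association records with canonical column names: \code{variant_id},
#' \code{chrom}, \code{pos} (1-based bp), \code{effect_allele},
#' \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#' and optionally \code{info} and \code{n}. For case-control GWAS,
#' \code{beta} is on the log-odds scale.
#'
#' @aliases SumStats-class
#' @exportClass SumStats
setClass("SumStats", contains = "DFrame")

setValidity("SumStats", function(object) {
    msg <- character()
    missing_cols <- setdiff(.SUMSTATS_REQUIRED, colnames(object))
    if (length(missing_cols))
        return(paste("missing required column(s):",
                     paste(missing_cols, collapse = ", ")))
    if (anyDuplicated(object$variant_id))
        msg <- c(msg, "variant_id must be unique within a table")
    if (any(object$effect_allele == object$other_allele))
        msg <- c(msg, "effect_allele must differ from other_allele")
    bad_allele <- !(object$effect_allele %in% .VALID_ALLELES) |
        !(object$other_allele %in% .VALID_ALLELES)
    if (any(bad_allele))
        msg <- c(msg, "alleles must be single bases A/C/G/T")
    if (any(!is.na(object$se) & object$se <= 0))
        msg <- c(msg, "se must be > 0")
    if (any(!is.na(object$pval) & (object$pval <= 0 | object$pval > 1)))
        msg <- c(msg, "pval must lie in (0, 1]")
    if (any(!is.na(object$eaf) & (object$eaf < 0 | object$eaf > 1)))
        msg <- c(msg, "eaf must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a SumStats object from a data.frame
#'
#' @param df data.frame (or DataFrame) with the canonical columns; alleles
#'   are upper-cased. Extra columns are retained.
#' @return A \linkS4class{SumStats} object.
#' @export
SumStats <- function(df) {
    df <- as(as.data.frame(df), "DataFrame")
    for (col in c("effect_allele", "other_allele"))
        if (col %in% colnames(df)) df[[col]] <- toupper(as.character(df[[col]]))
    if ("chrom" %in% colnames(df)) df[["chrom"]] <- as.character(df[["chrom"]])
    new("SumStats", df)
}

# Column replacement on DataFrame subclasses: S4Vectors' default [[<- for
# derived classes tries to re-wrap the value in the subclass; delegate to the
# parent and revalidate instead.
.replaceColumn <- function(x, i, value) {
    cls <- class(x)
    y <- as(x, "DFrame")
    y[[i]] <- value
    out <- new(cls, y)
    metadata(out) <- metadata(x)
    out
}

#' @export
setReplaceMethod("[[", "SumStats",
                 function(x, i, j, ..., value) .replaceColumn(x, i, value))

#' @export
setReplaceMethod("$", "SumStats",
                 function(x, name, value) .replaceColumn(x, name, value))

#' Quality-control attrition report
#'
#' Counts of variants removed by each QC filter, attributed to the first
#' filter that removes them, in the order MAF, biallelic, ambiguous
#' (A/T, C/G), INFO.
#'
#' @aliases QCReport-class
#' @exportClass QCReport
setClass("QCReport",
         representation(n_input = "integer", n_removed_maf = "integer",
                        n_removed_nonbiallelic = "integer",
                        n_removed_ambiguous = "integer",
                        n_removed_info = "integer", n_output = "integer"))

setValidity("QCReport", function(object) {
    removed <- object@n_removed_maf + object@n_removed_nonbiallelic +
        object@n_removed_ambiguous + object@n_removed_info
    if (object@n_output != object@n_input - removed)
        "n_output must equal n_input minus the sum of removals"
    else TRUE
})

#' Pairwise LD reference
#'
#' Squared-correlation lookup among variants, plus their genomic positions.
#' Pairs absent from the table (but both variants present, on the same
#' chromosome, within a query window) are treated as r-squared 0; pairs on
#' different chromosomes are always 0.
#'
#' @slot pairs data.frame with columns \code{id1}, \code{id2}, \code{r2}.
#' @slot positions data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}.
#' @aliases LDReference-class
#' @exportClass LDReference
setClass("LDReference",
         representation(pairs = "data.frame", positions = "data.frame"))

setValidity("LDReference", function(object) {
    msg <- character()
    if (!all(c("id1", "id2", "r2") %in% colnames(object@pairs)))
        msg <- c(msg, "pairs needs columns id1, id2, r2")
    else if (any(object@pairs$r2 < 0 | object@pairs$r2 > 1))
        msg <- c(msg, "r2 must lie in [0, 1]")
    if (!all(c("variant_id", "chrom", "pos") %in% colnames(object@positions)))
        msg <- c(msg, "positions needs columns variant_id, chrom, pos")
    else if (anyDuplicated(object@positions$variant_id))
        msg <- c(msg, "positions variant_id must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct an LDReference
#'
#' @param pairs data.frame (id1, id2, r2), long format; symmetry is implied
#'   and self-pairs are ignored (r2(v, v) is 1 by definition).
#' @param positions data.frame (variant_id, chrom, pos).
#' @return An \linkS4class{LDReference} object.
#' @export
LDReference <- function(pairs, positions) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    positions <- as.data.frame(positions, stringsAsFactors = FALSE)
    pairs$id1 <- as.character(pairs$id1)
    pairs$id2 <- as.character(pairs$id2)
    pairs <- pairs[pairs$id1 != pairs$id2, c("id1", "id2", "r2"), drop = FALSE]
    positions$variant_id <- as.character(positions$variant_id)
    positions$chrom <- as.character(positions$chrom)
    new("LDReference", pairs = pairs,
        positions = positions[, c("variant_id", "chrom", "pos")])
}

#' Selected instrumental SNPs
#'
#' Index SNPs from LD clumping, in selection order, with their clumping
#' p-values, F-statistics, and the number of neighbours each clump discarded.
#'
#' @aliases InstrumentSet-class
#' @exportClass InstrumentSet
setClass("InstrumentSet",
         representation(index_snps = "character", f_stats = "numeric",
                        pvals = "numeric", n_discarded = "integer",
                        params = "list"))

setValidity("InstrumentSet", function(object) {
    n <- length(object@index_snps)
    if (length(object@f_stats) != n || length(object@pvals) != n ||
        length(object@n_discarded) != n)
        "f_stats, pvals and n_discarded must parallel index_snps"
    else TRUE
})

#' Harmonized instrument effects
#'
#' A \linkS4class{DataFrame} subclass with one row per retained instrument:
#' \code{variant_id}, \code{beta_exp}, \code{se_exp}, \code{beta_out},
#' \code{se_out}, \code{effect_allele}, \code{other_allele}, all oriented to
#' the exposure's effect allele. \code{metadata()$provenance} records counts
#' of kept / flipped / dropped instruments.
#'
#' @aliases HarmonizedInstruments-class
#' @exportClass HarmonizedInstruments
setClass("HarmonizedInstruments", contains = "DFrame")

setValidity("HarmonizedInstruments", function(object) {
    req <- c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out",
             "effect_allele", "other_allele")
    missing_cols <- setdiff(req, colnames(object))
    if (length(missing_cols))
        return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
    msg <- character()
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pal <- object$other_allele == unname(comp[object$effect_allele])
    if (any(pal, na.rm = TRUE))
        msg <- c(msg, "palindromic (A/T, C/G) pairs must be removed upstream")
    if (any(object$se_exp <= 0) || any(object$se_out <= 0))
        msg <- c(msg, "standard errors must be > 0")
    if (length(msg)) msg else TRUE
})

#' Causal-effect estimate
#'
#' One estimator's result: the causal effect \code{beta} (log-odds of outcome
#' per SD of exposure for a binary outcome), its standard error, 95\% CI,
#' two-sided p-value, instrument count, and method-specific extras (Egger
#' intercept and its p; Cochran's Q and heterogeneity p).
#'
#' @aliases MREstimate-class
#' @exportClass MREstimate
setClass("MREstimate",
         representation(method = "character", beta = "numeric", se = "numeric",
                        ci_low = "numeric", ci_high = "numeric",
                        pval = "numeric", n_snps = "integer", extra = "list"))

setValidity("MREstimate", function(object) {
    msg <- character()
    if (!is.na(object@ci_low) && !is.na(object@ci_high) &&
        object@ci_low >= object@ci_high)
        msg <- c(msg, "ci_low must be < ci_high")
    if (!is.na(object@pval) && (object@pval <= 0 || object@pval > 1))
        msg <- c(msg, "pval must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Leave-one-out diagnostics
#'
#' IVW estimates recomputed after excluding each instrument in turn, plus the
#' overall estimate on the full set.
#'
#' @aliases LeaveOneOutResult-class
#' @exportClass LeaveOneOutResult
setClass("LeaveOneOutResult",
         representation(estimates = "list", overall = "MREstimate"))

#' MR-PRESSO test result
#'
#' Observed residual sum of squares, the Monte-Carlo global p-value, per-SNP
#' outlier p-values (filled by \code{\link{pressoOutlier}}), flagged variants,
#' and the stored simulated residuals needed for the outlier test.
#'
#' @aliases PressoResult-class
#' @exportClass PressoResult
setClass("PressoResult",
         representation(rss_obs = "numeric", global_p = "numeric",
                        outlier_p = "numeric", flagged = "character",
                        n_sim = "integer", seed = "integer",
                        obs_resid = "numeric", sim_resid = "matrix"))

setValidity("PressoResult", function(object) {
    lower <- 1 / (object@n_sim + 1)
    if (object@global_p < lower - 1e-12 || object@global_p > 1)
        "global_p must lie in [1/(n_sim+1), 1]"
    else if (!all(object@flagged %in% names(object@obs_resid)))
        "flagged must be a subset of the instrument ids"
    else TRUE
})

#' Ground truth of a simulated two-sample MR study
#'
#' Parameters and realized per-variant truth emitted by the synthetic
#' summary-statistics generator, for recovery tests: the true causal effect
#' \code{theta} (log-odds per SD exposure), per-variant instrument effects
#' \code{gamma}, pleiotropic effects \code{alpha}, the LD block partition,
#' and the two samples' effective sizes.
#'
#' @aliases SimTruth-class
#' @exportClass SimTruth
setClass("SimTruth",
         representation(theta = "numeric", theta_rev = "numeric",
                        gamma = "numeric", alpha = "numeric",
                        delta = "numeric",
                        prop_invalid = "numeric", pleiotropy_mode = "character",
                        ld_blocks = "list", n_exp = "numeric", n_out = "numeric",
                        case_frac = "numeric", eaf = "numeric",
                        prop_swap = "numeric", prop_flip = "numeric",
                        positions = "data.frame", alleles = "data.frame",
                        r2_within = "numeric", seed = "integer"))

setValidity("SimTruth", function(object) {
    msg <- character()
    n <- length(object@gamma)
    if (length(object@alpha) != n || length(object@eaf) != n ||
        length(object@delta) != n)
        msg <- c(msg, "gamma, alpha, delta and eaf must have equal length")
    if (!object@pleiotropy_mode %in% c("balanced", "directional"))
        msg <- c(msg, "pleiotropy_mode must be 'balanced' or 'directional'")
    if (object@prop_invalid < 0 || object@prop_invalid > 1)
        msg <- c(msg, "prop_invalid must lie in [0, 1]")
    if (object@pleiotropy_mode == "balanced") {
        inv <- object@alpha[object@alpha != 0]
        if (length(inv) && abs(mean(inv)) > 1e-10)
            msg <- c(msg, "balanced mode requires mean pleiotropy 0 among invalid instruments")
    }
    if (length(msg)) msg else TRUE
})
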