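#' Analysis configuration
#'
#' Bundles every tunable of the bidirectional analysis: clumping parameters,
#' the instrument p-value thresholds (primary 1e-6; stringent genome-wide
#' 5e-8 for sensitivity), the estimator set, the weak-instrument threshold,
#' MR-PRESSO settings, the IVW variant, and the seed that drives every
#' stochastic stage.
#'
#' @param clump list from \code{\link{clumpParams}}.
#' @param p_thresholds instrument significance thresholds; the first is the
#'   primary analysis threshold.
#' @param methods estimator labels among \code{"ivw"}, \code{"egger"},
#'   \code{"weighted_median"}, \code{"raps"}.
#' @param f_min weak-instrument F threshold (strict).
#' @param presso list: \code{n_sim}, \code{alpha}, \code{correction}.
#' @param re_mode IVW variant for the primary analysis.
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed integer seed.
#' @return A validated configuration list.
#' @export
analysisConfig <- function(clump = clumpParams(),
                           p_thresholds = c(1e-6, 5e-8),
                           methods = c("ivw", "egger", "weighted_median",
                                       "raps"),
                           f_min = 10,
                           presso = list(n_sim = 1000, alpha = 0.05,
                                         correction = "none"),
                           re_mode = "multiplicative",
                           n_boot = 1000, seed) {
    if (missing(seed)) stop("seed is required")
    stopifnot(all(p_thresholds > 0), all(p_thresholds < 1),
              length(p_thresholds) >= 1,
              all(methods %in% c("ivw", "egger", "weighted_median", "raps")))
    list(clump = clump, p_thresholds = p_thresholds, methods = methods,
         f_min = f_min, presso = presso, re_mode = re_mode, n_boot = n_boot,
         seed = as.integer(seed))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction across the tested
#' outcomes, returned in input order (delegates to
#' \code{stats::p.adjust(method = "BH")}).
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, capped at 1.
#' @export
fdrAdjust <- function(pvals) {
    stopifnot(all(pvals > 0 & pvals <= 1, na.rm = TRUE))
    stats::p.adjust(pvals, method = "BH")
}

# one exposure-outcome analysis at one threshold; returns estimate pieces
# plus the attrition trail. flag_ids, when non-NULL, are removed from the
# harmonized set before estimation (PRESSO trimming decided elsewhere).
.analyzePair <- function(exposure, outcome, ld, cfg, p1, seed,
                         run_presso = TRUE) {
    params <- cfg$clump
    params$p1 <- p1
    instr <- clumpInstruments(exposure, ld, params)
    attrition <- list(significant = sum(exposure$pval <= p1, na.rm = TRUE),
                      clumped = nSnps(instr))
    instr <- screenStrength(instr, exposure, cfg$f_min)
    attrition$f_screened <- nSnps(instr)
    h <- harmonizeInstruments(exposure, outcome, instr)
    attrition$harmonized <- nrow(h)

    presso_p <- NA_real_
    flagged <- character(0)
    if (run_presso && nrow(h) >= 4) {
        pg <- pressoGlobal(h, n_sim = cfg$presso$n_sim, seed = seed)
        presso_p <- globalP(pg)
        if (presso_p < cfg$presso$alpha) {
            po <- pressoOutlier(pg, h, alpha = cfg$presso$alpha,
                                correction = cfg$presso$correction)
            flagged <- flaggedSnps(po)
            if (length(flagged)) {
                h <- trimAndRefit(h, po)
                pg2 <- pressoGlobal(h, n_sim = cfg$presso$n_sim,
                                    seed = seed + 1L)
                message(sprintf(
                    "PRESSO: %d outlier(s) removed; global p %.3g -> %.3g",
                    length(flagged), presso_p, globalP(pg2)))
            }
        }
    }
    attrition$trimmed <- nrow(h)
    list(h = h, instr = instr, presso_p = presso_p, flagged = flagged,
         attrition = attrition)
}

.naRow <- function(label, reason, beta_scale) {
    row <- data.frame(outcome = label, NSNP = NA_integer_, beta = NA_real_,
                      se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      Het_p = NA_real_, presso_p = NA_real_, pval = NA_real_,
                      reason = reason, stringsAsFactors = FALSE)
    if (!beta_scale) {
        row$OR <- NA_real_; row$OR_low <- NA_real_; row$OR_high <- NA_real_
    }
    row
}

#' Run one causal direction across several outcomes
#'
#' For each outcome: clump instruments on the exposure's p-values at the
#' primary threshold, screen for strength, harmonize, run the MR-PRESSO
#' global test (trimming flagged outliers when the global test is
#' significant), estimate the causal effect by IVW, and report Cochran
#' heterogeneity. Benjamini-Hochberg adjustment is applied across the
#' direction's IVW p-values (the outcomes form one testing family).
#'
#' @param exposure the exposure \linkS4class{SumStats} (QC'd, intersected).
#' @param outcomes named list of outcome \linkS4class{SumStats}.
#' @param ld an \linkS4class{LDReference} for the exposure's variants.
#' @param cfg configuration from \code{\link{analysisConfig}}.
#' @param beta_scale report on the beta scale instead of odds ratios (used
#'   for the reverse direction, where the outcome is a quantitative trait).
#' @return data.frame with one row per outcome: NSNP, estimate, 95\% CI,
#'   Het_p, MR-PRESSO global p, pval, padj (plus OR columns unless
#'   \code{beta_scale}); failed outcomes carry NA estimates and a reason.
#'   The per-outcome attrition trail is in \code{attr(, "attrition")}.
#' @export
runDirection <- function(exposure, outcomes, ld, cfg, beta_scale = FALSE) {
    stopifnot(is.list(outcomes), length(outcomes) >= 1)
    if (is.null(names(outcomes)))
        names(outcomes) <- paste0("outcome", seq_along(outcomes))
    rows <- list()
    attritions <- list()
    for (k in seq_along(outcomes)) {
        label <- names(outcomes)[k]
        seed_k <- cfg$seed + 13L * k
        res <- tryCatch(
            .analyzePair(exposure, outcomes[[k]], ld, cfg,
                         p1 = cfg$p_thresholds[1], seed = seed_k),
            error = function(e) e)
        if (inherits(res, "error")) {
            message("outcome '", label, "' failed: ", conditionMessage(res))
            rows[[k]] <- .naRow(label, conditionMessage(res), beta_scale)
            next
        }
        attritions[[label]] <- res$attrition
        est <- tryCatch(mrIVW(res$h, re_mode = cfg$re_mode),
                        error = function(e) e)
        if (inherits(est, "error")) {
            message("outcome '", label, "' failed: ", conditionMessage(est))
            row <- .naRow(label, conditionMessage(est), beta_scale)
            row$NSNP <- nrow(res$h)
            rows[[k]] <- row
            next
        }
        row <- data.frame(outcome = label, NSNP = nSnps(est),
                          beta = mrBeta(est), se = mrSE(est),
                          ci_low = mrCI(est)[1], ci_high = mrCI(est)[2],
                          Het_p = mrExtra(est)$het_p,
                          presso_p = res$presso_p, pval = mrPval(est),
                          reason = NA_character_, stringsAsFactors = FALSE)
        if (!beta_scale) {
            row$OR <- oddsRatio(est)
            row$OR_low <- oddsRatioCI(est)[1]
            row$OR_high <- oddsRatioCI(est)[2]
        }
        rows[[k]] <- row
    }
    report <- do.call(rbind, rows)
    report$padj <- NA_real_
    ok <- !is.na(report$pval)
    report$padj[ok] <- fdrAdjust(report$pval[ok])
    attr(report, "attrition") <- attritions
    rownames(report) <- NULL
    report
}

#' Bidirectional two-sample MR
#'
#' Forward: the biomarker exposure against each disorder outcome, reported
#' as odds ratios. Reverse: each disorder as the exposure (instruments
#' clumped on the disorder's own p-values; betas are log-odds of liability)
#' against the biomarker, reported on the beta scale (SD units of the
#' biomarker per unit log-odds). The two directions form separate
#' Benjamini-Hochberg families.
#'
#' @param exposure the biomarker \linkS4class{SumStats}.
#' @param outcomes named list of disorder \linkS4class{SumStats}.
#' @param ld an \linkS4class{LDReference} covering all tables' variants.
#' @param cfg configuration from \code{\link{analysisConfig}}.
#' @return A list with data.frames \code{forward} and \code{reverse}.
#' @export
runBidirectional <- function(exposure, outcomes, ld, cfg) {
    forward <- runDirection(exposure, outcomes, ld, cfg, beta_scale = FALSE)
    rev_rows <- list()
    for (k in seq_along(outcomes)) {
        label <- names(outcomes)[k]
        cfg_k <- cfg
        cfg_k$seed <- cfg$seed + 1000L + 13L * k
        rev_rows[[k]] <- runDirection(outcomes[[k]],
                                      stats::setNames(list(exposure), label),
                                      ld, cfg_k, beta_scale = TRUE)
    }
    reverse <- do.call(rbind, rev_rows)
    ok <- !is.na(reverse$pval)
    reverse$padj <- NA_real_
    reverse$padj[ok] <- fdrAdjust(reverse$pval[ok])
    rownames(reverse) <- NULL
    list(forward = forward, reverse = reverse)
}

.fitMethod <- function(method, h, cfg, seed) {
    switch(method,
           ivw = mrIVW(h, re_mode = cfg$re_mode),
           egger = mrEgger(h),
           weighted_median = mrWeightedMedian(h, n_boot = cfg$n_boot,
                                              seed = seed),
           raps = mrRAPS(h),
           stop("unknown method: ", method))
}

#' Sensitivity grid across thresholds, methods and directions
#'
#' The full cross of instrument p-value threshold, estimator and causal
#' direction for every exposure-outcome pair. Outliers flagged by MR-PRESSO
#' at the primary threshold are removed from the instrument set at every
#' threshold (trimming decisions are not re-made per cell). Cells failing
#' minimum-instrument requirements yield NA rows with the reason recorded.
#'
#' @inheritParams runBidirectional
#' @return data.frame with one row per (direction, outcome, threshold,
#'   method) cell.
#' @export
sensitivityGrid <- function(exposure, outcomes, ld, cfg) {
    grid_rows <- list()
    i <- 0L
    for (direction in c("forward", "reverse")) {
        for (k in seq_along(outcomes)) {
            label <- names(outcomes)[k]
            exp_tab <- if (direction == "forward") exposure else outcomes[[k]]
            out_tab <- if (direction == "forward") outcomes[[k]] else exposure
            seed_k <- cfg$seed + 17L * k +
                if (direction == "reverse") 5000L else 0L
            # PRESSO flags at the primary threshold, reused at every threshold
            primary <- tryCatch(
                .analyzePair(exp_tab, out_tab, ld, cfg,
                             p1 = cfg$p_thresholds[1], seed = seed_k),
                error = function(e) e)
            flagged <- if (inherits(primary, "error")) character(0)
                       else primary$flagged
            for (p1 in cfg$p_thresholds) {
                res <- tryCatch(
                    .analyzePair(exp_tab, out_tab, ld, cfg, p1 = p1,
                                 seed = seed_k, run_presso = FALSE),
                    error = function(e) e)
                for (method in cfg$methods) {
                    i <- i + 1L
                    if (inherits(res, "error")) {
                        grid_rows[[i]] <- data.frame(
                            direction = direction, outcome = label,
                            threshold = p1, method = method,
                            n_snps = NA_integer_, beta = NA_real_,
                            se = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, pval = NA_real_,
                            reason = conditionMessage(res),
                            stringsAsFactors = FALSE)
                        next
                    }
                    h <- res$h
                    if (length(flagged))
                        h <- h[!(h$variant_id %in% flagged), ]
                    est <- tryCatch(.fitMethod(method, h, cfg, seed_k + i),
                                    error = function(e) e)
                    grid_rows[[i]] <- if (inherits(est, "error"))
                        data.frame(direction = direction, outcome = label,
                                   threshold = p1, method = method,
                                   n_snps = nrow(h), beta = NA_real_,
                                   se = NA_real_, ci_low = NA_real_,
                                   ci_high = NA_real_, pval = NA_real_,
                                   reason = conditionMessage(est),
                                   stringsAsFactors = FALSE)
                    else
                        data.frame(direction = direction, outcome = label,
                                   threshold = p1, method = method,
                                   n_snps = nSnps(est), beta = mrBeta(est),
                                   se = mrSE(est), ci_low = mrCI(est)[1],
                                   ci_high = mrCI(est)[2],
                                   pval = mrPval(est),
                                   reason = NA_character_,
                                   stringsAsFactors = FALSE)
                }
            }
        }
    }
    out <- do.call(rbind, grid_rows)
    rownames(out) <- NULL
    out
}

#' Cross-cohort effect concordance
#'
#' Restricts to variants significant in table \code{a} (p below
#' \code{sig_p}), aligns table \code{b}'s effects to \code{a}'s effect
#' alleles, and reports how many such variants are shared and the fraction
#' whose effects agree in sign — the summary behind a cross-cohort
#' comparison of association strengths for the same trait measured in two
#' samples.
#'
#' @param a,b two \linkS4class{SumStats} tables for the same trait.
#' @param sig_p significance threshold applied to \code{a}.
#' @return A list: \code{n_shared_significant} and
#'   \code{sign_agreement_fraction} (NA when nothing is significant).
#' @export
effectConcordance <- function(a, b, sig_p = 1e-6) {
    stopifnot(is(a, "SumStats"), is(b, "SumStats"))
    sig_ids <- a$variant_id[!is.na(a$pval) & a$pval < sig_p]
    h <- harmonizeInstruments(a, b, sig_ids)
    if (nrow(h) == 0)
        return(list(n_shared_significant = 0L,
                    sign_agreement_fraction = NA_real_))
    agree <- sign(h$beta_exp) == sign(h$beta_out)
    list(n_shared_significant = nrow(h),
         sign_agreement_fraction = mean(agree))
}

#' Write a Table-1-style report
#'
#' @param report data.frame from \code{\link{runDirection}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
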