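#' Clumping parameters
#'
#' Defaults follow standard PLINK-style clumping of sub-genome-wide
#' instruments: a 10,000 kb window, index p-value threshold 1e-6, and LD
#' pruning at r-squared 0.05.
#'
#' @param window_kb window half-width in kilobases around each index SNP.
#' @param p1 index significance threshold.
#' @param r2_max LD threshold; neighbours with r-squared at or above this are
#'   assigned to the index SNP's clump and discarded.
#' @return A list with components \code{window_kb}, \code{p1}, \code{r2_max}.
#' @export
clumpParams <- function(window_kb = 10000L, p1 = 1e-6, r2_max = 0.05) {
    stopifnot(window_kb > 0, p1 > 0, p1 <= 1, r2_max >= 0, r2_max <= 1)
    list(window_kb = as.integer(window_kb), p1 = p1, r2_max = r2_max)
}

#' Pairwise r-squared lookup
#'
#' Vectorized lookup of squared correlations in an \linkS4class{LDReference}.
#' Self-pairs return 1; pairs absent from the reference return 0 (unlinked),
#' as do pairs on different chromosomes.
#'
#' @param ld an \linkS4class{LDReference}.
#' @param id1,id2 character vectors of variant ids (recycled to a common
#'   length).
#' @return Numeric vector of r-squared values.
#' @export
ldR2 <- function(ld, id1, id2) {
    stopifnot(is(ld, "LDReference"))
    .ldLookup(.ldMap(ld), id1, id2)
}

.ldMap <- function(ld) {
    p <- ld@pairs
    stats::setNames(p$r2, paste(pmin(p$id1, p$id2),
                                pmax(p$id1, p$id2), sep = "\r"))
}

.ldLookup <- function(map, id1, id2) {
    n <- max(length(id1), length(id2))
    id1 <- rep_len(as.character(id1), n)
    id2 <- rep_len(as.character(id2), n)
    out <- unname(map[paste(pmin(id1, id2), pmax(id1, id2), sep = "\r")])
    out[is.na(out)] <- 0
    out[id1 == id2] <- 1
    out
}

#' Single-SNP F-statistic
#'
#' Instrument-strength measure from summary data: \eqn{F = (\beta/se)^2}.
#' The conventional weak-instrument cutoff is F > 10.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), all strictly positive.
#' @return Numeric vector of F-statistics.
#' @export
fStatistic <- function(beta, se) {
    if (any(se <= 0)) stop("se must be > 0")
    (beta / se)^2
}

#' Greedy LD clumping of significant variants
#'
#' Restricts the table to variants with \code{pval <= p1}, then repeatedly
#' selects the smallest-p unclaimed variant as an index SNP and discards all
#' unclaimed variants on the same chromosome within \code{window_kb} of it
#' whose r-squared with it is at least \code{r2_max}. Ties in p are broken by
#' (chrom, pos, variant_id). The result is independent of input row order.
#'
#' @param tab a QC-filtered \linkS4class{SumStats} object.
#' @param ld an \linkS4class{LDReference} whose positions cover every
#'   significant variant (a missing variant is a hard error: silently
#'   including it would fake independence).
#' @param params a list from \code{\link{clumpParams}}.
#' @return An \linkS4class{InstrumentSet} with index SNPs in selection order,
#'   their p-values, F-statistics, and per-clump discard counts.
#' @export
clumpInstruments <- function(tab, ld, params = clumpParams()) {
    stopifnot(is(tab, "SumStats"), is(ld, "LDReference"))
    sig <- as.data.frame(tab[!is.na(tab$pval) & tab$pval <= params$p1, ])
    if (nrow(sig) == 0)
        return(new("InstrumentSet", index_snps = character(0),
                   f_stats = numeric(0), pvals = numeric(0),
                   n_discarded = integer(0), params = params))
    missing_ids <- setdiff(sig$variant_id, ld@positions$variant_id)
    if (length(missing_ids))
        stop("significant variant(s) missing from the LD reference: ",
             paste(missing_ids, collapse = ", "))
    hit <- match(sig$variant_id, ld@positions$variant_id)
    sig$ld_chrom <- ld@positions$chrom[hit]
    sig$ld_pos <- ld@positions$pos[hit]
    ord <- order(sig$pval, sig$ld_chrom, sig$ld_pos, sig$variant_id)
    sig <- sig[ord, ]

    window_bp <- params$window_kb * 1000
    ld_map <- .ldMap(ld)
    claimed <- rep(FALSE, nrow(sig))
    idx_sel <- integer(0)
    n_disc <- integer(0)
    for (i in seq_len(nrow(sig))) {
        if (claimed[i]) next
        claimed[i] <- TRUE
        near <- which(!claimed & sig$ld_chrom == sig$ld_chrom[i] &
                          abs(sig$ld_pos - sig$ld_pos[i]) <= window_bp)
        if (length(near)) {
            r2 <- .ldLookup(ld_map, sig$variant_id[i], sig$variant_id[near])
            drop <- near[r2 >= params$r2_max]
            claimed[drop] <- TRUE
            n_disc <- c(n_disc, length(drop))
        } else {
            n_disc <- c(n_disc, 0L)
        }
        idx_sel <- c(idx_sel, i)
    }
    new("InstrumentSet",
        index_snps = sig$variant_id[idx_sel],
        f_stats = fStatistic(sig$beta[idx_sel], sig$se[idx_sel]),
        pvals = sig$pval[idx_sel],
        n_discarded = as.integer(n_disc),
        params = params)
}

#' Screen instruments for strength
#'
#' Retains index SNPs whose F-statistic in \code{tab} is strictly greater
#' than \code{f_min} (an instrument with F exactly at the threshold is
#' removed).
#'
#' @param instr an \linkS4class{InstrumentSet}.
#' @param tab the exposure \linkS4class{SumStats} containing every index SNP.
#' @param f_min weak-instrument threshold (default 10).
#' @return The filtered \linkS4class{InstrumentSet}.
#' @export
screenStrength <- function(instr, tab, f_min = 10) {
    stopifnot(is(instr, "InstrumentSet"), is(tab, "SumStats"))
    hit <- match(instr@index_snps, tab$variant_id)
    if (anyNA(hit))
        stop("index SNP(s) absent from the table: ",
             paste(instr@index_snps[is.na(hit)], collapse = ", "))
    f <- fStatistic(tab$beta[hit], tab$se[hit])
    keep <- f > f_min
    new("InstrumentSet",
        index_snps = instr@index_snps[keep],
        f_stats = f[keep],
        pvals = instr@pvals[keep],
        n_discarded = instr@n_discarded[keep],
        params = instr@params)
}

#' Write an InstrumentSet as a text table
#'
#' Mirrors the spirit of PLINK's .clumped output: one row per index SNP with
#' its p-value, F-statistic and the number of neighbours its clump discarded.
#'
#' @param instr an \linkS4class{InstrumentSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeInstruments <- function(instr, path) {
    stopifnot(is(instr, "InstrumentSet"))
    df <- data.frame(SNP = instr@index_snps, P = instr@pvals,
                     F = instr@f_stats, N_DISCARDED = instr@n_discarded)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
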