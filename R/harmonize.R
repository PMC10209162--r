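.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Align exposure and outcome effects to a shared effect allele
#'
#' For each instrument, the exposure's allele coding is the reference. If the
#' outcome reports the same allele pair in the same order, its effect is kept
#' as-is; if the pair is swapped (effect and other exchanged), the outcome
#' beta is negated and its effect-allele frequency reflected (eaf to 1-eaf);
#' if the outcome pair matches only after complementing both outcome alleles
#' (a strand flip), the same keep/swap logic applies on the complemented
#' pair. An instrument whose allele pairs cannot be reconciled even after
#' complementing, or that is missing from either table, is dropped and
#' counted. Strand-flip resolution is unambiguous only because palindromic
#' A/T and C/G variants are removed during QC; any that slip through are
#' dropped here.
#'
#' @param exposure the exposure \linkS4class{SumStats}.
#' @param outcome the outcome \linkS4class{SumStats}.
#' @param instr an \linkS4class{InstrumentSet} (or character vector of
#'   variant ids) naming the instruments to align.
#' @return A \linkS4class{HarmonizedInstruments} object;
#'   \code{\link{harmonizationProvenance}} returns the kept/flipped/dropped
#'   counts and dropped ids.
#' @export
harmonizeInstruments <- function(exposure, outcome, instr) {
    stopifnot(is(exposure, "SumStats"), is(outcome, "SumStats"))
    ids <- if (is(instr, "InstrumentSet")) indexSnps(instr)
           else as.character(instr)
    n_in <- length(ids)
    e_hit <- match(ids, exposure$variant_id)
    o_hit <- match(ids, outcome$variant_id)
    present <- !is.na(e_hit) & !is.na(o_hit)
    dropped_ids <- ids[!present]
    ids <- ids[present]
    e <- as.data.frame(exposure[e_hit[present], ])
    o <- as.data.frame(outcome[o_hit[present], ])

    pal <- e$other_allele == unname(.COMPLEMENT[e$effect_allele])
    same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
    swapped <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
    o_ea_c <- unname(.COMPLEMENT[o$effect_allele])
    o_oa_c <- unname(.COMPLEMENT[o$other_allele])
    flip_same <- o_ea_c == e$effect_allele & o_oa_c == e$other_allele
    flip_swapped <- o_ea_c == e$other_allele & o_oa_c == e$effect_allele

    keep_asis <- !pal & (same | flip_same)
    keep_neg <- !pal & !keep_asis & (swapped | flip_swapped)
    drop <- !(keep_asis | keep_neg)

    beta_out <- ifelse(keep_neg, -o$beta, o$beta)
    eaf_out <- if ("eaf" %in% colnames(o)) ifelse(keep_neg, 1 - o$eaf, o$eaf)
               else rep(NA_real_, nrow(o))
    keep <- keep_asis | keep_neg
    dropped_ids <- c(dropped_ids, ids[drop])

    df <- DataFrame(variant_id = ids[keep],
                    beta_exp = e$beta[keep], se_exp = e$se[keep],
                    beta_out = beta_out[keep], se_out = o$se[keep],
                    eaf_exp = e$eaf[keep], eaf_out = eaf_out[keep],
                    effect_allele = e$effect_allele[keep],
                    other_allele = e$other_allele[keep])
    h <- new("HarmonizedInstruments", df)
    metadata(h)$provenance <- list(
        n_input = n_in,
        kept = sum(keep),
        flipped = sum(keep_neg),
        dropped = n_in - sum(keep),
        dropped_ids = dropped_ids)
    h
}

#' Construct HarmonizedInstruments directly from aligned effect estimates
#'
#' Convenience constructor for already-aligned per-instrument quadruples,
#' used by simulations and tests.
#'
#' @param variant_id,beta_exp,se_exp,beta_out,se_out parallel vectors.
#' @param effect_allele,other_allele optional allele annotation (defaults to
#'   a non-palindromic placeholder pair).
#' @return A \linkS4class{HarmonizedInstruments} object.
#' @export
HarmonizedInstruments <- function(variant_id, beta_exp, se_exp, beta_out,
                                  se_out, effect_allele = "A",
                                  other_allele = "G") {
    n <- length(variant_id)
    df <- DataFrame(variant_id = as.character(variant_id),
                    beta_exp = beta_exp, se_exp = se_exp,
                    beta_out = beta_out, se_out = se_out,
                    effect_allele = rep_len(effect_allele, n),
                    other_allele = rep_len(other_allele, n))
    h <- new("HarmonizedInstruments", df)
    metadata(h)$provenance <- list(n_input = n, kept = n, flipped = 0L,
                                   dropped = 0L, dropped_ids = character(0))
    h
}

#' @export
setReplaceMethod("[[", "HarmonizedInstruments",
                 function(x, i, j, ..., value) .replaceColumn(x, i, value))

#' @export
setReplaceMethod("$", "HarmonizedInstruments",
                 function(x, name, value) .replaceColumn(x, name, value))

#' Write harmonized instruments as tab-delimited text
#'
#' The canonical interchange format between pipeline stages.
#'
#' @param h a \linkS4class{HarmonizedInstruments} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHarmonized <- function(h, path) {
    stopifnot(is(h, "HarmonizedInstruments"))
    utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
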