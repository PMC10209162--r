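# non-palindromic ordered allele pairs (effect/other)
.ALLELE_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2, byrow = TRUE)

#' Ground truth for a synthetic two-sample MR study
#'
#' Draws the structural truth of a simulated study: an LD block partition,
#' per-variant effect-allele frequencies and allele codings, instrument
#' effects on the exposure, and pleiotropic effects on the outcome. Variants
#' are organized in blocks of \code{block_size} proxies sharing one causal
#' signal with within-block r-squared \code{r2_within}, so LD clumping is
#' meaningfully exercised; a proxy's marginal effect is the index effect
#' scaled by \code{sqrt(r2_within)}. A fraction \code{prop_invalid} of the
#' causal blocks carries horizontal pleiotropy: \code{"directional"} draws
#' alpha magnitudes from N(\code{alpha_mean}, \code{alpha_sd}) with a
#' consistent sign relative to the exposure-increasing allele (so the mean
#' pleiotropic effect is non-zero after instrument orientation, the
#' canonical InSIDE-satisfying directional model); \code{"balanced"} draws
#' magnitudes and pairs them antithetically (+a, -a) so the mean pleiotropic
#' effect among invalid instruments is exactly zero (an odd invalid count is
#' rounded down to even).
#'
#' Defaults emulate the scale of a neonatal-biomarker exposure GWAS
#' (n_exp = 8,138) against a large case-control outcome GWAS
#' (n_out = 480,000, case fraction 0.28), yielding on the order of 35
#' clumpable instruments at p below 1e-6.
#'
#' In addition to the exposure's instruments, a disjoint set of
#' \code{n_causal_out} blocks carries direct genetic effects \code{delta} on
#' the outcome (the disorder's own GWAS signal); these are the reverse
#' direction's instruments. A reverse causal effect \code{theta_rev}
#' (SD of exposure per unit log-odds liability) propagates them into the
#' exposure's marginal effects: the exposure mean is
#' \code{gamma + theta_rev * delta} and the outcome mean is
#' \code{theta * gamma + alpha + delta}.
#'
#' @param n_variants total variants (must be divisible into blocks).
#' @param n_causal number of causal blocks (instruments).
#' @param n_causal_out number of outcome-specific causal blocks.
#' @param theta true causal effect, log-odds of outcome per SD exposure.
#' @param theta_rev true reverse effect of the outcome on the exposure.
#' @param gamma_sd SD of instrument effects on the exposure (SD units).
#' @param delta_sd SD of direct genetic effects on the outcome (log-odds).
#' @param prop_invalid fraction of instruments with pleiotropy.
#' @param pleiotropy_mode \code{"balanced"} or \code{"directional"}.
#' @param alpha_mean,alpha_sd pleiotropic-effect distribution (log-odds).
#' @param block_size variants per LD block.
#' @param r2_within squared correlation among proxies within a block.
#' @param n_exp,n_out effective sample sizes of the two GWAS.
#' @param case_frac case fraction of the binary-outcome GWAS.
#' @param prop_swap fraction of outcome rows with exchanged allele coding.
#' @param prop_flip fraction of outcome rows reported on the other strand.
#' @param seed integer seed; the truth is reproducible from it.
#' @return A \linkS4class{SimTruth} object.
#' @export
simTruth <- function(n_variants = 600, n_causal = 60, n_causal_out = 30,
                     theta = 0, theta_rev = 0,
                     gamma_sd = 0.2, delta_sd = 0.05, prop_invalid = 0,
                     pleiotropy_mode = c("balanced", "directional"),
                     alpha_mean = 0.05, alpha_sd = 0.02,
                     block_size = 5, r2_within = 0.8,
                     n_exp = 8138, n_out = 480000, case_frac = 0.28,
                     prop_swap = 0.3, prop_flip = 0.2, seed) {
    if (missing(seed)) stop("seed is required")
    pleiotropy_mode <- match.arg(pleiotropy_mode)
    if (n_variants %% block_size != 0)
        stop("n_variants must be a multiple of block_size")
    n_blocks <- n_variants %/% block_size
    if (n_causal + n_causal_out > n_blocks)
        stop("n_causal + n_causal_out exceeds the number of LD blocks")
    stopifnot(prop_invalid >= 0, prop_invalid <= 1,
              case_frac > 0, case_frac < 1, r2_within >= 0, r2_within <= 1)

    old <- .switchSeed(seed)
    on.exit(.restoreSeed(old))

    ids <- sprintf("rs%06d", seq_len(n_variants))
    block_of <- rep(seq_len(n_blocks), each = block_size)
    chrom <- as.character(((seq_len(n_blocks) - 1) %% 22) + 1)[block_of]
    # blocks 1 Mb apart along each chromosome, proxies 1 kb apart
    block_on_chrom <- (seq_len(n_blocks) - 1) %/% 22
    pos <- 1e6 * block_on_chrom[block_of] + 1e3 * ((seq_len(n_variants) - 1) %%
                                                       block_size) + 1
    positions <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                            block = block_of, stringsAsFactors = FALSE)

    eaf <- stats::runif(n_variants, 0.05, 0.5)
    pair_idx <- sample.int(nrow(.ALLELE_PAIRS), n_variants, replace = TRUE)
    alleles <- data.frame(variant_id = ids,
                          effect_allele = .ALLELE_PAIRS[pair_idx, 1],
                          other_allele = .ALLELE_PAIRS[pair_idx, 2],
                          stringsAsFactors = FALSE)

    picked <- sample.int(n_blocks, n_causal + n_causal_out)
    causal_blocks <- sort(picked[seq_len(n_causal)])
    out_blocks <- sort(picked[n_causal + seq_len(n_causal_out)])
    gamma_index <- stats::setNames(stats::rnorm(n_causal, 0, gamma_sd),
                                   causal_blocks)
    delta_index <- stats::setNames(stats::rnorm(n_causal_out, 0, delta_sd),
                                   out_blocks)
    n_invalid <- round(prop_invalid * n_causal)
    alpha_index <- stats::setNames(numeric(n_causal), causal_blocks)
    if (n_invalid > 0) {
        if (pleiotropy_mode == "directional") {
            # directional = consistent sign relative to the
            # exposure-increasing allele, the canonical InSIDE-satisfying
            # directional model; |alpha| independent of |gamma|
            which_inv <- sample.int(n_causal, n_invalid)
            alpha_index[which_inv] <- stats::rnorm(n_invalid, alpha_mean,
                                                   alpha_sd) *
                sign(gamma_index[which_inv])
        } else {
            n_invalid <- 2 * (n_invalid %/% 2)
            if (n_invalid > 0) {
                which_inv <- sample.int(n_causal, n_invalid)
                mags <- abs(stats::rnorm(n_invalid %/% 2, 0, alpha_sd))
                alpha_index[which_inv] <- c(mags, -mags)
            }
        }
    }

    gamma <- numeric(n_variants)
    alpha <- numeric(n_variants)
    delta <- numeric(n_variants)
    proxy_scale <- ifelse(((seq_len(n_variants) - 1) %% block_size) == 0,
                          1, sqrt(r2_within))
    in_causal <- block_of %in% causal_blocks
    gamma[in_causal] <- gamma_index[as.character(block_of[in_causal])] *
        proxy_scale[in_causal]
    alpha[in_causal] <- alpha_index[as.character(block_of[in_causal])] *
        proxy_scale[in_causal]
    in_out <- block_of %in% out_blocks
    delta[in_out] <- delta_index[as.character(block_of[in_out])] *
        proxy_scale[in_out]

    ld_blocks <- split(ids, block_of)
    new("SimTruth", theta = theta, theta_rev = theta_rev,
        gamma = stats::setNames(gamma, ids),
        alpha = stats::setNames(alpha, ids),
        delta = stats::setNames(delta, ids),
        prop_invalid = if (n_causal) n_invalid / n_causal else 0,
        pleiotropy_mode = pleiotropy_mode,
        ld_blocks = ld_blocks, n_exp = n_exp, n_out = n_out,
        case_frac = case_frac, eaf = stats::setNames(eaf, ids),
        prop_swap = prop_swap, prop_flip = prop_flip,
        positions = positions, alleles = alleles,
        r2_within = r2_within, seed = as.integer(seed))
}

.se_exp <- function(truth) {
    1 / sqrt(truth@n_exp * 2 * truth@eaf * (1 - truth@eaf))
}

.se_out <- function(truth) {
    v <- truth@case_frac
    1 / sqrt(truth@n_out * v * (1 - v) * 2 * truth@eaf * (1 - truth@eaf))
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Draws one exposure and one outcome summary-statistics table under the
#' supplied ground truth, with independent estimation noise in the two
#' samples (non-overlapping two-sample design):
#' \eqn{\hat\beta_{X_j} \sim N(\gamma_j, se_{X_j})} with
#' \eqn{se_{X_j} = 1/\sqrt{n_{exp}\, 2 f_j (1-f_j)}}, and
#' \eqn{\hat\beta_{Y_j} \sim N(\theta\gamma_j + \alpha_j, se_{Y_j})} with
#' \eqn{se_{Y_j} = 1/\sqrt{n_{out}\, v(1-v)\, 2 f_j (1-f_j)}} for case
#' fraction \eqn{v} (binary-outcome effects generated directly on the
#' log-odds scale). P-values are two-sided normal. The outcome table's
#' allele coding is randomized: a fraction of rows has effect/other
#' exchanged (beta negated, eaf reflected) and a fraction is reported on the
#' opposite strand, exercising harmonization. The LD reference reports
#' \code{r2_within} for every within-block pair.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param noise_seed seed for the estimation noise (defaults to
#'   \code{truth@seed}); distinct seeds with a shared truth yield independent
#'   GWAS realizations of the same study.
#' @return A list with elements \code{exposure} and \code{outcome}
#'   (\linkS4class{SumStats}) and \code{ld} (\linkS4class{LDReference}).
#' @export
simulatePair <- function(truth, noise_seed = truth@seed) {
    stopifnot(is(truth, "SimTruth"))
    n <- length(truth@gamma)
    ids <- names(truth@gamma)
    se_x <- .se_exp(truth)
    se_y <- .se_out(truth)

    old <- .switchSeed(noise_seed)
    on.exit(.restoreSeed(old))
    mu_x <- truth@gamma + truth@theta_rev * truth@delta
    mu_y <- truth@theta * truth@gamma + truth@alpha + truth@delta
    beta_x <- stats::rnorm(n, mu_x, se_x)
    beta_y <- stats::rnorm(n, mu_y, se_y)

    base <- data.frame(variant_id = ids,
                       chrom = truth@positions$chrom,
                       pos = truth@positions$pos,
                       effect_allele = truth@alleles$effect_allele,
                       other_allele = truth@alleles$other_allele,
                       eaf = unname(truth@eaf),
                       stringsAsFactors = FALSE)
    exposure <- base
    exposure$beta <- beta_x
    exposure$se <- se_x
    exposure$pval <- pmax(2 * stats::pnorm(-abs(beta_x / se_x)),
                          .Machine$double.xmin)
    exposure$n <- truth@n_exp

    outcome <- base
    outcome$beta <- beta_y
    outcome$se <- se_y
    outcome$n <- truth@n_out
    swap <- stats::runif(n) < truth@prop_swap
    flip <- stats::runif(n) < truth@prop_flip
    ea <- outcome$effect_allele; oa <- outcome$other_allele
    outcome$effect_allele <- ifelse(swap, oa, ea)
    outcome$other_allele <- ifelse(swap, ea, oa)
    outcome$beta <- ifelse(swap, -outcome$beta, outcome$beta)
    outcome$eaf <- ifelse(swap, 1 - outcome$eaf, outcome$eaf)
    outcome$effect_allele <- ifelse(flip,
                                    unname(.COMPLEMENT[outcome$effect_allele]),
                                    outcome$effect_allele)
    outcome$other_allele <- ifelse(flip,
                                   unname(.COMPLEMENT[outcome$other_allele]),
                                   outcome$other_allele)
    outcome$pval <- pmax(2 * stats::pnorm(-abs(outcome$beta / outcome$se)),
                         .Machine$double.xmin)

    blocks <- truth@ld_blocks
    pair_list <- lapply(blocks, function(members) {
        if (length(members) < 2) return(NULL)
        combs <- utils::combn(members, 2)
        data.frame(id1 = combs[1, ], id2 = combs[2, ],
                   r2 = truth@r2_within, stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pair_list)
    ld <- LDReference(pairs, truth@positions[, c("variant_id", "chrom", "pos")])

    list(exposure = SumStats(exposure), outcome = SumStats(outcome), ld = ld)
}

#' Simulate harmonized instrument effects directly
#'
#' Fast path for estimator calibration studies: skips the table/LD/allele
#' plumbing and draws the per-instrument quadruples (one per causal block's
#' index variant) already aligned, under the same model as
#' \code{\link{simulatePair}}.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param noise_seed seed for the estimation noise.
#' @return A \linkS4class{HarmonizedInstruments} with one row per instrument.
#' @export
simulateHarmonized <- function(truth, noise_seed = truth@seed) {
    stopifnot(is(truth, "SimTruth"))
    # index variant of each causal block: the block's first member
    first_in_block <- !duplicated(truth@positions$block)
    idx <- which(first_in_block & truth@gamma != 0)
    n <- length(idx)
    se_x <- .se_exp(truth)[idx]
    se_y <- .se_out(truth)[idx]
    old <- .switchSeed(noise_seed)
    on.exit(.restoreSeed(old))
    beta_x <- stats::rnorm(n, truth@gamma[idx], se_x)
    beta_y <- stats::rnorm(n, truth@theta * truth@gamma[idx] +
                               truth@alpha[idx], se_y)
    HarmonizedInstruments(names(truth@gamma)[idx], beta_x, se_x,
                          beta_y, se_y)
}

#' Serialize ground truth to JSON
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path optional output path.
#' @return The JSON string, invisibly when written to a file.
#' @export
truthReport <- function(truth, path = NULL) {
    stopifnot(is(truth, "SimTruth"))
    x <- list(theta = truth@theta, theta_rev = truth@theta_rev,
              gamma = as.list(truth@gamma[truth@gamma != 0]),
              alpha = as.list(truth@alpha[truth@alpha != 0]),
              delta = as.list(truth@delta[truth@delta != 0]),
              prop_invalid = truth@prop_invalid,
              pleiotropy_mode = truth@pleiotropy_mode,
              n_variants = length(truth@gamma),
              n_blocks = length(truth@ld_blocks),
              r2_within = truth@r2_within,
              n_exp = truth@n_exp, n_out = truth@n_out,
              case_frac = truth@case_frac,
              prop_swap = truth@prop_swap, prop_flip = truth@prop_flip,
              seed = truth@seed)
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(path)) {
        writeLines(json, path)
        return(invisible(json))
    }
    json
}
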