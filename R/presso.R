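# leave-one-out IVW estimates from sufficient statistics, vectorized:
# beta_(-j) = (S_xy - w_j x_j y_j) / (S_xx - w_j x_j^2), w = 1/se_out^2
.looBetas <- function(x, y, w) {
    sxy <- sum(w * x * y)
    sxx <- sum(w * x^2)
    (sxy - w * x * y) / (sxx - w * x^2)
}

#' MR-PRESSO global test for horizontal pleiotropy
#'
#' The observed residual sum of squares is
#' \eqn{RSS = \sum_j w_j (\beta_{Y_j} - \hat\beta_{(-j)} \beta_{X_j})^2}
#' with \eqn{w_j = 1/se_{out,j}^2} and \eqn{\hat\beta_{(-j)}} the
#' leave-one-out IVW estimate. The null distribution is simulated: in each
#' replicate, outcome effects are drawn from
#' \eqn{N(\hat\beta_{(-j)} \beta_{X_j}, se_{out,j})} and exposure effects
#' from \eqn{N(\beta_{X_j}, se_{exp,j})}, and RSS is recomputed on the
#' simulated data (including its own leave-one-out estimates). The global
#' p-value uses the add-one Monte-Carlo estimator
#' \eqn{(1 + \#\{RSS^* \ge RSS_{obs}\})/(n_{sim} + 1)}, so it is never 0.
#' Per-replicate, per-SNP simulated residual terms are stored for the
#' outlier test.
#'
#' @param h a \linkS4class{HarmonizedInstruments} with at least 4 instruments.
#' @param n_sim Monte-Carlo replicates (default 1000, minimum 1000).
#' @param seed integer seed, mandatory.
#' @return A \linkS4class{PressoResult} (outlier p-values unset until
#'   \code{\link{pressoOutlier}} is run).
#' @export
pressoGlobal <- function(h, n_sim = 1000, seed) {
    if (missing(seed)) stop("seed is required")
    d <- .h_xyws(h)
    n <- length(d$x)
    if (n < 4) stop("too few instruments for PRESSO (need >= 4)")
    if (n_sim < 1000) stop("n_sim must be >= 1000")
    n_sim <- as.integer(n_sim)
    w <- 1 / d$sy^2

    loo <- .looBetas(d$x, d$y, w)
    obs_resid <- w * (d$y - loo * d$x)^2
    rss_obs <- sum(obs_resid)

    old <- .switchSeed(seed)
    on.exit(.restoreSeed(old))
    # replicate matrices: n_sim x n, columns are instruments
    xs <- matrix(stats::rnorm(n_sim * n, mean = rep(d$x, each = n_sim),
                              sd = rep(d$sx, each = n_sim)), n_sim, n)
    ys <- matrix(stats::rnorm(n_sim * n, mean = rep(loo * d$x, each = n_sim),
                              sd = rep(d$sy, each = n_sim)), n_sim, n)
    wm <- matrix(w, n_sim, n, byrow = TRUE)
    sxy <- rowSums(wm * xs * ys)
    sxx <- rowSums(wm * xs^2)
    loo_sim <- (sxy - wm * xs * ys) / (sxx - wm * xs^2)
    sim_resid <- wm * (ys - loo_sim * xs)^2
    rss_sim <- rowSums(sim_resid)
    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

    colnames(sim_resid) <- h$variant_id
    new("PressoResult", rss_obs = rss_obs, global_p = global_p,
        outlier_p = stats::setNames(rep(NA_real_, n), h$variant_id),
        flagged = character(0), n_sim = n_sim, seed = as.integer(seed),
        obs_resid = stats::setNames(obs_resid, h$variant_id),
        sim_resid = sim_resid)
}

#' MR-PRESSO outlier test
#'
#' Compares each instrument's observed weighted residual against its own
#' simulated null distribution from \code{\link{pressoGlobal}}, with the
#' add-one Monte-Carlo p-value. Instruments with uncorrected p below
#' \code{alpha} are flagged; \code{correction = "bonferroni"} flags at
#' \code{alpha / n} instead.
#'
#' @param res the \linkS4class{PressoResult} from \code{\link{pressoGlobal}}.
#' @param h the same \linkS4class{HarmonizedInstruments} it was computed on.
#' @param alpha flagging level (default 0.05).
#' @param correction \code{"none"} (default) or \code{"bonferroni"}.
#' @return The \linkS4class{PressoResult} with \code{outlier_p} and
#'   \code{flagged} filled in.
#' @export
pressoOutlier <- function(res, h, alpha = 0.05,
                          correction = c("none", "bonferroni")) {
    correction <- match.arg(correction)
    stopifnot(is(res, "PressoResult"), is(h, "HarmonizedInstruments"))
    if (!identical(colnames(res@sim_resid), as.character(h$variant_id)))
        stop("PressoResult was not computed on these instruments")
    n <- nrow(h)
    exceed <- colSums(res@sim_resid >=
                          matrix(res@obs_resid, res@n_sim, n, byrow = TRUE))
    outlier_p <- (1 + exceed) / (res@n_sim + 1)
    names(outlier_p) <- h$variant_id
    thr <- if (correction == "bonferroni") alpha / n else alpha
    res@outlier_p <- outlier_p
    res@flagged <- names(outlier_p)[outlier_p < thr]
    validObject(res)
    res
}

#' Remove PRESSO-flagged instruments
#'
#' Returns the harmonized set minus flagged outliers. Callers re-run
#' \code{\link{pressoGlobal}} on the trimmed set to verify the global test
#' is no longer significant (logged, not enforced).
#'
#' @param h a \linkS4class{HarmonizedInstruments}.
#' @param res a \linkS4class{PressoResult} computed on \code{h} with the
#'   outlier test run.
#' @return The trimmed \linkS4class{HarmonizedInstruments}.
#' @export
trimAndRefit <- function(h, res) {
    stopifnot(is(h, "HarmonizedInstruments"), is(res, "PressoResult"))
    if (!length(res@flagged)) return(h)
    keep <- !(h$variant_id %in% res@flagged)
    if (sum(keep) < 2)
        stop("trimming would leave fewer than 2 instruments")
    h[keep, ]
}

#' Serialize a PressoResult to JSON
#'
#' @param res a \linkS4class{PressoResult}.
#' @param path optional output path.
#' @return The JSON string, invisibly when written to a file.
#' @export
pressoJSON <- function(res, path = NULL) {
    stopifnot(is(res, "PressoResult"))
    x <- list(rss_obs = res@rss_obs, global_p = res@global_p,
              n_sim = res@n_sim, seed = res@seed,
              outliers = data.frame(variant_id = names(res@outlier_p),
                                    outlier_p = unname(res@outlier_p),
                                    flagged = names(res@outlier_p) %in%
                                        res@flagged),
              flagged = res@flagged)
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(path)) {
        writeLines(json, path)
        return(invisible(json))
    }
    json
}
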