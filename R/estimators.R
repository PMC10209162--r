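Z95 <- 1.959964

.mrEstimate <- function(method, beta, se, n_snps, extra = list()) {
    # exact fits can yield a zero sampling SE; keep the CI non-degenerate
    se <- max(se, 4 * .Machine$double.eps * max(1, abs(beta)))
    pval <- 2 * stats::pnorm(-abs(beta / se))
    pval <- max(min(pval, 1), .Machine$double.xmin)
    new("MREstimate", method = method, beta = beta, se = se,
        ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
        pval = pval, n_snps = as.integer(n_snps), extra = extra)
}

.h_xyws <- function(h) {
    list(x = h$beta_exp, y = h$beta_out, sx = h$se_exp, sy = h$se_out)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights \eqn{w_j = 1/se_{out,j}^2}:
#' \eqn{\hat\beta = \sum w_j \beta_{X_j} \beta_{Y_j} / \sum w_j \beta_{X_j}^2}.
#' The fixed-effect SE is \eqn{(\sum w_j \beta_{X_j}^2)^{-1/2}}; the default
#' multiplicative random-effects SE multiplies it by
#' \eqn{\max(1, \sqrt{Q/(n-1)})}, which inflates the SE under heterogeneity
#' but never deflates it. With a single instrument (fixed mode) this is the
#' Wald ratio. Cochran's Q and its p-value are returned in \code{extra}.
#'
#' @param h a \linkS4class{HarmonizedInstruments} object.
#' @param re_mode \code{"multiplicative"} (random-effects, default) or
#'   \code{"fixed"}.
#' @return An \linkS4class{MREstimate}.
#' @export
mrIVW <- function(h, re_mode = c("multiplicative", "fixed")) {
    re_mode <- match.arg(re_mode)
    d <- .h_xyws(h)
    n <- length(d$x)
    if (n < 1 || (re_mode == "multiplicative" && n < 2))
        stop("too few instruments for IVW (need >= 2, or >= 1 for fixed)")
    if (all(d$x == 0)) stop("all exposure effects are zero: no identification")
    w <- 1 / d$sy^2
    sxx <- sum(w * d$x^2)
    beta <- sum(w * d$x * d$y) / sxx
    se_fixed <- 1 / sqrt(sxx)
    q <- .cochranQ(d$x, d$y, d$sy, beta)
    se <- if (re_mode == "multiplicative")
        se_fixed * max(1, sqrt(q$Q / (n - 1))) else se_fixed
    het_p <- if (n >= 2) q$het_p else NA_real_
    .mrEstimate(paste0("IVW (", re_mode, ")"), beta, se, n,
                extra = list(Q = q$Q, het_p = het_p))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights \eqn{1/se_{out}^2}, after re-orienting every instrument
#' so its exposure effect is non-negative (required for intercept
#' identifiability). The slope is the causal estimate; the intercept and its
#' p-value (the directional-pleiotropy test) are reported in \code{extra}
#' as \code{intercept}, \code{intercept_se}, \code{intercept_p}. SEs carry a
#' multiplicative overdispersion factor \eqn{\max(1, RSS_w/(n-2))}.
#'
#' @param h a \linkS4class{HarmonizedInstruments} with at least 3 instruments.
#' @return An \linkS4class{MREstimate}.
#' @export
mrEgger <- function(h) {
    d <- .h_xyws(h)
    n <- length(d$x)
    if (n < 3) stop("MR-Egger needs at least 3 instruments")
    flip <- d$x < 0
    x <- abs(d$x)
    y <- ifelse(flip, -d$y, d$y)
    if (stats::sd(x) == 0) stop("zero variance in exposure effects")
    w <- 1 / d$sy^2
    # weighted normal equations for (intercept, slope)
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
    swy <- sum(w * y); swxy <- sum(w * x * y)
    det <- sw * swxx - swx^2
    slope <- (sw * swxy - swx * swy) / det
    icpt <- (swxx * swy - swx * swxy) / det
    resid <- y - icpt - slope * x
    sigma2 <- max(1, sum(w * resid^2) / (n - 2))
    se_slope <- sqrt(sigma2 * sw / det)
    se_icpt <- sqrt(sigma2 * swxx / det)
    icpt_p <- 2 * stats::pnorm(-abs(icpt / se_icpt))
    .mrEstimate("MR-Egger", slope, se_slope, n,
                extra = list(intercept = icpt, intercept_se = se_icpt,
                             intercept_p = icpt_p))
}

.weightedMedian <- function(ratios, weights) {
    ord <- order(ratios)
    r <- ratios[ord]
    w <- weights[ord] / sum(weights)
    # interpolate the weighted empirical CDF evaluated at mid-weights
    p <- (cumsum(w) - w / 2)
    if (p[1] >= 0.5) return(r[1])
    if (p[length(p)] <= 0.5) return(r[length(r)])
    stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Per-instrument Wald ratios \eqn{\beta_j = \beta_{Y_j}/\beta_{X_j}} with
#' weights \eqn{w_j = \beta_{X_j}^2 / se_{out,j}^2}; the estimate is the
#' weighted median (linear interpolation of the weighted empirical CDF at
#' cumulative weight one half). Consistent as long as more than half the
#' weight comes from valid instruments. SE by parametric bootstrap:
#' exposure and outcome effects are resampled from normal distributions
#' centred on the observed values with their standard errors.
#'
#' @param h a \linkS4class{HarmonizedInstruments} with at least 3 instruments;
#'   instruments with a zero exposure effect are excluded with a warning.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed, mandatory for reproducibility.
#' @return An \linkS4class{MREstimate}.
#' @export
mrWeightedMedian <- function(h, n_boot = 1000, seed) {
    if (missing(seed)) stop("seed is required")
    d <- .h_xyws(h)
    zero <- d$x == 0
    if (any(zero)) {
        warning(sum(zero), " instrument(s) with zero exposure effect excluded")
        d <- lapply(d, function(v) v[!zero])
    }
    n <- length(d$x)
    if (n < 3) stop("weighted median needs at least 3 usable instruments")
    ratios <- d$y / d$x
    weights <- d$x^2 / d$sy^2
    est <- .weightedMedian(ratios, weights)

    old <- .switchSeed(seed)
    on.exit(.restoreSeed(old))
    boot <- vapply(seq_len(n_boot), function(b) {
        xb <- stats::rnorm(n, d$x, d$sx)
        yb <- stats::rnorm(n, d$y, d$sy)
        ok <- xb != 0
        .weightedMedian(yb[ok] / xb[ok], xb[ok]^2 / d$sy[ok]^2)
    }, numeric(1))
    se <- stats::sd(boot)
    if (se == 0) se <- .Machine$double.eps
    .mrEstimate("Weighted median", est, se, n,
                extra = list(n_boot = n_boot, seed = seed))
}

# Huber psi with the conventional 95%-efficiency constant
.huberPsi <- function(t, c = 1.345) pmin(pmax(t, -c), c)

.rapsScore <- function(beta, x, y, sx, sy, tau2, loss) {
    s2 <- sy^2 + beta^2 * sx^2 + tau2
    s <- sqrt(s2)
    t <- (y - beta * x) / s
    dt <- (-x * s - (y - beta * x) * beta * sx^2 / s) / s2
    psi <- if (loss == "huber") .huberPsi(t) else t
    sum(psi * dt)
}

#' Robust adjusted profile score estimator
#'
#' Solves the profile score equation
#' \eqn{\sum_j \psi(t_j(\beta))\, \partial t_j/\partial\beta = 0} with
#' standardized residuals
#' \eqn{t_j(\beta) = (\beta_{Y_j} - \beta\,\beta_{X_j}) /
#' \sqrt{se_{out,j}^2 + \beta^2 se_{exp,j}^2 + \tau^2}}, which accounts for
#' measurement error in the exposure effects (weak instruments). \eqn{\psi}
#' is the identity for \code{loss = "l2"} and the Huber function (c = 1.345)
#' otherwise. With overdispersion, \eqn{\tau^2 \ge 0} is profiled by
#' iterating a robust moment condition \eqn{\sum_j \delta_j (t_j^2 - 1) = 0}
#' (with Huber weights \eqn{\delta_j = \psi(t_j)/t_j}) against the score
#' equation until convergence. The root is found by bracketing the IVW
#' estimate and widening until the score changes sign. SE by the sandwich
#' formula with a numerical derivative of the score.
#'
#' @param h a \linkS4class{HarmonizedInstruments} with at least 3 instruments.
#' @param loss \code{"huber"} (default) or \code{"l2"}.
#' @param overdispersion profile an additive variance component (default
#'   TRUE).
#' @return An \linkS4class{MREstimate}; \code{extra$tau2} holds the profiled
#'   overdispersion.
#' @export
mrRAPS <- function(h, loss = c("huber", "l2"), overdispersion = TRUE) {
    loss <- match.arg(loss)
    d <- .h_xyws(h)
    n <- length(d$x)
    if (n < 3) stop("MR-RAPS needs at least 3 instruments")

    solve_beta <- function(tau2) {
        ivw <- sum(d$x * d$y / d$sy^2) / sum(d$x^2 / d$sy^2)
        ivw_se <- 1 / sqrt(sum(d$x^2 / d$sy^2))
        half <- max(10 * ivw_se, 0.5 * abs(ivw), 0.1)
        score <- function(b) .rapsScore(b, d$x, d$y, d$sx, d$sy, tau2, loss)
        for (k in 1:12) {
            lo <- ivw - half; hi <- ivw + half
            if (sign(score(lo)) != sign(score(hi)))
                return(stats::uniroot(score, c(lo, hi), tol = 1e-10)$root)
            half <- half * 2
        }
        stop("estimate did not converge: no sign change in profile score")
    }

    tau2 <- 0
    beta <- solve_beta(0)
    if (overdispersion) {
        for (it in 1:50) {
            s2 <- d$sy^2 + beta^2 * d$sx^2 + tau2
            t <- (d$y - beta * d$x) / sqrt(s2)
            delta <- if (loss == "huber")
                ifelse(t == 0, 1, .huberPsi(t) / t) else rep(1, n)
            # moment condition: weighted mean of (y - beta x)^2 equals
            # its model variance; solve for tau2, truncated at 0
            tau2_new <- max(0, sum(delta * ((d$y - beta * d$x)^2 -
                                            (d$sy^2 + beta^2 * d$sx^2))) /
                                sum(delta))
            beta_new <- solve_beta(tau2_new)
            if (abs(beta_new - beta) < 1e-10 && abs(tau2_new - tau2) < 1e-12) {
                beta <- beta_new; tau2 <- tau2_new; break
            }
            beta <- beta_new; tau2 <- tau2_new
        }
    }

    s2 <- d$sy^2 + beta^2 * d$sx^2 + tau2
    t <- (d$y - beta * d$x) / sqrt(s2)
    dt <- (-d$x * sqrt(s2) - (d$y - beta * d$x) * beta * d$sx^2 / sqrt(s2)) / s2
    psi <- if (loss == "huber") .huberPsi(t) else t
    meat <- sum(psi^2 * dt^2)
    eps <- 1e-6 * max(1, abs(beta))
    bread <- (.rapsScore(beta + eps, d$x, d$y, d$sx, d$sy, tau2, loss) -
              .rapsScore(beta - eps, d$x, d$y, d$sx, d$sy, tau2, loss)) /
        (2 * eps)
    se <- sqrt(meat) / abs(bread)
    .mrEstimate(sprintf("MR-RAPS (%s%s)", loss,
                        if (overdispersion) ", overdispersed" else ""),
                beta, se, n, extra = list(tau2 = tau2))
}

.cochranQ <- function(x, y, sy, beta) {
    ratios <- y / x
    w <- (sy / x)^-2
    Q <- sum(w * (ratios - beta)^2)
    list(Q = Q, het_p = stats::pchisq(Q, df = length(x) - 1,
                                      lower.tail = FALSE))
}

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j w_j (\beta_j - \beta)^2} over per-instrument Wald ratios
#' \eqn{\beta_j = \beta_{Y_j}/\beta_{X_j}} with inverse-variance weights
#' \eqn{w_j = (se_{out,j}/\beta_{X_j})^{-2}}, referred to a chi-square with
#' \code{n - 1} degrees of freedom.
#'
#' @param h a \linkS4class{HarmonizedInstruments} with at least 2 instruments.
#' @param beta the causal estimate to measure heterogeneity around; defaults
#'   to the fixed-effect IVW estimate.
#' @return A list with components \code{Q} and \code{het_p}.
#' @export
cochranQ <- function(h, beta = NULL) {
    d <- .h_xyws(h)
    if (length(d$x) < 2) stop("Cochran's Q needs at least 2 instruments")
    if (is.null(beta))
        beta <- sum(d$x * d$y / d$sy^2) / sum(d$x^2 / d$sy^2)
    .cochranQ(d$x, d$y, d$sy, beta)
}

#' Leave-one-out IVW diagnostics
#'
#' Recomputes the IVW estimate excluding each instrument in turn; a causal
#' signal carried by a single SNP shows as one exclusion shifting the
#' estimate far more than the others.
#'
#' @param h a \linkS4class{HarmonizedInstruments} with at least 3 instruments.
#' @param re_mode passed to \code{\link{mrIVW}}.
#' @return A \linkS4class{LeaveOneOutResult}; \code{looTable} flattens it.
#' @export
leaveOneOut <- function(h, re_mode = "multiplicative") {
    n <- nrow(h)
    if (n < 3) stop("leave-one-out needs at least 3 instruments")
    ests <- lapply(seq_len(n), function(j) mrIVW(h[-j, ], re_mode = re_mode))
    names(ests) <- h$variant_id
    new("LeaveOneOutResult", estimates = ests,
        overall = mrIVW(h, re_mode = re_mode))
}

#' Flatten a LeaveOneOutResult to a data.frame
#'
#' @param loo a \linkS4class{LeaveOneOutResult}.
#' @return data.frame with one row per excluded SNP plus an "All" row.
#' @export
looTable <- function(loo) {
    stopifnot(is(loo, "LeaveOneOutResult"))
    rows <- c(loo@estimates, list(All = loo@overall))
    data.frame(excluded = names(rows),
               beta = vapply(rows, mrBeta, numeric(1)),
               se = vapply(rows, mrSE, numeric(1)),
               ci_low = vapply(rows, function(e) mrCI(e)[1], numeric(1)),
               ci_high = vapply(rows, function(e) mrCI(e)[2], numeric(1)),
               pval = vapply(rows, mrPval, numeric(1)),
               n_snps = vapply(rows, nSnps, integer(1)),
               row.names = NULL)
}

#' Flatten MREstimates to a results table
#'
#' @param estimates a list of \linkS4class{MREstimate} objects.
#' @return data.frame with method, beta, se, CI, p, OR, OR CI, n_snps and
#'   flattened extras.
#' @export
estimateTable <- function(estimates) {
    if (is(estimates, "MREstimate")) estimates <- list(estimates)
    base <- data.frame(
        method = vapply(estimates, mrMethod, character(1)),
        beta = vapply(estimates, mrBeta, numeric(1)),
        se = vapply(estimates, mrSE, numeric(1)),
        ci_low = vapply(estimates, function(e) mrCI(e)[1], numeric(1)),
        ci_high = vapply(estimates, function(e) mrCI(e)[2], numeric(1)),
        pval = vapply(estimates, mrPval, numeric(1)),
        or = vapply(estimates, oddsRatio, numeric(1)),
        or_ci_low = vapply(estimates, function(e) oddsRatioCI(e)[1], numeric(1)),
        or_ci_high = vapply(estimates, function(e) oddsRatioCI(e)[2], numeric(1)),
        n_snps = vapply(estimates, nSnps, integer(1)),
        row.names = NULL)
    base
}

# seed hygiene: run seeded code without disturbing the caller's RNG stream
.switchSeed <- function(seed) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    old
}

.restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", old, envir = globalenv())
    }
}
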