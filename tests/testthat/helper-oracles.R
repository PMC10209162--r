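# Independent oracles and fixture builders. These deliberately use different
# code paths from the package: dense matrices instead of pair maps, lm()
# instead of summary-statistic formulas.

# quick SumStats from minimal fields
makeSumStats <- function(variant_id, beta, se, pval = NULL,
                         chrom = "1", pos = seq_along(variant_id),
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, info = NULL, n = NULL) {
    k <- length(variant_id)
    if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
    df <- data.frame(variant_id = variant_id,
                     chrom = rep_len(chrom, k), pos = rep_len(pos, k),
                     effect_allele = rep_len(effect_allele, k),
                     other_allele = rep_len(other_allele, k),
                     eaf = rep_len(eaf, k), beta = beta, se = se,
                     pval = pval, stringsAsFactors = FALSE)
    if (!is.null(info)) df$info <- rep_len(info, k)
    if (!is.null(n)) df$n <- rep_len(n, k)
    SumStats(df)
}

# dense-matrix LD reference for small instances
makeLDRef <- function(r2mat, chrom, pos) {
    ids <- rownames(r2mat)
    idx <- which(upper.tri(r2mat), arr.ind = TRUE)
    pairs <- data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                        r2 = r2mat[idx], stringsAsFactors = FALSE)
    pairs <- pairs[pairs$r2 > 0, , drop = FALSE]
    LDReference(pairs, data.frame(variant_id = ids, chrom = chrom, pos = pos,
                                  stringsAsFactors = FALSE))
}

# brute-force clump oracle: scan variants in (p, chrom, pos, id) order and
# keep each one unless an already-kept variant on the same chromosome within
# the window has r2 >= r2_max with it (dense-matrix lookup)
bruteClump <- function(df, r2mat, window_kb, p1, r2_max) {
    df <- df[df$pval <= p1, , drop = FALSE]
    df <- df[order(df$pval, df$chrom, df$pos, df$variant_id), , drop = FALSE]
    kept <- character(0)
    for (i in seq_len(nrow(df))) {
        v <- df$variant_id[i]
        conflict <- FALSE
        for (s in kept) {
            j <- match(s, df$variant_id)
            if (df$chrom[j] == df$chrom[i] &&
                abs(df$pos[j] - df$pos[i]) <= window_kb * 1000 &&
                r2mat[s, v] >= r2_max) {
                conflict <- TRUE
                break
            }
        }
        if (!conflict) kept <- c(kept, v)
    }
    kept
}

# random small clumping instance on 2 chromosomes
randomClumpInstance <- function(n = 10) {
    ids <- sprintf("v%02d", seq_len(n))
    chrom <- sample(c("1", "2"), n, replace = TRUE)
    pos <- sample.int(3e7, n)
    r2 <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (chrom[i] == chrom[j] && runif(1) < 0.5)
            r2[i, j] <- r2[j, i] <- runif(1)
    }
    diag(r2) <- 1
    pval <- 10^runif(n, -12, -1)
    list(df = data.frame(variant_id = ids, chrom = chrom, pos = pos,
                         pval = pval, stringsAsFactors = FALSE),
         r2 = r2)
}

# closed-form WLS oracles via lm(); SEs rescaled to the summary-data
# convention (unit residual variance, multiplicative overdispersion >= 1)
oracleIVW <- function(x, y, sy, re_mode = "multiplicative") {
    fit <- lm(y ~ 0 + x, weights = 1 / sy^2)
    sigma <- summary(fit)$sigma
    se_fixed <- sqrt(diag(vcov(fit)))[[1]] / sigma
    q <- sum((y - coef(fit)[[1]] * x)^2 / sy^2)
    se <- if (re_mode == "multiplicative")
        se_fixed * max(1, sqrt(q / (length(x) - 1))) else se_fixed
    list(beta = unname(coef(fit)[[1]]), se = unname(se), Q = q)
}

oracleEgger <- function(x, y, sy) {
    flip <- x < 0
    x2 <- abs(x); y2 <- ifelse(flip, -y, y)
    fit <- lm(y2 ~ x2, weights = 1 / sy^2)
    sigma <- summary(fit)$sigma
    ses <- sqrt(diag(vcov(fit))) / sigma * max(1, sigma)
    list(intercept = unname(coef(fit)[[1]]), slope = unname(coef(fit)[[2]]),
         se_intercept = unname(ses[[1]]), se_slope = unname(ses[[2]]))
}

# weighted-median oracle from the mid-weight interpolation formula
oracleWeightedMedian <- function(ratios, weights) {
    ord <- order(ratios)
    r <- ratios[ord]; w <- weights[ord]
    p <- (cumsum(w) - w / 2) / sum(w)
    if (p[1] >= 0.5) return(r[1])
    if (p[length(p)] <= 0.5) return(r[length(r)])
    j <- max(which(p < 0.5))
    r[j] + (r[j + 1] - r[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

# displace one instrument's outcome effect by k standard errors
plantOutlier <- function(h, j, k = 10) {
    beta_out <- h$beta_out
    beta_out[j] <- beta_out[j] + k * h$se_out[j]
    HarmonizedInstruments(h$variant_id, h$beta_exp, h$se_exp,
                          beta_out, h$se_out)
}

# harmonized fixture with optional planted pleiotropy/outliers
makeHarmonized <- function(n = 20, theta = 0.1, seed = 1, gamma_sd = 0.2,
                           se_x = 0.016, se_y = 0.005, alpha = 0) {
    set.seed(seed)
    gamma <- rnorm(n, 0, gamma_sd)
    alpha <- rep_len(alpha, n)
    HarmonizedInstruments(sprintf("rs%03d", seq_len(n)),
                          rnorm(n, gamma, se_x), rep(se_x, n),
                          rnorm(n, theta * gamma + alpha, se_y), rep(se_y, n))
}
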