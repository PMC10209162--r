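test_that("single-instrument fixed IVW is the Wald ratio", {
    h <- HarmonizedInstruments("r1", beta_exp = 0.5, se_exp = 0.02,
                               beta_out = 0.1, se_out = 0.05)
    est <- mrIVW(h, re_mode = "fixed")
    expect_equal(mrBeta(est), 0.2)
    expect_equal(mrSE(est), 0.05 / 0.5)
})

test_that("IVW is null and OR is 1 when all outcome effects vanish", {
    h <- HarmonizedInstruments(paste0("r", 1:4), beta_exp = c(0.2, 0.3, 0.4, 0.5),
                               se_exp = 0.02, beta_out = 0, se_out = 0.05)
    est <- mrIVW(h)
    expect_equal(mrBeta(est), 0)
    expect_equal(oddsRatio(est), 1)
    expect_error(mrIVW(HarmonizedInstruments(c("a", "b"), c(0, 0), 0.1,
                                             c(0.1, 0.2), 0.1)),
                 "identification")
})

test_that("IVW matches the closed-form WLS oracle on random instances", {
    set.seed(101)
    for (k in 1:30) {
        n <- sample(4:30, 1)
        x <- rnorm(n, 0, 0.3); x[x == 0] <- 0.1
        y <- rnorm(n, 0.1 * x, 0.05)
        sy <- runif(n, 0.01, 0.1)
        h <- HarmonizedInstruments(paste0("r", 1:n), x, 0.02, y, sy)
        for (mode in c("fixed", "multiplicative")) {
            got <- mrIVW(h, re_mode = mode)
            want <- oracleIVW(x, y, sy, re_mode = mode)
            expect_equal(mrBeta(got), want$beta, tolerance = 1e-10)
            expect_equal(mrSE(got), want$se, tolerance = 1e-10)
            expect_equal(mrExtra(got)$Q, want$Q, tolerance = 1e-10)
        }
    }
})

test_that("Egger recovers an exact linear law and matches the WLS oracle", {
    x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
    h_exact <- HarmonizedInstruments(paste0("r", 1:5), x, 0.02,
                                     0.02 + 0.3 * x, 0.05)
    est <- mrEgger(h_exact)
    expect_equal(mrBeta(est), 0.3, tolerance = 1e-12)
    expect_equal(mrExtra(est)$intercept, 0.02, tolerance = 1e-12)
    # proportional data: intercept exactly 0
    h_prop <- HarmonizedInstruments(paste0("r", 1:5), x, 0.02, 0.25 * x, 0.05)
    expect_equal(mrExtra(mrEgger(h_prop))$intercept, 0, tolerance = 1e-12)

    set.seed(202)
    for (k in 1:30) {
        n <- sample(5:25, 1)
        x <- rnorm(n, 0, 0.3)
        y <- rnorm(n, 0.01 + 0.2 * x, 0.04)
        sy <- runif(n, 0.01, 0.1)
        h <- HarmonizedInstruments(paste0("r", 1:n), x, 0.02, y, sy)
        got <- mrEgger(h)
        want <- oracleEgger(x, y, sy)
        expect_equal(mrBeta(got), want$slope, tolerance = 1e-10)
        expect_equal(mrSE(got), want$se_slope, tolerance = 1e-10)
        expect_equal(mrExtra(got)$intercept, want$intercept, tolerance = 1e-10)
        expect_equal(mrExtra(got)$intercept_se, want$se_intercept,
                     tolerance = 1e-10)
    }
    expect_error(mrEgger(h_exact[1:2, ]), "3 instruments")
})

test_that("weighted median interpolates the weighted CDF at half weight", {
    h <- HarmonizedInstruments(paste0("r", 1:3), beta_exp = 1, se_exp = 0.01,
                               beta_out = c(0.2, 0.4, 0.6), se_out = 0.05)
    expect_equal(mrBeta(mrWeightedMedian(h, seed = 1)), 0.4)

    # all ratios equal: estimate is that constant, bootstrap SE collapses
    # as the input SEs shrink
    h2 <- HarmonizedInstruments(paste0("r", 1:4), beta_exp = c(1, 2, 3, 4),
                                se_exp = 1e-8, beta_out = 0.3 * c(1, 2, 3, 4),
                                se_out = 1e-8)
    est2 <- mrWeightedMedian(h2, seed = 2)
    expect_equal(mrBeta(est2), 0.3, tolerance = 1e-6)
    expect_lt(mrSE(est2), 1e-6)

    set.seed(303)
    for (k in 1:20) {
        n <- sample(5:15, 1)
        x <- rnorm(n, 0, 0.4); x[abs(x) < 0.05] <- 0.1
        y <- rnorm(n, 0.1 * x, 0.03)
        sy <- runif(n, 0.01, 0.08)
        h <- HarmonizedInstruments(paste0("r", 1:n), x, 0.02, y, sy)
        got <- mrBeta(mrWeightedMedian(h, seed = k))
        want <- oracleWeightedMedian(y / x, x^2 / sy^2)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("weighted median excludes zero-exposure instruments with a warning", {
    h <- HarmonizedInstruments(paste0("r", 1:4), beta_exp = c(0, 1, 2, 3),
                               se_exp = 0.01, beta_out = c(5, 0.2, 0.4, 0.6),
                               se_out = 0.05)
    expect_warning(est <- mrWeightedMedian(h, seed = 3), "zero exposure")
    expect_equal(nSnps(est), 3L)
})

test_that("RAPS reduces to fixed IVW without exposure error and fits exact data", {
    set.seed(404)
    n <- 12
    x <- rnorm(n, 0, 0.3)
    y <- rnorm(n, 0.1 * x, 0.05)
    sy <- runif(n, 0.02, 0.08)
    h <- HarmonizedInstruments(paste0("r", 1:n), x, 1e-10, y, sy)
    raps <- mrRAPS(h, loss = "l2", overdispersion = FALSE)
    ivw <- mrIVW(h, re_mode = "fixed")
    expect_equal(mrBeta(raps), mrBeta(ivw), tolerance = 1e-6)
    # exactly proportional data: any loss returns theta
    h2 <- HarmonizedInstruments(paste0("r", 1:5), c(0.1, 0.2, 0.3, 0.4, 0.5),
                                0.02, 0.07 * c(0.1, 0.2, 0.3, 0.4, 0.5), 0.05)
    for (loss in c("l2", "huber"))
        expect_equal(mrBeta(mrRAPS(h2, loss = loss, overdispersion = FALSE)),
                     0.07, tolerance = 1e-8)
})

test_that("RAPS recovers a known effect with error on both sides", {
    theta <- 0.1
    reps <- 100
    est <- vapply(seq_len(reps), function(r) {
        tr <- simTruth(n_variants = 250, n_causal = 50, n_causal_out = 0, theta = theta,
                       block_size = 5, seed = 5000 + r)
        mrBeta(mrRAPS(simulateHarmonized(tr), loss = "l2",
                      overdispersion = FALSE))
    }, numeric(1))
    mc_se <- sd(est) / sqrt(reps)
    expect_lt(abs(mean(est) - theta), 3 * mc_se)
})

test_that("Egger separates slope and mean pleiotropy under InSIDE", {
    # truth redrawn each replicate so instrument strength and pleiotropy are
    # independent in expectation (InSIDE); intercept targets the
    # inverse-variance-weighted mean pleiotropic effect after orientation
    reps <- 120
    icpt_err <- slope <- numeric(reps)
    for (r in seq_len(reps)) {
        tr <- simTruth(n_variants = 150, n_causal = 30, n_causal_out = 0,
                       theta = 0.1, prop_invalid = 0.4,
                       pleiotropy_mode = "directional", seed = 12000 + r)
        h <- simulateHarmonized(tr, noise_seed = 13000 + r)
        e <- mrEgger(h)
        w <- 1 / h$se_out^2
        a_or <- tr@alpha[h$variant_id] * sign(h$beta_exp)
        icpt_err[r] <- mrExtra(e)$intercept - sum(w * a_or) / sum(w)
        slope[r] <- mrBeta(e)
    }
    expect_lt(abs(mean(icpt_err)), 3 * sd(icpt_err) / sqrt(reps))
    expect_lt(abs(mean(slope) - 0.1), 3 * sd(slope) / sqrt(reps))
})

test_that("IVW under valid instruments holds nominal 95% CI coverage", {
    reps <- 1000
    tr <- simTruth(n_variants = 150, n_causal = 30, n_causal_out = 0,
                   theta = 0.1, seed = 1234)
    covered <- vapply(seq_len(reps), function(r) {
        ci <- mrCI(mrIVW(simulateHarmonized(tr, noise_seed = 20000 + r)))
        ci[1] <= 0.1 && 0.1 <= ci[2]
    }, logical(1))
    expect_gte(mean(covered), 0.93)
    expect_lte(mean(covered), 0.97)
})

test_that("Cochran's Q is zero for identical ratios and grows with spread", {
    x <- c(0.2, 0.4)
    h0 <- HarmonizedInstruments(c("a", "b"), x, 0.02, 0.3 * x, 0.05)
    q0 <- cochranQ(h0, beta = 0.3)
    expect_equal(q0$Q, 0)
    expect_equal(q0$het_p, 1)

    # two instruments, hand-computed: ratios 0.5 and 0.25, w = (x/se)^2
    h <- HarmonizedInstruments(c("a", "b"), beta_exp = c(0.2, 0.4),
                               se_exp = 0.02, beta_out = c(0.1, 0.1),
                               se_out = c(0.05, 0.05))
    beta <- 0.3
    w <- (c(0.2, 0.4) / 0.05)^2
    q_hand <- w[1] * (0.5 - beta)^2 + w[2] * (0.25 - beta)^2
    expect_equal(cochranQ(h, beta = beta)$Q, q_hand)

    # monotonicity as one ratio departs
    qs <- vapply(c(0.1, 0.2, 0.4), function(d) {
        hh <- HarmonizedInstruments(c("a", "b", "c"), c(0.2, 0.3, 0.4), 0.02,
                                    c(0.06, 0.09, 0.12 + d), 0.05)
        cochranQ(hh, beta = 0.3)$Q
    }, numeric(1))
    expect_true(all(diff(qs) > 0))
})

test_that("leave-one-out is symmetric, counts right, and exposes outliers", {
    # identical instruments: every exclusion equals the overall estimate
    h <- HarmonizedInstruments(paste0("r", 1:4), beta_exp = 0.3, se_exp = 0.02,
                               beta_out = 0.03, se_out = 0.05)
    loo <- looTable(leaveOneOut(h))
    expect_equal(length(unique(round(loo$beta, 12))), 1L)

    # n = 3: three exclusions with two instruments each
    h3 <- HarmonizedInstruments(paste0("r", 1:3), c(0.2, 0.3, 0.4), 0.02,
                                c(0.02, 0.03, 0.04), 0.05)
    tab3 <- looTable(leaveOneOut(h3))
    expect_equal(nrow(tab3), 4L)
    expect_equal(tab3$n_snps, c(2L, 2L, 2L, 3L))

    # a planted outlier's exclusion shifts the estimate most
    set.seed(9)
    h_out <- makeHarmonized(n = 12, theta = 0.1, seed = 9)
    h_out <- plantOutlier(h_out, 5, 12)
    res <- leaveOneOut(h_out)
    overall <- mrBeta(res@overall)
    shifts <- abs(vapply(res@estimates, mrBeta, numeric(1)) - overall)
    expect_equal(names(which.max(shifts)), h_out$variant_id[5])
})

test_that("estimates are scale-equivariant in the exposure units", {
    h <- makeHarmonized(n = 15, theta = 0.1, seed = 31)
    c_scale <- 2.5
    h2 <- HarmonizedInstruments(h$variant_id, c_scale * h$beta_exp,
                                c_scale * h$se_exp, h$beta_out, h$se_out)
    expect_equal(mrBeta(mrIVW(h2)), mrBeta(mrIVW(h)) / c_scale)
    expect_equal(mrBeta(mrEgger(h2)), mrBeta(mrEgger(h)) / c_scale)
    expect_equal(mrBeta(mrWeightedMedian(h2, seed = 6)),
                 mrBeta(mrWeightedMedian(h, seed = 6)) / c_scale,
                 tolerance = 1e-6)
    expect_equal(mrBeta(mrRAPS(h2)), mrBeta(mrRAPS(h)) / c_scale,
                 tolerance = 1e-6)
})
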