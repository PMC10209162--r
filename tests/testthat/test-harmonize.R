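expTab <- function() {
    makeSumStats(c("r1", "r2", "r3", "r4"), beta = c(0.1, 0.2, 0.3, 0.4),
                 se = 0.02, effect_allele = "A", other_allele = "G")
}

test_that("the four allele configurations resolve as keep/flip/keep/drop", {
    exposure <- expTab()
    out <- data.frame(variant_id = c("r1", "r2", "r3", "r4"),
                      chrom = "1", pos = 1:4,
                      effect_allele = c("A", "G", "T", "A"),
                      other_allele = c("G", "A", "C", "C"),
                      eaf = 0.3, beta = c(0.2, 0.2, 0.2, 0.2), se = 0.05,
                      pval = 0.5)
    h <- harmonizeInstruments(exposure, SumStats(out),
                              c("r1", "r2", "r3", "r4"))
    # r1 same order: kept; r2 swapped: negated; r3 strand-flip of A/G: kept;
    # r4 irreconcilable: dropped
    expect_equal(h$variant_id, c("r1", "r2", "r3"))
    expect_equal(h$beta_out, c(0.2, -0.2, 0.2))
    prov <- harmonizationProvenance(h)
    expect_equal(prov$kept, 3L)
    expect_equal(prov$flipped, 1L)
    expect_equal(prov$dropped_ids, "r4")
})

test_that("swapped coding reflects the outcome allele frequency", {
    exposure <- expTab()[1:2, ]
    out <- data.frame(variant_id = c("r1", "r2"), chrom = "1", pos = 1:2,
                      effect_allele = c("A", "G"), other_allele = c("G", "A"),
                      eaf = c(0.3, 0.3), beta = c(0.1, 0.1), se = 0.05,
                      pval = 0.5)
    h <- harmonizeInstruments(exposure, SumStats(out), c("r1", "r2"))
    expect_equal(h$eaf_out, c(0.3, 0.7))
})

test_that("instruments missing from a table are dropped with a count", {
    exposure <- expTab()
    outcome <- makeSumStats(c("r1", "r2"), beta = 0.1, se = 0.05)
    h <- harmonizeInstruments(exposure, outcome, c("r1", "r2", "zz"))
    expect_equal(nrow(h), 2)
    expect_true("zz" %in% harmonizationProvenance(h)$dropped_ids)
})

test_that("harmonization is an involution under double allele swap", {
    exposure <- expTab()
    out <- data.frame(variant_id = exposure$variant_id, chrom = "1",
                      pos = 1:4, effect_allele = "A", other_allele = "G",
                      eaf = 0.4, beta = c(0.1, -0.2, 0.3, 0), se = 0.05,
                      pval = 0.5)
    swapTwice <- out
    # swapping coding twice restores the original orientation
    for (i in 1:2) {
        swapTwice <- transform(swapTwice,
                               effect_allele = other_allele,
                               other_allele = effect_allele,
                               beta = -beta, eaf = 1 - eaf)
    }
    h1 <- harmonizeInstruments(exposure, SumStats(out), exposure$variant_id)
    h2 <- harmonizeInstruments(exposure, SumStats(swapTwice),
                               exposure$variant_id)
    expect_equal(as.data.frame(h1), as.data.frame(h2))
})

test_that("|beta_out| is preserved for every kept instrument", {
    set.seed(3)
    tr <- simTruth(n_variants = 100, n_causal = 10, n_causal_out = 0, theta = 0.1, seed = 9)
    sim <- simulatePair(tr)
    ids <- sim$exposure$variant_id[sim$exposure$pval < 1e-4]
    h <- harmonizeInstruments(sim$exposure, sim$outcome, ids)
    hit <- match(h$variant_id, sim$outcome$variant_id)
    expect_equal(abs(h$beta_out), abs(sim$outcome$beta[hit]))
})

test_that("estimates are invariant to arbitrary per-SNP outcome recoding", {
    tr <- simTruth(n_variants = 200, n_causal = 20, n_causal_out = 0, theta = 0.08, seed = 21)
    sim <- simulatePair(tr)
    instr <- screenStrength(clumpInstruments(sim$exposure, sim$ld),
                            sim$exposure)
    # recode every outcome row arbitrarily: random swap and/or strand flip
    out <- as.data.frame(sim$outcome)
    set.seed(77)
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    swap <- runif(nrow(out)) < 0.5
    flip <- runif(nrow(out)) < 0.5
    ea <- out$effect_allele; oa <- out$other_allele
    out$effect_allele <- ifelse(swap, oa, ea)
    out$other_allele <- ifelse(swap, ea, oa)
    out$beta <- ifelse(swap, -out$beta, out$beta)
    out$eaf <- ifelse(swap, 1 - out$eaf, out$eaf)
    out$effect_allele <- ifelse(flip, unname(comp[out$effect_allele]),
                                out$effect_allele)
    out$other_allele <- ifelse(flip, unname(comp[out$other_allele]),
                               out$other_allele)
    h1 <- harmonizeInstruments(sim$exposure, sim$outcome, instr)
    h2 <- harmonizeInstruments(sim$exposure, SumStats(out), instr)
    expect_equal(h1$beta_out, h2$beta_out)
    for (fit in list(mrIVW, mrEgger))
        expect_equal(mrBeta(fit(h1)), mrBeta(fit(h2)))
    expect_equal(mrBeta(mrWeightedMedian(h1, seed = 4)),
                 mrBeta(mrWeightedMedian(h2, seed = 4)))
})
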