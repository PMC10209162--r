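writeFixture <- function(lines) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

test_that("readSumstats parses a well-formed file and canonicalizes it", {
    path <- writeFixture(c(
        "SNP\tCHR\tBP\tA1\tA2\tFRQ\tBETA\tSE\tP",
        "rs1\t1\t1000\ta\tg\t0.2\t0.1\t0.02\t5e-7",
        "rs2\t1\t2000\tC\tT\t0.4\t-0.05\t0.03\t0.096",
        "rs3\t2\t500\tG\ta\t0.1\t0.01\t0.05\t0.84"))
    tab <- readSumstats(path)
    expect_s4_class(tab, "SumStats")
    expect_equal(nrow(tab), 3)
    expect_equal(tab$effect_allele, c("A", "C", "G"))
    expect_equal(tab$other_allele, c("G", "T", "A"))
    expect_equal(tab$beta, c(0.1, -0.05, 0.01))
})

test_that("rows with missing or non-SNP fields are dropped and counted", {
    path <- writeFixture(c(
        "SNP\tCHR\tBP\tA1\tA2\tFRQ\tBETA\tSE\tP",
        "rs1\t1\t1000\tA\tG\t0.2\t0.1\t0.02\t5e-7",
        "rs2\t1\t2000\tC\tT\t0.4\t-0.05\tNA\t0.096",
        "rs3\t1\t3000\tAT\tG\t0.3\t0.02\t0.01\t0.05"))
    expect_message(tab <- readSumstats(path), "dropped 2")
    expect_equal(tab$variant_id, "rs1")
})

test_that("a missing mandatory column is a hard error naming it", {
    path <- writeFixture(c("SNP\tCHR\tBP\tA1\tA2\tFRQ\tSE\tP",
                           "rs1\t1\t1000\tA\tG\t0.2\t0.02\t5e-7"))
    expect_error(readSumstats(path), "beta")
})

test_that("custom column maps and gzip round-trip through write/read", {
    tab <- makeSumStats(c("rs1", "rs2"), beta = c(0.1, -0.2),
                        se = c(0.02, 0.05), eaf = c(0.2, 0.4))
    path <- withr::local_tempfile(fileext = ".tsv.gz")
    writeSumstats(tab, path)
    back <- readSumstats(path)
    expect_equal(as.data.frame(back), as.data.frame(tab)[colnames(back)])
})

test_that("qcFilter applies MAF, ambiguity and INFO filters in order", {
    # six rows: ambiguous A/T; MAF fail; ambiguous C/G; INFO fail; two pass
    df <- data.frame(
        variant_id = paste0("v", 1:6), chrom = "1", pos = 1:6 * 1000,
        effect_allele = c("A", "A", "C", "A", "A", "T"),
        other_allele = c("T", "G", "G", "G", "G", "C"),
        eaf = c(0.50, 0.04, 0.30, 0.30, 0.30, 0.10),
        beta = 0.1, se = 0.02, pval = 0.5,
        info = c(1, 1, 1, 0.5, 0.9, NA))
    res <- qcFilter(SumStats(df))
    expect_equal(res$table$variant_id, c("v5", "v6"))
    expect_equal(res$report@n_removed_maf, 1L)
    expect_equal(res$report@n_removed_ambiguous, 2L)
    expect_equal(res$report@n_removed_info, 1L)
    expect_equal(res$report@n_output, 2L)
})

test_that("each removal is attributed to the first failing filter", {
    # eaf 0.04 AND ambiguous: counted under MAF, not ambiguity
    df <- data.frame(variant_id = "v1", chrom = "1", pos = 1000,
                     effect_allele = "A", other_allele = "T",
                     eaf = 0.04, beta = 0.1, se = 0.02, pval = 0.5)
    rep <- qcFilter(SumStats(df))$report
    expect_equal(rep@n_removed_maf, 1L)
    expect_equal(rep@n_removed_ambiguous, 0L)
})

test_that("biallelic set and external frequencies are honoured", {
    tab <- makeSumStats(c("a", "b", "c"), beta = 0.1, se = 0.02,
                        eaf = c(0.3, 0.3, 0.3))
    res <- qcFilter(tab, biallelic_ids = c("a", "c"))
    expect_equal(res$table$variant_id, c("a", "c"))
    res2 <- qcFilter(tab, external_freq = c(b = 0.01))
    expect_equal(res2$table$variant_id, c("a", "c"))
    expect_equal(res2$report@n_removed_maf, 1L)
})

test_that("qcFilter is idempotent and counts reconcile on fuzzed tables", {
    set.seed(11)
    for (rep in 1:20) {
        n <- sample(5:40, 1)
        pairs <- rbind(c("A", "T"), c("C", "G"), c("A", "G"), c("T", "C"))
        pick <- pairs[sample.int(4, n, replace = TRUE), , drop = FALSE]
        tab <- SumStats(data.frame(
            variant_id = paste0("s", seq_len(n)), chrom = "1",
            pos = seq_len(n), effect_allele = pick[, 1],
            other_allele = pick[, 2], eaf = runif(n, 0, 0.5),
            beta = rnorm(n), se = runif(n, 0.01, 0.1),
            pval = runif(n), info = runif(n, 0.3, 1)))
        res <- qcFilter(tab)
        r <- res$report
        expect_equal(r@n_input - r@n_removed_maf - r@n_removed_nonbiallelic -
                         r@n_removed_ambiguous - r@n_removed_info, r@n_output)
        twice <- qcFilter(res$table)
        expect_equal(as.data.frame(twice$table), as.data.frame(res$table))
        expect_equal(twice$report@n_output, twice$report@n_input)
    }
})

test_that("intersectVariants keeps exactly the shared ids in original order", {
    t1 <- makeSumStats(c("a", "b", "c"), beta = 0.1, se = 0.02)
    t2 <- makeSumStats(c("b", "c", "d"), beta = 0.1, se = 0.02)
    res <- intersectVariants(list(t1, t2))
    expect_equal(res[[1]]$variant_id, c("b", "c"))
    expect_equal(res[[2]]$variant_id, c("b", "c"))
    # identity
    res2 <- intersectVariants(list(t1, t1))
    expect_equal(as.data.frame(res2[[1]]), as.data.frame(t1))
    # three tables sharing only one id
    t3 <- makeSumStats(c("x", "b"), beta = 0.1, se = 0.02)
    res3 <- intersectVariants(list(t1, t2, t3))
    expect_true(all(vapply(res3, nrow, integer(1)) == 1L))
    # permutation invariance as id sets
    resAB <- intersectVariants(list(t1, t2))
    resBA <- intersectVariants(list(t2, t1))
    expect_setequal(resAB[[1]]$variant_id, resBA[[2]]$variant_id)
    # empty intersection errors
    expect_error(intersectVariants(list(t1, makeSumStats("z", 0.1, 0.02))),
                 "shared")
})
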