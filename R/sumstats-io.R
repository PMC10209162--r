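.DEFAULT_COLUMN_MAP <- c(variant_id = "SNP", chrom = "CHR", pos = "BP",
                         effect_allele = "A1", other_allele = "A2",
                         eaf = "FRQ", beta = "BETA", se = "SE", pval = "P",
                         info = "INFO", n = "N")

.AMBIGUOUS_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

#' Read a GWAS summary-statistics file
#'
#' Parses a tab- or whitespace-delimited text file (gzip transparently
#' supported) with one header line into a \linkS4class{SumStats} object with
#' canonical column names. Alleles are upper-cased; rows with missing or
#' unparseable beta, se or alleles, with multi-character (indel) alleles, or
#' with alleles outside A/C/G/T are dropped and counted in a message.
#'
#' @param path path to the file.
#' @param column_map named character vector mapping canonical names
#'   (\code{variant_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#'   \code{info}, \code{n}) to the file's header names. Defaults to the
#'   PLINK-style header SNP/CHR/BP/A1/A2/FRQ/BETA/SE/P/INFO/N. \code{info}
#'   and \code{n} are optional; all others are mandatory.
#' @return A \linkS4class{SumStats} object.
#' @export
readSumstats <- function(path, column_map = .DEFAULT_COLUMN_MAP) {
    if (!file.exists(path)) stop("file not found: ", path)
    map <- .DEFAULT_COLUMN_MAP
    map[names(column_map)] <- column_map
    raw <- utils::read.table(path, header = TRUE, colClasses = "character",
                             check.names = FALSE, comment.char = "")
    mandatory <- setdiff(names(.DEFAULT_COLUMN_MAP), c("info", "n"))
    for (canon in mandatory)
        if (!map[[canon]] %in% colnames(raw))
            stop("missing mandatory column '", canon,
                 "' (expected header '", map[[canon]], "')")
    present <- names(map)[map %in% colnames(raw)]
    df <- stats::setNames(raw[, map[present], drop = FALSE], present)
    numeric_cols <- intersect(c("pos", "eaf", "beta", "se", "pval", "info", "n"),
                              colnames(df))
    for (col in numeric_cols)
        df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    df$effect_allele <- toupper(df$effect_allele)
    df$other_allele <- toupper(df$other_allele)

    n_in <- nrow(df)
    ok <- !is.na(df$beta) & !is.na(df$se) & df$se > 0 &
        !is.na(df$pval) & df$pval > 0 & df$pval <= 1 &
        df$effect_allele %in% .VALID_ALLELES &
        df$other_allele %in% .VALID_ALLELES &
        df$effect_allele != df$other_allele &
        !is.na(df$pos)
    n_dropped <- n_in - sum(ok)
    if (n_dropped > 0)
        message("readSumstats: dropped ", n_dropped,
                " row(s) with missing/unparseable fields or non-SNP alleles")
    df <- df[ok, , drop = FALSE]
    tab <- SumStats(df)

    # internal consistency: p should match 2*pnorm(-|beta/se|) within a
    # factor of 2 (summary files are often rounded); warn, don't fail
    p_expected <- 2 * stats::pnorm(-abs(tab$beta / tab$se))
    suspicious <- p_expected > 1e-300 & tab$pval > 1e-300 &
        (tab$pval / p_expected > 2 | p_expected / tab$pval > 2)
    if (any(suspicious, na.rm = TRUE))
        warning(sum(suspicious, na.rm = TRUE),
                " row(s) have p-values inconsistent with beta/se beyond a factor of 2")
    tab
}

#' Write a SumStats object as tab-delimited text
#'
#' @param tab a \linkS4class{SumStats} object.
#' @param path output path (".gz" suffix triggers gzip).
#' @param column_map named character vector mapping canonical names to output
#'   header names (defaults to the PLINK-style header).
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(tab, path, column_map = .DEFAULT_COLUMN_MAP) {
    stopifnot(is(tab, "SumStats"))
    df <- as.data.frame(tab)
    keep <- intersect(names(column_map), colnames(df))
    out <- stats::setNames(df[, keep, drop = FALSE], column_map[keep])
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Quality-filter a summary-statistics table
#'
#' Applies the pre-instrument QC filters in a fixed order so attrition counts
#' are reproducible: (1) minor-allele frequency \code{min(eaf, 1-eaf) >=
#' maf_min}; (2) membership in a supplied set of biallelic variants (skipped
#' when \code{biallelic_ids} is NULL); (3) removal of strand-ambiguous A/T
#' and C/G pairs; (4) imputation INFO \code{>= info_min} where an info column
#' exists (skipped otherwise). Each removed variant is attributed to the
#' first filter that removes it.
#'
#' @param tab a \linkS4class{SumStats} object.
#' @param biallelic_ids optional character vector of variant ids known to be
#'   biallelic in the reference panel.
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param info_min minimum imputation INFO score (default 0.6).
#' @param external_freq optional named numeric vector of effect-allele
#'   frequencies (e.g. from a reference panel) overriding the table's own
#'   \code{eaf} for the MAF filter only.
#' @return A list with elements \code{table} (the filtered
#'   \linkS4class{SumStats}) and \code{report} (a \linkS4class{QCReport}).
#' @export
qcFilter <- function(tab, biallelic_ids = NULL, maf_min = 0.05,
                     info_min = 0.6, external_freq = NULL) {
    stopifnot(is(tab, "SumStats"))
    n_in <- nrow(tab)
    eaf <- tab$eaf
    if (!is.null(external_freq)) {
        hit <- match(tab$variant_id, names(external_freq))
        eaf <- ifelse(is.na(hit), eaf, external_freq[hit])
    }
    maf_fail <- !is.na(eaf) & pmin(eaf, 1 - eaf) < maf_min
    bi_fail <- if (is.null(biallelic_ids)) rep(FALSE, n_in)
               else !(tab$variant_id %in% biallelic_ids)
    pair <- paste(tab$effect_allele, tab$other_allele, sep = "/")
    amb_fail <- pair %in% .AMBIGUOUS_PAIRS
    info_fail <- if ("info" %in% colnames(tab))
        !is.na(tab$info) & tab$info < info_min else rep(FALSE, n_in)

    # first-filter attribution, in order MAF -> biallelic -> ambiguous -> INFO
    rm_maf <- maf_fail
    rm_bi <- bi_fail & !rm_maf
    rm_amb <- amb_fail & !rm_maf & !rm_bi
    rm_info <- info_fail & !rm_maf & !rm_bi & !rm_amb
    keep <- !(rm_maf | rm_bi | rm_amb | rm_info)

    report <- new("QCReport", n_input = n_in,
                  n_removed_maf = sum(rm_maf),
                  n_removed_nonbiallelic = sum(rm_bi),
                  n_removed_ambiguous = sum(rm_amb),
                  n_removed_info = sum(rm_info),
                  n_output = sum(keep))
    list(table = tab[keep, ], report = report)
}

#' Serialize a QCReport
#'
#' @param report a \linkS4class{QCReport}.
#' @param path optional path; when given, JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
qcReportJSON <- function(report, path = NULL) {
    stopifnot(is(report, "QCReport"))
    x <- list(n_input = report@n_input,
              n_removed_maf = report@n_removed_maf,
              n_removed_nonbiallelic = report@n_removed_nonbiallelic,
              n_removed_ambiguous = report@n_removed_ambiguous,
              n_removed_info = report@n_removed_info,
              n_output = report@n_output)
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(path)) {
        writeLines(json, path)
        return(invisible(json))
    }
    json
}

#' Restrict several tables to their common variants
#'
#' Removes variants that only exist in a subset of the supplied GWAS tables,
#' so that every table covers exactly the shared variant set. Original row
#' order within each table is preserved.
#'
#' @param tables a list of two or more \linkS4class{SumStats} objects.
#' @return A list of \linkS4class{SumStats} objects, same length and order
#'   as the input.
#' @export
intersectVariants <- function(tables) {
    stopifnot(is.list(tables), length(tables) >= 2)
    for (tab in tables) stopifnot(is(tab, "SumStats"))
    shared <- Reduce(intersect, lapply(tables, function(t) t$variant_id))
    if (length(shared) == 0)
        stop("no variants are shared by all tables")
    lapply(tables, function(t) t[t$variant_id %in% shared, ])
}
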