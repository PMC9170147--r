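# File interchange: phased VCF, dosage CSV, pedigree TSV, phenotype CSV,
# and the marker QC filter.

#' Write a population as a phased VCF
#'
#' Emits a VCFv4.2 text file with contig headers from the map, one sample
#' column per individual and phased `GT` (`a|b`, allele 1 = capture-line
#' allele, REF = allele 0).
#'
#' @param pop a `gc_pop`.
#' @param path output path (`.vcf`).
#' @param ids optional sample names.
#' @return the path, invisibly.
#' @export
write_vcf <- function(pop, path, ids = NULL) {
  map <- pop$map
  n <- pop_size(pop)
  ids <- ids %||% sprintf("%s_%04d", pop$type, seq_len(n))
  chroms <- unique(map$chrom)
  lens <- vapply(chroms, function(ch) max(map$pos_bp[map$chrom == ch]), 0)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=chr%d,length=%d>", chroms, as.integer(lens)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  gt <- matrix(paste0(t(pop$geno_a), "|", t(pop$geno_b)), nrow = nrow(map))
  body <- paste(sprintf("chr%d", map$chrom), as.integer(map$pos_bp),
                map$marker, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased VCF into a population
#'
#' Parses with `vcfR`.  When `map` is supplied every record must match a
#' known contig and marker id (an unknown contig is an error naming it);
#' otherwise a map is reconstructed from the VCF coordinates at the
#' default 1 cM/Mb.
#'
#' @param path VCF path.
#' @param map optional `gc_map` to validate against.
#' @param type population tag for the result.
#' @return a `gc_pop`.
#' @export
read_vcf <- function(path, map = NULL, type = "LS") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  chrom <- as.integer(sub("^chr", "", fix[, "CHROM"]))
  if (!is.null(map)) {
    known <- unique(map$chrom)
    bad <- setdiff(unique(fix[, "CHROM"]), sprintf("chr%d", known))
    if (length(bad) > 0) stop_gc("unknown contig in VCF: ", paste(bad, collapse = ", "))
    if (!all(fix[, "ID"] %in% map$marker)) stop_gc("VCF contains markers absent from the map")
  } else {
    map <- data.frame(marker = fix[, "ID"], chrom = chrom,
                      pos_bp = as.numeric(fix[, "POS"]),
                      pos_cM = as.numeric(fix[, "POS"]) * 1e-6,
                      stringsAsFactors = FALSE)
    class(map) <- c("gc_map", "data.frame")
    validate_map(map)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  a <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  b <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  ord <- match(map$marker, fix[, "ID"])
  new_population(t(a[ord, , drop = FALSE]), t(b[ord, , drop = FALSE]),
                 type, map)
}

#' Write / read a dosage matrix as CSV
#'
#' Rows are entries (first column `entry`), remaining columns one marker
#' each with 0/1/2 dosages; missing values are empty cells (`NA`).
#' `read_dosage_csv` validates the coding and reports the offending row
#' and column on failure.
#'
#' @param x a `gc_pop` or dosage matrix with rownames.
#' @param path file path.
#' @export
write_dosage_csv <- function(x, path) {
  d <- if (inherits(x, "gc_pop")) dose_matrix(x) else x
  if (inherits(x, "gc_pop")) {
    rownames(d) <- sprintf("%s_%04d", x$type, seq_len(nrow(d)))
    colnames(d) <- x$map$marker
  }
  df <- data.frame(entry = rownames(d) %||% sprintf("entry_%04d", seq_len(nrow(d))),
                   d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_csv
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  bad <- which(!(is.na(m) | m %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_gc(sprintf("invalid dosage %s at row '%s', column '%s'",
                    m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                    colnames(m)[bad[1, 2]]))
  }
  m
}

#' Write a pedigree table
#'
#' @param pop a `gc_pop`.
#' @param path TSV path (columns individual, type, family, parent).
#' @export
write_pedigree <- function(pop, path) {
  df <- data.frame(individual = sprintf("%s_%04d", pop$type, seq_len(pop_size(pop))),
                   type = pop$type, family = pop$family,
                   parent = pop$parents %||% NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read plot-level phenotypes as long-format CSV
#' @param trial_data a `trial_data` data.frame.
#' @param path CSV path.
#' @export
write_phenotypes <- function(trial_data, path) {
  utils::write.csv(as.data.frame(trial_data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entry", "population", "env", "rep", "value")
  if (!all(need %in% names(df))) {
    stop_gc("phenotype file must have columns ", paste(need, collapse = ", "))
  }
  class(df) <- c("trial_data", "data.frame")
  df
}

#' Marker and individual quality filtering
#'
#' Replicates the standard array-QC rules: markers, then individuals, with
#' more than `max_missing_rate` missing calls are removed; for DH-tagged
#' data, individuals and then markers with more than `max_het_rate_dh`
#' heterozygous calls are additionally removed (rates recomputed after each
#' step) and the remaining heterozygous calls set to missing.  The filter
#' is idempotent.
#'
#' @param genotype_table entries x markers dosage matrix (0/1/2, `NA` =
#'   missing).
#' @param max_missing_rate missing-call threshold (default 0.10).
#' @param max_het_rate_dh heterozygosity threshold for DH data (default
#'   0.05).
#' @param is_dh apply the DH heterozygosity rules.
#' @return list with `genotypes` (filtered matrix) and `report` (counts
#'   removed at each step and heterozygous calls set to missing).
#' @export
qc_filter <- function(genotype_table, max_missing_rate = 0.10,
                      max_het_rate_dh = 0.05, is_dh = FALSE) {
  m <- as.matrix(genotype_table)
  report <- c(markers_missing = 0L, individuals_missing = 0L,
              markers_het = 0L, individuals_het = 0L, het_set_missing = 0L)
  drop_m <- colMeans(is.na(m)) > max_missing_rate
  report[["markers_missing"]] <- sum(drop_m)
  m <- m[, !drop_m, drop = FALSE]
  drop_i <- rowMeans(is.na(m)) > max_missing_rate
  report[["individuals_missing"]] <- sum(drop_i)
  m <- m[!drop_i, , drop = FALSE]
  if (is_dh) {
    het <- m == 1
    drop_i <- rowMeans(het, na.rm = TRUE) > max_het_rate_dh
    report[["individuals_het"]] <- sum(drop_i, na.rm = TRUE)
    m <- m[!drop_i, , drop = FALSE]
    het <- m == 1
    drop_m <- colMeans(het, na.rm = TRUE) > max_het_rate_dh
    report[["markers_het"]] <- sum(drop_m, na.rm = TRUE)
    m <- m[, !drop_m, drop = FALSE]
    het <- which(m == 1)
    report[["het_set_missing"]] <- length(het)
    m[het] <- NA
  }
  if (nrow(m) == 0 || ncol(m) == 0) {
    stop_gc("QC removed everything (report: ",
            paste(names(report), report, sep = "=", collapse = ", "), ")")
  }
  list(genotypes = m, report = report)
}
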