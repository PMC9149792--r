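#' Read a genotype panel from a VCF file
#'
#' Parses GT fields into allele counts. Haploid calls (`0`, `1`, `.`) and
#' diploid calls (`0/0`, `0|1`, `./.`, ...) are both supported; the ploidy
#' mode is detected from the first non-missing genotype unless given.
#' Multi-allelic records are retained (with their comma-separated `alt`
#' field) so that [filter_biallelic()] can be applied downstream; calls
#' carrying an allele index > 1 are counted as carrying a non-reference
#' allele.
#'
#' @param path VCF file (plain text or gzipped).
#' @param ploidy_mode `"auto"` (default), `"haploid"` or `"diploid"`.
#' @return A [genotype_panel()].
#' @export
read_vcf_panel <- function(path, ploidy_mode = c("auto", "haploid",
                                                 "diploid")) {
  ploidy_mode <- match.arg(ploidy_mode)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  if (ploidy_mode == "auto") {
    probe <- gt[!is.na(gt) & !grepl("^\\.", gt)]
    ploidy_mode <- if (length(probe) && grepl("/", probe[1]))
      "diploid" else "haploid"
  }
  count_call <- function(x) {
    if (is.na(x) || x == "." || x == "./.") return(NA_integer_)
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (any(parts == ".")) return(NA_integer_)
    sum(as.integer(parts) > 0L)
  }
  counts <- vapply(gt, count_call, integer(1))
  calls <- t(matrix(counts, nrow = nrow(gt)))  # samples x variants
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], is_cnv = FALSE,
    stringsAsFactors = FALSE)
  genotype_panel(calls, variants, sample_ids = colnames(gt),
                 ploidy_mode = ploidy_mode)
}

#' Write a genotype panel to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only genotype columns. Haploid panels
#' are written with single-allele calls; diploid counts 0/1/2 become
#' `0/0`, `0/1`, `1/1`.
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf_panel <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  if (panel$ploidy == 1L) {
    code <- c("0", "1")
    gt <- matrix(code[panel$calls + 1L], nrow = nrow(panel$calls))
    gt[is.na(panel$calls)] <- "."
  } else {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix(code[panel$calls + 1L], nrow = nrow(panel$calls))
    gt[is.na(panel$calls)] <- "./."
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gwasim",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t"))
  id <- if (is.null(v$id)) paste0(v$chrom, ":", v$pos) else v$id
  body <- paste(v$chrom, v$pos, id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write a PLINK-style transposed text panel
#'
#' The format is a pair of tab-separated files: `<prefix>.variants.tsv`
#' with the per-variant metadata (chrom, pos, id, ref, alt, is_cnv) and
#' `<prefix>.calls.tsv` holding the variants x samples integer call matrix
#' with sample identifiers as header and `NA` for missing calls.
#'
#' @param panel a [genotype_panel()].
#' @param prefix path prefix for the two files.
#' @param ploidy_mode ploidy of the stored calls (for reading).
#' @return `write_panel_table` returns `prefix` invisibly;
#'   `read_panel_table` returns a [genotype_panel()].
#' @export
write_panel_table <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  utils::write.table(panel$variants, paste0(prefix, ".variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- t(panel$calls)
  colnames(calls) <- panel$sample_ids
  utils::write.table(calls, paste0(prefix, ".calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_panel_table
#' @export
read_panel_table <- function(prefix, ploidy_mode = c("haploid", "diploid")) {
  ploidy_mode <- match.arg(ploidy_mode)
  variants <- utils::read.table(paste0(prefix, ".variants.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  calls <- utils::read.table(paste0(prefix, ".calls.tsv"), sep = "\t",
                             header = TRUE, check.names = FALSE)
  genotype_panel(t(as.matrix(calls)), variants,
                 sample_ids = colnames(calls), ploidy_mode = ploidy_mode)
}

#' Read/write phenotype tables
#'
#' Phenotypes travel as tab-separated files with columns `sample_id`,
#' `trait_id`, `value`; the causal ground truth of simulated traits as
#' `trait_id`, `variant_index`, `chrom`, `pos`, `effect`.
#'
#' @param traits a [trait_realization()] or list of them.
#' @param panel the panel the traits were simulated on.
#' @param path output/input file.
#' @return Data frames, written or read.
#' @export
write_phenotypes <- function(traits, panel, path) {
  if (inherits(traits, "trait_realization")) traits <- list(traits)
  rows <- do.call(rbind, lapply(seq_along(traits), function(i) {
    data.frame(sample_id = panel$sample_ids,
               trait_id = paste0("trait", i),
               value = traits[[i]]$phenotype, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}

#' @rdname write_phenotypes
#' @export
write_causal_table <- function(traits, panel, path) {
  if (inherits(traits, "trait_realization")) traits <- list(traits)
  rows <- do.call(rbind, lapply(seq_along(traits), function(i) {
    tr <- traits[[i]]
    data.frame(trait_id = paste0("trait", i),
               variant_index = tr$causal_ids,
               chrom = panel$variants$chrom[tr$causal_ids],
               pos = panel$variants$pos[tr$causal_ids],
               effect = tr$effects, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "value") %in% names(df)))
    stop("phenotype file needs columns sample_id and value")
  df
}

#' Serialize a population config as flat key=value text
#'
#' @param config a [population_config()].
#' @param path output/input file.
#' @return The config (read) or `path` invisibly (write).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "population_config"))
  kv <- c(
    n_samples = config$n_samples, n_variants = config$n_variants,
    genome_length = config$genome_length,
    structure_model = config$structure_model, n_clades = config$n_clades,
    clade_proportions = paste(config$clade_proportions, collapse = ","),
    clade_divergence = paste(config$clade_divergence, collapse = ","),
    recent_clone_fraction = config$recent_clone_fraction,
    clone_divergence = config$clone_divergence,
    singleton_rate = config$singleton_rate,
    maf_shape1 = config$maf_spectrum$shape1,
    maf_shape2 = config$maf_spectrum$shape2,
    missing_rate = config$missing_rate, ploidy_mode = config$ploidy_mode,
    seed = if (is.null(config$seed)) "" else config$seed)
  writeLines(paste0(names(kv), "=", kv), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x)
    paste(x[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1))
  num <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1]])
  population_config(
    n_samples = num("n_samples"), n_variants = num("n_variants"),
    genome_length = num("genome_length"),
    structure_model = vals[["structure_model"]],
    n_clades = num("n_clades"), clade_proportions = num("clade_proportions"),
    clade_divergence = num("clade_divergence"),
    recent_clone_fraction = num("recent_clone_fraction"),
    clone_divergence = num("clone_divergence"),
    singleton_rate = num("singleton_rate"),
    maf_spectrum = list(shape1 = num("maf_shape1"),
                        shape2 = num("maf_shape2")),
    missing_rate = num("missing_rate"), ploidy_mode = vals[["ploidy_mode"]],
    seed = if (nzchar(vals[["seed"]])) as.integer(vals[["seed"]]) else NULL)
}
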