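# Reading and writing genotype data. VCF reading goes through vcfR;
# the TSV AHB matrix format is: marker, chrom, pos, then one column per
# individual with calls A/H/B and "-" for missing.

#' Load a genotype matrix from VCF or TSV
#'
#' VCF input keeps biallelic SNP records only (multiallelic sites are
#' dropped) and converts GT fields to AHB coding (0/0 -> A, 0/1 -> H,
#' 1/1 -> B). Marker names are built as `{chrom}_{pos}`.
#'
#' @param path Path to a `.vcf` (optionally gzipped) or `.tsv` file.
#' @param parents Character vector of the two parent sample names.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @return A [geno_matrix()].
#' @export
load_genotypes <- function(path, parents, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.size(path) > 0) stop("empty input file: ", path)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    if (nrow(vcf@fix) == 0) stop("empty input file: no records in ", path)
    keep <- vcfR::is.biallelic(vcf)
    vcf <- vcf[keep, ]
    gt <- vcfR::extract.gt(vcf, element = "GT")
    chrom <- vcfR::getCHROM(vcf)
    pos <- vcfR::getPOS(vcf)
    code <- function(g) {
      g <- gsub("\\|", "/", g)
      out <- rep(NA_character_, length(g))
      out[g %in% c("0/0")] <- "A"
      out[g %in% c("0/1", "1/0")] <- "H"
      out[g %in% c("1/1")] <- "B"
      out
    }
    calls <- apply(gt, 2, code)
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt),
      dimnames = dimnames(gt))
    markers <- tibble::tibble(
      marker = paste0(chrom, "_", pos), chrom = chrom, pos = pos
    )
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
      stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("empty input file: no records in ", path)
    stopifnot(all(c("marker", "chrom", "pos") %in% names(df)))
    markers <- tibble::as_tibble(df[c("marker", "chrom", "pos")])
    calls <- as.matrix(df[setdiff(names(df), c("marker", "chrom", "pos"))])
    calls[calls %in% c("-", "", "NA", ".")] <- NA_character_
  }
  missing_parents <- setdiff(parents, colnames(calls))
  if (length(missing_parents)) {
    stop("parent column(s) not found: ", paste(missing_parents, collapse = ", "))
  }
  geno_matrix(markers, calls, parents)
}

#' Write a genotype matrix as a TSV AHB table
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(geno, path) {
  calls <- geno$calls
  calls[is.na(calls)] <- "-"
  df <- cbind(as.data.frame(geno$markers), as.data.frame(calls))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 file with GT-only genotype fields. AHB calls map
#' to 0/0, 0/1 and 1/1 on placeholder REF/ALT alleles.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno_vcf <- function(geno, path) {
  gt_map <- c(A = "0/0", H = "0/1", B = "1/1")
  calls <- geno$calls
  gt <- matrix(gt_map[calls], nrow = nrow(calls), dimnames = dimnames(calls))
  gt[is.na(calls)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=binqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", colnames(calls)), collapse = "\t")
  )
  body <- paste(
    geno$markers$chrom, geno$markers$pos, geno$markers$marker,
    "A", "T", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
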