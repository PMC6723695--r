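#' Read and write PLINK bed/bim/fam genotype filesets
#'
#' Minimal reader/writer for the binary PLINK 1 format (SNP-major bed with
#' the 0x6c 0x1b 0x01 magic). Dosage is the count of the A1 allele, which
#' PLINK conventionally makes the minor allele; the bim's allele columns
#' are carried into the map as \code{allele_minor} (A1) and
#' \code{allele_major} (A2), so the sign convention of downstream effect
#' estimates is "per minor allele".
#'
#' @param prefix path without extension; \code{.bed}, \code{.bim},
#'   \code{.fam} are appended.
#' @param genotypes a \code{"genotypes"} object to write.
#' @return \code{read_plink}: a \code{"genotypes"} object;
#'   \code{write_plink}: the prefix, invisibly.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "bp",
                                         "allele_minor", "allele_major"))
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(108L, 27L, 1L)))
    stop("not a SNP-major PLINK bed file")
  bps <- ceiling(n / 4)
  raw <- readBin(con, "raw", bps * m)
  codes <- matrix(0L, 4 * bps, m)
  for (shift in 0:3) {
    bits <- bitwAnd(bitwShiftR(as.integer(raw), 2 * shift), 3L)
    codes[seq(shift + 1, 4 * bps, by = 4), ] <- matrix(bits, bps, m)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1; 10 -> 1; 11 -> 0; 01 -> missing
  dos <- matrix(NA_integer_, n, m, dimnames = list(NULL, bim$snp_id))
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  map <- bim[c("snp_id", "chrom", "bp", "allele_minor", "allele_major")]
  map$chrom <- as.character(map$chrom)
  structure(list(dosage = dos, map = map, fam = fam), class = "genotypes")
}

#' @rdname read_plink
#' @export
write_plink <- function(genotypes, prefix) {
  G <- genotypes$dosage
  map <- genotypes$map
  n <- nrow(G); m <- ncol(G)
  a1 <- if (is.null(map$allele_minor)) rep("A", m) else map$allele_minor
  a2 <- if (is.null(map$allele_major)) rep("G", m) else map$allele_major
  chrom <- if (is.null(map$chrom)) rep("0", m) else as.character(map$chrom)
  bp <- if (is.null(map$bp)) seq_len(m) else map$bp
  utils::write.table(
    data.frame(chrom, map$snp_id, 0, bp, a1, a2),
    paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  utils::write.table(
    data.frame(sprintf("F%05d", seq_len(n)), sprintf("I%05d", seq_len(n)),
               0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  code <- matrix(1L, 4 * ceiling(n / 4), m)  # pad bytes read as missing
  code[seq_len(n), ][is.na(G)] <- 1L
  g <- G; g[is.na(g)] <- -1L
  code[seq_len(n), ][g == 2L] <- 0L
  code[seq_len(n), ][g == 1L] <- 2L
  code[seq_len(n), ][g == 0L] <- 3L
  idx <- seq(1, nrow(code), by = 4)
  bytes <- code[idx, , drop = FALSE] +
    4L * code[idx + 1, , drop = FALSE] +
    16L * code[idx + 2, , drop = FALSE] +
    64L * code[idx + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(108L, 27L, 1L)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read minor-allele dosages from a VCF
#'
#' Thin wrapper over \pkg{vcfR}: parses GT fields and counts ALT alleles,
#' flipping to the minor allele where ALT is the major one so the returned
#' dosage is always a minor-allele count (flips recorded in the map's
#' \code{flipped} column).
#'
#' @param path VCF file (plain or gzipped).
#' @return a \code{"genotypes"} object.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosage needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & x != "./." & x != "."
    al <- strsplit(gsub("\\|", "/", x[ok]), "/")
    out[ok] <- vapply(al, function(a) sum(a == "1"), integer(1))
    out
  }
  dos <- t(apply(gt, 1, count_alt))
  fx <- v@fix
  map <- data.frame(snp_id = fx[, "ID"], chrom = as.character(fx[, "CHROM"]),
                    bp = as.integer(fx[, "POS"]),
                    allele_major = fx[, "REF"], allele_minor = fx[, "ALT"],
                    stringsAsFactors = FALSE)
  flip <- rowMeans(dos, na.rm = TRUE) / 2 > 0.5
  if (any(flip)) {
    dos[flip, ] <- 2L - dos[flip, ]
    tmp <- map$allele_major[flip]
    map$allele_major[flip] <- map$allele_minor[flip]
    map$allele_minor[flip] <- tmp
  }
  map$flipped <- flip
  dos <- t(dos)
  colnames(dos) <- map$snp_id
  structure(list(dosage = dos, map = map), class = "genotypes")
}
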