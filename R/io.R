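# Readers for the standard input formats: PLINK BED/BIM/FAM (SNP-major
# bit-packed), plain integer genotype matrices, and two-column coordinate
# files.

#' Read genotypes from a PLINK BED/BIM/FAM fileset
#'
#' Standard SNP-major bit-packed BED (magic bytes 0x6c 0x1b 0x01); two bits
#' per genotype: 00 = homozygous first allele (dosage 2), 01 = missing,
#' 10 = heterozygous, 11 = homozygous second allele (dosage 0). Returns
#' minor-allele-style dosages counting the first (A1) allele.
#'
#' @param prefix path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return list(genotypes, fam, bim) with genotypes n x p (NA for missing).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"))
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "snp", "cm", "pos", "a1",
                                         "a2"))
  n <- nrow(fam); p <- nrow(bim)
  con <- file(bed, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK BED file: ", bed)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * p)
  if (length(raw) < bytes_per_snp * p) stop("truncated BED file: ", bed)
  # decode 2-bit fields; lookup per byte value for speed
  lut <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) {
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2 * k), 3L)
      lut[b + 1, k + 1] <- switch(code + 1L, 2L, NA_integer_, 1L, 0L)
    }
  }
  G <- matrix(NA_integer_, n, p)
  idx <- as.integer(raw) + 1L
  dim(idx) <- c(bytes_per_snp, p)
  for (j in seq_len(p)) {
    vals <- t(lut[idx[, j], , drop = FALSE])
    G[, j] <- vals[seq_len(n)]
  }
  list(genotypes = G, fam = fam, bim = bim)
}

#' Read a plain whitespace-delimited genotype matrix
#'
#' Header-free layout, one row per sample, integer dosages 0/1/2 (NA allowed
#' only if downstream imputation is enabled).
#'
#' @param path file path.
#' @return integer matrix.
#' @export
read_genotype_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Read sample coordinates
#'
#' Two whitespace-delimited columns (lon lat), one row per sample in the
#' genotype row order.
#'
#' @param path file path.
#' @return n x 2 matrix.
#' @export
read_coords <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 2) stop("coordinate file must have exactly two columns (lon lat)")
  colnames(m) <- c("lon", "lat")
  m
}

#' Write genotypes as a PLINK BED/BIM/FAM fileset
#'
#' @param genotypes n x p dosage matrix (0/1/2).
#' @param prefix output path prefix.
#' @export
write_plink <- function(genotypes, prefix) {
  G <- as.matrix(genotypes)
  n <- nrow(G); p <- ncol(G)
  fam <- data.frame(fid = seq_len(n), iid = seq_len(n), pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  bim <- data.frame(chr = 1, snp = paste0("snp", seq_len(p)), cm = 0,
                    pos = seq_len(p), a1 = "A", a2 = "T")
  utils::write.table(fam, paste0(prefix, ".fam"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(bim, paste0(prefix, ".bim"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  code <- c(`2` = 0L, `NA` = 1L, `1` = 2L, `0` = 3L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(p)) {
    g <- G[, j]
    codes <- ifelse(is.na(g), 1L, code[as.character(g)])
    codes <- c(codes, rep(0L, bytes_per_snp * 4 - n))
    m <- matrix(codes, nrow = 4)
    bytes <- m[1, ] + bitwShiftL(m[2, ], 2) + bitwShiftL(m[3, ], 4) +
      bitwShiftL(m[4, ], 6)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
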