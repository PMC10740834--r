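#' Read / write a plain dosage table
#'
#' Tab-separated dialect for dependency-free exchange: first column `id`,
#' then one column per variant named `<chr>_<bp>_<a1>_<a2>`, values 0/1/2 or
#' NA. All coordinates are 1-based inclusive bp.
#'
#' @param g A [geno_matrix()].
#' @param path File path.
#' @return `write_dosage_tsv` returns the path invisibly; `read_dosage_tsv`
#'   returns a `geno_matrix`.
#' @export
write_dosage_tsv <- function(g, path) {
  hdr <- paste0(g$map$chr, "_", g$map$bp, "_",
                g$map$a1 %||% "A", "_", g$map$a2 %||% "C")
  df <- data.frame(id = rownames(g$dosages), g$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", hdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop2("dosage table must start with an `id` column")
  parts <- strsplit(names(df)[-1], "_", fixed = TRUE)
  if (any(lengths(parts) != 4)) {
    stop2("variant columns must be named <chr>_<bp>_<a1>_<a2>")
  }
  map <- data.frame(chr = as.integer(vapply(parts, `[`, "", 1)),
                    bp = as.integer(vapply(parts, `[`, "", 2)),
                    a1 = vapply(parts, `[`, "", 3),
                    a2 = vapply(parts, `[`, "", 4),
                    stringsAsFactors = FALSE)
  d <- as.matrix(df[-1])
  rownames(d) <- df$id
  storage.mode(d) <- "double"
  geno_matrix(d, map)
}

#' Read / write a phenotype table
#'
#' CSV with columns `id`, the trait, and the fixed-effect factors.
#'
#' @param pheno Phenotype data frame.
#' @param path File path.
#' @param trait Trait column name expected on read.
#' @param factors Factor column names expected on read.
#' @return Path (write) or the phenotype data frame (read).
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path, trait = "trait",
                                factors = c("year", "season", "sex", "farm")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", trait, factors), names(df))
  if (length(miss)) {
    stop2("phenotype file lacks columns: ", paste(miss, collapse = ", "))
  }
  df
}

#' Read / write GWAS summary statistics
#'
#' Tab-separated with header columns CHR, BP, A1, BETA, SE, Z, P, N. On
#' read, CHR, BP, BETA, SE and P are required (A1 optional); rows with
#' non-finite BETA or SE are dropped with a message, and p-values are
#' clamped to (1e-300, 1].
#'
#' @param stats A `summary_stats` data frame.
#' @param path File path.
#' @return Path (write) or a `summary_stats` data frame (read).
#' @export
write_summary_stats_tsv <- function(stats, path) {
  out <- data.frame(CHR = stats$chr, BP = stats$bp, A1 = stats$a1,
                    BETA = stats$beta, SE = stats$se, Z = stats$z,
                    P = stats$p, N = stats$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats_tsv
#' @export
read_summary_stats_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("CHR", "BP", "BETA", "SE", "P")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop2(sprintf("summary statistics lack column(s) %s; found: %s",
                  paste(miss, collapse = ", "),
                  paste(names(df), collapse = ", ")))
  }
  ok <- is.finite(df$BETA) & is.finite(df$SE)
  if (any(!ok)) {
    message(sum(!ok), " row(s) with non-finite BETA/SE dropped")
    df <- df[ok, , drop = FALSE]
  }
  n_clamped <- sum(df$P <= 1e-300 | df$P > 1, na.rm = TRUE)
  if (n_clamped) message(n_clamped, " p-value(s) clamped to (1e-300, 1]")
  out <- data.frame(chr = df$CHR, bp = df$BP,
                    a1 = df$A1 %||% NA_character_,
                    beta = df$BETA, se = df$SE,
                    z = df$Z %||% (df$BETA / df$SE),
                    p = pmin(pmax(df$P, 1e-300), 1),
                    n = df$N %||% NA_integer_,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Read / write a kernel matrix as TSV
#'
#' Square matrix with the individual ids as header row and first column.
#'
#' @param K A `kernel_matrix`.
#' @param path File path.
#' @param label Label to attach on read.
#' @return Path (write) or a `kernel_matrix` (read).
#' @export
write_kernel_tsv <- function(K, path) {
  df <- data.frame(id = rownames(K), unclass(K), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path, label = "G") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[-1])
  rownames(M) <- df$id
  if (!identical(rownames(M), colnames(M))) {
    stop2("kernel row and column ids disagree")
  }
  kernel_matrix(M, label)
}

# ---- PLINK binary (.bed/.bim/.fam) ----
# SNP-major .bed with the standard 2-bit encoding, one variant per
# ceil(n/4)-byte block, low bits first:
#   00 -> two copies of allele 1 (dosage 2)   01 -> missing
#   10 -> heterozygous (dosage 1)             11 -> no copy of allele 1 (0)

plink_decode_table <- function() {
  # 256 x 4 dosage lookup, one row per byte value
  codes <- c(2, NA, 1, 0)
  t(vapply(0:255, function(b) {
    codes[c(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
            bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L)) + 1L]
  }, numeric(4)))
}

#' Write a genotype panel as PLINK .bed/.bim/.fam
#'
#' @param g A [geno_matrix()].
#' @param prefix Path prefix; `.bed`, `.bim` and `.fam` are appended. Allele
#'   1 in the files is the counted (dosage) allele.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(g, prefix) {
  n <- n_individuals(g)
  m <- n_variants(g)
  ids <- rownames(g$dosages)
  bim <- data.frame(chr = g$map$chr, id = variant_ids(g$map), cm = 0,
                    bp = g$map$bp, a1 = g$map$a1 %||% "A",
                    a2 = g$map$a2 %||% "C")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = ids, iid = ids, pat = 0, mat = 0, sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code_for <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # dosage -> 2-bit code
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per <- ceiling(n / 4)
  for (j in seq_len(m)) {
    d <- g$dosages[, j]
    code <- ifelse(is.na(d), 1L, code_for[as.character(d)])
    code <- c(code, rep(0L, bytes_per * 4 - n))
    idx <- seq(1, length(code), by = 4)
    byte <- code[idx] + bitwShiftL(code[idx + 1], 2L) +
      bitwShiftL(code[idx + 2], 4L) + bitwShiftL(code[idx + 3], 6L)
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam fileset
#'
#' Validates the magic bytes and the SNP-major flag, checks the file length
#' against the .bim/.fam row counts, and decodes dosages of allele 1.
#'
#' @param prefix Path prefix (companion `.bim` and `.fam` must exist).
#' @return A [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop2("missing PLINK file: ", f)
  }
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE,
                              col.names = c("chr", "id", "cm", "bp", "a1", "a2"))
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pat", "mat",
                                            "sex", "phe"))
  if (anyDuplicated(fam_df$iid)) stop2("duplicate individual ids in ", fam)
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop2("not a PLINK .bed file (bad magic bytes): ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop2("only SNP-major .bed supported: ", bed)
  bytes_per <- ceiling(n / 4)
  if (length(raw) - 3 != bytes_per * m) {
    stop2(sprintf("%s is truncated or does not match %d individuals x %d variants",
                  bed, n, m))
  }
  lut <- plink_decode_table()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bytes_per, ncol = m)
  d <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    vals <- t(lut[body[, j] + 1L, , drop = FALSE])
    d[, j] <- as.numeric(vals)[seq_len(n)]
  }
  rownames(d) <- fam_df$iid
  geno_matrix(d, bim_df[c("chr", "bp", "a1", "a2")])
}
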