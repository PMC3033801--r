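# Genotype containers and file readers/writers.
#
# The package works on 0/1/2 minor-allele dosage matrices with a binary
# phenotype. Two on-disk dialects are supported: PLINK-style text PED/MAP
# pairs and a self-describing TSV dialect (see write_genotypes_tsv) whose
# round-trip is exact.

#' Construct a genotype dataset
#'
#' @param dosages numeric matrix `n x P`, entries in `{0, 1, 2, NA}` (NA =
#'   missing genotype), coded as minor-allele counts.
#' @param y binary phenotype vector, 1 = affected, 0 = unaffected.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `minor_allele`, `major_allele`.
#' @param samples character vector of sample ids (default `s1..sn`).
#' @return object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, y, snps, samples = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  P <- ncol(dosages)
  y <- as.integer(y)
  if (length(y) != n) stop("phenotype length must equal the number of samples")
  if (!all(y %in% c(0L, 1L))) stop("phenotype must be coded 0/1")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (nrow(snps) != P) stop("snps table must have one row per dosage column")
  bad <- snps$pos < 1
  if (any(bad)) stop("SNP positions must be >= 1: ", paste(snps$snp_id[bad], collapse = ", "))
  same <- snps$minor_allele == snps$major_allele
  if (any(same)) stop("minor and major allele identical for: ",
                      paste(snps$snp_id[same], collapse = ", "))
  samples <- samples %||% paste0("s", seq_len(n))
  colnames(dosages) <- snps$snp_id
  rownames(dosages) <- samples
  structure(list(samples = samples, y = y, dosages = dosages,
                 snps = snps), class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases / %d controls), %d SNPs, %d missing calls\n",
              length(x$samples), sum(x$y), sum(1 - x$y), ncol(x$dosages),
              sum(is.na(x$dosages))))
  invisible(x)
}

# Recode a PED phenotype column to 0/1. Accepts PLINK 1/2 (unaffected /
# affected) or already-binary 0/1.
recode_phenotype <- function(ph) {
  ph <- as.integer(ph)
  if (all(ph %in% c(1L, 2L))) return(ph - 1L)
  if (all(ph %in% c(0L, 1L))) return(ph)
  stop("phenotype column must be coded 1/2 (PLINK) or 0/1; got values: ",
       paste(sort(unique(ph)), collapse = ", "))
}

read_ped_map <- function(path) {
  ped_path <- paste0(path, ".ped")
  map_path <- paste0(path, ".map")
  if (!file.exists(ped_path) || !file.exists(map_path))
    stop("PED/MAP pair not found at prefix: ", path)
  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf < 4L))
    stop("malformed MAP line ", which(nf < 4L)[1L], " in ", map_path)
  P <- length(map_fields)
  map <- data.frame(
    chrom = vapply(map_fields, `[`, "", 1L),
    snp_id = vapply(map_fields, `[`, "", 2L),
    pos = as.integer(vapply(map_fields, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * P
  nf <- lengths(fields)
  if (any(nf != want))
    stop("malformed PED line ", which(nf != want)[1L], ": expected ", want,
         " fields, got ", nf[which(nf != want)[1L]])
  n <- length(fields)
  samples <- vapply(fields, `[`, "", 2L)
  y <- recode_phenotype(vapply(fields, `[`, "", 6L))
  # alleles as an n x 2P character matrix
  al <- t(vapply(fields, function(f) f[-(1:6)], character(2L * P)))
  a1 <- al[, seq(1L, 2L * P, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * P, by = 2L), drop = FALSE]
  dos <- matrix(NA_real_, n, P)
  minor <- major <- character(P)
  for (j in seq_len(P)) {
    obs <- c(a1[, j], a2[, j])
    called <- obs != "0"
    alleles <- sort(unique(obs[called]))
    if (length(alleles) > 2L)
      stop("non-biallelic SNP rejected: ", map$snp_id[j],
           " (alleles ", paste(alleles, collapse = "/"), ")")
    if (length(alleles) == 0L)
      stop("SNP with no called genotypes: ", map$snp_id[j])
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    f1 <- mean(obs[called] == alleles[1L])
    # allele with frequency <= 0.5 is minor; exact tie -> lexicographically
    # smaller allele (alleles are sorted, so alleles[1]) is minor
    if (f1 <= 0.5) { minor[j] <- alleles[1L]; major[j] <- alleles[2L] }
    else { minor[j] <- alleles[2L]; major[j] <- alleles[1L] }
    if (minor[j] == major[j]) major[j] <- "N"  # monomorphic SNP
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dj <- (a1[, j] == minor[j]) + (a2[, j] == minor[j])
    dj[miss] <- NA_real_
    dos[, j] <- dj
  }
  snps <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                     minor_allele = minor, major_allele = major,
                     stringsAsFactors = FALSE)
  genotype_dataset(dos, y, snps, samples)
}

read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop("genotype TSV not found: ", path)
  lines <- readLines(path)
  meta <- grep("^##SNP\t", lines, value = TRUE)
  if (length(meta) == 0L) stop("no ##SNP metadata lines in ", path)
  mf <- strsplit(meta, "\t", fixed = TRUE)
  if (any(lengths(mf) != 6L))
    stop("malformed ##SNP line ", which(lengths(mf) != 6L)[1L], " in ", path)
  snps <- data.frame(
    snp_id = vapply(mf, `[`, "", 2L),
    chrom = vapply(mf, `[`, "", 3L),
    pos = as.integer(vapply(mf, `[`, "", 4L)),
    minor_allele = vapply(mf, `[`, "", 5L),
    major_allele = vapply(mf, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "sample_id" || header[2L] != "phenotype")
    stop("genotype TSV header must start with sample_id, phenotype")
  if (!identical(header[-(1:2)], snps$snp_id))
    stop("TSV column order disagrees with ##SNP metadata")
  rows <- fields[-1L]
  nf <- lengths(rows)
  if (any(nf != length(header)))
    stop("malformed genotype TSV data line ", which(nf != length(header))[1L])
  samples <- vapply(rows, `[`, "", 1L)
  y <- recode_phenotype(vapply(rows, `[`, "", 2L))
  dos <- t(vapply(rows, function(r) suppressWarnings(as.numeric(r[-(1:2)])),
                  numeric(nrow(snps))))
  if (nrow(snps) == 1L) dos <- matrix(dos, ncol = 1L)
  genotype_dataset(dos, y, snps, samples)
}

#' Read case-control genotypes
#'
#' Reads a 0/1/2 minor-allele dosage dataset either from a PLINK-style text
#' PED/MAP pair (whitespace-delimited; `0` = missing allele; phenotype column
#' coded 1/2 and recoded to 0/1) or from the package's TSV dialect written by
#' [write_genotypes_tsv()]. For PED input, the minor allele of each SNP is
#' determined from the sample itself: the allele with frequency <= 0.5 is
#' minor, exact ties resolved to the lexicographically smaller allele.
#'
#' @param path for `ped_map`, the file prefix (reads `<path>.ped` and
#'   `<path>.map`); for `tsv`, the file path.
#' @param format `"ped_map"` or `"tsv"`.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("ped_map", "tsv")) {
  format <- match.arg(format)
  switch(format, ped_map = read_ped_map(path), tsv = read_genotype_tsv(path))
}

#' Write genotypes in the package TSV dialect
#'
#' Self-describing tab-separated format: `##SNP` comment lines carry SNP
#' metadata (id, chromosome, position, minor and major allele), followed by a
#' `sample_id phenotype <snp...>` table of dosages with `NA` for missing.
#' [read_genotypes()] round-trips this format exactly.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  meta <- sprintf("##SNP\t%s\t%s\t%d\t%s\t%s", ds$snps$snp_id, ds$snps$chrom,
                  ds$snps$pos, ds$snps$minor_allele, ds$snps$major_allele)
  header <- paste(c("sample_id", "phenotype", ds$snps$snp_id), collapse = "\t")
  body <- vapply(seq_along(ds$samples), function(i) {
    paste(c(ds$samples[i], ds$y[i],
            ifelse(is.na(ds$dosages[i, ]), "NA",
                   format(ds$dosages[i, ], trim = TRUE, scientific = FALSE))),
          collapse = "\t")
  }, character(1L))
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' Write genotypes as a PED/MAP pair
#'
#' @param ds a [genotype_dataset()].
#' @param prefix output prefix (writes `<prefix>.ped` and `<prefix>.map`).
#' @return `prefix`, invisibly.
#' @export
write_genotypes_ped <- function(ds, prefix) {
  stopifnot(inherits(ds, "genotype_dataset"))
  writeLines(sprintf("%s\t%s\t0\t%d", ds$snps$chrom, ds$snps$snp_id,
                     ds$snps$pos), paste0(prefix, ".map"))
  n <- length(ds$samples)
  lines <- vapply(seq_len(n), function(i) {
    g <- ds$dosages[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, ds$snps$minor_allele,
                                       ds$snps$major_allele))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, ds$snps$minor_allele,
                                       ds$snps$major_allele))
    paste(c(ds$samples[i], ds$samples[i], "0", "0", "0", ds$y[i] + 1L,
            as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1L))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read a gene position table
#'
#' Four tab-separated columns with header: `gene_id`, `chrom`, `start`,
#' `end` (1-based inclusive base pairs).
#'
#' @param path TSV file path.
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(g)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (any(g$start > g$end)) stop("gene with start > end: ",
                                 g$gene_id[g$start > g$end][1L])
  g$chrom <- as.character(g$chrom)
  g
}

#' Read a per-SNP functional-category table
#'
#' Three tab-separated columns with header: `snp_id`, `gene_id`, `category`
#' (one of coding, intronic, utr5, utr3). Used by [map_snps_to_genes()] for
#' the hierarchical assignment tie-break.
#'
#' @param path TSV file path.
#' @return data.frame of category records.
#' @export
read_snp_categories <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("snp_id", "gene_id", "category")
  if (!all(need %in% names(x)))
    stop("category table must have columns: ", paste(need, collapse = ", "))
  bad <- !x$category %in% c("coding", "intronic", "utr5", "utr3")
  if (any(bad)) stop("unknown SNP category: ",
                     paste(unique(x$category[bad]), collapse = ", "))
  x
}

#' Drop SNPs inside a chromosome interval
#'
#' Optional exclusion filter (e.g. to remove a region with overwhelming
#' signal, such as the MHC, before pathway testing).
#'
#' @param ds a [genotype_dataset()].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval bounds.
#' @return a [genotype_dataset()] without the excluded SNPs.
#' @export
exclude_interval <- function(ds, chrom, start, end) {
  drop <- ds$snps$chrom == chrom & ds$snps$pos >= start & ds$snps$pos <= end
  if (all(drop)) stop("exclusion interval removes every SNP")
  genotype_dataset(ds$dosages[, !drop, drop = FALSE], ds$y,
                   ds$snps[!drop, , drop = FALSE], ds$samples)
}
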