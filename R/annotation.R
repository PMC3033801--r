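# SNP -> gene and gene -> pathway annotation.

CATEGORY_RANK <- c(coding = 1L, intronic = 2L, utr5 = 3L, utr3 = 4L)

#' Map SNPs to genes within a window
#'
#' A SNP is assigned to a gene when its position lies within `window_bp`
#' base pairs of the gene body (1-based inclusive coordinates:
#' `start - window_bp <= pos <= end + window_bp`). A SNP falling within the
#' window of several genes is resolved by a hierarchical functional-category
#' scheme (coding > intronic > 5'utr > 3'utr; genes without a category
#' annotation for the SNP rank below all annotated ones), then by smallest
#' distance to the gene body, then by lexicographic gene id. Each SNP is
#' assigned to at most one gene.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @param window_bp assignment window in base pairs (default 5000).
#' @param categories optional data.frame (`snp_id`, `gene_id`, `category`
#'   with values in coding/intronic/utr5/utr3) used for the hierarchical
#'   tie-break; when absent the tie-break degrades to distance then gene id.
#' @return object of class `gene_map`: list with `assignments` (named list,
#'   gene id -> integer vector of SNP column indices), `unmapped` (integer
#'   vector of SNP indices assigned to no gene) and `n_snps`.
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 5000, categories = NULL) {
  P <- nrow(snps)
  cat_key <- NULL
  if (!is.null(categories)) {
    bad <- !categories$category %in% names(CATEGORY_RANK)
    if (any(bad)) stop("unknown SNP category: ",
                       paste(unique(categories$category[bad]), collapse = ", "))
    cat_key <- stats::setNames(CATEGORY_RANK[categories$category],
                               paste(categories$snp_id, categories$gene_id))
  }
  assigned <- rep(NA_character_, P)
  for (i in seq_len(P)) {
    hit <- which(genes$chrom == snps$chrom[i] &
                   genes$start - window_bp <= snps$pos[i] &
                   snps$pos[i] <= genes$end + window_bp)
    if (length(hit) == 0L) next
    if (length(hit) > 1L) {
      rank <- rep(5L, length(hit))  # unannotated ranks below utr3
      if (!is.null(cat_key)) {
        r <- cat_key[paste(snps$snp_id[i], genes$gene_id[hit])]
        rank[!is.na(r)] <- r[!is.na(r)]
      }
      dist <- pmax(0L, genes$start[hit] - snps$pos[i],
                   snps$pos[i] - genes$end[hit])
      hit <- hit[order(rank, dist, genes$gene_id[hit])][1L]
    }
    assigned[i] <- genes$gene_id[hit]
  }
  assignments <- lapply(genes$gene_id, function(g) which(assigned == g))
  names(assignments) <- genes$gene_id
  assignments <- assignments[lengths(assignments) > 0L]
  structure(list(assignments = assignments,
                 unmapped = which(is.na(assigned)),
                 n_snps = P),
            class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  cat(sprintf("gene_map: %d of %d SNPs mapped to %d genes (%d unmapped)\n",
              x$n_snps - length(x$unmapped), x$n_snps,
              length(x$assignments), length(x$unmapped)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set id, description, then one gene id per field.
#' Duplicate genes within a line are dropped (first occurrence kept, order
#' preserved).
#'
#' @param path GMT file.
#' @return object of class `pathway_collection`: named list of
#'   `list(name = <description>, genes = <character vector>)`.
#' @export
read_pathways <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed GMT line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  pw <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    list(name = f[2L], genes = unique(genes))
  })
  names(pw) <- vapply(fields, `[`, "", 1L)
  structure(pw, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- vapply(x, function(p) length(p$genes), integer(1L))
  cat(sprintf("pathway_collection: %d pathways, %d-%d genes each\n",
              length(x), if (length(x)) min(sizes) else 0L,
              if (length(x)) max(sizes) else 0L))
  invisible(x)
}

#' Filter pathways by number of mapped genes
#'
#' Retains pathways with at least `min_genes` member genes that carry one or
#' more mapped SNPs, and restricts each retained pathway's gene list to those
#' mapped genes (testing overly narrow pathways is avoided by the size
#' floor).
#'
#' @param pc a [read_pathways()] collection.
#' @param gm a [map_snps_to_genes()] gene map.
#' @param min_genes minimum number of mapped genes (default 15).
#' @return filtered `pathway_collection`.
#' @export
filter_pathways <- function(pc, gm, min_genes = 15) {
  mapped <- names(gm$assignments)
  keep <- lapply(pc, function(p) {
    g <- p$genes[p$genes %in% mapped]
    if (length(g) >= min_genes) list(name = p$name, genes = g) else NULL
  })
  keep <- keep[!vapply(keep, is.null, logical(1L))]
  structure(keep, class = "pathway_collection")
}
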