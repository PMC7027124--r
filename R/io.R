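# File interfaces: per-source VCFs with GT/DP, tab-separated clinical,
# annotation, expression and driver tables, and the planted-truth JSON.

#' Write a genotype/depth call set as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with FORMAT fields GT and DP, one sample column
#' per patient, 1-based positions, and the alternate-dosage convention
#' GT = 0/0, 0/1, 1/1 (./. for unknown calls).
#'
#' @param calls a [source_call_set()].
#' @param variants annotation table supplying chrom/pos/ref/alt per variant.
#' @param path output path.
#' @export
write_vcf <- function(calls, variants, path) {
  g <- calls$genotypes; d <- calls$depth
  ann <- variants[match(colnames(g), variants$variant_id), ]
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  body <- matrix(paste0(gt, ":", d), nrow(g), ncol(g))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=germscan:%s", calls$source),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g)), collapse = "\t")), con)
  for (j in seq_len(ncol(g))) {
    writeLines(paste(c(ann$chrom[j], ann$pos[j], ann$variant_id[j], ann$ref[j],
                       ann$alt[j], ".", "PASS", ".", "GT:DP", body[, j]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a per-source VCF into a call set
#'
#' Parses GT and DP with vcfR. Multi-allelic records are split into one
#' bi-allelic variant per alternate allele; the dosage counts that allele.
#' Missing or malformed genotypes become unknown (NA).
#'
#' @param path VCF path.
#' @param source source label for the call set.
#' @return a [source_call_set()] plus attribute `variants` (chrom/pos/ref/
#'   alt/variant_id table parsed from the records).
#' @export
read_vcf_calls <- function(path, source) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  geno_list <- list(); depth_list <- list(); ann_rows <- list(); k <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gsub("\\|", "/", gt_raw[i, ]), "/", fixed = TRUE)
    for (a in seq_along(alts)) {
      dos <- vapply(alleles, function(al) {
        if (length(al) != 2L || any(al == ".")) return(NA_integer_)
        sum(al == as.character(a))
      }, 0L)
      k <- k + 1L
      geno_list[[k]] <- dos
      depth_list[[k]] <- dp_raw[i, ]
      id <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") fix$ID[i] else
        paste0(fix$CHROM[i], ":", fix$POS[i])
      ann_rows[[k]] <- data.frame(
        variant_id = if (length(alts) > 1) paste0(id, "_", alts[a]) else id,
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a], stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, ann_rows)
  g <- do.call(cbind, geno_list)
  d <- do.call(cbind, depth_list)
  d[is.na(d)] <- 0
  colnames(g) <- colnames(d) <- ann$variant_id
  cs <- source_call_set(source, g, d)
  attr(cs, "variants") <- ann
  cs
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read/write tab-separated tables with a stable column contract
#'
#' @param x data.frame (or matrix with row names for `write_matrix_tsv`).
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @param id_column name for the row-name column.
#' @export
write_matrix_tsv <- function(x, path, id_column = "id") {
  df <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write_tsv(df, path)
}

#' @rdname write_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Serialize / restore the planted truth of a simulation
#'
#' The effect plan is written as JSON next to the simulated data so every
#' downstream check can compare estimates against the planted values.
#'
#' @param plan an [effect_plan()].
#' @param path JSON path.
#' @export
write_truth <- function(plan, path) {
  x <- unclass(plan)
  # named numerics as JSON objects, not nameless arrays
  x$variant_effects <- as.list(x$variant_effects)
  x$covariate_effects <- as.list(x$covariate_effects)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (length(v)) unlist(v) else numeric()
  effect_plan(variant_effects = num(x$variant_effects),
              covariate_effects = num(x$covariate_effects),
              eqtl_effects = as.list(x$eqtl_effects),
              driver_assoc = as.list(x$driver_assoc),
              baseline_scale = x$baseline_scale,
              baseline_shape = x$baseline_shape,
              censoring_rate = x$censoring_rate)
}

#' Read a transcript model from a BED12 file
#'
#' Converts BED12 rows (0-based half-open) into the 1-based inclusive
#' transcript table used by [classify_region()]: thickStart/thickEnd become
#' the CDS and the block fields become exons.
#'
#' @param path BED12 path.
#' @return transcripts data.frame.
#' @export
read_gene_model <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(b) < 12L) .stopf("expected a 12-column BED file")
  rows <- lapply(seq_len(nrow(b)), function(i) {
    starts <- as.numeric(strsplit(b[i, 12], ",")[[1]])
    sizes <- as.numeric(strsplit(b[i, 11], ",")[[1]])
    es <- b[i, 2] + starts + 1L          # to 1-based inclusive
    ee <- b[i, 2] + starts + sizes
    data.frame(tx_id = b[i, 4], chrom = b[i, 1], strand = b[i, 6],
               tx_start = b[i, 2] + 1L, tx_end = b[i, 3],
               cds_start = b[i, 7] + 1L, cds_end = b[i, 8],
               exon_starts = paste(es, collapse = ","),
               exon_ends = paste(ee, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
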