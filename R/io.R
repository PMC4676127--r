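# File interchange: VCF, BED, TSV ----------------------------------------

#' Write a cohort (or any variant set) as VCF 4.2
#'
#' Emits diploid genotypes (`GT`, unphased) and per-sample depth (`DP`).
#' The ancestral allele is written as the `AA` INFO tag, and optionally as
#' a sidecar TSV (`scaffold`, `pos`, `allele`).
#'
#' @param vs variant set with `sites`, `geno` and `depth`.
#' @param path output VCF path.
#' @param ancestral_path optional path for the ancestral-allele TSV.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(vs, path, ancestral_path = NULL) {
  check_variant_set(vs, need_depth = TRUE)
  samples <- colnames(vs$geno) %||% sprintf("ind%d", seq_len(ncol(vs$geno)))
  gt_txt <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  if (nrow(vs$sites) > 0) {
    body <- vapply(seq_len(nrow(vs$sites)), function(i) {
      cells <- paste0(gt_txt[vs$geno[i, ] + 1L], ":", vs$depth[i, ])
      paste(c(vs$sites$scaffold[i], vs$sites$pos[i], ".",
              vs$sites$anc[i], vs$sites$der[i], ".", "PASS",
              paste0("AA=", vs$sites$anc[i]), "GT:DP", cells),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  if (!is.null(ancestral_path))
    write.table(
      data.frame(scaffold = vs$sites$scaffold, pos = vs$sites$pos,
                 allele = vs$sites$anc),
      ancestral_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VCF into a variant set
#'
#' Uses `vcfR` to parse the file and returns the package's variant-set
#' layout (`sites`, dosage `geno`, `depth`).
#'
#' @param path VCF path.
#' @return variant set list.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sites <- data.frame(scaffold = fix$CHROM, pos = as.integer(fix$POS),
                      anc = fix$REF, der = fix$ALT, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  dp <- suppressWarnings(
    matrix(as.integer(vcfR::extract.gt(v, "DP")), nrow(gt), ncol(gt),
           dimnames = dimnames(gt)))
  rownames(dose) <- rownames(dp) <- NULL
  list(sites = sites, geno = dose, depth = dp)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data.frame with `scaffold`, `start`, `end` and optionally
#'   further columns (written after the first three).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  first <- c("scaffold", "start", "end")
  df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open intervals)
#'
#' @param path BED path.
#' @param extra_names names for columns beyond the third, if present.
#' @return data.frame `scaffold`, `start`, `end`, plus extras.
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("scaffold", "start", "end")
  if (!is.null(extra_names) && ncol(df) >= 3 + length(extra_names))
    names(df)[3 + seq_along(extra_names)] <- extra_names
  df
}

#' Write and read per-position depth tracks
#'
#' Plain TSV with columns `scaffold`, `pos` (1-based), `depth`.
#'
#' @param track data.frame depth track.
#' @param path file path.
#' @export
write_depth_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_track
#' @export
read_depth_track <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write codon alignments as FASTA
#'
#' @param alignment named character vector of sequences.
#' @param path output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(alignment)), path)
  invisible(path)
}

#' Read a FASTA alignment into a named character vector
#'
#' @param path FASTA path.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
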