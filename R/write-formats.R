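#' Write genotypes to VCF
#'
#' Emits a minimal standards-conformant VCF 4.2 with GT-only genotype fields
#' (missing calls as `./.`), re-readable by [read_genotypes()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path (`.vcf`; use an uncompressed path).
#' @param chrom_lengths Optional named lengths written as `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, chrom_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow = nrow(gm$sites), ncol = length(gm$samples))
  ok <- !is.na(gm$calls)
  body[ok] <- gt_str[gm$calls[ok] + 1L]
  fixed <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
                 ".", "PASS", ".", "GT", sep = "\t")
  rows <- do.call(paste, c(list(fixed), asplit(body, 2), list(sep = "\t")))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kinwin",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(rows, con)
  invisible(path)
}

#' Write genotypes to PLINK PED+MAP
#'
#' Writes `<prefix>.ped` and `<prefix>.map` (4-column MAP plus two extra
#' columns carrying the ref and alt alleles, so allele coding round-trips).
#' Missing genotypes become `0 0`.
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @param ped Optional pedigree tibble supplying family/parent/sex columns
#'   for the PED preamble; unknowns are written as 0.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_ped_map <- function(gm, prefix, ped = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  writeLines(paste(gm$sites$chrom, paste0("s", seq_len(nrow(gm$sites))), 0,
                   gm$sites$pos, gm$sites$ref, gm$sites$alt, sep = "\t"),
             map_path)
  allele1 <- c("ref", "ref", "alt")
  allele2 <- c("ref", "alt", "alt")
  pre <- preamble_for(gm$samples, ped)
  lines <- vapply(seq_along(gm$samples), function(j) {
    g <- gm$calls[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g == 0, gm$sites$ref,
                                       ifelse(g == 1, gm$sites$ref, gm$sites$alt)))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 0, gm$sites$ref, gm$sites$alt))
    paste(pre[[j]], paste(rbind(a1, a2), collapse = " "), sep = " ")
  }, "")
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

preamble_for <- function(samples, ped) {
  vapply(samples, function(id) {
    if (!is.null(ped) && id %in% ped$id) {
      r <- ped[ped$id == id, ]
      paste(r$fam, id, r$father %|0|% "0", r$mother %|0|% "0", r$sex, "-9")
    } else {
      paste("FAM1", id, 0, 0, 0, "-9")
    }
  }, "")
}

`%|0|%` <- function(x, y) if (is.na(x)) y else x

#' Write genotypes to PLINK TPED (+TFAM)
#'
#' @inheritParams write_ped_map
#' @return Named character vector of the two paths, invisibly.
#' @export
write_tped <- function(gm, prefix, ped = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tped_path <- paste0(prefix, ".tped")
  tfam_path <- paste0(prefix, ".tfam")
  n <- nrow(gm$sites)
  allele_rows <- vapply(seq_len(n), function(i) {
    g <- gm$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g == 2, gm$sites$alt[[i]], gm$sites$ref[[i]]))
    a2 <- ifelse(is.na(g), "0", ifelse(g >= 1, gm$sites$alt[[i]], gm$sites$ref[[i]]))
    paste(rbind(a1, a2), collapse = " ")
  }, "")
  writeLines(paste(gm$sites$chrom, paste0("s", seq_len(n)), 0, gm$sites$pos,
                   allele_rows, sep = " "), tped_path)
  writeLines(preamble_for(gm$samples, ped), tfam_path)
  invisible(c(tped = tped_path, tfam = tfam_path))
}

CALLS_HEADER <- c("sample1", "sample2", "n_windows", "n_high_p2", "peak_flag",
                  "n_iw", "frac_contig_iw", "max_run", "predicted_label")

#' Write / read a relationship-call results table
#'
#' Tab-separated results file with one row per classified pair: the five
#' tree statistics plus the predicted label. An empty input writes a
#' header-only file.
#'
#' @param calls A tibble as returned by [relate_pairs()] (columns `sample1`,
#'   `sample2`, the [pair_metrics()] columns and `label`).
#' @param path Output path.
#' @return `write_calls()` returns `path` invisibly; `read_calls()` returns
#'   the tibble.
#' @export
write_calls <- function(calls, path) {
  if (is.null(calls) || nrow(as.data.frame(calls)) == 0) {
    writeLines(paste(CALLS_HEADER, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- tibble::as_tibble(calls)
  out$predicted_label <- as.character(out$label)
  out <- out[, CALLS_HEADER]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample1 = "c", sample2 = "c", peak_flag = "l",
                           predicted_label = "c", .default = "d"
                         ))
  out$label <- factor(out$predicted_label, levels = relationship_levels())
  out
}

#' Write / read a pair-truth table
#'
#' @param truth A tibble from [pair_truth()].
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(id1 = "c", id2 = "c", kinship = "d",
                                          degree = "i", label = "c"))
}
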