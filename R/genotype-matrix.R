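#' Construct a genotype matrix
#'
#' The central genotype container: biallelic SNV calls for a set of samples,
#' stored as alt-allele counts. Rows are sites (sorted by chromosome, then
#' position), columns are samples; `NA` encodes a missing (not fully called)
#' genotype.
#'
#' @param sites A data frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt` (single-character allele strings).
#' @param samples Character vector of sample IDs (unique).
#' @param calls Integer matrix, `nrow(sites)` x `length(samples)`, values in
#'   `{0, 1, 2, NA}` (count of alt alleles).
#' @return An object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(
#'   sites = tibble::tibble(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G"),
#'   samples = c("s1", "s2"),
#'   calls = matrix(c(0L, 1L, 2L, NA), nrow = 2)
#' )
#' gm
#' @export
genotype_matrix <- function(sites, samples, calls) {
  sites <- tibble::as_tibble(sites)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    is.matrix(calls),
    nrow(calls) == nrow(sites),
    ncol(calls) == length(samples),
    !anyDuplicated(samples)
  )
  if (nrow(sites) > 0 && any(sites$pos < 1)) {
    stop("site positions must be >= 1", call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  # canonical order: chromosome (order of first appearance), then position
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  colnames(calls) <- samples
  structure(
    list(sites = sites, samples = as.character(samples), calls = calls),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d sites x %d samples (%s)\n",
    nrow(x$sites), length(x$samples),
    if (nrow(x$sites)) paste0("chrom ", paste(unique(x$sites$chrom), collapse = ",")) else "empty"
  ))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  samples: %s\n", paste(head(x$samples, 8), collapse = ", ")))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$samples))

# internal row subset
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$sites[idx, , drop = FALSE], gm$samples,
                  gm$calls[idx, , drop = FALSE])
}

check_samples <- function(gm, ids) {
  missing <- setdiff(ids, gm$samples)
  if (length(missing)) {
    stop("unknown sample ID(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Restrict a genotype matrix to sites fully called in a pair
#'
#' Keeps exactly the sites where neither member of the pair has a missing
#' genotype; site order is preserved. The operation is symmetric in the two
#' sample IDs.
#'
#' @param gm A [genotype_matrix()].
#' @param a,b Sample IDs present in `gm`.
#' @return A `genotype_matrix` containing all samples but only the co-called
#'   sites for the pair.
#' @export
filter_pair_sites <- function(gm, a, b) {
  check_samples(gm, c(a, b))
  keep <- !is.na(gm$calls[, a]) & !is.na(gm$calls[, b])
  subset_sites(gm, which(keep))
}
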