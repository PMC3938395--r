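#' Classification statistics for many pairs
#'
#' Computes the five tree statistics ([pair_metrics()]) for each requested
#' pair of samples. When the genotype matrix has no missing calls a fast
#' vectorised path is used that tiles the genome once and tallies IBS states
#' per window for each pair; with missing data each pair falls back to
#' [filter_pair_sites()] + [window_ibs()].
#'
#' @param gm A [genotype_matrix()].
#' @param pairs Two-column data frame (or matrix) of sample IDs; `NULL` means
#'   all unordered pairs, enumerated in lexicographic order and reported once.
#' @inheritParams window_ibs
#' @return A tibble with `sample1`, `sample2` and the [pair_metrics()]
#'   columns.
#' @export
pairwise_metrics <- function(gm, pairs = NULL, chrom_lengths = NULL,
                             window_size = 1e6, se = 0,
                             p0_cutoff = p0_cutoff_for(se), min_sites = 10,
                             autosomes_only = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(pairs)) {
    ids <- sort(gm$samples)
    pairs <- t(utils::combn(ids, 2))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(pairs) >= 2)
  id1 <- as.character(pairs[[1]])
  id2 <- as.character(pairs[[2]])
  check_samples(gm, unique(c(id1, id2)))

  fast <- !anyNA(gm$calls)
  if (fast) {
    metrics <- fast_pairwise_metrics(gm, id1, id2, chrom_lengths, window_size,
                                     p0_cutoff, min_sites, autosomes_only)
  } else {
    metrics <- purrr::map2_dfr(id1, id2, function(a, b) {
      track <- window_ibs(filter_pair_sites(gm, a, b), c(a, b),
                          chrom_lengths = chrom_lengths,
                          window_size = window_size, p0_cutoff = p0_cutoff,
                          min_sites = min_sites,
                          autosomes_only = autosomes_only)
      pair_metrics(track)
    })
  }
  dplyr::bind_cols(tibble::tibble(sample1 = id1, sample2 = id2), metrics)
}

# Vectorised all-pairs path for fully called matrices. Window membership,
# per-window totals and adjacency structure are shared across pairs.
fast_pairwise_metrics <- function(gm, id1, id2, chrom_lengths, window_size,
                                  p0_cutoff, min_sites, autosomes_only) {
  keep_site <- if (autosomes_only) is_autosome(gm$sites$chrom) else
    rep(TRUE, nrow(gm$sites))
  chrom <- gm$sites$chrom[keep_site]
  pos <- gm$sites$pos[keep_site]
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(pos, factor(chrom, levels = unique(chrom)), max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  windows <- make_windows(chrom_lengths, window_size)
  gid <- site_window_gid(chrom, pos, windows, window_size)
  ok <- !is.na(gid)
  gid <- gid[ok]
  nb <- nrow(windows)
  nvec <- tabulate(gid, nbins = nb)
  keep_win <- nvec >= max(1L, min_sites)
  if (!any(keep_win)) {
    stop("insufficient marker density: no window reaches min_sites = ",
         min_sites, call. = FALSE)
  }
  w_chrom <- windows$chrom[keep_win]
  w_index <- windows$index[keep_win]
  n_w <- nvec[keep_win]
  # TRUE at i when retained window i is genomically adjacent to window i-1
  prev_same <- c(FALSE, w_chrom[-1] == w_chrom[-length(w_chrom)] &
                   w_index[-1] == w_index[-length(w_index)] + 1L)
  nwin <- length(n_w)

  one_pair <- function(a, b) {
    d <- abs(gm$calls[keep_site, a][ok] - gm$calls[keep_site, b][ok])
    n0 <- tabulate(gid[d == 2L], nbins = nb)[keep_win]
    n2 <- tabulate(gid[d == 0L], nbins = nb)[keep_win]
    P0 <- n0 / n_w
    P2 <- n2 / n_w
    iw <- if (p0_cutoff == 0) P0 == 0 else P0 < p0_cutoff

    counts <- tabulate(p2_bin(P2), nbins = 100L)
    n_iw <- sum(iw)
    nb_prev <- c(FALSE, iw[-nwin]) & prev_same
    nb_next <- c(iw[-1], FALSE) & c(prev_same[-1], FALSE)
    # runs of IWs over genomically adjacent windows
    blk <- cumsum(!prev_same)
    z <- ifelse(iw, blk, -seq_len(nwin))
    r <- rle(z)
    max_run <- if (any(r$values > 0)) max(r$lengths[r$values > 0]) else 0L
    tibble::tibble(
      n_windows = nwin,
      n_high_p2 = sum(P2 > 0.8),
      peak_flag = max(counts[81:100]) > max(counts[1:80]),
      n_iw = n_iw,
      frac_contig_iw = if (n_iw > 0) sum(iw & (nb_prev | nb_next)) / n_iw else 0,
      max_run = max_run
    )
  }
  purrr::map2_dfr(id1, id2, one_pair)
}

#' Estimate relationships for sample pairs
#'
#' The end-to-end estimator: computes the window-level IBS statistics for
#' each pair and runs them through the calibrated classification tree.
#'
#' @inheritParams pairwise_metrics
#' @inheritParams classify_pairs
#' @return A tibble with `sample1`, `sample2`, the pair statistics, `label`,
#'   `degree` and `note`.
#' @examples
#' \dontrun{
#' gm <- read_genotypes("cohort.vcf", format = "vcf")
#' relate_pairs(gm, se = 0.001)
#' }
#' @export
relate_pairs <- function(gm, pairs = NULL, thresholds = default_thresholds(),
                         chrom_lengths = NULL, window_size = 1e6, se = 0,
                         p0_cutoff = p0_cutoff_for(se), min_sites = 10,
                         min_windows = 100, autosomes_only = TRUE) {
  m <- pairwise_metrics(gm, pairs = pairs, chrom_lengths = chrom_lengths,
                        window_size = window_size, p0_cutoff = p0_cutoff,
                        min_sites = min_sites, autosomes_only = autosomes_only)
  classify_pairs(m, thresholds, min_windows = min_windows)
}
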