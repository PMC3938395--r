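# histogram bin index for the P2 peak comparison: width 0.01 over (0, 1]
p2_bin <- function(P2) pmin(pmax(ceiling(P2 * 100), 1L), 100L)

#' Classification-tree statistics for one pair
#'
#' Reduces a pair's per-window IBS track (the output of [window_ibs()]) to the
#' five statistics consumed by the relationship classifier:
#'
#' * `n_windows` — number of retained windows;
#' * `n_high_p2` — windows with P2 in (0.8, 1], the signature of IBD2 tracts
#'   in sibling (and twin/self) comparisons;
#' * `peak_flag` — whether the P2 histogram peak over (0.8, 1] exceeds the
#'   peak over (0, 0.8] (bin width 0.01);
#' * `n_iw` — number of identity windows;
#' * `frac_contig_iw` — fraction of IWs adjacent (same chromosome, consecutive
#'   window index) to another IW;
#' * `max_run` — length of the longest within-chromosome run of consecutive
#'   IWs.
#'
#' Adjacency is never counted across a chromosome boundary, and a dropped
#' (low-density) window between two IWs breaks contiguity.
#'
#' @param track A window tibble from [window_ibs()] (columns `chrom`, `index`,
#'   `P2`, `is_iw`).
#' @return A one-row tibble with the five statistics.
#' @examples
#' tr <- tibble::tibble(
#'   chrom = "1", index = 0:5, P2 = 1,
#'   is_iw = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
#' )
#' pair_metrics(tr)
#' @export
pair_metrics <- function(track) {
  if (is.null(track) || nrow(track) == 0) {
    stop("empty window track", call. = FALSE)
  }
  stopifnot(all(c("chrom", "index", "P2", "is_iw") %in% names(track)))
  track <- dplyr::arrange(track, match(.data$chrom, unique(.data$chrom)), .data$index)

  n_windows <- nrow(track)
  n_high_p2 <- sum(track$P2 > 0.8)

  # P2 histogram over (0, 1], bin width 0.01; P2 = 0 folded into the lowest
  # bin. Narrow bins keep the IBD2 mass (P2 at or near 1) in few bins while
  # the broad IBD1/IBD0 mass spreads, which is what the peak comparison needs.
  counts <- tabulate(p2_bin(track$P2), nbins = 100L)
  peak_flag <- max(counts[81:100]) > max(counts[1:80])

  per_chrom <- track %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(
      n_iw = sum(.data$is_iw),
      n_adj = {
        iw <- .data$is_iw
        idx <- .data$index
        nb_prev <- c(FALSE, iw[-length(iw)] & diff(idx) == 1L)
        nb_next <- c(iw[-1] & diff(idx) == 1L, FALSE)
        sum(iw & (nb_prev | nb_next))
      },
      max_run = {
        iw <- .data$is_iw
        idx <- .data$index
        # a run continues only over consecutive window indices
        grp <- cumsum(c(TRUE, diff(idx) != 1L))
        best <- 0L
        for (g in unique(grp)) {
          r <- rle(iw[grp == g])
          if (any(r$values)) best <- max(best, max(r$lengths[r$values]))
        }
        best
      },
      .groups = "drop"
    )

  n_iw <- sum(per_chrom$n_iw)
  tibble::tibble(
    n_windows = n_windows,
    n_high_p2 = n_high_p2,
    peak_flag = peak_flag,
    n_iw = n_iw,
    frac_contig_iw = if (n_iw > 0) sum(per_chrom$n_adj) / n_iw else 0,
    max_run = max(per_chrom$max_run)
  )
}
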