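#' Identity-by-state class of a genotype pair
#'
#' IBS2 when the two genotypes are identical, IBS1 when they share exactly one
#' allele, IBS0 when they share none (one homozygous reference, the other
#' homozygous alternate). For alt-allele-count codes this is `2 - |ga - gb|`.
#'
#' @param ga,gb Integer genotype codes in `{0, 1, 2}` (vectorised). Missing
#'   genotypes are a contract violation: filter the pair's sites first with
#'   [filter_pair_sites()].
#' @return Integer vector of IBS states in `{0, 1, 2}`.
#' @examples
#' ibs_state(c(0, 0, 0, 1), c(0, 1, 2, 2))
#' @export
ibs_state <- function(ga, gb) {
  if (anyNA(ga) || anyNA(gb)) {
    stop("ibs_state() requires fully called genotypes; pre-filter missing calls",
         call. = FALSE)
  }
  if (!all(ga %in% 0:2) || !all(gb %in% 0:2)) {
    stop("genotype codes must be 0, 1 or 2", call. = FALSE)
  }
  2L - abs(as.integer(ga) - as.integer(gb))
}

#' Tile chromosomes into fixed-size windows
#'
#' Segments each chromosome into non-overlapping windows of `window_size` bp
#' (default 1 Mb, the whole-genome-sequencing setting; 2 Mb is the usual
#' choice for genotyping-array density). Windows are half-open
#' `[start, end)` on 1-based coordinates, so a site at position `pos` belongs
#' to window index `floor((pos - 1) / window_size)` within its chromosome.
#' The last window of a chromosome may be shorter.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param window_size Window width in bp (> 0).
#' @return A tibble with columns `chrom`, `start`, `end` (exclusive), `index`
#'   (0-based ordinal within chromosome) and `gid` (global window id).
#' @examples
#' make_windows(c(`1` = 2.5e6), window_size = 1e6)
#' @export
make_windows <- function(chrom_lengths, window_size = 1e6) {
  if (length(chrom_lengths) == 0) stop("chrom_lengths is empty", call. = FALSE)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be named by chromosome", call. = FALSE)
  }
  stopifnot(window_size > 0, all(chrom_lengths > 0))
  per_chrom <- purrr::imap(as.list(chrom_lengths), function(len, chrom) {
    n <- ceiling(len / window_size)
    idx <- seq_len(n) - 1L
    tibble::tibble(
      chrom = chrom,
      start = idx * window_size + 1,
      end = pmin(idx * window_size + window_size, len) + 1,
      index = idx
    )
  })
  out <- dplyr::bind_rows(per_chrom)
  out$gid <- seq_len(nrow(out))
  out
}

# Map sites onto global window ids for a given window table.
# Returns NA for sites on chromosomes absent from `windows`.
site_window_gid <- function(chrom, pos, windows, window_size) {
  offsets <- windows %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(first_gid = min(.data$gid), n_win = dplyr::n(), .groups = "drop")
  m <- match(norm_chrom(chrom), norm_chrom(offsets$chrom))
  idx <- (pos - 1) %/% window_size
  gid <- offsets$first_gid[m] + idx
  gid[!is.na(m) & idx >= offsets$n_win[m]] <- NA # beyond stated chromosome length
  gid
}

#' P0 cutoff schedule as a function of sequencing error
#'
#' Returns the identity-window threshold on P0 for a per-genotype sequencing
#' error rate `se`. At the four calibrated anchor points
#' SE = (0, 0.001, 0.005, 0.01) the schedule is exactly
#' (0, 0.004, 0.01, 0.015); between anchors the cutoff is interpolated
#' linearly, and above SE = 0.01 it is extended proportionally (1.5 * se,
#' the anchor ratio at 0.01). The schedule is non-decreasing in `se`.
#'
#' @param se Per-genotype error rate(s), `0 <= se < 0.5`.
#' @return Numeric vector of P0 cutoffs.
#' @examples
#' p0_cutoff_for(c(0, 0.001, 0.005, 0.01))
#' @export
p0_cutoff_for <- function(se) {
  if (any(is.na(se)) || any(se < 0) || any(se >= 0.5)) {
    stop("se must satisfy 0 <= se < 0.5", call. = FALSE)
  }
  anchors_se <- c(0, 0.001, 0.005, 0.01)
  anchors_cut <- c(0, 0.004, 0.01, 0.015)
  out <- numeric(length(se))
  inside <- se <= 0.01
  if (any(inside)) {
    out[inside] <- approx(anchors_se, anchors_cut, xout = se[inside],
                          method = "linear", ties = "ordered")$y
  }
  out[!inside] <- 1.5 * se[!inside]
  out
}

#' Per-window IBS fractions and identity-window calls for one pair
#'
#' Tallies the IBS state of every co-called site of a pair within each genomic
#' window and derives the window-level fractions P0, P1, P2 (shares of sites
#' in IBS0/IBS1/IBS2). A window is flagged as an identity window (IW) —
#' evidence that the pair shares at least one haplotype across it — when its
#' P0 falls below `p0_cutoff`. The comparison is strict (`P0 < p0_cutoff`);
#' the error-free setting `p0_cutoff = 0` is special-cased to `P0 == 0`, since
#' error-free shared windows have exactly zero IBS0 sites.
#'
#' Windows with fewer than `min_sites` co-called sites are dropped from the
#' result (and from every downstream metric).
#'
#' @param gm A [genotype_matrix()].
#' @param pair Character vector of two sample IDs.
#' @param chrom_lengths Named lengths used for window tiling; defaults to the
#'   maximum observed position per chromosome.
#' @param window_size Window width in bp. Default 1 Mb (WGS); use 2 Mb for
#'   array-density data.
#' @param se Per-genotype sequencing error rate; sets the default `p0_cutoff`
#'   via [p0_cutoff_for()].
#' @param p0_cutoff Identity-window threshold on P0.
#' @param min_sites Minimum co-called sites for a window to be retained
#'   (default 10; 5 is a reasonable floor for array-density data).
#' @param autosomes_only Drop sites on non-autosomal chromosomes (default TRUE).
#' @return A tibble with one row per retained window: `chrom`, `start`, `end`,
#'   `index`, `gid`, counts `n0`, `n1`, `n2`, `n`, fractions `P0`, `P1`, `P2`
#'   and the logical `is_iw`.
#' @export
window_ibs <- function(gm, pair, chrom_lengths = NULL, window_size = 1e6,
                       se = 0, p0_cutoff = p0_cutoff_for(se), min_sites = 10,
                       autosomes_only = TRUE) {
  stopifnot(length(pair) == 2)
  check_samples(gm, pair)
  ga <- gm$calls[, pair[[1]]]
  gb <- gm$calls[, pair[[2]]]
  keep <- !is.na(ga) & !is.na(gb)
  if (autosomes_only) keep <- keep & is_autosome(gm$sites$chrom)
  if (!any(keep)) stop("no co-called sites for pair ", paste(pair, collapse = "/"),
                       call. = FALSE)
  chrom <- gm$sites$chrom[keep]
  pos <- gm$sites$pos[keep]
  d <- abs(ga[keep] - gb[keep]) # 0 -> IBS2, 1 -> IBS1, 2 -> IBS0

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(pos, factor(chrom, levels = unique(chrom)), max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  windows <- make_windows(chrom_lengths, window_size)
  gid <- site_window_gid(chrom, pos, windows, window_size)
  ok <- !is.na(gid)
  gid <- gid[ok]
  d <- d[ok]
  nb <- nrow(windows)

  out <- windows
  out$n2 <- tabulate(gid[d == 0L], nbins = nb)
  out$n1 <- tabulate(gid[d == 1L], nbins = nb)
  out$n0 <- tabulate(gid[d == 2L], nbins = nb)
  out$n <- out$n0 + out$n1 + out$n2
  out <- dplyr::filter(out, .data$n >= max(1L, min_sites))
  if (nrow(out) == 0) {
    stop("insufficient marker density: no window reaches min_sites = ",
         min_sites, call. = FALSE)
  }
  out <- dplyr::mutate(out,
    P0 = .data$n0 / .data$n,
    P1 = .data$n1 / .data$n,
    P2 = .data$n2 / .data$n,
    is_iw = if (p0_cutoff == 0) .data$P0 == 0 else .data$P0 < p0_cutoff
  )
  attr(out, "pair") <- as.character(pair)
  attr(out, "window_size") <- window_size
  attr(out, "p0_cutoff") <- p0_cutoff
  dplyr::select(out, "chrom", "start", "end", "index", "gid",
                "n0", "n1", "n2", "n", "P0", "P1", "P2", "is_iw")
}
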