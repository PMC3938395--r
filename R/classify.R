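#' Classification-tree threshold set
#'
#' Container for the numeric thresholds of the relationship tree. Normally
#' produced by [calibrate_thresholds()] rather than constructed by hand.
#'
#' @param twin_gate Minimum `n_high_p2 / n_windows` ratio for an identical
#'   twin / self call.
#' @param high_p2_min Minimum `n_high_p2` count (with `peak_flag`) for a
#'   full-sibling call.
#' @param iw_frac_cuts Named, strictly decreasing cutpoints on
#'   `n_iw / n_windows` separating PO, D2, D3, D4 and D5 (names
#'   `"PO","D2","D3","D4","D5"`); a pair at or above a cut gets that label.
#' @param contig_frac_min,max_run_min Gates distinguishing
#'   related-at-unknown-distance (UD) from unrelated (UN) below the D5 cut:
#'   UD if `frac_contig_iw >= contig_frac_min` **or** `max_run >= max_run_min`.
#' @param meta Optional named list of provenance fields (se, p0_cutoff, ...).
#' @export
kin_thresholds <- function(twin_gate = 0.95, high_p2_min, iw_frac_cuts,
                           contig_frac_min, max_run_min, meta = list()) {
  stopifnot(
    length(iw_frac_cuts) == 5,
    identical(names(iw_frac_cuts), c("PO", "D2", "D3", "D4", "D5")),
    all(diff(iw_frac_cuts) < 0),
    all(iw_frac_cuts >= 0 & iw_frac_cuts <= 1),
    twin_gate > 0, twin_gate <= 1,
    contig_frac_min >= 0, contig_frac_min <= 1,
    max_run_min >= 0
  )
  structure(
    list(
      twin_gate = twin_gate, high_p2_min = high_p2_min,
      iw_frac_cuts = iw_frac_cuts, contig_frac_min = contig_frac_min,
      max_run_min = max_run_min, meta = meta
    ),
    class = "kin_thresholds"
  )
}

#' @export
print.kin_thresholds <- function(x, ...) {
  cat("<kin_thresholds>\n")
  cat(sprintf("  twin gate (high-P2 window fraction) : %.4g\n", x$twin_gate))
  cat(sprintf("  full-sibling minimum high-P2 count  : %.4g\n", x$high_p2_min))
  cat("  IW-fraction cuts:\n")
  for (nm in names(x$iw_frac_cuts)) {
    cat(sprintf("    >= %-8.5f -> %s\n", x$iw_frac_cuts[[nm]], nm))
  }
  cat(sprintf("  UD gates: frac_contig_iw >= %.4g or max_run >= %.4g\n",
              x$contig_frac_min, x$max_run_min))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.kin_thresholds <- function(x, ...) {
  tibble::tibble(
    parameter = c(
      "twin_gate", "high_p2_min",
      paste0("iw_frac_cut_", names(x$iw_frac_cuts)),
      "contig_frac_min", "max_run_min"
    ),
    value = c(x$twin_gate, x$high_p2_min, unname(x$iw_frac_cuts),
              x$contig_frac_min, x$max_run_min)
  )
}

#' @export
glance.kin_thresholds <- function(x, ...) {
  tibble::tibble(
    n_train = x$meta$n_train %||% NA_integer_,
    train_accuracy = x$meta$train_accuracy %||% NA_real_,
    se = x$meta$se %||% NA_real_,
    p0_cutoff = x$meta$p0_cutoff %||% NA_real_
  )
}

relationship_levels <- function() c("IT", "FS", "PO", "D2", "D3", "D4", "D5", "UD", "UN")

degree_of_label <- function(label) {
  map <- c(IT = 0L, FS = 1L, PO = 1L, D2 = 2L, D3 = 3L, D4 = 4L, D5 = 5L,
           UD = NA_integer_, UN = NA_integer_)
  unname(map[label])
}

# Best 1-D decision boundary: classify x >= cut as "high". Among the cuts that
# maximise accuracy on the two labelled samples, pick the one closest to the
# midpoint of the gap between the class-conditional ranges (the exact midpoint
# when the classes are separable).
best_cut <- function(x_hi, x_lo) {
  stopifnot(length(x_hi) > 0, length(x_lo) > 0)
  vals <- sort(unique(c(x_hi, x_lo)))
  cand <- if (length(vals) > 1) (head(vals, -1) + tail(vals, -1)) / 2 else vals
  cand <- unique(c(cand, min(vals) - 1, max(vals) + 1))
  acc <- vapply(cand, function(cut) sum(x_hi >= cut) + sum(x_lo < cut), numeric(1))
  best <- cand[acc == max(acc)]
  mid <- (max(x_lo) + min(x_hi)) / 2
  best[which.min(abs(best - mid))]
}

#' Calibrate classification-tree thresholds from labelled pairs
#'
#' Learns the numeric thresholds of the relationship tree from pair statistics
#' with known true labels (normally pairs from one simulated training family,
#' mirroring how the method was originally trained). Each decision boundary is
#' a one-dimensional cut chosen to maximise exact-label accuracy between the
#' two classes it separates, with ties broken toward the midpoint of the gap
#' between the class-conditional ranges, so the procedure is deterministic
#' given the input.
#'
#' Required classes: `IT`, `FS`, `PO`, `D2`, `D3`, `D4`, `D5`, `UN`. Pairs
#' labelled `UD` (related, degree 6+) are used, together with `UN` pairs, to
#' set the contiguity gates; when absent, conservative defaults are kept.
#'
#' @param metrics A data frame of pair statistics (columns of
#'   [pair_metrics()]) plus a `true_label` column with values among
#'   `IT, FS, PO, D2, D3, D4, D5, UD, UN`.
#' @param true_label Name of the column holding the true labels.
#' @param twin_gate Identical-twin gate on the high-P2 window fraction; kept
#'   fixed (default 0.95) rather than fitted, since self/twin pairs sit at 1.
#' @param meta Named list of provenance fields stored with the thresholds.
#' @return A `kin_thresholds` object; `tidy()` lists the fitted cutpoints and
#'   `glance()` reports training accuracy.
#' @export
calibrate_thresholds <- function(metrics, true_label = "true_label",
                                 twin_gate = 0.95, meta = list()) {
  lab <- as.character(metrics[[true_label]])
  required <- c("IT", "FS", "PO", "D2", "D3", "D4", "D5", "UN")
  missing <- setdiff(required, unique(lab))
  if (length(missing)) {
    stop("calibration data lacks class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  r_iw <- metrics$n_iw / metrics$n_windows

  # sibling gate on the high-P2 window count, FS vs everything non-FS/IT
  high_p2_min <- best_cut(
    metrics$n_high_p2[lab == "FS"],
    metrics$n_high_p2[!lab %in% c("FS", "IT")]
  )

  # IW-fraction ladder: one cut per adjacent class boundary
  ladder <- c("PO", "D2", "D3", "D4", "D5")
  below_classes <- c("UD", "UN")
  cuts <- vapply(seq_along(ladder), function(i) {
    hi <- r_iw[lab == ladder[[i]]]
    lo_lab <- if (i < length(ladder)) ladder[[i + 1]] else below_classes
    best_cut(hi, r_iw[lab %in% lo_lab])
  }, numeric(1))
  names(cuts) <- ladder
  if (any(diff(cuts) >= 0)) {
    # adjacent classes overlap (sparse or low-density training data): force a
    # strictly decreasing ladder, conceding the overlapping boundaries
    warning("overlapping training classes; IW-fraction cuts adjusted to a ",
            "strictly decreasing ladder", call. = FALSE)
    for (i in 2:length(cuts)) {
      cuts[[i]] <- min(cuts[[i]], cuts[[i - 1]] - 1e-6)
    }
  }

  # UD-vs-UN contiguity gates (OR rule)
  if (any(lab == "UD")) {
    max_run_min <- best_cut(metrics$max_run[lab == "UD"],
                            metrics$max_run[lab == "UN"])
    # a cut above 1 means the contiguity fraction cannot separate the classes;
    # pin the gate shut at 1 (only fully contiguous tracks pass it)
    contig_frac_min <- min(1, max(0, best_cut(
      metrics$frac_contig_iw[lab == "UD"],
      metrics$frac_contig_iw[lab == "UN"]
    )))
  } else {
    max_run_min <- 2
    contig_frac_min <- 0.5
  }

  th <- kin_thresholds(
    twin_gate = twin_gate, high_p2_min = high_p2_min, iw_frac_cuts = cuts,
    contig_frac_min = contig_frac_min, max_run_min = max_run_min, meta = meta
  )
  pred <- classify_pairs(metrics, th)$label
  th$meta$n_train <- length(lab)
  th$meta$train_accuracy <- mean(pred == lab, na.rm = TRUE)
  th
}

#' Relationship call from pair statistics
#'
#' Applies the calibrated classification tree to one or more rows of pair
#' statistics. Decision order: (1) identical twin / self if the fraction of
#' high-P2 windows exceeds the twin gate; (2) full sibling if the P2 histogram
#' peak lies in the high region or the high-P2 window count clears its
#' calibrated minimum (either IBD2 signal suffices);
#' (3) otherwise the IW fraction `n_iw / n_windows` is mapped through the
#' decreasing cutpoint ladder to PO, D2, ..., D5; (4) below the D5 cut the
#' pair is called UD (related, unknown distance) if there is contiguity
#' evidence, else UN (unrelated).
#'
#' Pairs with fewer than `min_windows` retained windows get `NA` label and a
#' `"insufficient windows"` note instead of a call.
#'
#' @param metrics Data frame with the [pair_metrics()] columns (extra columns
#'   are carried through).
#' @param thresholds A `kin_thresholds` object (default: the packaged
#'   thresholds calibrated on a simulated training family at SE = 0).
#' @param min_windows Minimum retained window count for any call (default 100).
#' @return The input tibble with `label` (factor over
#'   `IT, FS, PO, D2..D5, UD, UN`), `degree` (0-5 or NA) and `note` columns
#'   appended.
#' @export
classify_pairs <- function(metrics, thresholds = default_thresholds(),
                           min_windows = 100) {
  stopifnot(inherits(thresholds, "kin_thresholds"))
  need <- c("n_windows", "n_high_p2", "peak_flag", "n_iw", "frac_contig_iw", "max_run")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("metrics lack column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  t <- thresholds
  out <- tibble::as_tibble(metrics)
  r_high <- out$n_high_p2 / out$n_windows
  r_iw <- out$n_iw / out$n_windows

  label <- rep(NA_character_, nrow(out))
  note <- rep(NA_character_, nrow(out))

  ok <- out$n_windows >= min_windows
  note[!ok] <- "insufficient windows"

  is_it <- ok & r_high > t$twin_gate
  # Either sibling signal suffices: the peak comparison loses sensitivity as
  # genotyping error smears the IBD2 spike, while the high-P2 count keeps a
  # wide margin over non-sibling classes; both are near-perfectly specific.
  is_fs <- ok & !is_it & (out$peak_flag | out$n_high_p2 >= t$high_p2_min)
  label[is_it] <- "IT"
  label[is_fs] <- "FS"

  rest <- ok & !is_it & !is_fs
  for (nm in names(t$iw_frac_cuts)) {
    hit <- rest & is.na(label) & r_iw >= t$iw_frac_cuts[[nm]]
    label[hit] <- nm
  }
  left <- rest & is.na(label)
  is_ud <- left & (out$frac_contig_iw >= t$contig_frac_min |
                     out$max_run >= t$max_run_min)
  label[is_ud] <- "UD"
  label[left & !is_ud] <- "UN"

  out$label <- factor(label, levels = relationship_levels())
  out$degree <- degree_of_label(label)
  out$note <- note
  out
}

#' Write / read a threshold configuration file
#'
#' Thresholds are persisted as a flat, versioned key-value text file
#' (tab-separated `key<TAB>value` lines, `#` comments).
#'
#' @param thresholds A `kin_thresholds` object.
#' @param path File path.
#' @return `write_thresholds()` returns `path` invisibly; `read_thresholds()`
#'   returns a `kin_thresholds` object.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "kin_thresholds"))
  td <- tidy(thresholds)
  meta <- thresholds$meta
  lines <- c(
    "# kinwin thresholds v1",
    sprintf("%s\t%.10g", td$parameter, td$value),
    if (length(meta)) sprintf("meta.%s\t%s", names(meta), unlist(meta))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop("malformed thresholds file at line ", bad[[1]], call. = FALSE)
  }
  kv <- setNames(vapply(parts, `[[`, "", 2), vapply(parts, `[[`, "", 1))
  is_meta <- grepl("^meta\\.", names(kv))
  num <- function(key) as.numeric(kv[[key]])
  meta <- as.list(kv[is_meta])
  names(meta) <- sub("^meta\\.", "", names(meta))
  meta <- lapply(meta, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (is.na(nv)) v else nv
  })
  kin_thresholds(
    twin_gate = num("twin_gate"),
    high_p2_min = num("high_p2_min"),
    iw_frac_cuts = setNames(
      vapply(paste0("iw_frac_cut_", c("PO", "D2", "D3", "D4", "D5")), num, numeric(1)),
      c("PO", "D2", "D3", "D4", "D5")
    ),
    contig_frac_min = num("contig_frac_min"),
    max_run_min = num("max_run_min"),
    meta = meta
  )
}

#' Packaged default thresholds
#'
#' The thresholds shipped with the package, produced by
#' [calibrate_thresholds()] on one simulated 26-member, 7-generation training
#' family (600k sites, SE = 0, fixed seed; see the methods vignette) and
#' stored as a versioned text config under `extdata/`.
#'
#' @return A `kin_thresholds` object.
#' @export
default_thresholds <- function() {
  read_thresholds(system.file("extdata", "default_thresholds.tsv",
                              package = "kinwin", mustWork = TRUE))
}
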