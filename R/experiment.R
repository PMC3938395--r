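#' Simulate-calibrate-evaluate relatedness experiment
#'
#' Runs the full validation loop the classifier is calibrated with: draw one
#' shared site map, gene-drop `n_families` replicate families over the
#' packaged 26-member pedigree (or a user pedigree), inject genotyping error
#' at each requested rate, calibrate the classification tree on one training
#' family (all its pairs plus self-pairs), and classify
#'
#' * every within-family pair of every family (training family flagged), and
#' * unrelated founder pairs formed across distinct held-out families.
#'
#' All randomness derives from `seed`.
#'
#' @param seed Integer seed for the whole experiment.
#' @param n_families Number of replicate families (first `train_family` used
#'   for calibration).
#' @param n_sites Sites genome-wide on the shared map.
#' @param se_levels Per-genotype error rates to evaluate; the P0 cutoff per
#'   level comes from [p0_cutoff_for()].
#' @param pedigree Pedigree tibble (default [default_pedigree()]).
#' @param chrom_lengths Chromosome lengths for simulation and windowing.
#' @param window_size,min_sites,min_windows Windowing parameters.
#' @param train_family Index of the family used for calibration.
#' @param max_unrelated_pairs Cap on the number of cross-family founder
#'   pairs evaluated (selected deterministically).
#' @param recomb_rate Crossovers per bp per meiosis.
#' @return An object of class `kin_experiment`: a list with `site_map` sizes,
#'   and per error rate a list holding `se`, `p0_cutoff`, `thresholds`, and
#'   `calls` — the classified pairs with columns `family` (integer, or `NA`
#'   for cross-family unrelated pairs), `true_label`, `true_degree`, the pair
#'   statistics, and the predicted `label`.
#' @export
relatedness_experiment <- function(seed = 1, n_families = 5, n_sites = 6e5,
                                   se_levels = 0,
                                   pedigree = default_pedigree(),
                                   chrom_lengths = grch37_lengths(),
                                   window_size = 1e6, min_sites = 10,
                                   min_windows = 100, train_family = 1,
                                   max_unrelated_pairs = 200,
                                   recomb_rate = 1e-8) {
  stopifnot(n_families >= 2, train_family %in% seq_len(n_families))
  ped <- validate_pedigree(pedigree)
  set.seed(seed)
  site_map <- make_site_map(n_sites = n_sites, chrom_lengths = chrom_lengths)
  dips <- lapply(seq_len(n_families), function(f) {
    simulate_family(ped, site_map, chrom_lengths = chrom_lengths,
                    recomb_rate = recomb_rate)
  })

  truth <- pair_truth(ped, include_self = FALSE)
  truth_train <- pair_truth(ped, include_self = TRUE)
  fnd <- founders(ped)
  eval_families <- setdiff(seq_len(n_families), train_family)

  # deterministic selection of cross-family founder pairs
  cross <- tidyr::expand_grid(
    fpair = utils::combn(eval_families, 2, simplify = FALSE),
    a = fnd, b = fnd
  )
  cross <- tibble::tibble(
    f1 = vapply(cross$fpair, `[[`, 0L, 1), id1 = cross$a,
    f2 = vapply(cross$fpair, `[[`, 0L, 2), id2 = cross$b
  )
  if (nrow(cross) > max_unrelated_pairs) {
    cross <- cross[sort(sample.int(nrow(cross), max_unrelated_pairs)), ]
  }

  results <- lapply(se_levels, function(se) {
    cutoff <- p0_cutoff_for(se)
    gms <- lapply(dips, function(d) apply_error(d, se))

    m_train <- pairwise_metrics(
      gms[[train_family]], pairs = truth_train[, c("id1", "id2")],
      chrom_lengths = chrom_lengths, window_size = window_size,
      p0_cutoff = cutoff, min_sites = min_sites
    )
    m_train$true_label <- truth_train$label
    th <- calibrate_thresholds(
      m_train,
      meta = list(se = se, p0_cutoff = cutoff, window_size = window_size,
                  n_sites = n_sites)
    )

    within <- purrr::map_dfr(seq_len(n_families), function(f) {
      m <- pairwise_metrics(
        gms[[f]], pairs = truth[, c("id1", "id2")],
        chrom_lengths = chrom_lengths, window_size = window_size,
        p0_cutoff = cutoff, min_sites = min_sites
      )
      m$family <- f
      m$true_label <- truth$label
      m$true_degree <- truth$degree
      m
    })

    # cross-family unrelated founder pairs on a combined matrix
    tag <- function(f, id) paste0("fam", f, ".", id)
    gm_cross <- genotype_matrix(
      site_map[c("chrom", "pos", "ref", "alt")],
      samples = unlist(lapply(eval_families, function(f) tag(f, fnd))),
      calls = do.call(cbind, lapply(eval_families, function(f) {
        gms[[f]]$calls[, fnd, drop = FALSE]
      }))
    )
    m_cross <- pairwise_metrics(
      gm_cross, pairs = cbind(tag(cross$f1, cross$id1), tag(cross$f2, cross$id2)),
      chrom_lengths = chrom_lengths, window_size = window_size,
      p0_cutoff = cutoff, min_sites = min_sites
    )
    m_cross$family <- NA_integer_
    m_cross$true_label <- "UN"
    m_cross$true_degree <- NA_integer_

    calls <- classify_pairs(dplyr::bind_rows(within, m_cross), th,
                            min_windows = min_windows)
    list(se = se, p0_cutoff = cutoff, thresholds = th, calls = calls)
  })
  names(results) <- paste0("se_", se_levels)

  structure(
    list(seed = seed, n_families = n_families, n_sites = n_sites,
         train_family = train_family, results = results),
    class = "kin_experiment"
  )
}

#' @export
print.kin_experiment <- function(x, ...) {
  cat(sprintf("<kin_experiment> %d families, %g sites, seed %d\n",
              x$n_families, x$n_sites, x$seed))
  for (r in x$results) {
    held <- dplyr::filter(r$calls, .data$family != x$train_family |
                            is.na(.data$family))
    cat(sprintf("  se = %g (P0 cutoff %g): held-out exact accuracy %.3f\n",
                r$se, r$p0_cutoff,
                mean(as.character(held$label) == held$true_label, na.rm = TRUE)))
  }
  invisible(x)
}

# UD is treated as "degree 6" for distance purposes, so a D5 pair predicted
# UD counts as within one degree, as does a 6th/7th-degree pair predicted D5.
distance_degree <- function(label) {
  d <- degree_of_label(label)
  d[label == "UD"] <- 6L
  d
}

#' Per-class accuracy of classified pairs
#'
#' Summarises classification results against truth: per true label the number
#' of pairs, the exact-label accuracy, the within-one-degree accuracy
#' (counting related-unknown-distance as one step beyond 5th degree) and the
#' fraction called related (any label other than UN).
#'
#' @param calls A classified tibble with `true_label` and `label` columns
#'   (e.g. from [relatedness_experiment()]).
#' @return A tibble with columns `true_label`, `n`, `exact`, `within_one`,
#'   `called_related`.
#' @export
accuracy_summary <- function(calls) {
  stopifnot(all(c("true_label", "label") %in% names(calls)))
  pred <- as.character(calls$label)
  truth <- as.character(calls$true_label)
  d_pred <- distance_degree(pred)
  d_true <- distance_degree(truth)
  within <- pred == truth |
    (!is.na(d_pred) & !is.na(d_true) & abs(d_pred - d_true) <= 1)
  tibble::tibble(
    true_label = factor(truth, levels = relationship_levels()),
    exact = pred == truth,
    within_one = within,
    called_related = !is.na(pred) & pred != "UN"
  ) %>%
    dplyr::group_by(.data$true_label) %>%
    dplyr::summarise(
      n = dplyr::n(),
      exact = mean(.data$exact, na.rm = TRUE),
      within_one = mean(.data$within_one, na.rm = TRUE),
      called_related = mean(.data$called_related),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$true_label)
}

#' Confusion matrix of classified pairs
#'
#' @inheritParams accuracy_summary
#' @return A tibble: one row per true label, one column per predicted label.
#' @export
confusion_matrix <- function(calls) {
  lv <- relationship_levels()
  tb <- table(
    true = factor(as.character(calls$true_label), levels = lv),
    predicted = factor(as.character(calls$label), levels = lv)
  )
  out <- tibble::as_tibble(as.data.frame.matrix(tb), rownames = "true_label")
  out[rowSums(out[, -1]) > 0, c(TRUE, colSums(tb) > 0)]
}
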