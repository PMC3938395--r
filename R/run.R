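log_msg <- function(..., log_file = NULL) {
  line <- paste0("[kinwin ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
}

#' Estimate relationships from a genotype file
#'
#' Reads genotypes, classifies the requested pairs and writes the
#' tab-separated results table. Progress (window counts, filters, thresholds
#' file) is logged to stderr and optionally to `log_file`.
#'
#' @param input Genotype file path.
#' @param out Results TSV path.
#' @param format Input format (see [read_genotypes()]).
#' @param array Array mode: switches the window size to 2 Mb and the
#'   per-window site floor to 5 (unless overridden).
#' @param thresholds A `kin_thresholds` object or path to a thresholds file;
#'   `NULL` uses the packaged defaults.
#' @param pairs `"all"` or a two-column data frame of sample IDs.
#' @param log_file Optional path to append log lines to.
#' @inheritParams relate_pairs
#' @return The classified tibble, invisibly.
#' @export
run_estimate <- function(input, out, format = "vcf", array = FALSE,
                         window_size = NULL, se = 0,
                         p0_cutoff = p0_cutoff_for(se), thresholds = NULL,
                         pairs = "all", min_sites = NULL, min_windows = 100,
                         chrom_lengths = NULL, log_file = NULL) {
  window_size <- window_size %||% if (array) 2e6 else 1e6
  min_sites <- min_sites %||% if (array) 5 else 10
  th <- if (is.null(thresholds)) {
    default_thresholds()
  } else if (inherits(thresholds, "kin_thresholds")) {
    thresholds
  } else {
    read_thresholds(thresholds)
  }
  log_msg("reading ", input, " (", format, ")", log_file = log_file)
  gm <- read_genotypes(input, format = format)
  log_msg(nrow(gm$sites), " biallelic SNVs, ", length(gm$samples), " samples",
          log_file = log_file)
  if (is.null(chrom_lengths)) chrom_lengths <- attr(gm, "chrom_lengths")
  if (!is.null(chrom_lengths)) {
    chrom_lengths <- chrom_lengths[is_autosome(names(chrom_lengths))]
    if (!length(chrom_lengths)) chrom_lengths <- NULL
  }
  log_msg("window size ", window_size, " bp, min ", min_sites,
          " sites/window, P0 cutoff ", p0_cutoff, log_file = log_file)
  pair_arg <- if (identical(pairs, "all")) NULL else pairs
  calls <- relate_pairs(gm, pairs = pair_arg, thresholds = th,
                        chrom_lengths = chrom_lengths,
                        window_size = window_size, p0_cutoff = p0_cutoff,
                        min_sites = min_sites, min_windows = min_windows)
  log_msg(nrow(calls), " pairs classified; windows retained per pair: ",
          paste(range(calls$n_windows), collapse = "-"), log_file = log_file)
  write_calls(calls, out)
  log_msg("results written to ", out, log_file = log_file)
  invisible(calls)
}

#' Simulate genotype files for a pedigree
#'
#' Gene-drops `replicates` families (sharing one site map) and writes one
#' genotype file plus one pair-truth table per replicate, with a provenance
#' line (seed and config hash) in the log.
#'
#' @param out_prefix Output path prefix; files are
#'   `<prefix>_fam<r>.vcf` / `.ped`+`.map` and `<prefix>_fam<r>.truth.tsv`.
#' @param pedigree Pedigree tibble or path to a pedigree file; `NULL` uses
#'   the packaged 26-member pedigree.
#' @param n_sites Sites genome-wide.
#' @param se Per-genotype error rate injected into the written genotypes.
#' @param seed Integer seed; fixes the site map and all gene drops.
#' @param replicates Number of replicate families.
#' @param format `"vcf"` or `"ped_map"`.
#' @inheritParams relatedness_experiment
#' @param log_file Optional log path.
#' @return Tibble of written file paths, invisibly.
#' @export
run_simulate <- function(out_prefix, pedigree = NULL, n_sites = 3.5e6,
                         chrom_lengths = grch37_lengths(), se = 0, seed = 1,
                         replicates = 1, format = c("vcf", "ped_map"),
                         recomb_rate = 1e-8, log_file = NULL) {
  format <- match.arg(format)
  ped <- if (is.null(pedigree)) {
    default_pedigree()
  } else if (is.character(pedigree)) {
    read_pedigree(pedigree)
  } else {
    validate_pedigree(pedigree)
  }
  cfg <- list(n_sites = n_sites, se = se, seed = seed, replicates = replicates,
              format = format, recomb_rate = recomb_rate,
              chrom_lengths = unname(chrom_lengths), ped = ped)
  log_msg("simulate: seed=", seed, " config_hash=", rlang::hash(cfg),
          log_file = log_file)
  set.seed(seed)
  site_map <- make_site_map(n_sites = n_sites, chrom_lengths = chrom_lengths)
  truth <- pair_truth(ped, include_self = FALSE)
  files <- purrr::map_dfr(seq_len(replicates), function(r) {
    dip <- simulate_family(ped, site_map, chrom_lengths = chrom_lengths,
                           recomb_rate = recomb_rate)
    gm <- apply_error(dip, se)
    base <- sprintf("%s_fam%d", out_prefix, r)
    geno <- if (format == "vcf") {
      write_vcf(gm, paste0(base, ".vcf"), chrom_lengths = chrom_lengths)
    } else {
      write_ped_map(gm, base, ped = ped)[["ped"]]
    }
    tr <- write_truth(truth, paste0(base, ".truth.tsv"))
    log_msg("family ", r, ": ", geno, log_file = log_file)
    tibble::tibble(replicate = r, genotypes = geno, truth = tr)
  })
  invisible(files)
}

#' Calibrate thresholds from simulated genotypes and a truth table
#'
#' Reads a genotype file and its pair-truth table, computes the pair
#' statistics for every truth pair (self-pairs included for the twin/self
#' class), fits the classification-tree thresholds, and writes the
#' thresholds config plus a per-class accuracy report (exact and
#' within-one-degree).
#'
#' @param input Genotype file of the training family.
#' @param truth Path to its truth table (see [write_truth()]); self-pairs
#'   with label `IT` are added automatically if absent.
#' @param out_prefix Prefix for `<prefix>.thresholds.tsv` and
#'   `<prefix>.report.tsv`.
#' @param format Input genotype format.
#' @param se Assumed per-genotype error rate (sets the P0 cutoff).
#' @inheritParams relate_pairs
#' @param log_file Optional log path.
#' @return The fitted `kin_thresholds`, invisibly.
#' @export
run_calibrate <- function(input, truth, out_prefix, format = "vcf", se = 0,
                          p0_cutoff = p0_cutoff_for(se), window_size = 1e6,
                          min_sites = 10, min_windows = 100,
                          chrom_lengths = NULL, log_file = NULL) {
  gm <- read_genotypes(input, format = format)
  tr <- read_truth(truth)
  if (!any(tr$id1 == tr$id2)) {
    tr <- dplyr::bind_rows(
      tr,
      tibble::tibble(id1 = gm$samples, id2 = gm$samples, kinship = NA_real_,
                     degree = 0L, label = "IT")
    )
  }
  if (is.null(chrom_lengths)) chrom_lengths <- attr(gm, "chrom_lengths")
  log_msg("calibrating on ", nrow(tr), " labelled pairs (se=", se,
          ", P0 cutoff ", p0_cutoff, ")", log_file = log_file)
  m <- pairwise_metrics(gm, pairs = tr[, c("id1", "id2")],
                        chrom_lengths = chrom_lengths,
                        window_size = window_size, p0_cutoff = p0_cutoff,
                        min_sites = min_sites)
  m$true_label <- tr$label
  th <- calibrate_thresholds(
    m, meta = list(se = se, p0_cutoff = p0_cutoff, window_size = window_size)
  )
  calls <- classify_pairs(m, th, min_windows = min_windows)
  report <- accuracy_summary(calls)
  write_thresholds(th, paste0(out_prefix, ".thresholds.tsv"))
  readr::write_tsv(report, paste0(out_prefix, ".report.tsv"))
  log_msg("training accuracy ", sprintf("%.3f", th$meta$train_accuracy),
          "; wrote ", out_prefix, ".thresholds.tsv", log_file = log_file)
  invisible(th)
}
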