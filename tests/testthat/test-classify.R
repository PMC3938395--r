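toy_thresholds <- function() {
  kin_thresholds(
    twin_gate = 0.95, high_p2_min = 50,
    iw_frac_cuts = c(PO = 0.85, D2 = 0.35, D3 = 0.17, D4 = 0.08, D5 = 0.03),
    contig_frac_min = 0.5, max_run_min = 2
  )
}

mrow <- function(n_windows = 1000, n_high_p2 = 0, peak_flag = FALSE, n_iw = 0,
                 frac_contig_iw = 0, max_run = 0) {
  tibble::tibble(n_windows = n_windows, n_high_p2 = n_high_p2,
                 peak_flag = peak_flag, n_iw = n_iw,
                 frac_contig_iw = frac_contig_iw, max_run = max_run)
}

test_that("the decision tree follows its stated order", {
  th <- toy_thresholds()
  call1 <- function(m) as.character(classify_pairs(m, th)$label)
  # twin gate first, even when everything else is extreme
  expect_equal(call1(mrow(n_high_p2 = 990, peak_flag = TRUE, n_iw = 1000,
                          frac_contig_iw = 1, max_run = 1000)), "IT")
  # sibling via peak dominance, despite a PO-like IW fraction
  expect_equal(call1(mrow(n_high_p2 = 300, peak_flag = TRUE, n_iw = 900,
                          frac_contig_iw = 1, max_run = 200)), "FS")
  # sibling via the high-P2 count alone (peak smeared by error)
  expect_equal(call1(mrow(n_high_p2 = 300, peak_flag = FALSE, n_iw = 900,
                          frac_contig_iw = 1, max_run = 200)), "FS")
  # neither sibling signal: falls through to the IW-fraction ladder
  expect_equal(call1(mrow(n_high_p2 = 10, peak_flag = FALSE, n_iw = 900,
                          frac_contig_iw = 1, max_run = 200)), "PO")
  # ladder mapping
  expect_equal(call1(mrow(n_iw = 860)), "PO")
  expect_equal(call1(mrow(n_iw = 400)), "D2")
  expect_equal(call1(mrow(n_iw = 200)), "D3")
  expect_equal(call1(mrow(n_iw = 90)), "D4")
  expect_equal(call1(mrow(n_iw = 31)), "D5")
  # below D5: contiguity evidence -> UD, else UN
  expect_equal(call1(mrow(n_iw = 10, max_run = 3)), "UD")
  expect_equal(call1(mrow(n_iw = 10, frac_contig_iw = 0.6, max_run = 1)), "UD")
  expect_equal(call1(mrow(n_iw = 10, max_run = 1)), "UN")
  # degree mapping
  got <- classify_pairs(dplyr::bind_rows(mrow(n_iw = 860), mrow(n_iw = 10)), th)
  expect_equal(got$degree, c(1L, NA_integer_))
})

test_that("the window-count gate refuses to call sparse inputs", {
  th <- toy_thresholds()
  out <- classify_pairs(mrow(n_windows = 40, n_iw = 39), th, min_windows = 100)
  expect_true(is.na(out$label))
  expect_equal(out$note, "insufficient windows")
})

test_that("calibration on separable toy classes puts cuts at range midpoints", {
  lv <- c("IT", "FS", "PO", "D2", "D3", "D4", "D5", "UD", "UN")
  mk <- function(label, n_iw, n_high_p2 = 0, peak_flag = FALSE, max_run = 0,
                 frac_contig_iw = 0) {
    cbind(mrow(n_windows = 1000, n_high_p2 = n_high_p2, peak_flag = peak_flag,
               n_iw = n_iw, frac_contig_iw = frac_contig_iw,
               max_run = max_run),
          tibble::tibble(true_label = label))
  }
  train <- dplyr::bind_rows(
    mk("IT", 1000, n_high_p2 = 1000, peak_flag = TRUE, max_run = 1000,
       frac_contig_iw = 1),
    mk("FS", c(700, 720), n_high_p2 = c(300, 340), peak_flag = TRUE,
       max_run = 60, frac_contig_iw = 1),
    mk("PO", c(995, 1000), max_run = 500, frac_contig_iw = 1),
    mk("D2", c(420, 480), max_run = 60, frac_contig_iw = 1),
    mk("D3", c(200, 240), max_run = 30, frac_contig_iw = 1),
    mk("D4", c(90, 110), max_run = 15, frac_contig_iw = 0.9),
    mk("D5", c(30, 50), max_run = 8, frac_contig_iw = 0.8),
    mk("UD", c(5, 10), max_run = c(3, 4), frac_contig_iw = 0.5),
    mk("UN", c(0, 1), max_run = c(0, 1), frac_contig_iw = 0)
  )
  th <- calibrate_thresholds(train)
  # separable: cut at the midpoint between adjacent class ranges (per 1000)
  expect_equal(unname(th$iw_frac_cuts["PO"]), (995 + 480) / 2 / 1000)
  expect_equal(unname(th$iw_frac_cuts["D2"]), (420 + 240) / 2 / 1000)
  expect_equal(unname(th$iw_frac_cuts["D5"]), (30 + 10) / 2 / 1000)
  expect_equal(th$high_p2_min, (300 + 0) / 2)
  expect_equal(th$max_run_min, (3 + 1) / 2)
  expect_equal(th$meta$train_accuracy, 1)
  # determinism
  expect_identical(tidy(calibrate_thresholds(train)), tidy(th))
  # missing class errors by name
  expect_error(calibrate_thresholds(train[train$true_label != "D4", ]), "D4")
})

test_that("thresholds round-trip through the key-value config file", {
  th <- toy_thresholds()
  th$meta <- list(se = 0.001, p0_cutoff = 0.004, note = "toy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_thresholds(th, path)
  back <- read_thresholds(path)
  expect_equal(tidy(back), tidy(th))
  expect_equal(back$meta$se, 0.001)
  expect_equal(back$meta$note, "toy")
  bad <- withr::local_tempfile()
  writeLines("twin_gate", bad)
  expect_error(read_thresholds(bad), "line 1")
})

test_that("tidy and glance expose the fitted parameters", {
  th <- toy_thresholds()
  td <- tidy(th)
  expect_equal(nrow(td), 9L)
  expect_true(all(c("iw_frac_cut_PO", "max_run_min") %in% td$parameter))
  gl <- glance(th)
  expect_true(is.na(gl$train_accuracy))
})

test_that("classification is invariant to pair order and chromosome order", {
  fam <- toy_family()
  th <- toy_thresholds()
  # chromosome order shuffled in the input matrix
  ord <- order(match(fam$gm$sites$chrom, c("3", "1", "5", "2", "4")),
               fam$gm$sites$pos)
  gm_shuf <- genotype_matrix(fam$gm$sites[ord, ], fam$gm$samples,
                             fam$gm$calls[ord, ])
  a <- relate_pairs(fam$gm, rbind(c("B1", "D1")), thresholds = th,
                    chrom_lengths = toy_lengths, p0_cutoff = 0.004,
                    min_windows = 50)
  b <- relate_pairs(fam$gm, rbind(c("D1", "B1")), thresholds = th,
                    chrom_lengths = toy_lengths, p0_cutoff = 0.004,
                    min_windows = 50)
  c <- relate_pairs(gm_shuf, rbind(c("B1", "D1")), thresholds = th,
                    chrom_lengths = toy_lengths[c("3", "1", "5", "2", "4")],
                    p0_cutoff = 0.004, min_windows = 50)
  expect_equal(as.character(a$label), as.character(b$label))
  expect_equal(as.character(a$label), as.character(c$label))
  expect_equal(a$n_iw, b$n_iw)
  expect_equal(a$n_iw, c$n_iw)
})
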