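test_that("VCF parsing keeps biallelic SNVs, codes alt counts, maps missing to NA", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(vcf)
  gm <- suppressMessages(read_genotypes(vcf, format = "vcf"))
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(dim(gm), c(4L, 3L)) # multi-allelic record dropped
  expect_equal(gm$samples, c("s1", "s2", "s3"))
  expect_identical(unname(gm$calls), unname(fixture_codes()))
  expect_true(is.na(gm$calls[2, "s1"])) # "./." at 1:300
  # contig header lines surface as chromosome lengths
  expect_equal(attr(gm, "chrom_lengths"), c(`1` = 2500000, `2` = 1500000))
})

test_that("TPED and PED+MAP load the same genotype content as the VCF", {
  dir <- withr::local_tempdir()
  vcf <- write_fixture_vcf(file.path(dir, "fix.vcf"))
  tped <- write_fixture_tped(file.path(dir, "fix"))
  pedp <- write_fixture_ped_map(file.path(dir, "fixp"))
  gm_v <- suppressMessages(read_genotypes(vcf, format = "vcf"))
  gm_t <- suppressMessages(read_genotypes(tped[["tped"]], format = "tped"))
  gm_p <- suppressMessages(read_genotypes(pedp[["ped"]], format = "ped_map"))
  expect_identical(gm_t$sites[c("chrom", "pos")], gm_v$sites[c("chrom", "pos")])
  expect_identical(unname(gm_t$calls), unname(gm_v$calls))
  expect_identical(unname(gm_p$calls), unname(gm_v$calls))
  expect_equal(gm_p$sites$ref, gm_v$sites$ref) # MAP allele columns take precedence
})

test_that("parse errors name the offending line; empty results error", {
  dir <- withr::local_tempdir()
  bad_tped <- file.path(dir, "bad.tped")
  writeLines(c("1 s1 0 100 A A G G", "1 s2 0"), bad_tped)
  expect_error(read_genotypes(bad_tped, format = "tped"), "line 2")
  expect_error(read_genotypes(file.path(dir, "nope.vcf")), "not found")
  # PED without its MAP
  ped_only <- file.path(dir, "alone.ped")
  writeLines("FAM1 s1 0 0 1 -9 A A", ped_only)
  expect_error(read_genotypes(ped_only, format = "ped_map"), "MAP not found")
  # a VCF whose only record is an indel leaves nothing
  vcf <- file.path(dir, "indel.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "1\t100\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1"
  ), vcf)
  expect_error(suppressMessages(read_genotypes(vcf, format = "vcf")),
               "no biallelic SNVs")
})

test_that("duplicate (chrom,pos) records keep the first with a warning", {
  dir <- withr::local_tempdir()
  tped <- file.path(dir, "dup.tped")
  writeLines(c(
    "1 a 0 100 A A A G",
    "1 b 0 100 C C C T",
    "1 c 0 200 G G G A"
  ), tped)
  expect_warning(gm <- suppressMessages(read_genotypes(tped, format = "tped")),
                 "duplicated")
  expect_equal(nrow(gm$sites), 2L)
  expect_equal(gm$sites$ref[gm$sites$pos == 100], "A")
})

test_that("filter_pair_sites keeps co-called sites, is symmetric, flags unknowns", {
  sites <- tibble::tibble(chrom = "1", pos = 1:10 * 100L, ref = "A", alt = "G")
  calls <- matrix(1L, nrow = 10, ncol = 3)
  calls[c(2, 5), 1] <- NA # a missing at 2 sites
  calls[8, 2] <- NA       # b missing at 1 disjoint site
  gm <- genotype_matrix(sites, c("a", "b", "c"), calls)

  ab <- filter_pair_sites(gm, "a", "b")
  expect_equal(nrow(ab$sites), 7L)
  expect_identical(ab$sites, filter_pair_sites(gm, "b", "a")$sites)
  # pair with no missing calls: identical site list
  bc <- filter_pair_sites(gm, "b", "c")
  expect_equal(nrow(bc$sites), 9L)
  # all-missing sample: empty matrix, downstream windowing errors
  calls2 <- calls; calls2[, 3] <- NA
  gm2 <- genotype_matrix(sites, c("a", "b", "c"), calls2)
  empty <- filter_pair_sites(gm2, "a", "c")
  expect_equal(nrow(empty$sites), 0L)
  expect_error(window_ibs(gm2, c("a", "c")), "no co-called sites")
  expect_error(filter_pair_sites(gm, "a", "zz"), "unknown sample")
})

test_that("results tables round-trip through write_calls/read_calls", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "calls.tsv")
  # empty input -> header-only file
  write_calls(NULL, path)
  expect_equal(readLines(path),
               paste(c("sample1", "sample2", "n_windows", "n_high_p2",
                       "peak_flag", "n_iw", "frac_contig_iw", "max_run",
                       "predicted_label"), collapse = "\t"))
  calls <- tibble::tibble(
    sample1 = c("x", "y"), sample2 = c("x", "z"),
    n_windows = c(200L, 200L), n_high_p2 = c(200L, 3L),
    peak_flag = c(TRUE, FALSE), n_iw = c(200L, 1L),
    frac_contig_iw = c(1, 0), max_run = c(200L, 1L),
    label = factor(c("IT", "UN"), levels = c("IT", "FS", "PO", "D2", "D3",
                                             "D4", "D5", "UD", "UN"))
  )
  write_calls(calls, path)
  back <- read_calls(path)
  expect_equal(as.character(back$label), c("IT", "UN"))
  expect_equal(back$n_iw, c(200, 1))
})

test_that("simulated genotypes survive a VCF and PED+MAP export/import round trip", {
  dir <- withr::local_tempdir()
  cl <- c(`1` = 5e6, `2` = 4e6)
  sm <- make_site_map(n_sites = 400, chrom_lengths = cl, seed = 5)
  dip <- simulate_family(default_pedigree(), sm, chrom_lengths = cl, seed = 6)
  gm <- apply_error(dip, se = 0.01, seed = 7)

  write_vcf(gm, file.path(dir, "fam.vcf"), chrom_lengths = cl)
  back_v <- suppressMessages(read_genotypes(file.path(dir, "fam.vcf")))
  expect_identical(unname(back_v$calls), unname(gm$calls))
  expect_identical(back_v$sites[c("chrom", "pos", "ref", "alt")],
                   gm$sites[c("chrom", "pos", "ref", "alt")])

  write_ped_map(gm, file.path(dir, "fam"), ped = default_pedigree())
  back_p <- suppressMessages(read_genotypes(file.path(dir, "fam.ped"),
                                            format = "ped_map"))
  expect_identical(unname(back_p$calls), unname(gm$calls))
})
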