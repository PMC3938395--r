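# Shared fixtures and brute-force oracles, built in code at test time.
# (helper file; loaded before every test file)

toy_lengths <- c(`1` = 80e6, `2` = 70e6, `3` = 60e6, `4` = 50e6, `5` = 40e6)

# --- tiny text-format fixtures -------------------------------------------

write_fixture_vcf <- function(path, with_contigs = TRUE) {
  # 5 records: one multi-allelic, one indel -> 3 usable biallelic SNVs + 1 more
  lines <- c(
    "##fileformat=VCFv4.2",
    if (with_contigs) c("##contig=<ID=1,length=2500000>",
                        "##contig=<ID=2,length=1500000>"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0\t0/2", # multi-allelic
    "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t0|1\t1|1",
    "2\t150\t.\tT\tC\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1",
    "2\t250\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1"
  )
  writeLines(lines, path)
  path
}

# TPED encoding the same biallelic SNVs/genotypes as write_fixture_vcf
# (sample order s1 s2 s3; missing as 0 0)
write_fixture_tped <- function(prefix) {
  tped <- paste0(prefix, ".tped")
  tfam <- paste0(prefix, ".tfam")
  writeLines(c(
    "1 s_a 0 100 A A A G G G",
    "1 s_b 0 300 0 0 G A A A",
    "2 s_c 0 150 T C T T C C",
    "2 s_d 0 250 A A A A C C"
  ), tped)
  writeLines(c("FAM1 s1 0 0 1 -9", "FAM1 s2 0 0 2 -9", "FAM1 s3 0 0 1 -9"), tfam)
  c(tped = tped, tfam = tfam)
}

write_fixture_ped_map <- function(prefix) {
  map <- paste0(prefix, ".map")
  ped <- paste0(prefix, ".ped")
  # 6-column MAP carries ref/alt so coding is explicit
  writeLines(c(
    "1\tm1\t0\t100\tA\tG",
    "1\tm2\t0\t300\tG\tA",
    "2\tm3\t0\t150\tT\tC",
    "2\tm4\t0\t250\tA\tC"
  ), map)
  writeLines(c(
    "FAM1 s1 0 0 1 -9 A A 0 0 T C A A",
    "FAM1 s2 0 0 2 -9 A G G A T T A A",
    "FAM1 s3 0 0 1 -9 G G A A C C C C"
  ), ped)
  c(ped = ped, map = map)
}

# expected codes (sites sorted chrom/pos) for the shared fixture genotypes
fixture_codes <- function() {
  matrix(c(
    0L, 1L, 2L,   # 1:100 A>G
    NA, 1L, 2L,   # 1:300 G>A
    1L, 0L, 2L,   # 2:150 T>C
    0L, 0L, 2L    # 2:250 A>C
  ), nrow = 4, byrow = TRUE, dimnames = list(NULL, c("s1", "s2", "s3")))
}

# --- brute-force oracles --------------------------------------------------

# site-by-site IBS recount for one pair over a window table
oracle_window_counts <- function(sites, ga, gb, windows, window_size) {
  out <- data.frame(gid = windows$gid, n0 = 0L, n1 = 0L, n2 = 0L)
  for (i in seq_along(ga)) {
    wrow <- which(windows$chrom == sites$chrom[[i]] &
                    windows$start <= sites$pos[[i]] &
                    windows$end > sites$pos[[i]])
    if (length(wrow) != 1) next
    s <- if (ga[[i]] == gb[[i]]) 2L else if (abs(ga[[i]] - gb[[i]]) == 2L) 0L else 1L
    col <- paste0("n", s)
    out[wrow, col] <- out[wrow, col] + 1L
  }
  out
}

# explicit scan for IW contiguity metrics on a per-chromosome flag sequence
oracle_contiguity <- function(chrom, index, iw) {
  ord <- order(match(chrom, unique(chrom)), index)
  chrom <- chrom[ord]; index <- index[ord]; iw <- iw[ord]
  n_adj <- 0L; max_run <- 0L; run <- 0L
  for (i in seq_along(iw)) {
    adj_prev <- i > 1 && chrom[i] == chrom[i - 1] && index[i] == index[i - 1] + 1
    adj_next <- i < length(iw) && chrom[i + 1] == chrom[i] &&
      index[i + 1] == index[i] + 1
    if (iw[i]) {
      if ((adj_prev && iw[i - 1]) || (adj_next && iw[i + 1])) n_adj <- n_adj + 1L
      run <- if (adj_prev && iw[i - 1]) run + 1L else 1L
      max_run <- max(max_run, run)
    } else {
      run <- 0L
    }
  }
  list(n_iw = sum(iw), n_adj = n_adj,
       frac_contig = if (sum(iw) > 0) n_adj / sum(iw) else 0,
       max_run = max_run)
}

# small simulated family, cached across test files
toy_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sm <- make_site_map(n_sites = 40000, chrom_lengths = toy_lengths, seed = 101)
      dip <- simulate_family(default_pedigree(), sm, chrom_lengths = toy_lengths,
                             seed = 102)
      cache <<- list(site_map = sm, dip = dip, gm = genotypes(dip))
    }
    cache
  }
})
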