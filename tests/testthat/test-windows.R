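test_that("ibs_state implements the allele-sharing classes", {
  g <- expand.grid(a = 0:2, b = 0:2)
  got <- ibs_state(g$a, g$b)
  want <- ifelse(g$a == g$b, 2L, ifelse(abs(g$a - g$b) == 2, 0L, 1L))
  expect_identical(got, want)
  # symmetry
  expect_identical(ibs_state(g$a, g$b), ibs_state(g$b, g$a))
  expect_error(ibs_state(NA, 1), "fully called")
  expect_error(ibs_state(3, 1), "0, 1 or 2")
})

test_that("make_windows tiles chromosomes half-open with a short last window", {
  w <- make_windows(c(`1` = 2.5e6), window_size = 1e6)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(1, 1e6 + 1, 2e6 + 1))
  expect_equal(w$end, c(1e6 + 1, 2e6 + 1, 2.5e6 + 1))
  expect_equal(w$index, 0:2)
  # window larger than the chromosome -> a single window
  expect_equal(nrow(make_windows(c(`1` = 5e5), 1e6)), 1L)
  expect_error(make_windows(numeric(0)), "empty")
  # tiling covers every bp exactly once
  w2 <- make_windows(c(`7` = 3.3e6), 1e6)
  expect_equal(w2$start[-1], w2$end[-nrow(w2)])
})

test_that("window_ibs fractions follow the per-window tallies and strict IW inequality", {
  sites <- tibble::tibble(chrom = "1", pos = c(10L, 20L, 30L, 40L),
                          ref = "A", alt = "G")
  # states [2,2,1,0]: P0=0.25 P1=0.25 P2=0.5
  calls <- matrix(c(0L, 1L, 1L, 0L,
                    0L, 1L, 0L, 2L), ncol = 2)
  gm <- genotype_matrix(sites, c("a", "b"), calls)
  w <- window_ibs(gm, c("a", "b"), chrom_lengths = c(`1` = 100), min_sites = 1)
  expect_equal(nrow(w), 1L)
  expect_equal(w$n0, 1L); expect_equal(w$n1, 1L); expect_equal(w$n2, 2L)
  expect_equal(c(w$P0, w$P1, w$P2), c(0.25, 0.25, 0.5))

  # strict inequality at the cutoff
  mk <- function(n0, n) {
    s <- tibble::tibble(chrom = "1", pos = seq_len(n) * 10L, ref = "A", alt = "G")
    ca <- rep(0L, n); cb <- rep(0L, n); cb[seq_len(n0)] <- 2L
    window_ibs(genotype_matrix(s, c("a", "b"), cbind(ca, cb)), c("a", "b"),
               chrom_lengths = c(`1` = n * 10), p0_cutoff = 0.004, min_sites = 1)
  }
  expect_true(mk(3, 1000)$is_iw)   # P0 = 0.003 < 0.004
  expect_false(mk(4, 1000)$is_iw)  # P0 = 0.004, not < 0.004
})

test_that("window counts equal a site-by-site brute-force recount", {
  set.seed(42)
  cl <- c(`1` = 2.5e6, `2` = 1.2e6)
  for (rep in 1:3) {
    n <- 100
    sites <- tibble::tibble(
      chrom = sample(names(cl), n, replace = TRUE),
      pos = as.integer(runif(n, 1, 2.4e6)), ref = "A", alt = "G"
    )
    sites <- sites[sites$pos <= cl[sites$chrom], ]
    sites <- sites[!duplicated(sites[c("chrom", "pos")]), ]
    ga <- sample(0:2, nrow(sites), replace = TRUE)
    gb <- sample(0:2, nrow(sites), replace = TRUE)
    gm <- genotype_matrix(sites, c("a", "b"), cbind(ga, gb))
    w <- window_ibs(gm, c("a", "b"), chrom_lengths = cl, min_sites = 1)
    wins <- make_windows(cl, 1e6)
    oracle <- oracle_window_counts(gm$sites, gm$calls[, 1], gm$calls[, 2],
                                   wins, 1e6)
    oracle <- oracle[oracle$n0 + oracle$n1 + oracle$n2 > 0, ]
    expect_equal(w$gid, oracle$gid)
    expect_equal(w$n0, oracle$n0)
    expect_equal(w$n1, oracle$n1)
    expect_equal(w$n2, oracle$n2)
  }
})

test_that("P0+P1+P2 sum to one and the track is pair-order symmetric", {
  fam <- toy_family()
  w_ab <- window_ibs(fam$gm, c("B1", "D1"), chrom_lengths = toy_lengths)
  w_ba <- window_ibs(fam$gm, c("D1", "B1"), chrom_lengths = toy_lengths)
  expect_equal(w_ab$P0 + w_ab$P1 + w_ab$P2, rep(1, nrow(w_ab)))
  for (col in c("n0", "n1", "n2", "is_iw")) {
    expect_equal(w_ab[[col]], w_ba[[col]])
  }
})

test_that("self-comparison yields P2 = 1 everywhere and all-IW at cutoff 0", {
  fam <- toy_family()
  w <- window_ibs(fam$gm, c("H1", "H1"), chrom_lengths = toy_lengths,
                  p0_cutoff = 0)
  expect_true(all(w$P2 == 1))
  expect_true(all(w$P0 == 0))
  expect_true(all(w$is_iw))
})

test_that("low-density windows are dropped and starved input errors", {
  sites <- tibble::tibble(chrom = "1", pos = c(1:20 * 10L, 3000001L),
                          ref = "A", alt = "G")
  calls <- matrix(0L, nrow = 21, ncol = 2)
  gm <- genotype_matrix(sites, c("a", "b"), calls)
  w <- window_ibs(gm, c("a", "b"), chrom_lengths = c(`1` = 4e6), min_sites = 10)
  expect_equal(nrow(w), 1L) # the lone site beyond 3 Mb is dropped
  expect_error(
    window_ibs(gm, c("a", "b"), chrom_lengths = c(`1` = 4e6), min_sites = 50),
    "insufficient marker density"
  )
})

test_that("the P0 cutoff schedule hits its anchors and is monotone", {
  expect_equal(p0_cutoff_for(c(0, 0.001, 0.005, 0.01)),
               c(0, 0.004, 0.01, 0.015))
  grid <- seq(0, 0.049, by = 0.0005)
  vals <- p0_cutoff_for(grid)
  expect_true(all(diff(vals) >= 0))
  expect_error(p0_cutoff_for(-0.1), "se must")
  expect_error(p0_cutoff_for(0.5), "se must")
})
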