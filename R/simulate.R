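#' Draw a shared site map for a simulation experiment
#'
#' Samples biallelic SNV positions uniformly over the given chromosome
#' lengths (without duplicates) and assigns each site a population alternate
#' allele frequency drawn from a Beta spectrum (default Beta(0.5, 0.5), a
#' U-shaped spectrum enriched for rare and near-fixed alleles). Replicate
#' families simulated on one site map share coordinates and frequencies, so
#' individuals from different replicates can be compared pair-wise.
#'
#' @param n_sites Total number of sites genome-wide (default 3.5 million, the
#'   scale of a whole-genome SNV callset).
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param maf_shape Two Beta shape parameters for the frequency spectrum.
#' @param seed Optional integer seed (fixes all randomness of the draw).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `freq`, sorted
#'   by chromosome and position.
#' @export
make_site_map <- function(n_sites = 3.5e6, chrom_lengths = grch37_lengths(),
                          maf_shape = c(0.5, 0.5), seed = NULL) {
  stopifnot(n_sites > 0, length(chrom_lengths) > 0)
  if (!is.null(seed)) set.seed(seed)
  share <- chrom_lengths / sum(chrom_lengths)
  n_per <- as.integer(round(n_sites * share))
  # fix rounding drift on the largest chromosome
  n_per[[which.max(chrom_lengths)]] <- n_per[[which.max(chrom_lengths)]] +
    (as.integer(n_sites) - sum(n_per))
  if (any(n_per > chrom_lengths)) {
    stop("n_sites exceeds available positions on some chromosome", call. = FALSE)
  }
  sites <- purrr::map2(names(chrom_lengths), seq_along(chrom_lengths), function(chrom, i) {
    pos <- sort(sample.int(as.integer(chrom_lengths[[i]]), n_per[[i]], replace = FALSE))
    tibble::tibble(chrom = chrom, pos = pos)
  })
  out <- dplyr::bind_rows(sites)
  alleles <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, nrow(out), replace = TRUE)
  alt_shift <- sample.int(3L, nrow(out), replace = TRUE)
  out$ref <- alleles[ref_i]
  out$alt <- alleles[(ref_i - 1L + alt_shift) %% 4L + 1L]
  out$freq <- rbeta(nrow(out), maf_shape[[1]], maf_shape[[2]])
  out
}

#' Simulate founder diplotypes
#'
#' Founder haplotype alleles are drawn independently per site as
#' Bernoulli(site frequency) — unrelated, unphased-equivalent synthetic
#' genomes standing in for real sequenced founders.
#'
#' @param site_map A site map from [make_site_map()].
#' @param founder_ids Character IDs of the founders.
#' @param seed Optional integer seed.
#' @return A `diplotypes` object: haplotype matrix (`0`/`1` alt-allele
#'   indicators) of dimension sites x 2*founders, plus the site map.
#' @export
simulate_founders <- function(site_map, founder_ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(site_map)
  k <- 2L * length(founder_ids)
  H <- matrix(rbinom(n * k, 1L, rep(site_map$freq, k)), nrow = n, ncol = k)
  storage.mode(H) <- "integer"
  colnames(H) <- paste(rep(founder_ids, each = 2), 1:2, sep = ".")
  new_diplotypes(site_map, founder_ids, H)
}

new_diplotypes <- function(site_map, members, H) {
  structure(list(sites = tibble::as_tibble(site_map),
                 members = as.character(members), H = H),
            class = "diplotypes")
}

#' @export
print.diplotypes <- function(x, ...) {
  cat(sprintf("<diplotypes> %d sites, %d individuals\n", nrow(x$sites),
              length(x$members)))
  invisible(x)
}

# chromosome run boundaries of a sorted site map
chrom_runs <- function(site_map) {
  r <- rle(site_map$chrom)
  ends <- cumsum(r$lengths)
  tibble::tibble(chrom = r$values, from = c(1L, head(ends, -1) + 1L), to = ends)
}

#' One meiosis: recombine a parent's two haplotypes into a gamete
#'
#' Per chromosome, the crossover count is Poisson(length x `recomb_rate`)
#' with breakpoints uniform along the chromosome (no interference; the
#' default rate 1e-8 per bp corresponds to a uniform 1 cM/Mb genetic map).
#' The gamete alternates between the parental haplotypes at breakpoints,
#' starting from one of the two chosen by a fair coin per chromosome.
#'
#' @param parent_haps Integer matrix, sites x 2: the parent's haplotypes.
#' @param site_map Site map aligned with the haplotype rows.
#' @param chrom_lengths Chromosome lengths in bp (defaults to GRCh37
#'   autosomes for chromosomes present in the map).
#' @param recomb_rate Expected crossovers per bp per meiosis.
#' @return Integer vector: the gamete haplotype.
#' @export
meiosis <- function(parent_haps, site_map, chrom_lengths = grch37_lengths(),
                    recomb_rate = 1e-8) {
  stopifnot(ncol(parent_haps) == 2, nrow(parent_haps) == nrow(site_map))
  gamete <- parent_haps[, 1L]
  runs <- chrom_runs(site_map)
  for (i in seq_len(nrow(runs))) {
    rng <- runs$from[[i]]:runs$to[[i]]
    j <- match(norm_chrom(runs$chrom[[i]]), norm_chrom(names(chrom_lengths)))
    len <- if (is.na(j)) max(site_map$pos[rng]) else chrom_lengths[[j]]
    n_x <- rpois(1L, len * recomb_rate)
    start <- sample.int(2L, 1L)
    if (n_x == 0L) {
      seg <- 0L
    } else {
      seg <- findInterval(site_map$pos[rng], sort(runif(n_x, min = 1, max = len)))
    }
    pick <- (start + seg) %% 2L + 1L
    sel <- pick == 2L
    g <- parent_haps[rng, 1L]
    g[sel] <- parent_haps[rng, 2L][sel]
    gamete[rng] <- g
  }
  gamete
}

#' Drop genes down a pedigree
#'
#' Extends founder diplotypes to the whole pedigree: in topological order,
#' each non-founder receives one [meiosis()]-derived gamete from each parent.
#'
#' @param ped A pedigree tibble (see [read_pedigree()]).
#' @param founder_dip A `diplotypes` object covering exactly the pedigree
#'   founders (e.g. from [simulate_founders()]).
#' @param chrom_lengths,recomb_rate Passed to [meiosis()].
#' @param seed Optional integer seed.
#' @return A `diplotypes` object for all pedigree members.
#' @export
gene_drop <- function(ped, founder_dip, chrom_lengths = grch37_lengths(),
                      recomb_rate = 1e-8, seed = NULL) {
  ped <- validate_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  fnd <- founders(ped)
  if (!setequal(fnd, founder_dip$members)) {
    stop("founder diplotypes do not match pedigree founders", call. = FALSE)
  }
  site_map <- founder_dip$sites
  ord <- pedigree_order(ped)
  H <- matrix(0L, nrow = nrow(site_map), ncol = 2L * length(ord))
  colnames(H) <- paste(rep(ord, each = 2), 1:2, sep = ".")
  H[, colnames(founder_dip$H)] <- founder_dip$H
  fa <- setNames(ped$father, ped$id)
  mo <- setNames(ped$mother, ped$id)
  for (id in ord) {
    if (is.na(fa[[id]])) next
    H[, paste0(id, ".1")] <- meiosis(H[, paste0(fa[[id]], c(".1", ".2"))],
                                     site_map, chrom_lengths, recomb_rate)
    H[, paste0(id, ".2")] <- meiosis(H[, paste0(mo[[id]], c(".1", ".2"))],
                                     site_map, chrom_lengths, recomb_rate)
  }
  new_diplotypes(site_map, ord, H)
}

#' Collapse diplotypes to genotypes
#'
#' @param dip A `diplotypes` object.
#' @return A [genotype_matrix()] of alt-allele counts (no missing calls).
#' @export
genotypes <- function(dip) {
  stopifnot(inherits(dip, "diplotypes"))
  m <- length(dip$members)
  G <- dip$H[, 2L * seq_len(m) - 1L, drop = FALSE] +
    dip$H[, 2L * seq_len(m), drop = FALSE]
  colnames(G) <- dip$members
  genotype_matrix(dip$sites[c("chrom", "pos", "ref", "alt")], dip$members, G)
}

#' Inject per-genotype errors
#'
#' With probability `se`, independently per genotype per individual, the
#' called genotype is replaced by one of the two other codes chosen
#' uniformly; otherwise it is unchanged. This symmetric replacement is the
#' simulator's model of a per-SNV sequencing/calling error rate.
#'
#' @param gm A [genotype_matrix()] (or a `diplotypes` object, collapsed
#'   first).
#' @param se Error rate, `0 <= se < 0.5`.
#' @param seed Optional integer seed.
#' @return A `genotype_matrix` with perturbed calls.
#' @export
apply_error <- function(gm, se, seed = NULL) {
  if (inherits(gm, "diplotypes")) gm <- genotypes(gm)
  stopifnot(inherits(gm, "genotype_matrix"), se >= 0, se < 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (se == 0) return(gm)
  calls <- gm$calls
  called <- which(!is.na(calls))
  hit <- called[runif(length(called)) < se]
  if (length(hit)) {
    shift <- sample.int(2L, length(hit), replace = TRUE)
    calls[hit] <- (calls[hit] + shift) %% 3L
  }
  genotype_matrix(gm$sites, gm$samples, calls)
}

#' Simulate one family on a site map
#'
#' Convenience wrapper: founder draw + gene drop for a pedigree, on a fixed
#' site map.
#'
#' @inheritParams gene_drop
#' @param site_map A site map from [make_site_map()].
#' @param seed Optional integer seed fixing the founder draw and all meioses.
#' @return A `diplotypes` object for the full pedigree.
#' @export
simulate_family <- function(ped, site_map, chrom_lengths = grch37_lengths(),
                            recomb_rate = 1e-8, seed = NULL) {
  ped <- validate_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  fd <- simulate_founders(site_map, founders(ped))
  gene_drop(ped, fd, chrom_lengths = chrom_lengths, recomb_rate = recomb_rate)
}
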