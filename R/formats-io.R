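GT_CODES <- c(
  "0/0" = 0L, "0|0" = 0L,
  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L
)

#' Read multi-sample genotypes from standard formats
#'
#' Loads VCF (4.x, plain or gzip), PED+MAP or TPED files into a
#' [genotype_matrix()]. Only biallelic SNVs survive loading: multi-allelic
#' records, indels and other non-SNV records are dropped (with a message
#' reporting the count). Any genotype with a missing allele is coded `NA`;
#' phase separators are accepted and phase discarded (the method is
#' phase-free). Duplicated `(chrom, pos)` records keep the first occurrence,
#' with a warning. By default sites are restricted to autosomes.
#'
#' @param path Input file. For `ped_map` this is the `.ped` file (the `.map`
#'   file is found by extension or given via `map`); for `tped`, sample IDs
#'   are taken from a `.tfam` file alongside if present.
#' @param format One of `"vcf"`, `"ped_map"` (alias `"ped"`), `"tped"`.
#' @param map Optional explicit path to the MAP file.
#' @param autosomes_only Keep autosomal sites only (default TRUE).
#' @return A `genotype_matrix`. The attribute `"chrom_lengths"` carries
#'   contig lengths parsed from a VCF header, when present.
#' @export
read_genotypes <- function(path, format = c("vcf", "ped_map", "ped", "tped"),
                           map = NULL, autosomes_only = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gm <- switch(format,
    vcf = read_vcf_genotypes(path),
    ped_map = ,
    ped = read_ped_map_genotypes(path, map),
    tped = read_tped_genotypes(path)
  )
  if (autosomes_only) {
    keep <- is_autosome(gm$sites$chrom)
    dropped <- sum(!keep)
    if (dropped) message("dropped ", dropped, " non-autosomal site(s)")
    gm2 <- subset_sites(gm, which(keep))
    attr(gm2, "chrom_lengths") <- attr(gm, "chrom_lengths")
    gm <- gm2
  }
  if (nrow(gm$sites) == 0) {
    stop("no biallelic SNVs left after parsing ", path, call. = FALSE)
  }
  gm
}

dedup_sites <- function(sites, calls) {
  key <- paste(sites$chrom, sites$pos)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicated (chrom, pos) site(s): keeping first occurrence",
            call. = FALSE)
  }
  list(sites = sites[!dup, , drop = FALSE], calls = calls[!dup, , drop = FALSE])
}

read_vcf_genotypes <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx) # single-record VCF comes back as a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF ", path, call. = FALSE)
  snv <- grepl("^[ACGT]$", fix$REF) & grepl("^[ACGT]$", fix$ALT)
  if (any(!snv)) {
    message("dropped ", sum(!snv),
            " non-SNV or multi-allelic record(s) from ", basename(path))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = nrow(fix),
                 dimnames = list(NULL, colnames(v@gt)[-1]))
  }
  gt <- gt[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]
  calls <- matrix(unname(GT_CODES[gt]), nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
  sites <- tibble::tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT)
  dd <- dedup_sites(sites, calls)
  gm <- genotype_matrix(dd$sites, colnames(calls), dd$calls)
  attr(gm, "chrom_lengths") <- vcf_contig_lengths(v)
  gm
}

vcf_contig_lengths <- function(v) {
  meta <- v@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  if (!length(contig)) return(NULL)
  id <- sub(".*[<,]ID=([^,>]+).*", "\\1", contig)
  len <- suppressWarnings(as.numeric(sub(".*[<,]length=([0-9]+).*", "\\1", contig)))
  ok <- !is.na(len)
  if (!any(ok)) return(NULL)
  setNames(len[ok], id[ok])
}

split_ws <- function(lines, path, min_fields) {
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < min_fields)
  if (length(bad)) {
    stop("parse error in ", path, " at line ", bad[[1]],
         ": expected at least ", min_fields, " fields", call. = FALSE)
  }
  parts
}

# Convert per-site allele pairs (character) into alt counts. REF is the first
# allele observed at the site unless ref/alt are supplied; "0" is missing.
code_allele_site <- function(a1, a2, ref = NA, alt = NA) {
  obs <- c(a1, a2)
  seen <- unique(obs[obs != "0"])
  if (length(seen) > 2) return(NULL) # multi-allelic
  if (is.na(ref)) {
    ref <- if (length(seen)) seen[[1]] else "0"
    alt <- if (length(seen) > 1) seen[[2]] else "N"
  }
  if (!all(seen %in% c(ref, alt))) return(NULL)
  g <- (a1 == alt) + (a2 == alt)
  g[a1 == "0" | a2 == "0"] <- NA
  list(ref = ref, alt = alt, g = as.integer(g))
}

read_ped_map_genotypes <- function(ped_path, map_path = NULL) {
  if (is.null(map_path)) map_path <- sub("\\.ped(\\.gz)?$", ".map", ped_path)
  if (!file.exists(map_path)) {
    stop("PED+MAP requires both files; MAP not found: ", map_path, call. = FALSE)
  }
  map_parts <- split_ws(readLines(map_path), map_path, 4)
  n_sites <- length(map_parts)
  map_ref <- vapply(map_parts, function(p) if (length(p) >= 6) p[[5]] else NA_character_, "")
  map_alt <- vapply(map_parts, function(p) if (length(p) >= 6) p[[6]] else NA_character_, "")
  ped_parts <- split_ws(readLines(ped_path), ped_path, 6 + 2 * n_sites)
  samples <- vapply(ped_parts, `[[`, "", 2)
  # site x sample allele matrices
  a1 <- matrix(vapply(ped_parts, function(p) p[6 + 2 * seq_len(n_sites) - 1],
                      character(n_sites)), nrow = n_sites)
  a2 <- matrix(vapply(ped_parts, function(p) p[6 + 2 * seq_len(n_sites)],
                      character(n_sites)), nrow = n_sites)
  build_from_alleles(
    chrom = vapply(map_parts, `[[`, "", 1),
    pos = as.integer(vapply(map_parts, `[[`, "", 4)),
    a1 = a1, a2 = a2, samples = samples, ref = map_ref, alt = map_alt,
    src = ped_path
  )
}

read_tped_genotypes <- function(tped_path) {
  lines <- readLines(tped_path)
  if (!length(lines)) stop("no records in ", tped_path, call. = FALSE)
  parts <- split_ws(lines, tped_path, 6)
  n_alleles <- unique(lengths(parts)) - 4L
  if (length(n_alleles) != 1 || n_alleles %% 2 != 0) {
    stop("parse error in ", tped_path, ": inconsistent field counts", call. = FALSE)
  }
  n_samples <- n_alleles / 2L
  tfam <- sub("\\.tped$", ".tfam", tped_path)
  samples <- if (file.exists(tfam)) {
    vapply(split_ws(readLines(tfam), tfam, 2), `[[`, "", 2)
  } else {
    paste0("S", seq_len(n_samples))
  }
  if (length(samples) != n_samples) {
    stop("sample count mismatch between ", tped_path, " and ", tfam, call. = FALSE)
  }
  a1 <- t(matrix(vapply(parts, function(p) p[4L + 2L * seq_len(n_samples) - 1L],
                        character(n_samples)), nrow = n_samples))
  a2 <- t(matrix(vapply(parts, function(p) p[4L + 2L * seq_len(n_samples)],
                        character(n_samples)), nrow = n_samples))
  build_from_alleles(
    chrom = vapply(parts, `[[`, "", 1),
    pos = as.integer(vapply(parts, `[[`, "", 4)),
    a1 = a1, a2 = a2, samples = samples, src = tped_path
  )
}

# a1, a2: site x sample allele matrices
build_from_alleles <- function(chrom, pos, a1, a2, samples, ref = NULL,
                               alt = NULL, src = "input") {
  n_sites <- length(chrom)
  if (is.null(ref)) ref <- rep(NA_character_, n_sites)
  if (is.null(alt)) alt <- rep(NA_character_, n_sites)
  calls <- matrix(NA_integer_, nrow = n_sites, ncol = length(samples))
  ref_out <- character(n_sites)
  alt_out <- character(n_sites)
  keep <- logical(n_sites)
  for (i in seq_len(n_sites)) {
    coded <- code_allele_site(a1[i, ], a2[i, ], ref[[i]], alt[[i]])
    if (is.null(coded)) next
    snv <- nchar(coded$ref) == 1 && nchar(coded$alt) == 1
    if (!snv) next
    keep[[i]] <- TRUE
    ref_out[[i]] <- coded$ref
    alt_out[[i]] <- coded$alt
    calls[i, ] <- coded$g
  }
  if (any(!keep)) {
    message("dropped ", sum(!keep),
            " multi-allelic or non-SNV site(s) from ", basename(src))
  }
  sites <- tibble::tibble(chrom = chrom[keep], pos = pos[keep],
                          ref = ref_out[keep], alt = alt_out[keep])
  dd <- dedup_sites(sites, calls[keep, , drop = FALSE])
  genotype_matrix(dd$sites, samples, dd$calls)
}
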