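#' GRCh37 autosome lengths
#'
#' Reference lengths (bp) of the 22 human autosomes on the GRCh37/hg19
#' assembly, used as the default coordinate system for window segmentation
#' and for placing simulated variant sites.
#'
#' @return A named numeric vector; names are chromosome labels `"1"`..`"22"`.
#' @examples
#' sum(grch37_lengths()) / 1e9 # ~2.88 Gb of autosome
#' @export
grch37_lengths <- function() {
  c(
    `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566
  )
}

# Strip an optional "chr" prefix so "chr1" and "1" compare equal.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

# Default include-list: autosomes only. IBS expectations differ on X, and the
# method is defined over autosomal windows.
is_autosome <- function(chrom) norm_chrom(chrom) %in% as.character(1:22)
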