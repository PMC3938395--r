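#' Read a pedigree file
#'
#' Reads a 5-column whitespace-delimited pedigree table following the PED
#' convention: family ID, individual ID, father ID, mother ID, sex (1 = male,
#' 2 = female, 0 = unknown). `0` (or `NA`) in the parent columns marks a
#' founder; an individual must have either both parents or neither.
#'
#' @param path Path to the pedigree file.
#' @return A tibble with columns `fam`, `id`, `father`, `mother`, `sex`
#'   (parents `NA` for founders).
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 5)
  if (length(bad)) {
    stop("pedigree parse error at line ", bad[[1]], ": expected 5 columns",
         call. = FALSE)
  }
  ped <- tibble::tibble(
    fam = vapply(parts, `[[`, "", 1),
    id = vapply(parts, `[[`, "", 2),
    father = vapply(parts, `[[`, "", 3),
    mother = vapply(parts, `[[`, "", 4),
    sex = as.integer(vapply(parts, `[[`, "", 5))
  )
  ped$father[ped$father %in% c("0", "")] <- NA
  ped$mother[ped$mother %in% c("0", "")] <- NA
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("id", "father", "mother") %in% names(ped)))
  if (!"fam" %in% names(ped)) ped$fam <- "FAM1"
  if (!"sex" %in% names(ped)) ped$sex <- 0L
  if (anyDuplicated(ped$id)) stop("duplicate individual IDs in pedigree", call. = FALSE)
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half)) {
    stop("individual(s) with exactly one parent: ",
         paste(ped$id[half], collapse = ", "), call. = FALSE)
  }
  known <- !is.na(ped$father)
  unknown_parent <- c(setdiff(ped$father[known], ped$id),
                      setdiff(ped$mother[known], ped$id))
  if (length(unknown_parent)) {
    stop("parent ID(s) absent from pedigree: ",
         paste(unique(unknown_parent), collapse = ", "), call. = FALSE)
  }
  pedigree_order(ped) # errors on cycles
  ped
}

founders <- function(ped) ped$id[is.na(ped$father)]

# Topological order (founders first); errors on cycles.
pedigree_order <- function(ped) {
  resolved <- character(0)
  todo <- ped
  while (nrow(todo) > 0) {
    ready <- is.na(todo$father) |
      (todo$father %in% resolved & todo$mother %in% resolved)
    if (!any(ready)) stop("pedigree contains a cycle", call. = FALSE)
    resolved <- c(resolved, todo$id[ready])
    todo <- todo[!ready, , drop = FALSE]
  }
  resolved
}

#' The packaged 26-member, 7-generation pedigree
#'
#' A synthetic pedigree topology with 26 members across 7 generations and 10
#' founders, constructed so that one family contains every relationship class
#' needed to train and evaluate the classifier: full siblings,
#' parent-offspring, 2nd- through 5th-degree pairs, 6th- to 8th-degree pairs
#' (labelled UD) and unrelated founder pairs.
#'
#' @return A pedigree tibble (see [read_pedigree()]).
#' @examples
#' table(pair_truth(default_pedigree())$label)
#' @export
default_pedigree <- function() {
  read_pedigree(system.file("extdata", "pedigree_7gen.ped",
                            package = "kinwin", mustWork = TRUE))
}

#' Kinship matrix of a pedigree
#'
#' Recursive kinship coefficients: founders are mutually unrelated and
#' non-inbred; for a non-founder `i` with parents `f`, `m`,
#' `phi(i, j) = (phi(f, j) + phi(m, j)) / 2` for previously placed `j`, and
#' `phi(i, i) = (1 + phi(f, m)) / 2`.
#'
#' @param ped A pedigree tibble.
#' @return A symmetric numeric matrix with dimnames the individual IDs.
#' @export
kinship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)
  ord <- pedigree_order(ped)
  n <- length(ord)
  phi <- matrix(0, n, n, dimnames = list(ord, ord))
  fa <- setNames(ped$father, ped$id)
  mo <- setNames(ped$mother, ped$id)
  for (k in seq_len(n)) {
    i <- ord[[k]]
    if (is.na(fa[[i]])) {
      phi[i, i] <- 0.5
    } else {
      f <- fa[[i]]; m <- mo[[i]]
      if (k > 1) {
        js <- ord[seq_len(k - 1)]
        phi[i, js] <- (phi[f, js] + phi[m, js]) / 2
        phi[js, i] <- phi[i, js]
      }
      phi[i, i] <- (1 + phi[f, m]) / 2
    }
  }
  phi
}

#' True relationship labels for every pair in a pedigree
#'
#' Derives the gene-dropping truth table: for each unordered pair the kinship
#' coefficient, the degree of relationship (the combined number of
#' generations separating the pair from their most recent common ancestors,
#' computed as `-log2(2 * phi)` rounded), and the classifier label —
#' `PO`/`FS` resolved structurally, degrees 2-5 as `D2`..`D5`, degree 6 and
#' beyond as `UD`, kinship zero as `UN`. With `include_self = TRUE`,
#' self-pairs are added with label `IT`.
#'
#' @param ped A pedigree tibble.
#' @param include_self Add one `IT` row per individual (id paired with
#'   itself)? Default `FALSE`.
#' @return A tibble with columns `id1`, `id2`, `kinship`, `degree`, `label`.
#' @export
pair_truth <- function(ped, include_self = FALSE) {
  ped <- validate_pedigree(ped)
  phi <- kinship_matrix(ped)
  ids <- ped$id
  fa <- setNames(ped$father, ped$id)
  mo <- setNames(ped$mother, ped$id)
  pairs <- utils::combn(ids, 2)
  id1 <- pairs[1, ]; id2 <- pairs[2, ]
  k <- phi[cbind(id1, id2)]
  is_po <- (!is.na(fa[id1]) & (fa[id1] == id2 | mo[id1] == id2)) |
    (!is.na(fa[id2]) & (fa[id2] == id1 | mo[id2] == id1))
  is_fs <- !is.na(fa[id1]) & !is.na(fa[id2]) &
    fa[id1] == fa[id2] & mo[id1] == mo[id2]
  degree <- rep(NA_integer_, length(k))
  degree[k > 0] <- as.integer(round(-log2(2 * k[k > 0])))
  degree[is_po | is_fs] <- 1L
  label <- dplyr::case_when(
    is_po ~ "PO",
    is_fs ~ "FS",
    k == 0 ~ "UN",
    degree >= 6 ~ "UD",
    TRUE ~ paste0("D", degree)
  )
  out <- tibble::tibble(id1 = id1, id2 = id2, kinship = unname(k),
                        degree = as.integer(degree), label = label)
  if (include_self) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(id1 = ids, id2 = ids, kinship = unname(diag(phi)),
                     degree = 0L, label = "IT")
    )
  }
  out
}
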