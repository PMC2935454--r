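# Gene-family copy-number dynamics: family assignment by similarity
# thresholds, rates of copy-number change relative to a reference species,
# rate-pattern groups, and lineage-specific presence/absence reports.

#' Construct a gene-family copy-number matrix
#'
#' @param counts families x species matrix of non-negative integer copy
#'   numbers, with dimnames.
#' @param reference name of the reference species (a column of `counts`).
#' @param times named numeric vector of divergence times (million years)
#'   from the reference, one per species; the reference's own time must be
#'   0.
#' @return object of class `copy_number_matrix`.
#' @export
copy_number_matrix <- function(counts, reference, times) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("copy numbers must be non-negative")
  if (!reference %in% colnames(counts))
    abort("reference species not in matrix")
  if (!all(colnames(counts) %in% names(times)))
    abort("missing divergence time for: %s",
          paste(setdiff(colnames(counts), names(times)), collapse = ", "))
  if (any(times < 0)) abort("divergence times must be non-negative")
  if (times[[reference]] != 0) abort("reference time must be 0")
  structure(list(counts = counts, reference = reference,
                 times = times[colnames(counts)]),
            class = "copy_number_matrix")
}

#' Assign a gene to a family from its similarity hits
#'
#' The best hit passing the strict thresholds (similarity strictly above
#' `min_similarity`, alignment coverage strictly above `min_coverage`)
#' propagates its family; ties are broken by higher similarity, then by
#' lexicographic family id. With no passing hit the gene stays unassigned.
#'
#' @param hits data frame with columns `reference_family`,
#'   `percent_similarity` (in [0, 100]) and `alignment_coverage` (in
#'   [0, 1]).
#' @param min_similarity similarity threshold, percent (default 75; strict
#'   inequality).
#' @param min_coverage alignment-coverage threshold, fraction (default
#'   0.25; strict inequality).
#' @return the family id, or `NA_character_` when unassigned.
#' @export
assign_family <- function(hits, min_similarity = 75, min_coverage = 0.25) {
  if (!nrow(hits)) return(NA_character_)
  if (any(hits$percent_similarity < 0 | hits$percent_similarity > 100) ||
      any(hits$alignment_coverage < 0 | hits$alignment_coverage > 1))
    abort("malformed hit bounds")
  ok <- hits[hits$percent_similarity > min_similarity &
               hits$alignment_coverage > min_coverage, , drop = FALSE]
  if (!nrow(ok)) return(NA_character_)
  ok <- ok[order(-ok$percent_similarity, ok$reference_family), ,
           drop = FALSE]
  ok$reference_family[1]
}

#' Rates of copy-number change relative to the reference species
#'
#' R_ij = (n_ij - n_ih) / T_jh: the observed change in copy number of
#' family i in species j relative to the reference h, per million years of
#' divergence. The reference column is zero by construction. The rate
#' function is pluggable; the alternative `"normalized"` divides the copy
#' difference by (n_ih + 1) before the time scaling.
#'
#' @param matrix a `copy_number_matrix`.
#' @param rate_fn `"difference"` (default) or `"normalized"`.
#' @return object of class `rate_matrix`: list with `rates` (families x
#'   species numeric matrix) and `reference`.
#' @export
rate_matrix <- function(matrix, rate_fn = c("difference", "normalized")) {
  rate_fn <- match.arg(rate_fn)
  stopifnot(inherits(matrix, "copy_number_matrix"))
  h <- matrix$reference
  nonref <- setdiff(colnames(matrix$counts), h)
  if (any(matrix$times[nonref] <= 0))
    abort("non-reference divergence times must be > 0")
  ref_counts <- matrix$counts[, h]
  delta <- matrix$counts - ref_counts
  if (rate_fn == "normalized") delta <- delta / (ref_counts + 1)
  rates <- sweep(delta, 2, ifelse(matrix$times > 0, matrix$times, 1), "/")
  rates[, h] <- 0
  structure(list(rates = rates, reference = h), class = "rate_matrix")
}

#' Group gene families into rate pattern groups (RPGs)
#'
#' Families are keyed by their cross-species rate signature and grouped by
#' identical keys. In `"sign"` mode (default, the robust reading) the key is
#' the per-species sign vector of R: expanded (+), contracted (-) or equal
#' (0) relative to the reference. In `"ranking"` mode the key is the
#' ordering of species sorted by R, ties broken by species id.
#'
#' @param rates a `rate_matrix`.
#' @param mode `"sign"` or `"ranking"`.
#' @return data frame `family`, `pattern` (key string), `group` (integer
#'   group id; groups partition the families).
#' @export
rpg_group <- function(rates, mode = c("sign", "ranking")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rates, "rate_matrix"))
  r <- rates$rates[, setdiff(colnames(rates$rates), rates$reference),
                   drop = FALSE]
  key <- if (mode == "sign") {
    apply(r, 1, function(x)
      paste(colnames(r), c("-", "0", "+")[sign(x) + 2], sep = "",
            collapse = " "))
  } else {
    apply(r, 1, function(x)
      paste(colnames(r)[order(-x, colnames(r))], collapse = " "))
  }
  df <- data.frame(family = rownames(r), pattern = unname(key),
                   stringsAsFactors = FALSE)
  df$group <- match(df$pattern, unique(df$pattern))
  df
}

#' Families present only (or absent only) in a focal species set
#'
#' `present_only` lists families with at least `presence_min` copies in
#' every focal species and zero copies in every background species;
#' `absent_only` is the converse (absent from all focal, present in all
#' background). The strict all-species rule means partial presence lands in
#' neither list. Typical parameterizations: birds vs non-birds,
#' turkey+chicken vs the rest, or egg-laying species (birds + platypus) vs
#' eutherians.
#'
#' @param matrix a `copy_number_matrix`.
#' @param focal,background disjoint character vectors of species names.
#' @param presence_min minimum copy count that counts as present (default
#'   1).
#' @return list with character vectors `present_only` and `absent_only`
#'   (family ids; always disjoint).
#' @export
lineage_specific_families <- function(matrix, focal, background,
                                      presence_min = 1L) {
  stopifnot(inherits(matrix, "copy_number_matrix"))
  if (length(intersect(focal, background)))
    abort("focal and background species sets must be disjoint")
  cn <- matrix$counts
  miss <- setdiff(c(focal, background), colnames(cn))
  if (length(miss)) abort("unknown species: %s", paste(miss, collapse = ", "))
  f <- cn[, focal, drop = FALSE]
  b <- cn[, background, drop = FALSE]
  present_only <- rownames(cn)[rowSums(f >= presence_min) == length(focal) &
                                 rowSums(b == 0) == length(background)]
  absent_only <- rownames(cn)[rowSums(f == 0) == length(focal) &
                                rowSums(b >= presence_min) ==
                                  length(background)]
  list(present_only = present_only, absent_only = absent_only)
}
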