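# Tiered SNV classification from pileup columns.
#
# A strong SNV requires, for each of >= 2 variant alleles, at least three
# supporting reads and a top-three quality sum of at least 60, with overall
# column depth at most 30. A weak SNV relaxes this to two reads and a
# top-two quality sum of 45, with no depth cap. Indels inside homopolymer
# runs additionally require at least one short-read-platform observation per
# variant, filtering the homopolymer indel error mode of pyrosequencing.

#' Classification thresholds for tiered SNV calling
#'
#' @param strong_min_support,strong_top_k,strong_qual_sum,strong_max_depth
#'   strong-tier thresholds: minimum reads per variant, number of top
#'   qualities summed, minimum quality sum, and maximum column depth.
#' @param weak_min_support,weak_top_k,weak_qual_sum weak-tier thresholds (no
#'   depth cap).
#' @param homopolymer_min_run minimum mononucleotide run length for the
#'   homopolymer indel rule to apply.
#' @param shortread_platform platform tag whose reads may validate a
#'   homopolymer indel.
#' @return a list of class `snv_config`.
#' @export
snv_config <- function(strong_min_support = 3L, strong_top_k = 3L,
                       strong_qual_sum = 60, strong_max_depth = 30L,
                       weak_min_support = 2L, weak_top_k = 2L,
                       weak_qual_sum = 45,
                       homopolymer_min_run = 2L,
                       shortread_platform = "short-read") {
  vals <- c(strong_min_support, strong_top_k, strong_qual_sum,
            strong_max_depth, weak_min_support, weak_top_k, weak_qual_sum,
            homopolymer_min_run)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all thresholds must be positive")
  structure(list(strong_min_support = strong_min_support,
                 strong_top_k = strong_top_k,
                 strong_qual_sum = strong_qual_sum,
                 strong_max_depth = strong_max_depth,
                 weak_min_support = weak_min_support,
                 weak_top_k = weak_top_k, weak_qual_sum = weak_qual_sum,
                 homopolymer_min_run = homopolymer_min_run,
                 shortread_platform = shortread_platform),
            class = "snv_config")
}

#' Quality of a gap observation from its flanking bases
#'
#' Gaps in a multiple alignment carry no base quality of their own; they are
#' assigned the minimum quality of the read's bases flanking the gap. At a
#' read end only one flank exists and its quality is used alone; a gap with
#' no flanking base on either side is unusable.
#'
#' @param column the `pileup_column` containing the observation (unused by
#'   the default rule but part of the interface; contexts may matter for
#'   alternative rules).
#' @param observation a single-row observation with `flank_left` and/or
#'   `flank_right` Phred qualities (`NA` where the read has no flank).
#' @return the assigned Phred quality (integer).
#' @export
assign_gap_quality <- function(column, observation) {
  fl <- suppressWarnings(as.numeric(observation$flank_left))
  fr <- suppressWarnings(as.numeric(observation$flank_right))
  if (length(fl) == 0) fl <- NA_real_
  if (length(fr) == 0) fr <- NA_real_
  vals <- c(fl, fr)
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    abort("gap observation has no flanking bases; unusable")
  as.integer(min(vals))
}

#' Is an indel column inside a homopolymer run?
#'
#' TRUE iff the indel base (the consensus base for deletions, the inserted
#' base for insertion columns) together with equal consensus neighbours forms
#' a mononucleotide run of length >= `min_run` spanning the column. The run
#' count includes the column's own base, so an insertion of `A` adjacent to a
#' single consensus `A` is a run of 2.
#'
#' @param column a `pileup_column` with an indel variant.
#' @param min_run minimum run length (default 2).
#' @param base the indel base; inferred when missing (consensus for
#'   deletions, most frequent non-gap observed symbol for insertion columns).
#' @return logical.
#' @export
is_homopolymer_indel <- function(column, min_run = 2L, base = NULL) {
  if (is.null(base)) {
    if (!column$insert && column$consensus != "-") {
      base <- column$consensus
    } else {
      sym <- column$obs$symbol
      sym <- sym[!sym %in% c("-", "N")]
      if (!length(sym)) return(FALSE)
      base <- names(sort(table(sym), decreasing = TRUE))[1]
    }
  }
  count_run <- function(ctx, from_end) {
    if (!nzchar(ctx)) return(0L)
    chars <- strsplit(ctx, "")[[1]]
    if (from_end) chars <- rev(chars)
    run <- 0L
    for (ch in chars) {
      if (ch == base) run <- run + 1L else break
    }
    run
  }
  run <- 1L + count_run(column$left_context, TRUE) +
    count_run(column$right_context, FALSE)
  run >= min_run
}

#' Tally variant evidence in a pileup column
#'
#' One entry per distinct non-N symbol observed, with its read support, the
#' sorted quality values, and the set of platforms carrying it. Gap
#' observations with `NA` quality take the flank-minimum quality via
#' [assign_gap_quality()]. Entries are ordered by support descending, allele
#' ascending on ties.
#'
#' @param column a `pileup_column`.
#' @return data frame with columns `allele`, `support`, `qualities` (list
#'   column, sorted decreasing) and `platforms` (list column).
#' @export
variant_evidence <- function(column) {
  obs <- column$obs
  obs <- obs[obs$symbol != "N", , drop = FALSE]
  if (nrow(obs)) {
    q <- obs$quality
    gap_na <- is.na(q) & obs$symbol == "-"
    if (any(gap_na))
      q[gap_na] <- vapply(which(gap_na), function(i)
        assign_gap_quality(column, obs[i, , drop = FALSE]), integer(1))
    obs$quality <- q
  }
  alleles <- sort(unique(obs$symbol))
  ev <- data.frame(allele = alleles,
                   support = vapply(alleles, function(a)
                     sum(obs$symbol == a), integer(1)),
                   stringsAsFactors = FALSE)
  ev$qualities <- lapply(alleles, function(a)
    sort(obs$quality[obs$symbol == a], decreasing = TRUE))
  ev$platforms <- lapply(alleles, function(a)
    sort(unique(obs$platform[obs$symbol == a])))
  ev <- ev[order(-ev$support, ev$allele), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Sum of the k largest quality values
#'
#' @param qualities numeric vector of Phred qualities.
#' @param k how many of the largest values to sum; if fewer are available
#'   all are summed.
#' @return numeric sum.
#' @export
top_quality_sum <- function(qualities, k) {
  sum(utils::head(sort(qualities, decreasing = TRUE), k))
}

# Alleles meeting a (min_support, top_k, qual_sum) per-allele threshold set.
.qualifying <- function(ev, min_support, top_k, qual_sum) {
  ok <- ev$support >= min_support &
    vapply(ev$qualities, top_quality_sum, numeric(1), k = top_k) >= qual_sum
  ev[ok, , drop = FALSE]
}

#' Classify a pileup column into an SNV tier
#'
#' Applies the tiered criteria: strong iff at least two alleles each meet
#' the strong per-allele thresholds and the column depth is within the cap;
#' otherwise weak iff at least two alleles meet the weak thresholds; else
#' none. Depth counts all non-N observations across both platforms. If the
#' variant is an indel within a homopolymer run, every qualifying variant
#' must additionally be supported by at least one short-read-platform
#' observation (in both tiers).
#'
#' @param column a `pileup_column`.
#' @param cfg an `snv_config`.
#' @return `"strong"`, `"weak"` or `"none"`.
#' @export
classify_column <- function(column, cfg = snv_config()) {
  stopifnot(inherits(cfg, "snv_config"))
  ev <- variant_evidence(column)
  depth <- sum(ev$support)
  tier_ok <- function(min_support, top_k, qual_sum) {
    q <- .qualifying(ev, min_support, top_k, qual_sum)
    if (nrow(q) < 2) return(FALSE)
    gap_involved <- column$insert || "-" %in% q$allele
    if (gap_involved &&
        is_homopolymer_indel(column, cfg$homopolymer_min_run)) {
      if (!all(vapply(q$platforms, function(p)
        cfg$shortread_platform %in% p, logical(1)))) return(FALSE)
    }
    TRUE
  }
  if (depth <= cfg$strong_max_depth &&
      tier_ok(cfg$strong_min_support, cfg$strong_top_k, cfg$strong_qual_sum))
    return("strong")
  if (tier_ok(cfg$weak_min_support, cfg$weak_top_k, cfg$weak_qual_sum))
    return("weak")
  "none"
}

#' Call SNVs over a stream of pileup columns
#'
#' Classifies every column and returns one call per column whose tier is not
#' none. A site qualifying as strong is reported strong and never relabelled
#' weak; the weak tier is the more inclusive catalogue. The call records the
#' two best-supported qualifying alleles, the variant kind (indel if any
#' qualifying allele is a gap or the column is an insertion column), and a
#' multiallelic flag when more than two alleles meet the tier's per-allele
#' thresholds.
#'
#' @param columns a `pileup` object (from [gen_columns()]) or a list of
#'   `pileup_column` objects sorted by (contig, position).
#' @param cfg an `snv_config`.
#' @return a data frame of class `snv_calls` with columns `contig`,
#'   `position` (0-based), `insert`, `tier`, `kind`, `allele1`, `allele2`,
#'   `depth`, `multiallelic`, `n_qualifying`.
#' @export
call_snvs <- function(columns, cfg = snv_config()) {
  if (inherits(columns, "pileup")) {
    pu <- columns
    obs <- pu$obs[pu$obs$symbol != "N", , drop = FALSE]
    key <- paste(obs$pos, obs$insert)
    # candidate columns: >= 2 distinct symbols observed
    nsym <- tapply(obs$symbol, key, function(s) length(unique(s)))
    cand <- names(nsym)[nsym >= 2]
    keys <- do.call(rbind, strsplit(cand, " ", fixed = TRUE))
    columns <- list()
    if (length(cand)) {
      pos <- as.integer(keys[, 1]); insrt <- keys[, 2] == "TRUE"
      o <- order(pos, insrt)
      columns <- lapply(o, function(i) .column_at(pu, pos[i], insrt[i]))
    }
  } else if (length(columns)) {
    pos <- vapply(columns, function(c) c$position, integer(1))
    ctg <- vapply(columns, function(c) c$contig, character(1))
    if (!identical(order(ctg, pos), seq_along(columns)))
      abort("columns must be sorted by (contig, position)")
  }
  rows <- lapply(columns, function(col) {
    tier <- classify_column(col, cfg)
    if (tier == "none") return(NULL)
    ev <- variant_evidence(col)
    q <- if (tier == "strong")
      .qualifying(ev, cfg$strong_min_support, cfg$strong_top_k,
                  cfg$strong_qual_sum)
    else
      .qualifying(ev, cfg$weak_min_support, cfg$weak_top_k,
                  cfg$weak_qual_sum)
    data.frame(contig = col$contig, position = col$position,
               insert = col$insert, tier = tier,
               kind = if (col$insert || "-" %in% q$allele) "indel"
                 else "substitution",
               allele1 = q$allele[1], allele2 = q$allele[2],
               depth = sum(ev$support), multiallelic = nrow(q) > 2,
               n_qualifying = nrow(q), stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(contig = character(0), position = integer(0),
                        insert = logical(0), tier = character(0),
                        kind = character(0), allele1 = character(0),
                        allele2 = character(0), depth = integer(0),
                        multiallelic = logical(0),
                        n_qualifying = integer(0), stringsAsFactors = FALSE)
  class(calls) <- c("snv_calls", class(calls))
  calls
}

#' Transition or transversion?
#'
#' @param a,b distinct nucleotides in `{A,C,G,T}`.
#' @return `"transition"` (purine-purine or pyrimidine-pyrimidine) or
#'   `"transversion"`.
#' @export
substitution_class <- function(a, b) {
  if (!all(c(a, b) %in% c("A", "C", "G", "T")) || a == b)
    abort("need two distinct bases in {A,C,G,T}")
  pur <- c("A", "G")
  if ((a %in% pur) == (b %in% pur)) "transition" else "transversion"
}

#' Transition/transversion ratio rounded to one decimal
#'
#' @param transitions,transversions non-negative counts.
#' @return numeric ratio rounded to one decimal; `NA` when transversions are
#'   zero.
#' @export
titv_ratio <- function(transitions, transversions) {
  if (transversions == 0) return(NA_real_)
  round(transitions / transversions, 1)
}

#' Summarize a set of SNV calls
#'
#' @param calls an `snv_calls` data frame.
#' @param tier which calls enter the depth moments: `"strong"` or `"total"`
#'   (strong + weak).
#' @return list of class `snv_summary`: `n_strong`, `n_total`, `transitions`,
#'   `transversions`, `titv` (ratio rounded to one decimal; `NA` with
#'   `titv_defined = FALSE` when undefined), `indels`, `multiallelic`,
#'   `depth_mean`, `depth_sd` (over the selected tier).
#' @export
summarize_calls <- function(calls, tier = c("strong", "total")) {
  tier <- match.arg(tier)
  sel <- if (tier == "strong") calls[calls$tier == "strong", , drop = FALSE]
    else calls
  subs <- calls[calls$kind == "substitution" & !calls$multiallelic, ,
                drop = FALSE]
  cls <- if (nrow(subs))
    vapply(seq_len(nrow(subs)), function(i)
      substitution_class(subs$allele1[i], subs$allele2[i]), character(1))
  else character(0)
  ts <- sum(cls == "transition"); tv <- sum(cls == "transversion")
  structure(list(
    n_strong = sum(calls$tier == "strong"), n_total = nrow(calls),
    transitions = ts, transversions = tv,
    titv = titv_ratio(ts, tv), titv_defined = tv > 0,
    indels = sum(calls$kind == "indel"),
    multiallelic = sum(calls$multiallelic),
    depth_mean = if (nrow(sel)) mean(sel$depth) else NA_real_,
    depth_sd = if (nrow(sel) > 1) stats::sd(sel$depth) else NA_real_,
    tier = tier), class = "snv_summary")
}

#' Watterson estimator of nucleotide diversity
#'
#' theta = S / (a * L) with a = sum_{i=1}^{n-1} 1/i, the per-base population
#' mutation rate estimated from S segregating sites over L covered bases in
#' n sampled sequences.
#'
#' @param S segregating-site count (>= 0).
#' @param L covered bases (> 0).
#' @param n number of sequences (>= 2).
#' @return list of class `diversity_estimate` with fields `theta`, `S`, `L`,
#'   `n`, `a`.
#' @export
watterson_theta <- function(S, L, n) {
  if (L <= 0) abort("L must be > 0")
  if (n < 2) abort("n must be >= 2")
  if (S < 0) abort("S must be >= 0")
  a <- sum(1 / seq_len(n - 1))
  structure(list(theta = S / (a * L), S = S, L = L, n = n, a = a),
            class = "diversity_estimate")
}

# Left-align a single-base indel against the reference: slide the event to
# the leftmost position of the mononucleotide run it sits in. Returns the
# 0-based anchor position (base preceding the event in VCF representation).
.left_normalize <- function(refv, pos, base, kind) {
  p <- if (kind == "deletion") pos else pos + 1L  # first base of/after event
  while (p > 0 && refv[p] == base) p <- p - 1L
  p - 1L  # anchor = base before the run start (0-based); may be -1
}

#' Write SNV calls as a VCF 4.2 document
#'
#' Positions are converted to 1-based; indels are anchored on the previous
#' reference base and left-normalized through mononucleotide runs. The tier
#' is carried in FILTER (`PASS` for strong, `weak` otherwise) and in the
#' `TIER` INFO key alongside `DP` and a `MULTI` flag.
#'
#' @param calls an `snv_calls` data frame sorted by position.
#' @param reference reference sequence: a single string or named character
#'   vector keyed by contig.
#' @param path output file path.
#' @return `path`, invisibly. `read_vcf_calls()` parses a file written by
#'   this function back into a data frame (CHROM, POS, REF, ALT, FILTER,
#'   TIER, DP, MULTI).
#' @export
write_vcf <- function(calls, reference, path) {
  if (is.null(names(reference)) && length(reference) == 1L)
    names(reference) <- unique(c(calls$contig, "ref"))[1]
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=TIER,Number=1,Type=String,Description=\"SNV evidence tier\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Column depth\">",
           "##INFO=<ID=MULTI,Number=0,Type=Flag,Description=\"More than two well-supported variants\">",
           "##FILTER=<ID=weak,Description=\"Weak-tier SNV\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    body <- vapply(seq_len(nrow(calls)), function(i) {
      ctg <- calls$contig[i]
      refstr <- reference[[ctg]]
      if (is.null(refstr)) abort("no reference sequence for contig %s", ctg)
      refv <- strsplit(refstr, "")[[1]]
      p0 <- calls$position[i]
      if (p0 >= length(refv) || p0 < 0)
        abort("call position %d outside reference", p0)
      a <- c(calls$allele1[i], calls$allele2[i])
      if (calls$kind[i] == "substitution") {
        refb <- refv[p0 + 1L]
        alt <- setdiff(a, refb)
        if (!length(alt)) alt <- a[2]
        pos1 <- p0 + 1L
        ref_field <- refb
        alt_field <- paste(alt, collapse = ",")
      } else if (calls$insert[i]) {
        base <- setdiff(a, "-")[1]
        anchor <- .left_normalize(refv, p0, base, "insertion")
        if (anchor < 0) anchor <- 0L  # clamp at contig start
        pos1 <- anchor + 1L
        ref_field <- refv[anchor + 1L]
        alt_field <- paste0(ref_field, base)
      } else {
        base <- refv[p0 + 1L]
        anchor <- .left_normalize(refv, p0, base, "deletion")
        if (anchor < 0) anchor <- 0L
        pos1 <- anchor + 1L
        ref_field <- paste0(refv[anchor + 1L], base)
        alt_field <- refv[anchor + 1L]
      }
      info <- sprintf("TIER=%s;DP=%d%s", calls$tier[i], calls$depth[i],
                      if (calls$multiallelic[i]) ";MULTI" else "")
      paste(ctg, pos1, ".", ref_field, alt_field, ".",
            if (calls$tier[i] == "strong") "PASS" else "weak",
            info, sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(CHROM = character(0), POS = integer(0),
                      REF = character(0), ALT = character(0),
                      FILTER = character(0), TIER = character(0),
                      DP = integer(0), MULTI = logical(0)))
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info <- f[, 8]
  data.frame(CHROM = f[, 1], POS = as.integer(f[, 2]), REF = f[, 4],
             ALT = f[, 5], FILTER = f[, 7],
             TIER = sub(".*TIER=([^;]+).*", "\\1", info),
             DP = as.integer(sub(".*DP=([0-9]+).*", "\\1", info)),
             MULTI = grepl("MULTI", info), stringsAsFactors = FALSE)
}
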