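# Fixture builders and independent brute-force oracles used across tests.

# Build a pileup column from terse allele spec: syms/quals/platforms vectors.
make_col <- function(syms, quals, platforms = rep("short-read", length(syms)),
                     consensus = "A", left = "", right = "",
                     contig = "c1", position = 10L,
                     insert = identical(consensus, "-")) {
  rid <- if (length(syms)) paste0("r", seq_along(syms)) else character(0)
  pileup_column(contig, position, consensus,
                data.frame(symbol = syms, quality = quals,
                           platform = platforms, read_id = rid,
                           stringsAsFactors = FALSE),
                left_context = left, right_context = right, insert = insert)
}

# n reads of one allele at a fixed quality
reads <- function(sym, n, q, platform = "short-read") {
  list(syms = rep(sym, n), quals = rep(q, n),
       platforms = rep(platform, n))
}

two_allele_col <- function(a, b, consensus = a$syms[1], ...) {
  make_col(c(a$syms, b$syms), c(a$quals, b$quals),
           c(a$platforms, b$platforms), consensus = consensus, ...)
}

# Literal, loop-based re-evaluation of the tier criteria, written
# independently of classify_column: evaluates each published criterion
# directly on the raw observations.
brute_tier <- function(col, cfg = snv_config()) {
  obs <- col$obs
  keep <- obs$symbol != "N"
  obs <- obs[keep, , drop = FALSE]
  for (i in seq_len(nrow(obs))) {
    if (is.na(obs$quality[i]) && obs$symbol[i] == "-") {
      fl <- c(obs$flank_left[i], obs$flank_right[i])
      obs$quality[i] <- min(fl[!is.na(fl)])
    }
  }
  depth <- nrow(obs)
  alleles <- sort(unique(obs$symbol))
  meets <- function(a, min_sup, k, qsum) {
    qs <- sort(obs$quality[obs$symbol == a], decreasing = TRUE)
    length(qs) >= min_sup && sum(qs[seq_len(min(k, length(qs)))]) >= qsum
  }
  run_base <- if (!col$insert && col$consensus != "-") col$consensus else {
    ng <- obs$symbol[obs$symbol != "-"]
    if (length(ng)) names(sort(table(ng), decreasing = TRUE))[1] else ""
  }
  in_hp_run <- function() {
    if (run_base == "") return(FALSE)
    run <- 1L
    lc <- strsplit(col$left_context, "")[[1]]
    for (ch in rev(lc)) if (ch == run_base) run <- run + 1L else break
    rc <- strsplit(col$right_context, "")[[1]]
    for (ch in rc) if (ch == run_base) run <- run + 1L else break
    run >= cfg$homopolymer_min_run
  }
  hp_ok <- function(a_set) {
    gap <- col$insert || "-" %in% a_set
    if (!gap || !in_hp_run()) return(TRUE)
    for (a in a_set) {
      if (!any(obs$platform[obs$symbol == a] == cfg$shortread_platform))
        return(FALSE)
    }
    TRUE
  }
  strong_set <- alleles[vapply(alleles, meets, logical(1),
                               cfg$strong_min_support, cfg$strong_top_k,
                               cfg$strong_qual_sum)]
  if (depth <= cfg$strong_max_depth && length(strong_set) >= 2 &&
      hp_ok(strong_set)) return("strong")
  weak_set <- alleles[vapply(alleles, meets, logical(1),
                             cfg$weak_min_support, cfg$weak_top_k,
                             cfg$weak_qual_sum)]
  if (length(weak_set) >= 2 && hp_ok(weak_set)) return("weak")
  "none"
}

# Random column generator for the oracle-equivalence suites.
random_column <- function() {
  bases <- c("A", "C", "G", "T")
  consensus <- sample(c(bases, "-"), 1, prob = c(rep(0.22, 4), 0.12))
  depth <- sample(1:40, 1)
  pool <- c(bases, "-", "N")
  # favour one or two dominant symbols so interesting tiers arise
  dom <- sample(pool[1:5], 2)
  syms <- sample(c(dom, pool), depth, replace = TRUE,
                 prob = c(8, 6, rep(0.6, 6)))
  quals <- sample(5:40, depth, replace = TRUE)
  plats <- sample(c("long-read", "short-read"), depth, replace = TRUE)
  ctx <- function() paste(sample(bases, sample(0:4, 1), replace = TRUE),
                          collapse = "")
  # sometimes force a homopolymer context around the consensus
  left <- ctx(); right <- ctx()
  if (stats::runif(1) < 0.4 && consensus %in% bases) {
    left <- paste0(ctx(), strrep(consensus, sample(0:3, 1)))
    right <- paste0(strrep(consensus, sample(0:3, 1)), ctx())
  }
  make_col(syms, quals, plats, consensus = consensus,
           left = left, right = right)
}

# Position-wise labelling oracle for coverage partition.
brute_partition_labels <- function(track) {
  a <- track$depths[[1]]; b <- track$depths[[2]]
  out <- character(track$length)
  for (i in seq_len(track$length)) {
    out[i] <- if (a[i] >= 1 && b[i] >= 1) "both"
      else if (a[i] >= 1) "only_A"
      else if (b[i] >= 1) "only_B"
      else "neither"
  }
  out
}

intervals_to_mask <- function(intervals, length) {
  m <- logical(length)
  for (i in seq_len(nrow(intervals)))
    m[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  m
}

# Brute-force minimum number of single-chromosome strictly monotone pieces
# over all contiguous partitions (dynamic program over prefixes).
brute_min_blocks <- function(hits) {
  n <- nrow(hits)
  if (n == 0) return(0L)
  valid <- function(i, j) {
    ch <- hits$chromosome[i:j]
    if (length(unique(ch)) > 1) return(FALSE)
    o <- hits$chrom_order[i:j]
    if (length(o) == 1) return(TRUE)
    d <- diff(o)
    all(d > 0) || all(d < 0)
  }
  best <- rep(Inf, n + 1)
  best[1] <- 0
  for (j in seq_len(n))
    for (i in seq_len(j))
      if (valid(i, j)) best[j + 1] <- min(best[j + 1], best[i] + 1)
  best[n + 1]
}
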