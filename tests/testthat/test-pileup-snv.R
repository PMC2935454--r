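# Tiered SNV classification: gap qualities, homopolymer predicate, evidence
# tallies, the strong/weak criteria, summaries, diversity, and VCF io.

test_that("gap observations take the minimum flanking quality", {
  col <- make_col("-", NA)
  obs <- function(l, r) data.frame(symbol = "-", quality = NA,
                                   flank_left = l, flank_right = r)
  expect_equal(assign_gap_quality(col, obs(20, 35)), 20L)
  expect_equal(assign_gap_quality(col, obs(30, 30)), 30L)
  expect_equal(assign_gap_quality(col, obs(NA, 25)), 25L)  # read-end gap
  expect_error(assign_gap_quality(col, obs(NA, NA)), "unusable")
})

test_that("homopolymer predicate counts the run spanning the column", {
  del_in_run <- make_col("-", 30, consensus = "A", left = "GA", right = "AC")
  expect_true(is_homopolymer_indel(del_in_run, 2))
  ins_no_run <- make_col("C", 30, consensus = "-", left = "TA", right = "GT",
                         insert = TRUE)
  expect_false(is_homopolymer_indel(ins_no_run, 2))

  # boundary: run of exactly min_run - 1 fails, exactly min_run passes,
  # enumerated over left/right split of the neighbours
  for (min_run in 2:4) {
    for (n_left in 0:(min_run - 1)) {
      n_right_pass <- min_run - 1 - n_left   # + the column's own base
      col_pass <- make_col("-", 30, consensus = "A",
                           left = paste0("G", strrep("A", n_left)),
                           right = paste0(strrep("A", n_right_pass), "C"))
      expect_true(is_homopolymer_indel(col_pass, min_run))
      if (n_right_pass > 0) {
        col_fail <- make_col("-", 30, consensus = "A",
                             left = paste0("G", strrep("A", n_left)),
                             right = paste0(strrep("A", n_right_pass - 1),
                                            "C"))
        expect_false(is_homopolymer_indel(col_fail, min_run))
      }
    }
  }
})

test_that("variant evidence tallies match a brute-force count", {
  a <- reads("A", 4, 30); g <- reads("G", 3, 25)
  ev <- variant_evidence(two_allele_col(a, g))
  expect_equal(ev$allele, c("A", "G"))
  expect_equal(ev$support, c(4L, 3L))

  ev1 <- variant_evidence(make_col(rep("T", 5), rep(20, 5)))
  expect_equal(nrow(ev1), 1)

  set.seed(99)
  for (i in 1:50) {
    col <- random_column()
    ev <- variant_evidence(col)
    keep <- col$obs$symbol != "N"
    tally <- table(col$obs$symbol[keep])
    expect_setequal(ev$allele, names(tally))
    expect_equal(ev$support[match(names(tally), ev$allele)],
                 unname(as.integer(tally)))
    # sorted by support desc, allele asc on ties
    expect_true(all(diff(ev$support) <= 0))
  }
})

test_that("N observations are excluded from evidence and depth", {
  col <- make_col(c("A", "A", "A", "G", "G", "G", "N", "N"),
                  c(30, 30, 30, 30, 30, 30, 30, 30))
  ev <- variant_evidence(col)
  expect_false("N" %in% ev$allele)
  expect_equal(sum(ev$support), 6)
})

test_that("tier criteria: worked strong/weak/none cases", {
  # depth 20 (incl. 4 concordant reads), two alleles with ample support
  a <- reads("A", 10, 30); g <- reads("G", 6, 30); c4 <- reads("A", 4, 30)
  col <- make_col(c(a$syms, g$syms, c4$syms), c(a$quals, g$quals, c4$quals),
                  consensus = "A")
  expect_equal(classify_column(col), "strong")

  # same evidence at depth 35: strong depth cap fails, weak has no cap
  deep <- make_col(c(rep("A", 25), rep("G", 10)), rep(30, 35),
                   consensus = "A")
  expect_equal(classify_column(deep), "weak")

  # homopolymer deletion with the gap allele seen only on long reads: none
  hp <- make_col(c(rep("A", 5), rep("-", 5)), rep(30, 10),
                 platforms = c(rep("short-read", 5), rep("long-read", 5)),
                 consensus = "A", left = "CA", right = "AG")
  expect_equal(classify_column(hp), "none")
  # the same column with short-read gap support is strong again
  hp2 <- make_col(c(rep("A", 5), rep("-", 5)), rep(30, 10),
                  consensus = "A", left = "CA", right = "AG")
  expect_equal(classify_column(hp2), "strong")

  # quality sums gate each variant at the threshold boundary
  expect_equal(classify_column(
    two_allele_col(reads("A", 10, 30), reads("G", 3, 20))), "strong")
  expect_equal(classify_column(  # top-3 sum 57 < 60, top-2 sum 38 < 45
    two_allele_col(reads("A", 10, 30), reads("G", 3, 19))), "none")
  expect_equal(classify_column(  # support 2, top-2 sum 46 >= 45
    two_allele_col(reads("A", 10, 30), reads("G", 2, 23))), "weak")
  expect_equal(classify_column(  # top-2 sum 44 < 45
    two_allele_col(reads("A", 10, 30), reads("G", 2, 22))), "none")
})

test_that("classifier equals the literal brute-force checker on random
           columns", {
  set.seed(1234)
  n_mismatch <- 0
  for (i in 1:2000) {
    col <- random_column()
    if (classify_column(col) != brute_tier(col)) n_mismatch <- n_mismatch + 1
  }
  expect_equal(n_mismatch, 0)
})

test_that("adding a supporting read never demotes a called column to none", {
  # scoped to the cases where the invariant genuinely holds: the read is
  # added to an allele already qualifying at the column's tier (a read that
  # promotes a short-read-free third allele into the qualifying set can
  # trip the homopolymer rule), the strong depth cap is not crossed, and
  # insertion columns are skipped because their homopolymer base is
  # inferred from the observation majority, which an added read can flip
  set.seed(77)
  cfg <- snv_config()
  for (i in 1:300) {
    col <- random_column()
    if (col$consensus == "-") next
    tier <- classify_column(col, cfg)
    if (tier == "none") next
    if (tier == "strong" && nrow(col$obs) >= cfg$strong_max_depth) next
    ev <- variant_evidence(col)
    q <- if (tier == "strong")
      meleagris:::.qualifying(ev, cfg$strong_min_support, cfg$strong_top_k,
                              cfg$strong_qual_sum)
    else
      meleagris:::.qualifying(ev, cfg$weak_min_support, cfg$weak_top_k,
                              cfg$weak_qual_sum)
    extra_sym <- sample(q$allele, 1)
    col2 <- col
    col2$obs <- rbind(col$obs,
                      data.frame(symbol = extra_sym,
                                 quality = sample(5:40, 1),
                                 platform = sample(c("long-read",
                                                     "short-read"), 1),
                                 read_id = "extra"))
    expect_true(classify_column(col2, cfg) != "none",
                info = sprintf("iteration %d", i))
  }
})

test_that("call_snvs: planted error-free het sites are fully recovered", {
  tr <- gen_diploid_truth(3000, 0.01, 0.004, 3, seed = 21)
  pu <- gen_columns(tr, default_platforms(6, 8), seed = 22)
  calls <- call_snvs(pu)
  truth_key <- paste(tr$variants$position,
                     tr$variants$kind == "insertion")
  call_key <- paste(calls$position, calls$insert)
  expect_true(all(call_key %in% truth_key))  # no false positives
  # all calls recover the planted alleles' kinds
  kind_truth <- ifelse(tr$variants$kind == "substitution",
                       "substitution", "indel")
  expect_equal(calls$kind,
               kind_truth[match(call_key, truth_key)])

  # concordant columns produce an empty call set
  none <- gen_columns(gen_diploid_truth(500, 0, 0, 1, seed = 1),
                      default_platforms(5, 5), seed = 2)
  expect_equal(nrow(call_snvs(none)), 0)
})

test_that("multiallelic columns are flagged", {
  col <- make_col(c(rep("A", 4), rep("C", 4), rep("G", 4)), rep(30, 12),
                  consensus = "A")
  calls <- call_snvs(list(col))
  expect_true(calls$multiallelic)
  expect_equal(calls$n_qualifying, 3)
})

test_that("call_snvs rejects unsorted column lists", {
  c1 <- make_col(rep("A", 3), rep(30, 3), position = 5L)
  c2 <- make_col(rep("A", 3), rep(30, 3), position = 2L)
  expect_error(call_snvs(list(c1, c2)), "sorted")
})

test_that("substitution classes and ti/tv ratio", {
  expect_equal(substitution_class("A", "G"), "transition")
  expect_equal(substitution_class("C", "T"), "transition")
  expect_equal(substitution_class("A", "C"), "transversion")
  expect_error(substitution_class("A", "A"), "distinct")
  expect_error(substitution_class("A", "N"), "distinct")
  expect_equal(titv_ratio(2, 1), 2.0)
  expect_true(is.na(titv_ratio(5, 0)))
})

test_that("summaries count tiers, classes and moments; order-invariant", {
  cols <- list(
    make_col(c(rep("A", 5), rep("G", 5)), rep(30, 10), position = 1L),
    make_col(c(rep("C", 5), rep("T", 5)), rep(30, 10), position = 2L,
             consensus = "C"),
    make_col(c(rep("A", 5), rep("C", 5)), rep(30, 10), position = 3L)
  )
  calls <- call_snvs(cols)
  s <- summarize_calls(calls)
  expect_equal(s$transitions, 2)
  expect_equal(s$transversions, 1)
  expect_equal(s$titv, 2.0)
  expect_equal(s$depth_mean, 10)

  perm <- calls[c(3, 1, 2), ]
  s2 <- summarize_calls(perm)
  expect_equal(s2[c("transitions", "transversions", "n_total")],
               s[c("transitions", "transversions", "n_total")])

  empty <- summarize_calls(call_snvs(list()))
  expect_equal(empty$n_total, 0)
  expect_false(empty$titv_defined)
})

test_that("watterson estimator matches closed form and scales in S", {
  expect_equal(watterson_theta(0, 1000, 5)$theta, 0)
  expect_equal(watterson_theta(5, 1000, 2)$theta, 0.005)
  # a = 1 + 1/2 + 1/3 = 11/6; theta = 11 / (11/6 * 1000) = 0.006
  expect_equal(watterson_theta(11, 1000, 4)$theta, 0.006)
  th1 <- watterson_theta(7, 500, 10)$theta
  th3 <- watterson_theta(21, 500, 10)$theta
  expect_equal(th3, 3 * th1)
  expect_error(watterson_theta(1, 0, 2), "L")
  expect_error(watterson_theta(1, 10, 1), "n")
})

test_that("VCF round-trips calls with 1-based, left-normalized coordinates", {
  ref <- "GTCAAATGCG"
  #       0123456789  (0-based)
  cols <- list(
    # deletion of an A inside the AAA run at 3..5 -> anchored at G (pos 2+1)
    make_col(c(rep("A", 4), rep("-", 4)), rep(30, 8), consensus = "A",
             position = 4L, left = "TCA", right = "AT"),
    # substitution at 0-based 9 -> POS 10
    make_col(c(rep("G", 4), rep("A", 4)), rep(30, 8), consensus = "G",
             position = 9L, left = "GC", right = "")
  )
  calls <- call_snvs(cols)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, c(c1 = ref), path)
  back <- read_vcf_calls(path)
  expect_equal(nrow(back), 2)
  del <- back[back$POS == 3, ]
  expect_equal(del$REF, "CA")
  expect_equal(del$ALT, "C")
  sub <- back[back$POS == 10, ]
  expect_equal(sub$REF, "G")
  expect_equal(sub$ALT, "A")
  expect_equal(back$TIER, calls$tier)
  expect_equal(back$DP, calls$depth)

  # header-only document for empty call sets
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(call_snvs(list()), c(c1 = ref), p2)
  expect_equal(nrow(read_vcf_calls(p2)), 0)
  expect_true(any(grepl("fileformat=VCFv4.2", readLines(p2))))
})

test_that("pileup TSV dialect round-trips columns", {
  cols <- list(
    make_col(c("A", "A", "G"), c(30, 28, 33),
             platforms = c("long-read", "short-read", "short-read"),
             position = 3L, left = "TT", right = "CC"),
    make_col(character(0), integer(0), platforms = character(0),
             consensus = "T", position = 7L)
  )
  path <- tempfile(fileext = ".tsv")
  write_pileup_tsv(cols, path)
  back <- read_pileup_tsv(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$obs$symbol, cols[[1]]$obs$symbol)
  expect_equal(back[[1]]$obs$quality, cols[[1]]$obs$quality)
  expect_equal(back[[1]]$left_context, "TT")
  expect_equal(back[[2]]$consensus, "T")
  expect_equal(nrow(back[[2]]$obs), 0)
})
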