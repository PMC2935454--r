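# Accelerated-evolution statistics on per-gene pairwise dN/dS (omega)
# tables: the differentially-evolved-gene (Devog) test, lineage assignment
# by paired t test, Benjamini-Hochberg FDR control, rank-sum group
# comparisons, chromosome-size trends, GO over-representation and GO-term
# dissimilarity clustering.

#' Log-transform an omega value under the package's exclusion policy
#'
#' The Devog machinery works on natural-log omega. Genes with omega = 0
#' (no non-synonymous changes) or an undefined ratio (dS = 0) cannot be log
#' transformed; under the default policy they are excluded rather than
#' pseudocounted.
#'
#' @param omega_value dN/dS ratio (>= 0); `NA` allowed (treated as
#'   excluded).
#' @param policy only `"exclude"` is implemented.
#' @return the natural log, or `NA` for excluded values; vectorized.
#' @export
safe_log_omega <- function(omega_value, policy = "exclude") {
  if (any(!is.na(omega_value) & omega_value < 0))
    abort("omega must be non-negative")
  if (!identical(policy, "exclude")) abort("unknown policy")
  ifelse(is.na(omega_value) | omega_value <= 0, NA_real_,
         log(omega_value))
}

#' One-gene Devog test of avian versus mammalian omega
#'
#' Tests whether a gene's avian-pair log-omega deviates from its mammalian
#' pairwise log-omega distribution: a two-sided one-sample t test of the
#' mammalian log-omega sample against the avian value as hypothesized mean
#' (each gene has exactly one avian pair, so a two-sample test is not
#' possible). Degrees of freedom are the number of mammalian pairs minus
#' one. Positive t means the avian pair evolves slower than mammals;
#' acceleration in the avian lineage shows as negative t (mammal mean below
#' the avian value).
#'
#' @param avian_log avian-pair log-omega (finite scalar).
#' @param mammal_log numeric vector of mammalian-pair log-omega (>= 2
#'   defined values).
#' @return list with `t`, `p`, `df`, and `degenerate` (TRUE when the
#'   mammalian sample has zero variance; then `t` is `+/-Inf` with p = 0
#'   unless the mean equals the avian value, in which case t = 0, p = 1).
#' @export
devog_gene_test <- function(avian_log, mammal_log) {
  mammal_log <- mammal_log[!is.na(mammal_log)]
  if (is.na(avian_log) || length(mammal_log) < 2)
    abort("need a defined avian value and >= 2 mammalian values")
  n <- length(mammal_log)
  m <- mean(mammal_log)
  s <- stats::sd(mammal_log)
  if (s == 0) {
    if (m == avian_log) return(list(t = 0, p = 1, df = n - 1,
                                    degenerate = TRUE))
    return(list(t = sign(m - avian_log) * Inf, p = 0, df = n - 1,
                degenerate = TRUE))
  }
  t <- (m - avian_log) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
       degenerate = FALSE)
}

#' Paired t test assigning an accelerated gene to a lineage
#'
#' Compares a gene's turkey-mammal log-omega values against its
#' chicken-mammal values, paired by mammal species. A positive mean
#' difference (turkey minus chicken) assigns the acceleration to the turkey
#' lineage, negative to chicken.
#'
#' @param turkey_mammal,chicken_mammal named numeric vectors of log-omega,
#'   keyed by mammal species; keys must match.
#' @return list with `t`, `p`, `df`, `direction` (`"turkey"`, `"chicken"`
#'   or `"none"`), `degenerate`.
#' @export
lineage_paired_test <- function(turkey_mammal, chicken_mammal) {
  if (is.null(names(turkey_mammal)) || is.null(names(chicken_mammal)) ||
      !setequal(names(turkey_mammal), names(chicken_mammal)))
    abort("the two sides must share mammal species names")
  chicken_mammal <- chicken_mammal[names(turkey_mammal)]
  d <- turkey_mammal - chicken_mammal
  d <- d[!is.na(d)]
  if (length(d) < 2) abort("need >= 2 paired differences")
  n <- length(d); m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1, direction = "none",
                            degenerate = TRUE))
    return(list(t = sign(m) * Inf, p = 0, df = n - 1,
                direction = if (m > 0) "turkey" else "chicken",
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
       direction = if (m > 0) "turkey" else if (m < 0) "chicken" else "none",
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' @param p_values numeric vector in [0, 1] (`NA` allowed, carried through).
#' @return adjusted p values aligned with the input order, monotone in the
#'   p-value ranking and capped at 1.
#' @export
adjust_bh <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    abort("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

# Reshape a long omega table into per-gene pieces used by the Devog tests.
# Returns a list with per-gene avian log-omega, a genes x mammal-pairs
# matrix, and genes x mammal matrices of turkey-X / chicken-X log-omega.
.omega_pieces <- function(omega) {
  need <- c("gene_id", "pair", "role", "omega")
  if (!all(need %in% names(omega)))
    abort("omega table needs columns %s", paste(need, collapse = ", "))
  omega$log_omega <- safe_log_omega(omega$omega)
  genes <- sort(unique(omega$gene_id))
  wide <- function(rows) {
    pairs <- sort(unique(rows$pair))
    mat <- matrix(NA_real_, length(genes), length(pairs),
                  dimnames = list(genes, pairs))
    mat[cbind(match(rows$gene_id, genes), match(rows$pair, pairs))] <-
      rows$log_omega
    mat
  }
  av <- omega[omega$role == "avian", , drop = FALSE]
  avian <- stats::setNames(rep(NA_real_, length(genes)), genes)
  avian[av$gene_id] <- av$log_omega
  list(genes = genes, avian = avian,
       mammal = wide(omega[omega$role == "mammal", , drop = FALSE]),
       avian_mammal = omega[omega$role == "avian_mammal", , drop = FALSE])
}

#' Catalogue differentially evolved genes (Devogs)
#'
#' Runs the Devog test for every gene with a defined avian log-omega and at
#' least two defined mammalian-pair log-omega values, adjusts the p values
#' by Benjamini-Hochberg, flags genes with adjusted p below `q` as
#' accelerated, and assigns each accelerated gene to the turkey or chicken
#' lineage via the paired t test on its avian-mammal log-omega values (when
#' present in the table). Genes excluded by the log-omega policy are
#' reported with `NA` statistics.
#'
#' @param omega long omega table: columns `gene_id`, `pair`, `role`
#'   (`avian`/`mammal`/`avian_mammal`), `omega` (plus anything else,
#'   ignored). Avian-mammal pair labels must be `<turkey|chicken>-<mammal>`.
#' @param q FDR level in (0, 1]; default 0.05.
#' @return data frame of class `devog_results`: `gene_id`, `t`, `p`,
#'   `adjusted_p`, `accelerated`, `lineage`, `lineage_t`, `lineage_p`,
#'   `excluded`.
#' @export
call_devogs <- function(omega, q = 0.05) {
  if (q <= 0 || q > 1) abort("q must lie in (0, 1]")
  pc <- .omega_pieces(omega)
  nm <- pc$mammal
  n_ok <- rowSums(!is.na(nm))
  testable <- !is.na(pc$avian) & n_ok >= 2
  # vectorized one-sample t against the avian value
  mean_m <- rowMeans(nm, na.rm = TRUE)
  sd_m <- apply(nm, 1, stats::sd, na.rm = TRUE)
  t <- (mean_m - pc$avian) / (sd_m / sqrt(n_ok))
  p <- 2 * stats::pt(-abs(t), df = n_ok - 1)
  t[!testable] <- NA; p[!testable] <- NA
  adj <- adjust_bh(p)
  res <- data.frame(gene_id = pc$genes, t = unname(t), p = unname(p),
                    adjusted_p = unname(adj),
                    accelerated = !is.na(adj) & adj < q,
                    lineage = "none", lineage_t = NA_real_,
                    lineage_p = NA_real_,
                    excluded = !testable, stringsAsFactors = FALSE)
  am <- pc$avian_mammal
  if (nrow(am) && any(res$accelerated)) {
    for (g in res$gene_id[res$accelerated]) {
      rows <- am[am$gene_id == g, , drop = FALSE]
      side <- sub("-.*$", "", rows$pair)
      mamsp <- sub("^[^-]+-", "", rows$pair)
      tk <- stats::setNames(rows$log_omega[side == "turkey"],
                            mamsp[side == "turkey"])
      ck <- stats::setNames(rows$log_omega[side == "chicken"],
                            mamsp[side == "chicken"])
      tk <- tk[!is.na(tk)]; ck <- ck[!is.na(ck)]
      common <- intersect(names(tk), names(ck))
      if (length(common) >= 2) {
        lt <- lineage_paired_test(tk[common], ck[common])
        i <- res$gene_id == g
        res$lineage[i] <- lt$direction
        res$lineage_t[i] <- lt$t
        res$lineage_p[i] <- lt$p
      }
    }
  }
  class(res) <- c("devog_results", class(res))
  res
}

#' Wilcoxon rank-sum comparison of two omega groups
#'
#' Rank-sum statistic with midranks for ties. Exact two-sided p values are
#' computed by complete enumeration of all group-label assignments when the
#' pooled size is at most `exact_limit` (deviations from the null mean of W
#' at least as large as observed); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @param exact_limit pooled-size cutoff for automatic exact enumeration.
#' @return list with `W` (rank sum of `group_a`), `p`, and `mode` used.
#' @export
wilcoxon_group_compare <- function(group_a, group_b, mode = "auto",
                                   exact_limit = 12L) {
  if (!length(group_a) || !length(group_b)) abort("both groups non-empty")
  mode <- match.arg(mode, c("auto", "exact", "approximate"))
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  if (mode == "auto") mode <- if (n <= exact_limit) "exact" else "approximate"
  if (mode == "exact") {
    mu <- na * (n + 1) / 2
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(W - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(W = W, p = p, mode = mode)
}

#' Trend of a per-gene statistic against chromosome size
#'
#' Summarizes a statistic (dS, dN or omega) per chromosome by its median and
#' relates the medians to log2 chromosome length: Pearson and Spearman
#' correlations plus the least-squares slope of median on log2(length).
#'
#' @param per_chromosome data frame with columns `chromosome`, `length`
#'   (bases) and `value` (one row per gene), or a list of per-chromosome
#'   numeric vectors with a `length` attribute -- use the data frame form.
#' @param statistic label carried through (`"dS"`, `"dN"` or `"omega"`).
#' @return list of class `trend_result`: `statistic`, `summary` (data frame
#'   `chromosome`, `length`, `log2_length`, `median`), `pearson`,
#'   `spearman`, `slope`.
#' @export
size_trend <- function(per_chromosome, statistic = "omega") {
  df <- per_chromosome
  chroms <- unique(df$chromosome)
  if (length(chroms) < 3) abort("need >= 3 chromosomes")
  med <- stats::aggregate(value ~ chromosome, df, stats::median)
  len <- df$length[match(med$chromosome, df$chromosome)]
  s <- data.frame(chromosome = med$chromosome, length = len,
                  log2_length = log2(len), median = med$value)
  slope <- if (stats::var(s$median) == 0) 0
    else unname(stats::coef(stats::lm(median ~ log2_length, s))[2])
  structure(list(statistic = statistic, summary = s,
                 pearson = suppressWarnings(
                   stats::cor(s$log2_length, s$median)),
                 spearman = suppressWarnings(
                   stats::cor(s$log2_length, s$median, method = "spearman")),
                 slope = slope), class = "trend_result")
}

#' GO term over-representation among Devogs
#'
#' One-sided hypergeometric upper-tail test per term (probability of drawing
#' at least the observed number of term genes when sampling the Devog set
#' from the background), Benjamini-Hochberg adjusted across terms. This is
#' the standard replacement for modified Fisher scores of enrichment tools.
#'
#' @param devog_genes character vector of accelerated genes (must be a
#'   subset of `background`).
#' @param background character vector of all tested genes.
#' @param terms named list of character vectors (term id -> gene set), each
#'   a subset of `background`.
#' @return data frame `term`, `n_term`, `n_overlap`, `p`, `adjusted_p`.
#' @export
go_overrepresentation <- function(devog_genes, background, terms) {
  if (!all(devog_genes %in% background))
    abort("devog genes outside background")
  N <- length(unique(background))
  k <- length(unique(devog_genes))
  res <- lapply(names(terms), function(tm) {
    g <- unique(terms[[tm]])
    if (!all(g %in% background)) abort("term %s has genes outside background",
                                       tm)
    K <- length(g)
    x <- length(intersect(g, devog_genes))
    p <- if (k == 0) 1
      else stats::phyper(x - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(term = tm, n_term = K, n_overlap = x, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- adjust_bh(out$p)
  out
}

#' Dissimilarity between two GO terms from their Devog sets
#'
#' d(X, Y) = 1 - |N(X) intersect N(Y)| / min(|N(X)|, |N(Y)|), where N(C) is
#' the set of Devogs assigned to term C. Zero iff the smaller set is
#' contained in the larger; one iff the sets are disjoint.
#'
#' @param x,y non-empty character vectors of gene ids.
#' @return dissimilarity in [0, 1].
#' @export
go_dissimilarity <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (!length(x) || !length(y)) abort("empty gene set")
  1 - length(intersect(x, y)) / min(length(x), length(y))
}

#' Pairwise GO dissimilarity matrix
#'
#' @param terms named list of gene-id vectors.
#' @return symmetric matrix of [go_dissimilarity()] values, zero diagonal.
#' @export
go_dissimilarity_matrix <- function(terms) {
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(names(terms), names(terms)))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- go_dissimilarity(terms[[i]], terms[[j]])
  m
}

#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering merging, at each step, the pair of clusters
#' with the smallest average inter-cluster dissimilarity (UPGMA linkage).
#' Ties are broken deterministically by the lowest index pair. The merge
#' tree is returned in the encoding used by [stats::hclust()]: negative
#' entries are singletons, positive entries earlier merges.
#'
#' @param d symmetric numeric matrix with zero diagonal.
#' @return list of class `avg_linkage_tree` with `merge` ((n-1) x 2 integer
#'   matrix), `height` (merge dissimilarities), `labels`, and `as_hclust`,
#'   an equivalent `hclust` object for plotting and cutting.
#' @export
average_linkage_cluster <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) abort("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1)
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), labels = labels,
                          as_hclust = NULL), class = "avg_linkage_tree"))
  members <- as.list(seq_len(n))       # leaf indices per active cluster
  code <- as.integer(-seq_len(n))      # hclust coding of each active cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  cur <- d
  for (step in seq_len(n - 1)) {
    k <- length(members)
    best <- c(Inf, 0L, 0L)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (cur[i, j] < best[1] - 1e-12) best <- c(cur[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    height[step] <- best[1]
    merge[step, ] <- sort(c(code[i], code[j]))
    new_members <- c(members[[i]], members[[j]])
    keep <- setdiff(seq_len(k), c(i, j))
    # average linkage: mean of original dissimilarities between members
    new_row <- vapply(keep, function(q)
      mean(d[new_members, members[[q]], drop = FALSE]), numeric(1))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], new_row),
                 c(new_row, 0))
    members <- c(members[keep], list(new_members))
    code <- c(code[keep], step)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = .tree_order(merge, n), labels = labels,
                       method = "average",
                       call = match.call(), dist.method = NULL),
                  class = "hclust")
  structure(list(merge = merge, height = height, labels = labels,
                 as_hclust = hc), class = "avg_linkage_tree")
}

# leaf order for plotting an hclust-coded merge matrix
.tree_order <- function(merge, n) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  if (n == 1) return(1L)
  as.integer(expand(nrow(merge)))
}
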