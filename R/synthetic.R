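# Seeded generators for synthetic inputs with planted truth. Every generator
# is fully deterministic given its seed; sub-streams derive child seeds so
# that one integer reproduces a whole simulated dataset.

#' Simulate a heterozygous diploid truth set
#'
#' Generates a random reference sequence and plants heterozygous variants on
#' it: substitutions, single-base deletions and single-base insertions. Indel
#' placement probability is multiplied by `homopolymer_bias` inside
#' mononucleotide runs, mimicking the homopolymer-concentrated indel errors of
#' pyrosequencing platforms (and hence exercising the homopolymer filter of
#' the SNV classifier).
#'
#' @param length reference length in bases (> 0).
#' @param snp_rate per-base probability of a heterozygous substitution.
#' @param indel_rate per-base probability of a heterozygous single-base indel
#'   (before homopolymer biasing).
#' @param homopolymer_bias multiplier applied to `indel_rate` at positions
#'   inside a mononucleotide run of length >= 2; the biased rate is capped at
#'   1.
#' @param seed integer seed; identical seeds give identical truth sets.
#' @return an object of class `diploid_truth`: a list with `reference` (a
#'   single nucleotide string) and `variants`, a data frame with columns
#'   `position` (0-based; for insertions, the base after which the extra base
#'   sits), `kind` (`"substitution"`, `"deletion"` or `"insertion"`), `ref`,
#'   `alt` (ordered allele pair; `"-"` denotes the gap allele), and
#'   `homopolymer` (TRUE iff the indel lies in a mononucleotide run of
#'   length >= 2, the classifier's default homopolymer predicate).
#' @export
gen_diploid_truth <- function(length, snp_rate, indel_rate,
                              homopolymer_bias = 1, seed = 1L) {
  if (length <= 0) abort("length must be positive")
  check_prob(snp_rate, "snp_rate")
  check_prob(indel_rate, "indel_rate")
  if (homopolymer_bias < 0) abort("homopolymer_bias must be non-negative")
  bases <- c("A", "C", "G", "T")
  with_seed(child_seed(seed, 0L), {
    ref <- sample(bases, length, replace = TRUE)
    is_snp <- stats::runif(length) < snp_rate
    # positions inside a homopolymer run (same base as a neighbour)
    in_run <- c(FALSE, ref[-1] == ref[-length]) |
      c(ref[-length] == ref[-1], FALSE)
    rate <- pmin(1, indel_rate * ifelse(in_run, homopolymer_bias, 1))
    is_indel <- stats::runif(length) < rate & !is_snp
    snp_pos <- which(is_snp)
    indel_pos <- which(is_indel)
    alt_snp <- character(0)
    if (length(snp_pos))
      alt_snp <- vapply(ref[snp_pos],
                        function(b) sample(setdiff(bases, b), 1L),
                        character(1))
    kind <- character(0)
    if (length(indel_pos))
      kind <- sample(c("deletion", "insertion"), length(indel_pos),
                     replace = TRUE)
    ins_base <- vapply(seq_along(indel_pos), function(i) {
      if (kind[i] == "insertion") sample(bases, 1L) else NA_character_
    }, character(1))
    v <- rbind(
      if (length(snp_pos))
        data.frame(position = snp_pos - 1L, kind = "substitution",
                   ref = ref[snp_pos], alt = alt_snp,
                   stringsAsFactors = FALSE),
      if (length(indel_pos))
        data.frame(position = indel_pos - 1L, kind = kind,
                   ref = ifelse(kind == "deletion", ref[indel_pos], "-"),
                   alt = ifelse(kind == "deletion", "-", ins_base),
                   stringsAsFactors = FALSE)
    )
    if (is.null(v))
      v <- data.frame(position = integer(0), kind = character(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
    v <- v[order(v$position), , drop = FALSE]
    rownames(v) <- NULL
    refstr <- paste(ref, collapse = "")
    v$homopolymer <- vapply(seq_len(nrow(v)), function(i) {
      if (v$kind[i] == "substitution") return(FALSE)
      base <- if (v$kind[i] == "deletion") v$ref[i] else v$alt[i]
      homopolymer_run_length(refstr, v$position[i], base, v$kind[i]) >= 2L
    }, logical(1))
    structure(list(reference = refstr, variants = v),
              class = "diploid_truth")
  })
}

# Length of the mononucleotide run of `base` spanning an indel column:
# includes the column's own base (the deleted consensus base, or the inserted
# base itself) plus equal consensus neighbours on both sides. For deletions
# `position` is the deleted base; for insertions the insert sits between
# `position` and `position + 1` (0-based).
homopolymer_run_length <- function(reference, position, base, kind) {
  n <- nchar(reference)
  at <- function(i) if (i >= 0 && i < n) substr(reference, i + 1L, i + 1L)
    else ""
  if (kind == "deletion") {
    left <- position - 1L
    right <- position + 1L
  } else {
    left <- position
    right <- position + 1L
  }
  run <- 1L
  while (at(left) == base && left >= 0) { run <- run + 1L; left <- left - 1L }
  while (at(right) == base && right < n) { run <- run + 1L; right <- right + 1L }
  run
}

#' Describe a sequencing platform for pileup simulation
#'
#' @param name platform tag carried by every simulated read observation.
#' @param read_length nominal read length in bases (bookkeeping only; columns
#'   are generated truth-aligned).
#' @param depth mean fold-coverage (Poisson per position), >= 0.
#' @param sub_error per-base substitution error probability.
#' @param homopolymer_indel_error per-base probability, at positions inside a
#'   mononucleotide run, of an erroneous gap observation (the classic
#'   pyrosequencing homopolymer error mode).
#' @param quality_range length-2 integer vector of Phred bounds; qualities are
#'   drawn uniformly within the bounds.
#' @return an object of class `platform_profile`.
#' @export
platform_profile <- function(name, read_length, depth,
                             sub_error = 0, homopolymer_indel_error = 0,
                             quality_range = c(20L, 40L)) {
  check_prob(sub_error, "sub_error")
  check_prob(homopolymer_indel_error, "homopolymer_indel_error")
  if (depth < 0) abort("depth must be >= 0")
  if (length(quality_range) != 2L || quality_range[1] > quality_range[2])
    abort("quality_range must be an ordered pair")
  structure(list(name = name, read_length = read_length, depth = depth,
                 sub_error = sub_error,
                 homopolymer_indel_error = homopolymer_indel_error,
                 quality_range = as.integer(quality_range)),
            class = "platform_profile")
}

#' Default long-read / short-read platform pair
#'
#' Emulates the contrast between a long-read pyrosequencing platform
#' (moderate coverage, homopolymer indel errors) and a short-read platform
#' (deep coverage, substitution errors): 5x at 366 b reads versus 25x at 74 b
#' reads, the fold-coverages and usable read lengths typical of early hybrid
#' avian genome projects.
#'
#' @param long_depth,short_depth mean fold-coverage of the two platforms.
#' @param long_error homopolymer indel error rate of the long-read platform.
#' @param short_error substitution error rate of the short-read platform.
#' @return list of two `platform_profile` objects named by platform tag.
#' @export
default_platforms <- function(long_depth = 5, short_depth = 25,
                              long_error = 0, short_error = 0) {
  list(
    `long-read` = platform_profile("long-read", 366L, long_depth,
                                   sub_error = 0,
                                   homopolymer_indel_error = long_error),
    `short-read` = platform_profile("short-read", 74L, short_depth,
                                    sub_error = short_error)
  )
}

#' Simulate truth-aligned pileup columns and per-platform coverage
#'
#' Produces one pileup column per reference position (plus one extra gap
#' column per planted insertion), with per-observation platform tags and
#' Phred qualities. No read mapping is simulated: observations are aligned
#' to the truth directly. Per-position per-platform depth is Poisson with the
#' profile's mean; at heterozygous sites each observation picks a haplotype
#' with probability 1/2, so with error rates 0 allele counts per haplotype
#' are Binomial(depth, 0.5).
#'
#' @param truth a `diploid_truth` object.
#' @param profiles list of `platform_profile` objects (>= 1).
#' @param seed integer seed.
#' @param contig contig name used in output.
#' @return an object of class `pileup`: list with `contig`, `consensus` (the
#'   reference string; heterozygous alternate alleles are never in the
#'   consensus), `obs` (data frame: `pos` 0-based, `insert` logical flag for
#'   insertion gap columns, `symbol`, `quality`, `platform`, `read_id`) and
#'   `coverage`, a named list of per-position integer depth vectors (one per
#'   platform, reference positions only).
#' @export
gen_columns <- function(truth, profiles, seed = 1L, contig = "contig1") {
  stopifnot(inherits(truth, "diploid_truth"))
  if (length(profiles) == 0) abort("at least one platform profile required")
  L <- nchar(truth$reference)
  refv <- strsplit(truth$reference, "")[[1]]
  v <- truth$variants
  subs <- v[v$kind == "substitution", , drop = FALSE]
  dels <- v[v$kind == "deletion", , drop = FALSE]
  ins  <- v[v$kind == "insertion", , drop = FALSE]
  alt_at <- rep(NA_character_, L)            # non-reference haplotype symbol
  alt_at[subs$position + 1L] <- subs$alt
  alt_at[dels$position + 1L] <- "-"
  in_run <- c(FALSE, refv[-1] == refv[-L]) | c(refv[-L] == refv[-1], FALSE)

  obs_list <- list()
  cov <- list()
  read_counter <- 0L
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    stopifnot(inherits(p, "platform_profile"))
    out <- with_seed(child_seed(seed, k), {
      depth <- stats::rpois(L, p$depth)
      ins_depth <- if (nrow(ins)) stats::rpois(nrow(ins), p$depth)
        else integer(0)
      n_ref <- sum(depth); n_ins <- sum(ins_depth)
      n <- n_ref + n_ins
      if (n == 0L) return(NULL)
      pos <- c(rep(0:(L - 1L), depth), rep(ins$position, ins_depth))
      is_ins <- c(rep(FALSE, n_ref), rep(TRUE, n_ins))
      hap2 <- stats::runif(n) < 0.5
      # consensus haplotype symbol
      sym <- ifelse(is_ins, "-", refv[pos + 1L])
      # non-reference haplotype symbol at planted sites
      alt <- rep(NA_character_, n)
      alt[!is_ins] <- alt_at[pos[!is_ins] + 1L]
      if (n_ins > 0) alt[is_ins] <- rep(ins$alt, ins_depth)
      sym[hap2 & !is.na(alt)] <- alt[hap2 & !is.na(alt)]
      # substitution errors: flip to a random different base
      err <- stats::runif(n) < p$sub_error & sym != "-"
      if (any(err)) {
        shift <- sample(1:3, sum(err), replace = TRUE)
        b <- c("A", "C", "G", "T")
        sym[err] <- b[(match(sym[err], b) - 1L + shift) %% 4L + 1L]
      }
      # homopolymer indel errors: gap observation inside a run
      hp <- !is_ins & in_run[pos + 1L] &
        stats::runif(n) < p$homopolymer_indel_error
      sym[hp] <- "-"
      qs <- p$quality_range[1]:p$quality_range[2]
      qual <- qs[sample.int(length(qs), n, replace = TRUE)]
      list(df = data.frame(pos = pos, insert = is_ins, symbol = sym,
                           quality = qual, platform = p$name,
                           read_id = paste0(p$name, ".", seq_len(n)),
                           stringsAsFactors = FALSE),
           depth = depth)
    })
    if (!is.null(out)) {
      obs_list[[p$name]] <- out$df
      cov[[p$name]] <- out$depth
    } else if (p$depth > 0) {
      cov[[p$name]] <- integer(L)
    }
  }
  obs <- do.call(rbind, obs_list)
  if (is.null(obs))
    obs <- data.frame(pos = integer(0), insert = logical(0),
                      symbol = character(0), quality = integer(0),
                      platform = character(0), read_id = character(0),
                      stringsAsFactors = FALSE)
  obs <- obs[order(obs$pos, obs$insert, obs$platform, obs$read_id), ,
             drop = FALSE]
  rownames(obs) <- NULL
  structure(list(contig = contig, consensus = truth$reference, obs = obs,
                 coverage = cov),
            class = "pileup")
}

#' Simulate a marker-map scenario with planted misjoins
#'
#' Builds a chromosome layout of scaffolds, each carrying ordered markers,
#' and emits the marker observation table a combined-map anchoring step would
#' consume. A fraction of scaffolds is reversed (marker order on the scaffold
#' runs against the chromosome order) and a fraction is misjoined: the
#' scaffold's trailing markers belong to a different chromosome, with the
#' recorded breakpoint interior to the scaffold. All non-misjoined scaffolds
#' are single-chromosome monotone, so they admit a zero-split placement.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param scaffolds_per_chrom scaffolds per chromosome (>= 1).
#' @param markers_per_scaffold markers per scaffold (>= 1; >= 2 required when
#'   `misjoin_fraction > 0` so breakpoints can be interior).
#' @param reversal_fraction fraction of scaffolds reversed.
#' @param misjoin_fraction fraction of scaffolds misjoined.
#' @param seed integer seed.
#' @return object of class `marker_scenario`: list with `observations` (data
#'   frame: `marker_id`, `source`, `chromosome`, `chrom_order`, `scaffold_id`,
#'   `scaffold_pos`), `scaffolds` (truth: `scaffold_id`, `chromosome`,
#'   `order_index`, `reversed`, `misjoined`, `span`), and `planted_misjoins`
#'   (`scaffold_id`, `breakpoint`, `chrom_a`, `chrom_b`).
#' @export
gen_marker_scenario <- function(n_chrom, scaffolds_per_chrom,
                                markers_per_scaffold,
                                reversal_fraction = 0, misjoin_fraction = 0,
                                seed = 1L) {
  if (n_chrom < 1 || scaffolds_per_chrom < 1 || markers_per_scaffold < 1)
    abort("counts must be >= 1")
  check_prob(reversal_fraction, "reversal_fraction")
  check_prob(misjoin_fraction, "misjoin_fraction")
  if (misjoin_fraction > 0 && markers_per_scaffold < 2)
    abort("misjoins need >= 2 markers per scaffold")
  if (misjoin_fraction > 0 && n_chrom < 2)
    abort("misjoins need >= 2 chromosomes")
  m <- markers_per_scaffold
  gap <- 1000L
  with_seed(child_seed(seed, 11L), {
    scaff <- expand.grid(slot = seq_len(scaffolds_per_chrom),
                         chrom = seq_len(n_chrom))
    scaff$scaffold_id <- sprintf("scf%03d", seq_len(nrow(scaff)))
    scaff$chromosome <- paste0("chr", scaff$chrom)
    scaff$reversed <- stats::runif(nrow(scaff)) < reversal_fraction
    scaff$misjoined <- stats::runif(nrow(scaff)) < misjoin_fraction
    scaff$span <- (m + 1L) * gap
    rows <- list()
    misjoins <- list()
    for (i in seq_len(nrow(scaff))) {
      sid <- scaff$scaffold_id[i]
      chrom <- scaff$chromosome[i]
      # chromosome order ranks occupied by this scaffold's own block
      own_rank <- (scaff$slot[i] - 1L) * m + seq_len(m)
      chrom_of <- rep(chrom, m)
      rank_of <- own_rank
      brk <- NA_real_
      if (scaff$misjoined[i]) {
        n_b <- m %/% 2L
        other <- sample(setdiff(seq_len(n_chrom), scaff$chrom[i]), 1L)
        # foreign block appended beyond the other chromosome's regular ranks;
        # offset by scaffold index so foreign blocks never collide
        foreign <- scaffolds_per_chrom * m + (i - 1L) * m + seq_len(n_b)
        chrom_of[(m - n_b + 1L):m] <- paste0("chr", other)
        rank_of[(m - n_b + 1L):m] <- foreign
        brk <- ((m - n_b) * gap + (m - n_b + 1L) * gap) / 2
        misjoins[[length(misjoins) + 1L]] <-
          data.frame(scaffold_id = sid, breakpoint = brk,
                     chrom_a = chrom, chrom_b = paste0("chr", other),
                     stringsAsFactors = FALSE)
      }
      spos <- seq_len(m) * gap
      if (scaff$reversed[i]) spos <- rev(spos)
      rows[[i]] <- data.frame(
        marker_id = sprintf("%s.m%02d", sid, seq_len(m)),
        source = sample(c("microsatellite-linkage", "snp-linkage",
                          "bes-physical"), m, replace = TRUE),
        chromosome = chrom_of, chrom_order = rank_of,
        scaffold_id = sid, scaffold_pos = spos,
        stringsAsFactors = FALSE)
    }
    obs <- do.call(rbind, rows)
    obs <- obs[order(obs$scaffold_id, obs$scaffold_pos), , drop = FALSE]
    rownames(obs) <- NULL
    truth <- data.frame(scaffold_id = scaff$scaffold_id,
                        chromosome = scaff$chromosome,
                        order_index = scaff$slot,
                        reversed = scaff$reversed,
                        misjoined = scaff$misjoined,
                        span = scaff$span, stringsAsFactors = FALSE)
    structure(list(observations = obs, scaffolds = truth,
                   planted_misjoins = if (length(misjoins))
                     do.call(rbind, misjoins)
                   else data.frame(scaffold_id = character(0),
                                   breakpoint = numeric(0),
                                   chrom_a = character(0),
                                   chrom_b = character(0))),
              class = "marker_scenario")
  })
}

#' Default species-pair layout for omega-table simulation
#'
#' One avian pair (turkey-chicken), the six unordered pairs of
#' {human, mouse, dog, opossum} as mammalian pairs, and the eight
#' avian-mammal pairs used for lineage assignment.
#'
#' @return data frame with columns `pair`, `role`
#'   (`avian`/`mammal`/`avian_mammal`), `species_a`, `species_b`.
#' @export
default_species_pairs <- function() {
  mam <- c("human", "mouse", "dog", "opossum")
  mp <- t(utils::combn(mam, 2))
  rbind(
    data.frame(pair = "turkey-chicken", role = "avian",
               species_a = "turkey", species_b = "chicken",
               stringsAsFactors = FALSE),
    data.frame(pair = paste(mp[, 1], mp[, 2], sep = "-"), role = "mammal",
               species_a = mp[, 1], species_b = mp[, 2],
               stringsAsFactors = FALSE),
    data.frame(pair = c(paste0("turkey-", mam), paste0("chicken-", mam)),
               role = "avian_mammal",
               species_a = rep(c("turkey", "chicken"), each = 4),
               species_b = rep(mam, 2), stringsAsFactors = FALSE)
  )
}

#' Simulate a per-gene pairwise omega (dN/dS) table with planted acceleration
#'
#' Each gene draws a latent log-omega level; mammalian pairs scatter around
#' it with standard deviation `sigma`, while the avian pair reports the gene
#' level exactly (plus the planted shift), so that under the null the
#' one-sample t statistic of the differentially-evolved-gene test follows its
#' reference t distribution exactly. A planted accelerated gene shifts its
#' avian-pair log-omega by `log(effect)` and, in its assigned lineage, the
#' corresponding avian-mammal pairs by the same amount.
#'
#' @param n_genes number of genes.
#' @param species_pairs pair layout as from [default_species_pairs()]; must
#'   contain one `avian` pair and >= 2 `mammal` pairs.
#' @param accel_fraction fraction of genes planted as accelerated.
#' @param effect multiplicative omega shift for accelerated genes (> 0).
#' @param seed integer seed.
#' @param mu,tau,sigma log-omega location, between-gene SD and between-pair
#'   SD of the null model; defaults reflect predominantly purifying selection
#'   (median omega 0.15).
#' @return list with `omega`, a long data frame (`gene_id`, `pair`, `role`,
#'   `dN`, `dS`, `omega`), and `truth` (`gene_id`, `accelerated`, `lineage`).
#' @export
gen_omega_table <- function(n_genes, species_pairs = default_species_pairs(),
                            accel_fraction = 0, effect = 1, seed = 1L,
                            mu = log(0.15), tau = 0.4, sigma = 0.3) {
  if (effect <= 0) abort("effect must be > 0")
  check_prob(accel_fraction, "accel_fraction")
  if (sum(species_pairs$role == "avian") != 1 ||
      sum(species_pairs$role == "mammal") < 2)
    abort("species_pairs needs one avian pair and >= 2 mammalian pairs")
  with_seed(child_seed(seed, 21L), {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    accelerated <- stats::runif(n_genes) < accel_fraction
    # lineage drawn unconditionally so the RNG stream (and hence every null
    # draw) is identical across accel_fraction settings
    lineage_draw <- sample(c("turkey", "chicken"), n_genes, replace = TRUE)
    lineage <- ifelse(accelerated, lineage_draw, "none")
    level <- stats::rnorm(n_genes, mu, tau)
    rows <- lapply(seq_len(nrow(species_pairs)), function(j) {
      role <- species_pairs$role[j]
      lo <- switch(role,
        avian = level + ifelse(accelerated, log(effect), 0),
        mammal = level + stats::rnorm(n_genes, 0, sigma),
        avian_mammal = {
          side <- species_pairs$species_a[j]
          level + stats::rnorm(n_genes, 0, sigma) +
            ifelse(accelerated & lineage == side, log(effect), 0)
        })
      dS <- exp(stats::rnorm(n_genes, log(0.3), 0.2))
      omega <- exp(lo)
      data.frame(gene_id = gene_id, pair = species_pairs$pair[j],
                 role = role, dN = omega * dS, dS = dS, omega = omega,
                 stringsAsFactors = FALSE)
    })
    omega <- do.call(rbind, rows)
    omega <- omega[order(omega$gene_id, omega$pair), , drop = FALSE]
    rownames(omega) <- NULL
    list(omega = omega,
         truth = data.frame(gene_id = gene_id, accelerated = accelerated,
                            lineage = lineage, stringsAsFactors = FALSE))
  })
}

#' Simulate a gene-family copy-number matrix with planted events
#'
#' Every family starts from a reference copy number; each non-reference
#' species independently suffers an expansion or contraction with probability
#' `event_rate`, changing the count by a positive Poisson-distributed number
#' of copies (contractions are floored at zero).
#'
#' @param n_families number of families.
#' @param species data frame with columns `species` and `time` (divergence
#'   time from the reference in million years); the reference species must
#'   appear with time 0.
#' @param event_rate per-family per-species probability of a gain/loss event.
#' @param reference name of the reference species.
#' @param seed integer seed.
#' @return list with `matrix`, a `copy_number_matrix` object (see
#'   [copy_number_matrix()]), and `truth`, a data frame (`family`, `species`,
#'   `event` in `{expanded, contracted}`) of planted events with nonzero
#'   realized change.
#' @export
gen_family_matrix <- function(n_families, species, event_rate = 0,
                              reference = "human", seed = 1L) {
  check_prob(event_rate, "event_rate")
  if (any(species$time < 0)) abort("divergence times must be non-negative")
  if (!reference %in% species$species ||
      species$time[species$species == reference] != 0)
    abort("reference species must be present with time 0")
  with_seed(child_seed(seed, 31L), {
    fam <- sprintf("fam%04d", seq_len(n_families))
    base <- 1L + stats::rpois(n_families, 2)
    counts <- matrix(rep(base, nrow(species)), nrow = n_families,
                     dimnames = list(fam, species$species))
    truth <- list()
    for (sp in setdiff(species$species, reference)) {
      hit <- stats::runif(n_families) < event_rate
      if (!any(hit)) next
      delta <- (1L + stats::rpois(sum(hit), 1)) *
        sample(c(-1L, 1L), sum(hit), replace = TRUE)
      new <- pmax(0L, base[hit] + delta)
      counts[hit, sp] <- new
      changed <- new != base[hit]
      if (any(changed))
        truth[[length(truth) + 1L]] <- data.frame(
          family = fam[hit][changed], species = sp,
          event = ifelse(new[changed] > base[hit][changed],
                         "expanded", "contracted"),
          stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth)
      else data.frame(family = character(0), species = character(0),
                      event = character(0), stringsAsFactors = FALSE)
    times <- stats::setNames(species$time, species$species)
    list(matrix = copy_number_matrix(counts, reference, times),
         truth = truth)
  })
}
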