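# Scaffold-to-chromosome anchoring: merge marker maps into a combined map,
# segment each scaffold's marker hits into consistent blocks, place and
# orient scaffold pieces on chromosomes, and emit AGP plus summary tables.

LINKAGE_SOURCES <- c("microsatellite-linkage", "snp-linkage")

#' Build a combined map from marker observations
#'
#' Merges markers from linkage and physical map sources into one ranked
#' order per chromosome. When sources disagree on a marker's chromosome the
#' linkage claim wins (genetic maps anchor chromosomes; the physical map
#' refines placement) and the conflict is logged. Within a chromosome
#' markers are ranked by their map position, ties broken by marker id.
#'
#' @param observations data frame with columns `marker_id`, `source` (one of
#'   `microsatellite-linkage`, `snp-linkage`, `bes-physical`), `chromosome`,
#'   `chrom_order` (comparable position or rank within the chromosome), and
#'   optionally `scaffold_id`, `scaffold_pos` (carried through).
#' @return object of class `combined_map`: list with `markers` (data frame
#'   `marker_id`, `chromosome`, `rank`, `source`) and `conflicts` (data
#'   frame of resolved chromosome conflicts).
#' @export
build_cmap <- function(observations) {
  if (!nrow(observations)) abort("no marker observations")
  o <- observations
  o$.linkage <- o$source %in% LINKAGE_SOURCES
  # one claim per marker: linkage beats physical, then first occurrence
  o <- o[order(o$marker_id, !o$.linkage), , drop = FALSE]
  first <- !duplicated(o$marker_id)
  chosen <- o[first, , drop = FALSE]
  conflicts <- do.call(rbind, lapply(split(o, o$marker_id), function(g) {
    if (length(unique(g$chromosome)) > 1)
      data.frame(marker_id = g$marker_id[1],
                 kept_chromosome = g$chromosome[1],
                 dropped_chromosome = paste(unique(
                   g$chromosome[g$chromosome != g$chromosome[1]]),
                   collapse = ","),
                 stringsAsFactors = FALSE)
    else NULL
  }))
  if (is.null(conflicts))
    conflicts <- data.frame(marker_id = character(0),
                            kept_chromosome = character(0),
                            dropped_chromosome = character(0))
  chosen <- chosen[order(chosen$chromosome, chosen$chrom_order,
                         chosen$marker_id), , drop = FALSE]
  chosen$rank <- stats::ave(seq_len(nrow(chosen)), chosen$chromosome,
                            FUN = seq_along)
  markers <- chosen[, c("marker_id", "chromosome", "rank", "source")]
  rownames(markers) <- NULL
  structure(list(markers = markers, conflicts = conflicts),
            class = "combined_map")
}

#' Segment a scaffold's marker hits into consistent blocks
#'
#' Greedy left-to-right maximal segmentation: each block is
#' single-chromosome with strictly monotone (ascending or descending)
#' chromosome order. A scaffold is map-consistent iff it yields one block.
#' Because any sub-interval of a valid block is itself valid, the greedy
#' maximal segmentation attains the minimum possible number of blocks.
#'
#' @param hits data frame of one scaffold's marker hits sorted by
#'   `scaffold_pos`, with columns `chromosome` and `chrom_order` (use the
#'   combined-map rank).
#' @return data frame with one row per block: `start`, `end` (1-based hit
#'   indices, inclusive), `chromosome`, `direction` (1 ascending, -1
#'   descending, 0 undetermined single-marker block).
#' @export
segment_blocks <- function(hits) {
  n <- nrow(hits)
  if (n == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      chromosome = character(0), direction = integer(0)))
  if (is.unsorted(hits$scaffold_pos))
    abort("hits must be sorted by scaffold_pos")
  start <- 1L
  dir <- 0L
  out <- list()
  close_block <- function(s, e, d)
    data.frame(start = s, end = e, chromosome = hits$chromosome[s],
               direction = d, stringsAsFactors = FALSE)
  for (j in seq_len(n)[-1]) {
    same <- hits$chromosome[j] == hits$chromosome[j - 1]
    step <- sign(hits$chrom_order[j] - hits$chrom_order[j - 1])
    ok <- same && step != 0 && (dir == 0L || step == dir)
    if (ok) {
      dir <- step
    } else {
      out[[length(out) + 1L]] <- close_block(start, j - 1L, dir)
      start <- j
      dir <- 0L
    }
  }
  out[[length(out) + 1L]] <- close_block(start, n, dir)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Place scaffolds on chromosomes via a combined map
#'
#' Each scaffold's marker hits (looked up in the combined map) are segmented
#' into consistent blocks; every block with at least `min_markers` markers
#' becomes a placed piece. Orientation is the sign of the Kendall rank
#' correlation between scaffold position and chromosome rank (single-marker
#' or tied blocks are reported forward with `orientation_known = FALSE`).
#' Pieces are ordered along each chromosome by the median chromosome rank of
#' their supporting markers, ties broken by piece id. Scaffolds segmented
#' into more than one qualifying block are split, with the breakpoint
#' recorded midway between the flanking conflicting hits. Scaffolds with no
#' qualifying block are pooled into ChrUn.
#'
#' @param observations marker observation table (same layout as
#'   [build_cmap()] input, with `scaffold_id` and `scaffold_pos`).
#' @param cmap a `combined_map`; built from `observations` when missing.
#' @param min_markers minimum markers per placed block (>= 1).
#' @param scaffold_ids optional character vector of all scaffold ids
#'   (so markerless scaffolds are reported in ChrUn).
#' @return list of class `placement_set`: `placements` (data frame
#'   `piece_id`, `scaffold_id`, `chromosome`, `order_index`, `orientation`
#'   (`"forward"`/`"reverse"`), `orientation_known`, `supporting_markers`,
#'   `split_from`), `splits` (`scaffold_id`, `breakpoint`), and `chr_un`
#'   (character vector of unplaced scaffold ids).
#' @export
place_scaffolds <- function(observations, cmap = NULL, min_markers = 1L,
                            scaffold_ids = NULL) {
  if (min_markers < 1) abort("min_markers must be >= 1")
  if (is.null(cmap)) cmap <- build_cmap(observations)
  m <- cmap$markers
  obs <- observations[observations$marker_id %in% m$marker_id, ,
                      drop = FALSE]
  idx <- match(obs$marker_id, m$marker_id)
  obs$chromosome <- m$chromosome[idx]
  obs$chrom_order <- m$rank[idx]
  obs <- obs[!duplicated(obs$marker_id), , drop = FALSE]
  placements <- list(); splits <- list(); chr_un <- character(0)
  for (sid in sort(unique(obs$scaffold_id))) {
    hits <- obs[obs$scaffold_id == sid, , drop = FALSE]
    hits <- hits[order(hits$scaffold_pos), , drop = FALSE]
    blocks <- segment_blocks(hits)
    blocks$n <- blocks$end - blocks$start + 1L
    keep <- blocks[blocks$n >= min_markers, , drop = FALSE]
    if (!nrow(keep)) { chr_un <- c(chr_un, sid); next }
    split_scaffold <- nrow(keep) > 1L
    for (b in seq_len(nrow(keep))) {
      bh <- hits[keep$start[b]:keep$end[b], , drop = FALSE]
      tau <- if (nrow(bh) > 1)
        suppressWarnings(stats::cor(bh$scaffold_pos, bh$chrom_order,
                                    method = "kendall"))
      else NA_real_
      known <- !is.na(tau) && tau != 0
      placements[[length(placements) + 1L]] <- data.frame(
        piece_id = if (split_scaffold) sprintf("%s.p%d", sid, b) else sid,
        scaffold_id = sid, chromosome = keep$chromosome[b],
        order_index = stats::median(bh$chrom_order),
        orientation = if (known && tau < 0) "reverse" else "forward",
        orientation_known = known,
        supporting_markers = nrow(bh),
        split_from = if (split_scaffold) sid else NA_character_,
        stringsAsFactors = FALSE)
    }
    if (split_scaffold) {
      for (b in seq_len(nrow(keep))[-1]) {
        left <- hits$scaffold_pos[keep$end[b - 1L]]
        right <- hits$scaffold_pos[keep$start[b]]
        splits[[length(splits) + 1L]] <- data.frame(
          scaffold_id = sid, breakpoint = (left + right) / 2,
          stringsAsFactors = FALSE)
      }
    }
  }
  pl <- do.call(rbind, placements)
  if (is.null(pl))
    pl <- data.frame(piece_id = character(0), scaffold_id = character(0),
                     chromosome = character(0), order_index = numeric(0),
                     orientation = character(0),
                     orientation_known = logical(0),
                     supporting_markers = integer(0),
                     split_from = character(0), stringsAsFactors = FALSE)
  pl <- pl[order(pl$chromosome, pl$order_index, pl$piece_id), , drop = FALSE]
  rownames(pl) <- NULL
  sp <- if (length(splits)) do.call(rbind, splits)
    else data.frame(scaffold_id = character(0), breakpoint = numeric(0))
  if (!is.null(scaffold_ids))
    chr_un <- sort(union(chr_un, setdiff(scaffold_ids, pl$scaffold_id)))
  structure(list(placements = pl, splits = sp, chr_un = chr_un),
            class = "placement_set")
}

#' Per-chromosome contig and base totals
#'
#' Sums contig counts and non-gap bases per chromosome over placed pieces
#' (ChrUn members included under `"Un"` when present in `placements`) and
#' appends a `Total` row.
#'
#' @param placements data frame with at least `piece_id` and `chromosome`
#'   (e.g. the `placements` element of a `placement_set`).
#' @param sizes data frame with `piece_id`, `contigs`, `bases`.
#' @return data frame `chromosome`, `contigs`, `bases`, last row `Total`.
#' @export
chromosome_table <- function(placements, sizes) {
  idx <- match(placements$piece_id, sizes$piece_id)
  if (any(is.na(idx)))
    abort("missing size records for: %s",
          paste(placements$piece_id[is.na(idx)], collapse = ", "))
  df <- data.frame(chromosome = placements$chromosome,
                   contigs = sizes$contigs[idx], bases = sizes$bases[idx])
  agg <- stats::aggregate(cbind(contigs, bases) ~ chromosome, df, sum)
  agg <- agg[order(agg$chromosome), , drop = FALSE]
  rbind(agg, data.frame(chromosome = "Total",
                        contigs = sum(agg$contigs),
                        bases = sum(agg$bases)))
}

#' Emit placements as an AGP 2.0 document
#'
#' One component line per placed piece in chromosome order, alternating with
#' fixed-size unknown ("U") gap lines. Orientation maps forward to `+`,
#' reverse to `-`, unknown to `?`.
#'
#' @param placements the `placements` data frame of a `placement_set`.
#' @param sizes data frame `piece_id`, `bases` (component lengths).
#' @param gap_size gap length between consecutive components (default 100,
#'   the AGP convention for unknown gap sizes).
#' @return data frame with the nine AGP columns (`object`, `object_beg`,
#'   `object_end`, `part_number`, `component_type`, `component_id`/
#'   `gap_length`, `component_beg`/`gap_type`, `component_end`/`linkage`,
#'   `orientation`/`evidence`). `write_agp()`/`read_agp()` serialize it;
#'   `read_agp()` recovers the placement order and orientation.
#' @export
emit_agp <- function(placements, sizes, gap_size = 100L) {
  rows <- list()
  for (chrom in unique(placements$chromosome)) {
    pc <- placements[placements$chromosome == chrom, , drop = FALSE]
    if (anyDuplicated(pc$order_index) &&
        anyDuplicated(paste(pc$order_index, pc$piece_id)))
      abort("duplicate order indices on %s", chrom)
    at <- 1L; part <- 1L
    for (i in seq_len(nrow(pc))) {
      len <- sizes$bases[match(pc$piece_id[i], sizes$piece_id)]
      if (is.na(len)) abort("no size for piece %s", pc$piece_id[i])
      if (i > 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          object = chrom, object_beg = at, object_end = at + gap_size - 1L,
          part_number = part, component_type = "U", col6 = gap_size,
          col7 = "scaffold", col8 = "yes", col9 = "map",
          stringsAsFactors = FALSE)
        at <- at + gap_size; part <- part + 1L
      }
      ori <- if (!pc$orientation_known[i]) "?"
        else if (pc$orientation[i] == "reverse") "-" else "+"
      rows[[length(rows) + 1L]] <- data.frame(
        object = chrom, object_beg = at, object_end = at + len - 1L,
        part_number = part, component_type = "W", col6 = pc$piece_id[i],
        col7 = 1L, col8 = len, col9 = ori, stringsAsFactors = FALSE)
      at <- at + len; part <- part + 1L
    }
  }
  agp <- do.call(rbind, rows)
  rownames(agp) <- NULL
  agp
}

#' @rdname emit_agp
#' @param agp an AGP data frame from [emit_agp()].
#' @param path file path.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname emit_agp
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(object = f[, 1], object_beg = as.integer(f[, 2]),
             object_end = as.integer(f[, 3]),
             part_number = as.integer(f[, 4]), component_type = f[, 5],
             col6 = f[, 6], col7 = f[, 7], col8 = f[, 8], col9 = f[, 9],
             stringsAsFactors = FALSE)
}
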