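# Pileup column container and the documented pileup TSV dialect.

SYMBOLS <- c("A", "C", "G", "T", "N", "-")

#' Construct a single pileup column
#'
#' One aligned position of an assembled contig: the consensus symbol plus the
#' multiset of per-read observations over it. Insertion columns (reads carry
#' a base the consensus does not) have consensus `"-"` and sit between two
#' consensus coordinates; their `position` is the 0-based coordinate of the
#' base to their left.
#'
#' @param contig contig id.
#' @param position 0-based position on the contig.
#' @param consensus consensus symbol (`A/C/G/T` or `"-"` for insertion
#'   columns).
#' @param observations data frame with columns `symbol` (one of
#'   `A,C,G,T,N,-`), `quality` (Phred integer; may be `NA` for gap
#'   observations whose quality is derived from flanks), `platform`,
#'   `read_id`, and optionally `flank_left`/`flank_right` (Phred qualities of
#'   the read's bases flanking a gap; `NA` when the read ends there).
#' @param left_context,right_context consensus bases flanking the column
#'   (strings; may be empty at contig ends).
#' @param insert logical; TRUE for insertion columns.
#' @return an object of class `pileup_column`.
#' @export
pileup_column <- function(contig, position, consensus, observations,
                          left_context = "", right_context = "",
                          insert = identical(consensus, "-")) {
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  if (nrow(obs) && !all(obs$symbol %in% SYMBOLS))
    abort("observation symbols must be in {A,C,G,T,N,-}")
  if (nrow(obs) && any(!is.na(obs$quality) & obs$quality < 0))
    abort("qualities must be >= 0")
  structure(list(contig = contig, position = as.integer(position),
                 consensus = consensus, obs = obs,
                 left_context = left_context, right_context = right_context,
                 insert = isTRUE(insert)),
            class = "pileup_column")
}

#' @export
print.pileup_column <- function(x, ...) {
  cat(sprintf("<pileup column %s:%d%s consensus=%s depth=%d>\n", x$contig,
              x$position, if (x$insert) "+" else "", x$consensus,
              nrow(x$obs)))
  invisible(x)
}

# Materialize pileup_column objects from a `pileup` (see gen_columns) at the
# given (pos, insert) keys; contexts are taken from the consensus sequence.
.column_at <- function(pileup, pos, insert = FALSE, context = 5L) {
  refv <- pileup$consensus
  L <- nchar(refv)
  sub <- pileup$obs[pileup$obs$pos == pos & pileup$obs$insert == insert, ,
                    drop = FALSE]
  if (insert) {
    left <- substr(refv, max(1L, pos - context + 2L), pos + 1L)
    right <- substr(refv, pos + 2L, min(L, pos + 1L + context))
    cons <- "-"
  } else {
    left <- if (pos > 0) substr(refv, max(1L, pos - context + 1L), pos)
      else ""
    right <- substr(refv, pos + 2L, min(L, pos + 1L + context))
    cons <- substr(refv, pos + 1L, pos + 1L)
  }
  pileup_column(pileup$contig, pos, cons,
                sub[, c("symbol", "quality", "platform", "read_id")],
                left_context = left, right_context = right, insert = insert)
}

#' Write / read pileup columns in the package's pileup TSV dialect
#'
#' One row per column, headered, tab-separated, with fields `contig`,
#' `position` (0-based), `insert` (0/1), `consensus`, `left_context`,
#' `right_context`, and `observations`: one space-separated field per read of
#' the form `symbol:quality:platform:read_id`.
#'
#' @param columns list of `pileup_column` objects, or a `pileup` object (all
#'   its columns are written).
#' @param path file path.
#' @return `read_pileup_tsv()` returns a list of `pileup_column` objects.
#' @export
write_pileup_tsv <- function(columns, path) {
  if (inherits(columns, "pileup")) {
    keys <- unique(columns$obs[, c("pos", "insert")])
    keys <- keys[order(keys$pos, keys$insert), , drop = FALSE]
    columns <- lapply(seq_len(nrow(keys)), function(i)
      .column_at(columns, keys$pos[i], keys$insert[i]))
  }
  rows <- vapply(columns, function(col) {
    o <- col$obs
    obs <- if (nrow(o)) paste(o$symbol, o$quality, o$platform, o$read_id,
                              sep = ":", collapse = " ") else ""
    paste(col$contig, col$position, as.integer(col$insert), col$consensus,
          col$left_context, col$right_context, obs, sep = "\t")
  }, character(1))
  writeLines(c(paste("contig", "position", "insert", "consensus",
                     "left_context", "right_context", "observations",
                     sep = "\t"), rows), path)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(list())
  lines <- lines[-1]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    f <- c(f, rep("", 7 - length(f)))
    obs <- if (nzchar(f[7])) {
      parts <- strsplit(strsplit(f[7], " ", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      data.frame(symbol = vapply(parts, `[`, "", 1),
                 quality = as.integer(vapply(parts, `[`, "", 2)),
                 platform = vapply(parts, `[`, "", 3),
                 read_id = vapply(parts, `[`, "", 4),
                 stringsAsFactors = FALSE)
    } else data.frame(symbol = character(0), quality = integer(0),
                      platform = character(0), read_id = character(0))
    pileup_column(f[1], as.integer(f[2]), f[4], obs,
                  left_context = f[5], right_context = f[6],
                  insert = f[3] == "1")
  })
}
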