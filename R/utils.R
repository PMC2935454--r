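# Internal helpers shared across modules.

#' Derive a deterministic child seed from a parent seed
#'
#' Generators that need several independent random streams derive one child
#' seed per stream from a single user-supplied integer seed, so that the whole
#' pipeline is reproducible from one number. The derivation is a fixed affine
#' map modulo a Mersenne prime; results stay below 2^31 - 1.
#'
#' @param seed parent integer seed.
#' @param offset non-negative integer distinguishing the child streams.
#' @return an integer seed usable with [set.seed()].
#' @keywords internal
child_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 48271) %% m + as.numeric(offset) * 69621) %% m)
}

# Evaluate `expr` with a local RNG state seeded at `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stop() with call. = FALSE and sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    abort("%s must lie in [0, 1]", name)
  invisible(x)
}

#' Read / write headered tab-separated tables
#'
#' Thin wrappers fixing the dialect used by every text interface in the
#' package: tab separator, header row, no quoting, no row names, `NA` empty.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

# Write a named character vector of sequences as FASTA (60-column wrap).
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("no FASTA records in %s", path)
  id <- cumsum(hdr)
  names <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  names(seqs) <- names
  seqs
}
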