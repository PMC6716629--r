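#' Read a DNA sequence set
#'
#' Reads either standard (possibly multi-line) FASTA via
#' [Biostrings::readBStringSet()], or a plain-text dialect with one sequence
#' per line where each line is either `sequence` or `id<TAB>sequence`
#' (missing ids default to `seq_<index>`). Sequences are uppercased on load
#' and must use only the `{A,C,G,T,N}` alphabet; record ids must be unique
#' because they key the site annotations.
#'
#' @param path Input file path.
#' @param format `"fasta"` or `"plain"`.
#' @return A data frame with columns `id` and `seq`, one row per record, in
#'   file order.
#' @export
read_sequences <- function(path, format = c("fasta", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- names(set)
    # keep only the first whitespace-delimited token of the header
    ids <- sub("\\s.*$", "", ids)
    seqs <- toupper(as.character(set))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    has_id <- grepl("\t", lines, fixed = TRUE)
    ids <- ifelse(has_id, sub("\t.*$", "", lines),
                  paste0("seq_", seq_along(lines)))
    seqs <- toupper(trimws(ifelse(has_id, sub("^[^\t]*\t", "", lines), lines)))
  }
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) {
      stop(sprintf("record '%s' is empty", ids[i]), call. = FALSE)
    }
    bad <- regexpr("[^ACGTN]", seqs[i])
    if (bad > 0L) {
      stop(sprintf(
        "record '%s': invalid character '%s' at position %d",
        ids[i], substr(seqs[i], bad, bad), bad), call. = FALSE)
    }
  }
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Read known-site annotations
#'
#' Tab-delimited lines `seq_id<TAB>start<TAB>end` in 0-based half-open
#' coordinates on the forward strand. Intervals are sorted per sequence and
#' must not overlap within a record. An empty file yields an empty
#' annotation table (a dataset may simply have no known sites).
#'
#' @param path Input file path.
#' @return A data frame with columns `seq_id`, `start`, `end`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("site lines must be seq_id<TAB>start<TAB>end", call. = FALSE)
  }
  seq_id <- vapply(parts, `[[`, "", 1L)
  start_c <- vapply(parts, `[[`, "", 2L)
  end_c <- vapply(parts, `[[`, "", 3L)
  if (!all(grepl("^-?[0-9]+$", c(start_c, end_c)))) {
    stop("site coordinates must be integers", call. = FALSE)
  }
  start <- as.integer(start_c)
  end <- as.integer(end_c)
  ann <- data.frame(seq_id = seq_id, start = start, end = end,
                    stringsAsFactors = FALSE)
  validate_sites(ann)
}

# Sort per id and enforce the interval invariants.
validate_sites <- function(ann) {
  if (any(ann$start < 0L)) stop("negative site start", call. = FALSE)
  if (any(ann$start >= ann$end)) {
    stop("site intervals need start < end (0-based half-open)", call. = FALSE)
  }
  ann <- ann[order(ann$seq_id, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  for (id in unique(ann$seq_id)) {
    sub <- ann[ann$seq_id == id, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("overlapping site intervals for sequence '", id, "'",
           call. = FALSE)
    }
  }
  ann
}

#' Write a placement report
#'
#' One tab-delimited row per placement: `seq_id`, `left_start`, `left_end`,
#' `gap_length`, `right_start`, `right_end`, `strand`, `site` (left block,
#' lowercase gap, right block) and the per-site log-odds `score` in bits.
#' Coordinates are 0-based half-open. A ZOOPS sequence with no occurrence is
#' emitted as a sentinel row whose fields after `seq_id` are `-`.
#'
#' @param result A [bimotif_search()] result (or any list carrying
#'   `sequences`, `placements`, `model` and `spec`).
#' @param path Output file path.
#' @return Invisibly, the report data frame.
#' @export
write_placements <- function(result, path) {
  spec <- result$spec
  seqs <- result$sequences
  pl <- result$placements
  header <- c("seq_id", "left_start", "left_end", "gap_length",
              "right_start", "right_end", "strand", "site", "score")
  rows <- character(0)
  for (r in seq_len(nrow(pl))) {
    i <- pl$seq_index[r]
    id <- seqs$id[i]
    if (!pl$present[r]) {
      rows <- c(rows, paste(c(id, rep("-", 8L)), collapse = "\t"))
      next
    }
    ls <- pl$left_start[r]
    gap <- pl$gap[r]
    le <- ls + spec$l_left
    rs <- le + gap
    re <- rs + spec$l_right
    s <- seqs$seq[i]
    site <- paste0(substr(s, ls + 1L, le),
                   tolower(substr(s, le + 1L, rs)),
                   substr(s, rs + 1L, re))
    score <- site_log_odds(result$model, seqs$seq[i], ls, gap, spec,
                           strand = pl$strand[r])
    rows <- c(rows, paste(id, ls, le, gap, rs, re, pl$strand[r], site,
                          sprintf("%.6f", score), sep = "\t"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), rows), con)
  invisible(pl)
}

#' Read a placement report back into a placement table
#'
#' Inverse of [write_placements()] for the placement coordinates; sentinel
#' rows become non-present placements.
#'
#' @param path Report file path.
#' @param sequences The sequence set the report refers to (for id-to-index
#'   mapping).
#' @return A placement data frame with columns `seq_index`, `left_start`,
#'   `gap`, `present`, `strand`.
#' @export
read_placements <- function(path, sequences) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  idx <- match(tab$seq_id, sequences$id)
  if (anyNA(idx)) {
    stop("report refers to unknown sequence ids: ",
         paste(unique(tab$seq_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  absent <- tab$left_start == "-"
  as_placements(
    seq_index = idx,
    left_start = ifelse(absent, 0L, suppressWarnings(as.integer(tab$left_start))),
    gap = ifelse(absent, 0L, suppressWarnings(as.integer(tab$gap_length))),
    present = !absent,
    strand = ifelse(absent, "+", tab$strand)
  )
}
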