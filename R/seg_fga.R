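# Segmented copy-number profiles and the fraction of genome altered (FGA).
#
# Internal coordinates are 0-based half-open, so a segment's length is simply
# end - start. SEG files on disk use the conventional 1-based inclusive
# coordinates and are converted on read/write (length = end - start + 1 in
# file coordinates).

#' Construct a copy-number segment profile
#'
#' A segment profile holds one sample's segmented copy-number calls: a table
#' of chromosome intervals with a log2 copy-number ratio each. Segments are
#' stored sorted by chromosome then start, in 0-based half-open coordinates,
#' and segments on the same chromosome must not overlap.
#'
#' @param sample_id Sample label.
#' @param segments Data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{log2_ratio}. Coordinates are 0-based half-open.
#' @return An object of class \code{segment_profile}.
#' @seealso [compute_fga()], [read_seg()]
#' @export
segment_profile <- function(sample_id, segments) {
  stopifnot(is.character(sample_id) || is.factor(sample_id), length(sample_id) == 1)
  required <- c("chrom", "start", "end", "log2_ratio")
  if (!all(required %in% names(segments))) {
    stop_ginscore(
      "segments must have columns ", paste(required, collapse = ", ")
    )
  }
  segments <- as.data.frame(segments)[required]
  segments$chrom <- as.character(segments$chrom)
  segments$start <- as.numeric(segments$start)
  segments$end <- as.numeric(segments$end)
  segments$log2_ratio <- as.numeric(segments$log2_ratio)
  if (any(!is.finite(segments$start)) || any(!is.finite(segments$end))) {
    stop_ginscore("sample ", sample_id, ": non-finite segment coordinates")
  }
  if (any(segments$start >= segments$end)) {
    stop_ginscore("sample ", sample_id, ": segment with start >= end")
  }
  if (any(!is.finite(segments$log2_ratio))) {
    stop_ginscore("sample ", sample_id, ": non-finite log2_ratio")
  }
  ord <- order(chrom_sort_key(segments$chrom), segments$start)
  segments <- segments[ord, , drop = FALSE]
  rownames(segments) <- NULL
  # overlap check within each chromosome (sorted, half-open intervals)
  for (ch in unique(segments$chrom)) {
    sub <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop_ginscore(
        "sample ", sample_id, ": overlapping segments on chromosome ", ch
      )
    }
  }
  structure(
    list(sample_id = as.character(sample_id), segments = segments),
    class = "segment_profile"
  )
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(
    "segment_profile:", x$sample_id, "-", nrow(x$segments), "segments on",
    length(unique(x$segments$chrom)), "chromosomes\n"
  )
  invisible(x)
}

.seg_columns <- list(
  sample = "^(id|sample|sample_id|sampleid)$",
  chrom = "^(chrom|chromosome|chr)$",
  start = "^(loc[._ ]?start|start)$",
  end = "^(loc[._ ]?end|end)$",
  value = "^(seg[._ ]?mean|seg[._ ]?value|value|log2|log2_ratio)$"
)

.match_seg_column <- function(header, pattern, what) {
  hit <- grep(pattern, header, ignore.case = TRUE)
  if (length(hit) == 0) {
    stop_ginscore("SEG header lacks a recognizable ", what, " column")
  }
  hit[1]
}

#' Read a SEG-style segmented copy-number file
#'
#' Reads a tab-separated SEG file (the cBioPortal dialect: header with
#' sample, chromosome, start, end and segment-mean columns; column names are
#' matched case-insensitively against the usual spellings). Coordinates in
#' the file are 1-based inclusive and are converted to the package's 0-based
#' half-open representation. Rows with a non-finite segment mean are dropped
#' with a message; malformed coordinates raise an error naming the offending
#' file line.
#'
#' @param path Path to a SEG file.
#' @return Named list of [segment_profile()] objects, one per sample, in
#'   order of first appearance.
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop_ginscore("SEG file not found: ", path)
  tab <- utils::read.delim(path,
    header = TRUE, sep = "\t", colClasses = "character",
    check.names = FALSE, blank.lines.skip = FALSE
  )
  header <- names(tab)
  idx <- vapply(
    names(.seg_columns),
    function(k) .match_seg_column(header, .seg_columns[[k]], k),
    integer(1)
  )
  if (nrow(tab) == 0) {
    return(structure(list(), names = character(0)))
  }
  lines <- seq_len(nrow(tab)) + 1L # header is line 1
  sample <- tab[[idx["sample"]]]
  chrom <- tab[[idx["chrom"]]]
  start <- suppressWarnings(as.numeric(tab[[idx["start"]]]))
  end <- suppressWarnings(as.numeric(tab[[idx["end"]]]))
  value <- suppressWarnings(as.numeric(tab[[idx["value"]]]))
  bad_coord <- which(
    !is.finite(start) | !is.finite(end) |
      start != floor(start) | end != floor(end)
  )
  if (length(bad_coord) > 0) {
    stop_ginscore(
      "malformed coordinates on line ", lines[bad_coord[1]], " of ", path
    )
  }
  bad_order <- which(start >= end)
  if (length(bad_order) > 0) {
    stop_ginscore(
      "start >= end on line ", lines[bad_order[1]], " of ", path
    )
  }
  drop <- !is.finite(value)
  if (any(drop)) {
    message(
      "read_seg: dropped ", sum(drop), " segment(s) with non-finite value"
    )
    sample <- sample[!drop]
    chrom <- chrom[!drop]
    start <- start[!drop]
    end <- end[!drop]
    value <- value[!drop]
  }
  if (length(sample) == 0) {
    return(structure(list(), names = character(0)))
  }
  ids <- unique(sample)
  profiles <- lapply(ids, function(sid) {
    keep <- sample == sid
    segment_profile(sid, data.frame(
      chrom = chrom[keep],
      start = start[keep] - 1, # 1-based inclusive -> 0-based half-open
      end = end[keep],
      log2_ratio = value[keep],
      stringsAsFactors = FALSE
    ))
  })
  names(profiles) <- ids
  profiles
}

#' Write segment profiles to a SEG file
#'
#' Inverse of [read_seg()]: emits a tab-separated SEG file with header
#' \code{sample_id, chrom, loc_start, loc_end, seg_mean}, converting the
#' internal 0-based half-open coordinates back to 1-based inclusive. An
#' empty collection yields a header-only file.
#'
#' @param profiles List of [segment_profile()] objects.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_seg <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "segment_profile"))
    data.frame(
      sample_id = p$sample_id,
      chrom = p$segments$chrom,
      loc_start = format(p$segments$start + 1, scientific = FALSE, trim = TRUE),
      loc_end = format(p$segments$end, scientific = FALSE, trim = TRUE),
      seg_mean = p$segments$log2_ratio,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(
      sample_id = character(0), chrom = character(0),
      loc_start = character(0), loc_end = character(0),
      seg_mean = numeric(0)
    )
  }
  ok <- try(
    utils::write.table(out, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = TRUE
    ),
    silent = TRUE
  )
  if (inherits(ok, "try-error")) {
    stop_ginscore("cannot write SEG file: ", path)
  }
  invisible(path)
}

#' Fraction of genome altered for one profile
#'
#' FGA is the summed length of segments whose copy-number value exceeds an
#' alteration threshold in magnitude, divided by the total length of all
#' measured segments. With log2 ratios (the default) a segment counts as
#' altered when \code{|log2_ratio| > threshold}, so deletions and
#' amplifications both contribute; with \code{linear = TRUE} the same
#' threshold is applied to \code{|value - 1|} for linear copy-number ratios.
#'
#' @param profile A [segment_profile()].
#' @param alteration_threshold Positive magnitude threshold (default 0.2).
#' @param linear If \code{TRUE} treat segment values as linear ratios
#'   centred at 1 rather than log2 ratios centred at 0.
#' @return A list of class \code{fga_value} with \code{sample_id},
#'   \code{fga}, \code{altered_length} and \code{total_length}.
#' @examples
#' p <- segment_profile("s1", data.frame(
#'   chrom = c("1", "1", "2"), start = c(0, 600, 0),
#'   end = c(600, 1000, 1000), log2_ratio = c(0.3, 0.1, -0.25)
#' ))
#' compute_fga(p)$fga # 1600 / 2000
#' @export
compute_fga <- function(profile, alteration_threshold = 0.2, linear = FALSE) {
  stopifnot(inherits(profile, "segment_profile"))
  if (!is.numeric(alteration_threshold) || alteration_threshold <= 0) {
    stop_ginscore("alteration_threshold must be positive")
  }
  seg <- profile$segments
  if (nrow(seg) == 0) {
    stop_ginscore(
      "sample ", profile$sample_id, ": empty profile, total length zero"
    )
  }
  len <- seg$end - seg$start
  dev <- if (linear) abs(seg$log2_ratio - 1) else abs(seg$log2_ratio)
  altered <- sum(len[dev > alteration_threshold])
  total <- sum(len)
  structure(
    list(
      sample_id = profile$sample_id,
      fga = altered / total,
      altered_length = altered,
      total_length = total
    ),
    class = "fga_value"
  )
}

#' @export
print.fga_value <- function(x, ...) {
  cat(sprintf(
    "FGA[%s] = %.4f (%g / %g bp)\n",
    x$sample_id, x$fga, x$altered_length, x$total_length
  ))
  invisible(x)
}

#' FGA for a collection of profiles
#'
#' @param profiles List of [segment_profile()] objects.
#' @inheritParams compute_fga
#' @return Data frame with columns \code{sample_id}, \code{fga},
#'   \code{altered_length}, \code{total_length}.
#' @export
fga_table <- function(profiles, alteration_threshold = 0.2, linear = FALSE) {
  rows <- lapply(profiles, function(p) {
    v <- compute_fga(p, alteration_threshold, linear)
    data.frame(
      sample_id = v$sample_id, fga = v$fga,
      altered_length = v$altered_length, total_length = v$total_length,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
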