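#' Monomer distance (MD) points
#'
#' For each monomer `i`, the period is the distance, in monomer units, to
#' the next monomer of the same family along the enumeration. A point
#' `(index, period)` is emitted whenever that next occurrence lies within
#' `max_period`; the last occurrence of each family emits nothing. The MD
#' diagram is the scatter of these points; dense horizontal runs of points
#' at one period mark HOR arrays.
#'
#' @param labels integer family labels in enumeration order (or an
#'   `hor_families` object).
#' @param max_period largest period reported, in monomer units. Default 50
#'   comfortably covers the periods satellite HOR diagrams display.
#' @return `data.frame` with columns `index` (0-based enumeration) and
#'   `period`, ordered by `index`.
#' @export
compute_md_points <- function(labels, max_period = 50) {
  labels <- as_label_vector(labels)
  n <- length(labels)
  if (n < 2) return(data.frame(index = integer(0), period = integer(0)))
  idx <- seq_len(n) - 1L
  chunks <- lapply(split(idx, labels), function(p) {
    if (length(p) < 2) return(NULL)
    cbind(p[-length(p)], diff(p))
  })
  m <- do.call(rbind, chunks)
  if (is.null(m)) return(data.frame(index = integer(0), period = integer(0)))
  m <- m[m[, 2] <= max_period, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(index = as.integer(m[, 1]), period = as.integer(m[, 2]))
}

as_label_vector <- function(labels) {
  if (inherits(labels, "hor_families")) labels <- labels$labels
  if (is.factor(labels)) labels <- as.integer(labels)
  as.integer(labels)
}

#' Global repeat map (GRM) histogram
#'
#' Tabulates MD points by period: the frequency of each repetition period
#' over all monomers. Distinct peaks at period `n` flag `n`mer HORs (or
#' their subfragments).
#'
#' @param points MD points from [compute_md_points()].
#' @return `data.frame` with columns `period` and `count`, ordered by
#'   period; periods with no points are absent.
#' @export
grm_histogram <- function(points) {
  if (nrow(points) == 0) return(data.frame(period = integer(0), count = integer(0)))
  tab <- table(points$period)
  data.frame(period = as.integer(names(tab)), count = as.integer(tab))
}

#' Detect dense MD-line segments
#'
#' Groups MD points of equal period into maximal runs in which consecutive
#' points are at most `max_gap` enumeration units apart, and keeps runs
#' supported by at least `min_support` points. These are the horizontal
#' "MD-line segments" that, to the eye, look like continuous lines in the
#' MD diagram.
#'
#' @param points MD points from [compute_md_points()].
#' @param min_support minimum number of points per segment (default 10).
#' @param max_gap largest allowed enumeration gap between consecutive points
#'   of a segment; `NULL` (default) uses `max(5 * period, 50)`. The
#'   proportional part lets sparse long periods tolerate larger holes; the
#'   floor keeps short subfragment periods intact, whose points recur only
#'   once per HOR copy (e.g. the period-2 line of a cascading 17mer emits
#'   one point every 17 monomers).
#' @return `data.frame` with columns `period`, `start_index`, `end_index`
#'   (enumeration interval covered, including the partner monomer of the
#'   last point), and `support`.
#' @export
detect_segments <- function(points, min_support = 10, max_gap = NULL) {
  out <- list()
  for (p in sort(unique(points$period))) {
    ix <- sort(points$index[points$period == p])
    gap <- if (is.null(max_gap)) max(5L * p, 50L) else max_gap
    brk <- c(0L, which(diff(ix) > gap), length(ix))
    for (k in seq_len(length(brk) - 1L)) {
      run <- ix[(brk[k] + 1L):brk[k + 1L]]
      if (length(run) >= min_support) {
        out[[length(out) + 1L]] <- data.frame(
          period = p, start_index = run[1],
          end_index = run[length(run)] + p, support = length(run))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(period = integer(0), start_index = integer(0),
                      end_index = integer(0), support = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start_index, -res$support), , drop = FALSE]
}

#' Classify MD-line segments as HOR or subfragment
#'
#' Within each group of segments whose enumeration intervals overlap by at
#' least 50% (of the shorter interval), the segment with the greatest
#' support is the HOR; the remaining co-located segments are its
#' subfragments (shorter intra- or inter-copy same-type distances, e.g.
#' periods 15 and 2 inside a cascading 17mer). Segments overlapping no
#' other segment are each the HOR of their own interval.
#'
#' @param segments output of [detect_segments()].
#' @return the same data frame with an added `kind` column
#'   (`"HOR"` or `"subfragment"`).
#' @export
classify_segments <- function(segments) {
  n <- nrow(segments)
  segments$kind <- rep(NA_character_, n)
  if (n == 0) return(segments)
  ord <- order(-segments$support, -segments$period, segments$start_index)
  for (i in ord) {
    assigned_hors <- which(segments$kind == "HOR")
    sub <- FALSE
    for (j in assigned_hors) {
      ov <- min(segments$end_index[i], segments$end_index[j]) -
        max(segments$start_index[i], segments$start_index[j])
      shorter <- min(segments$end_index[i] - segments$start_index[i],
                     segments$end_index[j] - segments$start_index[j])
      if (shorter <= 0) next
      if (ov / shorter >= 0.5) { sub <- TRUE; break }
    }
    segments$kind[i] <- if (sub) "subfragment" else "HOR"
  }
  segments
}

#' Write periodicity tables
#'
#' Plain TSV writers for the MD points (`index`, `period`), the GRM
#' histogram (`period`, `count`), and classified segments.
#'
#' @param points,grm,segments the respective data frames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_md_points_tsv <- function(points, path) write_tsv(points, path)

#' @rdname write_md_points_tsv
#' @export
write_grm_tsv <- function(grm, path) write_tsv(grm, path)

#' @rdname write_md_points_tsv
#' @export
write_segments_tsv <- function(segments, path) write_tsv(segments, path)
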