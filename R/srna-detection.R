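#' Detection parameters for coverage-based sRNA calling
#'
#' @param min_depth Minimum per-base read depth (reads/base) for a position
#'   to count as expressed.
#' @param min_length,max_length Size bounds (nt) for a call; the defaults
#'   bracket the 101-562 nt range typical of bacterial sRNAs.
#' @param merge_gap Maximum run of sub-threshold bases merged into one call.
#' @param utr_max_distance A same-strand candidate whose 3'-most end lies
#'   within this many nt upstream of a gene start is treated as a 5' UTR and
#'   dropped.
#' @param min_antisense_overlap Minimum fraction of a call's length that must
#'   overlap an opposite-strand gene for a cis classification.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_depth = 5, min_length = 50,
                             max_length = 700, merge_gap = 25,
                             utr_max_distance = 50,
                             min_antisense_overlap = 0.5) {
  abort_if(!(min_length > 0 && min_length < max_length),
           "need 0 < min_length < max_length")
  abort_if(min_depth < 0 || merge_gap < 0 || utr_max_distance < 0,
           "thresholds must be >= 0")
  abort_if(min_antisense_overlap <= 0 || min_antisense_overlap > 1,
           "min_antisense_overlap must be in (0, 1]")
  structure(as.list(environment()), class = "detection_params")
}

empty_candidates <- function() {
  tibble::tibble(replicon = character(), strand = character(),
                 start = integer(), end = integer(),
                 mean_depth = numeric())
}

#' Call candidate expressed intervals from strand-specific coverage
#'
#' Finds maximal runs of depth >= `min_depth` per replicon and strand,
#' merges runs separated by gaps of at most `merge_gap` bases, and filters
#' the merged intervals to `[min_length, max_length]`. Coordinates are
#' 0-based half-open.
#'
#' @param coverage A `strand_coverage` object.
#' @param params A [detection_params()].
#' @return A tibble with `replicon`, `strand`, `start`, `end`, `mean_depth`.
#' @export
call_candidate_intervals <- function(coverage, params = detection_params()) {
  out <- list()
  for (r in names(coverage)) {
    for (st in c("+", "-")) {
      depth <- coverage[[r]][[st]]
      rl <- rle(depth >= params$min_depth)
      if (!any(rl$values)) next
      e <- cumsum(rl$lengths)
      s <- e - rl$lengths            # 0-based starts
      runs <- data.frame(start = s[rl$values], end = e[rl$values])
      # merge across small gaps
      if (nrow(runs) > 1) {
        gap <- runs$start[-1] - runs$end[-nrow(runs)]
        grp <- cumsum(c(0L, as.integer(gap > params$merge_gap)))
        runs <- data.frame(start = tapply(runs$start, grp, min),
                           end = tapply(runs$end, grp, max))
      }
      len <- runs$end - runs$start
      runs <- runs[len >= params$min_length & len <= params$max_length, ,
                   drop = FALSE]
      if (nrow(runs) == 0) next
      md <- mapply(function(a, b) mean(depth[(a + 1):b]),
                   runs$start, runs$end)
      out[[length(out) + 1L]] <- tibble::tibble(
        replicon = r, strand = st, start = as.integer(runs$start),
        end = as.integer(runs$end), mean_depth = as.numeric(md))
    }
  }
  if (length(out) == 0) return(empty_candidates())
  dplyr::bind_rows(out)
}

#' Drop 5'-UTR-like candidates
#'
#' A candidate is removed iff it lies on the same strand as a gene and its
#' 3'-most end (in the gene's reading orientation) is within
#' `utr_max_distance` nt upstream of that gene's start: such signal is
#' contiguous leader sequence, not an independent sRNA. Antisense or
#' gene-desert candidates are untouched by this filter.
#'
#' @param candidates Tibble from [call_candidate_intervals()].
#' @param annotation A [genome_annotation()].
#' @param params A [detection_params()].
#' @return The filtered candidate tibble.
#' @export
remove_utr_like <- function(candidates, annotation,
                            params = detection_params()) {
  if (nrow(candidates) == 0) return(candidates)
  g <- annotation$genes
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    same <- g[g$replicon == cand$replicon & g$strand == cand$strand, ]
    if (nrow(same) == 0) return(TRUE)
    d <- if (cand$strand == "+") same$start - cand$end else
      cand$start - same$end
    !any(d >= 0 & d <= params$utr_max_distance)
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' Classify candidates as cis (antisense) or trans (intergenic) sRNA calls
#'
#' A candidate overlapping an opposite-strand gene by at least
#' `min_antisense_overlap` of its own length becomes a cis call whose
#' `antisense_locus` is the maximally overlapping gene (ties broken by the
#' lexicographically smaller locus tag). A candidate overlapping no gene on
#' either strand becomes a trans call. Candidates that merely run past a
#' same-strand gene 3' end are trimmed to their non-overlapping portion
#' (operon read-through is not an sRNA); candidates still overlapping a
#' same-strand gene body after trimming are discarded.
#'
#' @param candidates Tibble of candidates (after [remove_utr_like()]).
#' @param annotation A [genome_annotation()].
#' @param params A [detection_params()].
#' @param coverage Optional `strand_coverage` used to refresh `mean_depth`
#'   after trimming.
#' @return A tibble of sRNA calls: `id`, `replicon`, `start`, `end`,
#'   `strand`, `size`, `mode`, `antisense_locus`, `mean_depth`.
#' @export
classify_calls <- function(candidates, annotation,
                           params = detection_params(), coverage = NULL) {
  g <- annotation$genes
  calls <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    on_rep <- g[g$replicon == cand$replicon, ]
    same <- on_rep[on_rep$strand == cand$strand, ]
    ov_same <- overlap_len(cand$start, cand$end, same$start, same$end)
    if (any(ov_same > 0)) {
      # trim a 3'-end straddle; anything else same-strand is not an sRNA
      hit <- same[ov_same > 0, ]
      if (nrow(hit) > 1) next
      if (cand$strand == "+" && cand$start < hit$end &&
          cand$start >= hit$start && cand$end > hit$end) {
        cand$start <- hit$end
      } else if (cand$strand == "-" && cand$end > hit$start &&
                 cand$end <= hit$end && cand$start < hit$start) {
        cand$end <- hit$start
      } else {
        next
      }
      if (cand$end - cand$start < params$min_length) next
      if (!is.null(coverage)) {
        depth <- coverage[[cand$replicon]][[cand$strand]]
        cand$mean_depth <- mean(depth[(cand$start + 1):cand$end])
      }
    }
    anti <- on_rep[on_rep$strand != cand$strand, ]
    ov_anti <- overlap_len(cand$start, cand$end, anti$start, anti$end)
    len <- cand$end - cand$start
    if (any(ov_anti >= params$min_antisense_overlap * len)) {
      best <- which(ov_anti == max(ov_anti))
      locus <- sort(anti$locus_tag[best])[1]
      calls[[length(calls) + 1L]] <- tibble::tibble(
        replicon = cand$replicon, start = cand$start, end = cand$end,
        strand = cand$strand, size = len, mode = "cis",
        antisense_locus = locus, mean_depth = cand$mean_depth)
    } else if (all(ov_anti == 0)) {
      calls[[length(calls) + 1L]] <- tibble::tibble(
        replicon = cand$replicon, start = cand$start, end = cand$end,
        strand = cand$strand, size = len, mode = "trans",
        antisense_locus = NA_character_, mean_depth = cand$mean_depth)
    }
    # partial antisense overlap below the threshold: neither cis nor
    # intergenic; not called
  }
  if (length(calls) == 0)
    return(tibble::tibble(id = character(), replicon = character(),
                          start = integer(), end = integer(),
                          strand = character(), size = integer(),
                          mode = character(), antisense_locus = character(),
                          mean_depth = numeric()))
  calls <- dplyr::bind_rows(calls)
  calls <- calls[order(calls$replicon, calls$start), ]
  calls$size <- as.integer(calls$size)
  n_cis <- cumsum(calls$mode == "cis")
  n_trans <- cumsum(calls$mode == "trans")
  calls$id <- ifelse(calls$mode == "cis", sprintf("cis%d", n_cis),
                     sprintf("trans%d", n_trans))
  calls[, c("id", "replicon", "start", "end", "strand", "size", "mode",
            "antisense_locus", "mean_depth")]
}

#' Detect sRNAs from coverage and annotation
#'
#' Convenience wrapper running [call_candidate_intervals()],
#' [remove_utr_like()] and [classify_calls()] in sequence.
#'
#' @inheritParams classify_calls
#' @param coverage A `strand_coverage` object.
#' @return A tibble of sRNA calls.
#' @export
detect_srnas <- function(coverage, annotation, params = detection_params()) {
  cand <- call_candidate_intervals(coverage, params)
  cand <- remove_utr_like(cand, annotation, params)
  classify_calls(cand, annotation, params, coverage = coverage)
}
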