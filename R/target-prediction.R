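#' Assign cis-sRNA targets by antisense position
#'
#' Each cis call's regulatory target is the gene on the antisense strand.
#'
#' @param calls An sRNA call tibble (see [classify_calls()]).
#' @param annotation A [genome_annotation()] used to attach the target's
#'   product annotation.
#' @return A tibble with `srna_id`, `target_locus`, `target_annotation`.
#' @export
assign_cis_targets <- function(calls, annotation) {
  cis <- calls[calls$mode == "cis", , drop = FALSE]
  abort_if(any(is.na(cis$antisense_locus)),
           "cis call without antisense locus: %s",
           paste(cis$id[is.na(cis$antisense_locus)], collapse = ", "))
  i <- match(cis$antisense_locus, annotation$genes$locus_tag)
  tibble::tibble(srna_id = cis$id, target_locus = cis$antisense_locus,
                 target_annotation = annotation$genes$product[i])
}

BASES <- c("A", "C", "G", "T")

seq_to_bases <- function(x) {
  if (is(x, "XString")) x <- as.character(x)
  x <- chartr("u", "t", x)
  v <- strsplit(toupper(x), "")[[1]]
  v <- chartr("U", "T", v)
  abort_if(!all(v %in% BASES), "sequence contains non-ACGTU characters")
  v
}

# antiparallel pair weights: rows = sRNA base, cols = mRNA base;
# Watson-Crick = 1, G:U wobble = wobble_weight
pair_weight_matrix <- function(wobble_weight = 0.5) {
  W <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  W["A", "T"] <- W["T", "A"] <- W["C", "G"] <- W["G", "C"] <- 1
  W["G", "T"] <- W["T", "G"] <- wobble_weight
  W
}

#' Maximum perfect antisense seed score between an sRNA and a target window
#'
#' Scans every ungapped antiparallel alignment of the sRNA against the
#' window and scores each maximal run in which every opposing base pair is
#' Watson-Crick (weight 1) or G:U wobble (weight `wobble_weight`). Runs
#' shorter than `seed_min` bases score 0; the returned value is the best
#' run's summed weight.
#'
#' @param srna_seq,window_seq Sequences (character or Biostrings), both
#'   written 5'->3' in their own sense.
#' @param seed_min Minimum duplex run length (nt).
#' @param wobble_weight Weight of a G:U pair.
#' @return A single non-negative score.
#' @export
seed_score <- function(srna_seq, window_seq, seed_min = 7,
                       wobble_weight = 0.5) {
  s <- seq_to_bases(srna_seq)
  w <- seq_to_bases(window_seq)
  if (length(s) < seed_min || length(w) < seed_min) return(0)
  seed_score_idx(match(s, BASES), rev(match(w, BASES)), seed_min,
                 pair_weight_matrix(wobble_weight))
}

# s, rw: integer base codes (window already reversed); W: 4x4 weights.
# Aligned diagonals of the s x rw weight matrix are contiguous duplexes.
# All diagonals are laid out end to end (with a forced zero between them)
# so a single run-length pass finds the best perfect run.
seed_score_idx <- function(s, rw, seed_min, W) {
  score_window_batch(list(s), rw, seed_min, W)
}

# score many equal-length sRNA code vectors (observed + shuffles) against
# one reversed window, reusing the diagonal layout
score_window_batch <- function(seq_codes, rw, seed_min, W) {
  n <- length(seq_codes[[1]]); m <- length(rw)
  iv <- rep.int(seq_len(n), m)
  jv <- rep(seq_len(m), each = n)
  # column dd = diagonal i - j + m; row m + 1 stays zero and breaks runs
  lin <- jv + (iv - jv + m - 1L) * (m + 1L)
  rwj <- 4L * (rw[jv] - 1L)
  Wf <- as.vector(W)
  v <- numeric((m + 1L) * (n + m - 1L))
  vapply(seq_codes, function(sc) {
    v[lin] <<- Wf[sc[iv] + rwj]
    best_run_sum(v, seed_min)
  }, numeric(1))
}

best_run_sum <- function(v, seed_min) {
  r <- rle(v > 0)
  take <- r$values & r$lengths >= seed_min
  if (!any(take)) return(0)
  e <- cumsum(r$lengths)
  b <- e - r$lengths
  cs <- cumsum(v)
  max(cs[e[take]] - ifelse(b[take] > 0, cs[b[take]], 0))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random Eulerian-path shuffle: the returned sequence has exactly the same
#' dinucleotide (and hence mononucleotide) counts and the same first and
#' last base as the input.
#'
#' @param x A sequence (character string or base vector).
#' @return A character vector of bases.
#' @export
dinucleotide_shuffle <- function(x) {
  v <- if (length(x) == 1 && is.character(x)) seq_to_bases(x) else x
  n <- length(v)
  if (n < 4 || length(unique(v)) < 2) return(v)
  from <- v[-n]; to <- v[-1]
  verts <- unique(v)
  sn <- v[n]
  out <- lapply(setNames(verts, verts), function(u) which(from == u))
  pick <- function(idx) idx[sample.int(length(idx), 1)]
  repeat {
    last <- lapply(out, function(idx) if (length(idx)) pick(idx) else NA)
    ok <- TRUE
    for (u in verts) {
      if (u == sn || length(out[[u]]) == 0) next
      cur <- u
      for (step in seq_len(length(verts) + 1)) {
        if (cur == sn) break
        e <- last[[cur]]
        if (is.na(e)) { cur <- NA; break }
        cur <- to[e]
      }
      if (!identical(cur, sn)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  ord <- lapply(setNames(verts, verts), function(u) {
    idx <- out[[u]]
    if (length(idx) == 0) return(integer(0))
    if (u == sn) return(idx[sample.int(length(idx))])
    rest <- setdiff(idx, last[[u]])
    c(rest[sample.int(length(rest))], last[[u]])
  })
  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  cur <- v[1]
  res[1] <- cur
  for (k in 2:n) {
    e <- ord[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    cur <- to[e]
    res[k] <- cur
  }
  res
}

#' Extract the start-codon-anchored target window of a gene
#'
#' @param annotation A [genome_annotation()].
#' @param genome_seq Named character vector (or `DNAStringSet`) of replicon
#'   sequences.
#' @param locus_tag Gene id.
#' @param window_up,window_down nt upstream/downstream of the start codon.
#' @return The window sequence, mRNA sense, as a character string.
#' @export
gene_target_window <- function(annotation, genome_seq, locus_tag,
                               window_up = 80, window_down = 20) {
  g <- annotation$genes[annotation$genes$locus_tag == locus_tag, ]
  abort_if(nrow(g) != 1, "unknown locus %s", locus_tag)
  if (is(genome_seq, "DNAStringSet"))
    genome_seq <- as.character(genome_seq)
  chrom <- if (g$replicon %in% names(genome_seq))
    genome_seq[[g$replicon]] else NA_character_
  abort_if(is.na(chrom), "missing sequence for replicon of locus %s",
           locus_tag)
  L <- nchar(chrom)
  if (g$strand == "+") {
    a <- max(1L, g$start + 1L - window_up)
    b <- min(L, g$start + window_down)
    substr(chrom, a, b)
  } else {
    a <- max(1L, g$end + 1L - window_down)
    b <- min(L, g$end + window_up)
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(chrom, a, b))))
  }
}

#' Predict trans-sRNA targets by seed complementarity
#'
#' Scores each gene's start-codon-anchored window against the sRNA with
#' [seed_score()] and assesses significance against the empirical null of
#' scores obtained from dinucleotide-preserving shuffles of the sRNA
#' (`p = (1 + #{null >= observed}) / (n_shuffles + 1)`).
#'
#' @param srna_seq sRNA sequence.
#' @param annotation A [genome_annotation()].
#' @param genome_seq Named replicon sequences (character or `DNAStringSet`).
#' @param window_up,window_down Window geometry around the start codon.
#' @param seed_min Minimum duplex run length.
#' @param wobble_weight Weight of a G:U pair.
#' @param n_shuffles Size of the shuffle null.
#' @param p_threshold Report predictions with `p < p_threshold`.
#' @param seed Optional RNG seed for the shuffles.
#' @return A tibble with `target_locus`, `target_annotation`, `score`, `p`,
#'   sorted by p then locus tag.
#' @export
predict_trans_targets <- function(srna_seq, annotation, genome_seq,
                                  window_up = 80, window_down = 20,
                                  seed_min = 7, wobble_weight = 0.5,
                                  n_shuffles = 200, p_threshold = 0.01,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- seq_to_bases(srna_seq)
  empty <- tibble::tibble(target_locus = character(),
                          target_annotation = character(),
                          score = numeric(), p = numeric())
  if (length(s) < seed_min) return(empty)
  W <- pair_weight_matrix(wobble_weight)
  si <- match(s, BASES)
  shuf <- replicate(n_shuffles, match(dinucleotide_shuffle(s), BASES),
                    simplify = FALSE)
  g <- annotation$genes
  res <- lapply(seq_len(nrow(g)), function(i) {
    w <- gene_target_window(annotation, genome_seq, g$locus_tag[i],
                            window_up, window_down)
    abort_if(!nzchar(w), "empty target window for locus %s", g$locus_tag[i])
    rw <- rev(match(seq_to_bases(w), BASES))
    sc <- score_window_batch(c(list(si), shuf), rw, seed_min, W)
    obs <- sc[1]
    null <- sc[-1]
    tibble::tibble(target_locus = g$locus_tag[i],
                   target_annotation = g$product[i], score = obs,
                   p = (1 + sum(null >= obs)) / (n_shuffles + 1))
  })
  res <- dplyr::bind_rows(res)
  res <- res[res$p < p_threshold, , drop = FALSE]
  res[order(res$p, res$target_locus), ]
}

#' Random replicon sequences for an annotation
#'
#' Convenience generator of GC-biased random genome sequence matching the
#' annotation's replicon lengths (synthetic sequence; no gene structure).
#'
#' @param annotation A [genome_annotation()].
#' @param gc GC content (the organism modelled here is GC-rich).
#' @param seed RNG seed.
#' @return Named character vector of sequences.
#' @export
random_genome_sequence <- function(annotation, gc = 0.64, seed = 1L) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(annotation$replicons, function(L) {
    paste(sample(BASES, as.integer(L), replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}
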