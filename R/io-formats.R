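#' @importFrom methods is
#' @importFrom stats median qf qnorm quantile rnbinom rnorm rpois runif rgamma
#'   setNames aggregate coef vcov lm pnorm p.adjust dnbinom dpois pnbinom
#'   qnbinom rbinom qt glm Gamma binomial plogis lowess complete.cases cor sd
#'   var logLik optim predict
#' @importFrom utils head read.delim write.table URLencode URLdecode
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

#' Construct a genome annotation
#'
#' Bundles replicon lengths with a gene table. Gene coordinates follow the
#' package-wide convention: 0-based, half-open intervals `[start, end)`.
#' Conversion from the 1-based inclusive convention of GFF3 happens only in
#' [read_gff3()] / [write_gff3()].
#'
#' @param replicons Named numeric vector of replicon lengths in bp.
#' @param genes A data frame with columns `locus_tag`, `replicon`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`), `product`, and optionally `category`.
#' @return An object of class `genome_annotation`: a list with elements
#'   `replicons` and `genes` (a tibble).
#' @export
genome_annotation <- function(replicons, genes = NULL) {
  abort_if(length(replicons) == 0 || is.null(names(replicons)) ||
             any(!nzchar(names(replicons))),
           "replicons must be a named vector of lengths")
  abort_if(any(replicons <= 0), "replicon lengths must be > 0")
  if (is.null(genes) || nrow(genes) == 0) {
    genes <- tibble::tibble(locus_tag = character(), replicon = character(),
                            start = integer(), end = integer(),
                            strand = character(), product = character(),
                            category = character())
  } else {
    genes <- tibble::as_tibble(genes)
    if (is.null(genes$product)) genes$product <- NA_character_
    if (is.null(genes$category)) genes$category <- NA_character_
    abort_if(anyDuplicated(genes$locus_tag) > 0,
             "duplicate locus_tag: %s",
             paste(unique(genes$locus_tag[duplicated(genes$locus_tag)]),
                   collapse = ", "))
    abort_if(!all(genes$strand %in% c("+", "-")),
             "gene strand must be '+' or '-'")
    abort_if(!all(genes$start < genes$end), "gene start must be < end")
    abort_if(!all(genes$replicon %in% names(replicons)),
             "gene on undeclared replicon: %s",
             paste(setdiff(genes$replicon, names(replicons)), collapse = ", "))
    too_far <- genes$end > replicons[genes$replicon] | genes$start < 0
    abort_if(any(too_far), "gene outside replicon bounds: %s",
             paste(genes$locus_tag[too_far], collapse = ", "))
  }
  structure(list(replicons = replicons, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d replicon(s), %d gene(s)\n",
              length(x$replicons), nrow(x$genes)))
  for (r in names(x$replicons))
    cat(sprintf("  %s: %s bp, %d genes\n", r,
                format(x$replicons[[r]], big.mark = ","),
                sum(x$genes$replicon == r)))
  invisible(x)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Read a GFF3 genome annotation
#'
#' Parses gene features (those with a `locus_tag` attribute) and
#' `##sequence-region` directives. GFF3 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file with a `##gff-version 3` directive.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  abort_if(length(lines) == 0 || !grepl("^##gff-version\\s+3", lines[[1]]),
           "%s: missing ##gff-version 3 directive", path)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield != 9]
  abort_if(length(bad) > 0, "%s: malformed GFF3 line %d (%d fields, need 9)",
           path, bad[1], nfield[which(which(body) == bad[1])])
  sr <- grep("^##sequence-region\\b", lines, value = TRUE)
  abort_if(length(sr) == 0, "%s: no ##sequence-region directives", path)
  srf <- strsplit(trimws(sr), "\\s+")
  replicons <- vapply(srf, function(f) as.numeric(f[4]), numeric(1))
  names(replicons) <- vapply(srf, function(f) f[2], character(1))
  abort_if(anyDuplicated(names(replicons)) > 0,
           "%s: duplicate ##sequence-region", path)
  if (!any(body)) return(genome_annotation(replicons))

  gr <- rtracklayer::import(path, format = "gff3")
  keep <- !is.na(S4Vectors::mcols(gr)$locus_tag %||% rep(NA, length(gr)))
  gr <- gr[keep]
  if (length(gr) == 0) return(genome_annotation(replicons))
  m <- S4Vectors::mcols(gr)
  genes <- tibble::tibble(
    locus_tag = as.character(m$locus_tag),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = as.character(m$product %||% rep(NA_character_, length(gr))),
    category = as.character(m$category %||% rep(NA_character_, length(gr))))
  abort_if(!all(genes$replicon %in% names(replicons)),
           "%s: feature on undeclared replicon %s", path,
           paste(setdiff(genes$replicon, names(replicons)), collapse = ", "))
  out_of_bounds <- genes$end > replicons[genes$replicon]
  abort_if(any(out_of_bounds), "%s: feature beyond replicon end: %s", path,
           paste(genes$locus_tag[out_of_bounds], collapse = ", "))
  genome_annotation(replicons, genes)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_gff3()]: emits `##sequence-region` directives and one
#' `gene` feature per row, converting internal 0-based half-open coordinates
#' back to GFF3 1-based inclusive.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", names(annotation$replicons),
                   as.integer(annotation$replicons)))
  g <- annotation$genes
  rows <- character(0)
  if (nrow(g) > 0) {
    attrs <- sprintf("ID=%s;locus_tag=%s", g$locus_tag, g$locus_tag)
    has_p <- !is.na(g$product)
    attrs[has_p] <- paste0(attrs[has_p], ";product=",
                           gff3_escape(g$product[has_p]))
    has_c <- !is.na(g$category)
    attrs[has_c] <- paste0(attrs[has_c], ";category=",
                           gff3_escape(g$category[has_c]))
    rows <- sprintf("%s\tsrnapipe\tgene\t%d\t%d\t.\t%s\t.\t%s",
                    g$replicon, g$start + 1L, g$end, g$strand, attrs)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Construct an all-zero strand-specific coverage object
#'
#' @param annotation A [genome_annotation()] supplying replicon lengths.
#' @return An object of class `strand_coverage`: a list mapping replicon id
#'   to a list with `+` and `-` numeric depth vectors of replicon length.
#' @export
strand_coverage <- function(annotation) {
  out <- lapply(annotation$replicons, function(L) {
    L <- as.integer(L)
    list(`+` = numeric(L), `-` = numeric(L))
  })
  structure(out, class = "strand_coverage")
}

#' @export
print.strand_coverage <- function(x, ...) {
  cat(sprintf("<strand_coverage> %d replicon(s)\n", length(x)))
  for (r in names(x))
    cat(sprintf("  %s: %s bp, mean depth %.3f (+) / %.3f (-)\n", r,
                format(length(x[[r]][["+"]]), big.mark = ","),
                mean(x[[r]][["+"]]), mean(x[[r]][["-"]])))
  invisible(x)
}

bedgraph_to_depth <- function(path, annotation) {
  abort_if(!file.exists(path), "file not found: %s", path)
  depth <- lapply(annotation$replicons,
                  function(L) numeric(as.integer(L)))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^(track|#)", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) return(depth)
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  abort_if(!all(chrom %in% names(annotation$replicons)),
           "%s: unknown replicon %s", path,
           paste(setdiff(chrom, names(annotation$replicons)), collapse = ", "))
  score <- S4Vectors::mcols(gr)$score
  abort_if(any(score < 0), "%s: negative coverage value", path)
  for (r in unique(chrom)) {
    sel <- chrom == r
    s <- GenomicRanges::start(gr)[sel]   # 1-based after import
    e <- GenomicRanges::end(gr)[sel]
    abort_if(any(e > length(depth[[r]])) || any(s < 1),
             "%s: interval outside replicon %s", path, r)
    cov1 <- IRanges::coverage(IRanges::IRanges(s, e),
                              width = length(depth[[r]]))
    abort_if(max(cov1) > 1, "%s: overlapping bedGraph intervals on %s",
             path, r)
    v <- as.numeric(IRanges::coverage(IRanges::IRanges(s, e),
                                      weight = score[sel],
                                      width = length(depth[[r]])))
    depth[[r]] <- depth[[r]] + v
  }
  depth
}

#' Read a plus/minus bedGraph pair into strand-specific coverage
#'
#' bedGraph positions are 0-based half-open, matching the internal
#' convention directly. Positions absent from the file get depth 0;
#' overlapping intervals within one file are rejected.
#'
#' @param plus_path,minus_path bedGraph files for the + and - strand.
#' @param annotation A [genome_annotation()] declaring replicon lengths.
#' @return A `strand_coverage` object.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, annotation) {
  cov <- strand_coverage(annotation)
  plus <- bedgraph_to_depth(plus_path, annotation)
  minus <- bedgraph_to_depth(minus_path, annotation)
  for (r in names(cov)) {
    cov[[r]][["+"]] <- plus[[r]]
    cov[[r]][["-"]] <- minus[[r]]
  }
  cov
}

#' Write strand-specific coverage as a bedGraph pair
#'
#' @param coverage A `strand_coverage` object.
#' @param plus_path,minus_path Output paths for the two strands.
#' @return The two paths, invisibly.
#' @export
write_bedgraph_pair <- function(coverage, plus_path, minus_path) {
  write_one <- function(strand, path) {
    rows <- character(0)
    for (r in names(coverage)) {
      rl <- S4Vectors::Rle(coverage[[r]][[strand]])
      e <- cumsum(S4Vectors::runLength(rl))
      s <- e - S4Vectors::runLength(rl)     # 0-based starts
      v <- S4Vectors::runValue(rl)
      keep <- v != 0
      if (any(keep))
        rows <- c(rows, sprintf("%s\t%d\t%d\t%s", r, s[keep], e[keep],
                                format(v[keep], scientific = FALSE,
                                       trim = TRUE)))
    }
    writeLines(rows, path)
  }
  write_one("+", plus_path)
  write_one("-", minus_path)
  invisible(c(plus_path, minus_path))
}

#' Construct a two-condition count matrix
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param condition Factor or character vector (one per sample) with exactly
#'   two levels; the first level is the numerator of reported fold-changes
#'   (by convention the C-limited condition).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  abort_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "counts must carry feature and sample names")
  abort_if(anyDuplicated(rownames(counts)) > 0, "duplicate feature ids")
  abort_if(any(counts < 0) || any(counts != round(counts)),
           "counts must be non-negative integers")
  abort_if(length(condition) != ncol(counts),
           "one condition label per sample required")
  condition <- if (is.factor(condition)) condition else
    factor(condition, levels = unique(condition))
  abort_if(nlevels(condition) != 2, "exactly two conditions required")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", levels(x$condition),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Read a count matrix and sample sheet
#'
#' @param counts_path TSV with a `feature` column then one column per sample.
#' @param samples_path TSV with columns `sample` and `condition`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- read.delim(counts_path, check.names = FALSE)
  abort_if(names(tab)[1] != "feature", "%s: first column must be 'feature'",
           counts_path)
  sheet <- read.delim(samples_path)
  abort_if(!all(c("sample", "condition") %in% names(sheet)),
           "%s: needs columns sample, condition", samples_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$feature
  abort_if(!setequal(colnames(m), sheet$sample),
           "sample sheet does not match count columns")
  sheet <- sheet[match(colnames(m), sheet$sample), ]
  count_matrix(m, sheet$condition)
}

#' Write a count matrix and sample sheet
#'
#' @param cm A [count_matrix()].
#' @param counts_path,samples_path Output TSV paths.
#' @return The paths, invisibly.
#' @export
write_count_matrix <- function(cm, counts_path, samples_path) {
  tab <- data.frame(feature = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(cm$counts),
                         condition = as.character(cm$condition)),
              samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Signed-fold convention for reported fold-differences
#'
#' Maps a log2 fold-change to the signed ratio used in report tables:
#' magnitude is the ratio of normalized means (always >= 1), the sign marks
#' the higher condition (+ = higher under the first/numerator condition).
#'
#' @param log2fc Numeric vector of log2 fold-changes.
#' @return Numeric vector with `abs(value) >= 1`.
#' @export
signed_fold <- function(log2fc) {
  ifelse(is.na(log2fc), NA_real_,
         ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc))))
}

#' Write the sRNA report table
#'
#' One row per called sRNA with size, mode, assigned target, and the
#' differential-expression summary in the signed-fold convention.
#'
#' @param calls An `srna_calls` tibble (see [classify_calls()]).
#' @param de_results A tibble of DE results (see [nb_exact_test()]) or NULL.
#' @param targets Optional tibble with `srna_id`, `target_locus`,
#'   `target_annotation` (cis assignments and/or trans predictions).
#' @param path Output TSV path.
#' @return The report tibble, invisibly.
#' @export
write_srna_table <- function(calls, de_results = NULL, targets = NULL,
                             path) {
  tab <- tibble::tibble(
    id = calls$id, size_nt = calls$size, mode = calls$mode,
    detection = ifelse(calls$mode == "cis", "Antisense", "Intergenic"),
    target_locus = NA_character_, target_annotation = NA_character_,
    fold_difference = NA_real_, fdr_q = NA_real_)
  if (!is.null(targets) && nrow(targets) > 0) {
    abort_if(!all(targets$srna_id %in% calls$id),
             "targets reference unknown sRNA ids: %s",
             paste(setdiff(targets$srna_id, calls$id), collapse = ", "))
    i <- match(tab$id, targets$srna_id)
    tab$target_locus <- targets$target_locus[i]
    if (!is.null(targets$target_annotation))
      tab$target_annotation <- targets$target_annotation[i]
  }
  if (!is.null(de_results) && nrow(de_results) > 0) {
    i <- match(tab$id, de_results$feature)
    tab$fold_difference <- signed_fold(de_results$log2fc[i])
    tab$fdr_q <- de_results$q[i]
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read back an sRNA report table
#'
#' @param path TSV written by [write_srna_table()].
#' @return A tibble.
#' @export
read_srna_table <- function(path) {
  tibble::as_tibble(read.delim(path, na.strings = "NA"))
}

#' Read a directed edge list
#'
#' @param path TSV with columns `source` and `target` (gene ids).
#' @return A tibble with those two character columns.
#' @export
read_edge_list <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  abort_if(!all(c("source", "target") %in% names(tab)),
           "%s: needs columns source, target", path)
  tibble::as_tibble(tab[, c("source", "target")])
}

#' Write a directed edge list
#' @param edges Data frame with `source`, `target`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges[, c("source", "target")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an electrophoresis ladder table
#' @param path TSV with columns `size_nt`, `distance`.
#' @return A tibble.
#' @export
read_ladder <- function(path) {
  tab <- read.delim(path)
  abort_if(!all(c("size_nt", "distance") %in% names(tab)),
           "%s: needs columns size_nt, distance", path)
  tibble::as_tibble(tab)
}

#' Write an electrophoresis ladder table
#' @param ladder Data frame with `size_nt`, `distance`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ladder <- function(ladder, path) {
  write.table(ladder[, c("size_nt", "distance")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
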