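#' Pair peaks from two chromatin marks by distance
#'
#' Pairs mark-A peaks with mark-B peaks on the same chromosome whose
#' midpoint-to-midpoint distance is strictly below `max_distance`.
#' Matching is one-to-one and greedy nearest-first: candidate pairs are
#' ranked by distance and accepted while both partners are unused, so no
#' peak joins two pairs and the outcome is symmetric in the two mark
#' roles.  Unpaired peaks are dropped.
#'
#' @param peaks_a,peaks_b Peak [GenomicRanges::GRanges] for the two
#'   marks.
#' @param max_distance Pairing threshold in bp, exclusive (default 500).
#' @param method Distance measure: interval midpoints (default) or
#'   edge-to-edge gap (0 when intervals overlap).
#' @return A data.frame of colocalized loci: `chrom`, `mid_a`, `mid_b`,
#'   `distance`, `idx_a`, `idx_b` (row indices into the inputs), one row
#'   per pair, ordered by chromosome and `mid_a`.
#' @export
colocalize <- function(peaks_a, peaks_b, max_distance = 500,
                       method = c("midpoint", "edge")) {
  method <- match.arg(method)
  stopifnot(max_distance > 0)
  empty <- data.frame(chrom = character(0), mid_a = numeric(0),
                      mid_b = numeric(0), distance = numeric(0),
                      idx_a = integer(0), idx_b = integer(0))
  if (length(peaks_a) == 0L || length(peaks_b) == 0L) return(empty)
  mid <- function(g) {
    (GenomicRanges::start(g) + GenomicRanges::end(g)) / 2
  }
  chr_a <- as.character(GenomeInfoDb::seqnames(peaks_a))
  chr_b <- as.character(GenomeInfoDb::seqnames(peaks_b))
  ma <- mid(peaks_a)
  mb <- mid(peaks_b)
  out <- list()
  for (ch in intersect(unique(chr_a), unique(chr_b))) {
    ia <- which(chr_a == ch)
    ib <- which(chr_b == ch)
    if (method == "midpoint") {
      d <- abs(outer(ma[ia], mb[ib], "-"))
    } else {
      d <- pmax(outer(GenomicRanges::start(peaks_a)[ia],
                      GenomicRanges::end(peaks_b)[ib], "-"),
                -outer(GenomicRanges::end(peaks_a)[ia],
                       GenomicRanges::start(peaks_b)[ib], "-"),
                0)
    }
    cand <- which(d < max_distance, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    ord <- order(d[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    used_a <- logical(length(ia))
    used_b <- logical(length(ib))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, mid_a = ma[ia[i]], mid_b = mb[ib[j]],
        distance = d[i, j], idx_a = ia[i], idx_b = ib[j])
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$mid_a), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# strand-aware 5' end of each gene (1-based coordinate)
.tss <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::end(genes), GenomicRanges::start(genes))
}

#' Classify loci by genomic context
#'
#' Assigns each query position exactly one label with precedence
#' promoter > intragenic > intergenic.  A locus is promoter when it lies
#' in the strand-appropriate window around any gene's 5' end
#' (`promoter_up` bp upstream to `promoter_down` bp downstream);
#' intragenic when inside any gene body; otherwise intergenic, flagged
#' distal when the distance to the nearest 5' end exceeds `distal_cut`.
#'
#' @param chrom Character vector of locus chromosomes.
#' @param pos Numeric vector of locus positions (1-based midpoints).
#' @param genes [GenomicRanges::GRanges] gene models with strand.
#' @param promoter_up,promoter_down Promoter window half-widths in bp
#'   (defaults 2000 upstream, 500 downstream).
#' @param distal_cut Intergenic-distal threshold in bp (default 10000,
#'   exclusive).
#' @return A data.frame with `context` ("promoter"/"intragenic"/
#'   "intergenic"), `dist_to_tss` (bp to nearest 5' end, `Inf` with an
#'   empty annotation) and `distal` (logical).
#' @export
classify_locus <- function(chrom, pos, genes, promoter_up = 2000,
                           promoter_down = 500, distal_cut = 10000) {
  stopifnot(length(chrom) == length(pos))
  n <- length(pos)
  if (length(genes) == 0L) {
    return(data.frame(context = rep("intergenic", n),
                      dist_to_tss = rep(Inf, n),
                      distal = rep(TRUE, n)))
  }
  tss <- .tss(genes)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  prom_lo <- ifelse(minus, tss - promoter_down, tss - promoter_up)
  prom_hi <- ifelse(minus, tss + promoter_up, tss + promoter_down)
  gchr <- as.character(GenomeInfoDb::seqnames(genes))

  context <- character(n)
  dist_to_tss <- numeric(n)
  for (i in seq_len(n)) {
    same <- gchr == chrom[i]
    if (!any(same)) {
      context[i] <- "intergenic"
      dist_to_tss[i] <- Inf
      next
    }
    dist_to_tss[i] <- min(abs(pos[i] - tss[same]))
    if (any(same & pos[i] >= prom_lo & pos[i] <= prom_hi)) {
      context[i] <- "promoter"
    } else if (any(same & pos[i] >= GenomicRanges::start(genes) &
                   pos[i] <= GenomicRanges::end(genes))) {
      context[i] <- "intragenic"
    } else {
      context[i] <- "intergenic"
    }
  }
  data.frame(context = context, dist_to_tss = dist_to_tss,
             distal = context == "intergenic" & dist_to_tss > distal_cut)
}

#' Annotate colocalized loci with genomic context
#'
#' Convenience wrapper: classifies each pair's A-side midpoint via
#' [classify_locus()] and binds the result onto the pair table.
#'
#' @param loci A data.frame from [colocalize()].
#' @param genes Gene models ([GenomicRanges::GRanges]).
#' @param ... Passed to [classify_locus()].
#' @return `loci` with `context`, `dist_to_tss`, `distal` columns added.
#' @export
annotate_loci <- function(loci, genes, ...) {
  cls <- classify_locus(loci$chrom, round((loci$mid_a + loci$mid_b) / 2),
                        genes, ...)
  cbind(loci, cls)
}

#' Summarize context categories
#'
#' @param context Character vector of context labels (or a data.frame
#'   with a `context` column).
#' @return A data.frame with `context`, `count`, `fraction`; fractions
#'   sum to 1.
#' @export
summarize_contexts <- function(context) {
  if (is.data.frame(context)) context <- context$context
  if (length(context) == 0L) stop("no loci to summarize")
  lev <- c("promoter", "intragenic", "intergenic")
  cnt <- vapply(lev, function(l) sum(context == l), integer(1))
  data.frame(context = lev, count = cnt, fraction = cnt / sum(cnt),
             row.names = NULL)
}

#' Overlap of loci with an external gene list
#'
#' Counts loci whose midpoint falls within `window` bp of any listed
#' gene's span.  Gene names that cannot be resolved against the
#' annotation are skipped with a warning.
#'
#' @param chrom,pos Locus chromosomes and midpoints.
#' @param gene_list Character vector of gene names (resolved against
#'   `genes$name`) or a [GenomicRanges::GRanges] of intervals.
#' @param genes Annotation GRanges with a `name` column (needed only for
#'   name resolution).
#' @param window Extension in bp around each listed gene span (default
#'   0).
#' @return A list with `count` and `hits` (names or indices of the
#'   overlapped list entries).
#' @export
overlap_with_gene_list <- function(chrom, pos, gene_list, genes = NULL,
                                   window = 0) {
  if (is.character(gene_list)) {
    if (is.null(genes) || is.null(S4Vectors::mcols(genes)$name)) {
      stop("a named annotation is required to resolve gene names")
    }
    hit <- match(gene_list, S4Vectors::mcols(genes)$name)
    if (anyNA(hit)) {
      warning(sum(is.na(hit)), " gene name(s) not in annotation; skipped")
      hit <- hit[!is.na(hit)]
    }
    targets <- genes[hit]
  } else {
    targets <- gene_list
  }
  if (length(targets) == 0L || length(pos) == 0L) {
    return(list(count = 0L, hits = character(0)))
  }
  tchr <- as.character(GenomeInfoDb::seqnames(targets))
  lo <- GenomicRanges::start(targets) - window
  hi <- GenomicRanges::end(targets) + window
  in_any <- vapply(seq_along(pos), function(i) {
    any(tchr == chrom[i] & pos[i] >= lo & pos[i] <= hi)
  }, logical(1))
  hit_names <- S4Vectors::mcols(targets)$name
  hit_idx <- vapply(seq_along(targets), function(j) {
    any(chrom == tchr[j] & pos >= lo[j] & pos <= hi[j])
  }, logical(1))
  list(count = sum(in_any),
       hits = if (!is.null(hit_names)) hit_names[hit_idx]
              else which(hit_idx))
}
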