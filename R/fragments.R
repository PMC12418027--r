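#' Window-based fragment sampling for species-tree input
#'
#' Cuts per-sample consensus sequences (all aligned to the same reference
#' coordinates) into fixed-length fragments anchored at reference position
#' 0 and spaced `interval` bp apart: starts 0, interval, 2*interval, ...
#' while a full fragment fits. A fragment is discarded when any sample's
#' sub-sequence contains more than `max_ambiguous` `N` bases, or when no
#' alignment column free of `N` in every sample is variable (monomorphic
#' after ambiguity masking). Survivors are per-fragment alignments ready
#' for single-locus tree inference.
#'
#' @param seqs Named list, one element per sample; each element a named
#'   character vector of chromosome sequences. All samples must carry the
#'   same chromosomes at identical lengths.
#' @param fragment_len Fragment length in bp (default 1000).
#' @param interval Spacing between fragment starts in bp (default 20000).
#' @param max_ambiguous Maximum tolerated `N` count per sample per
#'   fragment (default 50).
#' @return A list of class `fragment_set`: `fragments` (data frame with
#'   `chrom`, `start` 0-based, `end` half-open, `status`
#'   kept/ambiguous/monomorphic, `max_n`), `alignments` (list of named
#'   character vectors, one per kept fragment), and the parameters.
#' @export
sample_fragments <- function(seqs, fragment_len = 1000, interval = 20000,
                             max_ambiguous = 50) {
  if (!length(seqs)) stop("no samples")
  chroms <- names(seqs[[1]])
  for (s in seqs) {
    if (!identical(names(s), chroms) ||
        !identical(nchar(s), nchar(seqs[[1]])))
      stop("all samples must have identical chromosomes and lengths")
  }
  rows <- list(); alns <- list()
  for (ch in chroms) {
    len <- nchar(seqs[[1]][[ch]])
    starts <- seq(0, len - fragment_len, by = interval)
    for (st in starts) {
      sub <- vapply(seqs, function(s)
        substr(s[[ch]], st + 1, st + fragment_len), "")
      ncounts <- vapply(strsplit(sub, ""), function(x) sum(x == "N"), 0L)
      status <- "kept"
      if (max(ncounts) > max_ambiguous) {
        status <- "ambiguous"
      } else {
        m <- do.call(rbind, strsplit(sub, ""))
        clean <- colSums(m == "N") == 0
        variable <- apply(m[, clean, drop = FALSE], 2,
                          function(col) length(unique(col)) > 1)
        if (!any(variable)) status <- "monomorphic"
      }
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, start = st, end = st + fragment_len,
                   status = status, max_n = max(ncounts),
                   stringsAsFactors = FALSE)
      if (status == "kept")
        alns[[paste0(ch, "_", st)]] <- sub
    }
  }
  frags <- do.call(rbind, rows)
  structure(list(fragments = frags, alignments = alns,
                 fragment_len = fragment_len, interval = interval,
                 max_ambiguous = max_ambiguous),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d candidates, %d kept (%d ambiguous, %d monomorphic)\n",
              nrow(x$fragments), sum(x$fragments$status == "kept"),
              sum(x$fragments$status == "ambiguous"),
              sum(x$fragments$status == "monomorphic")))
  invisible(x)
}

#' Write surviving fragments as per-locus FASTA alignments
#'
#' @param fs A [sample_fragments()] result.
#' @param dir Output directory (created if absent); one
#'   `<chrom>_<start>.fasta` per kept fragment.
#' @return Paths of the written files, invisibly.
#' @export
write_fragment_fastas <- function(fs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(fs$alignments), function(nm) {
    p <- file.path(dir, paste0(nm, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(fs$alignments[[nm]]), p)
    p
  }, "")
  invisible(paths)
}

#' Ploidy-aware pairwise divergence (Dxy)
#'
#' Per site, Dxy between two groups is the mean over every inter-group
#' pair of non-missing allele copies of the indicator that the two copies
#' differ; this accommodates arbitrary and mixed ploidies (a tetraploid
#' contributes four copies, a diploid two). Site values are averaged over
#' all sites supplied — monomorphic sites contribute 0, so the caller
#' fixes the denominator through the site set passed in.
#'
#' @param vm A [variant_matrix()].
#' @param groups Vector of group labels, one per sample (>= 2 groups).
#' @return A symmetric matrix of between-group Dxy values (diagonal is the
#'   within-group mean pairwise difference, for reference).
#' @export
dxy <- function(vm, groups) {
  groups <- as.character(groups)
  if (length(groups) != ncol(vm$gt))
    stop("one group label per sample required")
  labs <- unique(groups)
  if (length(labs) < 2) stop("need at least two groups")
  if (n_sites(vm) == 0) stop("no sites supplied")
  cc <- allele_copy_counts(vm)
  alt_g <- matrix(vapply(labs, function(g)
    rowSums(cc$alt[, groups == g, drop = FALSE]), numeric(n_sites(vm))),
    nrow = n_sites(vm))
  tot_g <- matrix(vapply(labs, function(g)
    rowSums(cc$called[, groups == g, drop = FALSE]), numeric(n_sites(vm))),
    nrow = n_sites(vm))
  if (any(colSums(tot_g) == 0))
    stop("group with zero non-missing allele copies")
  out <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      ok <- tot_g[, i] > 0 & tot_g[, j] > 0
      if (i == j) {
        # within-group: unordered pairs of distinct copies
        n <- tot_g[, i]; a <- alt_g[, i]
        ok <- n > 1
        site <- (a[ok] * (n[ok] - a[ok])) / (n[ok] * (n[ok] - 1) / 2)
        out[i, i] <- if (any(ok)) sum(site) / n_sites(vm) else 0
      } else {
        p1 <- alt_g[ok, i] / tot_g[ok, i]
        p2 <- alt_g[ok, j] / tot_g[ok, j]
        out[i, j] <- sum(p1 * (1 - p2) + p2 * (1 - p1)) / n_sites(vm)
      }
    }
  }
  out
}
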