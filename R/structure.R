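#' Mixed-ploidy STRUCTURE matrix
#'
#' Writes genotypes in the one-row-per-allele-copy STRUCTURE format with
#' every individual coded as tetraploid (four rows each): tetraploids
#' contribute their four allele copies, diploids contribute their two
#' copies followed by two padding rows of missing data (-9) across all
#' loci. Missing allele copies are likewise coded -9. Allele coding is the
#' VCF 0/1 index, column-consistent across rows.
#'
#' @param vm A [variant_matrix()] of biallelic sites, samples of ploidy 2
#'   or 4.
#' @param path Optional output path; when given the matrix is written as
#'   whitespace-delimited text (first column = individual label).
#' @return Invisibly (and visibly when `path` is NULL), an integer matrix
#'   with `4 * n_samples` rows and one column per locus, with rownames the
#'   individual labels.
#' @export
write_structure <- function(vm, path = NULL) {
  n <- ncol(vm$gt)
  l <- n_sites(vm)
  rows <- matrix(-9L, nrow = 4 * n, ncol = l)
  labels <- rep(colnames(vm$gt), each = 4)
  for (j in seq_len(n)) {
    copies <- strsplit(vm$gt[, j], "/", fixed = TRUE)
    k <- vm$ploidy[j]
    for (c_i in seq_len(k)) {
      a <- vapply(copies, `[`, "", c_i)
      v <- suppressWarnings(as.integer(a))
      v[is.na(v)] <- -9L
      rows[(j - 1) * 4 + c_i, ] <- v
    }
    # diploids: rows k+1..4 stay -9 (tetraploid padding)
  }
  rownames(rows) <- labels
  if (!is.null(path)) {
    lines <- vapply(seq_len(nrow(rows)), function(i)
      paste(c(labels[i], rows[i, ]), collapse = " "), "")
    writeLines(lines, path)
  }
  invisible(rows)
}
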