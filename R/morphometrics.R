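#' Wilcoxon rank-sum comparison of two trait samples
#'
#' Thin, reporting-oriented wrapper around [stats::wilcox.test()] applied
#' to untransformed measurements. The p-value is exact (full enumeration)
#' when the combined sample size is at most 12 and there are no ties;
#' otherwise the normal approximation with midranks, tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_limit Combined sample size at or below which the exact
#'   distribution is enumerated (default 12).
#' @return A `group_comparison` list: `test`, `statistic` (W), `p_value`,
#'   `n` (group sizes), `alternative`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided",
                              exact_limit = 12) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical in both samples; p = 1")
    return(group_comparison("wilcoxon_rank_sum",
                            statistic = length(x) * length(y) / 2,
                            p_value = 1, n = c(length(x), length(y)),
                            alternative = alternative, exact = FALSE))
  }
  exact <- !ties && (length(x) + length(y) <= exact_limit)
  w <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  group_comparison("wilcoxon_rank_sum", statistic = unname(w$statistic),
                   p_value = w$p.value, n = c(length(x), length(y)),
                   alternative = alternative, exact = exact)
}

#' Two-sample t comparison
#'
#' Wrapper around [stats::t.test()]. Welch's unequal-variance form is the
#' default; `variant = "student"` selects the pooled-variance form. Both
#' samples constant and equal means is reported as p = 1 with a warning
#' rather than an error.
#'
#' @param x,y Numeric samples of length >= 2.
#' @param variant `"welch"` (default) or `"student"`.
#' @param alternative Tail mode, default two-sided.
#' @return A `group_comparison` list with `statistic` (t), `df`,
#'   `p_value`, `n`, `alternative`.
#' @export
t_compare <- function(x, y, variant = c("welch", "student"),
                      alternative = "two.sided") {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("both samples constant with equal means; p = 1")
      return(group_comparison("t_test", statistic = 0, p_value = 1,
                              n = c(length(x), length(y)),
                              alternative = alternative, df = NA_real_))
    }
    stop("both samples constant with different means: zero variance")
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "student"),
                      alternative = alternative)
  group_comparison("t_test", statistic = unname(tt$statistic),
                   p_value = tt$p.value, n = c(length(x), length(y)),
                   alternative = alternative, df = unname(tt$parameter))
}

group_comparison <- function(test, statistic, p_value, n, alternative,
                             exact = NA, df = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, n = n, alternative = alternative,
                 exact = exact),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s, %s)\n", x$test,
              x$statistic, x$p_value, paste(x$n, collapse = "/"),
              x$alternative))
  invisible(x)
}

#' Tabulate leaflet-pair counts per species
#'
#' Contingency counts of compound leaves by number of leaflet pairs, the
#' summary used to contrast diploid and tetraploid leaf architecture.
#'
#' @param traits Data frame with columns `species` and `leaflet_pairs`.
#' @return An integer table, species x leaflet-pair count; row sums equal
#'   the number of leaves measured per species. Empty input gives an empty
#'   table.
#' @export
leaflet_pair_table <- function(traits) {
  if (!all(c("species", "leaflet_pairs") %in% names(traits)))
    stop("traits must have species and leaflet_pairs columns")
  table(species = traits$species, pairs = traits$leaflet_pairs)
}

# Character ranges of the determination key. Leaflet count 9, diameter
# 4 mm and flowering in May fall in both species' ranges and are
# deliberately indecisive.
key_ranges <- list(
  paliurus = list(leaflets = c(5, 9), diameter_mm = c(4, 6),
                  stamens = c(30, 35), month = c(4, 5)),
  serrata  = list(leaflets = c(9, 13), diameter_mm = c(3, 4),
                  stamens = c(18, 20), month = c(5, 6))
)

#' Determination-key classifier
#'
#' Each provided character votes according to the printed key: leaflets
#' per compound leaf 5-9 (tetraploid, *C. paliurus*) vs 9-13 (diploid,
#' *C. serrata*); male flower diameter 4-6 mm vs 3-4 mm; stamens 30-35 vs
#' 18-20; flowering mid-April to early May vs mid-May to early June
#' (months 4-5 vs 5-6). Range boundaries are inclusive, so values the key
#' ranges share (9 leaflets, 4 mm, month 5) match both species and
#' abstain. A specimen is assigned only when every provided character is
#' compatible with exactly one common species and at least one character
#' is decisive; any contradiction or residual tie is `"ambiguous"`.
#'
#' @param leaflets Integer leaflets per compound leaf (optional).
#' @param stamens Integer stamen count (optional).
#' @param diameter_mm Male flower diameter in mm (optional).
#' @param flowering_month Calendar month 1-12 (optional).
#' @return A list: `species` (`"C. paliurus"`, `"C. serrata"` or
#'   `"ambiguous"`) and `votes`, a per-character report of which species
#'   each character matched.
#' @export
classify_specimen <- function(leaflets = NULL, stamens = NULL,
                              diameter_mm = NULL, flowering_month = NULL) {
  vals <- list(leaflets = leaflets, stamens = stamens,
               diameter_mm = diameter_mm, month = flowering_month)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  if (!length(vals)) stop("provide at least one character")
  num <- unlist(vals)
  if (any(num < 0)) stop("character values must be non-negative")
  species_names <- c(paliurus = "C. paliurus", serrata = "C. serrata")
  votes <- lapply(names(vals), function(ch) {
    hit <- vapply(names(key_ranges), function(sp) {
      rng <- key_ranges[[sp]][[ch]]
      vals[[ch]] >= rng[1] && vals[[ch]] <= rng[2]
    }, TRUE)
    unname(species_names[names(key_ranges)[hit]])
  })
  names(votes) <- names(vals)
  if (any(lengths(votes) == 0))  # contradicts both ranges
    return(list(species = "ambiguous", votes = votes))
  common <- Reduce(intersect, votes)
  decisive <- any(lengths(votes) == 1)
  species <- if (length(common) == 1 && decisive) common else "ambiguous"
  list(species = species, votes = votes)
}
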