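#' Prune highly correlated predictors
#'
#' Collinear bioclim layers carry redundant niche information; the standard
#' remedy is to drop variables until no retained pair exceeds a Pearson
#' correlation threshold in absolute value (strong negative correlation is
#' equally redundant). The rule here is greedy: while any retained pair has
#' |r| > `r_threshold`, drop the variable involved in a violating pair with
#' the largest mean |r| against the other retained variables. Variables in
#' `keep` are never dropped. Constant (zero-variance) columns are dropped
#' first with a warning, since their correlation is undefined.
#'
#' @param env Numeric matrix, records x variables (named columns).
#' @param r_threshold Absolute Pearson correlation above which a pair is
#'   considered redundant (default 0.8, i.e. drop when |r| > 0.8).
#' @param keep Character vector of column names that must survive.
#' @return A list: `env` (the pruned matrix), `pruned` (data frame naming
#'   each dropped variable and the maximum |r| that condemned it), and
#'   `retained` (surviving names).
#' @export
prune_correlated <- function(env, r_threshold = 0.8, keep = character()) {
  if (ncol(env) < 2) stop("need at least two variables")
  if (is.null(colnames(env))) colnames(env) <- paste0("V", seq_len(ncol(env)))
  bad <- !is.na(colnames(env)) & !(keep %in% colnames(env))
  if (length(keep) && any(!(keep %in% colnames(env))))
    stop("keep names absent from matrix: ",
         paste(setdiff(keep, colnames(env)), collapse = ", "))
  pruned <- data.frame(variable = character(), reason = character(),
                       max_abs_r = numeric(), stringsAsFactors = FALSE)
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0)) {
    const <- colnames(env)[sds == 0]
    const <- setdiff(const, keep)
    if (length(const)) {
      warning("dropping constant column(s): ", paste(const, collapse = ", "))
      pruned <- rbind(pruned, data.frame(variable = const, reason = "constant",
                                         max_abs_r = NA_real_))
      env <- env[, setdiff(colnames(env), const), drop = FALSE]
    }
  }
  repeat {
    r <- abs(stats::cor(env))
    diag(r) <- 0
    viol <- which(r > r_threshold, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    cand <- setdiff(colnames(env)[unique(as.vector(viol))], keep)
    if (length(cand) == 0) {
      warning("correlated pair(s) remain but all members are in keep list")
      break
    }
    mean_r <- vapply(cand, function(v) mean(r[v, colnames(env) != v]), 0)
    drop_v <- cand[which.max(mean_r)]
    pruned <- rbind(pruned,
                    data.frame(variable = drop_v, reason = "correlated",
                               max_abs_r = max(r[drop_v, ])))
    env <- env[, setdiff(colnames(env), drop_v), drop = FALSE]
    if (ncol(env) < 2) break
  }
  list(env = env, pruned = pruned, retained = colnames(env))
}

#' Z-score standardization
#'
#' Centers and scales every column to mean 0, SD 1 (sample SD, denominator
#' n - 1), computed on the pooled matrix of all records so both species
#' share one standardized space.
#'
#' @param env Numeric matrix, records x variables.
#' @return Matrix of the same shape with standardized columns; attributes
#'   `center` and `scale` record the transform.
#' @export
zscore <- function(env) {
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(env)[sds == 0], collapse = ", "))
  mu <- colMeans(env)
  out <- sweep(sweep(env, 2, mu), 2, sds, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sds
  out
}
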