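#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection of `k` features against a continuous target.
#' Relevance of feature f is the F statistic of the univariate linear
#' regression of the target on f (computed as r^2 (n-2) / (1 - r^2) from the
#' Pearson correlation; constant features get relevance 0). Redundancy of a
#' candidate given the selected set S is its largest absolute Pearson
#' correlation R with any member of S (a candidate is as redundant as its most
#' collinear selected partner). The step score is relevance x (1 - R^2): an
#' approximate partial F that credits a candidate only for the share of its
#' variance not already carried by the selected set, so a perfect copy of a
#' selected feature scores exactly 0 at every step. The first feature is the relevance
#' maximum. Ties break toward the earlier column (catalog order), so selection
#' is fully deterministic, and the k-feature set is by construction a prefix
#' of any larger-k set.
#'
#' An alternative mutual-information estimator (equal-frequency discretization
#' of feature and target into `mi_bins` bins) can be selected with
#' `relevance = "mi"`; redundancy is then the mean pairwise MI and the step
#' score the classic MIQ quotient relevance / max(redundancy, `eps`).
#'
#' @param table data.frame of candidate feature columns (all numeric).
#' @param target numeric vector, one value per row (EE in kcal/min by
#'   default in the pipeline).
#' @param k number of features to select (1 <= k <= ncol(table)).
#' @param relevance "f_stat" (default) or "mi".
#' @param mi_bins bins for the MI estimator (default 10).
#' @param eps floor for the MIQ redundancy denominator (default 1e-6).
#' @return list of class `"mrmr_selection"`: `k`, `ordered_features`,
#'   `relevance` (named, all candidates), `step_scores`, `step_redundancy`.
#' @export
mrmr_select <- function(table, target, k, relevance = c("f_stat", "mi"),
                        mi_bins = 10, eps = 1e-6) {
  relevance <- match.arg(relevance)
  stopifnot(is.data.frame(table) || is.matrix(table))
  X <- as.matrix(table)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("need at least 2 rows")
  if (length(target) != n) stop("target length must match rows")
  if (k < 1L || k > p) stop("`k` must be between 1 and the number of features")
  feats <- colnames(X) %||% paste0("f", seq_len(p))
  colnames(X) <- feats

  sds <- apply(X, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (relevance == "f_stat") {
    r <- rep(0, p)
    ok <- !const & stats::sd(target) > 0
    if (any(ok)) r[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], target))
    rel <- ifelse(const, 0, r^2 * (n - 2) / pmax(1 - r^2, .Machine$double.eps))
    red_fun <- function(i, j) abs(pair_cor[i, j])
    pair_cor <- matrix(0, p, p)
    ok2 <- which(!const)
    if (length(ok2) > 1)
      pair_cor[ok2, ok2] <- stats::cor(X[, ok2, drop = FALSE])
  } else {
    disc <- apply(X, 2, discretize_ef, bins = mi_bins)
    yb <- discretize_ef(target, mi_bins)
    rel <- apply(disc, 2, mutual_info, yb)
    rel[const] <- 0
    red_fun <- function(i, j) mutual_info(disc[, i], disc[, j])
    pair_cor <- NULL
  }
  names(rel) <- feats

  selected <- integer(0)
  step_scores <- numeric(0)
  step_red <- numeric(0)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    if (step == 1L) {
      score <- rel[remaining]
      red <- rep(0, length(remaining))
    } else {
      agg <- if (relevance == "f_stat") max else mean
      red <- vapply(remaining, function(i)
        agg(vapply(selected, function(j) red_fun(i, j), numeric(1))),
        numeric(1))
      score <- if (relevance == "f_stat")
        rel[remaining] * pmax(1 - red^2, 0)
      else rel[remaining] / pmax(red, eps)
    }
    best <- remaining[which.max(score)] # which.max: first max = catalog order
    step_scores <- c(step_scores, score[which.max(score)])
    step_red <- c(step_red, red[which.max(score)])
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  structure(list(k = as.integer(k), ordered_features = feats[selected],
                 relevance = rel, step_scores = unname(step_scores),
                 step_redundancy = unname(step_red)),
            class = "mrmr_selection")
}

# equal-frequency discretization into `bins` levels
discretize_ef <- function(x, bins) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7))
  if (length(qs) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

# plug-in mutual information (nats) of two integer codes
mutual_info <- function(a, b) {
  tab <- table(a, b)
  pj <- tab / sum(tab)
  pa <- rowSums(pj); pb <- colSums(pj)
  e <- outer(pa, pb)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / e[nz]))
}

#' @export
print.mrmr_selection <- function(x, ...) {
  cat("mRMR selection of", x$k, "features:\n")
  cat(paste0(sprintf("%2d. %s (score %.3g)", seq_len(x$k),
                     x$ordered_features, x$step_scores), collapse = "\n"),
      "\n")
  invisible(x)
}
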