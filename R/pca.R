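#' Principal component analysis on the correlation matrix
#'
#' PCA of an exposure matrix using the correlation (not covariance)
#' matrix, so chemicals with very different measurement scales contribute
#' comparably.  Internally computed by singular value decomposition of the
#' standardized data.  Eigenvector sign is arbitrary, so each loading
#' column is flipped to a fixed convention: its largest-magnitude element
#' is made negative (matching the predominantly negative first components
#' seen in these exposure panels).
#'
#' @param X numeric matrix or data frame, participants x chemicals; at
#'   least 2 rows and 2 columns, no constant column, no missing values.
#' @return object of class `correlation_pca`: list with `eigenvalues`
#'   (nonincreasing, summing to the number of variables), `loadings`
#'   (chemicals x components, orthonormal columns), `scores`
#'   (participants x components), `variance_fractions`.
#' @export
correlation_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  if (anyNA(X))
    stop("missing exposure entries are not allowed; drop or impute upstream",
         call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  # pad: prcomp returns at most min(n-1, p) components
  p <- ncol(X)
  if (length(ev) < p) ev <- c(ev, rep(0, p - length(ev)))
  load <- pc$rotation
  scores <- pc$x
  # sign convention: largest-|loading| element of each column negative
  for (k in seq_len(ncol(load))) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] > 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(eigenvalues = ev,
                 loadings = load,
                 scores = scores,
                 variance_fractions = ev / sum(ev)),
            class = "correlation_pca")
}

#' @export
print.correlation_pca <- function(x, ...) {
  cat("Correlation PCA:", nrow(x$loadings), "variables,",
      nrow(x$scores), "observations\n")
  vf <- round(100 * x$variance_fractions, 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Retain components by cumulative variance
#'
#' Returns the smallest number of leading components whose cumulative
#' variance fraction meets the threshold (default 80%), and their scores;
#' in these exposure panels one or at most two components typically
#' suffice.
#'
#' @param r a [correlation_pca()] result.
#' @param threshold cumulative variance fraction to reach, default 0.80.
#' @return list with `k` (count) and `scores` (first k score columns).
#' @export
retain_components <- function(r, threshold = 0.80) {
  stopifnot(inherits(r, "correlation_pca"),
            threshold > 0, threshold <= 1)
  cum <- cumsum(r$variance_fractions)
  k <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(cum)
  list(k = k, scores = r$scores[, seq_len(k), drop = FALSE])
}

#' Signed-loading report for retained components
#'
#' Lists, per retained component, the chemicals whose absolute loading
#' reaches the display cutoff together with the loading sign — the
#' compact form in which component composition is usually reported for
#' exposure panels.
#'
#' @param r a [correlation_pca()] result.
#' @param k number of components to report.
#' @param cutoff display cutoff on |loading|, default 0.30.
#' @return object of class `loading_report`: list (one element per
#'   component) of data frames with columns chemical, loading, sign.
#' @export
loading_report <- function(r, k, cutoff = 0.30) {
  stopifnot(inherits(r, "correlation_pca"), k >= 1,
            k <= ncol(r$loadings))
  out <- lapply(seq_len(k), function(j) {
    l <- r$loadings[, j]
    sel <- abs(l) >= cutoff
    data.frame(chemical = rownames(r$loadings)[sel],
               loading = unname(l[sel]),
               sign = ifelse(l[sel] >= 0, "+", "-"),
               stringsAsFactors = FALSE)
  })
  names(out) <- paste0("PC", seq_len(k))
  class(out) <- "loading_report"
  out
}

#' @export
print.loading_report <- function(x, ...) {
  for (nm in names(x)) {
    df <- x[[nm]]
    if (nrow(df) == 0L) {
      cat(nm, ": (no loadings above cutoff)\n")
    } else {
      cat(nm, ": ",
          paste0(df$chemical, "(", df$sign, ")", collapse = ", "), "\n",
          sep = "")
    }
  }
  invisible(x)
}
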