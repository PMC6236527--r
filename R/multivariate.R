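# Ordination of the wells-by-analytes concentration matrix: PCA on the
# correlation (or covariance) structure, and correspondence analysis of the
# row/column profiles. Component sign convention throughout: the first
# nonzero loading (PCA) or column coordinate (CA) of each component is
# positive, so results are reproducible across LAPACK builds.

#' Wells-by-analytes concentration matrix
#'
#' @param summaries A well-summary tibble.
#' @param scope Summary scope to use (default `"overall"`).
#' @return A numeric matrix, wells in rows (names = well ids), analytes in
#'   columns.
#' @export
wells_matrix <- function(summaries, scope = "overall") {
  analytes <- intersect(GW_ANALYTES, unique(summaries$analyte))
  cols <- lapply(analytes, function(a) {
    sub <- scope_means(summaries, a, scope)
    sub <- sub[order(sub$well_id), , drop = FALSE]
    stats::setNames(sub$mean, sub$well_id)
  })
  wells <- names(cols[[1]])
  for (co in cols) {
    if (!identical(names(co), wells)) {
      gw_abort("wells differ between analytes", "gw_validation_error")
    }
  }
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(wells, analytes)
  mat
}

#' Analyte prevalence ordering
#'
#' Ranks analytes by their total (equivalently mean) concentration across
#' all wells, the mass ordering that a correspondence-analysis relay plot
#' expresses. Ties are broken alphabetically and flagged.
#'
#' @inheritParams wells_matrix
#' @return A tibble with columns `analyte`, `total`, `mean`, sorted by
#'   descending total, with attribute `tie` (logical: any exactly equal
#'   totals).
#' @export
#' @examples
#' prevalence_order(load_study_fixture())$analyte
#' # "antimony" "selenium" "arsenic"
prevalence_order <- function(summaries, scope = "overall") {
  mat <- wells_matrix(summaries, scope)
  totals <- colSums(mat)
  ord <- order(-totals, names(totals))
  out <- tibble::tibble(
    analyte = names(totals)[ord],
    total = unname(totals[ord]),
    mean = unname(totals[ord]) / nrow(mat)
  )
  attr(out, "tie") <- anyDuplicated(totals) > 0
  out
}

fix_signs <- function(loadings, scores) {
  for (k in seq_len(ncol(loadings))) {
    nz <- which(abs(loadings[, k]) > 1e-12)
    if (length(nz) && loadings[nz[1], k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component analysis of a concentration matrix
#'
#' Eigendecomposition of the correlation (`standardize = TRUE`, default) or
#' covariance matrix, via [stats::prcomp()]. Scores are the centered (and
#' scaled) data projected on the orthonormal loadings.
#'
#' @param mat Numeric matrix, observations in rows (`>= 2` rows and
#'   columns, finite entries).
#' @param standardize Use the correlation matrix (scale each column to unit
#'   variance). Zero-variance columns are rejected by name.
#' @return An object of class `gw_ordination`: a list with `method`
#'   (`"pca"`), `row_coords` (scores), `col_coords` (orthonormal loadings),
#'   `explained_fraction` (non-increasing, sums to 1), `total_variance` and
#'   `sdev`.
#' @export
pca_ordination <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2 || any(!is.finite(mat))) {
    gw_abort("need a finite matrix with >= 2 rows and columns", "gw_validation_error")
  }
  if (standardize) {
    v <- apply(mat, 2, stats::sd)
    if (any(v == 0)) {
      bad <- colnames(mat)[v == 0]
      if (is.null(bad)) bad <- which(v == 0)
      gw_abort(
        sprintf("zero-variance column(s) under standardization: %s",
          paste(bad, collapse = ", ")),
        "gw_validation_error"
      )
    }
  }
  fit <- stats::prcomp(mat, center = TRUE, scale. = standardize)
  fixed <- fix_signs(fit$rotation, fit$x)
  ev <- fit$sdev^2
  structure(
    list(
      method = "pca",
      row_coords = fixed$scores,
      col_coords = fixed$loadings,
      explained_fraction = ev / sum(ev),
      total_variance = sum(ev),
      sdev = fit$sdev
    ),
    class = "gw_ordination"
  )
}

#' Correspondence analysis of a non-negative matrix
#'
#' Singular value decomposition of the standardized Pearson-residual matrix
#' of the row/column profiles:
#' `S = Dr^{-1/2} (P - r c') Dc^{-1/2}` with `P` the matrix scaled to unit
#' total, `r`, `c` its margins. Row and column principal coordinates are
#' returned; the total inertia equals chi-squared / n. All-zero rows or
#' columns are dropped before the decomposition and reported.
#'
#' @param mat Non-negative numeric matrix.
#' @return A `gw_ordination` list with `method = "ca"`, `row_coords` and
#'   `col_coords` (principal coordinates), `explained_fraction`,
#'   `total_inertia`, `singular_values`, `row_mass`, `col_mass`, and
#'   `filtered_rows` / `filtered_cols` (names or indices dropped).
#' @export
ca_ordination <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat)) || any(mat < 0)) {
    gw_abort("matrix must be finite and non-negative", "gw_validation_error")
  }
  rs <- rowSums(mat); cs <- colSums(mat)
  filtered_rows <- rownames(mat)[rs == 0] %||% which(rs == 0)
  filtered_cols <- colnames(mat)[cs == 0] %||% which(cs == 0)
  mat <- mat[rs > 0, cs > 0, drop = FALSE]
  if (nrow(mat) == 0 || ncol(mat) == 0 || sum(mat) == 0) {
    gw_abort("matrix is all zero", "gw_validation_error")
  }
  n <- sum(mat)
  P <- mat / n
  r <- rowSums(P); c <- colSums(P)
  S <- diag(1 / sqrt(r), nrow = length(r)) %*% (P - outer(r, c)) %*%
    diag(1 / sqrt(c), nrow = length(c))
  dec <- svd(S)
  k <- min(nrow(mat), ncol(mat)) - 1
  d <- dec$d[seq_len(max(k, 1))]
  keep <- seq_along(d)
  # principal coordinates
  F_ <- diag(1 / sqrt(r), nrow = length(r)) %*% dec$u[, keep, drop = FALSE] %*%
    diag(d, nrow = length(d))
  G_ <- diag(1 / sqrt(c), nrow = length(c)) %*% dec$v[, keep, drop = FALSE] %*%
    diag(d, nrow = length(d))
  rownames(F_) <- rownames(mat); rownames(G_) <- colnames(mat)
  colnames(F_) <- colnames(G_) <- paste0("Dim", seq_along(d))
  fixed <- fix_signs(G_, F_)
  inertia <- sum(dec$d^2)
  expl <- if (inertia > 0) d^2 / inertia else rep(0, length(d))
  structure(
    list(
      method = "ca",
      row_coords = fixed$scores,
      col_coords = fixed$loadings,
      explained_fraction = expl,
      total_inertia = inertia,
      singular_values = d,
      row_mass = r,
      col_mass = c,
      filtered_rows = filtered_rows,
      filtered_cols = filtered_cols
    ),
    class = "gw_ordination"
  )
}

#' @export
print.gw_ordination <- function(x, ...) {
  cat(sprintf(
    "<gw_ordination: %s, %d x %d, components explain %s>\n",
    x$method, nrow(x$row_coords), nrow(x$col_coords),
    paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = " / ")
  ))
  invisible(x)
}
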