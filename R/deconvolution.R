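#' Build a cluster signature matrix from specific genes
#'
#' Rows are the union of all clusters' specific genes present in the
#' expression data; the entry for (gene, cluster) is the mean de-logged
#' expression of the gene over the cluster's cells. All-zero rows are
#' dropped.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param labels cluster id per cell.
#' @param specific_sets named list of per-cluster gene sets (e.g. from
#'   [specific_gene_sets()]).
#' @return Matrix, signature genes x clusters (columns named by cluster).
#' @export
build_signature <- function(norm, labels, specific_sets) {
  genes <- unique(unlist(specific_sets))
  if (!length(genes)) stop("build_signature: union of specific genes is empty")
  absent <- setdiff(genes, rownames(norm))
  if (length(absent)) {
    warning("build_signature: ", length(absent),
            " specific gene(s) absent from expression data were dropped")
    genes <- setdiff(genes, absent)
  }
  if (!length(genes)) stop("build_signature: no specific gene present in data")
  expd <- expm1(norm[genes, , drop = FALSE])
  if (is.factor(labels)) labels <- as.character(labels)
  clusters <- sort(unique(labels))
  sig <- vapply(clusters, function(cl) {
    rowMeans(expd[, labels == cl, drop = FALSE])
  }, numeric(length(genes)))
  sig <- matrix(sig, nrow = length(genes),
                dimnames = list(genes, as.character(clusters)))
  sig[rowSums(sig) > 0, , drop = FALSE]
}

shared_genes_or_stop <- function(signature, bulk, caller) {
  shared <- intersect(rownames(signature), rownames(bulk))
  if (!length(shared)) stop(caller, ": no shared genes between signature and bulk")
  shared
}

proportion_result <- function(props, rmse, corr, method) {
  structure(list(proportions = props, fit_rmse = rmse, fit_corr = corr,
                 method = method),
            class = "proportion_matrix")
}

#' Deconvolve bulk samples by non-negative least squares
#'
#' Reference solver: per sample, the bulk profile over the shared genes is
#' regressed on the signature columns under a nonnegativity constraint
#' (Lawson-Hanson NNLS); coefficients are renormalized to sum to 1.
#'
#' @param signature genes x clusters matrix from [build_signature()].
#' @param bulk genes x samples matrix.
#' @return `"proportion_matrix"`: `proportions` (samples x clusters, rows
#'   sum to 1), `fit_rmse` and `fit_corr` (reconstruction per sample),
#'   `method = "nnls"`.
#' @export
deconvolve_nnls <- function(signature, bulk) {
  shared <- shared_genes_or_stop(signature, bulk, "deconvolve_nnls")
  s <- signature[shared, , drop = FALSE]
  b <- as.matrix(bulk)[shared, , drop = FALSE]
  ns <- ncol(b); k <- ncol(s)
  props <- matrix(0, ns, k, dimnames = list(colnames(b), colnames(s)))
  rmse <- corr <- numeric(ns)
  for (j in seq_len(ns)) {
    fit <- pracma::lsqnonneg(s, b[, j])
    w <- fit$x
    recon <- as.numeric(s %*% w)
    rmse[j] <- sqrt(mean((recon - b[, j])^2))
    corr[j] <- if (stats::sd(recon) > 0 && stats::sd(b[, j]) > 0) {
      stats::cor(recon, b[, j])
    } else NA_real_
    props[j, ] <- if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
  }
  proportion_result(props, rmse, corr, "nnls")
}

#' Deconvolve bulk samples by linear nu-support-vector regression
#'
#' The signature matrix is standardized (global mean/sd) and each bulk
#' column is z-scored over the shared genes; a linear nu-SVR is fitted for
#' each value in `nu_grid` and the nu minimizing reconstruction RMSE is
#' kept. Negative coefficients are clipped to zero and the remainder
#' renormalized to sum to 1.
#'
#' @param signature genes x clusters matrix.
#' @param bulk genes x samples matrix.
#' @param nu_grid candidate nu values for model selection.
#' @return `"proportion_matrix"` as in [deconvolve_nnls()], with
#'   `method = "svr"`. If the signature is column-rank deficient a warning
#'   is raised and the result carries attribute `rank_deficient = TRUE`.
#' @export
deconvolve_svr <- function(signature, bulk, nu_grid = c(0.25, 0.5, 0.75)) {
  shared <- shared_genes_or_stop(signature, bulk, "deconvolve_svr")
  s <- signature[shared, , drop = FALSE]
  b <- as.matrix(bulk)[shared, , drop = FALSE]
  k <- ncol(s); ns <- ncol(b)
  rank_def <- qr(s)$rank < k
  if (rank_def) {
    warning("deconvolve_svr: signature matrix is rank deficient; ",
            "proportions may be unidentifiable")
  }
  xs <- (s - mean(s)) / stats::sd(as.vector(s))
  props <- matrix(0, ns, k, dimnames = list(colnames(b), colnames(s)))
  rmse <- corr <- numeric(ns)
  for (j in seq_len(ns)) {
    y <- b[, j]
    sdy <- stats::sd(y)
    if (sdy == 0) sdy <- 1
    y <- (y - mean(y)) / sdy
    best <- NULL
    for (nu in nu_grid) {
      fit <- e1071::svm(x = xs, y = y, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE)
      r <- sqrt(mean((stats::predict(fit, xs) - y)^2))
      if (is.null(best) || r < best$rmse) {
        w <- as.numeric(t(fit$coefs) %*% fit$SV)
        best <- list(rmse = r, w = w,
                     fitted = as.numeric(stats::predict(fit, xs)))
      }
    }
    w <- pmax(best$w, 0)
    rmse[j] <- best$rmse
    corr[j] <- if (stats::sd(best$fitted) > 0) stats::cor(best$fitted, y) else
      NA_real_
    props[j, ] <- if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
  }
  out <- proportion_result(props, rmse, corr, "svr")
  attr(out, "rank_deficient") <- rank_def
  out
}
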