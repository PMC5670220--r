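## De novo signature extraction by non-negative matrix factorization
## (Frobenius objective, Lee-Seung multiplicative updates, seeded
## multi-restart). Used both for the 96-category substitution catalog and
## the 38-category rearrangement catalog.

.nmf_once <- function(V, k, maxit = 500, tol = 1e-6) {
  nr <- nrow(V); nc <- ncol(V)
  eps <- .Machine$double.eps
  scale <- sqrt(mean(V) / k)
  W <- matrix(stats::runif(nr * k), nr, k) * scale
  H <- matrix(stats::runif(k * nc), k, nc) * scale
  rss_prev <- Inf
  for (it in seq_len(maxit)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == maxit) {
      rss <- sum((V - W %*% H)^2)
      if (is.finite(rss_prev) && (rss_prev - rss) <= tol * rss_prev) break
      rss_prev <- rss
    }
  }
  list(W = W, H = H, rss = sum((V - W %*% H)^2))
}

#' De novo signature extraction by NMF
#'
#' Factorizes a non-negative catalog `M ~ W %*% H` at each rank in
#' `ranks`, keeping the best of `nstart` random restarts by Frobenius
#' residual. Signature columns of `W` are normalized to sum to 1 with the
#' exposure rows of `H` rescaled compensatorily. Rank diagnostics report
#' the residual sum of squares and explained variance per rank; the
#' selected rank is the largest one whose step from the previous rank
#' still reduces the residual by more than 5% (an elbow rule; with a
#' single candidate rank it is returned as-is).
#'
#' @param M Non-negative catalog matrix (categories x samples).
#' @param ranks Integer vector of factorization ranks to try.
#' @param nstart Random restarts per rank (default 50).
#' @param maxit,tol Multiplicative-update iteration cap and relative
#'   convergence tolerance.
#' @param seed Integer seed making the extraction reproducible; the
#'   caller's RNG state is restored afterwards.
#' @return Object of class `denovo_nmf`: list with `fits` (per rank:
#'   `signatures` 96 x k, `exposures` k x n, `rss`), `diagnostics`
#'   data.frame, and `selected_rank`.
#' @export
extract_denovo <- function(M, ranks, nstart = 50, maxit = 500, tol = 1e-6,
                           seed = NULL) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("catalog must be non-negative")
  ranks <- as.integer(ranks)
  if (any(ranks < 1) || any(ranks > min(nrow(M), ncol(M)))) {
    stop("rank must be between 1 and min(n_categories, n_samples)")
  }
  fits <- with_seed(seed, {
    lapply(ranks, function(k) {
      best <- NULL
      for (r in seq_len(nstart)) {
        fit <- .nmf_once(M, k, maxit = maxit, tol = tol)
        if (is.null(best) || fit$rss < best$rss) best <- fit
      }
      s <- pmax(colSums(best$W), .Machine$double.eps)
      W <- sweep(best$W, 2, s, "/")
      H <- best$H * s
      ids <- sprintf("denovo%d.%d", k, seq_len(k))
      dimnames(W) <- list(rownames(M), ids)
      dimnames(H) <- list(ids, colnames(M))
      list(signatures = W, exposures = H, rss = best$rss)
    })
  })
  names(fits) <- as.character(ranks)
  tot <- sum(M^2)
  diagnostics <- data.frame(rank = ranks,
                            rss = vapply(fits, `[[`, numeric(1), "rss"),
                            explained_var = 1 - vapply(fits, `[[`, numeric(1), "rss") / tot)
  selected <- ranks[1]
  if (length(ranks) > 1) {
    ord <- order(ranks)
    for (i in seq_along(ord)[-1]) {
      prev <- diagnostics$rss[ord[i - 1]]
      cur <- diagnostics$rss[ord[i]]
      if (prev > 0 && (prev - cur) / prev > 0.05) selected <- ranks[ord[i]] else break
    }
  }
  structure(list(fits = fits, diagnostics = diagnostics, selected_rank = selected),
            class = "denovo_nmf")
}

#' @export
print.denovo_nmf <- function(x, ...) {
  cat("denovo_nmf: ranks", paste(x$diagnostics$rank, collapse = ", "),
      "- selected rank", x$selected_rank, "\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}
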