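#' Upper hypergeometric tail for gene-set overlap
#'
#' Probability of observing an overlap of at least `m` genes between a
#' selection of `n` genes and a set of `M` genes, drawn from a background of
#' `N` genes:
#' `P = 1 - sum_{i=0}^{m-1} choose(M, i) * choose(N-M, n-i) / choose(N, n)`.
#' Evaluated as an explicit log-binomial sum for numerical stability; the
#' empty sum (`m = 0`) gives `P = 1`.
#'
#' @param N Background size.
#' @param M Gene-set size (`M <= N`).
#' @param n Selection size (`n <= N`).
#' @param m Observed overlap (`m <= min(n, M)`).
#' @return The tail probability, in \[0, 1\].
#' @export
hypergeom_tail <- function(N, M, n, m) {
  if (M > N) stop_validation("M > N in hypergeometric overlap test")
  if (n > N) stop_validation("n > N in hypergeometric overlap test")
  if (m > min(n, M)) stop_validation("m exceeds min(n, M)")
  if (m == 0) return(1)
  i <- 0:(m - 1)
  ok <- (n - i) <= (N - M) & i <= M
  terms <- rep(0, length(i))
  terms[ok] <- exp(lchoose(M, i[ok]) + lchoose(N - M, n - i[ok]) - lchoose(N, n))
  max(0, min(1, 1 - sum(terms)))
}

correlation_report <- function(.method, ...) {
  structure(c(list(method = .method), list(...)), class = "CorrelationReport")
}

# Pearson r of a vector against every row of a matrix, with the usual
# t-distribution two-sided p. Zero-variance rows give NA.
.cor_with_p <- function(v, mat) {
  r <- suppressWarnings(as.vector(stats::cor(v, t(mat))))
  df <- length(v) - 2
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p)
}

#' Gene-vs-set correlation via principal-component regression
#'
#' Measures how strongly a single gene tracks the expression of a gene set.
#' PCA is run on the set's samples-by-genes submatrix (genes centered); if
#' the first two PCs explain at least `variance_gate` of the variance, the
#' gene's expression is regressed on PC1 and PC2 and the fit is summarized
#' by R-squared and the overall F-test p-value. When the two PCs fail the
#' variance gate the method falls back to the hypergeometric
#' [overlap_test()].
#'
#' @param g Gene id; must not be a member of `set`.
#' @param set A `GeneSet`.
#' @param em An `ExpressionMatrix` with at least 10 samples and at least 3
#'   set members present.
#' @param variance_gate Minimum PC1+PC2 variance fraction for the regression
#'   branch (default 0.75).
#' @param alpha FDR level passed to the fallback [overlap_test()].
#' @return A `CorrelationReport` with `method = "pc_regression"` (fields
#'   `variance_explained`, `beta0`, `beta1`, `beta2`, `r_squared`,
#'   `p_value`) or the fallback's report.
#' @export
gene_vs_set_correlation <- function(g, set, em, variance_gate = 0.75, alpha = 0.01) {
  if (g %in% set$members)
    stop_validation("gene is a member of the set; self-correlation undefined")
  if (!g %in% em$gene_ids) stop_validation(sprintf("gene %s absent from matrix", g))
  sub <- gene_submatrix(em, set$members)
  if (nrow(sub) < 3) stop_validation("need at least 3 set members present")
  if (ncol(sub) < 10) stop_validation("need at least 10 samples")
  X <- t(sub)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot < .Machine$double.eps)
    return(overlap_test(g, set, em, alpha = alpha))
  ve <- sum(pc$sdev[seq_len(min(2, length(pc$sdev)))]^2) / tot
  if (ve < variance_gate)
    return(overlap_test(g, set, em, alpha = alpha))
  eg <- em$values[g, ]
  pc1 <- pc$x[, 1]
  use2 <- length(pc$sdev) >= 2 && pc$sdev[2] > 1e-12
  fit <- if (use2) stats::lm(eg ~ pc1 + pc2, data = data.frame(eg = eg, pc1 = pc1, pc2 = pc$x[, 2]))
         else stats::lm(eg ~ pc1, data = data.frame(eg = eg, pc1 = pc1))
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) NA_real_
          else stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  cf <- stats::coef(fit)
  correlation_report("pc_regression",
    variance_explained = ve,
    beta0 = unname(cf["(Intercept)"]),
    beta1 = unname(cf["pc1"]),
    beta2 = if (use2) unname(cf["pc2"]) else 0,
    r_squared = sm$r.squared,
    p_value = unname(pval))
}

#' Gene-vs-set correlation via hypergeometric overlap
#'
#' The fallback significance procedure when PC regression is not justified:
#' Pearson-correlate the gene against every other gene of the matrix
#' (the background of `N` genes), select the `n` genes whose correlation is
#' significant under Benjamini-Hochberg control at `alpha`, count the
#' overlap `m` of the selection with the set, and report the upper
#' hypergeometric tail [hypergeom_tail()] as the correlation P-value.
#'
#' @inheritParams gene_vs_set_correlation
#' @param alpha FDR level of the correlation screen (default 0.01).
#' @return A `CorrelationReport` with `method = "overlap_test"` and fields
#'   `N`, `M`, `n`, `m`, `P`, `degenerate` (`TRUE` when no gene passed the
#'   screen, in which case `P = 1`).
#' @export
overlap_test <- function(g, set, em, alpha = 0.01) {
  if (!g %in% em$gene_ids) stop_validation(sprintf("gene %s absent from matrix", g))
  bg <- setdiff(em$gene_ids, g)
  cw <- .cor_with_p(em$values[g, ], em$values[bg, , drop = FALSE])
  tested <- !is.na(cw$p)
  bg <- bg[tested]
  q <- stats::p.adjust(cw$p[tested], method = "BH")
  selected <- bg[q < alpha]
  members <- intersect(setdiff(set$members, g), bg)
  N <- length(bg); M <- length(members)
  n <- length(selected); m <- length(intersect(selected, members))
  if (n == 0)
    return(correlation_report("overlap_test", N = N, M = M, n = 0L, m = 0L,
                              P = 1, degenerate = TRUE))
  correlation_report("overlap_test", N = N, M = M, n = n, m = m,
                     P = hypergeom_tail(N, M, n, m), degenerate = FALSE)
}

#' Fit a one-dimensional principal curve
#'
#' Hastie-Stuetzle projection-smoothing: arc-length positions are
#' initialized from PC1 scores, each coordinate is smoothed against the
#' current positions with a smoothing spline evaluated on a grid of up to
#' `n_vertices` positions, samples are re-projected onto the polyline
#' through the smoothed points, and the loop repeats until the relative
#' change in the total squared projection distance falls below `thresh`
#' (default 1e-4), the mean displacement of the projected points falls
#' below `tol` (default 1e-6), or `max_iter` iterations (default 30) are
#' reached. On diffuse point clouds the iteration keeps making slow,
#' oscillating progress indefinitely, so the distance-based criterion — the
#' standard stopping rule for this algorithm — is what terminates in
#' practice; the displacement rule fires on exactly-curved data.
#'
#' @param X Numeric matrix, samples in rows, variables (genes) in columns.
#' @param df Effective degrees of freedom of the coordinate smoother.
#' @param n_vertices Maximum number of polyline vertices.
#' @param max_iter,tol,thresh Convergence controls.
#' @return List with `lambda` (arc-length position of each sample along the
#'   curve), `points` (projection of each sample onto the curve),
#'   `converged`, `n_iter`.
#' @export
fit_principal_curve <- function(X, df = 5, n_vertices = 50, max_iter = 30,
                                tol = 1e-6, thresh = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 5) stop_validation("need at least 5 samples for a principal curve")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (sum(Xc^2) < .Machine$double.eps)
    stop_validation("degenerate point cloud: zero variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  lambda <- pc$x[, 1]
  proj <- outer(lambda, pc$rotation[, 1]) + rep(colMeans(X), each = n)
  if (p == 1 || length(unique(lambda)) < 4)
    return(list(lambda = lambda, points = proj, converged = TRUE, n_iter = 0L))
  d2 <- sum((X - proj)^2)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    grid <- if (length(unique(lambda)) > n_vertices)
      stats::quantile(lambda, probs = seq(0, 1, length.out = n_vertices),
                      names = FALSE)
    else sort(unique(lambda))
    # positions can collapse onto polyline endpoints; the smoother needs
    # at least 4 unique positions, so stop with the current projection
    if (length(unique(lambda)) < 4) break
    dfr <- min(df, length(unique(lambda)) - 1)
    if (dfr < 2) break
    S <- vapply(seq_len(p), function(j) {
      # smooth.spline may internally fall back to a straight-line fit on
      # near-degenerate position vectors; that is acceptable behaviour here
      fit <- suppressWarnings(stats::smooth.spline(lambda, X[, j], df = dfr))
      stats::predict(fit, grid)$y
    }, numeric(length(grid)))
    pr <- .project_polyline(X, S)
    disp <- mean(sqrt(rowSums((pr$points - proj)^2)))
    d2_new <- sum((X - pr$points)^2)
    lambda <- pr$lambda
    proj <- pr$points
    if (disp < tol || abs(d2 - d2_new) < thresh * max(d2, .Machine$double.eps)) {
      converged <- TRUE
      d2 <- d2_new
      break
    }
    d2 <- d2_new
  }
  list(lambda = lambda, points = proj, converged = converged, n_iter = iter)
}

# project rows of X onto the polyline through vertex matrix V (ordered);
# returns arc-length position and the foot of the projection for each row
.project_polyline <- function(X, V) {
  n <- nrow(X); p <- ncol(X); m <- nrow(V)
  seg_len <- sqrt(rowSums((V[-1, , drop = FALSE] - V[-m, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, n)
  best_lambda <- numeric(n)
  best_pt <- matrix(0, n, p)
  for (k in seq_len(m - 1)) {
    d <- V[k + 1, ] - V[k, ]
    len2 <- sum(d^2)
    if (len2 < .Machine$double.eps) next
    t <- pmin(1, pmax(0, (sweep(X, 2, V[k, ]) %*% d) / len2))
    pt <- rep(V[k, ], each = n) + outer(as.vector(t), d)
    d2 <- rowSums((X - pt)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lambda[upd] <- cum[k] + as.vector(t)[upd] * sqrt(len2)
    best_pt[upd, ] <- pt[upd, , drop = FALSE]
  }
  list(lambda = best_lambda, points = best_pt)
}

# arc-length score of a gene set's sample cloud, oriented so that the score
# correlates positively with the set's mean expression per sample
.oriented_curve_score <- function(sub) {
  fitc <- fit_principal_curve(t(sub))
  lam <- fitc$lambda
  ms <- colMeans(sub)
  if (stats::sd(lam) > 0 && stats::sd(ms) > 0 &&
      stats::cor(lam, ms) < 0) lam <- -lam
  lam
}

#' Set-vs-set correlation via principal-curve projections
#'
#' Each gene set's samples-by-genes cloud is summarized by a principal curve
#' ([fit_principal_curve()]); every sample is projected to its arc-length
#' position, the curve is oriented so that positions correlate positively
#' with the set's mean expression, and the Pearson correlation between the
#' two sets' position vectors (with its two-sided p-value) measures
#' set-to-set co-expression, capturing nonlinear within-set variation that a
#' straight PC1 would miss.
#'
#' @param A,B `GeneSet`s; shared genes are removed from both before fitting
#'   (the sets must be disjoint after this removal leaves each with members).
#' @param em An `ExpressionMatrix` with at least 10 samples.
#' @return A `CorrelationReport` with `method = "principal_curve"` and
#'   fields `DP1`, `DP2` (projection vectors), `pcc`, `p_value`.
#' @export
set_vs_set_correlation <- function(A, B, em) {
  shared <- intersect(A$members, B$members)
  a <- setdiff(A$members, shared); b <- setdiff(B$members, shared)
  if (!length(a) || !length(b))
    stop_validation("gene sets empty after removing their intersection")
  if (ncol(em$values) < 10) stop_validation("need at least 10 samples")
  subA <- gene_submatrix(em, a); subB <- gene_submatrix(em, b)
  if (!nrow(subA) || !nrow(subB))
    stop_validation("gene-set members absent from the matrix")
  dp1 <- .oriented_curve_score(subA)
  dp2 <- .oriented_curve_score(subB)
  ct <- suppressWarnings(stats::cor.test(dp1, dp2, method = "pearson"))
  correlation_report("principal_curve", DP1 = dp1, DP2 = dp2,
                     pcc = unname(ct$estimate), p_value = ct$p.value)
}

#' Gene-set enrichment by hypergeometric overlap
#'
#' Ranks a library of gene sets by the upper hypergeometric tail of their
#' overlap with a query set, with Benjamini-Hochberg q-values across the
#' library.
#'
#' @param query A `GeneSet` (e.g. genes correlated with a transporter).
#' @param library A non-empty list of `GeneSet`s.
#' @param N Background (genome) size; default 20000.
#' @param top_k Keep the `top_k` most enriched sets (default 100).
#' @return Data frame ranked by ascending `P`: `set`, `M`, `n`, `m`, `P`,
#'   `q`.
#' @export
enrich_genesets <- function(query, library, N = 20000, top_k = 100) {
  if (!length(library)) stop_validation("gene-set library is empty")
  n <- length(query$members)
  rows <- lapply(library, function(s) {
    M <- length(s$members)
    m <- length(intersect(query$members, s$members))
    data.frame(set = s$name, M = M, n = n, m = m,
               P = hypergeom_tail(N, M, n, m), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$P, method = "BH")
  tab <- tab[order(tab$P, tab$set), , drop = FALSE]
  utils::head(tab, top_k)
}
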