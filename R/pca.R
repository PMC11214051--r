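#' Principal component analysis with direct-oblimin rotation
#'
#' Standardizes the columns, eigendecomposes the correlation matrix,
#' retains components with eigenvalue > 1, and obliquely rotates the
#' retained loadings by direct oblimin with gamma = 0 (direct
#' quartimin) using the gradient-projection algorithm.  Component
#' scores are regression (Thurstone) scores of the rotated solution.
#' The same routine serves the behavioral "trait space" PCA and the
#' acoustic-measure PCA.
#'
#' @param data numeric items x variables matrix (or data.frame)
#' @param retain_rule only `"eigenvalue_gt_1"` is implemented
#' @param max_iter,tol rotation iteration cap and convergence tolerance
#' @return object of class `pca_solution`: `n_components`,
#'   `pattern_loadings` (variables x components), `factor_correlations`,
#'   `variance_explained_pct` (cumulative, retained components, from the
#'   unrotated eigenvalues), `component_scores` (items x components),
#'   `eigenvalues`, `unrotated_loadings`
#' @export
pca_oblimin <- function(data, retain_rule = "eigenvalue_gt_1",
                        max_iter = 1000, tol = 1e-6) {
  retain_rule <- match.arg(retain_rule)
  X <- as.matrix(data)
  if (ncol(X) < 2) stop("need >= 2 variables")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X)
  R <- cor(X)
  e <- eigen(R, symmetric = TRUE)
  k <- sum(e$values > 1)
  if (k < 1) stop("no component with eigenvalue > 1")
  A <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  rownames(A) <- colnames(X)
  if (k == 1) {
    L <- A; Phi <- matrix(1, 1, 1)
  } else {
    rot <- gpa_oblimin(A, max_iter = max_iter, tol = tol)
    if (!rot$converged)
      stop("oblimin rotation did not converge after ", rot$iterations,
           " iterations (criterion change ", format(rot$criterion), ")")
    L <- rot$loadings; Phi <- rot$phi
  }
  # deterministic orientation/order: flip columns so the loading with
  # the largest magnitude is positive; order by explained sum of squares
  flip <- vapply(seq_len(ncol(L)), function(j)
    sign(L[which.max(abs(L[, j])), j]), numeric(1))
  flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, "*")
  Phi <- diag(flip, ncol(L)) %*% Phi %*% diag(flip, ncol(L))
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  colnames(L) <- paste0("PC", seq_len(k))
  dimnames(Phi) <- list(colnames(L), colnames(L))
  # regression scores of the rotated solution; pseudo-inverse tolerates
  # exactly collinear variables (e.g. a dispersion measure that is a
  # linear function of the formants)
  structure_mat <- L %*% Phi
  pos <- e$values > 1e-10 * e$values[1]
  Rinv <- e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  scores <- Z %*% (Rinv %*% structure_mat)
  scores <- scale(scores)
  attr(scores, "scaled:center") <- attr(scores, "scaled:scale") <- NULL
  colnames(scores) <- colnames(L)
  structure(list(n_components = k, pattern_loadings = L,
                 factor_correlations = Phi,
                 variance_explained_pct =
                   100 * sum(e$values[seq_len(k)]) / ncol(X),
                 component_scores = scores,
                 eigenvalues = e$values, unrotated_loadings = A),
            class = "pca_solution")
}

#' @export
print.pca_solution <- function(x, ...) {
  cat("<pca_solution> ", x$n_components, " component(s), ",
      sprintf("%.1f", x$variance_explained_pct),
      "% of variance explained\n", sep = "")
  print(round(x$pattern_loadings, 2))
  invisible(x)
}

# Direct quartimin criterion and gradient for oblique rotation:
# f(L) = sum_{j != l} sum_i L_ij^2 L_il^2 / 4
quartimin_vgQ <- function(L) {
  L2 <- L^2
  N <- matrix(1, ncol(L), ncol(L)) - diag(ncol(L))
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# Gradient-projection algorithm for oblique rotation (direct quartimin),
# after Jennrich's GPA formulation.
gpa_oblimin <- function(A, max_iter = 1000, tol = 1e-6) {
  k <- ncol(A)
  Tm <- diag(k)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- quartimin_vgQ(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  iter <- 0
  s <- Inf
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in 1:20) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti_t <- solve(Tt)
      Lt <- A %*% t(Ti_t)
      vg_t <- quartimin_vgQ(Lt)
      if (vg_t$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt; Ti <- Ti_t; L <- Lt; f <- vg_t$f
    G <- -t(t(L) %*% vg_t$Gq %*% Ti)
  }
  list(loadings = L, phi = crossprod(Tm), Th = Tm,
       converged = s < tol, iterations = iter, criterion = s)
}
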