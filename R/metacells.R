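#' Adaptive Gaussian kernel over cells
#'
#' k-nearest-neighbor affinities in the embedding with per-cell adaptive
#' bandwidths: `sigma_i` is the distance to the `ceiling(k/3)`-th neighbor
#' and `m_ij = exp(-d_ij^2 / (sigma_i * sigma_j))` on the union of kNN
#' edges, symmetrized by the elementwise maximum; zeros elsewhere and 1 on
#' the diagonal.
#'
#' @param embedding cells x dims matrix with rownames.
#' @param k neighbors (default 15).
#' @return sparse symmetric `KernelMatrix` (dgCMatrix with dimnames), with
#'   the bandwidths attached as attribute `sigma`.
#' @export
build_kernel <- function(embedding, k = 15L) {
  n <- nrow(embedding)
  if (k >= n) stopf("k (%d) must be < number of cells (%d)", k, n)
  nn <- FNN::get.knn(embedding, k = k)
  sigma <- nn$nn.dist[, ceiling(k / 3)]
  sigma <- pmax(sigma, 1e-12)
  i <- rep(seq_len(n), k)
  j <- as.vector(nn$nn.index)
  d2 <- as.vector(nn$nn.dist)^2
  a <- exp(-d2 / (sigma[i] * sigma[j]))
  up <- Matrix::sparseMatrix(i = i, j = j, x = a, dims = c(n, n))
  M <- pmax_sparse(up, Matrix::t(up))
  Matrix::diag(M) <- 1
  dimnames(M) <- list(rownames(embedding), rownames(embedding))
  attr(M, "sigma") <- sigma
  attr(M, "k") <- k
  M
}

# elementwise max of two sparse matrices with identical dims
pmax_sparse <- function(a, b) {
  d <- a - b
  d@x <- pmax(d@x, 0)
  methods::as(Matrix::drop0(b + d), "CsparseMatrix")
}

#' Waypoint initialization of archetypes
#'
#' Takes the top `n_waypoint_eigs` eigenvectors of the degree-normalized
#' kernel and seeds one archetype at the argmax and argmin cell of each
#' eigenvector (deduplicated, in eigenvalue order); remaining slots are
#' filled by greedy max-min (farthest point) selection in the embedding.
#' Deterministic given the inputs; ties break by cell order.
#'
#' @param kernel from [build_kernel()].
#' @param embedding the embedding the kernel was built on.
#' @param n_archetypes number of metacells (default 90).
#' @param n_waypoint_eigs eigenvectors used for waypoint seeding (default 10).
#' @return integer vector of `n_archetypes` distinct cell indices.
#' @export
init_waypoints <- function(kernel, embedding, n_archetypes = 90L,
                           n_waypoint_eigs = 10L) {
  n <- nrow(kernel)
  if (n_archetypes > n) stopf("n_archetypes (%d) exceeds cell count (%d)",
                              n_archetypes, n)
  if (n_archetypes == n) return(seq_len(n))
  deg <- Matrix::rowSums(kernel)
  Dm <- Matrix::Diagonal(x = 1 / sqrt(pmax(deg, 1e-12)))
  S <- Dm %*% kernel %*% Dm
  ne <- min(n_waypoint_eigs, n - 1L)
  eig <- RSpectra::eigs_sym(methods::as(S, "dgCMatrix"), k = ne, which = "LA")
  sel <- integer(0)
  for (j in seq_len(ncol(eig$vectors))) {
    v <- eig$vectors[, j]
    sel <- c(sel, which.max(v), which.min(v))
  }
  sel <- unique(sel)
  if (length(sel) > n_archetypes) {
    # more waypoint candidates than slots: keep the leading candidate and
    # spread the rest by farthest-point sampling over all cells, so every
    # well-separated population still receives an archetype
    sel <- sel[1]
  }
  # fill remaining slots by farthest-point sampling in the embedding
  while (length(sel) < n_archetypes) {
    d <- FNN::knnx.dist(embedding[sel, , drop = FALSE], embedding, k = 1L)[, 1]
    d[sel] <- -Inf
    sel <- c(sel, which.max(d))
  }
  sel
}

#' Fit kernel archetypal analysis
#'
#' Minimizes `|| M - M B A ||_F^2` over column-stochastic `A`
#' (n_archetypes x n_cells) and `B` (n_cells x n_archetypes) by alternating
#' Frank-Wolfe updates with exact line search (each inner step solves the
#' linear minimization over the simplex and takes the optimal step length,
#' so the objective never increases). Iterates until the relative objective
#' change drops below `epsilon` after at least `min_iter` outer iterations,
#' or `max_iter` is reached; then runs `refine_iter` further iterations.
#'
#' @param kernel the cell-cell kernel `M` from [build_kernel()].
#' @param init initial archetype cell indices from [init_waypoints()].
#' @param epsilon relative-change convergence tolerance (default 1e-5).
#' @param min_iter,max_iter iteration bounds (defaults 10 and 50).
#' @param refine_iter post-convergence refinement iterations (default 5).
#' @param inner_steps Frank-Wolfe steps per A/B update (default 8).
#' @return an `archetype_model`: list with `A`, `B`, `objective` (per-
#'   iteration RSS trace including refinement), `converged`, `iterations`,
#'   `init`.
#' @export
fit_archetypes <- function(kernel, init, epsilon = 1e-5, min_iter = 10L,
                           max_iter = 50L, refine_iter = 5L,
                           inner_steps = 8L) {
  n <- nrow(kernel)
  k <- length(init)
  M <- methods::as(kernel, "CsparseMatrix")
  G <- as.matrix(Matrix::crossprod(M))       # G = M'M, n x n
  trG <- sum(diag(G))

  # B: n x k column-stochastic, start at indicator of init cells
  B <- matrix(0, n, k)
  B[cbind(init, seq_len(k))] <- 1
  GB <- G[, init, drop = FALSE]              # cache G %*% B
  # A: k x n column-stochastic, start uniform
  A <- matrix(1 / k, k, n)

  objective <- function() {
    H <- crossprod(B, GB)                    # B'GB, k x k
    trG - 2 * sum(t(GB) * A) + sum(H * tcrossprod(A))
  }

  update_A <- function() {
    W <- t(GB)                               # B'G, k x n
    H <- crossprod(B, GB)
    cols <- seq_len(n)
    for (s in seq_len(inner_steps)) {
      Gr <- H %*% A - W                      # gradient / 2
      if (s %% 2L == 1L) {
        # classic Frank-Wolfe step towards the best vertex, per column
        istar <- max.col(-t(Gr), ties.method = "first")
        S <- matrix(0, k, n); S[cbind(istar, cols)] <- 1
        D <- S - A
        HD <- H[, istar, drop = FALSE] - H %*% A
        dHd <- colSums(D * HD)
        gd <- 2 * colSums(Gr * D)
        gam <- ifelse(dHd > 1e-15, pmin(1, pmax(0, -gd / (2 * dHd))), 0)
        A <<- A + sweep(D, 2L, gam, "*")
      } else {
        # pairwise step: shift mass from the worst active coordinate to the
        # best one (linearly convergent near simplex faces)
        istar <- max.col(-t(Gr), ties.method = "first")
        GrMask <- Gr - 1e9 * (A <= 1e-12)    # only active coords eligible
        vstar <- max.col(t(GrMask), ties.method = "first")
        cap <- A[cbind(vstar, cols)]
        gd <- 2 * (Gr[cbind(istar, cols)] - Gr[cbind(vstar, cols)])
        dHd <- H[cbind(istar, istar)] - 2 * H[cbind(istar, vstar)] +
          H[cbind(vstar, vstar)]
        gam <- ifelse(dHd > 1e-15 & gd < 0,
                      pmin(cap, -gd / (2 * dHd)), 0)
        A[cbind(istar, cols)] <<- A[cbind(istar, cols)] + gam
        A[cbind(vstar, cols)] <<- A[cbind(vstar, cols)] - gam
      }
    }
  }

  update_B <- function() {
    AAt <- tcrossprod(A)                     # k x k
    GAt <- G %*% t(A)                        # n x k
    ks <- seq_len(k)
    for (s in seq_len(inner_steps)) {
      Gr <- GB %*% AAt - GAt                 # gradient / 2, n x k
      if (s %% 2L == 1L) {
        istar <- max.col(-t(Gr), ties.method = "first")
        S <- matrix(0, n, k); S[cbind(istar, ks)] <- 1
        GS <- G[, istar, drop = FALSE]
        # line search: f(B + g D) quadratic; D = S - B
        SGS <- G[cbind(rep(istar, k), rep(istar, each = k))]
        dim(SGS) <- c(k, k)
        SGB <- GB[istar, , drop = FALSE]     # S'GB, k x k
        BGB <- crossprod(B, GB)
        DGD <- SGS - SGB - t(SGB) + BGB
        quad <- sum(DGD * AAt)
        lin <- 2 * (sum(Gr * S) - sum(Gr * B))
        gam <- if (quad > 1e-15) min(1, max(0, -lin / (2 * quad))) else 0
        if (gam > 0) {
          B <<- B + gam * (S - B)
          GB <<- (1 - gam) * GB + gam * GS
        }
      } else {
        # pairwise step with one exact line search over the joint direction
        istar <- max.col(-t(Gr), ties.method = "first")
        GrMask <- Gr - 1e9 * (B <= 1e-12)
        vstar <- max.col(t(GrMask), ties.method = "first")
        cap <- B[cbind(vstar, ks)]
        live <- cap > 0 & istar != vstar
        if (!any(live)) next
        cap[!live] <- 0
        co <- tcrossprod(cap)
        DGD <- co * (G[istar, istar] - G[istar, vstar] -
                       G[vstar, istar] + G[vstar, vstar])
        quad <- sum(DGD * AAt)
        lin <- 2 * sum(cap * (Gr[cbind(istar, ks)] - Gr[cbind(vstar, ks)]))
        gam <- if (quad > 1e-15 && lin < 0) min(1, -lin / (2 * quad)) else 0
        if (gam > 0) {
          step <- gam * cap
          B[cbind(istar, ks)] <<- B[cbind(istar, ks)] + step
          B[cbind(vstar, ks)] <<- B[cbind(vstar, ks)] - step
          GB <<- GB + sweep(G[, istar, drop = FALSE] -
                              G[, vstar, drop = FALSE], 2L, step, "*")
        }
      }
    }
  }

  trace <- objective()
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    update_A()
    update_B()
    obj <- objective()
    if (!is.finite(obj)) stopf("non-finite objective at iteration %d", it)
    prev <- trace[length(trace)]
    trace <- c(trace, obj)
    rel <- abs(prev - obj) / max(abs(prev), 1e-12)
    if (it >= min_iter && rel < epsilon) { converged <- TRUE; break }
  }
  for (r in seq_len(refine_iter)) {
    update_A(); update_B()
    trace <- c(trace, objective())
  }
  check_stochastic(A, "A"); check_stochastic(B, "B")
  structure(list(A = A, B = B, objective = trace, converged = converged,
                 iterations = it, init = init,
                 barcodes = rownames(kernel)),
            class = "archetype_model")
}

check_stochastic <- function(X, name) {
  if (any(X < -1e-8) || any(abs(colSums(X) - 1) > 1e-8)) {
    stopf("matrix %s violates simplex constraints", name)
  }
  invisible(TRUE)
}

#' Assign cells to metacells and aggregate profiles
#'
#' Each cell goes to the archetype with the largest weight in its column of
#' `A` (ties to the lowest archetype id). The aggregated profile of a
#' metacell is the column sum of its member cells' peak counts. All
#' `n_archetypes` metacell ids appear in the output; empty ones are flagged.
#'
#' @param model an `archetype_model`.
#' @param peak_matrix a [feature_matrix()] whose rows cover the model's
#'   cells.
#' @return list with `assignment` (data.table: barcode, metacell),
#'   `profiles` (metacells x features dense matrix of summed counts),
#'   `sizes` (named integer), `empty` (integer ids with no cells).
#' @export
assign_metacells <- function(model, peak_matrix) {
  k <- nrow(model$A)
  mc <- apply(model$A, 2L, which.max)  # ties: which.max takes the first
  barcodes <- model$barcodes %||% rownames(peak_matrix$counts)
  assignment <- data.table::data.table(barcode = barcodes, metacell = mc)
  counts <- peak_matrix$counts[barcodes, , drop = FALSE]
  prof <- rowsum_sparse(counts, factor(mc, levels = seq_len(k)))
  rownames(prof) <- as.character(seq_len(k))
  sizes <- table(factor(mc, levels = seq_len(k)))
  empty <- as.integer(names(sizes))[sizes == 0]
  if (length(empty)) {
    warnf("%d empty metacell id(s): %s", length(empty),
          paste(empty, collapse = ", "))
  }
  list(assignment = assignment, profiles = prof,
       sizes = stats::setNames(as.integer(sizes), names(sizes)),
       empty = empty)
}
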