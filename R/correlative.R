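# Landmark-based registration between two modality frames and one-to-one
# matching of segmented pores, replacing manual rotate/perspective
# alignment with a least-squares planar transform plus an optimal gated
# assignment.

#' Fit a planar transform from landmark pairs
#'
#' Least-squares estimate of the transform T minimizing
#' `sum ||T(a_i) - b_i||^2` over landmark pairs.  Kinds: "similarity"
#' (rotation + isotropic scale + translation; closed-form Procrustes
#' solution), "affine" (linear least squares), "projective" (normalized
#' direct linear transform).
#'
#' @param landmarks data frame or matrix with columns x_a, y_a, x_b, y_b
#'   (nm).
#' @param kind transform family.
#' @param allow_reflection permit a reflection in the similarity fit.
#' @return an object of class `planar_transform`: 3x3 homogeneous `matrix`,
#'   `kind`, `rms_residual` (nm) and `n_landmarks`.
#' @export
fit_transform <- function(landmarks,
                          kind = c("similarity", "affine", "projective"),
                          allow_reflection = FALSE) {
  kind <- match.arg(kind)
  lm <- as.matrix(as.data.frame(landmarks)[, 1:4])
  if (!all(is.finite(lm))) stop("landmark coordinates must be finite")
  a <- lm[, 1:2, drop = FALSE]; b <- lm[, 3:4, drop = FALSE]
  n <- nrow(a)
  need <- c(similarity = 2, affine = 3, projective = 4)[[kind]]
  if (n < need) stop(sprintf("%s transform needs at least %d landmark pairs",
                             kind, need))

  M <- switch(kind,
    similarity = {
      ca <- colMeans(a); cb <- colMeans(b)
      A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
      S <- crossprod(B, A)                      # 2x2 covariance
      sv <- svd(S)
      d <- diag(2)
      if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) d[2, 2] <- -1
      R <- sv$u %*% d %*% t(sv$v)
      va <- sum(A^2)
      if (va < 1e-12) stop("degenerate landmark configuration (coincident points)")
      s <- sum(diag(d) * sv$d) / va
      t <- cb - s * as.vector(R %*% ca)
      rbind(cbind(s * R, t), c(0, 0, 1))
    },
    affine = {
      if (qr(cbind(a, 1))$rank < 3) {
        stop("degenerate (collinear) landmark configuration for an affine fit")
      }
      fx <- lm.fit(cbind(a, 1), b[, 1])$coefficients
      fy <- lm.fit(cbind(a, 1), b[, 2])$coefficients
      rbind(fx, fy, c(0, 0, 1))
    },
    projective = {
      if (qr(cbind(a, 1))$rank < 3) {
        stop("degenerate (collinear) landmark configuration for a projective fit")
      }
      # Hartley-normalized DLT
      norm_t <- function(p) {
        c0 <- colMeans(p)
        sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, c0)^2)))
        rbind(c(sc, 0, -sc * c0[1]), c(0, sc, -sc * c0[2]), c(0, 0, 1))
      }
      Ta <- norm_t(a); Tb <- norm_t(b)
      an <- t(Ta %*% rbind(t(a), 1)); bn <- t(Tb %*% rbind(t(b), 1))
      rows <- lapply(seq_len(n), function(i) {
        x <- an[i, 1]; y <- an[i, 2]; u <- bn[i, 1]; v <- bn[i, 2]
        rbind(c(-x, -y, -1, 0, 0, 0, u * x, u * y, u),
              c(0, 0, 0, -x, -y, -1, v * x, v * y, v))
      })
      Amat <- do.call(rbind, rows)
      h <- svd(Amat, nu = 0)$v[, 9]
      H <- solve(Tb) %*% matrix(h, 3, 3, byrow = TRUE) %*% Ta
      H / H[3, 3]
    })

  dimnames(M) <- NULL
  tr <- structure(list(matrix = M, kind = kind, rms_residual = NA_real_,
                       n_landmarks = n),
                  class = "planar_transform")
  pred <- map_points(tr, a)
  tr$rms_residual <- sqrt(mean(rowSums((pred - b)^2)))
  tr
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("<planar_transform> %s, rms residual %.3g nm (%d landmarks)\n",
              x$kind, x$rms_residual, x$n_landmarks))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Identity transform
#' @export
identity_transform <- function() {
  structure(list(matrix = diag(3), kind = "similarity", rms_residual = 0,
                 n_landmarks = 0L), class = "planar_transform")
}

#' Invert a planar transform
#' @param t a `planar_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "planar_transform"))
  M <- solve(t$matrix)
  M <- M / M[3, 3]
  structure(list(matrix = M, kind = t$kind, rms_residual = t$rms_residual,
                 n_landmarks = t$n_landmarks), class = "planar_transform")
}

#' Apply a planar transform to points
#'
#' Homogeneous application with perspective division for projective
#' transforms; points mapped (numerically) to infinity get NaN coordinates
#' and a warning.
#'
#' @param t a `planar_transform`.
#' @param points n x 2 matrix or data frame of (x, y) nm.
#' @return n x 2 matrix of mapped points.
#' @export
map_points <- function(t, points) {
  stopifnot(inherits(t, "planar_transform"))
  p <- as.matrix(as.data.frame(points))
  if (ncol(p) < 2) stop("points must have two columns")
  ph <- t$matrix %*% rbind(t(p[, 1:2, drop = FALSE]), 1)
  w <- ph[3, ]
  bad <- abs(w) < 1e-12
  if (any(bad)) {
    warning(sprintf("%d point(s) mapped to infinity", sum(bad)))
    w[bad] <- NaN
  }
  cbind(ph[1, ] / w, ph[2, ] / w)
}

# Solve one dense assignment subproblem: square-pad the gated cost matrix
# so max-cardinality matching is enforced first, minimal total distance
# second.
solve_assignment <- function(cost, big) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  padded <- matrix(big, n, n)
  padded[seq_len(nr), seq_len(nc)] <- cost
  sol <- as.integer(clue::solve_LSAP(padded))
  pairs <- cbind(seq_len(nr), sol[seq_len(nr)])
  pairs <- pairs[pairs[, 2] <= nc, , drop = FALSE]
  pairs[cost[pairs] < big, , drop = FALSE]
}

#' Match pores one-to-one between two modalities
#'
#' Maps the centroids of table A into B's frame via the planar transform,
#' builds the gated candidate graph (pairs closer than `gate`), and finds
#' the one-to-one assignment that maximizes the number of matches and,
#' among those, minimizes the total distance (Hungarian-type optimal
#' assignment on each connected component of the gated graph; the
#' assignment problem separates exactly over components).  Pores without a
#' partner are listed unmatched on both sides — e.g. closed pores that
#' opened on drying exist only in the dried table.
#'
#' @param table_a,table_b `pore_table`s in physical nm coordinates.
#' @param transform a `planar_transform` from A's frame to B's frame.
#' @param gate maximal matching distance, nm (default 150: about a mean
#'   pore radius plus registration slack).
#' @return an object of class `match_table`: data frame `pairs`
#'   (pore_id_a, pore_id_b, distance_nm, merged_candidate), id vectors
#'   `unmatched_a`, `unmatched_b`, the `transform` and the `gate`.
#' @export
match_pores <- function(table_a, table_b, transform = identity_transform(),
                        gate = 150) {
  stopifnot(is.data.frame(table_a), is.data.frame(table_b), gate > 0)
  na <- nrow(table_a); nb <- nrow(table_b)
  empty <- data.frame(pore_id_a = integer(0), pore_id_b = integer(0),
                      distance_nm = numeric(0), merged_candidate = logical(0))
  if (na == 0 || nb == 0) {
    return(structure(list(pairs = empty,
                          unmatched_a = table_a$pore_id,
                          unmatched_b = table_b$pore_id,
                          transform = transform, gate = gate),
                     class = "match_table"))
  }
  pa <- map_points(transform, cbind(table_a$x_nm, table_a$y_nm))
  pb <- cbind(table_b$x_nm, table_b$y_nm)

  # gated candidate pairs via light spatial binning (cells of size `gate`)
  binb <- floor(pb / gate)
  keyb <- paste(binb[, 1], binb[, 2])
  bmap <- split(seq_len(nb), keyb)
  cand_a <- integer(0); cand_b <- integer(0); cand_d <- numeric(0)
  bina <- floor(pa / gate)
  for (i in seq_len(na)) {
    neigh <- as.vector(outer(bina[i, 1] + (-1:1), bina[i, 2] + (-1:1), paste))
    js <- unlist(bmap[neigh], use.names = FALSE)
    if (length(js) == 0) next
    d <- sqrt((pb[js, 1] - pa[i, 1])^2 + (pb[js, 2] - pa[i, 2])^2)
    keep <- d <= gate
    if (any(keep)) {
      cand_a <- c(cand_a, rep.int(i, sum(keep)))
      cand_b <- c(cand_b, js[keep])
      cand_d <- c(cand_d, d[keep])
    }
  }

  if (length(cand_a) == 0) {
    return(structure(list(pairs = empty,
                          unmatched_a = table_a$pore_id,
                          unmatched_b = table_b$pore_id,
                          transform = transform, gate = gate),
                     class = "match_table"))
  }

  # connected components of the bipartite candidate graph
  root <- uf_union_pairs(na + nb, cand_a, na + cand_b)
  comp_of_pair <- root[cand_a]
  big <- 1e9
  pa_deg <- tabulate(cand_a, na)   # >= 2 gated candidates -> merged flag

  out_a <- integer(0); out_b <- integer(0); out_d <- numeric(0)
  for (cp in unique(comp_of_pair)) {
    sel <- comp_of_pair == cp
    ia <- sort(unique(cand_a[sel])); ib <- sort(unique(cand_b[sel]))
    cost <- matrix(big, length(ia), length(ib))
    cost[cbind(match(cand_a[sel], ia), match(cand_b[sel], ib))] <- cand_d[sel]
    prs <- solve_assignment(cost, big)
    out_a <- c(out_a, ia[prs[, 1]])
    out_b <- c(out_b, ib[prs[, 2]])
    out_d <- c(out_d, cost[prs])
  }

  ord <- order(out_a)
  pairs <- data.frame(pore_id_a = table_a$pore_id[out_a][ord],
                      pore_id_b = table_b$pore_id[out_b][ord],
                      distance_nm = out_d[ord],
                      merged_candidate = (pa_deg[out_a] >= 2)[ord])
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(table_a$pore_id, pairs$pore_id_a),
                 unmatched_b = setdiff(table_b$pore_id, pairs$pore_id_b),
                 transform = transform, gate = gate),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("<match_table> %d pairs (gate %g nm), %d unmatched in A, %d in B\n",
              nrow(x$pairs), x$gate, length(x$unmatched_a),
              length(x$unmatched_b)))
  invisible(x)
}
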