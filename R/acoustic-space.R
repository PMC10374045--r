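#' Non-metric MDS embedding of a similarity matrix
#'
#' Converts similarity to dissimilarity (`1 - s` by default, `sqrt(1 - s)`
#' optionally), collapses duplicate calls (zero dissimilarity) so they embed
#' to coincident coordinates, and minimizes Kruskal stress-1 with
#' `vegan::monoMDS` over one metric-scaling start plus random restarts,
#' keeping the best solution. Seed-deterministic.
#'
#' @param m A [similarity_matrix()] or a symmetric non-negative distance
#'   matrix (treated as dissimilarities directly).
#' @param k Embedding dimensionality (default 2).
#' @param restarts Number of random restarts beyond the metric start
#'   (default 20).
#' @param seed Integer seed.
#' @param transform `"one_minus"` (default) or `"sqrt"` dissimilarity
#'   transform for similarity input.
#'
#' @return An `acoustic_embedding`: list with `coords` (tibble `call_id`,
#'   `dim1..dimk`), `stress`, `k`, `restarts`, `method`.
#' @export
nmds_embed <- function(m, k = 2, restarts = 20, seed = 1,
                       transform = c("one_minus", "sqrt")) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  if (n < k + 1) stop("Need at least k + 1 calls to embed.", call. = FALSE)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- if (inherits(m, "similarity_matrix")) {
    if (transform == "one_minus") 1 - unclass(m) else sqrt(1 - unclass(m))
  } else {
    unclass(m)
  }
  diag(d) <- 0
  off <- d[upper.tri(d)]
  if (length(off) && max(off) - min(off) < 1e-12 && max(off) < 1e-12) {
    # every call identical: all coordinates coincide at the origin
    coords <- matrix(0, n, k)
  } else if (length(off) && max(off) - min(off) < 1e-12) {
    stop("All dissimilarities equal; embedding is degenerate.", call. = FALSE)
  } else {
    groups <- stats::cutree(stats::hclust(stats::as.dist(d), "single"),
                            h = 1e-12)
    reps <- match(unique(groups), groups)
    du <- d[reps, reps, drop = FALSE]
    nu <- length(reps)
    set.seed(seed)
    if (nu <= k + 1) {
      # tiny unique set: classical scaling is exact enough
      cu <- stats::cmdscale(stats::as.dist(du), k = min(k, nu - 1))
      cu <- cbind(cu, matrix(0, nu, k - ncol(cu)))
      stress <- 0
    } else {
      dd <- stats::as.dist(du)
      best <- NULL
      # random-restart inits are drawn for calls in sorted-id order, so the
      # search (and its best solution) is invariant to input ordering
      canon_pos <- match(ids[reps], sort(ids[reps]))
      for (r in seq_len(restarts + 1)) {
        y0 <- if (r == 1) {
          y <- stats::cmdscale(dd, k = k)
          if (ncol(y) < k) y <- cbind(y, matrix(0, nu, k - ncol(y)))
          y
        } else {
          set.seed(seed * 131 + r)
          m0 <- matrix(stats::runif(nu * k, -1, 1), nu, k)
          m0[canon_pos, , drop = FALSE]
        }
        fit <- try(vegan::monoMDS(dd, y = y0, k = k, model = "global",
                                  maxit = 500), silent = TRUE)
        if (inherits(fit, "try-error")) next
        if (is.null(best) || fit$stress < best$stress) best <- fit
      }
      if (is.null(best)) stop("nMDS failed to converge.", call. = FALSE)
      cu <- best$points
      stress <- best$stress
    }
    coords <- cu[groups, , drop = FALSE]
  }
  if (!exists("stress", inherits = FALSE)) stress <- 0
  ct <- tibble::as_tibble(coords, .name_repair = "minimal")
  names(ct) <- paste0("dim", seq_len(k))
  structure(list(
    coords = dplyr::bind_cols(tibble::tibble(call_id = ids), ct),
    stress = stress,
    k = k,
    restarts = restarts,
    method = attr(m, "method") %||% "distance"
  ), class = "acoustic_embedding")
}

#' @export
print.acoustic_embedding <- function(x, ...) {
  cat(sprintf("<acoustic_embedding: %d calls, k = %d, stress = %.4f, source %s>\n",
              nrow(x$coords), x$k, x$stress, x$method))
  print(utils::head(x$coords), ...)
  invisible(x)
}

polygon_area <- function(xy) {
  # shoelace; xy is an ordered polygon matrix (n x 2)
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

clip_polygon <- function(subject, clip) {
  # Sutherland-Hodgman: intersect convex polygon `subject` with convex `clip`
  # (both counter-clockwise n x 2 matrices)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    inside <- function(p) {
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    }
    inter <- function(p, q) {
      dc <- a - b
      dp <- p - q
      n1 <- a[1] * b[2] - a[2] * b[1]
      n2 <- p[1] * q[2] - p[2] * q[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c(n1 * dp[1] - n2 * dc[1], n1 * dp[2] - n2 * dc[2]) / den
    }
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    np <- nrow(inp)
    for (j in seq_len(np)) {
      p <- inp[j, ]
      q <- inp[if (j == np) 1 else j + 1, ]
      if (inside(p)) {
        out <- rbind(out, p)
        if (!inside(q)) out <- rbind(out, inter(p, q))
      } else if (inside(q)) {
        out <- rbind(out, inter(p, q))
      }
    }
  }
  out
}

convex_hull_ccw <- function(xy) {
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  if (polygon_signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), ,
                                                  drop = FALSE]
  hull
}

polygon_signed_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Convex-hull area and overlap per category in acoustic space
#'
#' Computes the convex-hull polygon area occupied by each category's calls
#' in a 2-D embedding, and for each category pair the overlap fraction
#' (intersection area / union area). Degenerate hulls (< 3 distinct
#' non-collinear points) have area 0; a pair of identical point sets has
#' overlap 1.
#'
#' @param embedding An `acoustic_embedding` with `k = 2`.
#' @param labels Category label per call (metadata order must match the
#'   embedded matrix order).
#'
#' @return List with tibbles `areas` (`category`, `n_calls`, `area`) and
#'   `overlaps` (`category_a`, `category_b`, `overlap`).
#' @export
hull_metrics <- function(embedding, labels) {
  stopifnot(inherits(embedding, "acoustic_embedding"), embedding$k >= 2)
  xy <- as.matrix(embedding$coords[, c("dim1", "dim2")])
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(xy))
  cats <- unique(labels)
  hulls <- lapply(cats, function(cc) {
    pts <- unique(xy[labels == cc, , drop = FALSE])
    if (nrow(pts) < 3) return(pts)
    convex_hull_ccw(pts)
  })
  names(hulls) <- cats
  areas <- tibble::tibble(
    category = cats,
    n_calls = vapply(cats, function(cc) sum(labels == cc), integer(1)),
    area = vapply(hulls, polygon_area, numeric(1))
  )
  pairs <- if (length(cats) > 1) utils::combn(cats, 2) else
    matrix(character(0), 2, 0)
  overlaps <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    ha <- hulls[[a]]; hb <- hulls[[b]]
    aa <- polygon_area(ha); ab <- polygon_area(hb)
    ov <- if (aa == 0 || ab == 0) {
      if (nrow(ha) == nrow(hb) &&
          isTRUE(all.equal(ha[order(ha[, 1], ha[, 2]), , drop = FALSE],
                           hb[order(hb[, 1], hb[, 2]), , drop = FALSE],
                           tolerance = 1e-9))) 1 else 0
    } else {
      inter <- polygon_area(clip_polygon(ha, hb))
      inter / (aa + ab - inter)
    }
    tibble::tibble(category_a = a, category_b = b, overlap = ov)
  })
  list(areas = areas, overlaps = overlaps)
}
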