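#' Construct a validated similarity matrix
#'
#' A similarity matrix is a symmetric numeric matrix with unit diagonal,
#' values in `[0, 1]`, call-id dimnames, and a `method` attribute ("SPCC" or
#' "RF-proximity"). All pipeline producers validate through this
#' constructor.
#'
#' @param m Square numeric matrix.
#' @param method Method tag, e.g. `"SPCC"`.
#' @param call_ids Optional character vector of ids (defaults to existing
#'   dimnames).
#'
#' @return A `similarity_matrix` (base matrix subclass).
#' @export
similarity_matrix <- function(m, method = "SPCC", call_ids = rownames(m)) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(call_ids)) call_ids <- as.character(seq_len(nrow(m)))
  stopifnot(length(call_ids) == nrow(m), !anyDuplicated(call_ids))
  if (any(!is.finite(m))) stop("Similarity values must be finite.", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) {
    stop("Similarity matrix must be symmetric.", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  if (any(m < -1e-8) || any(m > 1 + 1e-8)) {
    stop("Similarity values must lie in [0, 1].", call. = FALSE)
  }
  m <- pmin(pmax(m, 0), 1)
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop("Similarity matrix must have unit diagonal.", call. = FALSE)
  }
  diag(m) <- 1
  dimnames(m) <- list(call_ids, call_ids)
  structure(m, method = method, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix: %d calls, method %s>\n",
              nrow(x), attr(x, "method")))
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE],
                    6), ...)
  invisible(x)
}

#' Tidy a similarity matrix into unordered pairs
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#'
#' @return Tibble with `call_a`, `call_b` (each unordered pair once, a < b by
#'   matrix order) and `similarity`.
#' @export
tidy.similarity_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    call_a = ids[idx[, 1]],
    call_b = ids[idx[, 2]],
    similarity = x[idx]
  )
}

#' Write / read a similarity matrix as CSV
#'
#' Square CSV with a leading `call_id` column and one column per call.
#'
#' @param x A `similarity_matrix`.
#' @param path Output path.
#' @return `path` invisibly (write); a `similarity_matrix` (read).
#' @export
write_similarity_csv <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(call_id = rownames(x)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @param method Method tag for the reconstructed matrix.
#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path, method = "SPCC") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ids <- df$call_id
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  similarity_matrix(m, method = method, call_ids = ids)
}
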