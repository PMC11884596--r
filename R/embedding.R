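#' Embedder configuration
#'
#' @param backend `"mock"` (built-in deterministic embedder) or `"plm"`
#'   (external pretrained protein language model; must be wired in by
#'   the caller and is never used silently).
#' @param mock_dim Embedding width of the mock backend.
#' @param crop_window Maximum sequence length the backend accepts;
#'   longer sequences are centre-cropped around the site of interest.
#' @param seed Integer seed for the mock backend.
#' @return An `embedder_config` list.
#' @export
embedder_config <- function(backend = c("mock", "plm"), mock_dim = 64,
                            crop_window = 1022, seed = 1) {
  stopifnot(mock_dim > 0, crop_window > 1)
  structure(list(backend = match.arg(backend),
                 mock_dim = as.integer(mock_dim),
                 crop_window = as.integer(crop_window),
                 seed = as.integer(seed)),
            class = "embedder_config")
}

# Deterministic unit vector keyed by (seed, tag): the basis of the mock
# embedder. Same key always returns the same vector.
mock_basis_vector <- function(seed, tag, dim) {
  with_local_seed(derive_seed(seed, tag), {
    v <- stats::rnorm(dim)
    v / sqrt(sum(v^2))
  })
}

#' Embed a protein sequence
#'
#' The mock backend produces, for residue i, the unit-normalised sum of
#' a letter vector and a half-weight context vector keyed by the
#' residue's coarse position bucket (16 residues per bucket), both
#' deterministic functions of `(seed, letter, bucket)`. Identical
#' residues in nearby positions therefore embed similarly, different
#' letters embed near-orthogonally, and identical inputs always give
#' bitwise-identical output. The `plm` backend is an explicit extension
#' point: requesting it without an installed model raises a backend
#' error rather than silently falling back.
#'
#' @param sequence Non-empty amino-acid string.
#' @param config An [embedder_config()].
#' @return An `embedding_matrix`: list with `per_residue` (L x D),
#'   `global_vector` (column mean of `per_residue`), `backend_tag`, `dim`.
#' @export
embed_sequence <- function(sequence, config = embedder_config()) {
  stopifnot(nchar(sequence) > 0)
  if (config$backend == "plm") {
    stop_pf(paste("plm backend requested but no protein language model is",
                  "wired in; use backend = 'mock' or supply embeddings"),
            "phosfusion_backend_error")
  }
  letters_ <- strsplit(toupper(sequence), "")[[1]]
  L <- length(letters_)
  D <- config$mock_dim
  buckets <- (seq_len(L) - 1L) %/% 16L
  keys <- paste(letters_, buckets, sep = "@")
  uniq <- unique(keys)
  rows <- matrix(0, length(uniq), D)
  for (u in seq_along(uniq)) {
    parts <- strsplit(uniq[[u]], "@", fixed = TRUE)[[1]]
    a <- mock_basis_vector(config$seed, paste0("letter:", parts[[1]]), D)
    b <- mock_basis_vector(config$seed, paste0("bucket:", uniq[[u]]), D)
    v <- a + 0.5 * b
    rows[u, ] <- v / sqrt(sum(v^2))
  }
  per_residue <- rows[match(keys, uniq), , drop = FALSE]
  structure(list(per_residue = per_residue,
                 global_vector = colMeans(per_residue),
                 backend_tag = config$backend, dim = D),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d x %d (%s backend)\n",
              nrow(x$per_residue), x$dim, x$backend_tag))
  invisible(x)
}

#' Centre-crop a sequence window around a site
#'
#' For sequences longer than `window`, returns the 1-based index range
#' of a `window`-long stretch containing the site as centrally as the
#' chain ends allow, plus the site's index relative to the crop.
#'
#' @param length Sequence length.
#' @param site 1-based site position.
#' @param window Maximum window length.
#' @return List with `start`, `end`, `site_rel`.
#' @export
crop_window_indices <- function(length, site, window) {
  stopifnot(site >= 1, site <= length)
  if (length <= window) {
    return(list(start = 1L, end = as.integer(length), site_rel = as.integer(site)))
  }
  half <- window %/% 2L
  start <- min(max(1L, as.integer(site) - half), as.integer(length) - window + 1L)
  list(start = start, end = start + window - 1L,
       site_rel = as.integer(site) - start + 1L)
}

#' Project an embedding matrix into the fusion dimension
#'
#' Row-wise affine map `X %*% weights + bias`, the linear layer that
#' adapts backend-native embedding widths to the model width.
#'
#' @param matrix An `embedding_matrix` or a plain numeric matrix.
#' @param weights D x C numeric matrix.
#' @param bias Length-C numeric vector (default zero).
#' @return Projected matrix (L x C); for an `embedding_matrix` input a
#'   projected `embedding_matrix` is returned.
#' @export
project_embeddings <- function(matrix, weights, bias = NULL) {
  is_em <- inherits(matrix, "embedding_matrix")
  X <- if (is_em) matrix$per_residue else as.matrix(matrix)
  if (ncol(X) != nrow(weights)) {
    stop_pf("projection shape mismatch: %d columns vs %d rows",
            "phosfusion_shape_error", ncol(X), nrow(weights))
  }
  bias <- bias %||% numeric(ncol(weights))
  P <- X %*% weights
  P <- sweep(P, 2, bias, "+")
  if (!is_em) return(P)
  structure(list(per_residue = P, global_vector = colMeans(P),
                 backend_tag = matrix$backend_tag, dim = ncol(P)),
            class = "embedding_matrix")
}

#' Build the sequence-side query tokens for a site
#'
#' Default (`window = 0`): a two-token query, token 1 the global
#' (mean-pooled) vector and token 2 the site residue's row. With
#' `window = w > 0` the query is the global token followed by the
#' `2w + 1` rows centred on the site, zero-padded past the chain ends,
#' giving a fixed `2w + 2` tokens.
#'
#' @param matrix An `embedding_matrix` (raw or projected) or matrix.
#' @param site_position 1-based site position.
#' @param window Half-width of the residue window (0 = site token only).
#' @return Numeric token matrix (tokens x width).
#' @export
build_query <- function(matrix, site_position, window = 0) {
  X <- if (inherits(matrix, "embedding_matrix")) matrix$per_residue else
    as.matrix(matrix)
  L <- nrow(X)
  site_position <- as.integer(site_position)
  if (site_position < 1 || site_position > L) {
    stop_pf("site position %d outside embedding of length %d",
            "phosfusion_out_of_range", site_position, L)
  }
  g <- if (inherits(matrix, "embedding_matrix")) matrix$global_vector else
    colMeans(X)
  if (window == 0) {
    return(rbind(g, X[site_position, , drop = FALSE], deparse.level = 0))
  }
  idx <- (site_position - window):(site_position + window)
  W <- base::matrix(0, length(idx), ncol(X))
  ok <- idx >= 1 & idx <= L
  W[ok, ] <- X[idx[ok], , drop = FALSE]
  rbind(g, W, deparse.level = 0)
}
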