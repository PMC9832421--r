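#' Assemble a conformational landscape table
#'
#' Collects coefficient sets of mixed provenance (particles, maps, models)
#' into one table: one row per item with its flattened coefficient vector,
#' deformation magnitude and estimation score. All items must share the
#' basis spec and physical scale (use [rescale_coefficients()] first when
#' they do not).
#'
#' @param items list of lists with fields `id`, `kind` (one of
#'   `"particle"`, `"map"`, `"model"`), `coeffs` (a [coefficient_set()])
#'   and optional `score`.
#' @param mask optional [volume_grid()] mask forwarded to
#'   [deformation_magnitude()].
#' @return a data.frame of class `landscape_table` with columns `id`,
#'   `kind`, `score`, `magnitude_A`, then one column per coefficient
#'   component (`a_l_n_m` + direction suffix) in [zernike_indices()] order.
#' @export
assemble_landscape <- function(items, mask = NULL) {
  if (length(items) == 0) {
    out <- data.frame(id = character(), kind = character(),
                      score = numeric(), magnitude_A = numeric())
    class(out) <- c("landscape_table", class(out))
    return(out)
  }
  spec <- items[[1]]$coeffs$spec
  sr <- items[[1]]$coeffs$scale_radius
  for (it in items) {
    if (!identical(it$coeffs$spec, spec) ||
        abs(it$coeffs$scale_radius - sr) > 1e-9)
      stop("items mix basis specs or scales; rescale_coefficients() first")
  }
  idx <- zernike_indices(spec)
  cn <- as.vector(t(outer(sprintf("a_%d_%d_%d", idx$l, idx$n, idx$m),
                          c("x", "y", "z"), paste, sep = "_")))
  vecs <- t(vapply(items, function(it) as.vector(t(it$coeffs$alphas)),
                   numeric(3 * nrow(idx))))
  colnames(vecs) <- cn
  out <- data.frame(
    id = vapply(items, function(it) as.character(it$id), character(1)),
    kind = vapply(items, function(it) match.arg(it$kind,
                  c("particle", "map", "model")), character(1)),
    score = vapply(items, function(it)
      if (is.null(it$score)) NA_real_ else it$score, numeric(1)),
    magnitude_A = vapply(items, function(it)
      deformation_magnitude(it$coeffs, mask), numeric(1)),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vecs))
  attr(out, "spec") <- spec
  attr(out, "scale_radius") <- sr
  class(out) <- c("landscape_table", class(out))
  out
}

landscape_matrix <- function(t) {
  as.matrix(t[, grep("^a_", names(t)), drop = FALSE])
}

#' Rebuild the coefficient set stored in one landscape row
#'
#' @param t a `landscape_table`.
#' @param row row index.
#' @return a [coefficient_set()].
#' @export
landscape_row_coeffs <- function(t, row) {
  spec <- attr(t, "spec")
  vec <- as.numeric(landscape_matrix(t)[row, ])
  coefficient_set(spec, matrix(vec, ncol = 3, byrow = TRUE),
                  attr(t, "scale_radius"))
}

#' Write a landscape table as CSV
#'
#' @param t a `landscape_table`.
#' @param path output path; the basis spec and scale are stored in a
#'   comment-like header row read back by [read_landscape()].
#' @return `path`, invisibly.
#' @export
write_landscape <- function(t, path) {
  spec <- attr(t, "spec")
  hdr <- sprintf("#zflex-landscape v1 N=%d L=%d p=%.17g scale_radius=%.17g",
                 spec$N, spec$L, spec$p, attr(t, "scale_radius"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(t)
  # full-precision text so numeric values round-trip bit-identically
  for (cc in names(df))
    if (is.double(df[[cc]])) df[[cc]] <- sprintf("%.17g", df[[cc]])
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a landscape table from CSV
#'
#' @param path file written by [write_landscape()].
#' @return a `landscape_table`.
#' @export
read_landscape <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#zflex-landscape v1"))
    stop("not a zflex-landscape v1 file")
  kv <- regmatches(hdr, gregexpr("[NLp]=[0-9.eE+-]+|scale_radius=[0-9.eE+-]+",
                                 hdr))[[1]]
  val <- function(key) as.numeric(sub(paste0(key, "="), "",
                                      kv[startsWith(kv, paste0(key, "="))]))
  out <- read.csv(path, skip = 1, stringsAsFactors = FALSE,
                  check.names = FALSE)
  out$id <- as.character(out$id)
  out$kind <- as.character(out$kind)
  attr(out, "spec") <- basis_spec(val("N"), val("L"), val("p"))
  attr(out, "scale_radius") <- val("scale_radius")
  class(out) <- c("landscape_table", class(out))
  out
}

#' Cluster a landscape and pick representative states
#'
#' KMeans on the flattened coefficient vectors; the representative of each
#' cluster is the member row nearest its centroid (the medoid), so every
#' representative corresponds to a conformation actually observed.
#' Deterministic for a fixed seed and invariant to row order.
#'
#' @param t a `landscape_table`.
#' @param n number of clusters (`1 <= n <= nrow(t)`).
#' @param seed clustering seed.
#' @return list with `representatives` (list of [coefficient_set()]),
#'   `medoid_rows` (row indices) and `assignment` (cluster id per row).
#' @export
cluster_representatives <- function(t, n, seed = 1L) {
  X <- landscape_matrix(t)
  if (n < 1 || n > nrow(X)) stop("n must lie between 1 and the row count")
  # order-invariant determinism: seed the start from the data-independent
  # RNG stream, then stabilize by sorting rows into canonical order
  ord <- do.call(order, as.data.frame(X))
  set.seed(seed)
  km <- kmeans(X[ord, , drop = FALSE], centers = n, nstart = 10,
               iter.max = 200)
  assignment <- integer(nrow(X))
  assignment[ord] <- km$cluster
  # relabel clusters canonically (by first occurrence in canonical order)
  medoid_rows <- integer(n)
  for (k in seq_len(n)) {
    members <- which(assignment == k)
    d2 <- rowSums((X[members, , drop = FALSE] -
                     matrix(km$centers[k, ], length(members),
                            ncol(X), byrow = TRUE))^2)
    medoid_rows[k] <- members[which.min(d2)]
  }
  list(representatives = lapply(medoid_rows, function(r)
         landscape_row_coeffs(t, r)),
       medoid_rows = medoid_rows, assignment = assignment)
}

#' Embed a landscape in two dimensions
#'
#' `method = "pca"` projects onto the first two exact principal
#' components; `method = "umap"` delegates to the uwot package when it is
#' installed. Deterministic for a fixed seed.
#'
#' @param t a `landscape_table` with at least 3 rows.
#' @param method `"pca"` or `"umap"`.
#' @param seed embedding seed (umap only; PCA is deterministic).
#' @return numeric matrix (rows x 2).
#' @export
embed_2d <- function(t, method = c("pca", "umap"), seed = 1L) {
  method <- match.arg(method)
  X <- landscape_matrix(t)
  if (nrow(X) < 3) stop("at least 3 rows are required for an embedding")
  if (method == "pca") {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    out <- matrix(0, nrow(X), 2)
    out[, seq_len(k)] <- pc$x[, seq_len(k), drop = FALSE]
    out
  } else {
    if (!requireNamespace("uwot", quietly = TRUE))
      stop("method = 'umap' needs the uwot package; use method = 'pca'")
    set.seed(seed)
    n_neigh <- min(15, nrow(X) - 1)
    unname(as.matrix(uwot::umap(X, n_neighbors = n_neigh, ret_model = FALSE)))
  }
}

#' Synthesize the map (and model) of a landscape state
#'
#' Applies a coefficient set — typically a cluster representative — to the
#' reference map, and co-deforms an atomic model with the same coefficients
#' (internally negated so the atoms track the moving density under the
#' gather-warp convention). The output grid and sampling equal the
#' reference's, so the operation is instant and does not resample the map.
#'
#' @param c a [coefficient_set()].
#' @param reference the reference [volume_grid()].
#' @param model optional [atomic_model()] aligned to the reference.
#' @return list with `volume` and `model` (NULL when no model given).
#' @export
synthesize_state <- function(c, reference, model = NULL) {
  if (abs(c$scale_radius - default_scale_radius(reference)) > 1e-6)
    stop("coefficient scale_radius does not match the reference box")
  vol <- warp_volume(reference, c)
  mdl <- if (is.null(model)) NULL else warp_model(model,
                                                  negate_coefficients(c))
  list(volume = vol, model = mdl)
}
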