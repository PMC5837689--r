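# Robinson-Foulds tree space: pairwise distance matrices, classical MDS
# embedding, hexagonal binning, and the within/between marker-group summary
# statistics that quantify cytonuclear discordance.

#' Pairwise Robinson-Foulds distance matrix over a tree set
#'
#' When all trees span the same taxon set the split sets are computed once
#' per tree; otherwise each pair is restricted to its shared taxa.
#'
#' @param ts a \code{tree_set}.
#' @return symmetric integer matrix with zero diagonal, dimnames = analysis
#'   ids; attribute \code{groups} carries the group label per id.
#' @export
pairwise_rf_matrix <- function(ts) {
  .assert(inherits(ts, "tree_set"), "ts must be a tree_set")
  trees <- as.list(ts$trees)
  ids <- ts$info$id
  n <- length(trees)
  universe <- tree_set_taxa(ts)
  .assert(length(universe) >= 4, "tree set spans fewer than 4 taxa")
  same <- all(vapply(trees, function(t) setequal(t$tip.label, universe), TRUE))
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (same) {
    keysets <- lapply(trees, function(t) as.character(.splits_keys(t, universe)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- length(setdiff(keysets[[i]], keysets[[j]])) +
           length(setdiff(keysets[[j]], keysets[[i]]))
      m[i, j] <- m[j, i] <- d
    }
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- tryCatch(rf_distance(trees[[i]], trees[[j]]), error = function(e)
        stop(sprintf("rf failed for pair (%s, %s): %s", ids[i], ids[j],
                     conditionMessage(e)), call. = FALSE))
      m[i, j] <- m[j, i] <- d
    }
  }
  attr(m, "groups") <- stats::setNames(ts$info$group, ids)
  m
}

#' Within/between group summary of a distance matrix
#'
#' Mean pairwise distance within each group, mean and minimum across-group
#' distance, pair counts, and the number of pairs strictly exceeding a
#' cutoff per comparison type.
#'
#' @param dm symmetric distance matrix with dimnames ids.
#' @param groups named character vector mapping id to group label (defaults
#'   to the matrix's \code{groups} attribute).
#' @param cutoff integer; pairs strictly greater than it are counted.
#' @return list: \code{within_means} (named, NA for singleton groups),
#'   \code{between_mean}, \code{min_between}, \code{pair_counts},
#'   \code{exceed_counts}, \code{cutoff}.
#' @export
group_summary <- function(dm, groups = attr(dm, "groups"), cutoff = 0L) {
  ids <- rownames(dm)
  .assert(!is.null(ids) && !is.null(groups), "dm needs ids and a group mapping")
  g <- as.character(groups[ids])
  .assert(!anyNA(g), "every id needs a group label")
  glev <- sort(unique(g))
  n <- length(ids)
  iu <- which(upper.tri(dm), arr.ind = TRUE)
  vals <- dm[iu]
  gi <- g[iu[, 1]]; gj <- g[iu[, 2]]
  within_means <- stats::setNames(rep(NA_real_, length(glev)), glev)
  pair_counts <- list(); exceed_counts <- list()
  for (lev in glev) {
    sel <- gi == lev & gj == lev
    key <- paste0("within_", lev)
    pair_counts[[key]] <- sum(sel)
    exceed_counts[[key]] <- sum(vals[sel] > cutoff)
    if (any(sel)) within_means[lev] <- mean(vals[sel])
  }
  btw <- gi != gj
  pair_counts[["between"]] <- sum(btw)
  exceed_counts[["between"]] <- sum(vals[btw] > cutoff)
  between_mean <- if (any(btw)) mean(vals[btw]) else NA_real_
  min_between <- if (any(btw)) min(vals[btw]) else NA_real_
  # combinatorial identities
  sizes <- table(g)
  for (lev in glev) {
    stopifnot(pair_counts[[paste0("within_", lev)]] == choose(sizes[[lev]], 2))
  }
  list(within_means = within_means, between_mean = between_mean,
       min_between = min_between, pair_counts = pair_counts,
       exceed_counts = exceed_counts, cutoff = cutoff)
}

#' Classical (Torgerson) metric MDS embedding of a distance matrix
#'
#' Double-centers the squared distances and takes the top-\code{dims}
#' spectral axes (\code{stats::cmdscale}), then applies a fixed sign
#' convention (largest-magnitude coordinate on each axis positive) so the
#' embedding is deterministic up to nothing. Negative eigenvalues arising
#' from non-Euclidean RF matrices are truncated; their total magnitude is
#' reported alongside the stress.
#'
#' @param dm symmetric distance matrix.
#' @param dims embedding dimension, default 2; must be < nrow(dm).
#' @return object of class \code{tree_embedding}: list with \code{ids},
#'   \code{coordinates} (n x dims matrix), \code{stress} (relative
#'   root-square misfit of configuration vs input distances),
#'   \code{negative_eigenvalue_mass}, \code{groups} (carried through).
#' @export
embed_cmds <- function(dm, dims = 2) {
  n <- nrow(dm)
  .assert(dims >= 1 && dims < n, "dims must be in [1, n_ids - 1]")
  # cmdscale warns when fewer than dims eigenvalues are positive (routine for
  # degenerate or strongly non-Euclidean RF matrices); we pad coordinates
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = dims, eig = TRUE))
  coords <- fit$points
  if (is.null(coords) || ncol(coords) < dims) {
    # degenerate (e.g. all-zero matrix): pad with zero coordinates
    pad <- matrix(0, n, dims - (if (is.null(coords)) 0 else ncol(coords)))
    coords <- cbind(if (is.null(coords)) NULL else coords, pad)
  }
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  dhat <- as.matrix(stats::dist(coords))
  num <- sum((dhat[upper.tri(dhat)] - dm[upper.tri(dm)])^2)
  den <- sum(dm[upper.tri(dm)]^2)
  stress <- if (den > 0) sqrt(num / den) else 0
  structure(list(ids = rownames(dm), coordinates = coords, stress = stress,
                 negative_eigenvalue_mass = sum(abs(fit$eig[fit$eig < 0])),
                 groups = attr(dm, "groups")),
            class = "tree_embedding")
}

#' Hexagonal bin counts over a 2-D embedding
#'
#' Tessellates the bounding box of the points with \code{gridsize} hexagon
#' columns and counts the points falling in each occupied cell; counts sum
#' to the number of points.
#'
#' @param emb a \code{tree_embedding} with >= 2 dimensions (the first two are
#'   used), or an n x 2 coordinate matrix.
#' @param gridsize number of hexagon columns across the x range, default 25.
#' @return data.frame: cell_x, cell_y (hexagon centers in data units), count.
#' @export
hexbin_counts <- function(emb, gridsize = 25) {
  coords <- if (inherits(emb, "tree_embedding")) emb$coordinates else as.matrix(emb)
  .assert(ncol(coords) >= 2, "hexagonal binning needs a 2-D embedding")
  x <- coords[, 1]; y <- coords[, 2]
  rx <- range(x); ry <- range(y)
  spanx <- max(rx[2] - rx[1], .Machine$double.eps)
  spany <- max(ry[2] - ry[1], .Machine$double.eps)
  sx <- gridsize / spanx
  sy <- gridsize / (spany * sqrt(3))
  xs <- (x - rx[1]) * sx; ys <- (y - ry[1]) * sy
  # two offset rectangular lattices; each point takes the nearer center
  j1 <- round(xs); i1 <- round(ys)
  j2 <- floor(xs) + 0.5; i2 <- floor(ys) + 0.5
  d1 <- (xs - j1)^2 + 3 * (ys - i1)^2
  d2 <- (xs - j2)^2 + 3 * (ys - i2)^2
  use2 <- d2 < d1
  cx <- ifelse(use2, j2, j1); cy <- ifelse(use2, i2, i1)
  key <- paste(cx, cy)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, " "))
  out <- data.frame(cell_x = as.numeric(parts[, 1]) / sx + rx[1],
                    cell_y = as.numeric(parts[, 2]) / sy + ry[1],
                    count = as.integer(agg$Freq))
  stopifnot(sum(out$count) == length(x))
  out[order(out$cell_x, out$cell_y), , drop = FALSE]
}

#' Write a distance matrix as square TSV with header ids
#' @param dm matrix from \code{pairwise_rf_matrix}.
#' @param file output path.
#' @export
write_distance_tsv <- function(dm, file) {
  utils::write.table(cbind(id = rownames(dm), as.data.frame(dm)), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a square distance TSV written by \code{write_distance_tsv}
#' @param file path.
#' @export
read_distance_tsv <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  storage.mode(m) <- "numeric"
  m
}

#' Write an embedding as TSV (id, group, coordinates)
#' @param emb a \code{tree_embedding}.
#' @param file output path.
#' @export
write_embedding_tsv <- function(emb, file) {
  tab <- data.frame(id = emb$ids,
                    group = if (is.null(emb$groups)) NA else emb$groups[emb$ids],
                    emb$coordinates)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
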