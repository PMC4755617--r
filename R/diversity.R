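check_proportions <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || any(!is.finite(p)))
    stop_ecodiv("proportions must be finite numbers", "ecodiv_domain_error")
  if (any(p < 0))
    stop_ecodiv("proportions must be non-negative", "ecodiv_domain_error")
  if (abs(sum(p) - 1) > tol)
    stop_ecodiv("proportions must sum to 1", "ecodiv_domain_error")
  p
}

#' Shannon diversity index
#'
#' Entropy of a composition over cell types, `-sum(p_i * log(p_i))` in
#' natural-log units (nats), with the usual convention `0 * log 0 = 0`.
#' Ranges from 0 (a single type) to `log(m)` (equal proportions of `m`
#' types).
#'
#' @param proportions non-negative numeric vector summing to 1.
#' @return Shannon index in nats.
#' @examples
#' shannon_index(c(1/3, 1/3, 1/3))  # log(3)
#' shannon_index(c(1, 0, 0))        # 0
#' @export
shannon_index <- function(proportions) {
  p <- check_proportions(proportions)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Simpson diversity index
#'
#' `1 - sum(p_i^2)`; an alternative diversity measure more dominated by
#' common types than the Shannon index, provided for comparison.
#'
#' @inheritParams shannon_index
#' @return Simpson index in `[0, 1 - 1/m]`.
#' @export
simpson_index <- function(proportions) {
  p <- check_proportions(proportions)
  1 - sum(p^2)
}

#' Tile a cell map into square regions
#'
#' Divides the section into half-open square tiles of side `region_size`
#' and counts cells of each class per tile. A cell at `(x, y)` falls in
#' tile column `floor((x - x0) / r)` and row `floor((y - y0) / r)`; by
#' default the grid origin `(x0, y0)` is the bounding-box minimum of the
#' cells, so the tiling is translation invariant.
#'
#' @param cellmap a non-empty [cell_map()].
#' @param region_size tile side in micrometres (default 200).
#' @param origin optional numeric `(x0, y0)` grid anchor in micrometres.
#' @return A `data.frame` of class `"region_grid"` with columns
#'   `region_row`, `region_col` and one count column per cell class, plus
#'   `region_size` and `origin` attributes. Only occupied tiles are listed.
#' @export
tile_regions <- function(cellmap, region_size = 200, origin = NULL) {
  stopifnot(inherits(cellmap, "cell_map"))
  if (!is.numeric(region_size) || length(region_size) != 1L || region_size <= 0)
    stop_ecodiv("region_size must be a single positive number", "ecodiv_parameter_error")
  if (nrow(cellmap) == 0L)
    stop_ecodiv("cannot tile an empty cell map", "ecodiv_empty_input_error")
  if (is.null(origin)) origin <- c(min(cellmap$x_um), min(cellmap$y_um))
  row <- floor((cellmap$y_um - origin[2L]) / region_size)
  col <- floor((cellmap$x_um - origin[1L]) / region_size)
  key <- paste(row, col, sep = ":")
  tab <- table(key, cellmap$cell_type)
  ids <- rownames(tab)
  parts <- do.call(rbind, strsplit(ids, ":", fixed = TRUE))
  grid <- data.frame(region_row = as.integer(parts[, 1L]),
                     region_col = as.integer(parts[, 2L]))
  for (cls in cell_classes())
    grid[[paste0("n_", cls)]] <- as.integer(tab[, cls])
  grid <- grid[order(grid$region_row, grid$region_col), , drop = FALSE]
  rownames(grid) <- NULL
  structure(grid, region_size = region_size, origin = origin,
            tumor_id = attr(cellmap, "tumor_id"),
            class = c("region_grid", "data.frame"))
}

region_count_matrix <- function(grid) {
  as.matrix(grid[, paste0("n_", cell_classes()), drop = FALSE])
}

#' Regional diversity profile
#'
#' Computes the Shannon index of each tile's cell-type composition,
#' dropping sparse tiles with fewer than `min_cells` cells (local
#' proportions from a handful of cells are too noisy to score).
#'
#' @param grid a `"region_grid"` from [tile_regions()], or a list of grids
#'   (sections of the same tumor) whose retained regions are pooled.
#' @param min_cells minimum cells for a tile to be scored (default 10).
#' @return A list of class `"diversity_profile"`: `d` (regional Shannon
#'   scores, nats), `n` (number of retained regions), `m` (number of cell
#'   classes, 3), `counts` (retained per-type count matrix), `regions`
#'   (retained tile coordinates and section index), `excluded_regions`
#'   (tiles dropped by the filter).
#' @export
regional_diversity <- function(grid, min_cells = 10) {
  if (inherits(grid, "region_grid")) grid <- list(grid)
  stopifnot(length(grid) >= 1L, all(vapply(grid, inherits, TRUE, "region_grid")))
  if (min_cells < 1) stop_ecodiv("min_cells must be >= 1", "ecodiv_parameter_error")
  counts <- do.call(rbind, lapply(grid, region_count_matrix))
  regions <- do.call(rbind, lapply(seq_along(grid), function(s)
    data.frame(section = s,
               region_row = grid[[s]]$region_row,
               region_col = grid[[s]]$region_col)))
  total <- rowSums(counts)
  keep <- total >= min_cells
  if (!any(keep))
    stop_ecodiv("all regions excluded by the min_cells filter", "ecodiv_empty_profile_error")
  counts <- counts[keep, , drop = FALSE]
  p <- counts / rowSums(counts)
  d <- apply(p, 1L, shannon_index)
  structure(list(d = unname(d), n = sum(keep), m = length(cell_classes()),
                 counts = counts, regions = regions[keep, , drop = FALSE],
                 excluded_regions = sum(!keep), min_cells = min_cells,
                 region_size = attr(grid[[1L]], "region_size"),
                 tumor_id = attr(grid[[1L]], "tumor_id")),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("Diversity profile: %d regions (%d excluded), region size %s um\n",
              x$n, x$excluded_regions, format(x$region_size)))
  cat(sprintf("  Shannon scores: %.3f-%.3f nats (median %.3f)\n",
              min(x$d), max(x$d), stats::median(x$d)))
  invisible(x)
}

#' Whole-tumor Shannon index
#'
#' The Shannon index of the pooled cell-type proportions of the entire
#' tumor, ignoring spatial structure. A tumor can have a high whole-tumor
#' index yet be spatially homogeneous; contrast with [edi()].
#'
#' @param cellmap a non-empty [cell_map()] or list of cell maps (sections).
#' @return Shannon index in nats.
#' @export
whole_tumor_shannon <- function(cellmap) {
  if (inherits(cellmap, "cell_map")) cellmap <- list(cellmap)
  types <- unlist(lapply(cellmap, function(cm) as.character(cm$cell_type)))
  if (length(types) == 0L)
    stop_ecodiv("empty cell map", "ecodiv_empty_input_error")
  counts <- table(factor(types, levels = cell_classes()))
  shannon_index(as.numeric(counts) / sum(counts))
}
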