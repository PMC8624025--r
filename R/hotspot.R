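#' Map a clinical severity grade to its Delta-T cut-off
#'
#' Severe inflammation uses a 3 degC cut-off for the matrix subtraction,
#' moderate inflammation a 2 degC cut-off.  Grade matching is
#' case-insensitive.
#'
#' @param grade `"severe"` or `"moderate"` (any case).
#' @return A [threshold_policy()] with `source = "severity_grade"`.
#' @export
#' @examples
#' threshold_for_grade("severe")$delta_t    # 3
#' threshold_for_grade("moderate")$delta_t  # 2
threshold_for_grade <- function(grade) {
  if (!is.character(grade) || length(grade) != 1L)
    ht_enum_error("grade must be a single string; valid grades: severe, moderate")
  g <- tolower(trimws(grade))
  dt <- switch(g, severe = 3.0, moderate = 2.0,
               ht_enum_error("unknown severity grade '%s'; valid grades: severe, moderate",
                             grade))
  threshold_policy(dt, source = "severity_grade", grade = g)
}

# Connected components of a logical matrix via a pixel-adjacency graph.
# Returns an integer matrix of labels (0 = background), unordered.
label_components <- function(fg, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    ht_precondition_error("connectivity must be 4 or 8")
  m <- nrow(fg); n <- ncol(fg)
  id <- matrix(seq_len(m * n), m, n)
  pairs <- function(a, b, fa, fb) {
    keep <- fa & fb
    cbind(a[keep], b[keep])
  }
  ed <- list()
  if (n > 1L)  # horizontal neighbours
    ed[[length(ed) + 1L]] <- pairs(id[, -n, drop = FALSE], id[, -1L, drop = FALSE],
                                   fg[, -n, drop = FALSE], fg[, -1L, drop = FALSE])
  if (m > 1L)  # vertical neighbours
    ed[[length(ed) + 1L]] <- pairs(id[-m, , drop = FALSE], id[-1L, , drop = FALSE],
                                   fg[-m, , drop = FALSE], fg[-1L, , drop = FALSE])
  if (connectivity == 8L && m > 1L && n > 1L) {
    ed[[length(ed) + 1L]] <- pairs(id[-m, -n, drop = FALSE], id[-1L, -1L, drop = FALSE],
                                   fg[-m, -n, drop = FALSE], fg[-1L, -1L, drop = FALSE])
    ed[[length(ed) + 1L]] <- pairs(id[-1L, -n, drop = FALSE], id[-m, -1L, drop = FALSE],
                                   fg[-1L, -n, drop = FALSE], fg[-m, -1L, drop = FALSE])
  }
  ed <- do.call(rbind, c(ed, list(matrix(integer(), 0L, 2L))))
  g <- igraph::make_empty_graph(n = m * n, directed = FALSE)
  if (nrow(ed)) g <- igraph::add_edges(g, t(ed))
  memb <- igraph::components(g)$membership
  lab <- matrix(0L, m, n)
  lab[fg] <- match(memb[fg], unique(memb[fg]))
  lab
}

# Elongation (major/minor axis ratio) of a pixel set from its inertia
# tensor, treating each pixel as a unit square (adds 1/12 to each diagonal
# second moment, so a single pixel has elongation 1 and an a x b rectangle
# exactly a/b).
pixel_elongation <- function(px) {
  ctr <- colMeans(px)
  d <- sweep(px, 2L, ctr)
  cov <- crossprod(d) / nrow(px) + diag(1 / 12, 2L)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / min(ev))
}

#' Segment suprathreshold pixels into hotspot regions
#'
#' Labels the connected components of the suprathreshold set (`value > 0`)
#' of a thresholded differential map, discards components smaller than
#' `min_region_area`, and returns the survivors sorted by descending area
#' (ties: higher max Delta-T, then top-left-most centroid).  The first
#' region is taken as the main inflammation site.
#'
#' @param Rp A thresholded [temperature_matrix()] (see [threshold_map()]).
#' @param connectivity Pixel adjacency: 8 (default, diagonals connect) or 4.
#' @param min_region_area Minimum component area in pixels (default 5;
#'   0 disables the filter).
#' @return A list of `hotspot_region` objects, each with elements `label`
#'   (rank, 1 = main site), `pixels` (two-column 0-based `(row, col)`
#'   matrix), `area`, `max_delta_t`, `mean_delta_t`, `centroid` (fractional
#'   0-based `(row, col)`), `bbox` (`top`, `left`, `height`, `width`) and
#'   `elongation` (major/minor axis ratio, >= 1).  Empty list when no
#'   component survives.
#' @export
segment_hotspots <- function(Rp, connectivity = 8L, min_region_area = 5L) {
  expect_kind(Rp, "thresholded", "Rp")
  if (!is.numeric(min_region_area) || min_region_area < 0)
    ht_precondition_error("min_region_area must be >= 0")
  v <- unclass_tm(Rp)
  fg <- is.finite(v) & v > 0
  if (!any(fg)) return(list())
  lab <- label_components(fg, as.integer(connectivity))
  regions <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k)
    if (length(idx) < min_region_area) return(NULL)
    px <- arrayInd(idx, dim(v)) - 1L  # 0-based (row, col)
    vals <- v[idx]
    ctr <- colMeans(px)
    structure(list(label = NA_integer_,
                   pixels = px,
                   area = length(idx),
                   max_delta_t = max(vals),
                   mean_delta_t = mean(vals),
                   centroid = c(row = ctr[1L], col = ctr[2L]),
                   bbox = c(top = min(px[, 1L]), left = min(px[, 2L]),
                            height = diff(range(px[, 1L])) + 1L,
                            width = diff(range(px[, 2L])) + 1L),
                   elongation = pixel_elongation(px)),
              class = "hotspot_region")
  })
  regions <- Filter(Negate(is.null), regions)
  if (!length(regions)) return(list())
  ord <- order(-vapply(regions, `[[`, numeric(1), "area"),
               -vapply(regions, `[[`, numeric(1), "max_delta_t"),
               vapply(regions, function(r) r$centroid[["row"]], numeric(1)),
               vapply(regions, function(r) r$centroid[["col"]], numeric(1)))
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]$label <- i
  regions
}

#' @export
print.hotspot_region <- function(x, ...) {
  cat(sprintf("<hotspot_region #%d> area %d px, max dT %.2f, mean dT %.2f, centroid (%.1f, %.1f), elongation %.2f\n",
              x$label, x$area, x$max_delta_t, x$mean_delta_t,
              x$centroid[1L], x$centroid[2L], x$elongation))
  invisible(x)
}

#' Tabulate hotspot regions
#'
#' @param regions List of regions from [segment_hotspots()].
#' @return A data frame with one row per region: `label`, `area_px`,
#'   `max_delta_t_C`, `mean_delta_t_C`, `centroid_row`, `centroid_col`,
#'   `bbox_top`, `bbox_left`, `bbox_height`, `bbox_width`, `elongation`.
#' @export
region_table <- function(regions) {
  if (!length(regions))
    return(data.frame(label = integer(), area_px = integer(),
                      max_delta_t_C = numeric(), mean_delta_t_C = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      bbox_top = integer(), bbox_left = integer(),
                      bbox_height = integer(), bbox_width = integer(),
                      elongation = numeric()))
  do.call(rbind, lapply(regions, function(r)
    data.frame(label = r$label, area_px = r$area,
               max_delta_t_C = r$max_delta_t, mean_delta_t_C = r$mean_delta_t,
               centroid_row = r$centroid[["row"]],
               centroid_col = r$centroid[["col"]],
               bbox_top = r$bbox[["top"]], bbox_left = r$bbox[["left"]],
               bbox_height = r$bbox[["height"]], bbox_width = r$bbox[["width"]],
               elongation = r$elongation)))
}

#' Overlap between a detected mask and a ground-truth mask
#'
#' Quantifies recovery of a known inflammation focus (e.g. from a synthetic
#' phantom): Dice coefficient `2|A&B| / (|A| + |B|)`, Jaccard index
#' `|A&B| / |A|B|`, and the Euclidean distance between the mask centroids in
#' pixels.  When both masks are empty Dice and Jaccard are defined as 1 and
#' the centroid distance as 0; when exactly one is empty they are 0 and the
#' distance is `NA`.
#'
#' @param detected,truth Logical matrices of identical shape.
#' @return A list with `dice`, `jaccard`, `centroid_distance`, `n_detected`,
#'   `n_truth`.
#' @export
evaluate_recovery <- function(detected, truth) {
  if (!is.matrix(detected) || !is.matrix(truth) ||
      !is.logical(detected) || !is.logical(truth))
    ht_precondition_error("masks must be logical matrices")
  if (!identical(dim(detected), dim(truth)))
    ht_dimension_error("mask shapes differ: %s vs %s",
                       paste(dim(detected), collapse = "x"),
                       paste(dim(truth), collapse = "x"))
  na <- sum(detected); nb <- sum(truth); ni <- sum(detected & truth)
  if (na == 0L && nb == 0L)
    return(list(dice = 1, jaccard = 1, centroid_distance = 0,
                n_detected = 0L, n_truth = 0L))
  dice <- 2 * ni / (na + nb)
  jac <- ni / (na + nb - ni)
  cd <- if (na == 0L || nb == 0L) NA_real_ else {
    ca <- colMeans(arrayInd(which(detected), dim(detected)))
    cb <- colMeans(arrayInd(which(truth), dim(truth)))
    sqrt(sum((ca - cb)^2))
  }
  list(dice = dice, jaccard = jac, centroid_distance = cd,
       n_detected = as.integer(na), n_truth = as.integer(nb))
}
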