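# Height + extent thresholding, connected components, cross-contrast
# overlap, conjunction maps, and spherical executive ROIs.

#' Threshold specification
#'
#' Strict height and extent rules, following the printed conventions
#' "t > t_min, k > k_min": voxels with t exactly at the height threshold
#' are excluded and clusters of exactly `k_min` voxels are removed.
#'
#' @param t_min voxelwise height threshold
#' @param k_min cluster extent threshold (clusters must be larger)
#' @param connectivity neighborhood: 6, 18 or 26
#' @param level `"group"` or `"participant"`
#' @return a `threshold_spec`
#' @export
threshold_spec <- function(t_min = 2.7, k_min = 250L, connectivity = 26L,
                           level = "group") {
  stopifnot(k_min >= 0, connectivity %in% c(6L, 18L, 26L),
            level %in% c("group", "participant"))
  structure(list(t_min = t_min, k_min = as.integer(k_min),
                 connectivity = as.integer(connectivity), level = level),
            class = "threshold_spec")
}

#' @rdname threshold_spec
#' @details `participant_threshold_spec()` is the liberal participant-level
#'   default (t > 1.3, k > 100).
#' @param ... passed to `threshold_spec`
#' @export
participant_threshold_spec <- function(...)
  threshold_spec(t_min = 1.3, k_min = 100L, level = "participant", ...)

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

# connected components of a 3D logical array; returns integer labels
# (0 background), labels ordered by first-encountered voxel
label_components <- function(bin, connectivity = 26L) {
  d <- dim(bin)
  labels <- array(0L, d)
  offs <- neighbor_offsets(connectivity)
  # linear-index offsets plus coordinate bookkeeping to respect borders
  idx_all <- which(bin)
  if (length(idx_all) == 0) return(labels)
  coord <- arrayInd(idx_all, d)
  inside <- array(0L, d)
  inside[idx_all] <- seq_along(idx_all)
  lab <- 0L
  assigned <- integer(length(idx_all))
  for (s in seq_along(idx_all)) {
    if (assigned[s] > 0L) next
    lab <- lab + 1L
    queue <- s
    assigned[s] <- lab
    while (length(queue) > 0) {
      cur <- coord[queue, , drop = FALSE]
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(cur, 2, offs[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1, drop = TRUE] + (nb[ok, 2] - 1) * d[1] +
          (nb[ok, 3] - 1) * d[1] * d[2]
        cand <- inside[lin]
        cand <- cand[cand > 0L]
        cand <- cand[assigned[cand] == 0L]
        if (length(cand) > 0) {
          assigned[cand] <- lab
          nxt <- c(nxt, cand)
        }
      }
      queue <- unique(nxt)
    }
  }
  labels[idx_all] <- assigned
  labels
}

#' Threshold a contrast map and label suprathreshold clusters
#'
#' Retains the strict suprathreshold set \{t > t_min\} within the mask,
#' labels its connected components under the requested neighborhood, and
#' removes components with size <= k_min.
#'
#' @param map a `contrast_map` (or bare 3D t array)
#' @param spec a [threshold_spec()]
#' @param mask optional 3D logical mask
#' @param affine optional affine for mm cluster coordinates
#' @return a `cluster_map`: integer `labels` array (0 background, labels
#'   contiguous from 1, ordered by decreasing size), logical `retained`
#'   array, and a cluster `table` (label, size, centre of mass, peak)
#' @export
threshold_and_cluster <- function(map, spec = threshold_spec(), mask = NULL,
                                  affine = NULL) {
  tarr <- if (inherits(map, "contrast_map")) map$t else map
  if (is.null(mask) && inherits(map, "contrast_map")) mask <- map$mask
  if (is.null(mask)) mask <- array(TRUE, dim(tarr))
  if (!any(mask)) stopf("empty mask")
  if (any(!is.finite(tarr[mask]))) stopf("non-finite t values within mask")
  bin <- (tarr > spec$t_min) & mask
  labels <- label_components(bin, spec$connectivity)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes > spec$k_min)
  relabel <- integer(length(sizes))
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  relabel[keep] <- seq_along(keep)
  out <- array(0L, dim(tarr))
  nz <- labels > 0L
  out[nz] <- relabel[labels[nz]]
  d <- dim(tarr)
  tab <- data.frame()
  if (length(keep) > 0) {
    tab <- do.call(rbind, lapply(seq_along(keep), function(i) {
      vox <- which(out == i)
      co <- arrayInd(vox, d)
      pk <- vox[which.max(tarr[vox])]
      com <- colMeans(co) - 1
      pkc <- arrayInd(pk, d)[1, ] - 1
      if (!is.null(affine)) {
        com <- drop(affine[1:3, 1:3] %*% com + affine[1:3, 4])
        pkc <- drop(affine[1:3, 1:3] %*% pkc + affine[1:3, 4])
      }
      data.frame(label = i, size = length(vox),
                 com_x = com[1], com_y = com[2], com_z = com[3],
                 peak_t = tarr[pk], peak_x = pkc[1], peak_y = pkc[2],
                 peak_z = pkc[3])
    }))
  }
  structure(list(labels = out, retained = out > 0L, table = tab,
                 spec = spec), class = "cluster_map")
}

retained_set <- function(x) {
  if (inherits(x, "cluster_map")) x$retained
  else if (is.logical(x)) x
  else stopf("expected a cluster_map or logical array")
}

#' Overlap percentage between two retained voxel sets
#'
#' Primary definition: `100 * mean(|A∩B|/|A|, |A∩B|/|B|)` — the average of
#' the two directional percentages. Jaccard and both directional variants
#' are returned as attributes. Two empty sets give 0.
#'
#' @param a,b `cluster_map`s or logical arrays on the same grid
#' @return the averaged percentage, with attributes `jaccard`,
#'   `a_in_b`, `b_in_a` (all percentages)
#' @export
overlap_percentage <- function(a, b) {
  A <- retained_set(a); B <- retained_set(b)
  if (!identical(dim(A), dim(B))) stopf("grid mismatch")
  na <- sum(A); nb <- sum(B); ni <- sum(A & B); nu <- sum(A | B)
  frac <- function(num, den) if (den == 0) 0 else num / den
  # a pair with any empty set overlaps 0 (an undefined direction scores 0)
  avg <- if (na > 0 && nb > 0) 100 * mean(c(ni / na, ni / nb)) else 0
  structure(avg, jaccard = 100 * frac(ni, nu),
            a_in_b = 100 * frac(ni, na), b_in_a = 100 * frac(ni, nb))
}

#' Pairwise overlap matrix over the four executive contrasts
#'
#' @param maps named list of 4 `cluster_map`s (names = contrast labels)
#' @return a symmetric 4x4 percentage matrix with diagonal 100
#' @export
overlap_matrix <- function(maps) {
  n <- length(maps)
  nm <- names(maps) %||% paste0("map", seq_len(n))
  M <- matrix(100, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- as.numeric(overlap_percentage(maps[[i]], maps[[j]]))
  }
  M
}

#' Conjunction count map
#'
#' @param maps list of `cluster_map`s (or logical arrays)
#' @return 3D integer array; voxel value = number of maps retaining it
#' @export
conjunction_count_map <- function(maps) {
  sets <- lapply(maps, retained_set)
  out <- array(0L, dim(sets[[1]]))
  for (s in sets) out <- out + s
  out
}

#' Spherical ROI set
#'
#' @param names ROI names
#' @param centers_mm n x 3 matrix of centre coordinates
#' @param radius_mm sphere radius
#' @param region region class per ROI (e.g. MFG/SMA/Prc/SPL)
#' @return an object of class `roi_set`; hemisphere is assigned from the
#'   sign of x (negative = L)
#' @export
roi_set <- function(names, centers_mm, radius_mm = 7, region = NULL) {
  centers_mm <- matrix(centers_mm, ncol = 3)
  stopifnot(radius_mm > 0, all(is.finite(centers_mm)),
            length(names) == nrow(centers_mm), !anyDuplicated(names))
  structure(list(name = as.character(names), centers_mm = centers_mm,
                 radius_mm = radius_mm,
                 hemisphere = ifelse(centers_mm[, 1] < 0, "L", "R"),
                 region = region %||% rep(NA_character_, length(names))),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d spheres, radius %.1f mm\n", length(x$name),
              x$radius_mm))
  print(data.frame(name = x$name, x = x$centers_mm[, 1],
                   y = x$centers_mm[, 2], z = x$centers_mm[, 3],
                   hemisphere = x$hemisphere, region = x$region))
  invisible(x)
}

#' Reference executive ROI sets
#'
#' `paper_executive_rois()` returns the eight published frontoparietal
#' sphere centres (MNI mm, radius 7 mm). `desk_executive_rois()` is a
#' synthetic stand-in with the same hemisphere/region structure scaled to
#' fit the default 24x28x24 desk grid (centres >= 15 mm apart so 7 mm
#' spheres never share voxels).
#'
#' @return a `roi_set`
#' @export
paper_executive_rois <- function() {
  roi_set(c("rMFG", "lMFG", "rSMA", "lSMA", "rPrc", "lPrc", "rSPL", "lSPL"),
          rbind(c(36, 2, 50), c(-37, 13, 34), c(9, 20, 47), c(-7, 9, 53),
                c(8, -62, 52), c(-13, -56, 50), c(33, -62, 45),
                c(-26, -59, 50)),
          radius_mm = 7,
          region = rep(c("MFG", "SMA", "Prc", "SPL"), each = 2))
}

#' @rdname paper_executive_rois
#' @export
desk_executive_rois <- function() {
  roi_set(c("rMFG", "lMFG", "rSMA", "lSMA", "rPrc", "lPrc", "rSPL", "lSPL"),
          rbind(c(16, 16, 14), c(-16, 16, 14), c(8, 8, 24), c(-8, 8, 24),
                c(8, -24, 22), c(-8, -24, 22), c(16, -18, 10),
                c(-16, -18, 10)),
          radius_mm = 7,
          region = rep(c("MFG", "SMA", "Prc", "SPL"), each = 2))
}

# acquisition grid that covers the published ROI centres plus sphere radius
paper_roi_acq <- function(tr_seconds = 2.5, n_volumes = 155L) {
  aff <- diag(4); diag(aff)[1:3] <- 3
  aff[1:3, 4] <- c(-45, -70, 20)
  acq_spec(tr_seconds = tr_seconds, n_volumes = n_volumes, n_dummy = 4L,
           grid_shape = c(30L, 34L, 16L), voxel_size_mm = c(3, 3, 3),
           affine = aff)
}

# logical membership array of one sphere on a grid
roi_membership <- function(rois, acq_or_vol) {
  co <- voxel_coords_mm(acq_or_vol)
  lapply(seq_along(rois$name), function(i) {
    d2 <- (co[, 1] - rois$centers_mm[i, 1])^2 +
      (co[, 2] - rois$centers_mm[i, 2])^2 +
      (co[, 3] - rois$centers_mm[i, 3])^2
    which(d2 <= rois$radius_mm^2)
  })
}

#' Derive spherical executive ROIs from cohort conjunction maps
#'
#' Voxels where at least `min_cohorts` cohort all-four-contrast conjunction
#' maps agree are clustered; each retained cluster yields one sphere at its
#' centre of mass. Hemisphere comes from the sign of x; region class from
#' the nearest prototype centre when prototypes are supplied.
#'
#' @param cohort_maps list of 3D logical arrays (voxel = all four contrasts
#'   active in that cohort)
#' @param affine voxel-to-mm affine of the maps' grid
#' @param min_cohorts minimum number of agreeing cohorts (default 2)
#' @param radius_mm sphere radius (default 7)
#' @param k_min cluster extent threshold (strict; default 10 for desk grids)
#' @param connectivity neighborhood
#' @param prototypes optional `roi_set` of labelled prototype centres
#' @return a `roi_set` (empty, with a warning, if nothing survives)
#' @export
derive_executive_rois <- function(cohort_maps, affine, min_cohorts = 2L,
                                  radius_mm = 7, k_min = 10L,
                                  connectivity = 26L, prototypes = NULL) {
  d <- dim(cohort_maps[[1]])
  for (m in cohort_maps) if (!identical(dim(m), d)) stopf("grid mismatch")
  count <- conjunction_count_map(cohort_maps)
  agree <- count >= min_cohorts
  cl <- threshold_and_cluster(array(as.numeric(agree), d),
                              threshold_spec(t_min = 0.5, k_min = k_min,
                                             connectivity = connectivity),
                              affine = affine)
  if (nrow(cl$table) == 0) {
    warnf("no clusters survive in >= %d cohorts; empty ROI set", min_cohorts)
    return(roi_set(character(0), matrix(numeric(0), 0, 3), radius_mm))
  }
  centers <- as.matrix(cl$table[, c("com_x", "com_y", "com_z")])
  region <- rep(NA_character_, nrow(centers))
  if (!is.null(prototypes)) {
    for (i in seq_len(nrow(centers))) {
      dd <- rowSums(sweep(prototypes$centers_mm, 2, centers[i, ])^2)
      region[i] <- prototypes$region[which.min(dd)]
    }
  }
  hemi <- ifelse(centers[, 1] < 0, "l", "r")
  nm <- paste0(hemi, ifelse(is.na(region), paste0("ROI", seq_len(nrow(centers))),
                            region))
  nm <- make.unique(nm)
  roi_set(nm, centers, radius_mm, region)
}

#' Participant-level active-voxel counts and overlaps at the liberal
#' threshold
#'
#' @param contrast_maps named list of 4 participant `contrast_map`s
#' @param spec a participant-level [threshold_spec()]
#' @return list with `counts` (named active-voxel counts) and `overlaps`
#'   (named vector over the 6 unordered contrast pairs, averaged
#'   percentages)
#' @export
participant_overlap_analysis <- function(contrast_maps,
                                         spec = participant_threshold_spec()) {
  cl <- lapply(contrast_maps, threshold_and_cluster, spec = spec)
  counts <- vapply(cl, function(x) sum(x$retained), numeric(1))
  nm <- names(cl)
  ov <- c(); lab <- c()
  for (i in seq_len(length(cl) - 1)) for (j in (i + 1):length(cl)) {
    ov <- c(ov, as.numeric(overlap_percentage(cl[[i]], cl[[j]])))
    lab <- c(lab, paste(nm[i], nm[j], sep = "_"))
  }
  names(ov) <- lab
  list(counts = counts, overlaps = ov)
}
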