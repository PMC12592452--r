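#' Logarithmic LISST size-class grid
#'
#' The laser diffraction instrument reports particle volume concentration in
#' 32 logarithmically spaced size classes with centers between 1.36 and
#' 230.14 µm. Centers follow a geometric progression (ratio ~1.18); bin
#' edges are placed at the geometric midpoints so that classes tile the size
#' axis contiguously, giving bandwidths from ~0.22 µm at the fine end to
#' ~38 µm at the coarse end.
#'
#' @param n_bins number of size classes.
#' @param min_center_um center of the smallest class (µm).
#' @param max_center_um center of the largest class (µm).
#' @param edges optional explicit (n_bins + 1) vector of class edges (µm)
#'   overriding the geometric reconstruction.
#' @return data.frame with columns `bin`, `center_um`, `lower_um`,
#'   `upper_um`, `bandwidth_um`.
#' @export
lisst_size_grid <- function(n_bins = 32, min_center_um = 1.36,
                            max_center_um = 230.14, edges = NULL) {
  centers <- exp(seq(log(min_center_um), log(max_center_um),
                     length.out = n_bins))
  if (is.null(edges)) {
    ratio <- (max_center_um / min_center_um)^(1 / (n_bins - 1))
    edges <- c(centers / sqrt(ratio), centers[n_bins] * sqrt(ratio))
  }
  if (length(edges) != n_bins + 1) stop("edges must have length n_bins + 1")
  data.frame(bin = seq_len(n_bins), center_um = centers,
             lower_um = edges[-(n_bins + 1)], upper_um = edges[-1],
             bandwidth_um = diff(edges))
}

#' Construct a LISST cast object
#'
#' @param depth_db numeric vector of pressures (db).
#' @param volumes matrix (length(depth_db) x 32) of volume concentrations
#'   (µL/L), columns ordered by size class.
#' @param cast_id cast identifier.
#' @param cast_type `"background"` or `"plume"`.
#' @param grid size-class grid from [lisst_size_grid()].
#' @param calibrated,binned processing-state flags.
#' @return object of class `lisst_cast`.
#' @export
lisst_cast <- function(depth_db, volumes, cast_id = "cast",
                       cast_type = c("background", "plume"),
                       grid = lisst_size_grid(),
                       calibrated = FALSE, binned = FALSE) {
  cast_type <- match.arg(cast_type)
  volumes <- as.matrix(volumes)
  if (length(depth_db) == 0) stop("empty cast")
  if (nrow(volumes) != length(depth_db)) {
    stop("volumes must have one row per depth sample")
  }
  if (ncol(volumes) != nrow(grid)) stop("volumes must have one column per size class")
  colnames(volumes) <- sprintf("bin_%02d", grid$bin)
  structure(list(cast_id = cast_id, cast_type = cast_type,
                 depth_db = as.numeric(depth_db), volumes = volumes,
                 grid = grid, calibrated = calibrated, binned = binned),
            class = "lisst_cast")
}

#' @export
print.lisst_cast <- function(x, ...) {
  cat(sprintf("LISST cast '%s' (%s): %d depth samples, %.0f-%.0f db%s%s\n",
              x$cast_id, x$cast_type, length(x$depth_db),
              min(x$depth_db), max(x$depth_db),
              if (x$binned) ", binned" else "",
              if (x$calibrated) ", calibrated" else ""))
  invisible(x)
}

#' Bin a raw cast to fixed depth intervals
#'
#' Raw profiles are over-sampled relative to the reporting grid; each size
#' class is averaged within consecutive depth intervals (1 db by default)
#' and the bin is labelled by its center. Bins with no samples are absent
#' from the output. Unordered depths are sorted first.
#'
#' @param cast a `lisst_cast`.
#' @param bin_size_db depth bin width (db).
#' @return the binned `lisst_cast`.
#' @export
bin_to_depth <- function(cast, bin_size_db = 1) {
  stopifnot(inherits(cast, "lisst_cast"))
  if (length(cast$depth_db) == 0) stop("empty cast")
  ord <- order(cast$depth_db)
  depth <- cast$depth_db[ord]
  vol <- cast$volumes[ord, , drop = FALSE]
  idx <- floor(depth / bin_size_db)
  counts <- as.vector(table(factor(idx, levels = sort(unique(idx)))))
  binned <- rowsum(vol, group = idx, reorder = TRUE) / counts
  cast$depth_db <- sort(unique(idx) + 0.5) * bin_size_db
  cast$volumes <- binned
  colnames(cast$volumes) <- sprintf("bin_%02d", cast$grid$bin)
  cast$binned <- TRUE
  cast
}

#' Baseline-calibrate a cast against its deepest quiescent segment
#'
#' Per size class, the minimum volume concentration over the deepest 10 db
#' of the cast is subtracted (the deep water below the particle features is
#' taken as the instrument's clean-water baseline), and results are floored
#' at zero. Calibration is idempotent: the deepest segment maps to zero, so
#' a second pass subtracts nothing.
#'
#' @param cast a `lisst_cast`.
#' @param window_db depth extent of the quiescent segment (db).
#' @return the calibrated `lisst_cast`.
#' @export
baseline_calibrate <- function(cast, window_db = 10) {
  stopifnot(inherits(cast, "lisst_cast"))
  span <- max(cast$depth_db) - min(cast$depth_db)
  if (span < window_db) {
    stop(sprintf("cast spans %.1f db; calibration needs >= %.0f db", span,
                 window_db))
  }
  deep <- cast$depth_db >= max(cast$depth_db) - window_db
  minima <- apply(cast$volumes[deep, , drop = FALSE], 2, min)
  cast$volumes <- pmax(sweep(cast$volumes, 2, minima, "-"), 0)
  cast$calibrated <- TRUE
  cast
}

#' Aggregate size classes into fraction volume series
#'
#' Sums class volumes whose bin centers fall inside each window
#' (half-open, `[lower, upper)` µm). Assignment is by bin center, not
#' partial-bin splitting, matching how the fractions are labelled.
#'
#' @param cast a `lisst_cast` (calibrate first for physically meaningful
#'   totals).
#' @param windows named list of `c(lower, upper)` µm windows; defaults to
#'   the small (1.25–6 µm) and large (6–250 µm) fractions.
#' @return data.frame with `depth_db`, one µL/L column per window, and
#'   `total_ul_l` over all windowed bins.
#' @export
aggregate_fractions <- function(cast,
                                windows = list(small = c(1.25, 6),
                                               large = c(6, 250))) {
  stopifnot(inherits(cast, "lisst_cast"))
  out <- data.frame(depth_db = cast$depth_db)
  used <- rep(FALSE, nrow(cast$grid))
  for (w in names(windows)) {
    win <- windows[[w]]
    sel <- cast$grid$center_um >= win[1] & cast$grid$center_um < win[2]
    if (any(sel & used)) {
      warning("windows overlap; bins assigned to the first matching window")
      sel <- sel & !used
    }
    used <- used | sel
    out[[paste0(w, "_ul_l")]] <- rowSums(cast$volumes[, sel, drop = FALSE])
  }
  out$total_ul_l <- rowSums(cast$volumes[, used, drop = FALSE])
  out
}

#' Convert volume concentrations to number concentrations
#'
#' Particles are modelled as spheres at the class center diameter:
#' `N_i = V_i / ((pi/6) d_i^3)`, with volumes in µL/L
#' (1 µL = 1e12 µm^3) and counts in particles/L.
#'
#' @param cast a `lisst_cast`.
#' @param windows fraction windows as in [aggregate_fractions()].
#' @return list with `counts` (matrix, particles/L per class) and
#'   `fractions` (data.frame of per-depth summed counts per window).
#' @export
volume_to_counts <- function(cast,
                             windows = list(small = c(1.25, 6),
                                            large = c(6, 250))) {
  stopifnot(inherits(cast, "lisst_cast"))
  per_particle_ul <- (pi / 6) * cast$grid$center_um^3 / 1e12 # µL per sphere
  counts <- sweep(cast$volumes, 2, per_particle_ul, "/")
  fr <- data.frame(depth_db = cast$depth_db)
  for (w in names(windows)) {
    win <- windows[[w]]
    sel <- cast$grid$center_um >= win[1] & cast$grid$center_um < win[2]
    fr[[paste0(w, "_per_l")]] <- rowSums(counts[, sel, drop = FALSE])
  }
  list(counts = counts, fractions = fr)
}

#' Modal diameters of the particle size distribution
#'
#' Within a depth window, size classes are averaged over depth and the bin
#' center(s) maximizing mean volume concentration are reported. Ties are
#' all reported; an all-zero window reports none.
#'
#' @param cast a `lisst_cast`.
#' @param depth_window `c(lower, upper)` db window (default whole cast).
#' @param tol relative tolerance for declaring a tie with the maximum.
#' @return numeric vector of modal bin centers (µm); length 0 if the
#'   window is empty of volume.
#' @export
psd_maxima <- function(cast, depth_window = range(cast$depth_db),
                       tol = 1e-9) {
  stopifnot(inherits(cast, "lisst_cast"))
  sel <- cast$depth_db >= depth_window[1] & cast$depth_db <= depth_window[2]
  if (!any(sel)) return(numeric(0))
  psd <- colMeans(cast$volumes[sel, , drop = FALSE])
  if (max(psd) <= 0) return(numeric(0))
  cast$grid$center_um[psd >= max(psd) * (1 - tol)]
}
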