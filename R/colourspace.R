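# Avian tetrahedral colourspace for the violet-sensitive (VS) visual system.
#
# Coordinate convention (the standard avian tetrahedral colourspace): the
# achromatic point (equal relative stimulation of all four cones) sits at the
# origin and the four pure-receptor points are vertices at distance 0.75 from
# it, with the v (violet) vertex on the vertical (z) axis:
#   x = sqrt(3/2) * (1 - 2s - m - v) / 2
#   y = (-1 + 3m + v) / (2 * sqrt(2))
#   z = v - 1/4
# The map is affine and invertible on the simplex.

.channel_names <- c("v", "s", "m", "l")

#' Convert receptor (cone-catch) values to relative stimuli
#'
#' Each record's four receptor values are divided by their sum, giving a point
#' on the 3-simplex (components in `[0, 1]`, summing to 1); the achromatic
#' (luminance) dimension is thereby removed.
#'
#' @param q numeric vector of length 4, or a matrix/data.frame with four
#'   columns ordered v, s, m, l (columns named `channel_*` or `v/s/m/l` are
#'   picked up by name).
#' @return matrix with columns `v, s, m, l`, one row per record.
#' @export
to_relative_stimuli <- function(q) {
  q <- .as_channel_matrix(q)
  if (any(q < 0)) stop("receptor values must be non-negative")
  tot <- rowSums(q)
  if (any(tot <= 0))
    stop("all-zero receptor record(s) at row(s) ",
         paste(which(tot <= 0), collapse = ", "),
         ": chromaticity undefined")
  out <- q / tot
  colnames(out) <- .channel_names
  out
}

.as_channel_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  cn <- colnames(q)
  if (!is.null(cn)) {
    # subset named channel columns *before* matrix coercion: as.matrix() on a
    # mixed data.frame would round the numbers through format()
    if (all(paste0("channel_", .channel_names) %in% cn))
      q <- q[, paste0("channel_", .channel_names), drop = FALSE]
    else if (all(.channel_names %in% cn))
      q <- q[, .channel_names, drop = FALSE]
  }
  q <- as.matrix(q)
  if (ncol(q) != 4) stop("expected four receptor channels (v, s, m, l)")
  storage.mode(q) <- "double"
  colnames(q) <- .channel_names
  q
}

#' Project relative cone stimuli into the tetrahedral colourspace
#'
#' @param usml matrix (or vector) of relative stimuli `v, s, m, l`; rows must
#'   sum to 1 within `tol`.
#' @param tol tolerance on the simplex constraint.
#' @return matrix with columns `x, y, z`.
#' @export
to_tetrahedral <- function(usml, tol = 1e-8) {
  usml <- .as_channel_matrix(usml)
  if (any(abs(rowSums(usml) - 1) > tol))
    stop("relative stimuli must sum to 1 (within ", tol, ")")
  v <- usml[, "v"]; s <- usml[, "s"]; m <- usml[, "m"]
  cbind(x = sqrt(3 / 2) * (1 - 2 * s - m - v) / 2,
        y = (-1 + 3 * m + v) / (2 * sqrt(2)),
        z = v - 0.25)
}

#' Invert the tetrahedral projection back to relative stimuli
#'
#' @param xyz matrix (or length-3 vector) of tetrahedral coordinates.
#' @return matrix of relative stimuli `v, s, m, l` (rows sum to 1).  Fails if
#'   any point lies outside the tetrahedron (negative stimuli).
#' @export
tetrahedral_to_stimuli <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("expected three columns (x, y, z)")
  v <- xyz[, 1] * 0 + xyz[, 3] + 0.25
  m <- (2 * sqrt(2) * xyz[, 2] + 1 - v) / 3
  s <- (1 - m - v - 2 * xyz[, 1] / sqrt(3 / 2)) / 2
  l <- 1 - v - s - m
  out <- cbind(v = v, s = s, m = m, l = l)
  if (any(out < -1e-9))
    stop("point(s) outside the colour tetrahedron (negative relative stimuli)")
  pmax(out, 0)
}

#' Fit a polynomial mapping from device colour channels to cone catches
#'
#' Ordinary least squares per receptor: each of the four receptor channels is
#' regressed on the device channels (degree 1) or on the device channels plus
#' their squares and pairwise products (degree 2).  The per-receptor Pearson
#' correlation between fitted and known values is reported as the validation
#' diagnostic.
#'
#' @param device matrix/data.frame of device channel values (rows = calibration
#'   pairs), non-negative.
#' @param cone matrix/data.frame of known receptor stimulation values, four
#'   columns (v, s, m, l).
#' @param degree 1 (linear) or 2 (quadratic with interactions).
#' @return object of class `device_mapping`: coefficients (terms x 4
#'   receptors), per-receptor `r`, `degree`, term labels.
#' @export
fit_device_mapping <- function(device, cone, degree = 1) {
  device <- as.matrix(device)
  cone <- .as_channel_matrix(cone)
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  if (nrow(device) != nrow(cone))
    stop("device and cone tables must have the same number of rows")
  X <- .mapping_design(device, degree)
  if (nrow(X) < ncol(X))
    stop("underdetermined fit: ", nrow(X), " calibration pairs for ",
         ncol(X), " coefficients per receptor")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient calibration design (rank ", qrX$rank, " < ",
         ncol(X), " coefficients); affected receptors: ",
         paste(.channel_names, collapse = ", "))
  coef <- qr.coef(qrX, cone)
  fitted <- X %*% coef
  r <- vapply(seq_len(4), function(j) {
    if (sd(cone[, j]) == 0 || sd(fitted[, j]) == 0) return(NA_real_)
    stats::cor(fitted[, j], cone[, j])
  }, numeric(1))
  names(r) <- .channel_names
  structure(list(coefficients = coef, r = r, degree = degree,
                 terms = colnames(X)),
            class = "device_mapping")
}

.mapping_design <- function(device, degree) {
  if (is.null(colnames(device)))
    colnames(device) <- paste0("d", seq_len(ncol(device)))
  X <- cbind(`(Intercept)` = 1, device)
  if (degree == 2) {
    k <- ncol(device)
    sq <- device^2
    colnames(sq) <- paste0(colnames(device), "^2")
    X <- cbind(X, sq)
    if (k >= 2) {
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        cp <- device[, i] * device[, j]
        X <- cbind(X, cp)
        colnames(X)[ncol(X)] <- paste0(colnames(device)[i], ":",
                                       colnames(device)[j])
      }
    }
  }
  X
}

#' Predict cone catches from device channels with a fitted mapping
#'
#' @param mapping a `device_mapping`.
#' @param device device channel matrix.
#' @return matrix of predicted receptor values (columns v, s, m, l).
#' @export
predict_cone_catch <- function(mapping, device) {
  stopifnot(inherits(mapping, "device_mapping"))
  X <- .mapping_design(as.matrix(device), mapping$degree)
  out <- X %*% mapping$coefficients
  colnames(out) <- .channel_names
  out
}

#' @export
print.device_mapping <- function(x, ...) {
  cat("Device-to-cone-catch mapping (degree ", x$degree, ")\n", sep = "")
  cat("validation r per receptor:\n")
  print(round(x$r, 4))
  invisible(x)
}

#' Principal component analysis of tetrahedral colourspace points
#'
#' Centred (unscaled) PCA of `(x, y, z)` points pooled across species, sexes
#' and patches, giving one common set of colour axes.  For reproducibility the
#' sign of each axis is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param xyz matrix of tetrahedral coordinates (>= 3 distinct rows).
#' @return object of class `colour_pca`: `scores`, `loadings` (columns PC1-3),
#'   `var_explained`, `center`.
#' @export
pca_colourspace <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3)
    stop("need at least 3 points for a colourspace PCA")
  if (nrow(unique(xyz)) < 2)
    stop("degenerate input: all colour points identical")
  pc <- prcomp(xyz, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation, var_explained = ve,
                 center = pc$center),
            class = "colour_pca")
}

#' Project new tetrahedral points onto fitted colour PC axes
#'
#' @param pca a `colour_pca`.
#' @param xyz matrix of points.
#' @return score matrix (same columns as the PCA).
#' @export
project_colour_pca <- function(pca, xyz) {
  stopifnot(inherits(pca, "colour_pca"))
  sweep(as.matrix(xyz), 2, pca$center) %*% pca$loadings
}

#' Species-level colour profiles from specimen records
#'
#' Converts each specimen's receptor channels to tetrahedral coordinates,
#' averages within species x sex x patch cells, reports per-cell specimen
#' counts and dispersion (root mean squared distance to the cell mean), and
#' attaches PC1/PC2 scores from one common colourspace PCA fitted to the cell
#' means pooled across species, sexes and patches.
#'
#' @param records data.frame with columns `species`, `sex`, `specimen`,
#'   `patch`, `channel_v`, `channel_s`, `channel_m`, `channel_l` (a
#'   `colour_dataset` is also accepted).
#' @return object of class `colour_profile`: data.frame (`species`, `sex`,
#'   `patch`, `x`, `y`, `z`, `pc1`, `pc2`, `n_specimens`, `dispersion`) with
#'   the fitted `colour_pca` in attribute `pca`.
#' @export
species_means <- function(records) {
  if (inherits(records, "colour_dataset")) records <- records$specimens
  need <- c("species", "sex", "specimen", "patch",
            paste0("channel_", .channel_names))
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("specimen table lacks column(s): ", paste(miss, collapse = ", "))
  xyz <- to_tetrahedral(to_relative_stimuli(records))
  keystr <- paste(records$species, records$sex, records$patch, sep = "\x1f")
  key <- factor(keystr)
  idx <- split(seq_len(nrow(xyz)), key)
  agg <- t(vapply(idx, function(i) colMeans(xyz[i, , drop = FALSE]),
                  numeric(3)))
  counts <- as.integer(lengths(idx))
  disp <- vapply(seq_along(idx), function(k) {
    d <- xyz[idx[[k]], , drop = FALSE]
    sqrt(mean(rowSums(sweep(d, 2, agg[k, ])^2)))
  }, numeric(1))
  first <- match(levels(key), keystr)
  prof <- data.frame(species = records$species[first],
                     sex = records$sex[first],
                     patch = records$patch[first],
                     x = agg[, 1], y = agg[, 2],
                     z = agg[, 3], n_specimens = counts, dispersion = disp,
                     row.names = NULL, stringsAsFactors = FALSE)
  # completeness: every species must have every sex x patch cell
  all_cells <- expand.grid(species = unique(prof$species),
                           sex = unique(prof$sex),
                           patch = unique(prof$patch),
                           stringsAsFactors = FALSE)
  have <- paste(prof$species, prof$sex, prof$patch)
  missing_cells <- all_cells[!paste(all_cells$species, all_cells$sex,
                                    all_cells$patch) %in% have, ]
  if (nrow(missing_cells))
    stop("missing species x sex x patch cell(s): ",
         paste(paste(missing_cells$species, missing_cells$sex,
                     missing_cells$patch, sep = "/"), collapse = "; "))
  pts <- as.matrix(prof[, c("x", "y", "z")])
  if (nrow(pts) >= 3 && nrow(unique(pts)) >= 2) {
    pca <- pca_colourspace(pts)
    prof$pc1 <- pca$scores[, 1]
    prof$pc2 <- pca$scores[, 2]
  } else {
    pca <- NULL
    prof$pc1 <- NA_real_
    prof$pc2 <- NA_real_
  }
  prof <- prof[order(prof$species, prof$sex, prof$patch),
               c("species", "sex", "patch", "x", "y", "z", "pc1", "pc2",
                 "n_specimens", "dispersion")]
  rownames(prof) <- NULL
  structure(prof, pca = pca, class = c("colour_profile", "data.frame"))
}

#' Per-species plumage dichromatism
#'
#' For each species and patch, the Euclidean distance in tetrahedral
#' coordinates between the male and female mean points; aggregated across
#' patches by the mean (the usual dichromatism proxy) or the maximum (the
#' maximum extent of colour difference across body regions).
#'
#' @param profile a `colour_profile` (or data.frame with its columns).
#' @param variant `"mean"` or `"max"`.
#' @return data.frame (`species`, `dichromatism`, `variant`).  Species missing
#'   one sex are dropped with a warning and listed in attribute `excluded`.
#' @export
compute_dichromatism <- function(profile, variant = c("mean", "max")) {
  variant <- match.arg(variant)
  m <- profile[profile$sex == "male", ]
  f <- profile[profile$sex == "female", ]
  key_m <- paste(m$species, m$patch)
  key_f <- paste(f$species, f$patch)
  common <- intersect(key_m, key_f)
  excluded <- setdiff(union(unique(m$species), unique(f$species)),
                      intersect(unique(m$species), unique(f$species)))
  if (length(excluded))
    warning("species missing one sex, excluded: ",
            paste(excluded, collapse = ", "))
  m <- m[match(common, key_m), ]
  f <- f[match(common, key_f), ]
  d <- sqrt((m$x - f$x)^2 + (m$y - f$y)^2 + (m$z - f$z)^2)
  agg <- tapply(d, m$species, if (variant == "mean") mean else max)
  out <- data.frame(species = names(agg), dichromatism = as.vector(agg),
                    variant = variant, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Classify colours into colouration-mechanism categories
#'
#' Deterministic three-way classification of a colour point by its dominant
#' receptor-stimulation pattern: long-wavelength-dominated points (relative
#' l-stimulation at least `th_l`) are consistent with carotenoid pigmentation;
#' otherwise short-wavelength-dominated points (relative v + s at least
#' `th_vs`) are consistent with structural colouration; everything else is
#' intermediate.  The default thresholds make the three regions exhaustive and
#' non-overlapping, with the achromatic centre falling in the intermediate
#' category.
#'
#' @param x a `colour_profile`, a matrix of tetrahedral `(x, y, z)`
#'   coordinates, or a matrix of relative stimuli `(v, s, m, l)`.
#' @param th_l threshold on relative l-stimulation for carotenoid-consistent.
#' @param th_vs threshold on relative v + s for structural-consistent.
#' @return factor with levels `carotenoid`, `intermediate`, `structural`.
#' @export
classify_mechanism <- function(x, th_l = 0.4, th_vs = 0.55) {
  if (inherits(x, "colour_profile") ||
      (is.data.frame(x) && all(c("x", "y", "z") %in% names(x))))
    x <- as.matrix(x[, c("x", "y", "z")])
  x <- as.matrix(x)
  usml <- if (ncol(x) == 3) tetrahedral_to_stimuli(x) else
    .as_channel_matrix(x)
  lab <- ifelse(usml[, "l"] >= th_l, "carotenoid",
                ifelse(usml[, "v"] + usml[, "s"] >= th_vs, "structural",
                       "intermediate"))
  factor(lab, levels = c("carotenoid", "intermediate", "structural"))
}
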