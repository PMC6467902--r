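# Synthetic colour datasets with known ground truth.
#
# The generator emulates the structure of a museum-style plumage dataset:
# species x sex x specimen x patch rows of four receptor-channel values for a
# violet-sensitive visual system, produced by (i) simulating 2-D (PC-like)
# patch colour values under sex-specific variable-rate Brownian motion,
# (ii) optionally biasing the direction of tip displacements on fast terminal
# branches, (iii) adding isotropic specimen-level noise, and (iv) encoding
# each specimen point as receptor channels by inverting the tetrahedral
# projection, so that the colourspace module can round-trip the values.

# Sample from a von Mises distribution (Best & Fisher 1979 rejection method).
# mu in radians; kappa = 0 gives the circular uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

# The 10 plumage patches measured on each specimen.
plumage_patches <- c("crown", "nape", "mantle", "rump", "tail",
                     "wing_coverts", "wing_primaries", "throat", "breast",
                     "belly")

#' Simulate a specimen-level colour dataset with known ground truth
#'
#' For each sex and patch, 2-D patch colour values evolve by Brownian motion
#' under the sex's rate regime.  On "fast" terminal branches — those whose
#' effective scalar strictly exceeds the `fast_quantile` quantile of terminal
#' scalars — the direction of the terminal displacement is redrawn from a von
#' Mises distribution centred on `bias_angle` with concentration
#' `bias_concentration` (magnitude kept), injecting a known directional bias
#' into recent fast divergence.  `bias_concentration = 0` leaves directions
#' isotropic.  Specimen replicates add isotropic Gaussian noise with standard
#' deviation `intraspecific_sd` per axis.  `male_offset` is added to every
#' male patch value, programming a known level of dichromatism.
#'
#' All values are then rescaled by a common factor `pc_scale` so the most
#' extreme specimen lies inside the colour tetrahedron, and encoded as
#' receptor channels by inverting the tetrahedral projection with the point
#' placed in the z = 0 plane (PC1 along x, PC2 along y).
#'
#' @param tree a `phylo` tree; tip labels become species names.
#' @param regime_male,regime_female `rate_regime` objects (or `NULL` for
#'   homogeneous unit-rate regimes).
#' @param n_patches number of patches (1-10, named from the standard set).
#' @param n_specimens specimens per species and sex.
#' @param intraspecific_sd specimen noise sd per PC axis (same units as the
#'   simulated PC values).
#' @param male_offset length-2 numeric added to male PC values (dichromatism
#'   ground truth).
#' @param bias_angle direction (degrees) toward which fast terminal
#'   displacements are biased; `NULL` disables direction redrawing entirely.
#' @param bias_concentration von Mises concentration (>= 0; 0 = isotropic).
#' @param fast_quantile quantile of terminal-branch scalars above which a
#'   branch counts as fast (strict exceedance).
#' @param shared_sex_draw if `TRUE`, both sexes share the same per-patch
#'   Brownian realisation (the male adds `male_offset`), so the programmed
#'   dichromatism equals `male_offset` exactly up to specimen noise; with the
#'   default `FALSE` the sexes are independent draws and dichromatism emerges
#'   from their divergence.
#' @param seed optional integer seed.
#' @return an object of class `colour_dataset`: list with `specimens` (tidy
#'   data.frame: species, sex, specimen, patch, channel_v/s/m/l), `true_tips`
#'   (species, sex, patch, pc1, pc2), `displacements` (per sex/patch/species:
#'   terminal displacement components, angle in degrees, and whether the
#'   branch was fast), `true_rates` (per-sex per-edge scalar vectors),
#'   `fast_edges`, `pc_scale`, and the simulation parameters.
#' @export
simulate_colour_dataset <- function(tree, regime_male = NULL,
                                    regime_female = NULL, n_patches = 10,
                                    n_specimens = 3, intraspecific_sd = 0.02,
                                    male_offset = c(0, 0), bias_angle = NULL,
                                    bias_concentration = 0,
                                    fast_quantile = 0.9,
                                    shared_sex_draw = FALSE, seed = NULL) {
  check_tree(tree)
  if (n_patches < 1 || n_patches > length(plumage_patches))
    stop("n_patches must be between 1 and ", length(plumage_patches))
  if (n_specimens < 1) stop("n_specimens must be >= 1")
  if (bias_concentration < 0) stop("bias_concentration must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  patches <- plumage_patches[seq_len(n_patches)]
  ntip <- ape::Ntip(tree)
  terminal <- which(tree$edge[, 2L] <= ntip)
  tip_of_terminal <- tree$edge[terminal, 2L]
  parent_of_terminal <- tree$edge[terminal, 1L]
  regimes <- list(male = regime_male, female = regime_female)

  true_tips <- list()
  displacements <- list()
  shared_draws <- list()
  fast_edges <- list(male = integer(0), female = integer(0))
  true_rates <- list()
  for (sex in c("male", "female")) {
    reg <- regimes[[sex]]
    r <- if (is.null(reg)) rep(1, nrow(tree$edge)) else
      regime_scalars(reg, tree)
    true_rates[[sex]] <- r
    thr <- quantile(r[terminal], fast_quantile, names = FALSE)
    fast <- terminal[r[terminal] > thr]
    fast_edges[[sex]] <- fast
    is_fast <- terminal %in% fast
    if (!is.null(bias_angle) && bias_concentration > 0 && !length(fast))
      warning("directional bias requested for ", sex,
              " but no terminal branch exceeds the fast-rate threshold; ",
              "bias is vacuous")
    for (patch in patches) {
      if (shared_sex_draw && sex == "female") {
        vals <- shared_draws[[patch]]
      } else {
        vals <- .simulate_bm_nodes(tree, reg, root_state = c(0, 0))$values
      }
      if (!is.null(bias_angle) && length(fast) &&
          !(shared_sex_draw && sex == "female")) {
        idx <- tree$edge[fast, 2L]
        delta <- vals[idx, , drop = FALSE] -
          vals[tree$edge[fast, 1L], , drop = FALSE]
        mag <- sqrt(rowSums(delta^2))
        th <- rvonmises(length(fast), bias_angle * pi / 180,
                        bias_concentration)
        vals[idx, ] <- vals[tree$edge[fast, 1L], , drop = FALSE] +
          mag * cbind(cos(th), sin(th))
      }
      if (shared_sex_draw && sex == "male") shared_draws[[patch]] <- vals
      tips <- vals[seq_len(ntip), , drop = FALSE]
      rownames(tips) <- tree$tip.label
      if (sex == "male") tips <- sweep(tips, 2L, male_offset, `+`)
      d <- vals[tip_of_terminal, , drop = FALSE] -
        vals[parent_of_terminal, , drop = FALSE]
      displacements[[length(displacements) + 1L]] <- data.frame(
        species = tree$tip.label[tip_of_terminal], sex = sex, patch = patch,
        d1 = d[, 1L], d2 = d[, 2L],
        angle = (atan2(d[, 2L], d[, 1L]) * 180 / pi) %% 360,
        fast = is_fast, row.names = NULL, stringsAsFactors = FALSE)
      true_tips[[length(true_tips) + 1L]] <- data.frame(
        species = rownames(tips), sex = sex, patch = patch,
        pc1 = tips[, 1L], pc2 = tips[, 2L], row.names = NULL,
        stringsAsFactors = FALSE)
    }
  }
  true_tips <- do.call(rbind, true_tips)
  displacements <- do.call(rbind, displacements)

  # specimen replicates with isotropic noise
  spec <- true_tips[rep(seq_len(nrow(true_tips)), each = n_specimens), ]
  spec$specimen <- paste0(spec$species, "_", substr(spec$sex, 1, 1),
                          rep_len(seq_len(n_specimens), nrow(spec)))
  spec$pc1 <- spec$pc1 + rnorm(nrow(spec), 0, intraspecific_sd)
  spec$pc2 <- spec$pc2 + rnorm(nrow(spec), 0, intraspecific_sd)

  # common rescaling into the tetrahedron (inradius 0.25; keep a margin)
  maxr <- max(sqrt(spec$pc1^2 + spec$pc2^2),
              sqrt(true_tips$pc1^2 + true_tips$pc2^2))
  pc_scale <- if (maxr > 0) 0.23 / maxr else 1
  xyz <- cbind(x = spec$pc1 * pc_scale, y = spec$pc2 * pc_scale, z = 0)
  ch <- tetrahedral_to_stimuli(xyz)
  specimens <- data.frame(
    species = spec$species, sex = spec$sex, specimen = spec$specimen,
    patch = spec$patch,
    channel_v = ch[, "v"], channel_s = ch[, "s"], channel_m = ch[, "m"],
    channel_l = ch[, "l"], row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    specimens = specimens, true_tips = true_tips,
    displacements = displacements, true_rates = true_rates,
    fast_edges = fast_edges, pc_scale = pc_scale, patches = patches,
    n_specimens = n_specimens, intraspecific_sd = intraspecific_sd,
    male_offset = male_offset,
    bias = list(angle = bias_angle, concentration = bias_concentration,
                fast_quantile = fast_quantile),
    tree_tips = tree$tip.label
  ), class = "colour_dataset")
}

#' @export
print.colour_dataset <- function(x, ...) {
  cat("Synthetic colour dataset:",
      length(unique(x$specimens$species)), "species x 2 sexes x",
      x$n_specimens, "specimens x", length(x$patches), "patches\n")
  cat("pc_scale:", signif(x$pc_scale, 6),
      " intraspecific_sd:", x$intraspecific_sd, "\n")
  invisible(x)
}

#' Write the specimen table of a colour dataset as tidy CSV
#'
#' @param dataset a `colour_dataset` (or any data.frame with the specimen
#'   columns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_colour_dataset <- function(dataset, path) {
  df <- if (inherits(dataset, "colour_dataset")) dataset$specimens else dataset
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
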