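# End-to-end orchestration: simulate -> colourspace -> variable rates (per
# sex) -> TRES -> RMA -> direction bias, with deterministic per-stage seeds,
# resumable stages and a JSON run manifest.

#' Read and validate a tree file
#'
#' Newick (`.nwk`, `.tre`, `.txt`) or NEXUS (`.nex`, `.nexus`) by extension.
#' Fails on duplicate or empty tip labels or missing branch lengths.
#'
#' @param path tree file.
#' @return a `phylo` tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tree <- if (ext %in% c("nex", "nexus")) ape::read.nexus(path) else
    ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabelled tips")
  if (anyDuplicated(tree$tip.label))
    stop("tree has duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  check_tree(tree)
}

#' Write a tree as Newick or NEXUS
#'
#' Branch lengths are written with 15 significant digits so that a
#' write/read round trip preserves them.
#'
#' @param tree a `phylo` tree.
#' @param path output path; `.nex`/`.nexus` selects NEXUS.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  check_tree(tree)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nex", "nexus")) {
    old <- options(digits = 15); on.exit(options(old))
    ape::write.nexus(tree, file = path)
  } else {
    cat(ape::write.tree(tree, digits = 15), "\n", sep = "", file = path)
  }
  invisible(path)
}

#' Read a trait / measurement CSV with header validation
#'
#' @param path CSV file.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
read_traits <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("'", basename(path), "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' field overridable.  `scale = "test"` uses a small tree, few patches and
#' short chains (minutes on one CPU); `scale = "full"` uses study-sized
#' settings (hundreds of tips, 10 patches, 1e6-iteration chains).
#'
#' @param out_dir output directory.
#' @param seed top-level integer seed; all stage seeds derive from it
#'   (stage k uses `seed + k`).
#' @param scale `"test"` or `"full"`.
#' @param ... named overrides for any top-level config entry (`sim`,
#'   `chain`, `segments` are themselves lists and are merged field-wise).
#' @return a config list.
#' @export
pipeline_config <- function(out_dir, seed = 1, scale = c("test", "full"),
                            ...) {
  scale <- match.arg(scale)
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), scale = scale,
    sim = list(
      n_tips = if (scale == "test") 16L else 372L,
      birth_rate = 1, death_rate = 0,
      n_clade_shifts = 1L, n_branch_shifts = 1L, log_scalar_sd = 1,
      min_clade_size = if (scale == "test") 4L else 10L,
      n_patches = if (scale == "test") 2L else 10L,
      n_specimens = 3L, intraspecific_sd = 0.02,
      male_offset = c(0, 0), bias_angle = NULL, bias_concentration = 0,
      sigma2 = c(1, 0.6), trait_corr = 0.3),
    chain = list(
      iterations = if (scale == "test") 2e4 else 1e6,
      burnin = 0.25,
      thin = if (scale == "test") 20 else 1000),
    segments = list(width = 20, n_perm = if (scale == "test") 200L else
      1000L),
    stages = c("simulate", "colourspace", "rates", "tres", "rma",
               "direction")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

.stage_outputs <- function(cfg) {
  d <- cfg$out_dir
  patches <- plumage_patches[seq_len(cfg$sim$n_patches)]
  list(
    simulate = file.path(d, c("tree.nwk", "specimens.csv", "true_tips.csv",
                              "regime_male.yml", "regime_female.yml",
                              "truth.json")),
    colourspace = file.path(d, c("profile.csv", "pca_loadings.csv",
                                 "dichromatism.csv")),
    rates = file.path(d, c(
      paste0("phenogram_", c("male", "female"), ".nwk"),
      paste0("branches_", c("male", "female"), ".csv"),
      paste0("posterior_", c("male", "female"), ".csv"),
      as.vector(outer(c("male", "female"), patches,
                      function(s, p) paste0("branches_", s, "_", p,
                                            ".csv"))))),
    tres = file.path(d, "tres.csv"),
    rma = file.path(d, "rma.csv"),
    direction = file.path(d, c("trajectories.csv", "segments_all.csv",
                               "segments_male.csv", "segments_female.csv"))
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing each stage's outputs
#' before the next starts.  A stage whose declared outputs all exist is
#' skipped (resume semantics) unless `force = TRUE`.  Re-running with the
#' same config and seed reproduces byte-identical tables.  A JSON manifest
#' (config, stage seeds, timings, file list) is written at the end.
#'
#' @param config a config list from [pipeline_config()], or a path to a
#'   YAML file holding one.
#' @param force re-run stages even when their outputs exist.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    do.call(pipeline_config, c(raw[c("out_dir", "seed", "scale")],
                               raw[setdiff(names(raw),
                                           c("out_dir", "seed",
                                             "scale"))]))
  } else config
  if (is.null(cfg$out_dir)) stop("config lacks out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- .stage_outputs(cfg)
  unknown <- setdiff(cfg$stages, names(outputs))
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  # fail-fast: every requested stage's inputs must be producible
  need <- match(cfg$stages, names(outputs))
  if (any(diff(need) <= 0))
    stop("stages must be in dependency order: ",
         paste(names(outputs), collapse = " -> "))
  stage_fns <- list(simulate = .stage_simulate,
                    colourspace = .stage_colourspace,
                    rates = .stage_rates, tres = .stage_tres,
                    rma = .stage_rma, direction = .stage_direction)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("plumrates")),
                   seed = cfg$seed, scale = cfg$scale,
                   config = cfg[c("sim", "chain", "segments")],
                   stages = list())
  for (k in seq_along(cfg$stages)) {
    st <- cfg$stages[k]
    outs <- outputs[[st]]
    if (!force && all(file.exists(outs))) {
      message("stage '", st, "': outputs exist, skipping")
      manifest$stages[[st]] <- list(status = "skipped")
      next
    }
    stage_seed <- cfg$seed + match(st, names(outputs))
    t0 <- proc.time()[["elapsed"]]
    message("stage '", st, "' (seed ", stage_seed, ") ...")
    ok <- try(stage_fns[[st]](cfg, stage_seed), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("stage '", st, "' failed: ", attr(ok, "condition")$message)
    manifest$stages[[st]] <- list(status = "run", seed = stage_seed,
                                  elapsed_s = round(proc.time()[["elapsed"]]
                                                    - t0, 2),
                                  files = basename(outs))
    stopifnot(all(file.exists(outs)))
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.stage_simulate <- function(cfg, seed) {
  s <- cfg$sim
  tree <- simulate_tree(s$n_tips, s$birth_rate, s$death_rate, seed = seed)
  corr <- matrix(c(1, s$trait_corr, s$trait_corr, 1), 2)
  reg_m <- assign_rate_regime(tree, s$n_clade_shifts, s$n_branch_shifts,
                              s$log_scalar_sd, s$min_clade_size,
                              sigma2 = s$sigma2, corr = corr)
  reg_f <- assign_rate_regime(tree, s$n_clade_shifts, s$n_branch_shifts,
                              s$log_scalar_sd, s$min_clade_size,
                              sigma2 = s$sigma2, corr = corr)
  ds <- simulate_colour_dataset(tree, reg_m, reg_f, s$n_patches,
                                s$n_specimens, s$intraspecific_sd,
                                s$male_offset, s$bias_angle,
                                s$bias_concentration)
  write_tree(tree, file.path(cfg$out_dir, "tree.nwk"))
  write_colour_dataset(ds, file.path(cfg$out_dir, "specimens.csv"))
  write.csv(ds$true_tips, file.path(cfg$out_dir, "true_tips.csv"),
            row.names = FALSE)
  write_regime(reg_m, file.path(cfg$out_dir, "regime_male.yml"))
  write_regime(reg_f, file.path(cfg$out_dir, "regime_female.yml"))
  jsonlite::write_json(
    list(pc_scale = ds$pc_scale, fast_edges = ds$fast_edges,
         true_rates = ds$true_rates),
    file.path(cfg$out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
}

.stage_colourspace <- function(cfg, seed) {
  rec <- read_traits(file.path(cfg$out_dir, "specimens.csv"),
                     c("species", "sex", "specimen", "patch", "channel_v",
                       "channel_s", "channel_m", "channel_l"))
  prof <- species_means(rec)
  pca <- attr(prof, "pca")
  write.csv(as.data.frame(prof), file.path(cfg$out_dir, "profile.csv"),
            row.names = FALSE)
  load <- data.frame(axis = colnames(pca$loadings),
                     t(pca$loadings),
                     var_explained = pca$var_explained)
  names(load)[2:4] <- c("x", "y", "z")
  write.csv(load, file.path(cfg$out_dir, "pca_loadings.csv"),
            row.names = FALSE)
  di <- rbind(compute_dichromatism(prof, "mean"),
              compute_dichromatism(prof, "max"))
  write.csv(di, file.path(cfg$out_dir, "dichromatism.csv"),
            row.names = FALSE)
}

.stage_rates <- function(cfg, seed) {
  tree <- read_tree(file.path(cfg$out_dir, "tree.nwk"))
  prof <- read_traits(file.path(cfg$out_dir, "profile.csv"),
                      c("species", "sex", "patch", "pc1", "pc2"))
  patches <- plumage_patches[seq_len(cfg$sim$n_patches)]
  for (sex in c("male", "female")) {
    sub <- prof[prof$sex == sex, ]
    # whole-plumage trait matrix: PC1/PC2 of each patch side by side
    wide <- NULL
    for (p in patches) {
      pp <- sub[sub$patch == p, ]
      M <- as.matrix(pp[, c("pc1", "pc2")])
      rownames(M) <- pp$species
      colnames(M) <- paste0(p, c("_pc1", "_pc2"))
      wide <- if (is.null(wide)) M else
        cbind(wide, M[rownames(wide), , drop = FALSE])
    }
    post <- rjmcmc_variable_rates(
      tree, wide, iterations = cfg$chain$iterations,
      burnin = cfg$chain$burnin, thin = cfg$chain$thin,
      seed = seed + match(sex, c("male", "female")) * 10L)
    ph <- summarise_rate_phenogram(post)
    write_tree(ph$scaled_tree,
               file.path(cfg$out_dir, paste0("phenogram_", sex, ".nwk")))
    write.csv(data.frame(branch = seq_along(ph$l),
                         time_length = tree$edge.length,
                         mean_scalar = ph$mean_scalar, l = ph$l,
                         pp_cover = ph$pp_cover, pp_branch = ph$pp_branch,
                         pp_clade = ph$pp_clade),
              file.path(cfg$out_dir, paste0("branches_", sex, ".csv")),
              row.names = FALSE)
    write.csv(data.frame(iter = post$samples$iter, K = post$samples$K,
                         loglik = post$samples$loglik),
              file.path(cfg$out_dir, paste0("posterior_", sex, ".csv")),
              row.names = FALSE)
    # per-patch chains (2-trait blocks) for patch-specific rates
    for (p in patches) {
      pp <- sub[sub$patch == p, ]
      M <- as.matrix(pp[, c("pc1", "pc2")])
      rownames(M) <- pp$species
      postp <- rjmcmc_variable_rates(
        tree, M, iterations = cfg$chain$iterations,
        burnin = cfg$chain$burnin, thin = cfg$chain$thin,
        seed = seed + 100L * match(p, patches) +
          match(sex, c("male", "female")))
      php <- summarise_rate_phenogram(postp)
      write.csv(data.frame(branch = seq_along(php$l),
                           mean_scalar = php$mean_scalar, l = php$l,
                           pp_cover = php$pp_cover),
                file.path(cfg$out_dir,
                          paste0("branches_", sex, "_", p, ".csv")),
                row.names = FALSE)
    }
  }
}

.stage_tres <- function(cfg, seed) {
  tree <- read_tree(file.path(cfg$out_dir, "tree.nwk"))
  patches <- plumage_patches[seq_len(cfg$sim$n_patches)]
  rows <- list()
  for (sex in c("male", "female")) {
    br <- read_traits(file.path(cfg$out_dir,
                                paste0("branches_", sex, ".csv")),
                      c("branch", "l"))
    ph <- rate_phenogram(tree, br$l / tree$edge.length)
    tt <- tres(ph)
    tt$sex <- sex; tt$scope <- "whole_plumage"
    rows[[length(rows) + 1L]] <- tt
    for (p in patches) {
      brp <- read_traits(file.path(cfg$out_dir,
                                   paste0("branches_", sex, "_", p,
                                          ".csv")),
                         c("branch", "l"))
      ttp <- tres(rate_phenogram(tree, brp$l / tree$edge.length))
      ttp$sex <- sex; ttp$scope <- p
      rows[[length(rows) + 1L]] <- ttp
    }
  }
  out <- do.call(rbind, rows)[, c("tip", "sex", "scope", "tres",
                                  "log10_tres", "n_edges")]
  write.csv(out, file.path(cfg$out_dir, "tres.csv"), row.names = FALSE)
}

.stage_rma <- function(cfg, seed) {
  tree <- read_tree(file.path(cfg$out_dir, "tree.nwk"))
  tt <- read_traits(file.path(cfg$out_dir, "tres.csv"),
                    c("tip", "sex", "scope", "log10_tres"))
  wp <- tt[tt$scope == "whole_plumage", ]
  xm <- setNames(wp$log10_tres[wp$sex == "male"],
                 wp$tip[wp$sex == "male"])
  xf <- setNames(wp$log10_tres[wp$sex == "female"],
                 wp$tip[wp$sex == "female"])
  fit <- phylo_rma(tree, x = xf, y = xm, h0_slope = 1)
  write.csv(data.frame(slope = fit$slope, intercept = fit$intercept,
                       r2 = fit$r2, lambda = fit$lambda, T = fit$T,
                       df = fit$df, p_value = fit$p_value, n = fit$n),
            file.path(cfg$out_dir, "rma.csv"), row.names = FALSE)
}

.stage_direction <- function(cfg, seed) {
  tree <- read_tree(file.path(cfg$out_dir, "tree.nwk"))
  prof <- read_traits(file.path(cfg$out_dir, "profile.csv"),
                      c("species", "sex", "patch", "pc1", "pc2"))
  tt <- read_traits(file.path(cfg$out_dir, "tres.csv"),
                    c("tip", "sex", "scope", "tres"))
  rates <- tt[tt$scope != "whole_plumage", ]
  names(rates)[names(rates) == "scope"] <- "patch"
  traj <- tip_trajectories(tree, prof, rates)
  write.csv(as.data.frame(traj),
            file.path(cfg$out_dir, "trajectories.csv"), row.names = FALSE)
  res <- segment_rate_test(traj, cfg$segments$width, cfg$segments$n_perm,
                           seed = seed)
  write.csv(as.data.frame(res), file.path(cfg$out_dir, "segments_all.csv"),
            row.names = FALSE)
  per_sex <- pooled_and_stratified(traj, "sex",
                                   segment_width = cfg$segments$width,
                                   n_perm = cfg$segments$n_perm,
                                   seed = seed + 1L)
  for (sex in c("male", "female"))
    write.csv(as.data.frame(per_sex[[sex]]),
              file.path(cfg$out_dir, paste0("segments_", sex, ".csv")),
              row.names = FALSE)
}
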