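# Direction of recent colour divergence: ML ancestral states, tip divergence
# trajectories in PC space, and the randomisation test for rate-direction
# association over 20-degree segments.

#' Maximum likelihood ancestral states under Brownian motion
#'
#' GLS (= ML under Brownian motion) estimates for every internal node,
#' computed per trait by the standard two-pass (Gaussian message passing)
#' algorithm: a rootward pass combines descendant information into
#' per-node means and variances, a tipward pass folds in the rest of the
#' tree.  Zero-length internal branches are allowed and collapse to shared
#' estimates; negative branch lengths are an error.
#'
#' @param tree a `phylo` tree.
#' @param traits named tip vector, or tip matrix (columns treated
#'   independently).
#' @return matrix of ancestral estimates with one row per internal node
#'   (rownames = node numbers `ntip+1 ...`), one column per trait.
#' @export
ancestral_states_ml <- function(tree, traits) {
  check_tree(tree)
  if (is.null(dim(traits)))
    traits <- matrix(traits, ncol = 1, dimnames = list(names(traits)))
  traits <- as.matrix(traits)
  if (!all(tree$tip.label %in% rownames(traits)))
    stop("traits missing for some tips")
  X <- traits[tree$tip.label, , drop = FALSE]
  if (anyNA(X)) stop("traits contain missing values")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  N <- ntip + nnode
  edge <- tree$edge
  elen <- tree$edge.length
  po <- postorder_edges(tree)
  children <- split(seq_len(nrow(edge)), edge[, 1L])  # edges below each node

  out <- matrix(NA_real_, nnode, ncol(X),
                dimnames = list(as.character((ntip + 1L):N), colnames(X)))
  for (tr in seq_len(ncol(X))) {
    x <- X[, tr]
    # rootward pass: conditional mean/variance of each node given its subtree
    dm <- numeric(N); dv <- numeric(N)
    dm[seq_len(ntip)] <- x
    # combine children sequentially at each internal node (postorder)
    has <- logical(N)
    has[seq_len(ntip)] <- TRUE
    for (e in po) {
      par <- edge[e, 1L]; ch <- edge[e, 2L]
      mm <- dm[ch]; vv <- dv[ch] + elen[e]
      if (!has[par]) { dm[par] <- mm; dv[par] <- vv; has[par] <- TRUE }
      else {
        s <- dv[par] + vv
        if (s == 0) { dm[par] <- (dm[par] + mm) / 2; dv[par] <- 0 }
        else {
          dm[par] <- (vv * dm[par] + dv[par] * mm) / s
          dv[par] <- dv[par] * vv / s
        }
      }
    }
    # tipward pass: message from the rest of the tree into each node
    um <- numeric(N); uv <- rep(Inf, N)   # Inf variance = no information
    root <- edge[po[length(po)], 1L]
    est <- numeric(N)
    est[root] <- dm[root]
    for (e in rev(po)) {                  # parents before children
      par <- edge[e, 1L]; ch <- edge[e, 2L]
      if (ch <= ntip) next
      # combine parent's other children and the parent's own up-message
      mm <- um[par]; vv <- uv[par]
      for (e2 in children[[as.character(par)]]) {
        if (e2 == e) next
        c2 <- edge[e2, 2L]
        m2 <- dm[c2]; v2 <- dv[c2] + elen[e2]
        if (is.infinite(vv)) { mm <- m2; vv <- v2 }
        else if (vv + v2 == 0) { mm <- (mm + m2) / 2; vv <- 0 }
        else { mm <- (v2 * mm + vv * m2) / (vv + v2); vv <- vv * v2 /
          (vv + v2) }
      }
      um[ch] <- mm; uv[ch] <- vv + elen[e]
      # node estimate: combine subtree message with rest-of-tree message
      if (is.infinite(uv[ch])) est[ch] <- dm[ch]
      else if (uv[ch] + dv[ch] == 0) est[ch] <- (dm[ch] + um[ch]) / 2
      else est[ch] <- (uv[ch] * dm[ch] + dv[ch] * um[ch]) /
          (uv[ch] + dv[ch])
    }
    out[, tr] <- est[(ntip + 1L):N]
  }
  out
}

#' Tip divergence trajectories in PC colour space
#'
#' For each tip (and optionally each patch and sex), the divergence vector
#' from the ML-reconstructed state of the tip's parent node to the observed
#' tip value, with its angle (degrees in `[0, 360)`), magnitude, and the
#' associated evolutionary rate (typically the tip's patch-specific TRES).
#' Zero-magnitude trajectories have no defined direction and are dropped
#' with a warning.
#'
#' @param tree a `phylo` tree.
#' @param tip_values two-column matrix of tip PC values with tip labels as
#'   row names, or a data.frame with columns `species`, `pc1`, `pc2` and
#'   optionally `sex` and `patch` (each sex/patch block is processed
#'   separately).
#' @param rates named vector of per-tip rates, or a data.frame with columns
#'   `tip`/`species` and `tres` (and optionally `sex`, `patch` to match
#'   blocks).  Tips without a rate are excluded and listed in attribute
#'   `excluded`.
#' @return object of class `trajectory_set`: data.frame (`species`, `sex`,
#'   `patch`, `d1`, `d2`, `angle`, `magnitude`, `rate`).
#' @export
tip_trajectories <- function(tree, tip_values, rates) {
  check_tree(tree)
  blocks <- .traj_blocks(tip_values)
  rate_tab <- .traj_rates(rates)
  ntip <- ape::Ntip(tree)
  parent_of_tip <- integer(ntip)
  term <- tree$edge[, 2L] <= ntip
  parent_of_tip[tree$edge[term, 2L]] <- tree$edge[term, 1L]
  out <- list()
  excluded <- character(0)
  for (b in blocks) {
    M <- as.matrix(b$values[tree$tip.label, c("pc1", "pc2"), drop = FALSE])
    anc <- ancestral_states_ml(tree, M)
    d <- M - anc[as.character(parent_of_tip), , drop = FALSE]
    mag <- sqrt(rowSums(d^2))
    ang <- (atan2(d[, 2], d[, 1]) * 180 / pi) %% 360
    df <- data.frame(species = tree$tip.label, sex = b$sex, patch = b$patch,
                     d1 = d[, 1], d2 = d[, 2], angle = ang, magnitude = mag,
                     row.names = NULL, stringsAsFactors = FALSE)
    key <- paste(df$species, df$sex, df$patch)
    rkey <- paste(rate_tab$tip, rate_tab$sex, rate_tab$patch)
    if (all(is.na(rate_tab$sex)))
      { key <- df$species; rkey <- rate_tab$tip }
    df$rate <- rate_tab$rate[match(key, rkey)]
    drop_rate <- is.na(df$rate)
    if (any(drop_rate))
      excluded <- c(excluded, paste(df$species[drop_rate], b$sex, b$patch))
    zero <- !drop_rate & df$magnitude == 0
    if (any(zero))
      warning(sum(zero), " zero-magnitude trajectory(ies) dropped ",
              "(direction undefined)")
    out[[length(out) + 1L]] <- df[!drop_rate & !zero, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(excluded)) attr(res, "excluded") <- excluded
  class(res) <- c("trajectory_set", "data.frame")
  res
}

.traj_blocks <- function(tip_values) {
  if (is.matrix(tip_values)) {
    stopifnot(ncol(tip_values) == 2, !is.null(rownames(tip_values)))
    v <- data.frame(pc1 = tip_values[, 1], pc2 = tip_values[, 2],
                    row.names = rownames(tip_values))
    return(list(list(values = v, sex = NA_character_,
                     patch = NA_character_)))
  }
  df <- as.data.frame(tip_values)
  if (!all(c("species", "pc1", "pc2") %in% names(df)))
    stop("tip_values needs columns species, pc1, pc2")
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  if (!"patch" %in% names(df)) df$patch <- NA_character_
  split_keys <- unique(df[, c("sex", "patch")])
  lapply(seq_len(nrow(split_keys)), function(i) {
    sub <- df[(df$sex %in% split_keys$sex[i] |
                 (is.na(df$sex) & is.na(split_keys$sex[i]))) &
                (df$patch %in% split_keys$patch[i] |
                   (is.na(df$patch) & is.na(split_keys$patch[i]))), ]
    if (anyDuplicated(sub$species))
      stop("duplicate species within a sex/patch block")
    v <- data.frame(pc1 = sub$pc1, pc2 = sub$pc2, row.names = sub$species)
    list(values = v, sex = split_keys$sex[i], patch = split_keys$patch[i])
  })
}

.traj_rates <- function(rates) {
  if (is.data.frame(rates)) {
    tipcol <- intersect(c("tip", "species"), names(rates))[1]
    if (is.na(tipcol) || !"tres" %in% names(rates))
      stop("rates data.frame needs columns tip/species and tres")
    data.frame(tip = rates[[tipcol]],
               sex = if ("sex" %in% names(rates)) rates$sex else
                 NA_character_,
               patch = if ("patch" %in% names(rates)) rates$patch else
                 NA_character_,
               rate = rates$tres, stringsAsFactors = FALSE)
  } else {
    if (is.null(names(rates))) stop("rates vector must be named by tip")
    data.frame(tip = names(rates), sex = NA_character_,
               patch = NA_character_, rate = as.numeric(rates),
               stringsAsFactors = FALSE)
  }
}

#' Randomisation test for rate-direction association
#'
#' Partitions trajectories into half-open angular segments (default
#' `[0, 20), [20, 40), ...`), computes the observed mean rate per segment,
#' and builds the null by permuting rate labels across all trajectories
#' while keeping angles fixed — the minimal exchangeable null preserving
#' both the rate and the angular distribution.  Per segment: the 95%
#' confidence band of the permuted means (2.5/97.5 percentiles), a
#' two-sided empirical p-value with the +1 correction, and a flag:
#' `faster` if the observed mean exceeds the upper band, `slower` if below
#' the lower band, `untestable` for empty segments, else `null`.
#'
#' @param trajectories a `trajectory_set` (or data.frame with `angle` and
#'   `rate`).
#' @param segment_width segment width in degrees; must divide 360.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed; fixing it fixes the bands exactly.
#' @param conf confidence level of the null band.
#' @return object of class `segment_test`: data.frame (`segment`,
#'   `angle_lo`, `angle_hi`, `count`, `observed_mean`, `null_lo`,
#'   `null_hi`, `p_value`, `flag`).
#' @export
segment_rate_test <- function(trajectories, segment_width = 20,
                              n_perm = 1000, seed = NULL, conf = 0.95) {
  df <- as.data.frame(trajectories)
  if (!all(c("angle", "rate") %in% names(df)))
    stop("trajectories need columns angle and rate")
  if (360 %% segment_width != 0)
    stop("segment_width must divide 360")
  if (n_perm < 100)
    stop("n_perm < 100 gives unstable null percentiles; refused")
  if (!is.null(seed)) set.seed(seed)
  nseg <- 360 %/% segment_width
  # canonical internal ordering: the permutation null then depends only on
  # the multiset of (angle, rate) pairs, never on input row order
  df <- df[order(df$angle, df$rate), , drop = FALSE]
  ang <- df$angle %% 360
  seg <- floor(ang / segment_width) + 1L
  n <- length(ang)
  counts <- tabulate(seg, nseg)
  obs <- rep(NA_real_, nseg)
  sums <- vapply(seq_len(nseg), function(k) sum(df$rate[seg == k]),
                 numeric(1))
  obs[counts > 0] <- sums[counts > 0] / counts[counts > 0]
  # Permutation null: segment means under shuffled rate labels.  Permuted
  # rates are allocated to segments in a rotation-invariant order (largest
  # count first, observed mean breaking ties), so that the null — and hence
  # the flags — co-rotate exactly when all angles are shifted by a multiple
  # of the segment width under the same seed.
  ordseg <- order(-counts, ifelse(is.na(obs), Inf, obs), seq_len(nseg))
  offsets <- c(0L, cumsum(counts[ordseg]))
  rates_sorted <- sort(df$rate)
  P <- matrix(rates_sorted[vapply(seq_len(n_perm),
                                  function(b) sample.int(n), integer(n))],
              n, n_perm)
  nullM <- matrix(NA_real_, nseg, n_perm)
  for (r in seq_len(nseg)) {
    k <- ordseg[r]
    if (counts[k] == 0) { nullM[k, ] <- 0; next }
    block <- (offsets[r] + 1L):offsets[r + 1L]
    nullM[k, ] <- colMeans(P[block, , drop = FALSE])
  }
  alpha <- (1 - conf) / 2
  lo <- apply(nullM, 1, quantile, probs = alpha)
  hi <- apply(nullM, 1, quantile, probs = 1 - alpha)
  pv <- vapply(seq_len(nseg), function(k) {
    if (counts[k] == 0) return(NA_real_)
    ge <- (sum(nullM[k, ] >= obs[k]) + 1) / (n_perm + 1)
    le <- (sum(nullM[k, ] <= obs[k]) + 1) / (n_perm + 1)
    min(1, 2 * min(ge, le))
  }, numeric(1))
  flag <- rep("null", nseg)
  flag[counts > 0 & obs > hi] <- "faster"
  flag[counts > 0 & obs < lo] <- "slower"
  flag[counts == 0] <- "untestable"
  lo[counts == 0] <- NA_real_
  hi[counts == 0] <- NA_real_
  out <- data.frame(segment = seq_len(nseg),
                    angle_lo = (seq_len(nseg) - 1L) * segment_width,
                    angle_hi = seq_len(nseg) * segment_width,
                    count = counts, observed_mean = obs, null_lo = lo,
                    null_hi = hi, p_value = pv, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("segment_test", "data.frame")
  out
}

#' Segment tests pooled and within strata
#'
#' Runs [segment_rate_test()] on all trajectories pooled (`"all"`), or
#' within each patch (`"patch"`) or sex (`"sex"`).  Empty strata are
#' skipped and listed in attribute `skipped`.
#'
#' @param trajectories a `trajectory_set`.
#' @param strata `"all"`, `"patch"` or `"sex"`.
#' @param ... passed to [segment_rate_test()].
#' @return named list of `segment_test` objects.
#' @export
pooled_and_stratified <- function(trajectories,
                                  strata = c("all", "patch", "sex"), ...) {
  strata <- match.arg(strata)
  df <- as.data.frame(trajectories)
  if (strata == "all")
    return(list(all = segment_rate_test(df, ...)))
  labs <- df[[strata]]
  if (is.null(labs) || all(is.na(labs)))
    stop("stratum labels '", strata, "' absent from the trajectory set")
  out <- list()
  skipped <- character(0)
  for (s in unique(labs)) {
    sub <- df[!is.na(labs) & labs == s, , drop = FALSE]
    if (!nrow(sub)) { skipped <- c(skipped, s); next }
    out[[s]] <- segment_rate_test(sub, ...)
  }
  if (length(skipped)) attr(out, "skipped") <- skipped
  out
}
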