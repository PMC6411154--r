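#' Group-mean expression profile
#'
#' Averages expression within each (region, treatment group) cell of a
#' long-form expression table, yielding one value per group and region.
#'
#' @param table data.frame with columns `region`, `group`, `animal`,
#'   `value` (non-negative expression).
#' @param regions,groups Optional orderings; default is order of first
#'   appearance in the table.
#' @return Numeric region-by-group matrix with attribute
#'   `standardized = FALSE`.
#' @export
group_mean_profile <- function(table, regions = NULL, groups = NULL) {
  stopifnot(is.data.frame(table),
            all(c("region", "group", "animal", "value") %in% names(table)))
  if (any(!is.finite(table$value))) stopf("expression values must be finite")
  if (is.null(regions)) regions <- unique(table$region)
  if (is.null(groups)) groups <- unique(table$group)
  prof <- matrix(NA_real_, length(regions), length(groups),
                 dimnames = list(regions, groups))
  for (r in regions) {
    for (g in groups) {
      v <- table$value[table$region == r & table$group == g]
      if (length(v) == 0L) {
        stopf("no records for region '%s', group '%s'", r, g)
      }
      prof[r, g] <- sum(v) / length(v)
    }
  }
  attr(prof, "standardized") <- FALSE
  prof
}

#' Region-wise z-scoring of a group-mean profile
#'
#' Standardizes each region row to mean 0 and population SD 1 over the
#' listed groups. Groups outside `groups` (e.g. a home-cage group kept only
#' for clustering) are projected with the same per-region center and scale,
#' so one standardized profile can serve both the clustering and the
#' correlation stages.
#'
#' @param profile Region-by-group matrix from [group_mean_profile()].
#' @param groups Groups over which center and scale are computed; default
#'   all columns.
#' @param sd_type `"population"` (divide by N; default) or `"sample"`.
#' @return Standardized matrix with attributes `standardized = TRUE`,
#'   `center`, `scale`, and `zscore_groups`.
#' @export
zscore_profile <- function(profile, groups = colnames(profile),
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.matrix(profile))
  missing <- setdiff(groups, colnames(profile))
  if (length(missing)) stopf("groups not in profile: %s",
                             paste(missing, collapse = ", "))
  sub <- profile[, groups, drop = FALSE]
  center <- rowMeans(sub)
  scale <- apply(sub, 1, if (sd_type == "population") pop_sd else sd)
  zero <- scale <= 0 | !is.finite(scale)
  if (any(zero)) {
    stopf("zero variance over the standardization groups for region(s): %s",
          paste(rownames(profile)[zero], collapse = ", "))
  }
  z <- (profile - center) / scale
  attr(z, "standardized") <- TRUE
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  attr(z, "zscore_groups") <- groups
  z
}

#' Per-state 4-vectors of z-scored activity
#'
#' Extracts, for one drug state, each region's vector of z-scores over the
#' anxiety conditions (in fixed order). These vectors are what gets
#' correlated between regions; a home-cage group, if present, is not part
#' of any state and is therefore excluded automatically.
#'
#' @param zprofile Standardized profile from [zscore_profile()].
#' @param state Drug-state label (e.g. `"saline"`).
#' @param conditions Ordered anxiety-condition labels.
#' @param sep Separator used in crossed group labels (see [group_label()]).
#' @return Region-by-condition matrix with attributes `state` and
#'   `zero_variance` (logical per region: constant across conditions, so
#'   its Pearson correlations are undefined).
#' @export
build_state_vectors <- function(zprofile, state,
                                conditions = c("none", "EPM", "shock",
                                               "shock_EPM"),
                                sep = "_") {
  stopifnot(is.matrix(zprofile))
  cols <- group_label(state, conditions, sep)
  missing <- setdiff(cols, colnames(zprofile))
  if (length(missing)) {
    stopf("state '%s' is missing group(s): %s", state,
          paste(missing, collapse = ", "))
  }
  vec <- zprofile[, cols, drop = FALSE]
  colnames(vec) <- conditions
  attr(vec, "state") <- state
  attr(vec, "zero_variance") <- apply(vec, 1, function(x) pop_sd(x) == 0)
  vec
}

#' Between-region correlation matrix for one drug state
#'
#' Pearson correlation of every pair of region vectors across the anxiety
#' conditions. Pairs involving a zero-variance vector have an undefined
#' correlation; those entries are set to 0 and flagged in the `undefined`
#' attribute so downstream sums treat them as a neutral contribution.
#'
#' @param vectors Region-by-condition matrix from [build_state_vectors()].
#' @return Square region correlation matrix with unit diagonal and
#'   attributes `state` and `undefined` (logical matrix).
#' @export
state_correlation_matrix <- function(vectors) {
  stopifnot(is.matrix(vectors), nrow(vectors) >= 2L)
  zv <- attr(vectors, "zero_variance")
  if (is.null(zv)) zv <- apply(vectors, 1, function(x) pop_sd(x) == 0)
  rho <- matrix(0, nrow(vectors), nrow(vectors),
                dimnames = list(rownames(vectors), rownames(vectors)))
  ok <- !zv
  if (any(ok)) {
    rho[ok, ok] <- cor(t(vectors[ok, , drop = FALSE]))
  }
  undefined <- outer(zv, zv, `|`)
  diag(undefined) <- zv
  diag(rho) <- ifelse(zv, 0, 1)
  if (any(zv)) {
    warning(sprintf("zero-variance state vector(s): %s; correlations flagged undefined",
                    paste(rownames(vectors)[zv], collapse = ", ")),
            call. = FALSE)
  }
  attr(rho, "state") <- attr(vectors, "state")
  attr(rho, "undefined") <- undefined
  rho
}

#' Per-region network correlation sum (phi)
#'
#' For each region, the sum of its pairwise correlations with all other
#' regions (self-correlation excluded; undefined entries contribute 0).
#' Bounded by the number of regions minus one in absolute value.
#'
#' @param corr Correlation matrix from [state_correlation_matrix()].
#' @return Named numeric vector of phi values.
#' @export
phi <- function(corr) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  x <- corr
  diag(x) <- 0
  rowSums(x)
}

#' Drug-minus-saline difference of phi
#'
#' @param phi_drug,phi_saline Named phi vectors over the same regions.
#' @return Named numeric vector `phi_drug - phi_saline`.
#' @export
delta_phi <- function(phi_drug, phi_saline) {
  if (!identical(names(phi_drug), names(phi_saline))) {
    stopf("region sets of the two states differ")
  }
  phi_drug - phi_saline
}

#' Out-normalize a connectome
#'
#' Divides every edge weight by the total outgoing weight of its source
#' region, so each source's outgoing weights sum to 1. Idempotent.
#'
#' @param conn A `connectome` (see [simulate_connectome()] or
#'   [read_connectome()]).
#' @return The connectome with normalized weights and
#'   `attr(, "normalized") = TRUE`.
#' @export
normalize_connectome <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  out_sum <- tapply(conn$weight, conn$source, sum)
  if (any(out_sum <= 0)) {
    stopf("non-positive outgoing weight sum for region(s): %s",
          paste(names(out_sum)[out_sum <= 0], collapse = ", "))
  }
  conn$weight <- as.numeric(conn$weight / out_sum[conn$source])
  attr(conn, "normalized") <- TRUE
  conn
}

#' Connectome-weighted correlation sum (phi_con)
#'
#' Restricts phi to each region's first-order anatomical neighbors,
#' weighting every correlation by the (out-normalized) connection strength.
#' With `direction = "output"`, region i sums `rho(i, j) * zeta(i -> j)`
#' over its outgoing edges; with `direction = "input"` it sums
#' `rho(i, j) * zeta(j -> i)` over its incoming edges, reusing the same
#' out-normalized weights. Missing edges and undefined correlations
#' contribute 0. Edges to regions absent from the correlation matrix are an
#' error; regions with no edge in the requested direction score 0.
#'
#' @param corr Correlation matrix from [state_correlation_matrix()].
#' @param conn An out-normalized `connectome` (see
#'   [normalize_connectome()]).
#' @param direction `"output"` or `"input"`.
#' @return Named numeric vector of phi_con values over the correlation
#'   matrix's regions, with attribute `direction`.
#' @export
phi_con <- function(corr, conn, direction = c("output", "input")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(corr), inherits(conn, "connectome"))
  if (!isTRUE(attr(conn, "normalized"))) {
    stopf("connectome must be out-normalized first (see normalize_connectome)")
  }
  regions <- rownames(corr)
  unknown <- setdiff(unique(c(conn$source, conn$target)), regions)
  if (length(unknown)) {
    stopf("connectome region(s) absent from correlation matrix: %s",
          paste(unknown, collapse = ", "))
  }
  undef <- attr(corr, "undefined")
  rho <- corr
  if (!is.null(undef)) rho[undef] <- 0
  res <- setNames(numeric(length(regions)), regions)
  # region whose score is accumulated: the edge source for "output",
  # the edge target for "input"; zeta stays out-normalized in both cases
  node <- if (direction == "output") conn$source else conn$target
  neigh <- if (direction == "output") conn$target else conn$source
  contrib <- rho[cbind(node, neigh)] * conn$weight
  agg <- tapply(contrib, node, sum)
  res[names(agg)] <- agg
  attr(res, "direction") <- direction
  res
}

#' Drug-minus-saline difference of phi_con
#'
#' @param phicon_drug,phicon_saline phi_con vectors over the same regions
#'   and direction.
#' @return Named numeric vector `phicon_drug - phicon_saline` with the
#'   shared `direction` attribute.
#' @export
delta_phi_con <- function(phicon_drug, phicon_saline) {
  if (!identical(names(phicon_drug), names(phicon_saline))) {
    stopf("region sets of the two states differ")
  }
  d1 <- attr(phicon_drug, "direction"); d2 <- attr(phicon_saline, "direction")
  if (!is.null(d1) && !is.null(d2) && !identical(d1, d2)) {
    stopf("direction mismatch: '%s' vs '%s'", d1, d2)
  }
  out <- phicon_drug - phicon_saline
  attr(out, "direction") <- d1
  out
}

#' Rank regions by a node score
#'
#' @param scores Node-score data.frame from [cfos_network_scores()] (or any
#'   data.frame with a `region` column).
#' @param key Score column to rank by (e.g. `"delta_phicon_out"`).
#' @param by_absolute Rank by absolute value (default) or signed value.
#' @return Character vector of regions in descending score order; ties are
#'   broken lexicographically by region label.
#' @export
rank_regions <- function(scores, key, by_absolute = TRUE) {
  stopifnot(is.data.frame(scores), "region" %in% names(scores))
  if (!key %in% names(scores)) stopf("unknown score key '%s'", key)
  v <- scores[[key]]
  if (by_absolute) v <- abs(v)
  scores$region[order(-v, scores$region)]
}
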