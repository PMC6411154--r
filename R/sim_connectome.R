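#' Simulate a toy directed weighted connectome
#'
#' Draws a random directed graph over the given regions: each ordered pair
#' of distinct regions carries an edge with probability `density`, with a
#' weight uniform in `weight_range`. The whole graph is re-drawn until every
#' region has at least one outgoing edge (required for out-normalization),
#' so the generator is deterministic given the seed.
#'
#' @param regions Character vector of region labels (>= 2).
#' @param density Edge probability in `(0, 1]`.
#' @param weight_range Length-2 numeric `(lo, hi)` with `0 < lo <= hi`.
#' @param seed Integer seed.
#' @param max_tries Maximum number of re-draws before giving up.
#' @return A `connectome` data.frame with columns `source`, `target`,
#'   `weight` and attribute `normalized = FALSE`.
#' @seealso [normalize_connectome()]
#' @export
#' @examples
#' conn <- simulate_connectome(limbic_regions(), density = 0.5, seed = 1)
#' nrow(conn)
simulate_connectome <- function(regions, density = 0.5,
                                weight_range = c(0.5, 1.5), seed = 1L,
                                max_tries = 1000L) {
  regions <- as.character(regions)
  if (length(regions) < 2L) stopf("need at least 2 regions")
  check_scalar_number(density, "density", lower = 0, upper = 1,
                      strict_lower = TRUE)
  lo <- weight_range[1]; hi <- weight_range[2]
  if (!(lo > 0 && hi >= lo)) stopf("need 0 < weight_range[1] <= weight_range[2]")
  R <- length(regions)
  pairs <- expand.grid(source = regions, target = regions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  with_local_seed(seed, {
    for (try in seq_len(max_tries)) {
      keep <- runif(nrow(pairs)) < density
      edges <- pairs[keep, , drop = FALSE]
      if (all(regions %in% edges$source)) {
        edges$weight <- runif(nrow(edges), lo, hi)
        rownames(edges) <- NULL
        return(as_connectome(edges, normalized = FALSE))
      }
    }
    stopf("no draw with >= 1 outgoing edge per region in %d tries", max_tries)
  })
}

# Internal constructor; validates the edge list.
as_connectome <- function(edges, normalized = FALSE) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "weight") %in% names(edges)))
  if (any(edges$source == edges$target)) stopf("self-edges are not allowed")
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    stopf("edge weights must be finite and > 0")
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate directed edges are not allowed")
  edges <- edges[, c("source", "target", "weight")]
  class(edges) <- c("connectome", "data.frame")
  attr(edges, "normalized") <- isTRUE(normalized)
  edges
}
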