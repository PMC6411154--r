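#' Hierarchical clustering of treatment groups
#'
#' Agglomerative clustering of the treatment groups (profile columns) by
#' their region-wise z-score vectors: Euclidean distance, average linkage
#' by default (both configurable). This is the stage where a home-cage
#' group participates; it plays no role in any correlation score.
#'
#' @param zprofile Standardized region-by-group matrix from
#'   [zscore_profile()].
#' @param method Linkage passed to [stats::hclust()].
#' @param metric Distance metric passed to [stats::dist()].
#' @return A list with:
#'   \describe{
#'     \item{hclust}{the [stats::hclust] object;}
#'     \item{newick}{Newick serialization of the dendrogram;}
#'     \item{merges}{data.frame of merge steps (`step`, `height`, and the
#'       two merged clusters as leaf-label sets).}
#'   }
#' @export
#' @examples
#' prof <- matrix(rnorm(30), 5, 6,
#'                dimnames = list(paste0("r", 1:5), paste0("g", 1:6)))
#' cl <- cluster_groups(zscore_profile(prof))
#' cl$newick
cluster_groups <- function(zprofile, method = "average",
                           metric = "euclidean") {
  stopifnot(is.matrix(zprofile))
  if (ncol(zprofile) < 2L) stopf("need >= 2 groups (columns) to cluster")
  d <- dist(t(zprofile), method = metric)
  hc <- hclust(d, method = method)
  labels <- hc$labels
  members <- vector("list", nrow(hc$merge))
  leafset <- function(idx, step_members) {
    if (idx < 0) labels[-idx] else step_members[[idx]]
  }
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       height = hc$height,
                       cluster_a = NA_character_,
                       cluster_b = NA_character_,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hc$merge))) {
    a <- leafset(hc$merge[i, 1], members)
    b <- leafset(hc$merge[i, 2], members)
    members[[i]] <- c(a, b)
    merges$cluster_a[i] <- paste(sort(a), collapse = ",")
    merges$cluster_b[i] <- paste(sort(b), collapse = ",")
  }
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = newick, merges = merges)
}
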