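#' Mean affect-rating profile of each activity
#'
#' For every activity reported in sets A/B/C, the episode-mean rating of
#' each of the seven adjectives. These profiles are the objects clustered
#' by [cluster_activities()]. Sleep-type activities (affect is not coded
#' while asleep) are excluded by default; activities appearing only in set
#' D carry no activity-coded affect and never enter.
#'
#' @param survey A [drm_survey()] or an episode tibble.
#' @param exclude Activity codes to drop (default `"sleep"`).
#' @param min_episodes Activities with fewer scorable episodes are omitted
#'   with a warning (default 1, i.e. keep all observed).
#' @return Tibble: `activity_code`, the seven item means, `n_episodes`.
#' @export
activity_profiles <- function(survey, exclude = "sleep", min_episodes = 1) {
  ep <- if (inherits(survey, "drm_survey")) survey$episodes else
    as_tibble(survey)
  ep <- ep[ep$set_id %in% c("A", "B", "C") & !is.na(ep$activity_code) &
             !ep$activity_code %in% exclude, ]
  ep <- ep[stats::complete.cases(ep[DRM_ITEMS]), ]
  if (!nrow(ep)) {
    abort("No scorable set A/B/C episodes with activity codes.",
          class = "drmwell_validation_error")
  }
  out <- ep |>
    group_by(activity_code = .data$activity_code) |>
    summarise(across(all_of(DRM_ITEMS), mean), n_episodes = n(),
              .groups = "drop")
  thin <- out$n_episodes < min_episodes
  if (any(thin)) {
    warn(sprintf("Omitting %d activit(ies) with fewer than %d episodes: %s",
                 sum(thin), min_episodes,
                 paste(out$activity_code[thin], collapse = ", ")))
    out <- out[!thin, ]
  }
  out
}

#' Column-standardize activity profiles
#'
#' Z-scores each adjective column across activities (mean 0, sd 1 with the
#' n-1 denominator). Zero-variance columns are left at 0 and flagged in the
#' `constant_columns` attribute.
#'
#' @param profiles Output of [activity_profiles()] (or any matrix/data
#'   frame of numeric profile columns with an `activity_code` column or
#'   rownames).
#' @return Numeric matrix (activities x adjectives) with rownames, plus a
#'   `constant_columns` attribute.
#' @export
standardize_profiles <- function(profiles) {
  if (is.data.frame(profiles)) {
    m <- as.matrix(profiles[, intersect(DRM_ITEMS, names(profiles)),
                            drop = FALSE])
    rownames(m) <- profiles$activity_code
  } else {
    m <- as.matrix(profiles)
  }
  if (nrow(m) < 2) {
    abort("Need at least two activities to standardize.",
          class = "drmwell_validation_error")
  }
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  const <- s == 0
  s[const] <- 1
  z <- sweep(sweep(m, 2, mu), 2, s, "/")
  z[, const] <- 0
  if (any(const)) {
    warn(sprintf("Zero-variance column(s) left at 0: %s",
                 paste(colnames(m)[const], collapse = ", ")))
  }
  attr(z, "constant_columns") <- colnames(m)[const]
  z
}

#' Hierarchical clustering of activity profiles
#'
#' Agglomerative clustering of the standardized profiles with Euclidean
#' dissimilarity and average linkage (UPGMA) by default — the combination
#' that tends to maximize the cophenetic correlation for these data. Merge
#' ties are broken deterministically by input order.
#'
#' @param z Standardized profile matrix from [standardize_profiles()] (or
#'   a profile tibble, standardized internally).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return A `drm_dendro`: list with the `hclust` object, the input
#'   distance matrix (`dist`) and `labels`.
#' @export
cluster_activities <- function(z, linkage = c("average", "single",
                                              "complete")) {
  linkage <- match.arg(linkage)
  if (is.data.frame(z)) z <- standardize_profiles(z)
  if (is.null(rownames(z))) rownames(z) <- paste0("a", seq_len(nrow(z)))
  if (anyDuplicated(rownames(z))) {
    abort("Duplicate activity codes.", class = "drmwell_validation_error")
  }
  if (nrow(z) < 2) {
    abort("Need at least two activities to cluster.",
          class = "drmwell_validation_error")
  }
  d <- dist(z, method = "euclidean")
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, dist = d, labels = rownames(z),
                 linkage = linkage),
            class = "drm_dendro")
}

#' @export
print.drm_dendro <- function(x, ...) {
  cat(sprintf("<drm_dendro> %d activities, %s linkage\n",
              length(x$labels), x$linkage))
  invisible(x)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise dissimilarities and
#' the cophenetic distances (the merge height at which two activities first
#' join). Equals 1 exactly when the input distances are ultrametric.
#'
#' @param dendro A `drm_dendro` from [cluster_activities()].
#' @return A single correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(dendro) {
  stopifnot(inherits(dendro, "drm_dendro"))
  if (length(dendro$labels) < 3) {
    abort("Cophenetic correlation needs at least 3 leaves.",
          class = "drmwell_validation_error")
  }
  cor(as.vector(dendro$dist), as.vector(cophenetic(dendro$hclust)))
}

# Leaf sets of every internal node of an hclust, as sorted label signatures.
# Node i corresponds to merge row i; the root is the last row.
hclust_leafsets <- function(hc) {
  n <- length(hc$labels %||% hc$order)
  labs <- hc$labels %||% as.character(seq_len(n))
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    kids <- hc$merge[i, ]
    members <- unlist(lapply(kids, function(k) {
      if (k < 0) -k else sets[[k]]
    }))
    sets[[i]] <- sort.int(members)
  }
  lapply(sets, function(ix) labs[ix])
}

leafset_signature <- function(labels) {
  paste(sort(labels), collapse = "\x1f")
}

#' Internal nodes of a dendrogram as a tidy table
#'
#' @param dendro A `drm_dendro`.
#' @return Tibble: `node` (merge index; the last is the root), `height`,
#'   `n_leaves`, `leaves` (list column of activity codes).
#' @export
dendro_nodes <- function(dendro) {
  stopifnot(inherits(dendro, "drm_dendro"))
  sets <- hclust_leafsets(dendro$hclust)
  tibble(node = seq_along(sets),
         height = dendro$hclust$height,
         n_leaves = lengths(sets),
         leaves = sets)
}

#' Export a dendrogram (optionally with AU support) to Newick
#'
#' Branch lengths are merge heights; when a `drm_cluster_support` fit is given,
#' internal nodes are labelled with their AU values.
#'
#' @param x A `drm_dendro` or `drm_cluster_support`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
export_newick <- function(x, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export needs the 'ape' package.",
          class = "drmwell_config_error")
  }
  dendro <- if (inherits(x, "drm_cluster_support")) x$dendro else x
  stopifnot(inherits(dendro, "drm_dendro"))
  phy <- ape::as.phylo(dendro$hclust)
  if (inherits(x, "drm_cluster_support")) {
    sigs <- purrr::map_chr(hclust_leafsets(dendro$hclust),
                           leafset_signature)
    # ape internal node i corresponds to the clade with the same leaf set
    node_sig <- purrr::map_chr(seq_len(phy$Nnode) + length(phy$tip.label),
      function(nd) {
        tips <- phy$tip.label[unlist(phangorn_free_descendants(phy, nd))]
        leafset_signature(tips)
      })
    au <- x$nodes$au[match(node_sig, sigs)]
    phy$node.label <- ifelse(is.na(au), "", sprintf("%.3f", au))
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

# tip indices descending from an internal node (small trees; plain recursion)
phangorn_free_descendants <- function(phy, node) {
  ntip <- length(phy$tip.label)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) {
    if (k <= ntip) k else phangorn_free_descendants(phy, k)
  }))
}
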