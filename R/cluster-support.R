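#' Multiscale bootstrap support for activity clusters
#'
#' Assesses how strongly the data support each cluster of the activity
#' dendrogram, following the multiscale bootstrap of Shimodaira's
#' approximately unbiased (AU) p-value. The resampling unit is the episode:
#' at every scale `r` the episodes are resampled with replacement to size
#' `ceiling(r * n)`, the activity profiles are recomputed, standardized and
#' re-clustered, and each original cluster's bootstrap probability `BP_r`
#' is the fraction of replicate trees containing exactly the same leaf set.
#' The signed distance `v` and curvature `c` are then estimated by weighted
#' least squares of `qnorm(1 - BP_r)` on `(sqrt(r), 1/sqrt(r))` and
#' `AU = 1 - pnorm(v - c)`. `BP` is reported at the scale closest to 1.
#'
#' Clusters never (always) recovered across all scales receive AU 0 (1)
#' with a degeneracy flag; the root always receives AU 1. BP values are
#' clamped to `[1/(2B), 1 - 1/(2B)]` before the probit transform.
#'
#' @param survey A [drm_survey()] or episode tibble (set A/B/C).
#' @param nboot Bootstrap replicates per scale (default 1000; the classical
#'   recipe of ten scales gives 10,000 resampled trees in total).
#' @param scales Resampling ratios (default `seq(0.5, 1.4, by = 0.1)`).
#' @param seed Integer seed; fixed seed gives identical AU/BP on repeats.
#' @param linkage Linkage passed to [cluster_activities()].
#' @param exclude Activities excluded from profiling (default `"sleep"`).
#' @return A `drm_cluster_support`: list with `dendro` (the observed tree),
#'   `nodes` (tibble: `node`, `height`, `n_leaves`, `leaves`, `bp`, `au`,
#'   `v`, `c`, `flag`), `bp_table` (per-scale counts), `scales`, `nboot`,
#'   `seed`.
#' @export
cluster_support <- function(survey, nboot = 1000,
                            scales = seq(0.5, 1.4, by = 0.1),
                            seed = 1,
                            linkage = c("average", "single", "complete"),
                            exclude = "sleep") {
  linkage <- match.arg(linkage)
  if (any(scales <= 0)) {
    abort("All resampling scales must be positive.",
          class = "drmwell_config_error")
  }
  ep <- if (inherits(survey, "drm_survey")) survey$episodes else
    as_tibble(survey)
  ep <- ep[ep$set_id %in% c("A", "B", "C") & !is.na(ep$activity_code) &
             !ep$activity_code %in% exclude, ]
  ep <- ep[stats::complete.cases(ep[DRM_ITEMS]), ]
  X <- as.matrix(ep[DRM_ITEMS])
  act <- factor(ep$activity_code)
  acts <- levels(act)
  if (length(acts) < 3) {
    abort("Need at least three activities for cluster support.",
          class = "drmwell_validation_error")
  }

  prof <- rowsum(X, act) / as.vector(table(act))
  z <- standardize_z(prof)
  dendro <- cluster_activities(z, linkage = linkage)
  obs_sets <- hclust_leafsets(dendro$hclust)
  obs_sigs <- purrr::map_chr(obs_sets, leafset_signature)
  n_nodes <- length(obs_sigs)
  n <- nrow(X)
  acti <- as.integer(act)

  counts <- withr::with_seed(as.integer(seed), {
    cts <- matrix(0L, n_nodes, length(scales))
    for (si in seq_along(scales)) {
      m <- ceiling(scales[si] * n)
      for (b in seq_len(nboot)) {
        idx <- sample.int(n, m, replace = TRUE)
        tab <- tabulate(acti[idx], nbins = length(acts))
        present <- tab > 0
        if (sum(present) < 2) next
        pm <- rowsum(X[idx, , drop = FALSE], acti[idx])
        pm <- pm / tab[present]
        rownames(pm) <- acts[present]
        zb <- standardize_z(pm)
        hb <- hclust(dist(zb), method = linkage)
        hb$labels <- rownames(zb)
        sigs <- purrr::map_chr(hclust_leafsets(hb), leafset_signature)
        hit <- match(sigs, obs_sigs)
        hit <- hit[!is.na(hit)]
        cts[hit, si] <- cts[hit, si] + 1L
      }
    }
    cts
  })

  fits <- lapply(seq_len(n_nodes), function(i) {
    fit_au(counts[i, ], nboot, scales)
  })
  near1 <- which.min(abs(scales - 1))
  nodes <- dendro_nodes(dendro)
  nodes$bp <- counts[, near1] / nboot
  nodes$au <- purrr::map_dbl(fits, "au")
  nodes$v <- purrr::map_dbl(fits, "v")
  nodes$c <- purrr::map_dbl(fits, "c")
  nodes$flag <- purrr::map_chr(fits, "flag")
  # the root contains every leaf in every replicate by construction
  root <- n_nodes
  nodes$au[root] <- 1
  nodes$bp[root] <- 1
  nodes$flag[root] <- "root"

  bp_table <- tibble(
    node = rep(seq_len(n_nodes), times = length(scales)),
    scale = rep(scales, each = n_nodes),
    count = as.vector(counts),
    bp = as.vector(counts) / nboot
  )
  structure(
    list(dendro = dendro, nodes = nodes, bp_table = bp_table,
         scales = scales, nboot = nboot, seed = seed),
    class = "drm_cluster_support"
  )
}

# z-scoring used inside the bootstrap loop (no warnings, constant cols -> 0)
standardize_z <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  bad <- !is.finite(s) | s == 0
  s[bad] <- 1
  z <- sweep(sweep(m, 2, mu), 2, s, "/")
  z[, bad] <- 0
  z
}

# Weighted-least-squares fit of the multiscale BP curve for one node.
# Scales where the count saturates at 0 or B carry no information about
# the probit curve (the clamp would flatten it), so the curve is fitted on
# the informative scales only; clusters recovered in (almost) every
# replicate, or (almost) none, are reported at the corresponding boundary.
fit_au <- function(k, B, scales) {
  if (all(k == 0)) {
    return(list(au = 0, v = NA_real_, c = NA_real_, flag = "never_observed"))
  }
  if (all(k == B)) {
    return(list(au = 1, v = NA_real_, c = NA_real_, flag = "always_observed"))
  }
  # the probit curve is only estimable when the counts sit away from the
  # boundaries: with fewer than ~5 expected misses (or hits) per scale the
  # binomial noise swamps the curve and the clamp would flatten it toward
  # AU ~ 0.5, so such clusters are reported at the boundary instead
  inform <- k > 0 & k < B
  mbp <- mean(k / B)
  if (sum(inform) < 3 || mbp >= 1 - 5 / B || mbp <= 5 / B) {
    if (mbp >= 0.5) {
      return(list(au = 1, v = NA_real_, c = NA_real_,
                  flag = "near_always_observed"))
    }
    return(list(au = 0, v = NA_real_, c = NA_real_,
                flag = "near_never_observed"))
  }
  bp <- pmin(pmax(k[inform] / B, 1 / (2 * B)), 1 - 1 / (2 * B))
  r <- scales[inform]
  zz <- qnorm(1 - bp)
  Xd <- cbind(sqrt(r), 1 / sqrt(r))
  w <- B * dnorm(zz)^2 / (bp * (1 - bp))
  XtW <- t(Xd * w)
  beta <- solve(XtW %*% Xd, XtW %*% zz)
  v <- beta[1]; cc <- beta[2]
  list(au = pnorm(cc - v), v = v, c = cc, flag = "ok")
}

#' @export
print.drm_cluster_support <- function(x, ...) {
  cat(sprintf(
    "<drm_cluster_support> %d activities, %d scales x %d replicates (seed %d)\n",
    length(x$dendro$labels), length(x$scales), x$nboot, x$seed))
  print(x$nodes[, c("node", "height", "n_leaves", "bp", "au", "flag")])
  invisible(x)
}

#' Clusters strongly supported by the data
#'
#' Internal nodes with AU above the threshold (the conventional 0.95
#' highlight level). The root, which is supported trivially, is excluded
#' unless requested.
#'
#' @param fit A `drm_cluster_support` from [cluster_support()].
#' @param threshold AU threshold (default 0.95; strict inequality).
#' @param include_root Keep the root node? Default `FALSE`.
#' @return The supported rows of `fit$nodes`.
#' @export
supported_clusters <- function(fit, threshold = 0.95,
                               include_root = FALSE) {
  stopifnot(inherits(fit, "drm_cluster_support"))
  nodes <- fit$nodes
  if (!include_root) nodes <- nodes[nodes$flag != "root", ]
  nodes[nodes$au > threshold, ]
}

#' Serialize a cluster-support fit to JSON
#'
#' Writes the dendrogram as nested `{children, height, au, bp}` nodes.
#'
#' @param fit A `drm_cluster_support`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_cluster_json <- function(fit, path) {
  stopifnot(inherits(fit, "drm_cluster_support"))
  hc <- fit$dendro$hclust
  labs <- fit$dendro$labels
  build <- function(k) {
    if (k < 0) return(list(leaf = labs[-k]))
    list(children = lapply(hc$merge[k, ], build),
         height = hc$height[k],
         au = fit$nodes$au[k],
         bp = fit$nodes$bp[k])
  }
  tree <- build(nrow(hc$merge))
  jsonlite::write_json(
    list(seed = fit$seed, nboot = fit$nboot, scales = fit$scales,
         tree = tree),
    path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' @export
autoplot.drm_cluster_support <- function(object, threshold = 0.95, ...) {
  hc <- object$dendro$hclust
  n <- length(object$dendro$labels)
  xpos <- numeric(2 * n - 1)  # leaves 1..n (as -i), nodes n+1..
  leaf_x <- match(seq_len(n), hc$order)
  coord <- function(k) if (k < 0) c(leaf_x[-k], 0) else
    c(node_x[k], hc$height[k])
  node_x <- numeric(n - 1)
  segs <- list()
  for (k in seq_len(n - 1)) {
    a <- coord(hc$merge[k, 1]); b <- coord(hc$merge[k, 2])
    node_x[k] <- (a[1] + b[1]) / 2
    h <- hc$height[k]
    segs[[k]] <- tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], h, b[2]), yend = c(h, h, h))
  }
  segs <- bind_rows(segs)
  nodes <- tibble(x = node_x, y = hc$height,
                  au = object$nodes$au,
                  supported = object$nodes$au > threshold &
                    object$nodes$flag != "root")
  leaves <- tibble(x = leaf_x, label = object$dendro$labels)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = sprintf("%.2f", .data$au),
                                     colour = .data$supported),
                        size = 2.7, label.padding = ggplot2::unit(0.1, "lines")) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red3",
                                            `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = -0.02, label = .data$label),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(y = "merge height (Euclidean, average linkage)", x = NULL,
                  title = "Activity clusters with AU support") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
plot.drm_cluster_support <- function(x, ...) print(autoplot(x, ...))
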