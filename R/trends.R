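## Copy-number trend detection: per-group gene counts are regressed on each
## species' phylogenetic distance from the in-group last common ancestor;
## groups whose slope ("rate of gene number change", copies per unit branch
## length) is a Tukey-fence outlier of the slope distribution are called
## contracting (negative) or expanding (positive).

#' Distance from the in-group LCA to each tip
#'
#' Sums branch lengths on the path from the most recent common ancestor of
#' `in_group` to each of its tips.
#'
#' @param tree An [ape::phylo] object or path to a Newick file. Branch
#'   lengths are required and must be non-negative.
#' @param in_group Character vector of tip labels (>= 1).
#' @return Named numeric vector of distances (branch-length units), one per
#'   in-group tip.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
#' distances_from_tree(tr, c("A", "B"))
#' @export
distances_from_tree <- function(tree, in_group) {
  if (is.character(tree) && length(tree) == 1L && file.exists(tree)) {
    tree <- ape::read.tree(tree)
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick file")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  missing <- setdiff(in_group, tree$tip.label)
  if (length(missing) > 0) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  tips <- match(in_group, tree$tip.label)
  if (length(in_group) == 1L) {
    return(stats::setNames(0, in_group))
  }
  mrca <- ape::getMRCA(tree, in_group)
  dd <- ape::dist.nodes(tree)
  stats::setNames(dd[mrca, tips], in_group)
}

#' Eligibility filter for orthologous groups
#'
#' A group enters the rate analysis only if it has genes in at least two
#' species (count > 0) and its per-species counts are not all identical.
#'
#' @param counts Integer matrix, rows = groups (rownames = group ids),
#'   columns = species.
#' @return List with `eligible` (character vector of group ids) and
#'   `excluded` (data frame `group_id`, `reason` with reasons
#'   `"fewer_than_2_species"` or `"identical_counts"`).
#' @export
filter_groups <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  n_present <- rowSums(counts > 0)
  identical_counts <- apply(counts, 1L, function(r) all(r == r[1L]))
  reason <- rep(NA_character_, nrow(counts))
  reason[identical_counts] <- "identical_counts"
  reason[n_present < 2] <- "fewer_than_2_species"
  ok <- is.na(reason)
  list(eligible = ids[ok],
       excluded = data.frame(group_id = ids[!ok], reason = reason[!ok]))
}

#' Ordinary least-squares rate of gene-number change
#'
#' Fits count ~ distance by OLS over all species (zero counts included) and
#' returns the slope — the rate of copy-number change per unit distance —
#' and intercept, via the closed form
#' `slope = sum((x - mean(x)) (y - mean(y))) / sum((x - mean(x))^2)`.
#'
#' @param counts Per-species counts.
#' @param distances Per-species distances to the LCA, matched to `counts`
#'   by name when both are named, else by position.
#' @return List with `slope` and `intercept`.
#' @examples
#' ols_rate(c(5, 3, 1), c(1, 2, 3))  # slope -2, intercept 7
#' @export
ols_rate <- function(counts, distances) {
  if (!is.null(names(counts)) && !is.null(names(distances))) {
    distances <- distances[names(counts)]
  }
  if (length(counts) != length(distances)) {
    stop("counts and distances must align")
  }
  x <- as.numeric(distances); y <- as.numeric(counts)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("slope undefined: all distances are equal")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Tukey-fence outliers of a rate distribution
#'
#' Quartiles are computed by linear interpolation (type-7, the default of
#' [stats::quantile()]); values below `Q1 - multiplier * IQR` or above
#' `Q3 + multiplier * IQR` are flagged.
#'
#' @param rates Named numeric vector (>= 4 finite values).
#' @param multiplier Fence multiplier (default 1.5).
#' @return List with `lower_fence`, `upper_fence`, `q1`, `q3`,
#'   `outlier_low`, `outlier_high` (names of flagged entries).
#' @examples
#' tukey_outliers(c(a = 0, b = 0, c = 0, d = 0, e = -5))
#' @export
tukey_outliers <- function(rates, multiplier = 1.5) {
  rates <- rates[is.finite(rates)]
  if (length(rates) < 4) stop("need at least 4 finite rates")
  if (is.null(names(rates))) names(rates) <- as.character(seq_along(rates))
  q <- stats::quantile(rates, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lower <- q[1] - multiplier * iqr
  upper <- q[2] + multiplier * iqr
  list(lower_fence = lower, upper_fence = upper, q1 = q[1], q3 = q[2],
       outlier_low = names(rates)[rates < lower],
       outlier_high = names(rates)[rates > upper])
}

#' Scan a count matrix for contracting and expanding groups
#'
#' The full trend pipeline: eligibility filtering ([filter_groups()]),
#' per-group OLS rates (vectorized closed form, identical to [ols_rate()]),
#' and Tukey-fence outlier calling over all eligible slopes
#' ([tukey_outliers()]). Groups below the lower fence are contracting,
#' above the upper fence expanding, within the fences neutral.
#'
#' @param counts Group x species integer matrix (rownames = group ids).
#' @param distances Named per-species distances to the LCA covering every
#'   column of `counts` (see [distances_from_tree()]).
#' @param multiplier Tukey fence multiplier (default 1.5).
#' @param include_zero_species Keep species with zero copies in each fit
#'   (default TRUE; zeros are data). When FALSE each group is fit on its
#'   nonzero species only (needs >= 2 distinct distances there).
#' @return Object of class `trend_scan`: a data frame with columns
#'   `group_id`, `slope`, `intercept`, `status`
#'   (expanding/contracting/neutral/excluded) and `reason_excluded`, plus
#'   attributes `fences` (from [tukey_outliers()]) and `summary` (counts of
#'   eligible/contracting/expanding groups).
#' @examples
#' d <- c(A = 1, B = 2, C = 3)
#' m <- rbind(g1 = c(5, 3, 1), g2 = c(2, 2, 3), g3 = c(2, 3, 2),
#'            g4 = c(3, 2, 2), g5 = c(2, 2, 2))
#' colnames(m) <- names(d)
#' classify_trends(m, d)
#' @export
classify_trends <- function(counts, distances, multiplier = 1.5,
                            include_zero_species = TRUE) {
  counts <- as.matrix(counts)
  ids <- rownames(counts)
  if (is.null(ids)) {
    ids <- as.character(seq_len(nrow(counts)))
    rownames(counts) <- ids
  }
  if (is.null(colnames(counts))) stop("counts must have species column names")
  missing <- setdiff(colnames(counts), names(distances))
  if (length(missing) > 0) {
    stop("distances missing for species: ", paste(missing, collapse = ", "))
  }
  x <- as.numeric(distances[colnames(counts)])

  flt <- filter_groups(counts)
  slope <- rep(NA_real_, nrow(counts)); names(slope) <- ids
  intercept <- slope
  elig <- ids %in% flt$eligible
  if (any(elig)) {
    if (include_zero_species) {
      xc <- x - mean(x)
      sxx <- sum(xc^2)
      if (sxx == 0) stop("slope undefined: all distances are equal")
      y <- counts[elig, , drop = FALSE]
      slope[elig] <- as.vector(y %*% xc) / sxx
      intercept[elig] <- rowMeans(y) - slope[elig] * mean(x)
    } else {
      for (g in ids[elig]) {
        keep <- counts[g, ] > 0
        if (length(unique(x[keep])) < 2) {
          elig[ids == g] <- FALSE
          flt$excluded <- rbind(flt$excluded, data.frame(
            group_id = g, reason = "fewer_than_2_distances_nonzero"))
          next
        }
        fit <- ols_rate(counts[g, keep], x[keep])
        slope[g] <- fit$slope; intercept[g] <- fit$intercept
      }
    }
  }

  status <- rep("excluded", nrow(counts)); names(status) <- ids
  fences <- NULL
  if (sum(elig) >= 4) {
    fences <- tukey_outliers(slope[elig], multiplier = multiplier)
    status[elig] <- "neutral"
    status[fences$outlier_low] <- "contracting"
    status[fences$outlier_high] <- "expanding"
  } else if (any(elig)) {
    status[elig] <- "neutral"
  }
  reason <- rep(NA_character_, nrow(counts)); names(reason) <- ids
  reason[flt$excluded$group_id] <- flt$excluded$reason

  out <- data.frame(group_id = ids, slope = slope, intercept = intercept,
                    status = status, reason_excluded = reason,
                    row.names = NULL)
  attr(out, "fences") <- fences
  attr(out, "summary") <- c(n_groups = nrow(counts),
                            n_eligible = sum(elig),
                            n_contracting = sum(status == "contracting"),
                            n_expanding = sum(status == "expanding"))
  class(out) <- c("trend_scan", "data.frame")
  out
}

#' @export
print.trend_scan <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "Trend scan: %d groups, %d eligible; %d contracting, %d expanding\n",
    s["n_groups"], s["n_eligible"], s["n_contracting"], s["n_expanding"]))
  f <- attr(x, "fences")
  if (!is.null(f)) {
    cat(sprintf("Tukey fences on rates: [%.4g, %.4g]\n",
                f$lower_fence, f$upper_fence))
  }
  invisible(x)
}

#' @method summary trend_scan
#' @export
summary.trend_scan <- function(object, ...) {
  s <- attr(object, "summary")
  f <- attr(object, "fences")
  structure(list(summary = s, fences = f,
                 contracting = object$group_id[object$status == "contracting"],
                 expanding = object$group_id[object$status == "expanding"]),
            class = "summary.trend_scan")
}

#' @export
print.summary.trend_scan <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$fences)) {
    cat(sprintf("fences: [%.4g, %.4g]\n",
                x$fences$lower_fence, x$fences$upper_fence))
  }
  cat("contracting:", paste(utils::head(x$contracting, 20), collapse = " "),
      if (length(x$contracting) > 20) "..." else "", "\n")
  cat("expanding:  ", paste(utils::head(x$expanding, 20), collapse = " "),
      if (length(x$expanding) > 20) "..." else "", "\n")
  invisible(x)
}

#' Plot a rate distribution with its Tukey fences
#'
#' Strip plot of per-group rates; the band between the fences holds the
#' neutral groups, points outside are contracting/expanding outliers.
#'
#' @param x A `trend_scan`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @method plot trend_scan
#' @export
plot.trend_scan <- function(x, ...) {
  ok <- x$status != "excluded"
  r <- x$slope[ok]
  jitter_y <- stats::runif(length(r))
  cols <- c(neutral = "grey50", contracting = "firebrick",
            expanding = "steelblue")
  plot(r, jitter_y, pch = 16, col = cols[x$status[ok]],
       xlab = "rate of gene number change (copies per unit distance)",
       ylab = "", yaxt = "n", ...)
  f <- attr(x, "fences")
  if (!is.null(f)) abline(v = c(f$lower_fence, f$upper_fence), lty = 2)
  invisible(x)
}
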