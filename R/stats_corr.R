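# Source-screening statistics: normality pre-check, Spearman correlation
# matrix with significance flags, and hierarchical clustering of the metals
# for heatmap ordering.

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of a vector against a normal distribution with the
#' sample's own mean and SD. Used as a pre-check to justify the
#' nonparametric correlation choice; with fitted parameters the p-values
#' are conservative, which is acceptable for that purpose.
#'
#' @param values Numeric vector, at least 5 non-degenerate observations.
#' @return List with `statistic` and `p.value`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 observations")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero standard deviation")
  kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values), s))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Spearman correlation matrix across metals
#'
#' Pairs observations of two metals by (site, date) within the requested
#' period, drops unmatched records pairwise, and computes the Spearman rank
#' correlation (average ranks for ties) with the large-sample two-sided
#' p-value. Pairs with fewer than `min_n` complete observations are marked
#' missing (`NA`), never reported as zero.
#'
#' @param dataset An `"hm_dataset"`.
#' @param period `"APR_SEP"`, `"OCT_MAR"` or `"ALL"` (pool both periods).
#' @param min_n Minimum complete pairs per correlation (default 5).
#' @return Object of class `"hm_cormat"`: matrices `rho`, `p`, `n` and a
#'   character `flag` matrix (`"p<0.01"`, `"p<0.05"`, `"ns"`).
#' @export
spearman_matrix <- function(dataset, period = c("ALL", "APR_SEP", "OCT_MAR"),
                            min_n = 5) {
  stopifnot(inherits(dataset, "hm_dataset"))
  period <- match.arg(period)
  r <- dataset$records
  if (period != "ALL") r <- r[assign_period(r$date) == period, , drop = FALSE]
  if (!nrow(r)) stop("no records in the requested period")
  wide <- stats::reshape(r, idvar = c("site", "date"), timevar = "metal",
                         direction = "wide")
  m <- hm_metals()
  cols <- paste0("concentration_ugL.", m)
  X <- as.matrix(wide[, intersect(cols, names(wide)), drop = FALSE])
  colnames(X) <- sub("^concentration_ugL\\.", "", colnames(X))
  k <- length(m)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(m, m))
  nmat <- matrix(0L, k, k, dimnames = list(m, m))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- m[i]; b <- m[j]
    if (!all(c(a, b) %in% colnames(X))) next
    ok <- stats::complete.cases(X[, c(a, b)])
    nmat[a, b] <- nmat[b, a] <- sum(ok)
    if (sum(ok) < min_n) next
    ct <- suppressWarnings(stats::cor.test(X[ok, a], X[ok, b],
                                           method = "spearman", exact = FALSE))
    rho[a, b] <- rho[b, a] <- unname(ct$estimate)
    p[a, b] <- p[b, a] <- ct$p.value
  }
  diag(nmat) <- if (nrow(X)) nrow(X) else 0L
  flag <- ifelse(is.na(p), NA_character_,
                 ifelse(p < 0.01, "p<0.01", ifelse(p < 0.05, "p<0.05", "ns")))
  structure(list(rho = rho, p = p, n = nmat, flag = flag, period = period),
            class = "hm_cormat")
}

#' @export
print.hm_cormat <- function(x, digits = 2, ...) {
  cat("Spearman correlation matrix (", x$period, ")\n", sep = "")
  print(round(x$rho, digits))
  cat("significance flags:\n")
  f <- x$flag; diag(f) <- ""
  print(f, quote = FALSE)
  invisible(x)
}

#' Hierarchical clustering of the metals
#'
#' Agglomerative clustering of the correlation matrix using the
#' dissimilarity `d = 1 - rho` and, by default, average linkage - the
#' standard choice for correlation heatmaps. The merge heights are
#' non-decreasing and the leaves are a permutation of the eight metals, in
#' an order fully determined by the matrix.
#'
#' @param cormat An `"hm_cormat"` (or a complete square correlation matrix).
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return Object of class `"hm_clust"` wrapping the `hclust` tree.
#' @export
cluster_metals <- function(cormat, method = "average") {
  rho <- if (inherits(cormat, "hm_cormat")) cormat$rho else as.matrix(cormat)
  if (any(is.na(rho))) {
    idx <- which(is.na(rho) & upper.tri(rho), arr.ind = TRUE)
    stop("incomplete correlation matrix; missing pair(s): ",
         paste(rownames(rho)[idx[, 1]], colnames(rho)[idx[, 2]],
               sep = "-", collapse = ", "))
  }
  hc <- stats::hclust(stats::as.dist(1 - rho), method = method)
  structure(list(hclust = hc, labels = rownames(rho), method = method),
            class = "hm_clust")
}

#' Cut the metal tree into groups
#'
#' @param tree An `"hm_clust"`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_metal_tree <- function(tree, k) stats::cutree(tree$hclust, k = k)

#' Export the cluster tree in Newick format
#'
#' @param tree An `"hm_clust"`.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
export_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' @export
print.hm_clust <- function(x, ...) {
  cat("Metal cluster tree (", x$method, " linkage, d = 1 - rho)\n", sep = "")
  cat("leaf order:", paste(x$labels[x$hclust$order], collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.hm_clust <- function(x, ...) {
  plot(x$hclust, main = "Metal clustering (d = 1 - Spearman rho)",
       xlab = "", sub = "", ...)
  invisible(x)
}

#' @export
plot.hm_cormat <- function(x, ...) {
  hc <- cluster_metals(x)$hclust
  stats::heatmap(x$rho, Rowv = stats::as.dendrogram(hc), symm = TRUE,
                 scale = "none", main = paste("Spearman rho,", x$period), ...)
  invisible(x)
}
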