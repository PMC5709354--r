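#' Hypergeometric gene-set over-representation test
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' query gene list and a gene set when drawing `|query|` genes from the
#' universe (`stats::phyper`). The gene set is intersected with the universe
#' before testing. When scanning a collection, apply [benjamini_hochberg()]
#' across the resulting p-values.
#'
#' @param query character vector of genes of interest (must lie in `universe`).
#' @param gene_set character vector defining the set.
#' @param universe character vector of all considered genes.
#' @return list with `p_value`, `overlap`, `set_size` (after intersection),
#'   `query_size` and `universe_size`.
#' @export
hypergeometric_enrichment <- function(query, gene_set, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (length(universe) == 0L) stop_ntp("empty universe")
  if (length(query) == 0L) stop_ntp("empty query")
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    stop_ntp("query gene(s) outside universe: ",
             paste(utils::head(outside, 5L), collapse = ", "))
  }
  set_u <- intersect(unique(as.character(gene_set)), universe)
  k <- length(intersect(query, set_u))
  p <- stats::phyper(k - 1, length(set_u), length(universe) - length(set_u),
                     length(query), lower.tail = FALSE)
  list(p_value = p, overlap = k, set_size = length(set_u),
       query_size = length(query), universe_size = length(universe))
}

#' Competitive gene-set test with fixed inter-gene correlation
#'
#' Tests whether the genes of a set have systematically larger (or smaller)
#' ranking statistics than the remaining genes, via a two-sample z-test on the
#' mean statistic with the in-set variance term inflated by
#' `VIF = 1 + (m - 1) * rho` to account for inter-gene correlation. A fixed,
#' user-settable `rho` (default 0.01) replaces residual-based estimation.
#'
#' @param stats named numeric vector of per-gene ranking statistics (e.g.
#'   moderated t from a contrast).
#' @param gene_set character vector; must overlap `stats` in >= 2 genes, else
#'   the test is skipped with a warning and `NA` p-values.
#' @param inter_gene_correlation assumed average correlation between set genes
#'   (>= 0).
#' @return list with `p_up`, `p_down` (one-sided normal p-values), `z`,
#'   `set_size`.
#' @export
competitive_gene_set_test <- function(stats, gene_set,
                                      inter_gene_correlation = 0.01) {
  stopifnot(is.numeric(stats), !is.null(names(stats)),
            inter_gene_correlation >= 0)
  in_set <- names(stats) %in% gene_set
  m <- sum(in_set)
  m2 <- sum(!in_set)
  if (m < 2L || m2 < 2L) {
    warning("gene set overlaps the statistics in < 2 genes (or leaves < 2 out); skipped",
            call. = FALSE)
    return(list(p_up = NA_real_, p_down = NA_real_, z = NA_real_, set_size = m))
  }
  vif <- 1 + (m - 1) * inter_gene_correlation
  delta <- mean(stats[in_set]) - mean(stats[!in_set])
  s2 <- ((m - 1) * stats::var(stats[in_set]) +
           (m2 - 1) * stats::var(stats[!in_set])) / (m + m2 - 2)
  z <- delta / sqrt(s2 * (vif / m + 1 / m2))
  list(p_up = stats::pnorm(z, lower.tail = FALSE),
       p_down = stats::pnorm(z, lower.tail = TRUE),
       z = z, set_size = m)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum score for one sample: genes are ordered by
#' decreasing expression; in-set genes add their rank weight
#' `|r|^weight` (normalized to sum 1 over the set), out-of-set genes subtract
#' a uniform step `1 / (N - m)`. The score is the sum of the running
#' statistic (the integrated deviation from zero); positive scores indicate
#' concentration of the set at the top of the ranking.
#'
#' @param sample_expr named numeric vector: one sample's expression per gene.
#' @param gene_set character vector; >= 2 genes must be present.
#' @param weight exponent on the rank weights (default 0.25; 0 gives equal
#'   weights and makes the score a pure rank statistic).
#' @return numeric enrichment score.
#' @export
ssgsea_score <- function(sample_expr, gene_set, weight = 0.25) {
  stopifnot(is.numeric(sample_expr), !is.null(names(sample_expr)), weight >= 0)
  in_set <- names(sample_expr) %in% gene_set
  if (sum(in_set) < 2L) stop_ntp("gene set overlaps the sample in < 2 genes")
  n <- length(sample_expr)
  m <- sum(in_set)
  if (n == m) stop_ntp("gene set covers every gene; score undefined")
  if (length(unique(sample_expr)) == 1L) {
    warning("degenerate ranking (all values equal); score 0", call. = FALSE)
    return(0)
  }
  # rank n = highest expression; walk the ranking from the top
  r <- rank(sample_expr, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  in_ord <- in_set[ord]
  w <- abs(r[ord])^weight
  steps <- ifelse(in_ord, w / sum(w[in_ord]), -1 / (n - m))
  sum(cumsum(steps))
}

#' Gene-set diagnostics across predicted classes
#'
#' For each assigned class, contrasts the class against the remaining assigned
#' samples with [moderated_t_test()] and runs [competitive_gene_set_test()] on
#' every set of the collection. Significance is reported as signed
#' -log10 p (positive = up in the class) with BH adjustment across all
#' class-by-set cells.
#'
#' @param emat genes x samples log2 expression matrix.
#' @param preds an `ntp` fit, or a class label vector (NA = not assigned)
#'   aligned with the columns of `emat`.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param inter_gene_correlation passed to [competitive_gene_set_test()].
#' @return data frame with columns `class`, `set`, `direction`, `p`, `adj_p`,
#'   `signed_log10_p`.
#' @export
gsa_summary <- function(emat, preds, collection, inter_gene_correlation = 0.01) {
  emat <- as_expression_matrix(emat)
  if (inherits(preds, "ntp")) {
    labels <- stats::setNames(preds$predictions$prediction,
                              preds$predictions$sample)
  } else {
    labels <- preds
  }
  labels <- stats::setNames(align_labels(labels, colnames(emat)), colnames(emat))
  labels <- labels[!is.na(labels)]
  counts <- table(labels)
  classes <- names(counts)[counts >= 2L]
  if (length(classes) < 2L) stop_ntp("need >= 2 assigned classes with >= 2 samples")
  if (length(collection) == 0L) {
    return(data.frame(class = character(0), set = character(0),
                      direction = character(0), p = numeric(0),
                      adj_p = numeric(0), signed_log10_p = numeric(0)))
  }
  rows <- list()
  for (cl in classes) {
    in_cl <- names(labels)[labels == cl]
    out_cl <- names(labels)[labels != cl & labels %in% classes]
    de <- moderated_t_test(emat, in_cl, out_cl)
    tstats <- stats::setNames(de$t_stat, de$gene)
    for (s in names(collection)) {
      res <- suppressWarnings(
        competitive_gene_set_test(tstats, collection[[s]],
                                  inter_gene_correlation))
      if (is.na(res$z)) next
      up <- res$p_up <= res$p_down
      p2 <- min(1, 2 * min(res$p_up, res$p_down))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, set = s, direction = if (up) "up" else "down",
        p = p2, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$signed_log10_p <- ifelse(out$direction == "up", 1, -1) *
    -log10(pmax(out$p, .Machine$double.xmin))
  out
}

#' Basic heatmap of a gene-set diagnostics table
#'
#' @param gsa_tab data frame from [gsa_summary()].
#' @param cap absolute cap on signed -log10 p for the color scale.
#' @param ... passed to [graphics::image()].
#' @export
plot_gsa_heatmap <- function(gsa_tab, cap = 10, ...) {
  sets <- unique(gsa_tab$set)
  classes <- unique(gsa_tab$class)
  z <- matrix(0, length(sets), length(classes),
              dimnames = list(sets, classes))
  z[cbind(match(gsa_tab$set, sets), match(gsa_tab$class, classes))] <-
    pmin(pmax(gsa_tab$signed_log10_p, -cap), cap)
  graphics::image(seq_along(classes), seq_along(sets), t(z), axes = FALSE,
                  xlab = "", ylab = "", zlim = c(-cap, cap),
                  col = grDevices::hcl.colors(51, "Blue-Red 2"), ...)
  graphics::axis(1, seq_along(classes), classes, las = 2, tick = FALSE)
  graphics::axis(2, seq_along(sets), sets, las = 2, tick = FALSE, cex.axis = 0.7)
  graphics::box()
  invisible(z)
}
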