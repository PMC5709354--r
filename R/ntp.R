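#' Cosine similarity between two vectors
#'
#' On row-centered data cosine similarity equals the Pearson correlation, which
#' is why nearest-template prediction defaults to centered/scaled input.
#'
#' @param x,t numeric vectors of equal length >= 2, neither all-zero.
#' @return similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(x, t) {
  if (length(x) != length(t)) stop_ntp("vectors must have equal length")
  if (length(x) < 2L) stop_ntp("vectors must have length >= 2")
  nx <- sqrt(sum(x^2))
  nt <- sqrt(sum(t^2))
  if (nx == 0 || nt == 0) stop_ntp("similarity undefined for a zero-norm vector")
  sum(x * t) / (nx * nt)
}

#' Build the gene-by-class indicator matrix for a template set
#'
#' Restricts the template to genes present in the expression matrix (in matrix
#' row order) and encodes class membership as a 0/1 indicator matrix. Each
#' class must retain at least `min_fraction` of its genes.
#'
#' @param templates a [template_set()].
#' @param emat genes x samples expression matrix.
#' @param min_fraction minimum fraction of each class's genes that must be
#'   present in `emat`.
#' @return list with `genes` (retained template genes, in `emat` order) and
#'   `indicators` (genes x classes 0/1 matrix).
#' @export
build_template_matrix <- function(templates, emat, min_fraction = 0.5) {
  stopifnot(inherits(templates, "template_set"))
  emat <- as_expression_matrix(emat)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  present <- lapply(templates$members, function(g) g[g %in% rownames(emat)])
  frac <- lengths(present) / lengths(templates$members)
  if (any(frac < min_fraction)) {
    bad <- which(frac < min_fraction)
    stop_ntp("template coverage below ", min_fraction, " for class(es): ",
             paste(sprintf("%s (%d/%d)", templates$classes[bad],
                           lengths(present)[bad],
                           lengths(templates$members)[bad]),
                   collapse = ", "))
  }
  missing_n <- lengths(templates$members) - lengths(present)
  for (i in which(missing_n > 0L)) {
    message(templates$classes[i], ": ", lengths(present)[i], "/",
            lengths(templates$members)[i], " template genes matched")
  }
  genes <- rownames(emat)[rownames(emat) %in% unlist(present, use.names = FALSE)]
  ind <- vapply(templates$classes,
                function(cl) as.numeric(genes %in% present[[cl]]),
                numeric(length(genes)))
  ind <- matrix(ind, nrow = length(genes),
                dimnames = list(genes, templates$classes))
  list(genes = genes, indicators = ind)
}

# Cosine similarities between every sample (column of X, genes x samples) and
# every class indicator column. Returns samples x classes.
template_similarities <- function(X, ind) {
  dots <- crossprod(X, ind)                       # samples x classes
  xn <- sqrt(colSums(X^2))
  tn <- sqrt(colSums(ind))
  sweep(dots / pmax(xn, .Machine$double.eps), 2L, pmax(tn, .Machine$double.eps), "/")
}

# Null distribution of the max-over-class similarity: `n_resample` random gene
# sets of the template's total size drawn without replacement from all genes of
# X, reusing the same indicator partition. Returns n_resample x samples matrix.
# Draws are shared across samples and processed in chunks to bound memory.
null_max_similarity <- function(X, ind, n_resample, chunk_elems = 5e6) {
  m <- nrow(ind)
  n_all <- nrow(X)
  k <- ncol(ind)
  tn <- sqrt(colSums(ind))
  pos <- lapply(seq_len(k), function(j) which(ind[, j] == 1))
  X2 <- X^2
  chunk <- max(1L, as.integer(chunk_elems / (m * ncol(X))))
  out <- matrix(NA_real_, n_resample, ncol(X))
  done <- 0L
  while (done < n_resample) {
    r <- min(chunk, n_resample - done)
    idx <- vapply(seq_len(r), function(i) sample.int(n_all, m), integer(m))
    grp_all <- rep(seq_len(r), each = m)
    norms <- sqrt(rowsum(X2[as.vector(idx), , drop = FALSE], grp_all))
    best <- matrix(-Inf, r, ncol(X))
    for (j in seq_len(k)) {
      rows <- idx[pos[[j]], , drop = FALSE]
      dots <- rowsum(X[as.vector(rows), , drop = FALSE],
                     rep(seq_len(r), each = length(pos[[j]])))
      sim <- dots / pmax(norms, .Machine$double.eps) / tn[j]
      best <- pmax(best, sim)
    }
    out[done + seq_len(r), ] <- best
    done <- done + r
  }
  out
}

#' Nearest-template prediction
#'
#' Classifies each sample to the subtype template with the highest cosine
#' similarity between the sample's (optionally row-centered/scaled) expression
#' over the template genes and the class's 0/1 indicator vector. Prediction
#' confidence is estimated by gene resampling: random gene sets of the
#' template's total size are drawn without replacement from all genes of the
#' matrix, the indicator partition is reused, and the per-sample p-value is the
#' fraction of null maximum similarities at least as large as the observed
#' maximum, with a `(1 + x) / (n + 1)` correction so p is never zero. P-values
#' are Benjamini-Hochberg adjusted across samples and samples with adjusted
#' p > `alpha` are left not assigned.
#'
#' @param emat genes x samples expression matrix (log2 scale). Rows with
#'   missing values are dropped with a message.
#' @param templates a [template_set()].
#' @param n_resample number of random gene sets for the null (default 1000).
#' @param alpha adjusted-p threshold above which a sample is not assigned.
#' @param seed integer seed for the resampling draws (default 7); the caller's
#'   RNG state is untouched.
#' @param do_row_scale row-center and scale `emat` first (default TRUE;
#'   requires >= 2 samples). On centered data cosine similarity equals Pearson
#'   correlation.
#' @param min_fraction per-class minimum template coverage, see
#'   [build_template_matrix()].
#' @param warn_small warn when fewer than 40 samples are scaled (cross-sample
#'   statistics from small cohorts make predictions unstable).
#' @return an object of class `ntp`; see [as.data.frame.ntp()].
#' @examples
#' sim <- simulate_cohort(n_samples = 40, n_genes = 300, markers_per_class = 10,
#'                        seed = 1)
#' tpl <- template_set(sim$truth$marker_map)
#' fit <- ntp(sim$emat, tpl, n_resample = 200, seed = 1)
#' fit
#' @export
ntp <- function(emat, templates, n_resample = 1000, alpha = 0.05, seed = 7,
                do_row_scale = TRUE, min_fraction = 0.5, warn_small = TRUE) {
  emat <- as_expression_matrix(emat)
  stopifnot(inherits(templates, "template_set"))
  if (n_resample < 1L) stop_ntp("n_resample must be >= 1")
  stopifnot(alpha > 0, alpha < 1)
  emat <- drop_incomplete_rows(emat, "nearest-template prediction")
  if (do_row_scale) {
    if (ncol(emat) < 2L) {
      stop_ntp("row scaling needs >= 2 samples; use do_row_scale = FALSE for a single sample")
    }
    if (warn_small && ncol(emat) < 40L) {
      warning("fewer than 40 samples: cross-sample centering/scaling from ",
              "small cohorts makes predictions uncertain", call. = FALSE)
    }
    emat <- row_center_scale(emat)
  }
  tm <- build_template_matrix(templates, emat, min_fraction)
  X_t <- emat[tm$genes, , drop = FALSE]
  sims <- template_similarities(X_t, tm$indicators)
  obs_max <- apply(sims, 1L, max)
  top <- apply(sims, 1L, function(s) {
    hits <- which(s >= max(s) - 1e-12)
    c(which.max(s), length(hits))
  })
  pred_idx <- top[1L, ]
  tie_flag <- top[2L, ] > 1L
  if (any(tie_flag)) {
    warning(sum(tie_flag), " sample(s) with tied similarities; ",
            "broken toward the earliest template class", call. = FALSE)
    pred_idx[tie_flag] <- apply(sims[tie_flag, , drop = FALSE], 1L, function(s) {
      min(which(s >= max(s) - 1e-12))
    })
  }
  null_max <- with_seed(seed, null_max_similarity(emat, tm$indicators, n_resample))
  exceed <- colSums(null_max >= rep(obs_max - 1e-12, each = n_resample))
  p <- (1 + exceed) / (n_resample + 1)
  fdr <- stats::p.adjust(p, method = "BH")
  prediction <- templates$classes[pred_idx]
  prediction[fdr > alpha] <- NA_character_
  res <- list(
    predictions = data.frame(
      sample = colnames(emat),
      prediction = prediction,
      p_value = p, fdr = fdr, tie_flag = tie_flag,
      stringsAsFactors = FALSE, row.names = NULL),
    similarity = sims,
    best_class = templates$classes[pred_idx],
    templates = templates,
    template_genes = tm$genes,
    scaled = if (do_row_scale) X_t else NULL,
    n_resample = n_resample, alpha = alpha, seed = seed,
    do_row_scale = do_row_scale,
    call = match.call())
  class(res) <- "ntp"
  res
}

#' Extract the prediction table from an `ntp` fit
#'
#' @param x an `ntp` fit.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with columns `sample`, `prediction` (`NA` when not
#'   assigned), one `similarity.<class>` column per class, `p_value`, `fdr`
#'   and `tie_flag`.
#' @export
as.data.frame.ntp <- function(x, row.names = NULL, optional = FALSE, ...) {
  sims <- as.data.frame(x$similarity)
  names(sims) <- paste0("similarity.", colnames(x$similarity))
  cbind(x$predictions[, c("sample", "prediction")], sims,
        x$predictions[, c("p_value", "fdr", "tie_flag")])
}

#' @export
print.ntp <- function(x, ...) {
  cat("Nearest-template prediction fit\n")
  cat("  ", ncol(x$similarity), " classes, ", length(x$template_genes),
      " template genes, ", nrow(x$predictions), " samples\n", sep = "")
  cat("  resampling n = ", x$n_resample, ", alpha = ", x$alpha, "\n", sep = "")
  tab <- table(factor(x$predictions$prediction, levels = x$templates$classes),
               useNA = "ifany")
  n_na <- sum(is.na(x$predictions$prediction))
  cat("  calls:", paste(sprintf("%s=%d", names(tab)[!is.na(names(tab))],
                                tab[!is.na(names(tab))]), collapse = " "),
      sprintf("not_assigned=%d", n_na), "\n")
  invisible(x)
}

#' @export
summary.ntp <- function(object, ...) {
  pr <- object$predictions
  out <- list(
    n = nrow(pr),
    n_assigned = sum(!is.na(pr$prediction)),
    class_counts = table(factor(pr$prediction, levels = object$templates$classes)),
    median_p = stats::median(pr$p_value),
    alpha = object$alpha)
  class(out) <- "summary.ntp"
  out
}

#' @export
print.summary.ntp <- function(x, ...) {
  cat("Samples:", x$n, " assigned:", x$n_assigned,
      sprintf("(%.1f%%)", 100 * x$n_assigned / x$n), "\n")
  print(x$class_counts)
  cat("Median resampling p:", signif(x$median_p, 3),
      " (alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Heatmap of template-gene expression ordered by prediction
#'
#' Displays the row-scaled expression of the template genes with samples
#' grouped by predicted class and genes grouped by template class.
#'
#' @param x an `ntp` fit produced with `do_row_scale = TRUE`.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.ntp <- function(x, main = "template-gene expression", ...) {
  if (is.null(x$scaled)) {
    stop_ntp("plotting needs a fit with do_row_scale = TRUE")
  }
  pred <- factor(x$best_class, levels = x$templates$classes)
  s_ord <- order(pred, x$predictions$fdr)
  gene_cls <- factor(
    rep(x$templates$classes,
        vapply(x$templates$members,
               function(g) sum(g %in% x$template_genes), integer(1))),
    levels = x$templates$classes)
  g_ord <- order(gene_cls)
  z <- x$scaled[x$template_genes[g_ord], s_ord, drop = FALSE]
  z <- pmin(pmax(z, -3), 3)
  graphics::image(t(z), axes = FALSE, main = main,
                  col = grDevices::hcl.colors(51, "Blue-Red 2"), ...)
  graphics::box()
  cuts <- cumsum(table(pred)[-nlevels(pred)]) / length(pred)
  graphics::abline(v = cuts, lwd = 2)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Validating wrapper over `stats::p.adjust(method = "BH")`: step-up adjusted
#' values `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted values in input order; elementwise >= `pvals`.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0L) stop_ntp("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop_ntp("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}
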