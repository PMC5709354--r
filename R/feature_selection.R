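#' Moderated two-group differential expression
#'
#' Empirical-Bayes moderated t-tests (limma `lmFit` + `eBayes`) for one
#' group-A-versus-group-B contrast on log2 expression. Gene-wise residual
#' variances are shrunk toward a common prior estimated from all genes; with
#' homogeneous gene variances the moderated t reduces to the ordinary pooled
#' two-sample t.
#'
#' @param emat genes x samples log2 expression matrix.
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   length >= 2.
#' @return data frame with columns `gene`, `lfc` (mean A - mean B), `t_stat`,
#'   `p`, `adj_p` (BH) and `mean_expr`.
#' @export
moderated_t_test <- function(emat, group_a, group_b) {
  emat <- as_expression_matrix(emat)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_ntp("each group needs >= 2 samples")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop_ntp("groups must be disjoint")
  }
  missing_s <- setdiff(c(group_a, group_b), colnames(emat))
  if (length(missing_s) > 0L) {
    stop_ntp("sample id(s) not in matrix: ", paste(missing_s, collapse = ", "))
  }
  sub <- emat[, c(group_a, group_b), drop = FALSE]
  sub <- drop_incomplete_rows(sub, "differential expression")
  design <- cbind(intercept = 1,
                  groupA = as.numeric(colnames(sub) %in% group_a))
  fit <- limma::eBayes(limma::lmFit(sub, design))
  tab <- limma::topTable(fit, coef = "groupA", number = Inf, sort.by = "none")
  data.frame(gene = rownames(sub),
             lfc = tab$logFC,
             t_stat = tab$t,
             p = tab$P.Value,
             adj_p = tab$adj.P.Val,
             mean_expr = rowMeans(sub),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Candidate subtype markers by one-versus-rest differential expression
#'
#' For each class, genes over-expressed versus the remaining samples
#' (`lfc > lfc_min` and BH-adjusted `p < adjp_max`). A gene qualifying for
#' several classes is assigned to the class with the largest fold change; an
#' exact tie excludes the gene with a message.
#'
#' @param emat genes x samples log2 expression matrix.
#' @param labels class label per sample (named by sample id, or in column
#'   order); >= 2 classes, each with >= 2 samples.
#' @param lfc_min log2 fold-change threshold (default 1).
#' @param adjp_max adjusted-p threshold (default 0.1).
#' @return named list, class -> candidate gene vector, with attribute
#'   `tables` holding the per-class DE tables.
#' @export
candidate_markers <- function(emat, labels, lfc_min = 1, adjp_max = 0.1) {
  emat <- as_expression_matrix(emat)
  labels <- align_labels(labels, colnames(emat))
  classes <- unique(labels)
  if (length(classes) < 2L) stop_ntp("need >= 2 classes")
  counts <- table(factor(labels, levels = classes))
  small <- classes[counts < 2L]
  if (length(small) > 0L) {
    stop_ntp("class(es) with < 2 samples: ", paste(small, collapse = ", "))
  }
  tables <- lapply(classes, function(cl) {
    moderated_t_test(emat, colnames(emat)[labels == cl],
                     colnames(emat)[labels != cl])
  })
  names(tables) <- classes
  pass <- lapply(tables, function(tb) {
    tb$gene[tb$lfc > lfc_min & tb$adj_p < adjp_max]
  })
  # resolve multi-class qualifiers by largest lfc; exact ties excluded
  all_pass <- unique(unlist(pass, use.names = FALSE))
  out <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) out[[cl]] <- character(0)
  for (g in all_pass) {
    hit <- classes[vapply(classes, function(cl) g %in% pass[[cl]], logical(1))]
    if (length(hit) == 1L) {
      out[[hit]] <- c(out[[hit]], g)
    } else {
      lfcs <- vapply(hit, function(cl) {
        tb <- tables[[cl]]
        tb$lfc[tb$gene == g]
      }, numeric(1))
      best <- which(lfcs == max(lfcs))
      if (length(best) > 1L) {
        message("gene ", g, " tied between classes ",
                paste(hit[best], collapse = ", "), "; excluded")
      } else {
        out[[hit[best]]] <- c(out[[hit[best]]], g)
      }
    }
  }
  attr(out, "tables") <- tables
  out
}

#' Robust cell-line marker filter
#'
#' Keeps genes that are informative in pure cancer cell populations: (i) the
#' cross-sample 10th-to-90th inter-percentile range (IPR) of expression lies in
#' the top `ipr_top_fraction` of all genes, and (ii) the gene's expression is
#' in the top `expr_top_fraction` of its sample's genes in at least
#' `min_samples` samples. Both "top" thresholds are strict (>) at the
#' corresponding percentile, computed with linear interpolation.
#'
#' @param cellline_emat genes x samples log2 expression matrix from a panel
#'   without stromal content.
#' @param ipr_top_fraction fraction of genes kept by the IPR criterion.
#' @param expr_top_fraction within-sample top-expression fraction.
#' @param min_samples minimum number of samples for criterion (ii).
#' @return character vector of genes passing both criteria.
#' @export
robust_intrinsic_filter <- function(cellline_emat, ipr_top_fraction = 0.25,
                                    expr_top_fraction = 0.25, min_samples = 3) {
  emat <- as_expression_matrix(cellline_emat)
  stopifnot(ipr_top_fraction > 0, ipr_top_fraction <= 1,
            expr_top_fraction > 0, expr_top_fraction <= 1)
  if (ncol(emat) < min_samples) {
    stop_ntp("need >= ", min_samples, " samples, got ", ncol(emat))
  }
  emat <- drop_incomplete_rows(emat, "robust marker filtering")
  q <- apply(emat, 1L, stats::quantile, probs = c(0.1, 0.9), names = FALSE)
  ipr <- q[2L, ] - q[1L, ]
  ipr_cut <- stats::quantile(ipr, probs = 1 - ipr_top_fraction, names = FALSE)
  pass_ipr <- ipr > ipr_cut
  col_cuts <- apply(emat, 2L, stats::quantile,
                    probs = 1 - expr_top_fraction, names = FALSE)
  n_top <- rowSums(sweep(emat, 2L, col_cuts, ">"))
  pass_expr <- n_top >= min_samples
  keep <- rownames(emat)[pass_ipr & pass_expr]
  if (length(keep) == 0L) {
    warning("no genes pass the robust filter (degenerate input?)", call. = FALSE)
  }
  keep
}

#' Intrinsic marker filter from a tumor/xenograft contrast
#'
#' Genes strongly reduced in xenografts relative to primary tumors are
#' attributable to the human tumor microenvironment (stroma, immune
#' infiltrate). The filter keeps genes whose primary-versus-xenograft log2
#' fold-change is below `lfc_max`; no p-value threshold is applied.
#'
#' @param pcrc_emat primary-tumor expression matrix.
#' @param pdx_emat xenograft expression matrix (the gene intersection with
#'   `pcrc_emat` is used).
#' @param lfc_max exclusion threshold on the tumor-minus-xenograft fold change
#'   (default 2).
#' @return character vector of intrinsic genes (lfc < `lfc_max`).
#' @export
intrinsic_filter <- function(pcrc_emat, pdx_emat, lfc_max = 2) {
  pcrc_emat <- as_expression_matrix(pcrc_emat)
  pdx_emat <- as_expression_matrix(pdx_emat)
  genes <- intersect(rownames(pcrc_emat), rownames(pdx_emat))
  if (length(genes) == 0L) stop_ntp("empty gene intersection between cohorts")
  a <- pcrc_emat[genes, , drop = FALSE]
  b <- pdx_emat[genes, , drop = FALSE]
  colnames(a) <- paste0("pcrc.", colnames(a))
  colnames(b) <- paste0("pdx.", colnames(b))
  de <- moderated_t_test(cbind(a, b), colnames(a), colnames(b))
  de$gene[de$lfc < lfc_max]
}

#' Intersect the three marker filters into a template set
#'
#' Per class, the template is `candidates\[class\] ∩ robust ∩
#' intrinsic`. A filter report records, for every candidate gene, the first
#' filter it failed.
#'
#' @param candidates named list from [candidate_markers()].
#' @param robust gene vector from [robust_intrinsic_filter()].
#' @param intrinsic gene vector from [intrinsic_filter()].
#' @return object of class `template_derivation`: list with `template`
#'   (a [template_set()]) and `report` (data frame with columns `gene`,
#'   `candidate_for`, `passed_robust`, `passed_intrinsic`, `final_class`,
#'   `removal_reason`).
#' @export
derive_template <- function(candidates, robust, intrinsic) {
  if (!is.list(candidates) || is.null(names(candidates))) {
    stop_ntp("candidates must be a named list (class -> genes)")
  }
  genes <- unlist(candidates, use.names = FALSE)
  cls <- rep(names(candidates), lengths(candidates))
  passed_robust <- genes %in% robust
  passed_intrinsic <- genes %in% intrinsic
  final <- ifelse(passed_robust & passed_intrinsic, cls, NA_character_)
  reason <- ifelse(!passed_robust, "not_robust",
                   ifelse(!passed_intrinsic, "not_intrinsic", "retained"))
  report <- data.frame(gene = genes, candidate_for = cls,
                       passed_robust = passed_robust,
                       passed_intrinsic = passed_intrinsic,
                       final_class = final, removal_reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  members <- lapply(stats::setNames(names(candidates), names(candidates)),
                    function(cl) genes[cls == cl & !is.na(final)])
  empty <- names(members)[lengths(members) == 0L]
  if (length(empty) > 0L) {
    stop_ntp("class(es) with empty template after filtering: ",
             paste(empty, collapse = ", "))
  }
  structure(list(template = template_set(members), report = report),
            class = "template_derivation")
}

#' @export
print.template_derivation <- function(x, ...) {
  cat("Template derivation:", nrow(x$report), "candidate genes ->",
      sum(x$report$removal_reason == "retained"), "template genes\n")
  print(table(x$report$removal_reason))
  print(x$template)
  invisible(x)
}

#' Run the full three-filter template derivation
#'
#' Convenience wrapper: candidate markers from a labeled tumor cohort, the
#' robustness filter from a cell-line panel, the intrinsic filter from a
#' paired tumor/xenograft contrast, intersected per class.
#'
#' @param tumor_emat labeled tumor cohort expression matrix.
#' @param tumor_labels class label per tumor sample.
#' @param cellline_emat cell-line panel expression matrix.
#' @param pcrc_emat,pdx_emat tumor and xenograft matrices for the intrinsic
#'   contrast.
#' @param lfc_min,adjp_max candidate thresholds, see [candidate_markers()].
#' @param ipr_top_fraction,expr_top_fraction,min_samples robustness thresholds,
#'   see [robust_intrinsic_filter()].
#' @param lfc_max intrinsic threshold, see [intrinsic_filter()].
#' @return a `template_derivation`, see [derive_template()].
#' @export
build_intrinsic_template <- function(tumor_emat, tumor_labels, cellline_emat,
                                     pcrc_emat, pdx_emat,
                                     lfc_min = 1, adjp_max = 0.1,
                                     ipr_top_fraction = 0.25,
                                     expr_top_fraction = 0.25, min_samples = 3,
                                     lfc_max = 2) {
  cand <- candidate_markers(tumor_emat, tumor_labels, lfc_min, adjp_max)
  robust <- robust_intrinsic_filter(cellline_emat, ipr_top_fraction,
                                    expr_top_fraction, min_samples)
  intrinsic <- intrinsic_filter(pcrc_emat, pdx_emat, lfc_max)
  derive_template(cand, robust, intrinsic)
}

# Align a label vector with sample ids: accepts a vector named by sample id or
# an unnamed vector in column order.
align_labels <- function(labels, sample_ids) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    missing_s <- setdiff(sample_ids, names(labels))
    if (length(missing_s) > 0L) {
      stop_ntp("no label for sample(s): ", paste(missing_s, collapse = ", "))
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop_ntp("labels length (", length(labels), ") != sample count (",
             length(sample_ids), ")")
  }
  unname(labels)
}
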