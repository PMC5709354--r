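#' Overall classification accuracy with not-assigned exclusion
#'
#' Overall accuracy is the number of classification agreements divided by the
#' number of cases, with not-assigned predictions (`NA`) excluded. Also
#' returns the confusion matrix and class-wise sensitivity/specificity over
#' the assigned samples.
#'
#' @param pred predicted labels (`NA` = not assigned), or an `ntp` fit.
#' @param ref reference labels of the same length.
#' @return list of class `accuracy_summary`: `accuracy`, `n_assigned`,
#'   `confusion` (reference x prediction), `sensitivity`, `specificity`.
#' @export
overall_accuracy <- function(pred, ref) {
  if (inherits(pred, "ntp")) pred <- pred$predictions$prediction
  pred <- as.character(pred)
  ref <- as.character(ref)
  if (length(pred) != length(ref)) stop_ntp("pred and ref lengths differ")
  keep <- !is.na(pred)
  if (!any(keep)) stop_ntp("accuracy undefined: zero assigned predictions")
  pred <- pred[keep]
  ref_k <- ref[keep]
  classes <- sort(unique(c(pred, ref_k)))
  conf <- table(reference = factor(ref_k, classes),
                prediction = factor(pred, classes))
  sens <- diag(conf) / pmax(rowSums(conf), 1L)
  spec <- vapply(classes, function(cl) {
    tn <- sum(conf[classes != cl, classes != cl])
    fp <- sum(conf[classes != cl, cl])
    if (tn + fp == 0L) NA_real_ else tn / (tn + fp)
  }, numeric(1))
  structure(list(accuracy = mean(pred == ref_k),
                 n_assigned = sum(keep),
                 n_total = length(keep),
                 confusion = conf,
                 sensitivity = sens,
                 specificity = spec),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("Overall accuracy %.3f over %d assigned of %d samples\n",
              x$accuracy, x$n_assigned, x$n_total))
  print(x$confusion)
  invisible(x)
}

#' Exact binomial test of accuracy against the no-information rate
#'
#' One-sided exact binomial p-value for observing at least `n_correct`
#' successes under the no-information rate (majority-class frequency), plus
#' the exact Clopper-Pearson 95% confidence interval for the accuracy.
#'
#' @param n_correct number of correct (assigned) classifications.
#' @param n_total number of assigned classifications.
#' @param no_information_rate baseline success probability in (0, 1).
#' @return list with `p_value`, `conf_int` (length 2), `estimate`.
#' @export
binomial_accuracy_test <- function(n_correct, n_total, no_information_rate) {
  stopifnot(n_total >= 1L, n_correct >= 0L, n_correct <= n_total)
  if (no_information_rate <= 0 || no_information_rate >= 1) {
    stop_ntp("no_information_rate must lie in (0, 1)")
  }
  bt <- stats::binom.test(n_correct, n_total, p = no_information_rate,
                          alternative = "greater")
  ci <- stats::binom.test(n_correct, n_total)$conf.int
  list(p_value = bt$p.value, conf_int = as.numeric(ci),
       estimate = n_correct / n_total)
}

#' Concordance between two classifications
#'
#' Fraction of agreements among samples assigned in both vectors.
#'
#' @param pred_a,pred_b label vectors of equal length (`NA` = not assigned).
#' @return list with `concordance` and `n_joint` (jointly assigned count).
#' @export
concordance <- function(pred_a, pred_b) {
  pred_a <- as.character(pred_a)
  pred_b <- as.character(pred_b)
  if (length(pred_a) != length(pred_b)) stop_ntp("prediction lengths differ")
  joint <- !is.na(pred_a) & !is.na(pred_b)
  if (!any(joint)) stop_ntp("concordance undefined: zero jointly assigned samples")
  list(concordance = mean(pred_a[joint] == pred_b[joint]),
       n_joint = sum(joint))
}

#' Fraction of samples consistently assigned across classifications
#'
#' A sample is consistently assigned when every classification in the list
#' assigns it, and always to the same class.
#'
#' @param pred_list list of label vectors of equal length.
#' @return fraction of consistently assigned samples.
#' @export
consistent_assignment <- function(pred_list) {
  stopifnot(is.list(pred_list), length(pred_list) >= 2L)
  mat <- do.call(cbind, lapply(pred_list, as.character))
  mean(apply(mat, 1L, function(r) !anyNA(r) && length(unique(r)) == 1L))
}

#' Random-subset stability of nearest-template prediction
#'
#' Repeatedly classifies random sample subsets of varying size against a fixed
#' template and records the overall accuracy versus a reference. Expression is
#' re-centered/scaled within each subset by default — the mechanism that makes
#' small cohorts unstable, since the cross-sample statistics then come from
#' few samples.
#'
#' @param emat genes x samples expression matrix (unscaled log2 data).
#' @param templates a [template_set()].
#' @param ref reference labels aligned with `emat` columns.
#' @param sizes subset sizes (default 10, 20, ..., 80).
#' @param reps subsets per size.
#' @param seed integer seed.
#' @param n_resample,alpha forwarded to [ntp()].
#' @param rescale_within_subset re-scale within each subset (default TRUE);
#'   FALSE scales once on the full matrix.
#' @return data frame with columns `size`, `rep`, `accuracy`, `n_assigned`.
#' @export
subset_stability <- function(emat, templates, ref, sizes = seq(10, 80, by = 10),
                             reps = 1000, seed = NULL, n_resample = 100,
                             alpha = 0.05, rescale_within_subset = TRUE) {
  emat <- as_expression_matrix(emat)
  ref <- align_labels(ref, colnames(emat))
  if (any(sizes < 2L)) stop_ntp("subset sizes must be >= 2 (scaling undefined)")
  if (max(sizes) > ncol(emat)) {
    stop_ntp("largest subset size exceeds the sample count")
  }
  base <- if (rescale_within_subset) emat else row_center_scale(emat)
  with_seed(seed, {
    grid <- expand.grid(rep = seq_len(reps), size = sizes)
    acc <- mapply(function(size, rep_i) {
      idx <- sample.int(ncol(emat), size)
      fit <- suppressWarnings(
        ntp(base[, idx, drop = FALSE], templates, n_resample = n_resample,
            alpha = alpha, seed = NULL,
            do_row_scale = rescale_within_subset, warn_small = FALSE))
      res <- tryCatch(overall_accuracy(fit, ref[idx]),
                      error = function(e) NULL)
      if (is.null(res)) c(NA_real_, 0) else c(res$accuracy, res$n_assigned)
    }, grid$size, grid$rep)
    data.frame(size = grid$size, rep = grid$rep,
               accuracy = acc[1L, ], n_assigned = acc[2L, ])
  })
}

#' Cycle-consistency experiment
#'
#' Tests whether classifications survive a round trip between sample types:
#' a fresh one-versus-rest marker template is derived from cohort A and its
#' (predicted) labels — excluding a given gene list, typically the original
#' template, from eligibility — and used to classify cohort B against
#' reference labels.
#'
#' @param emat_a cohort A expression matrix.
#' @param labels_a cohort A labels (e.g. predictions); >= 2 classes with >= 2
#'   samples each.
#' @param emat_b cohort B expression matrix.
#' @param ref_b cohort B reference labels.
#' @param exclude_genes genes barred from the new template.
#' @param lfc_min,adjp_max candidate thresholds, see [candidate_markers()].
#' @param n_resample,alpha,seed forwarded to [ntp()].
#' @return list with `accuracy` (an `accuracy_summary`), `template`, `fit`.
#' @export
cycle_consistency <- function(emat_a, labels_a, emat_b, ref_b,
                              exclude_genes = character(0),
                              lfc_min = 1, adjp_max = 0.1,
                              n_resample = 1000, alpha = 0.05, seed = 7) {
  emat_a <- as_expression_matrix(emat_a)
  labels_a <- align_labels(labels_a, colnames(emat_a))
  keep <- !is.na(labels_a)
  emat_a <- emat_a[, keep, drop = FALSE]
  labels_a <- labels_a[keep]
  counts <- table(labels_a)
  if (sum(counts >= 2L) < 2L) {
    stop_ntp("cohort A needs >= 2 classes with >= 2 samples each")
  }
  cand <- candidate_markers(emat_a, labels_a, lfc_min, adjp_max)
  cand <- lapply(cand, setdiff, y = exclude_genes)
  empty <- names(cand)[lengths(cand) == 0L]
  if (length(empty) > 0L) {
    stop_ntp("empty new template for class(es) after exclusion: ",
             paste(empty, collapse = ", "))
  }
  tpl <- template_set(cand)
  fit <- ntp(emat_b, tpl, n_resample = n_resample, alpha = alpha, seed = seed,
             warn_small = FALSE)
  ref_b <- align_labels(ref_b, colnames(emat_b))
  list(accuracy = overall_accuracy(fit, ref_b), template = tpl, fit = fit)
}

#' Template-perturbation concordance experiment
#'
#' Re-derives the template under perturbed settings (stringent candidate
#' adjusted-p, an independently simulated cell-line panel, a stricter
#' intrinsic fold-change threshold, exclusion of an extra stromal gene list),
#' classifies a cohort with each variant, and reports pairwise concordance
#' among jointly assigned samples.
#'
#' @param study a [simulate_study()] result (or an equivalently shaped list).
#' @param emat cohort to classify (defaults to the study's test cohort).
#' @param n_resample,alpha,seed forwarded to [ntp()].
#' @param strict_adjp perturbed candidate adjusted-p threshold (default 1e-4).
#' @param strict_lfc_max perturbed intrinsic threshold (default 1).
#' @param extra_exclude extra gene list to exclude (defaults to the study's
#'   true stromal genes, emulating an independently reported stromal list).
#' @return list with `predictions` (per-variant label matrix), `concordance`
#'   (pairwise matrix), `templates`.
#' @export
template_perturbation_concordance <- function(study, emat = NULL,
                                              n_resample = 1000, alpha = 0.05,
                                              seed = 7, strict_adjp = 1e-4,
                                              strict_lfc_max = 1,
                                              extra_exclude = NULL) {
  emat <- emat %||% study$test$emat
  extra_exclude <- extra_exclude %||% study$structure$stromal_genes
  tum <- study$tumor
  cand <- candidate_markers(tum$emat, tum$truth$labels)
  cand_strict <- candidate_markers(tum$emat, tum$truth$labels,
                                   adjp_max = strict_adjp)
  robust <- robust_intrinsic_filter(study$celllines$emat)
  alt_cell <- simulate_cohort(
    n_samples = ncol(study$celllines$emat),
    marker_lfc = study$tumor$truth$params$marker_lfc,
    noise_sd = study$tumor$truth$params$noise_sd,
    stromal_present = FALSE, structure = study$structure,
    seed = seed + 101)
  robust_alt <- robust_intrinsic_filter(alt_cell$emat)
  intrinsic <- intrinsic_filter(study$pair$tumor, study$pair$xenograft)
  intrinsic_strict <- intrinsic_filter(study$pair$tumor, study$pair$xenograft,
                                       lfc_max = strict_lfc_max)
  templates <- list(
    reference = derive_template(cand, robust, intrinsic)$template,
    strict_adjp = derive_template(cand_strict, robust, intrinsic)$template,
    alt_celllines = derive_template(cand, robust_alt, intrinsic)$template,
    strict_intrinsic = derive_template(cand, robust, intrinsic_strict)$template,
    extra_stromal = derive_template(
      cand, robust, setdiff(intrinsic, extra_exclude))$template)
  preds <- vapply(templates, function(tpl) {
    ntp(emat, tpl, n_resample = n_resample, alpha = alpha, seed = seed,
        warn_small = FALSE)$predictions$prediction
  }, character(ncol(emat)))
  nv <- length(templates)
  conc <- matrix(NA_real_, nv, nv, dimnames = list(names(templates),
                                                   names(templates)))
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      conc[i, j] <- concordance(preds[, i], preds[, j])$concordance
    }
  }
  list(predictions = preds, concordance = conc, templates = templates)
}
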