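#' Draw the shared gene structure for a synthetic study
#'
#' Baseline per-gene means (Normal(7, 1.5) on the log2 scale), disjoint
#' per-class marker blocks and a stromal gene block. Cohorts simulated from the
#' same structure share marker identities, which is what makes cross-cohort
#' experiments (template derivation on one cohort, classification of another)
#' meaningful.
#'
#' @param n_genes total gene count.
#' @param k_classes number of subtype classes.
#' @param markers_per_class planted markers per class.
#' @param stromal_genes number of stroma-associated genes.
#' @param seed integer seed.
#' @return list with `gene_ids`, `classes`, `baseline`, `marker_map`,
#'   `stromal_genes`.
#' @export
simulate_structure <- function(n_genes = 2000, k_classes = 4,
                               markers_per_class = 50, stromal_genes = 100,
                               seed = NULL) {
  if (k_classes * markers_per_class + stromal_genes > n_genes) {
    stop_ntp("gene budget infeasible: ", k_classes, "x", markers_per_class,
             " markers + ", stromal_genes, " stromal > ", n_genes, " genes")
  }
  if (k_classes < 2L) stop_ntp("need >= 2 classes")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  classes <- paste0("S", seq_len(k_classes))
  with_seed(seed, {
    baseline <- stats::setNames(stats::rnorm(n_genes, 7, 1.5), gene_ids)
    marker_map <- stats::setNames(lapply(seq_len(k_classes), function(i) {
      gene_ids[(i - 1L) * markers_per_class + seq_len(markers_per_class)]
    }), classes)
    stromal <- if (stromal_genes > 0L) {
      gene_ids[k_classes * markers_per_class + seq_len(stromal_genes)]
    } else character(0)
    list(gene_ids = gene_ids, classes = classes, baseline = baseline,
         marker_map = marker_map, stromal_genes = stromal)
  })
}

# One cohort from an existing structure; assumes the RNG is already seeded by
# the caller.
simulate_from_structure <- function(structure, n_samples, marker_lfc, noise_sd,
                                    stromal_lfc, stromal_present,
                                    sample_prefix = "s", count_mode = FALSE,
                                    class_overlap = 0) {
  k <- length(structure$classes)
  labels <- sample(rep(structure$classes, length.out = n_samples))
  n_genes <- length(structure$gene_ids)
  vals <- matrix(structure$baseline, n_genes, n_samples)
  dimnames(vals) <- list(structure$gene_ids,
                         sprintf("%s%03d", sample_prefix, seq_len(n_samples)))
  for (cl in structure$classes) {
    vals[structure$marker_map[[cl]], labels == cl] <-
      vals[structure$marker_map[[cl]], labels == cl] + marker_lfc
  }
  if (class_overlap > 0) {
    # class-boundary samples: each sample leans toward one random other class
    # with weight Uniform(0, class_overlap) on that class's markers
    neighbor <- vapply(labels, function(cl) {
      sample(setdiff(structure$classes, cl), 1L)
    }, character(1))
    w <- stats::runif(n_samples, 0, class_overlap)
    for (i in seq_len(n_samples)) {
      mk <- structure$marker_map[[neighbor[i]]]
      vals[mk, i] <- vals[mk, i] + w[i] * marker_lfc
    }
  }
  if (stromal_present && length(structure$stromal_genes) > 0L) {
    f_s <- stats::runif(n_samples, 0.3, 1)
    vals[structure$stromal_genes, ] <- vals[structure$stromal_genes, ] +
      stromal_lfc * rep(f_s, each = length(structure$stromal_genes))
  }
  vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                        n_genes, n_samples)
  if (count_mode) {
    counts <- matrix(stats::rpois(length(vals), lambda = 2^pmax(vals, 0)),
                     n_genes, n_samples, dimnames = dimnames(vals))
    libsize <- colSums(counts)
    vals <- log2(sweep(counts, 2L, stats::median(libsize) / libsize, "*") + 1)
  }
  list(emat = vals, labels = stats::setNames(labels, colnames(vals)))
}

#' Simulate a labeled expression cohort with planted subtype structure
#'
#' Gaussian log2-scale model: baseline per-gene means Normal(7, 1.5); each
#' sample of class c gains `marker_lfc` on that class's marker genes; in
#' stroma-containing cohorts (tumors) every sample gains
#' `stromal_lfc * f_s` on the stromal genes, where `f_s ~ Uniform(0.3, 1)` is
#' the sample's stromal fraction; i.i.d. Normal(0, `noise_sd`) noise is added.
#' Class proportions are equal up to rounding. With `count_mode = TRUE`,
#' Poisson counts with log-normal rates are drawn and returned as
#' library-size-scaled log2(count + 1).
#'
#' @param n_samples,n_genes,k_classes,markers_per_class,stromal_genes cohort
#'   dimensions; the defaults define the package's reference study conditions.
#' @param marker_lfc planted marker log2 fold-change (default 2).
#' @param noise_sd residual noise standard deviation (default 1).
#' @param stromal_lfc stromal log2 fold-change at full stromal fraction.
#'   The default 4.6 makes the expected realized stromal fold change
#'   `stromal_lfc * E[f_s] = 4.6 * 0.65` about 3, the scale at which
#'   stroma-derived markers collapse in xenografts.
#' @param stromal_present whether the cohort contains stroma (tumors TRUE,
#'   cell lines / xenografts FALSE).
#' @param class_overlap boundary-blending amount in \[0, 1\] (default 0).
#'   When positive, each sample additionally gains
#'   `Uniform(0, class_overlap) * marker_lfc` on the markers of one random
#'   other class, creating class-boundary samples like the intermediate
#'   tumors on which real subtype classifiers disagree.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param structure optional pre-drawn [simulate_structure()] (its dimensions
#'   override the corresponding arguments).
#' @param count_mode return Poisson-lognormal pseudo-counts on the log2 scale.
#' @return list with `emat` (genes x samples matrix) and `truth` (list:
#'   `labels`, `marker_map`, `stromal_genes`, `params`).
#' @export
simulate_cohort <- function(n_samples = 120, n_genes = 2000, k_classes = 4,
                            markers_per_class = 50, marker_lfc = 2,
                            noise_sd = 1, stromal_genes = 100, stromal_lfc = 4.6,
                            stromal_present = TRUE, seed = NULL,
                            structure = NULL, count_mode = FALSE,
                            class_overlap = 0) {
  params <- list(n_samples = n_samples, n_genes = n_genes,
                 k_classes = k_classes, markers_per_class = markers_per_class,
                 marker_lfc = marker_lfc, noise_sd = noise_sd,
                 stromal_genes = stromal_genes, stromal_lfc = stromal_lfc,
                 stromal_present = stromal_present, seed = seed,
                 count_mode = count_mode, class_overlap = class_overlap)
  with_seed(seed, {
    if (is.null(structure)) {
      structure <- simulate_structure(n_genes, k_classes, markers_per_class,
                                      stromal_genes, seed = NULL)
    }
    cohort <- simulate_from_structure(structure, n_samples, marker_lfc,
                                      noise_sd, stromal_lfc, stromal_present,
                                      count_mode = count_mode,
                                      class_overlap = class_overlap)
    list(emat = cohort$emat,
         truth = list(labels = cohort$labels,
                      marker_map = structure$marker_map,
                      stromal_genes = structure$stromal_genes,
                      structure = structure,
                      params = params))
  })
}

#' Simulate a paired tumor/xenograft cohort
#'
#' Two cohorts drawn from one shared gene structure with identical marker
#' effects; the tumor cohort carries the stromal signal
#' (`stromal_present = TRUE`), the xenograft cohort does not. Sample labels
#' are drawn independently per cohort.
#'
#' @inheritParams simulate_cohort
#' @return list with `tumor`, `xenograft` (each genes x samples matrices) and
#'   `truth` (shared structure plus per-cohort labels).
#' @export
simulate_model_pair <- function(n_samples = 120, n_genes = 2000, k_classes = 4,
                                markers_per_class = 50, marker_lfc = 2,
                                noise_sd = 1, stromal_genes = 100,
                                stromal_lfc = 4.6, seed = NULL,
                                structure = NULL) {
  with_seed(seed, {
    if (is.null(structure)) {
      structure <- simulate_structure(n_genes, k_classes, markers_per_class,
                                      stromal_genes, seed = NULL)
    }
    tum <- simulate_from_structure(structure, n_samples, marker_lfc, noise_sd,
                                   stromal_lfc, stromal_present = TRUE,
                                   sample_prefix = "t")
    xen <- simulate_from_structure(structure, n_samples, marker_lfc, noise_sd,
                                   stromal_lfc, stromal_present = FALSE,
                                   sample_prefix = "x")
    list(tumor = tum$emat, xenograft = xen$emat,
         truth = list(tumor_labels = tum$labels,
                      xenograft_labels = xen$labels,
                      marker_map = structure$marker_map,
                      stromal_genes = structure$stromal_genes,
                      structure = structure,
                      params = list(n_samples = n_samples, n_genes = n_genes,
                                    k_classes = k_classes,
                                    markers_per_class = markers_per_class,
                                    marker_lfc = marker_lfc,
                                    noise_sd = noise_sd,
                                    stromal_genes = stromal_genes,
                                    stromal_lfc = stromal_lfc, seed = seed)))
  })
}

#' Simulate the full multi-cohort study
#'
#' One shared gene structure feeding four cohorts: a stroma-containing labeled
#' tumor training cohort, a cell-line panel without stroma, a paired
#' tumor/xenograft cohort for the intrinsic contrast, and a fresh
#' stroma-containing tumor test cohort. This is the test bed for the
#' end-to-end template-derivation-plus-classification pipeline.
#'
#' @inheritParams simulate_cohort
#' @param n_celllines,n_pair,n_test sizes of the cell-line panel, each arm of
#'   the tumor/xenograft pair, and the test cohort.
#' @return list with `tumor`, `celllines`, `pair` (tumor/xenograft pair),
#'   `test` and the shared `structure`.
#' @export
simulate_study <- function(n_samples = 120, n_celllines = 120, n_pair = 40,
                           n_test = 120, n_genes = 2000, k_classes = 4,
                           markers_per_class = 50, marker_lfc = 2,
                           noise_sd = 1, stromal_genes = 100, stromal_lfc = 4.6,
                           seed = NULL) {
  with_seed(seed, {
    structure <- simulate_structure(n_genes, k_classes, markers_per_class,
                                    stromal_genes, seed = NULL)
    tumor <- simulate_cohort(n_samples, marker_lfc = marker_lfc,
                             noise_sd = noise_sd, stromal_lfc = stromal_lfc,
                             stromal_present = TRUE, structure = structure)
    cell <- simulate_cohort(n_celllines, marker_lfc = marker_lfc,
                            noise_sd = noise_sd, stromal_lfc = stromal_lfc,
                            stromal_present = FALSE, structure = structure)
    pair <- simulate_model_pair(n_pair, marker_lfc = marker_lfc,
                                noise_sd = noise_sd,
                                stromal_lfc = stromal_lfc,
                                structure = structure)
    test <- simulate_cohort(n_test, marker_lfc = marker_lfc,
                            noise_sd = noise_sd, stromal_lfc = stromal_lfc,
                            stromal_present = TRUE, structure = structure)
    list(tumor = tumor, celllines = cell, pair = pair, test = test,
         structure = structure)
  })
}
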