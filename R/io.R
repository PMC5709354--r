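#' Read a gene-by-sample expression matrix
#'
#' Reads tab-separated expression tables (first column gene ids, header row of
#' sample ids) or GCT 1.2 files. Gene identifiers are opaque strings matched by
#' exact, case-sensitive equality; duplicated gene ids are rejected.
#' Non-numeric cells become missing values with a message reporting the count.
#'
#' @param path path to the file.
#' @param format `"auto"` (from file extension), `"tsv"` or `"gct"`.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ntp("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || trimws(header[1L]) != "#1.2") {
      stop_ntp("malformed GCT header: line 1 must be '#1.2' in ", path)
    }
    dims <- suppressWarnings(as.integer(strsplit(header[2L], "\t")[[1L]][1:2]))
    if (any(is.na(dims))) {
      stop_ntp("malformed GCT dimension line (line 2) in ", path)
    }
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             stringsAsFactors = FALSE, colClasses = "character")
    if (ncol(tab) < 3L) stop_ntp("GCT table must have Name, Description and sample columns")
    ids <- tab[[1L]]
    raw <- tab[, -(1:2), drop = FALSE]
    if (nrow(tab) != dims[1L] || ncol(raw) != dims[2L]) {
      stop_ntp("GCT dimension line (", dims[1L], " x ", dims[2L],
               ") does not match table (", nrow(tab), " x ", ncol(raw), ")")
    }
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE, colClasses = "character")
    if (ncol(tab) < 2L) {
      stop_ntp("malformed header: expected gene id column plus >=1 sample column in ", path)
    }
    ids <- tab[[1L]]
    raw <- tab[, -1L, drop = FALSE]
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop_ntp("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, colnames(raw)))
  n_bad <- sum(is.na(vals) & !(raw == "NA" | raw == "" | is.na(raw)))
  if (n_bad > 0L) message(n_bad, " non-numeric cell(s) set to missing")
  as_expression_matrix(vals)
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' @param emat genes x samples numeric matrix.
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(emat, path, format = c("tsv", "gct")) {
  emat <- as_expression_matrix(emat)
  format <- match.arg(format)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(emat), ncol(emat), sep = "\t")), con)
    tab <- data.frame(Name = rownames(emat), Description = rownames(emat),
                      emat, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene = rownames(emat), emat,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a template set
#'
#' A template set maps each subtype class to its marker-gene list. Classes keep
#' their given order (ties in nearest-template prediction are broken toward the
#' earliest class); a gene may belong to at most one class.
#'
#' @param members named list, class label -> character vector of gene ids.
#' @return an object of class `template_set`.
#' @export
template_set <- function(members) {
  if (!is.list(members) || is.null(names(members)) || any(names(members) == "")) {
    stop_ntp("members must be a named list of gene id vectors")
  }
  if (length(members) < 2L) stop_ntp("a template set needs >= 2 classes")
  members <- lapply(members, function(g) unique(as.character(g)))
  empty <- names(members)[lengths(members) == 0L]
  if (length(empty) > 0L) {
    stop_ntp("class(es) with no genes: ", paste(empty, collapse = ", "))
  }
  all_genes <- unlist(members, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup) > 0L) {
    cls <- vapply(dup, function(g) {
      paste(names(members)[vapply(members, function(m) g %in% m, logical(1))],
            collapse = "+")
    }, character(1))
    stop_ntp("gene(s) assigned to multiple classes: ",
             paste(paste0(dup, " (", cls, ")"), collapse = ", "))
  }
  structure(list(classes = names(members), members = members),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat("Template set:", length(x$classes), "classes,",
      sum(lengths(x$members)), "genes\n")
  for (cl in x$classes) {
    g <- x$members[[cl]]
    cat("  ", cl, ": ", length(g), " genes (",
        paste(utils::head(g, 5L), collapse = ", "),
        if (length(g) > 5L) ", ..." else "", ")\n", sep = "")
  }
  invisible(x)
}

#' Read a template set from a two-column table
#'
#' Expects tab-separated columns gene id, class label; a header row is
#' auto-detected (first line starting with "gene" + tab, case-insensitive).
#' Classes are ordered by first appearance.
#'
#' @param path path to the template file.
#' @return a [template_set()].
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop_ntp("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_ntp("no template rows in ", path)
  if (grepl("^(gene|probe|id)\\b", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) stop_ntp("no template rows in ", path)
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) {
    stop_ntp("template rows must have two tab-separated columns (gene, class)")
  }
  gene <- vapply(parts, `[[`, character(1), 1L)
  cls <- vapply(parts, `[[`, character(1), 2L)
  template_set(split(gene, factor(cls, levels = unique(cls))))
}

#' Write a template set to a two-column TSV
#' @param templates a [template_set()].
#' @param path output path.
#' @export
write_template <- function(templates, path) {
  stopifnot(inherits(templates, "template_set"))
  tab <- data.frame(
    gene = unlist(templates$members, use.names = FALSE),
    class = rep(templates$classes, lengths(templates$members)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated fields name, description, gene ids.
#'
#' @param path path to the .gmt file.
#' @return named list of gene id vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_ntp("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 3L)) {
    stop_ntp("GMT lines must have >= 3 fields (name, description, genes)")
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop_ntp("duplicate gene set names: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  if (any(lengths(sets) == 0L)) {
    stop_ntp("empty gene set(s): ", paste(nm[lengths(sets) == 0L], collapse = ", "))
  }
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), nm)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of gene id vectors.
#' @param path output path.
#' @param description optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description") %||%
    rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write a prediction table
#'
#' Serializes per-sample class calls with per-class similarities, resampling
#' p-values and BH-adjusted p-values. Unassigned samples are written as the
#' literal `NA` in the prediction column.
#'
#' @param preds an `ntp` fit or the data frame from [as.data.frame.ntp()].
#' @param path output path.
#' @export
write_predictions <- function(preds, path) {
  if (inherits(preds, "ntp")) preds <- as.data.frame(preds)
  utils::write.table(preds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#' @param path path to the TSV.
#' @return data frame with a character `prediction` column (`NA` = unassigned).
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "NA")
}
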