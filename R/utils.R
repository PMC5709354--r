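#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL runs code with the current RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ntp <- function(...) stop(..., call. = FALSE)

# Validate a genes x samples expression matrix: numeric, unique finite-checked
# dimnames. Missing values (NA) are allowed; Inf is not.
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_ntp("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_ntp("expression matrix must have gene row names and sample column names")
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g) > 0L) {
    stop_ntp("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s) > 0L) {
    stop_ntp("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  }
  if (any(is.infinite(x))) {
    stop_ntp("expression matrix contains non-finite (Inf) values")
  }
  x
}

# Drop rows containing missing values, with a message stating how many.
drop_incomplete_rows <- function(x, context = "analysis") {
  bad <- rowSums(is.na(x)) > 0L
  if (any(bad)) {
    message(sum(bad), " gene(s) with missing values dropped before ", context)
    x <- x[!bad, , drop = FALSE]
  }
  x
}
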