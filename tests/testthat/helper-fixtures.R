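# Shared fixture builders: everything is generated in code at test time.

# tiny 3-gene x 2-sample matrix used by the io round-trip tests
tiny_emat <- function() {
  matrix(c(1.5, 2.25, 0, 3.125, 4, 5.5), nrow = 3,
         dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
}

write_tsv_fixture <- function(emat, path = tempfile(fileext = ".tsv")) {
  write_expression(emat, path, format = "tsv")
  path
}

write_gct_fixture <- function(emat, path = tempfile(fileext = ".gct")) {
  write_expression(emat, path, format = "gct")
  path
}

write_template_fixture <- function(members, path = tempfile(fileext = ".tsv"),
                                   header = TRUE) {
  lines <- unlist(mapply(function(cl, genes) paste(genes, cl, sep = "\t"),
                         names(members), members, SIMPLIFY = FALSE),
                  use.names = FALSE)
  if (header) lines <- c("gene\tclass", lines)
  writeLines(lines, path)
  path
}

# a small labeled cohort + matching template for classifier tests
small_labeled_case <- function(seed = 1, n = 30, genes = 400, markers = 8,
                               lfc = 3, sd = 0.5) {
  sim <- simulate_cohort(n_samples = n, n_genes = genes, k_classes = 3,
                         markers_per_class = markers, marker_lfc = lfc,
                         noise_sd = sd, stromal_genes = 0,
                         stromal_present = FALSE, seed = seed)
  list(sim = sim, tpl = template_set(sim$truth$marker_map))
}

# exact resampling-null p-value by enumerating every unordered split of
# `n_all` genes into the template's per-class blocks (independent oracle for
# the Monte-Carlo gene-resampling p)
enumerate_null_p <- function(x, class_sizes, obs_max) {
  n_all <- length(x)
  m <- sum(class_sizes)
  stopifnot(length(class_sizes) == 2L)  # oracle handles the 2-class case
  combs_a <- utils::combn(n_all, class_sizes[1L], simplify = FALSE)
  count <- 0L
  total <- 0L
  for (a in combs_a) {
    remaining <- setdiff(seq_len(n_all), a)
    combs_b <- utils::combn(remaining, class_sizes[2L], simplify = FALSE)
    for (b in combs_b) {
      sel <- c(x[a], x[b])
      ind_a <- c(rep(1, class_sizes[1L]), rep(0, class_sizes[2L]))
      ind_b <- 1 - ind_a
      nx <- sqrt(sum(sel^2))
      sim_a <- sum(sel * ind_a) / (nx * sqrt(class_sizes[1L]))
      sim_b <- sum(sel * ind_b) / (nx * sqrt(class_sizes[2L]))
      if (max(sim_a, sim_b) >= obs_max - 1e-12) count <- count + 1L
      total <- total + 1L
    }
  }
  c(p = count / total, total = total)
}
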