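# In-code fixture builders shared across test files.

# A dataset bundle with given expression values and minimal DFS clinical data.
make_bundle <- function(id, values, dfs_time = NULL, dfs_event = NULL,
                        clinical_extra = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("%s_s%02d", id, 1:n)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", 1:nrow(values))
  clin <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  if (!is.null(dfs_time)) {
    clin$dfs_time <- dfs_time
    clin$dfs_event <- dfs_event
  }
  if (!is.null(clinical_extra)) clin <- cbind(clin, clinical_extra)
  dataset_bundle(gene_matrix(values, id), clinical_table(clin))
}

# A small centroid model; `geometry` varies the separation structure so the
# recovery property is checked on models with distinct shapes.
make_centroid_fixture <- function(n_genes = 30, geometry = c("orthogonal", "shifted", "correlated"),
                                  name = "fixture") {
  geometry <- match.arg(geometry)
  subtypes <- c("luminal_A", "luminal_B", "HER2", "normal_like", "basal")
  set.seed(match(geometry, c("orthogonal", "shifted", "correlated")) * 100 + n_genes)
  tab <- switch(geometry,
    orthogonal = {
      m <- matrix(0, n_genes, 5)
      blk <- split(1:n_genes, cut(1:n_genes, 5, labels = FALSE))
      for (k in 1:5) m[blk[[k]], k] <- 3
      m + matrix(rnorm(n_genes * 5, sd = 0.3), n_genes)
    },
    shifted = {
      base <- rnorm(n_genes)
      sapply(1:5, function(k) base + rnorm(n_genes, mean = 0, sd = 1.5))
    },
    correlated = {
      core <- rnorm(n_genes)
      sapply(1:5, function(k) 0.5 * core + rnorm(n_genes, sd = 1.2))
    })
  rownames(tab) <- sprintf("g%03d", 1:n_genes)
  colnames(tab) <- subtypes
  centroid_model(tab, paste0(name, "_", geometry))
}

# Random strictly increasing transform used for the monotone-invariance
# properties.
random_monotone <- function() {
  a <- runif(1, 0.2, 3); b <- runif(1, -5, 5); c <- runif(1, 0.05, 0.5)
  function(x) a * x + b + c * x^3 + 0.5 * atan(x)
}
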